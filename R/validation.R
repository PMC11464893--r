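#' Rank cross-validation of a selection surface
#'
#' Bins the availability predictions into ranked, (near) equal-area
#' bins, computes each bin's expected share of use as its share of the
#' total selection weight (area-adjusted because the bins have equal
#' area), and compares the observed counts of withheld test points per
#' bin: Spearman rank correlation between observed counts and bin rank,
#' and the R-squared and slope of observed on expected counts. A
#' well-calibrated model gives high rank correlation and a slope near 1;
#' a model with no information gives a slope near 0. Being rank-based on
#' equal-area bins, the diagnostic is invariant to strictly monotone
#' transforms of the prediction surface.
#'
#' @param pred_test RSF predictions (w or any monotone transform) at the
#'   withheld test points.
#' @param pred_ref predictions over the availability reference (map
#'   pixels or available points).
#' @param bins number of ranked bins (default 10).
#' @return list: \code{rho}, \code{r2}, \code{slope}, \code{table}
#'   (bin, expected, observed).
#' @export
rsf_cross_validate <- function(pred_test, pred_ref, bins = 10) {
  br <- unique(stats::quantile(pred_ref, seq(0, 1, length.out = bins + 1),
                               names = FALSE))
  if (length(br) < 3) stop("fewer than 2 non-empty bins; surface too flat")
  if (length(br) < bins + 1) {
    warning("collapsing tied bin boundaries: ", bins + 1 - length(br),
            " bin(s) merged")
  }
  br[1] <- -Inf; br[length(br)] <- Inf
  ref_bin <- cut(pred_ref, br, labels = FALSE)
  test_bin <- cut(pred_test, br, labels = FALSE)
  k <- length(br) - 1
  wsum <- vapply(seq_len(k), function(j) sum(pred_ref[ref_bin == j]),
                 numeric(1))
  expected <- length(pred_test) * wsum / sum(wsum)
  observed <- tabulate(test_bin, nbins = k)
  fit <- stats::lm(observed ~ expected)
  list(rho = stats::cor(observed, seq_len(k), method = "spearman"),
       r2 = summary(fit)$r.squared,
       slope = unname(stats::coef(fit)[2]),
       table = data.frame(bin = seq_len(k), expected = expected,
                          observed = observed))
}

#' Used-habitat calibration envelopes
#'
#' For each covariate, uses the fitted RSF to generate the predictive
#' distribution of used habitat: per posterior draw, availability rows
#' are resampled with weight exp(X beta_draw) and the covariate's
#' density is evaluated on a fixed grid. The pointwise envelope across
#' draws is compared with the observed density at the withheld test
#' points; a well-specified model should contain the observed curve
#' almost everywhere.
#'
#' @param fit an RSF \code{ss_fit}.
#' @param avail availability rows with the model's covariate columns on
#'   the fitted (standardised) scale.
#' @param test withheld used points with the same columns.
#' @param covariates columns to calibrate (default: the model's habitat
#'   covariates).
#' @param n_draws posterior draws used (>= 100).
#' @param level envelope mass (default 0.95).
#' @param n_grid density evaluation points.
#' @param seed RNG seed.
#' @return list: \code{coverage} (named fraction of grid points where
#'   the observed density lies inside the envelope) and
#'   \code{envelopes} (per-covariate data.frame x, lo, hi, obs).
#' @export
uhc_envelope <- function(fit, avail, test, covariates = fit$covariates,
                         n_draws = 200, level = 0.95, n_grid = 100,
                         seed = 1) {
  if (!is.null(seed)) set.seed(seed)
  M <- draw_matrix(fit)
  if (nrow(M) < 100) stop("need at least 100 posterior draws")
  use <- M[sample.int(nrow(M), min(n_draws, nrow(M))), , drop = FALSE]
  B <- use[, fit$covariates, drop = FALSE]
  Xa <- as.matrix(avail[, fit$covariates, drop = FALSE])
  lw <- Xa %*% t(B) # n_avail x n_draws log-weights
  n_sim <- nrow(test)
  a <- (1 - level) / 2
  coverage <- numeric(0)
  envelopes <- list()
  for (cv in covariates) {
    xa <- avail[[cv]]; xt <- test[[cv]]
    if (stats::sd(xt) == 0 || stats::sd(xa) == 0) {
      warning("degenerate covariate skipped in calibration: ", cv)
      next
    }
    rng <- range(c(xa, xt))
    dens <- matrix(NA_real_, n_grid, ncol(lw))
    for (s in seq_len(ncol(lw))) {
      w <- exp(lw[, s] - max(lw[, s]))
      pick <- sample.int(nrow(avail), n_sim, replace = TRUE, prob = w)
      dens[, s] <- stats::density(xa[pick], from = rng[1], to = rng[2],
                                  n = n_grid)$y
    }
    lo <- apply(dens, 1, stats::quantile, probs = a)
    hi <- apply(dens, 1, stats::quantile, probs = 1 - a)
    dob <- stats::density(xt, from = rng[1], to = rng[2], n = n_grid)
    coverage[cv] <- mean(dob$y >= lo & dob$y <= hi)
    envelopes[[cv]] <- data.frame(x = dob$x, lo = lo, hi = hi, obs = dob$y)
  }
  list(coverage = coverage, envelopes = envelopes)
}

#' Interval-censored survival curve from an encounter history
#'
#' Product-limit estimate on the check-day grid: at each distinct exit
#' day, survival is multiplied by (intervals at risk - failures) /
#' intervals at risk.
#'
#' @param eh encounter history (columns \code{exit}, \code{y}).
#' @return data.frame: \code{day}, \code{surv}.
#' @export
km_exposure <- function(eh) {
  days <- sort(unique(eh$exit))
  s <- 1
  out <- numeric(length(days))
  for (i in seq_along(days)) {
    at <- eh$exit == days[i]
    r <- sum(at)
    f <- sum(at & eh$y == 0)
    if (r > 0) s <- s * (r - f) / r
    out[i] <- s
  }
  data.frame(day = days, surv = out)
}

#' Posterior predictive check of a survival model
#'
#' For each posterior draw, simulates fates for the withheld units over
#' their observed exposure structure, computes the survival curve of the
#' replicate and of the observed data, and measures each one's maximum
#' absolute distance from the draw's model-implied curve. The predictive
#' p-value is the share of draws whose replicate discrepancy is at least
#' the observed discrepancy; values near 0 or 1 indicate poor fit.
#'
#' @param fit a survival \code{ss_fit}.
#' @param test withheld encounter history (columns \code{unit},
#'   \code{entry}, \code{exit}, \code{t}, \code{y} and the model's
#'   covariates).
#' @param n_draws posterior draws used.
#' @param seed RNG seed.
#' @return list: \code{p_value}, \code{observed_curve},
#'   \code{discrepancy} (data.frame obs, rep per draw).
#' @export
survival_ppc <- function(fit, test, n_draws = 500, seed = 1) {
  stopifnot(fit$kind == "survival")
  if (!nrow(test)) stop("empty testing encounter history")
  if (sum(test$t) <= 0) stop("testing data carry zero exposure")
  if (!is.null(seed)) set.seed(seed)
  M <- draw_matrix(fit)
  use <- M[sample.int(nrow(M), min(n_draws, nrow(M))), , drop = FALSE]
  X <- if (length(fit$covariates)) {
    as.matrix(test[, fit$covariates, drop = FALSE])
  } else {
    matrix(0, nrow(test), 0)
  }
  ord <- order(test$unit, test$entry)
  test <- test[ord, , drop = FALSE]
  X <- X[ord, , drop = FALSE]
  unit_f <- factor(test$unit)
  unit_rows <- split(seq_len(nrow(test)), unit_f)
  days <- sort(unique(test$exit))
  # per-unit exposure endpoint for the model-implied curve
  obs_curve <- km_exposure(test)

  d_obs <- numeric(nrow(use)); d_rep <- numeric(nrow(use))
  for (s in seq_len(nrow(use))) {
    lp <- use[s, "intercept"] +
      if (ncol(X)) drop(X %*% use[s, fit$covariates]) else rep(0, nrow(test))
    ds <- stats::plogis(lp)
    # model-implied marginal curve: mean over units of DS^day, using
    # each unit's first-interval daily survival as its hazard level
    ds_unit <- vapply(unit_rows, function(r) ds[r[1]], numeric(1))
    s_mod <- vapply(days, function(d) mean(ds_unit^d), numeric(1))
    # replicate fates over the observed interval structure
    yrep <- integer(nrow(test))
    for (r in unit_rows) {
      alive <- TRUE
      for (i in r) {
        if (alive && stats::runif(1) < ds[i]^test$t[i]) {
          yrep[i] <- 1L
        } else if (alive) {
          yrep[i] <- 0L
          alive <- FALSE
        } else {
          yrep[i] <- NA_integer_ # beyond replicate failure
        }
      }
    }
    rep_eh <- data.frame(exit = test$exit, y = yrep)
    rep_eh <- rep_eh[!is.na(rep_eh$y), , drop = FALSE]
    s_rep <- km_exposure(rep_eh)
    s_rep <- s_rep$surv[match(days, s_rep$day)]
    s_rep[is.na(s_rep)] <- 1
    s_obs <- obs_curve$surv[match(days, obs_curve$day)]
    d_obs[s] <- max(abs(s_obs - s_mod))
    d_rep[s] <- max(abs(s_rep - s_mod))
  }
  list(p_value = mean(d_rep >= d_obs),
       observed_curve = obs_curve,
       discrepancy = data.frame(obs = d_obs, rep = d_rep))
}
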