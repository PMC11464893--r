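#' MCMC settings
#'
#' Defaults follow the study protocol: 3 independent chains of 30,000
#' iterations, the first 20,000 discarded as burn-in, thinned by 5.
#' Synthetic checks use shorter runs via these arguments.
#'
#' @param n_iter total iterations per chain.
#' @param n_burnin iterations discarded.
#' @param thin thinning factor.
#' @param n_chains number of chains.
#' @param n_adapt JAGS adaptation steps (in addition to burn-in).
#' @return an \code{mcmc_control} list.
#' @export
mcmc_control <- function(n_iter = 30000, n_burnin = 20000, thin = 5,
                         n_chains = 3, n_adapt = 1000) {
  stopifnot(n_iter > n_burnin, thin >= 1, n_chains >= 1)
  list(n_iter = n_iter, n_burnin = n_burnin, thin = thin,
       n_chains = n_chains, n_adapt = n_adapt)
}

# Assemble the JAGS model string for either likelihood.
# kind "rsf": y[i] ~ dbern(p), logit(p) = b0 + Xb + intercepts
# kind "survival": y[i] ~ dbern(ds^t), logit(ds) = g0 + Xb + intercepts
build_jags_model <- function(kind, has_fixed, n_groups, random,
                             lambda_fixed = FALSE) {
  lp <- c("b0")
  if (has_fixed) lp <- c(lp, "inprod(Xf[i,], bf)")
  if (n_groups > 0) lp <- c(lp, "sum(xb[i,])")
  for (f in random) lp <- c(lp, sprintf("re_%s[%s[i]]", f, f))
  lp <- paste(lp, collapse = " + ")

  lik <- if (kind == "rsf") {
    c(sprintf("    logit(p[i]) <- %s", lp),
      "    y[i] ~ dbern(p[i])")
  } else {
    c(sprintf("    logit(ds[i]) <- %s", lp),
      "    theta[i] <- pow(ds[i], tt[i])",
      "    y[i] ~ dbern(theta[i])")
  }
  body <- c("model {", "  for (i in 1:n) {")
  if (n_groups > 0) {
    body <- c(body,
      "    for (g in 1:G) { xb[i,g] <- bg[g] * Xg[i,g,z[g]] }")
  }
  body <- c(body, lik, "  }")
  if (n_groups > 0) {
    body <- c(body,
      "  for (g in 1:G) {",
      "    z[g] ~ dcat(pz[g,1:Kmax])",
      "    bg[g] ~ ddexp(0, lambda)",
      "  }")
  }
  if (has_fixed) {
    body <- c(body, "  for (j in 1:J) { bf[j] ~ ddexp(0, lambda) }")
  }
  if ((has_fixed || n_groups > 0) && !lambda_fixed) {
    body <- c(body, "  lambda ~ dunif(0.001, 10)")
  }
  for (f in random) {
    body <- c(body,
      sprintf("  for (k in 1:n_%s) { re_%s[k] ~ dnorm(0, tau_%s) }", f, f, f),
      sprintf("  tau_%s <- 1 / sig2_%s", f, f),
      sprintf("  sig2_%s ~ dunif(0, 100)", f))
  }
  body <- c(body, "  b0 ~ dnorm(0, 0.001)", "}")
  paste(body, collapse = "\n")
}

#' Fit a hierarchical Bayesian selection or survival model
#'
#' Both model families share one MCMC engine (JAGS). The used/available
#' (RSF) likelihood is Bernoulli with a logit link on the use indicator;
#' the exposure-time survival likelihood is Bernoulli with success
#' probability equal to daily survival raised to the interval length, so
#' intervals of unequal length contribute correctly. Habitat coefficients
#' carry Laplace (Lasso) shrinkage priors with a shared tuning parameter
#' lambda ~ Uniform(0.001, 10); random intercepts are normal with a
#' Uniform(0, 100) prior on their variance; the baseline intercept has a
#' vague normal prior. When \code{groups} is supplied, a latent
#' categorical indicator per group picks which candidate variable-scale
#' column enters the linear predictor at each iteration (latent-indicator
#' scale selection), giving posterior frequencies for each candidate
#' scale without collinearity among scales.
#'
#' @param data design table (RSF) or encounter history (survival); both
#'   outcome classes must be present.
#' @param kind "rsf" or "survival".
#' @param covariates columns entering with individual Laplace
#'   coefficients (the final-model pathway).
#' @param groups named list, group -> candidate column names, for scale
#'   selection; each group gets one coefficient plus a scale indicator.
#' @param confounders columns (e.g. decayed distance to lek or nest)
#'   with Laplace coefficients, exempt from scale-selection groups.
#' @param random random-intercept factors: subset of
#'   \code{c("site", "year", "animal")} for RSF, \code{c("site",
#'   "year")} for survival.
#' @param response response column ("used" for RSF designs, "y" for
#'   encounter histories).
#' @param t_col interval-length column (survival only).
#' @param control \code{\link{mcmc_control}} settings.
#' @param seed integer seed; chain RNGs derive from it.
#' @param lambda optional fixed value for the Laplace tuning parameter;
#'   by default lambda gets its Uniform(0.001, 10) hyperprior.
#' @param quiet suppress JAGS progress output.
#' @return an \code{ss_fit}: renamed \code{coda::mcmc.list} draws plus
#'   metadata.
#' @export
fit_model <- function(data, kind = c("rsf", "survival"),
                      covariates = character(), groups = NULL,
                      confounders = character(), random = character(),
                      response = if (kind == "rsf") "used" else "y",
                      t_col = "t", control = mcmc_control(), seed = 1,
                      lambda = NULL, quiet = TRUE) {
  kind <- match.arg(kind)
  if (kind == "survival" && "animal" %in% random) {
    stop("survival models admit site and year intercepts only")
  }
  y <- data[[response]]
  if (is.null(y)) stop("response column not found: ", response)
  if (length(unique(y[!is.na(y)])) < 2) {
    stop("degenerate data: both outcome classes must be present")
  }
  fixed <- c(covariates, confounders)
  if (anyDuplicated(fixed)) stop("duplicated fixed-effect columns")

  jd <- list(n = nrow(data), y = as.numeric(y))
  if (kind == "survival") jd$tt <- as.numeric(data[[t_col]])
  if (length(fixed)) {
    jd$Xf <- as.matrix(data[, fixed, drop = FALSE])
    jd$J <- length(fixed)
  }
  grp_names <- names(groups)
  if (length(groups)) {
    cand <- unlist(groups)
    if (anyDuplicated(cand)) stop("duplicated candidate columns in groups")
    K <- vapply(groups, length, integer(1))
    Kmax <- max(K)
    Xg <- array(0, dim = c(nrow(data), length(groups), Kmax))
    pz <- matrix(0, length(groups), Kmax)
    for (g in seq_along(groups)) {
      for (k in seq_len(K[g])) Xg[, g, k] <- data[[groups[[g]][k]]]
      pz[g, seq_len(K[g])] <- 1 / K[g]
    }
    jd$Xg <- Xg; jd$G <- length(groups); jd$Kmax <- Kmax; jd$pz <- pz
  }
  for (f in random) {
    if (!f %in% names(data)) stop("missing grouping column: ", f)
    idx <- as.integer(factor(data[[f]]))
    jd[[f]] <- idx
    jd[[paste0("n_", f)]] <- max(idx)
  }

  if (!is.null(lambda)) jd$lambda <- lambda
  model_str <- build_jags_model(kind, length(fixed) > 0, length(groups),
                                random, lambda_fixed = !is.null(lambda))
  inits <- lapply(seq_len(control$n_chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (as.numeric(seed) * 97 + ch * 7919) %%
           .Machine$integer.max)
  })
  monitors <- "b0"
  if (length(fixed)) monitors <- c(monitors, "bf")
  if (length(groups)) monitors <- c(monitors, "bg", "z")
  if ((length(fixed) || length(groups)) && is.null(lambda)) {
    monitors <- c(monitors, "lambda")
  }
  if (length(random)) monitors <- c(monitors, paste0("sig2_", random))

  run <- function() {
    jm <- rjags::jags.model(textConnection(model_str), data = jd,
                            inits = inits, n.chains = control$n_chains,
                            n.adapt = control$n_adapt, quiet = quiet)
    if (control$n_burnin > 0) {
      stats::update(jm, control$n_burnin,
                    progress.bar = if (quiet) "none" else "text")
    }
    rjags::coda.samples(jm, monitors,
                        n.iter = control$n_iter - control$n_burnin,
                        thin = control$thin,
                        progress.bar = if (quiet) "none" else "text")
  }
  draws <- NULL
  for (attempt in 1:3) {
    draws <- tryCatch(run(), error = function(e) e)
    if (!inherits(draws, "error")) break
    inits <- lapply(inits, function(i) {
      i$.RNG.seed <- (i$.RNG.seed + 104729) %% .Machine$integer.max
      i
    })
  }
  if (inherits(draws, "error")) {
    stop("MCMC initialization failed after 3 attempts: ",
         conditionMessage(draws))
  }

  # rename parameters to their covariate / group names
  rename <- function(nm) {
    nm <- sub("^b0$", "intercept", nm)
    for (j in seq_along(fixed)) {
      nm[nm == sprintf("bf[%d]", j)] <- fixed[j]
    }
    for (g in seq_along(grp_names)) {
      nm[nm == sprintf("bg[%d]", g)] <- grp_names[g]
      nm[nm == sprintf("z[%d]", g)] <- paste0("z_", grp_names[g])
    }
    nm
  }
  # single-parameter edge cases: JAGS drops the index bracket
  for (ch in seq_along(draws)) {
    cn <- colnames(draws[[ch]])
    if (length(fixed) == 1) cn[cn == "bf"] <- fixed
    if (length(grp_names) == 1) {
      cn[cn == "bg"] <- grp_names
      cn[cn == "z"] <- paste0("z_", grp_names)
    }
    colnames(draws[[ch]]) <- rename(cn)
  }

  structure(list(draws = draws, kind = kind, covariates = covariates,
                 groups = groups, confounders = confounders,
                 random = random, response = response, control = control,
                 seed = seed, n = nrow(data)),
            class = "ss_fit")
}

#' @export
print.ss_fit <- function(x, ...) {
  cat(sprintf("<ss_fit> %s model, n = %d rows, %d chains x %d retained\n",
              x$kind, x$n, length(x$draws), nrow(x$draws[[1]])))
  if (length(x$groups)) {
    cat("  scale-selection groups:", paste(names(x$groups), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Pooled posterior draws as a matrix
#' @param fit an \code{ss_fit} (or \code{coda::mcmc.list}).
#' @return numeric matrix, draws x parameters.
#' @export
draw_matrix <- function(fit) {
  d <- if (inherits(fit, "ss_fit")) fit$draws else fit
  as.matrix(d)
}

#' Latent-indicator scale selection across covariate groups
#'
#' Fits the scale-selection model and summarises, for every group, the
#' posterior frequency with which each candidate variable-scale column
#' was the one in the linear predictor, plus the modal winner. Ties are
#' broken toward the smallest radius (candidates are ordered by the
#' radius parsed from a \code{_r<radius>} suffix when present, else by
#' their given order).
#'
#' @inheritParams fit_model
#' @param ... passed to \code{\link{fit_model}}.
#' @return list: \code{frequencies} (data.frame group, candidate, freq),
#'   \code{winners} (named character), \code{fit} (the \code{ss_fit}).
#' @export
bliss_select <- function(data, groups, kind = "rsf", ..., control =
                         mcmc_control(), seed = 1) {
  if (any(vapply(groups, length, integer(1)) < 1)) {
    stop("every group needs at least one candidate column")
  }
  ord_groups <- lapply(groups, function(cand) {
    rad <- suppressWarnings(
      as.numeric(sub(".*_r([0-9.]+)$", "\\1", cand)))
    if (any(is.na(rad))) cand else cand[order(rad)]
  })
  fit <- fit_model(data, kind = kind, groups = ord_groups, ...,
                   control = control, seed = seed)
  M <- draw_matrix(fit)
  freq <- do.call(rbind, lapply(names(ord_groups), function(g) {
    cand <- ord_groups[[g]]
    zc <- M[, paste0("z_", g)]
    data.frame(group = g, candidate = cand,
               freq = vapply(seq_along(cand),
                             function(k) mean(zc == k), numeric(1)))
  }))
  winners <- vapply(split(freq, freq$group), function(fg) {
    fg$candidate[which.max(fg$freq)] # first max = smallest radius on ties
  }, character(1))
  winners <- winners[names(ord_groups)]
  list(frequencies = freq, winners = winners, fit = fit)
}

#' Gelman-Rubin convergence diagnostic
#'
#' Potential scale reduction factor per monitored continuous parameter
#' (discrete scale indicators are excluded); values below 1.1 indicate
#' adequate mixing. Parameters constant across all chains are reported
#' as exactly 1.
#'
#' @param fit an \code{ss_fit} or \code{coda::mcmc.list} with at least
#'   two chains.
#' @return named numeric vector of point estimates.
#' @export
gelman_rubin <- function(fit) {
  d <- if (inherits(fit, "ss_fit")) fit$draws else fit
  if (!inherits(d, "mcmc.list")) d <- coda::as.mcmc.list(d)
  if (length(d) < 2) stop("need at least 2 chains for Gelman-Rubin")
  if (nrow(d[[1]]) < 10) stop("need at least 10 retained draws per chain")
  keep <- !grepl("^z_", colnames(d[[1]]))
  d <- d[, keep, drop = FALSE]
  pooled <- do.call(rbind, lapply(d, as.matrix))
  vr <- apply(pooled, 2, stats::var)
  out <- rep(1, length(vr))
  names(out) <- colnames(pooled)
  varying <- which(vr > 0)
  if (length(varying)) {
    gd <- coda::gelman.diag(d[, varying, drop = FALSE],
                            autoburnin = FALSE, multivariate = FALSE)
    psrf <- gd$psrf[, "Point est."]
    # chains identical for a parameter: no between-chain variance, so
    # the scale reduction is 1 by definition (coda yields NaN there)
    if (any(!is.finite(psrf))) {
      mats <- lapply(d, as.matrix)
      for (k in which(!is.finite(psrf))) {
        mns <- vapply(mats, function(m) mean(m[, varying[k]]), numeric(1))
        if (stats::var(mns) < 1e-12) psrf[k] <- 1
      }
    }
    out[varying] <- psrf
  }
  out
}

#' Rebuild a fit object from a long-format draws CSV
#'
#' Inverse of \code{\link{write_draws}}: reconstructs the
#' \code{coda::mcmc.list} and enough metadata for the summary,
#' validation and mapping functions to run in a later session.
#'
#' @param path CSV written by \code{\link{write_draws}}.
#' @param kind "rsf" or "survival".
#' @param covariates,confounders,random metadata of the original fit.
#' @return an \code{ss_fit}.
#' @export
read_draws <- function(path, kind = "rsf", covariates = character(),
                       confounders = character(), random = character()) {
  long <- utils::read.csv(path)
  pars <- unique(long$parameter)
  chains <- lapply(split(long, long$chain), function(ch) {
    m <- vapply(pars, function(p) ch$value[ch$parameter == p],
                numeric(sum(ch$parameter == pars[1])))
    colnames(m) <- pars
    coda::mcmc(m)
  })
  structure(list(draws = coda::as.mcmc.list(unname(chains)), kind = kind,
                 covariates = covariates, groups = NULL,
                 confounders = confounders, random = random,
                 control = NULL, seed = NA, n = NA),
            class = "ss_fit")
}

#' Write posterior draws to long-format CSV
#'
#' @param fit an \code{ss_fit}.
#' @param path output file.
#' @export
write_draws <- function(fit, path) {
  long <- do.call(rbind, lapply(seq_along(fit$draws), function(ch) {
    m <- as.matrix(fit$draws[[ch]])
    data.frame(chain = ch, iteration = rep(seq_len(nrow(m)), ncol(m)),
               parameter = rep(colnames(m), each = nrow(m)),
               value = as.vector(m))
  }))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
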