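#' Relative selection strength
#'
#' exp(beta) per posterior draw for a covariate on the standardised
#' scale: the relative selection intensity of two locations that differ
#' by one covariate SD and are equally available. RSS > 1 is selection,
#' RSS < 1 avoidance.
#'
#' @param fit an \code{ss_fit}.
#' @param covariate covariate name(s); default: every habitat covariate
#'   in the final model.
#' @param level credible-interval mass (default 0.95; the companion
#'   figures use 0.85).
#' @return data.frame: covariate, rss median, lower, upper.
#' @export
rss <- function(fit, covariate = NULL,
                level = 0.95) {
  M <- draw_matrix(fit)
  if (is.null(covariate)) covariate <- fit$covariates
  bad <- setdiff(covariate, colnames(M))
  if (length(bad)) stop("unknown covariate(s): ", paste(bad, collapse = ", "))
  a <- (1 - level) / 2
  out <- lapply(covariate, function(cv) {
    r <- exp(M[, cv])
    data.frame(covariate = cv, rss = stats::median(r),
               lower = stats::quantile(r, a, names = FALSE),
               upper = stats::quantile(r, 1 - a, names = FALSE))
  })
  do.call(rbind, out)
}

#' Probability of direction
#'
#' The posterior probability that a coefficient is strictly on its
#' dominant side of zero: max(P(beta > 0), P(beta < 0)), in [0.5, 1].
#' Values of at least 0.85 flag a moderate effect and at least 0.95 a
#' strong one.
#'
#' @param draws numeric vector of posterior draws (>= 100), or an
#'   \code{ss_fit} together with \code{parameter}.
#' @param parameter parameter name when \code{draws} is a fit.
#' @return list: \code{pd}, \code{effect} ("none", "moderate", "strong").
#' @export
probability_of_direction <- function(draws, parameter = NULL) {
  if (inherits(draws, "ss_fit")) {
    stopifnot(!is.null(parameter))
    draws <- draw_matrix(draws)[, parameter]
  }
  if (length(draws) < 100) stop("need at least 100 draws")
  pd <- max(mean(draws > 0), mean(draws < 0))
  list(pd = pd,
       effect = if (pd >= 0.95) "strong" else if (pd >= 0.85) "moderate"
                else "none")
}

#' Cumulative survival over a period
#'
#' Daily survival raised to the number of days in the period (38 for
#' nesting, 21 for early and 28 for late brood rearing).
#'
#' @param ds daily survival in (0, 1]: scalar, vector or
#'   \code{grid_raster}.
#' @param days period length (positive integer).
#' @return same shape as \code{ds}.
#' @export
cumulative_survival <- function(ds, days) {
  if (!is.numeric(days) || length(days) != 1L || days <= 0) {
    stop("days must be a positive number")
  }
  if (inherits(ds, "grid_raster")) {
    return(grid_raster(ds$values^days, ds$xmin, ds$ymin, ds$res))
  }
  ds^days
}

#' Posterior summary table for a fitted model
#'
#' Median, credible interval and probability of direction per continuous
#' parameter, with RSS attached for habitat covariates of RSF fits.
#'
#' @param fit an \code{ss_fit}.
#' @param level credible-interval mass.
#' @return data.frame.
#' @export
fit_summary <- function(fit, level = 0.95) {
  M <- draw_matrix(fit)
  keep <- !grepl("^z_", colnames(M))
  a <- (1 - level) / 2
  out <- do.call(rbind, lapply(colnames(M)[keep], function(p) {
    v <- M[, p]
    pd <- if (stats::var(v) > 0) max(mean(v > 0), mean(v < 0)) else 1
    data.frame(parameter = p, median = stats::median(v),
               lower = stats::quantile(v, a, names = FALSE),
               upper = stats::quantile(v, 1 - a, names = FALSE), pd = pd)
  }))
  if (fit$kind == "rsf" && length(fit$covariates)) {
    out$rss <- ifelse(out$parameter %in% fit$covariates,
                      exp(out$median), NA_real_)
  }
  rownames(out) <- NULL
  out
}

#' Posterior-median daily survival of an intercept-only survival fit
#'
#' @param fit a survival \code{ss_fit}.
#' @return logit^-1 of the posterior-median intercept.
#' @export
median_daily_survival <- function(fit) {
  stopifnot(fit$kind == "survival")
  stats::plogis(stats::median(draw_matrix(fit)[, "intercept"]))
}
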