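#' Candidate moving-window radii (m)
#'
#' The spatial scales at which land-cover covariates are summarised:
#' minimum, mean and maximum daily movement distances (167.9, 439.5,
#' 1451.7 m), the core nesting recess area (75 m), the mean nesting
#' recess / early-brood movement distance (260 m) and the median
#' late-brood movement distance (370 m).
#'
#' @export
CANDIDATE_RADII <- c(75, 167.9, 260, 370, 439.5, 1451.7)

#' Describe one habitat covariate
#'
#' @param name covariate (band) name.
#' @param group one of the 12 covariate groups used to structure scale
#'   selection; variables within a group compete, variables across groups
#'   do not.
#' @param kind "proportion", "height", "distance" or "topographic".
#'   Proportion/height kinds are summarised with moving windows at the
#'   candidate radii; distance kinds are decay-transformed instead.
#' @param radii candidate moving-window radii (m); must be a subset of
#'   \code{\link{CANDIDATE_RADII}}.
#' @param temporal does the band vary by year?
#' @return a \code{covariate_spec} list.
#' @export
covariate_spec <- function(name, group, kind = c("proportion", "height",
                           "distance", "topographic"),
                           radii = numeric(), temporal = FALSE) {
  kind <- match.arg(kind)
  if (length(radii) && !all(radii %in% CANDIDATE_RADII)) {
    stop("radii must be a subset of CANDIDATE_RADII: ",
         paste(setdiff(radii, CANDIDATE_RADII), collapse = ", "))
  }
  structure(list(name = name, group = group, kind = kind,
                 radii = sort(radii), temporal = temporal),
            class = "covariate_spec")
}

# 2-D linear convolution by FFT; 'kern' is a (2k+1)x(2k+1) 0/1 mask.
# Zero-padded, so edges see only in-grid pixels; returns the central
# (same-size) part of the full convolution.
conv2_fft <- function(a, kern) {
  na <- dim(a); nk <- dim(kern)
  np <- na + nk - 1
  pa <- matrix(0, np[1], np[2]); pa[seq_len(na[1]), seq_len(na[2])] <- a
  pk <- matrix(0, np[1], np[2]); pk[seq_len(nk[1]), seq_len(nk[2])] <- kern
  full <- Re(stats::fft(stats::fft(pa) * stats::fft(pk), inverse = TRUE)) /
    prod(np)
  k <- (nk - 1) / 2
  full[k[1] + seq_len(na[1]), k[2] + seq_len(na[2])]
}

# Circular 0/1 window mask: pixel centres within 'radius' metres of the
# focal pixel centre (membership is metric, not pixel-count, so the
# fractional radii behave as intended on a 30 m grid).
window_mask <- function(radius, res) {
  k <- floor(radius / res)
  off <- seq(-k, k)
  d2 <- outer(off^2, off^2, "+") * res^2
  (d2 <= radius^2) * 1
}

#' Moving-window proportion / density of a raster band
#'
#' Mean of the band over a circular window of the given metric radius
#' centred on each pixel. For 0/1 feature bands the mean is the feature
#' proportion (equivalently density per unit area up to the constant
#' pixel area). Edge pixels are normalised by the number of valid
#' in-window pixels; windows with no valid pixel return NA.
#'
#' @param r a \code{grid_raster}.
#' @param radius window radius (m); must be at least the pixel size.
#' @return a \code{grid_raster} of window means.
#' @export
focal_proportion <- function(r, radius) {
  stopifnot(inherits(r, "grid_raster"))
  if (radius < r$res) {
    stop(sprintf("radius (%g m) must be >= pixel size (%g m)", radius, r$res))
  }
  d <- dim(r$values)
  k <- floor(radius / r$res)
  if (2 * k + 1 > min(d)) {
    stop(sprintf(
      "grid (%d x %d px) too small for moving-window radius %g m (%d px)",
      d[1], d[2], radius, k))
  }
  kern <- window_mask(radius, r$res)
  v <- r$values
  valid <- is.finite(v) * 1
  v[!is.finite(v)] <- 0
  num <- conv2_fft(v, kern)
  den <- conv2_fft(valid, kern)
  out <- num / den
  out[den < 0.5] <- NA_real_
  grid_raster(out, r$xmin, r$ymin, r$res)
}

#' Exponential decay transform of distances
#'
#' Maps a distance d (m) to exp(-d/alpha), so a predictor's influence
#' decays smoothly with distance: 1 at the feature, exp(-1) at d = alpha.
#' By convention alpha is the mean raw distance over the rows of the
#' analysis at hand, so it is estimated per life stage, not from the map.
#'
#' @param d distances (vector, matrix or \code{grid_raster}), >= 0.
#' @param alpha decay scale (m), > 0.
#' @return same shape as \code{d}, values in (0, 1].
#' @export
decay_distance <- function(d, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0) {
    stop("alpha must be a single positive number")
  }
  if (inherits(d, "grid_raster")) {
    return(grid_raster(exp(-d$values / alpha), d$xmin, d$ymin, d$res))
  }
  exp(-d / alpha)
}

#' Centre and scale covariate columns
#'
#' Standardises each named column to mean 0, SD 1 over the fitting rows
#' using the population (divide-by-n) SD. The returned parameters must be
#' reused verbatim for any prediction (map) data so that model
#' coefficients keep their per-SD interpretation.
#'
#' @param df data.frame.
#' @param cols columns to standardise (default: all numeric columns).
#' @return list with \code{table} (standardised data.frame) and
#'   \code{params} (data.frame: column, mean, sd).
#' @export
scale_and_center <- function(df, cols = NULL) {
  if (is.null(cols)) {
    cols <- names(df)[vapply(df, is.numeric, logical(1))]
  }
  mu <- vapply(df[cols], function(v) mean(v, na.rm = TRUE), numeric(1))
  sdv <- vapply(df[cols], function(v) {
    v <- v[!is.na(v)]
    sqrt(mean((v - mean(v))^2))
  }, numeric(1))
  bad <- cols[!is.finite(sdv) | sdv <= 0]
  if (length(bad)) {
    stop("zero-variance covariate column(s): ", paste(bad, collapse = ", "))
  }
  for (j in seq_along(cols)) {
    df[[cols[j]]] <- (df[[cols[j]]] - mu[j]) / sdv[j]
  }
  list(table = df,
       params = data.frame(column = cols, mean = unname(mu),
                           sd = unname(sdv), stringsAsFactors = FALSE))
}

#' Apply stored scaling parameters
#'
#' @param df data.frame (or \code{grid_raster} when \code{params} has a
#'   single row) to standardise with previously estimated parameters.
#' @param params the \code{params} element from
#'   \code{\link{scale_and_center}}.
#' @return standardised object of the same class.
#' @export
apply_scaling <- function(df, params) {
  if (inherits(df, "grid_raster")) {
    stopifnot(nrow(params) == 1L)
    return(grid_raster((df$values - params$mean) / params$sd,
                       df$xmin, df$ymin, df$res))
  }
  for (j in seq_len(nrow(params))) {
    cl <- params$column[j]
    if (!cl %in% names(df)) stop("missing column for scaling: ", cl)
    df[[cl]] <- (df[[cl]] - params$mean[j]) / params$sd[j]
  }
  df
}

#' Save / load scaling parameters as JSON
#' @param params,path see \code{\link{scale_and_center}}.
#' @export
write_scaling <- function(params, path) {
  jsonlite::write_json(params, path, dataframe = "rows", digits = NA)
  invisible(path)
}

#' @rdname write_scaling
#' @export
read_scaling <- function(path) {
  as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
}
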