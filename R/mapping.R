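#' Predict the habitat selection surface
#'
#' Applies posterior-median coefficients pixelwise: w = exp(X beta) with
#' no intercept, no random effects and no movement confounders (distance
#' to lek/nest is deliberately excluded so the map reflects underlying
#' habitat, not current occupancy), then the bounded habitat selection
#' index HSI = w / (1 + w) in (0, 1). Covariate rasters are
#' decay-transformed (distance covariates) and standardised with the
#' scaling parameters estimated from the fitting data, never from the
#' map.
#'
#' @param fit an RSF \code{ss_fit}.
#' @param stack a \code{landscape_stack} holding one band per model
#'   covariate (focal bands as \code{<name>_r<radius>}).
#' @param scaling \code{params} from \code{\link{scale_and_center}} on
#'   the fitting rows.
#' @param alphas named decay scales (m) for raw-distance bands.
#' @param year year used for temporal bands.
#' @return a \code{selection_surface}: list with \code{hsi} and \code{w}
#'   \code{grid_raster}s plus provenance.
#' @export
predict_selection <- function(fit, stack, scaling, alphas = NULL,
                              year = NULL) {
  stopifnot(fit$kind == "rsf")
  M <- draw_matrix(fit)
  lp <- matrix(0, stack$ny, stack$nx)
  for (nm in fit$covariates) {
    b <- covariate_raster(stack, nm, scaling, alphas, year)
    lp <- lp + stats::median(M[, nm]) * b$values
  }
  w <- exp(lp)
  structure(list(
    hsi = grid_raster(w / (1 + w), stack$xmin, stack$ymin, stack$res),
    w = grid_raster(w, stack$xmin, stack$ymin, stack$res),
    covariates = fit$covariates, year = year), class = "selection_surface")
}

# resolve, transform and standardise one model covariate as a raster
covariate_raster <- function(stack, nm, scaling, alphas = NULL,
                             year = NULL) {
  b <- tryCatch(stack_band(stack, nm, year), error = function(e) {
    stop("missing band for model covariate '", nm, "'",
         if (!is.null(year)) paste0(" (year ", year, ")"), call. = FALSE)
  })
  if (!is.null(alphas) && nm %in% names(alphas)) {
    b <- decay_distance(b, alphas[[nm]])
  }
  p <- scaling[scaling$column == nm, , drop = FALSE]
  if (nrow(p) != 1) stop("no scaling parameters for covariate ", nm)
  apply_scaling(b, p)
}

#' Predict daily and cumulative survival surfaces
#'
#' Pixelwise logit^-1(gamma0 + X beta) at posterior-median coefficients
#' (random intercepts at their zero mean), exponentiated over the
#' stage's exposure period to give cumulative survival.
#'
#' @inheritParams predict_selection
#' @param fit a survival \code{ss_fit}.
#' @param days exposure days (38 nesting, 21 early, 28 late brood).
#' @return a \code{survival_surface}: list with \code{ds} (daily) and
#'   \code{cumulative} \code{grid_raster}s and \code{days}.
#' @export
predict_survival <- function(fit, stack, scaling, days, alphas = NULL,
                             year = NULL) {
  stopifnot(fit$kind == "survival")
  M <- draw_matrix(fit)
  lp <- matrix(stats::median(M[, "intercept"]), stack$ny, stack$nx)
  for (nm in fit$covariates) {
    b <- covariate_raster(stack, nm, scaling, alphas, year)
    lp <- lp + stats::median(M[, nm]) * b$values
  }
  ds <- grid_raster(stats::plogis(lp), stack$xmin, stack$ymin, stack$res)
  structure(list(ds = ds, cumulative = cumulative_survival(ds, days),
                 days = days, year = year), class = "survival_surface")
}

#' Categorize a selection surface by the percent-isopleth method
#'
#' Thresholds are set so that the high class contains the top 5% of
#' used locations, moderate the next 20% (to the 25% isopleth), low the
#' next 25% (to the 50% isopleth) and nonhabitat everything below the
#' value enclosing half the used locations. Because the thresholds are
#' defined at used points, the categorization is equivariant to strictly
#' monotone transforms of the surface.
#'
#' @param surface a \code{selection_surface} or \code{grid_raster} of
#'   HSI values.
#' @param used_values HSI values at the used locations (>= 20).
#' @return a \code{categorized_surface}: integer raster with codes
#'   0 = nonhabitat, 1 = low, 2 = moderate, 3 = high, plus thresholds.
#' @export
categorize_selection <- function(surface, used_values) {
  r <- if (inherits(surface, "selection_surface")) surface$hsi else surface
  used_values <- used_values[!is.na(used_values)]
  if (length(used_values) < 20) stop("need at least 20 used locations")
  th <- stats::quantile(used_values, c(0.50, 0.75, 0.95), names = FALSE)
  if (any(diff(th) <= 0)) {
    stop(sprintf(
      paste0("non-monotone isopleth thresholds (50%%: %.6g, 25%%: %.6g, ",
             "5%%: %.6g); used-location values are too tied"),
      th[1], th[2], th[3]))
  }
  cls <- matrix(NA_integer_, nrow(r$values), ncol(r$values))
  v <- r$values
  cls[v < th[1]] <- 0L
  cls[v >= th[1] & v < th[2]] <- 1L
  cls[v >= th[2] & v < th[3]] <- 2L
  cls[v >= th[3]] <- 3L
  structure(list(
    raster = grid_raster(cls, r$xmin, r$ymin, r$res),
    thresholds = c(isopleth_50 = th[1], isopleth_25 = th[2],
                   isopleth_5 = th[3]),
    labels = c(`0` = "nonhabitat", `1` = "low", `2` = "moderate",
               `3` = "high"),
    kind = "selection"), class = "categorized_surface")
}

#' Categorize a survival surface from failed and successful points
#'
#' Boundaries come from the empirical distributions of predicted
#' survival at failed and successful units: very-low/low at the median
#' of the failed-point values, moderate/high at the median of the
#' successful-point values, and low/moderate at the midpoint of the two
#' medians. Intervals are half-open and lower-inclusive; ties at a
#' threshold fall to the lower class.
#'
#' @param surface a \code{survival_surface} or \code{grid_raster} of
#'   cumulative survival.
#' @param failed_values,success_values predicted survival at failed and
#'   successful units (both non-empty).
#' @return a \code{categorized_surface}: codes 1 = very low, 2 = low,
#'   3 = moderate, 4 = high (NA where the surface is NA / masked).
#' @export
categorize_survival <- function(surface, failed_values, success_values) {
  r <- if (inherits(surface, "survival_surface")) surface$cumulative
       else surface
  failed_values <- failed_values[!is.na(failed_values)]
  success_values <- success_values[!is.na(success_values)]
  if (!length(failed_values) || !length(success_values)) {
    stop("both failed and successful point sets must be non-empty")
  }
  b1 <- stats::median(failed_values)
  b3 <- stats::median(success_values)
  if (b1 == b3) warning("failed and successful distributions coincide")
  b2 <- (b1 + b3) / 2
  th <- c(b1, b2, b3)
  if (any(diff(th) <= 0)) {
    stop(sprintf(
      "non-monotone survival thresholds (%.6g, %.6g, %.6g)",
      th[1], th[2], th[3]))
  }
  v <- r$values
  cls <- matrix(NA_integer_, nrow(v), ncol(v))
  ok <- !is.na(v)
  cls[ok & v < th[1]] <- 1L
  cls[ok & v >= th[1] & v < th[2]] <- 2L
  cls[ok & v >= th[2] & v < th[3]] <- 3L
  cls[ok & v >= th[3]] <- 4L
  structure(list(
    raster = grid_raster(cls, r$xmin, r$ymin, r$res),
    thresholds = c(very_low_low = th[1], low_moderate = th[2],
                   moderate_high = th[3]),
    labels = c(`1` = "very low", `2` = "low", `3` = "moderate",
               `4` = "high"),
    kind = "survival"), class = "categorized_surface")
}

#' Composite selection index across life stages
#'
#' Each stage's HSI surface is relativised by its own maximum (equal
#' weighting of the stages) and the relativised surfaces are multiplied;
#' the composite has maximum exactly 1 and preserves the ranking of any
#' single stage when the stages agree.
#'
#' @param surfaces list of \code{selection_surface}s or HSI
#'   \code{grid_raster}s on the same grid.
#' @return a \code{grid_raster}.
#' @export
composite_selection <- function(surfaces) {
  rs <- lapply(surfaces, function(s) {
    if (inherits(s, "selection_surface")) s$hsi else s
  })
  d1 <- dim(rs[[1]]$values)
  out <- matrix(1, d1[1], d1[2])
  for (r in rs) {
    if (!identical(dim(r$values), d1) || r$res != rs[[1]]$res) {
      stop("selection surfaces are not on the same grid")
    }
    out <- out * r$values / max(r$values, na.rm = TRUE)
  }
  out <- out / max(out, na.rm = TRUE)
  grid_raster(out, rs[[1]]$xmin, rs[[1]]$ymin, rs[[1]]$res)
}

#' Composite survival index across life stages
#'
#' Product of the stage cumulative-survival surfaces (not relativised:
#' the values are true survival probabilities, so the product is
#' survival over the whole reproductive period), evaluated only in
#' pixels the composite selection categorization calls habitat.
#'
#' @param surfaces list of \code{survival_surface}s or cumulative
#'   \code{grid_raster}s.
#' @param habitat_mask a selection \code{categorized_surface} (or
#'   integer raster): pixels with class 0 (nonhabitat) or NA are masked.
#' @return a \code{grid_raster} with NA outside habitat.
#' @export
composite_survival <- function(surfaces, habitat_mask = NULL) {
  rs <- lapply(surfaces, function(s) {
    if (inherits(s, "survival_surface")) s$cumulative else s
  })
  d1 <- dim(rs[[1]]$values)
  out <- matrix(1, d1[1], d1[2])
  for (r in rs) {
    if (!identical(dim(r$values), d1)) {
      stop("survival surfaces are not on the same grid")
    }
    out <- out * r$values
  }
  if (!is.null(habitat_mask)) {
    m <- if (inherits(habitat_mask, "categorized_surface")) {
      habitat_mask$raster$values
    } else if (inherits(habitat_mask, "grid_raster")) {
      habitat_mask$values
    } else {
      habitat_mask
    }
    if (!identical(dim(m), d1)) stop("habitat mask is not on the same grid")
    out[is.na(m) | m == 0] <- NA_real_
  }
  grid_raster(out, rs[[1]]$xmin, rs[[1]]$ymin, rs[[1]]$res)
}

#' Rank habitat from productive (source) to maladaptive (sink)
#'
#' Overlays the categorized selection (low/moderate/high habitat) and
#' survival (very low..high) maps into an ordinal rank per pixel on a
#' 3 x 4 table. Within the low-to-high survival tiers, more selection is
#' better; within the very-low-survival tier, more selection is worse,
#' because strong selection for lethal habitat is the maladaptive (sink)
#' signature. Rank 12 is high selection with high survival (productive
#' source habitat); rank 1 is high selection with very low survival.
#' Nonhabitat pixels carry no rank.
#'
#' @param sel_cat selection \code{categorized_surface}.
#' @param surv_cat survival \code{categorized_surface} on the same grid.
#' @return a \code{ranked_habitat_map}: rank raster, the 12-cell legend,
#'   and an area table (pixels, km2, percent of ranked area).
#' @export
rank_overlay <- function(sel_cat, surv_cat) {
  s <- sel_cat$raster$values
  v <- surv_cat$raster$values
  if (!identical(dim(s), dim(v))) stop("categorized grids do not align")
  hab <- !is.na(s) & s >= 1L
  if (any(hab & is.na(v))) {
    stop("unclassified survival pixel inside habitat")
  }
  rank <- matrix(NA_integer_, nrow(s), ncol(s))
  idx <- which(hab)
  rank[idx] <- ifelse(v[idx] >= 2L,
                      (v[idx] - 2L) * 3L + s[idx] + 3L,
                      4L - s[idx])
  legend <- expand.grid(selection = 1:3, survival = 1:4)
  legend$rank <- ifelse(legend$survival >= 2,
                        (legend$survival - 2) * 3 + legend$selection + 3,
                        4 - legend$selection)
  legend$selection_label <- c("low", "moderate", "high")[legend$selection]
  legend$survival_label <- c("very low", "low", "moderate",
                             "high")[legend$survival]
  legend <- legend[order(-legend$rank),
                   c("rank", "selection_label", "survival_label")]
  res <- sel_cat$raster$res
  px <- tabulate(rank[idx], nbins = 12)
  area <- data.frame(rank = 12:1, pixels = px[12:1],
                     km2 = px[12:1] * res^2 / 1e6)
  area$percent <- 100 * area$pixels / sum(area$pixels)
  structure(list(raster = grid_raster(rank, sel_cat$raster$xmin,
                                      sel_cat$raster$ymin, res),
                 legend = legend, area = area),
            class = "ranked_habitat_map")
}

#' Example management categories
#'
#' Combines the composite selection categories, the composite survival
#' categories and a binary abundance-and-space-use index (ASUI; an
#' external occupancy layer, 1 = high use) into four categories:
#' priority+ (source habitat - high selection and high survival - inside
#' high-use areas), priority (any habitat inside high use, or source
#' habitat outside it; source = the top two overlay ranks), general
#' (high selection with low/no use, or nonhabitat inside high use) and
#' other (moderate selection with low/no use). Remaining pixels are
#' unclassified (NA). If no ASUI layer is supplied the overlay ranking
#' alone is the product and NULL is returned with a notice.
#'
#' @param sel_cat composite-selection \code{categorized_surface}.
#' @param surv_cat composite-survival \code{categorized_surface}.
#' @param asui binary \code{grid_raster} (1 = high use, 0 = low/no use),
#'   pre-thresholded by the caller, or NULL.
#' @return a \code{categorized_surface} with codes 1 = priority+,
#'   2 = priority, 3 = general, 4 = other, or NULL when \code{asui} is
#'   missing.
#' @export
management_categories <- function(sel_cat, surv_cat, asui = NULL) {
  if (is.null(asui)) {
    message("no ASUI layer supplied; only the selection-survival ",
            "ranking is produced")
    return(NULL)
  }
  s <- sel_cat$raster$values
  v <- surv_cat$raster$values
  a <- asui$values
  if (!identical(dim(s), dim(a))) stop("ASUI grid does not align")
  rank <- rank_overlay(sel_cat, surv_cat)$raster$values
  source_px <- !is.na(rank) & rank >= 11L
  out <- matrix(NA_integer_, nrow(s), ncol(s))
  high_use <- !is.na(a) & a >= 1
  pplus <- !is.na(s) & s == 3L & !is.na(v) & v == 4L & high_use
  prio <- (!is.na(s) & s >= 1L & high_use) | (source_px & !high_use)
  gen <- (!is.na(s) & s == 3L & !high_use) |
         (!is.na(s) & s == 0L & high_use)
  oth <- !is.na(s) & s == 2L & !high_use
  out[oth] <- 4L
  out[gen] <- 3L
  out[prio] <- 2L
  out[pplus] <- 1L
  structure(list(
    raster = grid_raster(out, sel_cat$raster$xmin, sel_cat$raster$ymin,
                         sel_cat$raster$res),
    thresholds = NULL,
    labels = c(`1` = "priority+", `2` = "priority", `3` = "general",
               `4` = "other"),
    kind = "management"), class = "categorized_surface")
}

#' Class-area summary of a categorized surface
#'
#' Reports pixels, km2 and percent per class. Percentages are given
#' against both the whole grid and the classified (non-NA) area, since
#' the two denominators answer different management questions.
#'
#' @param cat a \code{categorized_surface}.
#' @return data.frame: class, label, pixels, km2, pct_of_region,
#'   pct_of_classified.
#' @export
area_summary <- function(cat) {
  r <- cat$raster
  v <- r$values
  codes <- sort(as.integer(names(cat$labels)))
  px <- vapply(codes, function(k) sum(v == k, na.rm = TRUE), numeric(1))
  data.frame(
    class = codes, label = unname(cat$labels[as.character(codes)]),
    pixels = px, km2 = px * r$res^2 / 1e6,
    pct_of_region = 100 * px / length(v),
    pct_of_classified = 100 * px / sum(!is.na(v)))
}

#' Write a categorized surface and its area table
#'
#' @param cat a \code{categorized_surface}.
#' @param prefix file-path prefix; writes \code{<prefix>.asc} and
#'   \code{<prefix>_area.csv}.
#' @export
write_categorized <- function(cat, prefix) {
  write_asc(cat$raster, paste0(prefix, ".asc"), digits = 1)
  utils::write.csv(area_summary(cat), paste0(prefix, "_area.csv"),
                   row.names = FALSE)
  invisible(prefix)
}
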