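#' Build a used/available design table
#'
#' The availability radius is the 90th percentile of observed movement
#' distances from the anchor (lek for nesting, the individual's nest for
#' broods), a cutoff that captures routine movements while excluding
#' extreme ones. Five available points are drawn uniformly within that
#' radius of each used point's anchor (5:1 available:used); points
#' falling off the raster are rejected and redrawn so the ratio is
#' exact. Available rows inherit the used row's grouping ids, and every
#' row carries its distance to the anchor as a movement confounder.
#'
#' @param used used-point table (columns \code{x}, \code{y},
#'   \code{site}, \code{year}, \code{animal}, \code{anchor_x},
#'   \code{anchor_y}; see \code{\link{simulate_used_points}}).
#' @param distances movement distances (m) from which the availability
#'   radius is taken; at least 10 values. Default: the used points' own
#'   anchor distances, pooled across individuals.
#' @param ratio available:used ratio (design constant 5).
#' @param prob percentile of \code{distances} defining the radius
#'   (default 0.90, linear interpolation between order statistics).
#' @param stack optional \code{landscape_stack}; when given, available
#'   points are constrained to the raster extent.
#' @param seed RNG seed.
#' @return a design data.frame with response \code{y} (1 = used,
#'   0 = available), coordinates, grouping ids, stage and
#'   \code{dist_anchor}.
#' @export
sample_available <- function(used, distances = used$dist_anchor,
                             ratio = 5, prob = 0.90, stack = NULL,
                             seed = NULL) {
  if (nrow(used) == 0) {
    return(data.frame(used = integer(0), x = numeric(0), y = numeric(0),
                      site = integer(0), year = integer(0),
                      animal = integer(0), stage = character(0),
                      anchor_x = numeric(0), anchor_y = numeric(0),
                      dist_anchor = numeric(0)))
  }
  if (length(distances) < 10) {
    stop("need at least 10 movement distances to estimate the ",
         "availability radius")
  }
  radius <- stats::quantile(distances, prob, names = FALSE, type = 7)
  if (radius <= 0) stop("availability radius must be positive")
  if (!is.null(seed)) set.seed(seed)

  n_av <- nrow(used) * ratio
  idx <- rep(seq_len(nrow(used)), each = ratio)
  ax <- used$anchor_x[idx]; ay <- used$anchor_y[idx]
  px <- rep(NA_real_, n_av); py <- rep(NA_real_, n_av)
  todo <- seq_len(n_av)
  guard <- 0
  while (length(todo)) {
    r <- radius * sqrt(stats::runif(length(todo)))
    th <- stats::runif(length(todo), 0, 2 * pi)
    cx <- ax[todo] + r * cos(th); cy <- ay[todo] + r * sin(th)
    ok <- rep(TRUE, length(todo))
    if (!is.null(stack)) {
      ok <- cx >= stack$xmin & cx <= stack$xmin + stack$nx * stack$res &
            cy >= stack$ymin & cy <= stack$ymin + stack$ny * stack$res
    }
    px[todo[ok]] <- cx[ok]; py[todo[ok]] <- cy[ok]
    todo <- todo[!ok]
    guard <- guard + 1
    if (guard > 1000) stop("could not place available points on the raster")
  }
  avail <- data.frame(
    resp = 0L, x = px, y = py, site = used$site[idx],
    year = used$year[idx], animal = used$animal[idx],
    stage = used$stage[idx], anchor_x = ax, anchor_y = ay,
    dist_anchor = sqrt((px - ax)^2 + (py - ay)^2))
  used_rows <- data.frame(
    resp = 1L, x = used$x, y = used$y, site = used$site,
    year = used$year, animal = used$animal, stage = used$stage,
    anchor_x = used$anchor_x, anchor_y = used$anchor_y,
    dist_anchor = used$dist_anchor)
  out <- rbind(used_rows, avail)
  names(out)[names(out) == "resp"] <- "used"
  attr(out, "avail_radius") <- radius
  out
}

#' Build an encounter history from monitoring visits
#'
#' Turns a per-unit visit log into interval records: one row per
#' inter-visit interval with entry day, exit day, length and fate.
#' Covariates present on the visit rows are attached from the interval
#' start. Survivors contribute only fate-1 intervals; a failed unit's
#' final interval carries fate 0.
#'
#' @param visits data.frame with columns \code{unit}, \code{day}
#'   (visit day, increasing within unit), \code{fate} (1 while the unit
#'   is intact; 0 at the visit where failure was discovered) and
#'   optional covariate columns.
#' @return encounter-history data.frame (unit, entry, exit, t, y,
#'   covariates measured at interval start). Units whose fate is missing
#'   are dropped with a warning.
#' @export
build_encounter_history <- function(visits) {
  stopifnot(all(c("unit", "day", "fate") %in% names(visits)))
  drop <- unique(visits$unit[is.na(visits$fate)])
  if (length(drop)) {
    warning("dropping unit(s) with unknown fate: ",
            paste(drop, collapse = ", "))
    visits <- visits[!visits$unit %in% drop, , drop = FALSE]
  }
  extra <- setdiff(names(visits), c("unit", "day", "fate"))
  out <- lapply(split(visits, visits$unit), function(v) {
    v <- v[order(v$day), , drop = FALSE]
    if (any(diff(v$day) <= 0)) {
      stop("non-monotone visit days for unit ", v$unit[1])
    }
    if (nrow(v) < 2) return(NULL)
    k <- nrow(v) - 1
    rec <- data.frame(unit = v$unit[1],
                      entry = v$day[-nrow(v)], exit = v$day[-1],
                      t = diff(v$day), y = v$fate[-1])
    for (nm in extra) rec[[nm]] <- v[[nm]][-nrow(v)]
    # failure ends observation: keep rows up to the first fate-0 interval
    f <- which(rec$y == 0)
    if (length(f)) rec <- rec[seq_len(f[1]), , drop = FALSE]
    rec
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Individual-level holdout split
#'
#' Withholds whole individuals (or broods) so the testing data are
#' independent of every training individual; splitting by row would leak
#' within-individual correlation.
#'
#' @param data data.frame.
#' @param id_col grouping column (individual / brood id).
#' @param n_withhold number of ids withheld (default 50).
#' @param seed RNG seed.
#' @return list with \code{train}, \code{test} and \code{withheld_ids}.
#' @export
holdout_split <- function(data, id_col = "animal", n_withhold = 50,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- unique(data[[id_col]])
  if (n_withhold >= length(ids)) {
    stop("cannot withhold ", n_withhold, " of ", length(ids), " individuals")
  }
  wd <- sample(ids, n_withhold)
  list(train = data[!data[[id_col]] %in% wd, , drop = FALSE],
       test = data[data[[id_col]] %in% wd, , drop = FALSE],
       withheld_ids = wd)
}

#' Attach exponential-decay distance covariates to a design table
#'
#' For each raw distance column, sets the decay scale alpha to the mean
#' raw distance over the table's rows (so alpha is tied to the analysis
#' at hand, estimated per life stage) and replaces the column with
#' exp(-d/alpha).
#'
#' @param df design or encounter-history data.frame.
#' @param cols raw distance column names.
#' @param alphas optional named vector of pre-estimated alphas (m), used
#'   for prediction-time consistency.
#' @return list with \code{table} and \code{alphas}.
#' @export
add_decay_columns <- function(df, cols, alphas = NULL) {
  out_a <- numeric(0)
  for (cl in cols) {
    a <- if (!is.null(alphas) && cl %in% names(alphas)) alphas[[cl]]
         else mean(df[[cl]], na.rm = TRUE)
    df[[cl]] <- decay_distance(df[[cl]], a)
    out_a[cl] <- a
  }
  list(table = df, alphas = out_a)
}

#' Candidate covariate columns for a set of specs
#'
#' Ensures the needed focal bands exist on the stack and extracts, for
#' every spec, its candidate columns: one per radius for windowed
#' covariates (\code{<name>_r<radius>}), the raw Euclidean distance for
#' distance covariates (\code{dist_<name>}), and the native band for
#' topographic covariates.
#'
#' @param stack a \code{landscape_stack}.
#' @param pts point rows (x, y, and year for temporal bands).
#' @param specs covariate specs.
#' @param radii optional radii override for every windowed spec.
#' @return list: \code{table} (pts + columns), \code{stack} (with focal
#'   bands added), \code{groups} (group -> candidate columns, distance
#'   columns still on the raw scale), \code{distance_cols}.
#' @export
design_columns <- function(stack, pts, specs = stack$covariates,
                           radii = NULL) {
  stack <- add_focal_bands(stack, specs, radii)
  groups <- list()
  dist_cols <- character()
  bands <- character()
  for (cs in specs) {
    cols <- switch(cs$kind,
      proportion = ,
      height = {
        rr <- if (is.null(radii)) cs$radii else radii
        paste0(cs$name, "_r", vapply(rr, format, "", trim = TRUE))
      },
      distance = {
        dc <- paste0("dist_", cs$name)
        dist_cols <- c(dist_cols, dc)
        dc
      },
      topographic = cs$name)
    bands <- c(bands, cols)
    groups[[cs$group]] <- c(groups[[cs$group]], cols)
  }
  pts <- extract_covariates(stack, pts, bands)
  list(table = pts, stack = stack, groups = groups,
       distance_cols = dist_cols)
}

#' Assemble a full used/available design table
#'
#' Chains the design steps: draw available points (5:1 within the 90th
#' percentile of movement distances), extract every candidate
#' variable-scale column, decay-transform raw distances (alpha = mean
#' over the design rows of this analysis) and centre/scale all
#' covariates plus the movement confounder.
#'
#' @inheritParams design_columns
#' @param used used-point table from \code{\link{simulate_used_points}}
#'   (or equivalently structured telemetry).
#' @param seed RNG seed for availability sampling.
#' @return list: \code{table} (standardised design table with response
#'   \code{used}), \code{groups} (candidate columns per scale-selection
#'   group), \code{covariates} (all candidate columns),
#'   \code{confounder}, \code{scaling}, \code{alphas}, \code{stack}.
#' @export
build_design_table <- function(stack, used, specs = stack$covariates,
                               radii = NULL, seed = NULL) {
  des <- sample_available(used, stack = stack, seed = seed)
  dc <- design_columns(stack, des, specs, radii)
  tab <- dc$table
  dec <- add_decay_columns(tab, dc$distance_cols)
  tab <- dec$table
  covs <- unique(unlist(dc$groups))
  sc <- scale_and_center(tab, c(covs, "dist_anchor"))
  list(table = sc$table, groups = dc$groups, covariates = covs,
       confounder = "dist_anchor", scaling = sc$params,
       alphas = dec$alphas, stack = dc$stack,
       avail_radius = attr(des, "avail_radius"))
}
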