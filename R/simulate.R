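#' Realise the ground truth of a synthetic study
#'
#' Draws the random-intercept values (site, year and bird/brood for
#' selection; site and year for survival) for every life stage from the
#' configured spreads. Together with the configured coefficients these
#' define the exact generative model, so downstream fits can be checked
#' against known truth. Reproducible bit-for-bit from the config seed.
#'
#' @param config a \code{\link{sim_config}}.
#' @return a \code{sim_truth}: the config plus realised intercepts.
#' @export
sim_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream_seed(config$seed, "truth"))
  stages <- c("nest", "early_brood", "late_brood")
  intercepts <- lapply(stages, function(st) {
    list(
      sel = list(site = stats::rnorm(config$n_sites, 0, config$sd_site),
                 year = stats::rnorm(length(config$years), 0, config$sd_year),
                 animal = stats::rnorm(config$n_animals, 0, config$sd_animal)),
      surv = list(site = stats::rnorm(config$n_sites, 0, config$sd_site),
                  year = stats::rnorm(length(config$years), 0, config$sd_year))
    )
  })
  names(intercepts) <- stages
  structure(list(config = config, intercepts = intercepts),
            class = "sim_truth")
}

# Resolve the generating band for one covariate at its group's true
# scale: windowed kinds use the focal band at that radius, distance kinds
# the decay-transformed distance (alpha = map mean distance), topographic
# kinds the native band. Returned standardised to map-wide mean 0 / SD 1.
truth_band <- function(stack, config, name, year = NULL) {
  spec <- NULL
  for (cs in config$covariates) if (cs$name == name) spec <- cs
  if (is.null(spec)) stop("unknown covariate in truth coefficients: ", name)
  v <- switch(spec$kind,
    proportion = ,
    height = {
      rad <- config$true_scales[[spec$group]]
      if (is.null(rad)) stop("no true scale for group ", spec$group)
      base <- stack_band(stack, name, if (spec$temporal) year else NULL)
      focal_proportion(base, rad)$values
    },
    distance = {
      d <- stack$bands[[paste0("dist_", name)]]
      exp(-d / mean(d))
    },
    topographic = stack_band(stack, name)$values
  )
  (v - mean(v)) / sqrt(mean((v - mean(v))^2))
}

#' True relative selection weight surface
#'
#' exp(X beta_true) over the landscape with X the generating-scale,
#' map-standardised covariates of the given stage.
#'
#' @param stack a \code{landscape_stack}.
#' @param truth a \code{\link{sim_truth}}.
#' @param stage life stage.
#' @param year year used to resolve temporal covariates.
#' @return a \code{grid_raster} of weights.
#' @export
truth_selection_weights <- function(stack, truth, stage, year = NULL) {
  config <- truth$config
  beta <- config$beta_sel[[stage]]
  lp <- matrix(0, stack$ny, stack$nx)
  for (nm in names(beta)) {
    lp <- lp + beta[[nm]] * truth_band(stack, config, nm, year)
  }
  grid_raster(exp(lp), stack$xmin, stack$ymin, stack$res)
}

#' Simulate used telemetry locations under the true selection model
#'
#' Draws points within the stage's availability domain (a disc of the
#' configured radius around each anchor: the site lek for nesting, the
#' individual's nest for broods) with probability proportional to
#' exp(X beta_true). Points are jittered uniformly within their pixel
#' and labelled with site, year and animal ids.
#'
#' @param stack a \code{landscape_stack}.
#' @param truth a \code{\link{sim_truth}}.
#' @param stage life stage.
#' @param n number of used points.
#' @param anchors optional anchor table (columns \code{x}, \code{y},
#'   \code{site}, optionally \code{animal}, \code{year}); default: the
#'   stack's leks (one anchor per site), appropriate for nesting.
#' @param seed RNG seed (default: a named substream of the config seed).
#' @return data.frame: x, y, site, year, animal, stage, anchor
#'   coordinates and distance to anchor.
#' @export
simulate_used_points <- function(stack, truth, stage, n,
                                 anchors = NULL, seed = NULL) {
  config <- truth$config
  if (is.null(seed)) seed <- substream_seed(config$seed, paste0("used_", stage))
  set.seed(seed)
  if (n == 0) {
    return(data.frame(x = numeric(), y = numeric(), site = integer(),
                      year = integer(), animal = integer(),
                      stage = character(), anchor_x = numeric(),
                      anchor_y = numeric(), dist_anchor = numeric()))
  }
  if (is.null(anchors)) anchors <- stack$features$leks
  radius <- config$avail_radius[[stage]]
  beta <- config$beta_sel[[stage]]
  temporal <- any(vapply(config$covariates, function(cs) {
    cs$name %in% names(beta) && cs$temporal
  }, logical(1)))

  # assign each point an animal; each animal one site/anchor and one year
  animal <- sort(sample(config$n_animals, n, replace = TRUE))
  ids <- unique(animal)
  arow <- if ("animal" %in% names(anchors)) {
    match(((ids - 1) %% nrow(anchors)) + 1, seq_len(nrow(anchors)))
  } else {
    ((ids - 1) %% nrow(anchors)) + 1
  }
  a_year <- sample(config$years, length(ids), replace = TRUE)
  if ("year" %in% names(anchors)) a_year <- anchors$year[arow]

  co <- raster_coords(grid_raster(matrix(0, stack$ny, stack$nx),
                                  stack$xmin, stack$ymin, stack$res))
  wcache <- list()
  weight_map <- function(year) {
    key <- if (temporal) as.character(year) else "static"
    if (is.null(wcache[[key]])) {
      wcache[[key]] <<- truth_selection_weights(stack, truth, stage,
                                                year)$values
    }
    wcache[[key]]
  }

  out <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    ax <- anchors$x[arow[k]]; ay <- anchors$y[arow[k]]
    dom <- which((co$x - ax)^2 + (co$y - ay)^2 <= radius^2)
    if (!length(dom)) stop("availability domain empty for anchor at (",
                           ax, ", ", ay, ")")
    w <- weight_map(a_year[k])
    wd <- w[cbind(co$row[dom], co$col[dom])]
    if (all(wd <= 0)) stop("all selection weights zero within the domain")
    ni <- sum(animal == ids[k])
    pick <- dom[sample.int(length(dom), ni, replace = TRUE, prob = wd)]
    px <- co$x[pick] + stats::runif(ni, -0.5, 0.5) * stack$res
    py <- co$y[pick] + stats::runif(ni, -0.5, 0.5) * stack$res
    out[[k]] <- data.frame(
      x = px, y = py, site = anchors$site[arow[k]], year = a_year[k],
      animal = ids[k], stage = stage, anchor_x = ax, anchor_y = ay,
      dist_anchor = sqrt((px - ax)^2 + (py - ay)^2))
  }
  do.call(rbind, out)
}

#' Extract generating-scale covariates at point locations
#'
#' Attaches the stage's true-model covariates (map-standardised, at each
#' group's generating scale) to a point table, for building unit tables
#' whose fates are then simulated from known coefficients.
#'
#' @param stack a \code{landscape_stack}.
#' @param truth a \code{\link{sim_truth}}.
#' @param stage life stage.
#' @param pts data.frame with \code{x}, \code{y} (and \code{year} for
#'   temporal covariates).
#' @param model "surv" (default) or "sel": which coefficient set's
#'   covariates to attach.
#' @return \code{pts} with one standardised column per covariate.
#' @export
extract_truth_covariates <- function(stack, truth, stage, pts,
                                     model = c("surv", "sel")) {
  model <- match.arg(model)
  config <- truth$config
  beta <- if (model == "surv") config$beta_surv[[stage]]
          else config$beta_sel[[stage]]
  for (nm in names(beta)) {
    spec <- NULL
    for (cs in config$covariates) if (cs$name == nm) spec <- cs
    if (!is.null(spec) && spec$temporal) {
      v <- rep(NA_real_, nrow(pts))
      for (yr in unique(pts$year)) {
        b <- grid_raster(truth_band(stack, config, nm, yr),
                         stack$xmin, stack$ymin, stack$res)
        i <- pts$year == yr
        v[i] <- extract_at(b, pts$x[i], pts$y[i])
      }
      pts[[nm]] <- v
    } else {
      b <- grid_raster(truth_band(stack, config, nm),
                       stack$xmin, stack$ymin, stack$res)
      pts[[nm]] <- extract_at(b, pts$x, pts$y)
    }
  }
  pts
}

#' Generating-scale covariate raster
#'
#' The standardised band a truth coefficient applies to: focal mean at
#' the group's generating radius for windowed covariates, decayed
#' distance for distance covariates, the native band for topographic
#' ones, each standardised map-wide. Used to build survival prediction
#' surfaces that match the generative model's covariate definition.
#'
#' @inheritParams truth_selection_weights
#' @param name covariate name.
#' @return a \code{grid_raster}.
#' @export
truth_covariate_raster <- function(stack, truth, name, year = NULL) {
  grid_raster(truth_band(stack, truth$config, name, year),
              stack$xmin, stack$ymin, stack$res)
}

#' Simulate nest/brood fates into an encounter history
#'
#' Each unit survives day-to-day with probability
#' logit^-1(gamma0 + X beta + site + year intercepts); monitoring visits
#' every \code{check_interval} days partition the stage duration into
#' intervals. The failure day itself is unobservable: a failure is
#' recorded against the whole interval in which it happened (fate 0 on
#' that interval, which is the unit's last), mirroring interval-censored
#' field data.
#'
#' @param units data.frame with one row per nest/brood: \code{unit},
#'   \code{site}, \code{year} (indices into the truth's intercepts) and
#'   the standardised covariate columns named by the stage's true
#'   survival coefficients.
#' @param truth a \code{\link{sim_truth}}.
#' @param stage life stage (sets gamma0, coefficients and the default
#'   duration).
#' @param check_interval days between visits (default from config).
#' @param duration exposure days (default \code{\link{stage_duration}});
#'   must be positive.
#' @param seed RNG seed (default: substream of the config seed).
#' @return encounter-history data.frame (unit, site, year, stage, entry,
#'   exit, t, y, covariates; unit coordinates are carried through when
#'   present), with the per-unit true daily survival in
#'   \code{attr(, "true_ds")}.
#' @export
simulate_fates <- function(units, truth, stage,
                           check_interval = NULL, duration = NULL,
                           seed = NULL) {
  config <- truth$config
  if (is.null(check_interval)) check_interval <- config$check_interval
  if (is.null(duration)) duration <- stage_duration(stage)
  if (duration <= 0) stop("duration must be positive")
  if (check_interval <= 0) stop("check_interval must be positive")
  if (is.null(seed)) seed <- substream_seed(config$seed, paste0("fate_", stage))
  set.seed(seed)

  beta <- config$beta_surv[[stage]]
  miss <- setdiff(names(beta), names(units))
  if (length(miss)) {
    stop("units lack covariate column(s): ", paste(miss, collapse = ", "))
  }
  lp <- rep(config$gamma0[[stage]], nrow(units))
  for (nm in names(beta)) lp <- lp + beta[[nm]] * units[[nm]]
  ic <- truth$intercepts[[stage]]$surv
  if ("site" %in% names(units)) lp <- lp + ic$site[units$site]
  if ("year" %in% names(units)) {
    lp <- lp + ic$year[match(units$year, config$years)]
  }
  ds <- stats::plogis(lp)

  checks <- seq(check_interval, duration, by = check_interval)
  if (length(checks) == 0 || checks[length(checks)] < duration) {
    checks <- c(checks, duration)
  }
  entry <- c(0, checks[-length(checks)])

  # first failure day ~ geometric in days; > duration means survived
  fail_day <- stats::rgeom(nrow(units), prob = 1 - ds) + 1
  cov_cols <- intersect(names(beta), names(units))
  carry_xy <- all(c("x", "y") %in% names(units))
  rows <- vector("list", nrow(units))
  for (i in seq_len(nrow(units))) {
    if (fail_day[i] > duration) {
      keep <- seq_along(checks); y <- rep(1L, length(keep))
    } else {
      keep <- seq_len(which(fail_day[i] <= checks)[1])
      y <- c(rep(1L, length(keep) - 1L), 0L)
    }
    rows[[i]] <- data.frame(
      unit = units$unit[i],
      site = if ("site" %in% names(units)) units$site[i] else NA,
      year = if ("year" %in% names(units)) units$year[i] else NA,
      stage = stage, entry = entry[keep], exit = checks[keep],
      t = checks[keep] - entry[keep], y = y)
    for (nm in cov_cols) rows[[i]][[nm]] <- units[[nm]][i]
    if (carry_xy) { # unit location (fate y is already taken)
      rows[[i]]$x <- units$x[i]
      rows[[i]]$y_coord <- units$y[i]
    }
  }
  eh <- do.call(rbind, rows)
  rownames(eh) <- NULL
  attr(eh, "true_ds") <- ds
  eh
}
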