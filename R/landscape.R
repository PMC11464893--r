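#' Default covariate set
#'
#' Fourteen synthetic environmental covariates organised into the twelve
#' groups used for scale selection: shrub cover and height, herbaceous
#' cover, bare ground, invasive annual grass, conifer (pinyon-juniper)
#' cover, burned area, streams, springs, saline lakes, elevation,
#' topography (slope, roughness) and a temperature/moisture index.
#' Annual grass and burned area vary by year.
#'
#' @param radii candidate moving-window radii (m) attached to every
#'   windowed covariate; subset per life stage at design time.
#' @return list of \code{\link{covariate_spec}}.
#' @export
default_covariates <- function(radii = c(167.9, 439.5, 1451.7)) {
  list(
    covariate_spec("pct_sagebrush",   "shrubs",        "proportion", radii),
    covariate_spec("sagebrush_height","shrubs",        "height",     radii),
    covariate_spec("pct_herbaceous",  "herb_meadow",   "proportion", radii),
    covariate_spec("pct_bare",        "bare_ground",   "proportion", radii),
    covariate_spec("annual_grass",    "annual_grass",  "proportion", radii,
                   temporal = TRUE),
    covariate_spec("pct_pj",          "conifer",       "proportion", radii),
    covariate_spec("burned",          "burned",        "proportion", radii,
                   temporal = TRUE),
    covariate_spec("streams",         "streams",       "distance"),
    covariate_spec("springs",         "springs",       "distance"),
    covariate_spec("saline_lakes",    "saline_lakes",  "distance"),
    covariate_spec("elevation",       "elevation",     "topographic"),
    covariate_spec("slope",           "topography",    "topographic"),
    covariate_spec("roughness",       "topography",    "topographic"),
    covariate_spec("hli",             "temp_moisture", "topographic")
  )
}

#' Reproductive life stages and their durations (days)
#'
#' Nesting spans the 38-day laying and incubation period; brood rearing
#' is split into early (21 days post-hatch) and late (a further 28 days,
#' to 49-50 days post-hatch when chicks are independent).
#'
#' @param stage "nest", "early_brood" or "late_brood".
#' @return integer number of days.
#' @export
stage_duration <- function(stage) {
  switch(match.arg(stage, c("nest", "early_brood", "late_brood")),
         nest = 38L, early_brood = 21L, late_brood = 28L)
}

#' Configuration of the synthetic study system
#'
#' Bundles every quantity the generator needs: the grid, the population
#' structure (sites, years, marked females), the covariate set, the true
#' selection and survival coefficients per life stage, the true scale per
#' covariate group, and random-intercept spreads. Defaults emulate the
#' study system: 10 subpopulations monitored 2003-2019, 419 marked
#' females and 579 nests, 30 m pixels, nest survival 0.38 over 38 days
#' and brood survival 0.74 over 50 days at baseline.
#'
#' @param nx,ny grid size (pixels).
#' @param res pixel size (m).
#' @param seed master RNG seed; all substreams derive from it.
#' @param n_sites,years,n_animals population structure.
#' @param n_nests,n_broods_early,n_broods_late default unit counts.
#' @param covariates list of \code{\link{covariate_spec}}.
#' @param grf_range Gaussian-random-field autocorrelation range (pixels).
#' @param true_scales named vector: covariate group -> generating radius (m).
#' @param beta_sel,beta_surv per-stage named coefficient vectors on the
#'   standardised covariate scale (names are covariate names).
#' @param gamma0 per-stage baseline logit daily survival.
#' @param sd_site,sd_year,sd_animal random-intercept SDs.
#' @param avail_radius per-stage availability radius (m) around the
#'   anchor (lek for nesting, nest for broods).
#' @param check_interval days between monitoring visits.
#' @param constant_fields optional named list forcing a band to a
#'   constant value (degenerate-field option for testing).
#' @return a \code{sim_config} list.
#' @export
sim_config <- function(nx = 200, ny = 200, res = 30, seed = 1,
                       n_sites = 10, years = 2003:2019, n_animals = 419,
                       n_nests = 579, n_broods_early = 285,
                       n_broods_late = 209,
                       covariates = default_covariates(),
                       grf_range = 8,
                       true_scales = c(shrubs = 439.5, herb_meadow = 439.5,
                                       bare_ground = 167.9,
                                       annual_grass = 439.5,
                                       conifer = 439.5, burned = 439.5),
                       beta_sel = list(
                         nest = c(sagebrush_height = 0.8, elevation = 0.6,
                                  pct_pj = -0.9, pct_bare = -0.5,
                                  pct_herbaceous = -0.4),
                         early_brood = c(sagebrush_height = 0.6,
                                         pct_bare = 0.4, elevation = 0.5,
                                         pct_pj = -0.7, burned = -0.4),
                         late_brood = c(sagebrush_height = 0.5,
                                        pct_herbaceous = 0.6,
                                        elevation = 0.6, pct_pj = -0.6,
                                        slope = -0.4)),
                       beta_surv = list(
                         nest = c(burned = 0.3, roughness = 0.3,
                                  elevation = 0.3),
                         early_brood = c(burned = 0.3, pct_sagebrush = -0.3),
                         late_brood = c(springs = 0.3, slope = 0.3)),
                       gamma0 = c(nest = stats::qlogis(0.9749),
                                  early_brood = stats::qlogis(0.9940),
                                  late_brood = stats::qlogis(0.9940)),
                       sd_site = 0.3, sd_year = 0.2, sd_animal = 0.2,
                       avail_radius = c(nest = 2400, early_brood = 1000,
                                        late_brood = 1400),
                       check_interval = 10,
                       constant_fields = list()) {
  stopifnot(res > 0, nx >= 4, ny >= 4, n_sites >= 1)
  if (!all(true_scales %in% CANDIDATE_RADII)) {
    stop("every true scale must be one of the candidate radii")
  }
  cfg <- list(nx = nx, ny = ny, res = res, seed = as.integer(seed),
              n_sites = n_sites, years = years, n_animals = n_animals,
              n_nests = n_nests, n_broods_early = n_broods_early,
              n_broods_late = n_broods_late,
              covariates = covariates, grf_range = grf_range,
              true_scales = true_scales, beta_sel = beta_sel,
              beta_surv = beta_surv, gamma0 = gamma0,
              sd_site = sd_site, sd_year = sd_year, sd_animal = sd_animal,
              avail_radius = avail_radius, check_interval = check_interval,
              constant_fields = constant_fields)
  class(cfg) <- "sim_config"
  cfg
}

# Deterministic substream seed: master seed + a small hash of the label,
# kept within 32-bit integer range.
substream_seed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 1000003
  as.integer((as.numeric(seed) + h) %% .Machine$integer.max)
}

# Standard Gaussian random field: white noise smoothed with a Gaussian
# kernel (kernel-convolution synthesis), edge-corrected and standardised.
gaussian_field <- function(nx, ny, range_px) {
  z <- matrix(stats::rnorm(nx * ny), ny, nx)
  if (range_px > 0) {
    k <- max(1L, ceiling(3 * range_px))
    off <- seq(-k, k)
    g <- exp(-outer(off^2, off^2, "+") / (2 * range_px^2))
    num <- conv2_fft(z, g)
    den <- sqrt(conv2_fft(matrix(1, ny, nx), g^2)) # edge variance correction
    z <- num / den
  }
  (z - mean(z)) / stats::sd(z)
}

# min distance (m) from every pixel centre to a set of feature points
distance_band <- function(nx, ny, res, px, py) {
  cx <- (seq_len(nx) - 0.5) * res
  cy <- ((ny:1) - 0.5) * res # row 1 = north
  out <- matrix(Inf, ny, nx)
  for (j in seq_along(px)) {
    dx2 <- (cx - px[j])^2
    dy2 <- (cy - py[j])^2
    out <- pmin(out, outer(dy2, dx2, "+"))
  }
  sqrt(out)
}

#' Generate a synthetic landscape stack
#'
#' Builds one band per continuous covariate as a spatially autocorrelated
#' Gaussian random field (transformed to the covariate's natural range),
#' point/line features (leks, streams, springs, saline lakes) with
#' derived Euclidean-distance bands, and per-year bands for temporal
#' covariates. Bit-for-bit reproducible from the configuration seed.
#'
#' @param config a \code{\link{sim_config}}.
#' @return a \code{landscape_stack}: grid metadata, named band matrices
#'   (temporal bands are named \code{<covariate>.<year>}) and feature
#'   point tables.
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  radii <- unlist(lapply(config$covariates, `[[`, "radii"))
  if (length(radii)) {
    need <- 2 * floor(max(radii) / config$res) + 1
    if (need > min(config$nx, config$ny)) {
      stop(sprintf(
        "grid (%d x %d px) too small for moving-window radius %g m",
        config$nx, config$ny, max(radii)))
    }
  }
  set.seed(substream_seed(config$seed, "landscape"))
  nx <- config$nx; ny <- config$ny; res <- config$res
  rng <- config$grf_range
  bands <- list()

  field <- function(name) {
    if (name %in% names(config$constant_fields)) {
      matrix(config$constant_fields[[name]], ny, nx)
    } else {
      gaussian_field(nx, ny, rng)
    }
  }
  mean_props <- c(pct_sagebrush = 0.25, pct_herbaceous = 0.12,
                  pct_bare = 0.20, annual_grass = 0.05, pct_pj = 0.08,
                  burned = 0.04)

  elev_z <- NULL
  for (cs in config$covariates) {
    nm <- cs$name
    if (cs$kind == "distance") next
    make_one <- function() {
      z <- field(nm)
      const <- nm %in% names(config$constant_fields)
      if (const) return(z)
      switch(cs$kind,
        proportion = {
          m <- if (nm %in% names(mean_props)) mean_props[[nm]] else 0.15
          stats::plogis(stats::qlogis(m) + 1.2 * z)
        },
        height = pmax(35 + 18 * z, 0),
        topographic = {
          if (nm == "elevation") {
            elev_z <<- z
            2000 + 180 * z
          } else if (nm == "slope" && !is.null(elev_z)) {
            gx <- cbind(elev_z[, -1] - elev_z[, -nx], 0)
            gy <- rbind(elev_z[-1, ] - elev_z[-ny, ], 0)
            atan(sqrt(gx^2 + gy^2) * 180 / res) * 180 / pi / 10
          } else {
            z
          }
        })
    }
    if (cs$temporal) {
      for (yr in config$years) {
        bands[[paste(nm, yr, sep = ".")]] <- make_one()
      }
    } else {
      bands[[nm]] <- make_one()
    }
  }

  # point/line features; coordinates in metres with origin (0, 0)
  xmax <- nx * res; ymax <- ny * res
  unif_pts <- function(n) data.frame(x = stats::runif(n, 0.05, 0.95) * xmax,
                                     y = stats::runif(n, 0.05, 0.95) * ymax)
  features <- list()
  leks <- unif_pts(config$n_sites)
  leks$site <- seq_len(config$n_sites)
  features$leks <- leks
  # streams as random-walk polylines densified to pixel spacing
  stream_pts <- do.call(rbind, lapply(seq_len(3), function(s) {
    n_step <- nx * 2
    ang <- cumsum(c(stats::runif(1, 0, 2 * pi),
                    stats::rnorm(n_step - 1, 0, 0.25)))
    x <- cumsum(c(stats::runif(1, 0.1, 0.9) * xmax, res * cos(ang[-1])))
    y <- cumsum(c(stats::runif(1, 0.1, 0.9) * ymax, res * sin(ang[-1])))
    keep <- x > 0 & x < xmax & y > 0 & y < ymax
    data.frame(x = x[keep], y = y[keep])
  }))
  features$streams <- stream_pts
  features$springs <- unif_pts(12)
  features$saline_lakes <- unif_pts(3)

  for (cs in config$covariates) {
    if (cs$kind != "distance") next
    f <- features[[cs$name]]
    if (is.null(f) || !nrow(f)) stop("no feature points for ", cs$name)
    bands[[paste0("dist_", cs$name)]] <-
      distance_band(nx, ny, res, f$x, f$y)
  }

  structure(list(nx = nx, ny = ny, res = res, xmin = 0, ymin = 0,
                 bands = bands, features = features,
                 years = config$years, covariates = config$covariates),
            class = "landscape_stack")
}

#' @export
print.landscape_stack <- function(x, ...) {
  cat(sprintf("<landscape_stack> %d x %d px at %g m; %d bands; features: %s\n",
              x$ny, x$nx, x$res, length(x$bands),
              paste(names(x$features), collapse = ", ")))
  invisible(x)
}

#' Fetch a band of a landscape stack as a grid_raster
#'
#' Temporal bands are stored as \code{<name>.<year>}; pass \code{year}
#' to resolve them.
#'
#' @param stack a \code{landscape_stack}.
#' @param name band name.
#' @param year year for temporal bands (ignored when a static band with
#'   this name exists).
#' @return a \code{grid_raster}.
#' @export
stack_band <- function(stack, name, year = NULL) {
  key <- if (name %in% names(stack$bands)) name
         else if (!is.null(year)) paste(name, year, sep = ".")
         else NA_character_
  if (is.na(key) || !key %in% names(stack$bands)) {
    stop("band not found in stack: ", name,
         if (!is.null(year)) paste0(" (year ", year, ")"))
  }
  grid_raster(stack$bands[[key]], stack$xmin, stack$ymin, stack$res)
}

#' Add moving-window bands to a stack
#'
#' For every windowed covariate spec, computes
#' \code{\link{focal_proportion}} at each candidate radius and stores the
#' result as band \code{<name>_r<radius>} (per year for temporal
#' covariates).
#'
#' @param stack a \code{landscape_stack}.
#' @param specs covariate specs (default: the stack's own).
#' @param radii optional radii override applied to every windowed spec.
#' @return the stack with the focal bands added.
#' @export
add_focal_bands <- function(stack, specs = stack$covariates, radii = NULL) {
  for (cs in specs) {
    if (!cs$kind %in% c("proportion", "height")) next
    rr <- if (is.null(radii)) cs$radii else radii
    yrs <- if (cs$temporal) stack$years else NA
    for (yr in yrs) {
      base <- stack_band(stack, cs$name, if (is.na(yr)) NULL else yr)
      for (rad in rr) {
        foc <- focal_proportion(base, rad)
        key <- paste0(cs$name, "_r", format(rad, trim = TRUE))
        if (!is.na(yr)) key <- paste(key, yr, sep = ".")
        stack$bands[[key]] <- foc$values
      }
    }
  }
  stack
}

#' Extract band values at point rows
#'
#' Resolves temporal bands through each row's \code{year} column.
#'
#' @param stack a \code{landscape_stack}.
#' @param pts data.frame with \code{x}, \code{y} (m) and, for temporal
#'   bands, \code{year}.
#' @param bands band names to extract.
#' @return \code{pts} with one new column per band.
#' @export
extract_covariates <- function(stack, pts, bands) {
  for (nm in bands) {
    if (nm %in% names(stack$bands)) {
      pts[[nm]] <- extract_at(stack_band(stack, nm), pts$x, pts$y)
    } else {
      if (!"year" %in% names(pts)) {
        stop("band ", nm, " is temporal but points have no year column")
      }
      v <- rep(NA_real_, nrow(pts))
      for (yr in unique(pts$year)) {
        i <- pts$year == yr
        v[i] <- extract_at(stack_band(stack, nm, yr), pts$x[i], pts$y[i])
      }
      pts[[nm]] <- v
    }
  }
  pts
}
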