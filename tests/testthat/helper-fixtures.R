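# Shared fixtures, built once per test run. All synthetic, all seeded.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

# a compact study system: 3 covariate groups, 2 candidate scales
small_specs <- function() {
  list(
    covariate_spec("pct_sagebrush", "shrubs", "proportion",
                   c(167.9, 1451.7)),
    covariate_spec("pct_pj", "conifer", "proportion", c(167.9, 1451.7)),
    covariate_spec("streams", "streams", "distance"),
    covariate_spec("elevation", "elevation", "topographic"))
}

small_config <- function(seed = 11, ...) {
  defaults <- list(
    nx = 120, ny = 120, seed = seed, years = 2010:2012, n_sites = 4,
    n_animals = 80, covariates = small_specs(), grf_range = 3,
    true_scales = c(shrubs = 167.9, conifer = 1451.7),
    beta_sel = list(
      nest = c(pct_sagebrush = 1.0, pct_pj = -0.8, elevation = 0.6),
      early_brood = c(pct_sagebrush = 0.5),
      late_brood = c(pct_sagebrush = 0.5)),
    beta_surv = list(nest = c(elevation = 0.3), early_brood = c(),
                     late_brood = c()),
    avail_radius = c(nest = 1500, early_brood = 800, late_brood = 1000))
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

small_world <- function() {
  fixture("small_world", function() {
    cfg <- small_config()
    stack <- generate_landscape(cfg)
    truth <- sim_truth(cfg)
    list(cfg = cfg, stack = stack, truth = truth)
  })
}

# design table from 400 used nest points on the small world
small_design <- function() {
  fixture("small_design", function() {
    w <- small_world()
    used <- simulate_used_points(w$stack, w$truth, "nest", 400)
    dt <- build_design_table(w$stack, used, seed = 5)
    dt$used <- used
    dt
  })
}

# a hand-made fit object with known draws, for summary-level tests
fake_fit <- function(draws_named, kind = "rsf", covariates = NULL,
                     n_chains = 2) {
  m <- as.matrix(as.data.frame(draws_named))
  half <- nrow(m) %/% n_chains
  chains <- lapply(seq_len(n_chains), function(ch) {
    coda::mcmc(m[seq_len(half) + (ch - 1) * half, , drop = FALSE])
  })
  structure(list(draws = coda::as.mcmc.list(chains), kind = kind,
                 covariates = covariates %||% setdiff(colnames(m),
                                                      "intercept"),
                 groups = NULL, confounders = character(),
                 random = character(), control = NULL, seed = 1,
                 n = nrow(m)),
            class = "ss_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force focal window mean at one pixel (independent oracle)
brute_focal <- function(vals, res, row, col, radius) {
  d <- dim(vals)
  acc <- c()
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      if (((i - row) * res)^2 + ((j - col) * res)^2 <= radius^2) {
        acc <- c(acc, vals[i, j])
      }
    }
  }
  mean(acc, na.rm = TRUE)
}

quick_ctrl <- function(n_iter = 2000, n_burnin = 800, thin = 1,
                       n_chains = 2, n_adapt = 300) {
  mcmc_control(n_iter, n_burnin, thin, n_chains, n_adapt)
}
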