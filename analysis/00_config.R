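# Shared configuration for the numbered analysis scripts.
# Every script regenerates deterministic inputs from this seed rather
# than serialising the landscape; all tabular artefacts land in results/.

library(selsurv)

SEED <- 20240101 %% 1e6
OUT <- "results"
STAGES <- c("nest", "early_brood", "late_brood")

# a desk-scale study system: 4.5 x 4.5 km at 30 m, 6 subpopulations,
# five windowed covariate groups at two candidate scales plus distance
# and topographic groups (12-group structure scaled down for runtime)
analysis_specs <- function() {
  sc <- c(167.9, 1451.7)
  list(
    covariate_spec("pct_sagebrush", "shrubs", "proportion", sc),
    covariate_spec("sagebrush_height", "shrubs", "height", sc),
    covariate_spec("pct_herbaceous", "herb_meadow", "proportion", sc),
    covariate_spec("pct_bare", "bare_ground", "proportion", sc),
    covariate_spec("pct_pj", "conifer", "proportion", sc),
    covariate_spec("streams", "streams", "distance"),
    covariate_spec("springs", "springs", "distance"),
    covariate_spec("elevation", "elevation", "topographic"),
    covariate_spec("slope", "topography", "topographic"),
    covariate_spec("roughness", "topography", "topographic"))
}

analysis_config <- function() {
  sim_config(
    nx = 150, ny = 150, res = 30, seed = SEED,
    n_sites = 6, years = 2012:2016, n_animals = 180,
    covariates = analysis_specs(), grf_range = 4,
    true_scales = c(shrubs = 167.9, herb_meadow = 439.5,
                    bare_ground = 167.9, conifer = 1451.7,
                    annual_grass = 439.5, burned = 439.5),
    beta_sel = list(
      nest = c(sagebrush_height = 0.8, elevation = 0.6, pct_pj = -0.9,
               pct_bare = -0.5, pct_herbaceous = -0.4),
      early_brood = c(sagebrush_height = 0.6, pct_bare = 0.4,
                      elevation = 0.5, pct_pj = -0.7),
      late_brood = c(sagebrush_height = 0.5, pct_herbaceous = 0.6,
                     elevation = 0.6, pct_pj = -0.6, slope = -0.4)),
    beta_surv = list(
      nest = c(roughness = 0.3, elevation = 0.3),
      early_brood = c(pct_sagebrush = -0.3),
      late_brood = c(springs = 0.3, slope = 0.3)),
    avail_radius = c(nest = 1800, early_brood = 900, late_brood = 1200))
}

# desk-scale effort: used points and monitored units per stage
N_USED <- c(nest = 400, early_brood = 300, late_brood = 300)
N_UNITS <- c(nest = 250, early_brood = 180, late_brood = 160)

# reduced chains for the drivers; the full study protocol
# (3 x 30,000, burn-in 20,000, thin 5) is the package default
CTRL_BLISS <- mcmc_control(2500, 1000, 1, 2, 400)
CTRL_FINAL <- mcmc_control(4000, 1500, 2, 3, 400)
# survival histories are small, so the full study protocol is cheap and
# the random-intercept variances need the length to mix
CTRL_SURV <- mcmc_control(30000, 10000, 5, 3, 1000)

world <- function() {
  cfg <- analysis_config()
  list(cfg = cfg, stack = generate_landscape(cfg), truth = sim_truth(cfg))
}

stage_anchors <- function(stack, truth, stage, used_nests = NULL) {
  if (stage == "nest") return(NULL) # leks by default
  # broods anchor on their female's nest
  used_nests[!duplicated(used_nests$animal),
             c("x", "y", "site", "animal", "year")]
}

dir.create(OUT, showWarnings = FALSE)
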