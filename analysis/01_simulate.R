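# Stage 1: generate the synthetic study system with known ground truth.
# Writes used-location tables, nest/brood encounter histories and a
# truth manifest under results/sim/, plus a couple of landscape bands as
# ASCII grids for inspection.

source("analysis/00_config.R")
dir.create(file.path(OUT, "sim"), recursive = TRUE, showWarnings = FALSE)

w <- world()
message(sprintf("landscape: %d x %d px at %g m, %d bands",
                w$cfg$ny, w$cfg$nx, w$cfg$res, length(w$stack$bands)))
write_asc(stack_band(w$stack, "elevation"),
          file.path(OUT, "sim", "elevation.asc"))
write_asc(stack_band(w$stack, "dist_streams"),
          file.path(OUT, "sim", "dist_streams.asc"))

used_nest <- NULL
for (st in STAGES) {
  anchors <- stage_anchors(w$stack, w$truth, st, used_nest)
  used <- simulate_used_points(w$stack, w$truth, st, N_USED[[st]],
                               anchors = anchors)
  if (st == "nest") used_nest <- used
  utils::write.csv(used, file.path(OUT, "sim", paste0("used_", st, ".csv")),
                   row.names = FALSE)
  message(sprintf("%s: %d used locations from %d females across %d sites",
                  st, nrow(used), length(unique(used$animal)),
                  length(unique(used$site))))

  # monitored units: one location per animal, covariates at truth scales
  units <- used[!duplicated(used$animal), ]
  units <- units[seq_len(min(N_UNITS[[st]], nrow(units))), ]
  units$unit <- seq_len(nrow(units))
  units <- extract_truth_covariates(w$stack, w$truth, st, units)
  eh <- simulate_fates(units, w$truth, st, check_interval = 10)
  utils::write.csv(eh, file.path(OUT, "sim", paste0("eh_", st, ".csv")),
                   row.names = FALSE)
  fail <- sum(eh$y == 0)
  message(sprintf("%s: %d units, %d intervals, %d failures (apparent %d-day survival %.2f)",
                  st, length(unique(eh$unit)), nrow(eh), fail,
                  stage_duration(st),
                  mean(tapply(eh$y, eh$unit, function(z) all(z == 1)))))
}

truth_out <- list(
  seed = w$cfg$seed,
  true_scales = as.list(w$cfg$true_scales),
  beta_sel = lapply(w$cfg$beta_sel, as.list),
  beta_surv = lapply(w$cfg$beta_surv, as.list),
  gamma0 = as.list(w$cfg$gamma0),
  sd = list(site = w$cfg$sd_site, year = w$cfg$sd_year,
            animal = w$cfg$sd_animal))
jsonlite::write_json(truth_out, file.path(OUT, "sim", "truth.json"),
                     auto_unbox = TRUE, digits = NA)
message("wrote ", file.path(OUT, "sim"))
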