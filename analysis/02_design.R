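# Stage 2: build the used/available design tables (5:1 within the 90th
# percentile of movement distances, all candidate variable-scale
# columns, decayed distances, centred/scaled) and standardise the
# encounter-history covariates. Writes results/design/.

source("analysis/00_config.R")
dir.create(file.path(OUT, "design"), recursive = TRUE,
           showWarnings = FALSE)

w <- world()
for (st in STAGES) {
  used <- utils::read.csv(file.path(OUT, "sim",
                                    paste0("used_", st, ".csv")))
  dt <- build_design_table(w$stack, used, seed = SEED + 20)
  utils::write.csv(dt$table,
                   file.path(OUT, "design", paste0("design_", st, ".csv")),
                   row.names = FALSE)
  write_scaling(dt$scaling,
                file.path(OUT, "design", paste0("scaling_", st, ".json")))
  manifest <- list(groups = dt$groups, alphas = as.list(dt$alphas),
                   confounder = dt$confounder,
                   avail_radius = dt$avail_radius)
  jsonlite::write_json(manifest,
                       file.path(OUT, "design",
                                 paste0("manifest_", st, ".json")),
                       auto_unbox = TRUE, digits = NA)
  message(sprintf(
    "%s design: %d rows (%d used), availability radius %.0f m, %d candidate columns in %d groups",
    st, nrow(dt$table), sum(dt$table$used == 1), dt$avail_radius,
    length(dt$covariates), length(dt$groups)))

  # survival covariates: standardise the encounter history's columns
  eh <- utils::read.csv(file.path(OUT, "sim", paste0("eh_", st, ".csv")))
  cov_cols <- setdiff(names(eh), c("unit", "site", "year", "stage",
                                   "entry", "exit", "t", "y", "x", "y_coord"))
  if (length(cov_cols)) {
    sc <- scale_and_center(eh, cov_cols)
    eh <- sc$table
    write_scaling(sc$params,
                  file.path(OUT, "design",
                            paste0("scaling_eh_", st, ".json")))
  }
  utils::write.csv(eh, file.path(OUT, "design", paste0("eh_", st, ".csv")),
                   row.names = FALSE)
}
message("wrote ", file.path(OUT, "design"))
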