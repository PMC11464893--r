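# Stage 3: selection models. Per life stage: withhold individuals for
# validation, run latent-indicator scale selection (BLISS) over the
# covariate groups on the training rows, refit the final model with the
# winning variable-scale per group, and write draws + summaries.

source("analysis/00_config.R")
dir.create(file.path(OUT, "fit_selection"), recursive = TRUE,
           showWarnings = FALSE)

for (st in STAGES) {
  des <- utils::read.csv(file.path(OUT, "design",
                                   paste0("design_", st, ".csv")))
  man <- jsonlite::read_json(file.path(OUT, "design",
                                       paste0("manifest_", st, ".json")),
                             simplifyVector = TRUE)
  sp <- holdout_split(des, "animal", n_withhold = 30, seed = SEED + 30)
  utils::write.csv(sp$test,
                   file.path(OUT, "fit_selection",
                             paste0("test_", st, ".csv")),
                   row.names = FALSE)

  bs <- bliss_select(sp$train, man$groups, kind = "rsf",
                     confounders = man$confounder, response = "used",
                     random = c("site", "year"),
                     control = CTRL_BLISS, seed = SEED + 31)
  utils::write.csv(bs$frequencies,
                   file.path(OUT, "fit_selection",
                             paste0("bliss_", st, ".csv")),
                   row.names = FALSE)
  message(sprintf("%s scale winners: %s", st,
                  paste(names(bs$winners), unname(bs$winners),
                        sep = "=", collapse = ", ")))

  fit <- fit_model(sp$train, "rsf", covariates = unname(bs$winners),
                   confounders = man$confounder,
                   random = c("site", "year", "animal"),
                   control = CTRL_FINAL, seed = SEED + 32)
  gr <- gelman_rubin(fit)
  message(sprintf("%s final RSF: max Gelman-Rubin %.3f", st, max(gr)))
  summ <- fit_summary(fit, level = 0.85)
  utils::write.csv(summ,
                   file.path(OUT, "fit_selection",
                             paste0("summary_", st, ".csv")),
                   row.names = FALSE)
  utils::write.csv(rss(fit),
                   file.path(OUT, "fit_selection",
                             paste0("rss_", st, ".csv")),
                   row.names = FALSE)
  write_draws(fit, file.path(OUT, "fit_selection",
                             paste0("draws_", st, ".csv")))
  jsonlite::write_json(
    list(covariates = fit$covariates, confounders = fit$confounders,
         random = fit$random, seed = fit$seed, max_gelman_rubin = max(gr),
         withheld = sp$withheld_ids),
    file.path(OUT, "fit_selection", paste0("meta_", st, ".json")),
    auto_unbox = TRUE, digits = NA)
  print(summ[, c("parameter", "median", "lower", "upper", "pd")])
}
message("wrote ", file.path(OUT, "fit_selection"))
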