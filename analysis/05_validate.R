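# Stage 5: out-of-sample validation on the withheld individuals.
# Selection: rank cross-validation (Spearman rho, R2, slope) and
# used-habitat calibration envelopes. Survival: Bayesian posterior
# predictive p-value on the survival curves.

source("analysis/00_config.R")
dir.create(file.path(OUT, "validation"), recursive = TRUE,
           showWarnings = FALSE)

report <- list()
for (st in STAGES) {
  meta <- jsonlite::read_json(file.path(OUT, "fit_selection",
                                        paste0("meta_", st, ".json")),
                              simplifyVector = TRUE)
  fit <- read_draws(file.path(OUT, "fit_selection",
                              paste0("draws_", st, ".csv")),
                    kind = "rsf", covariates = meta$covariates,
                    confounders = meta$confounders, random = meta$random)
  test <- utils::read.csv(file.path(OUT, "fit_selection",
                                    paste0("test_", st, ".csv")))
  M <- draw_matrix(fit)
  med <- apply(M[, meta$covariates, drop = FALSE], 2, stats::median)
  lp <- function(df) as.matrix(df[, meta$covariates, drop = FALSE]) %*% med
  w_test <- exp(lp(test[test$used == 1, ]))
  w_ref <- exp(lp(test[test$used == 0, ])) # availability reference
  cv <- rsf_cross_validate(w_test, w_ref, bins = 10)
  message(sprintf(
    "%s selection: Spearman rho = %.2f, R2 = %.2f, slope = %.2f",
    st, cv$rho, cv$r2, cv$slope))

  uhc <- uhc_envelope(fit, test[test$used == 0, ], test[test$used == 1, ],
                      n_draws = 150, seed = SEED + 50)
  for (cv_name in names(uhc$coverage)) {
    utils::write.csv(uhc$envelopes[[cv_name]],
                     file.path(OUT, "validation",
                               paste0("uhc_", st, "_", cv_name, ".csv")),
                     row.names = FALSE)
  }
  message(sprintf("%s calibration coverage: %s", st,
                  paste(names(uhc$coverage),
                        sprintf("%.2f", uhc$coverage),
                        sep = "=", collapse = ", ")))

  smeta <- jsonlite::read_json(file.path(OUT, "fit_survival",
                                         paste0("meta_", st, ".json")),
                               simplifyVector = TRUE)
  sfit <- read_draws(file.path(OUT, "fit_survival",
                               paste0("draws_", st, ".csv")),
                     kind = "survival", covariates = smeta$covariates,
                     random = smeta$random)
  stest <- utils::read.csv(file.path(OUT, "fit_survival",
                                     paste0("test_", st, ".csv")))
  ppc <- survival_ppc(sfit, stest, n_draws = 300, seed = SEED + 51)
  message(sprintf("%s survival: Bayesian predictive p-value = %.2f",
                  st, ppc$p_value))

  report[[st]] <- list(
    cross_validation = list(rho = cv$rho, r2 = cv$r2, slope = cv$slope),
    uhc_coverage = as.list(uhc$coverage),
    survival_ppc = ppc$p_value)
}
jsonlite::write_json(report, file.path(OUT, "validation", "report.json"),
                     auto_unbox = TRUE, digits = NA)
message("wrote ", file.path(OUT, "validation"))
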