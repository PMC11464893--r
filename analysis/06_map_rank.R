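# Stage 6: spatial products. Per life stage: HSI selection surface and
# isopleth categories, cumulative-survival surface and categories from
# failed/successful units; then the composite indices, the
# source-to-sink rank overlay and example management categories against
# a synthetic binary use layer.

source("analysis/00_config.R")
dir.create(file.path(OUT, "maps"), recursive = TRUE, showWarnings = FALSE)

w <- world()
stack_f <- add_focal_bands(w$stack)

sel_surf <- list(); sel_cat <- list()
surv_surf <- list(); surv_vals <- list()
used_all <- list()

for (st in STAGES) {
  meta <- jsonlite::read_json(file.path(OUT, "fit_selection",
                                        paste0("meta_", st, ".json")),
                              simplifyVector = TRUE)
  man <- jsonlite::read_json(file.path(OUT, "design",
                                       paste0("manifest_", st, ".json")),
                             simplifyVector = TRUE)
  fit <- read_draws(file.path(OUT, "fit_selection",
                              paste0("draws_", st, ".csv")),
                    kind = "rsf", covariates = meta$covariates,
                    confounders = meta$confounders)
  scaling <- read_scaling(file.path(OUT, "design",
                                    paste0("scaling_", st, ".json")))
  ss <- predict_selection(fit, stack_f, scaling,
                          alphas = unlist(man$alphas))
  sel_surf[[st]] <- ss
  used <- utils::read.csv(file.path(OUT, "sim",
                                    paste0("used_", st, ".csv")))
  used_all[[st]] <- used
  used_hsi <- extract_at(ss$hsi, used$x, used$y)
  cs <- categorize_selection(ss, used_hsi)
  sel_cat[[st]] <- cs
  write_asc(ss$hsi, file.path(OUT, "maps", paste0("hsi_", st, ".asc")))
  write_categorized(cs, file.path(OUT, "maps", paste0("sel_cat_", st)))
  a <- area_summary(cs)
  message(sprintf(
    "%s selection: %.1f%% high, %.1f%% moderate, %.1f%% low, %.1f%% nonhabitat",
    st, a$pct_of_region[4], a$pct_of_region[3], a$pct_of_region[2],
    a$pct_of_region[1]))

  # survival surface on the generative covariate definition
  smeta <- jsonlite::read_json(file.path(OUT, "fit_survival",
                                         paste0("meta_", st, ".json")),
                               simplifyVector = TRUE)
  sfit <- read_draws(file.path(OUT, "fit_survival",
                               paste0("draws_", st, ".csv")),
                     kind = "survival", covariates = smeta$covariates)
  sscal <- read_scaling(file.path(OUT, "design",
                                  paste0("scaling_eh_", st, ".json")))
  stack_s <- w$stack
  for (nm in smeta$covariates) {
    stack_s$bands[[nm]] <- truth_covariate_raster(w$stack, w$truth,
                                                  nm)$values
  }
  sv <- predict_survival(sfit, stack_s, sscal, days = stage_duration(st))
  surv_surf[[st]] <- sv
  write_asc(sv$cumulative,
            file.path(OUT, "maps", paste0("cumsurv_", st, ".asc")))

  # surface values at failed vs successful unit locations set the
  # class thresholds; a stage whose weak effects leave the surface too
  # flat to separate fates cannot be categorized and is skipped
  eh <- utils::read.csv(file.path(OUT, "design", paste0("eh_", st, ".csv")))
  u1 <- eh[!duplicated(eh$unit), ]
  fate <- tapply(eh$y, eh$unit, function(z) all(z == 1))[
    as.character(u1$unit)]
  pred <- extract_at(sv$cumulative, u1$x, u1$y_coord)
  surv_vals[[st]] <- list(x = u1$x, y = u1$y_coord, fate = unname(fate))
  scat <- tryCatch(categorize_survival(sv, pred[!fate], pred[fate]),
                   error = function(e) {
                     message(st, ": survival categories skipped (", 
                             conditionMessage(e), ")")
                     NULL
                   })
  if (!is.null(scat)) {
    write_categorized(scat, file.path(OUT, "maps",
                                      paste0("surv_cat_", st)))
  }
}

## composite indices over the reproductive period ------------------------
comp_sel <- composite_selection(lapply(sel_surf, `[[`, "hsi"))
used_pool <- do.call(rbind, lapply(used_all, function(u) u[, c("x", "y")]))
comp_used <- extract_at(comp_sel, used_pool$x, used_pool$y)
comp_sel_cat <- categorize_selection(comp_sel, comp_used)
write_asc(comp_sel, file.path(OUT, "maps", "hsi_composite.asc"))
write_categorized(comp_sel_cat, file.path(OUT, "maps",
                                          "sel_cat_composite"))

comp_surv <- composite_survival(lapply(surv_surf, `[[`, "cumulative"),
                                habitat_mask = comp_sel_cat)
# composite thresholds from composite values at unit locations,
# pooled across stages
units_pool <- do.call(rbind, lapply(surv_vals, as.data.frame))
cval <- extract_at(comp_surv, units_pool$x, units_pool$y)
comp_surv_cat <- categorize_survival(comp_surv, cval[!units_pool$fate],
                                     cval[units_pool$fate])
write_asc(comp_surv, file.path(OUT, "maps", "cumsurv_composite.asc"))
write_categorized(comp_surv_cat, file.path(OUT, "maps",
                                           "surv_cat_composite"))

a_sel <- area_summary(comp_sel_cat)
a_surv <- area_summary(comp_surv_cat)
message(sprintf(
  "composite selection: %.1f%% high, %.1f%% moderate, %.1f%% low, %.1f%% nonhabitat",
  a_sel$pct_of_region[4], a_sel$pct_of_region[3], a_sel$pct_of_region[2],
  a_sel$pct_of_region[1]))
message(sprintf(
  "composite survival (habitat only): %.1f%% high, %.1f%% moderate, %.1f%% low, %.1f%% very low",
  a_surv$pct_of_classified[4], a_surv$pct_of_classified[3],
  a_surv$pct_of_classified[2], a_surv$pct_of_classified[1]))

## source-to-sink ranking and management categories ----------------------
rk <- rank_overlay(comp_sel_cat, comp_surv_cat)
write_asc(rk$raster, file.path(OUT, "maps", "rank_composite.asc"),
          digits = 2)
utils::write.csv(rk$area, file.path(OUT, "maps", "rank_area.csv"),
                 row.names = FALSE)
utils::write.csv(rk$legend, file.path(OUT, "maps", "rank_legend.csv"),
                 row.names = FALSE)
prod_ranks <- rk$legend$rank[
  rk$legend$selection_label %in% c("moderate", "high") &
  rk$legend$survival_label %in% c("moderate", "high")]
sink_ranks <- rk$legend$rank[
  rk$legend$selection_label %in% c("moderate", "high") &
  rk$legend$survival_label %in% c("very low", "low")]
n_px <- length(rk$raster$values)
message(sprintf(
  "productive habitat %.1f%%, potentially maladaptive selection %.1f%% of the region",
  100 * sum(rk$raster$values %in% prod_ranks) / n_px,
  100 * sum(rk$raster$values %in% sink_ranks) / n_px))

# synthetic binary use layer: high use within 800 m of a lek
co <- raster_coords(comp_sel)
leks <- w$stack$features$leks
dmin <- rep(Inf, nrow(co))
for (i in seq_len(nrow(leks))) {
  dmin <- pmin(dmin, sqrt((co$x - leks$x[i])^2 + (co$y - leks$y[i])^2))
}
asui <- grid_raster(matrix((dmin < 800) * 1, nrow(comp_sel$values),
                           ncol(comp_sel$values)),
                    comp_sel$xmin, comp_sel$ymin, comp_sel$res)
mc <- management_categories(comp_sel_cat, comp_surv_cat, asui)
write_categorized(mc, file.path(OUT, "maps", "management"))
print(area_summary(mc))
message("wrote ", file.path(OUT, "maps"))
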