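test_that("availability sampling is exactly 5:1 and inherits ids", {
  w <- small_world()
  used <- simulate_used_points(w$stack, w$truth, "nest", 100)
  des <- sample_available(used, stack = w$stack, seed = 2)
  expect_equal(sum(des$used == 1), 100)
  expect_equal(sum(des$used == 0), 500)
  # grouping ids of available rows mirror their used row
  av <- des[des$used == 0, ]
  expect_equal(av$animal, rep(used$animal, each = 5))
  expect_equal(av$site, rep(used$site, each = 5))
  # ratio invariant to seed
  des2 <- sample_available(used, stack = w$stack, seed = 99)
  expect_equal(sum(des2$used == 0) / sum(des2$used == 1), 5)
})

test_that("availability radius follows the order-statistic convention", {
  w <- small_world()
  used <- simulate_used_points(w$stack, w$truth, "nest", 20)
  # equal distances D -> radius D, all available points within D
  des <- sample_available(used, distances = rep(700, 20), seed = 1)
  expect_equal(attr(des, "avail_radius"), 700)
  av <- des[des$used == 0, ]
  expect_true(all(av$dist_anchor <= 700 + 1e-9))
  # 1..100 -> linear interpolation between the 90th and 91st order stats
  d <- sample(1:100)
  des2 <- sample_available(used, distances = d, seed = 1)
  manual <- sort(d)[90] + 0.1 * (sort(d)[91] - sort(d)[90])
  expect_equal(attr(des2, "avail_radius"), manual)
})

test_that("degenerate design inputs are handled", {
  w <- small_world()
  used <- simulate_used_points(w$stack, w$truth, "nest", 20)
  empty <- used[0, ]
  out <- sample_available(empty)
  expect_equal(nrow(out), 0)
  expect_true("used" %in% names(out))
  expect_error(sample_available(used, distances = rep(500, 5)),
               "at least 10")
})

test_that("encounter histories are built interval by interval", {
  v <- data.frame(unit = c(1, 1, 1), day = c(0, 10, 20), fate = c(1, 1, 1))
  eh <- build_encounter_history(v)
  expect_equal(eh$t, c(10, 10))
  expect_equal(eh$y, c(1, 1))
  v2 <- data.frame(unit = 2, day = c(0, 10), fate = c(1, 0))
  eh2 <- build_encounter_history(v2)
  expect_equal(nrow(eh2), 1)
  expect_equal(eh2$y, 0)
  expect_equal(eh2$t, 10)
  # brood schedule: checks every 10 days for 50 days
  v3 <- data.frame(unit = 3, day = seq(0, 50, 10), fate = 1)
  eh3 <- build_encounter_history(v3)
  expect_equal(nrow(eh3), 5)
  expect_equal(sum(eh3$t), 50)
})

test_that("visit-log problems are surfaced", {
  bad <- data.frame(unit = 1, day = c(0, 10, 10), fate = 1)
  expect_error(build_encounter_history(bad), "non-monotone")
  unk <- data.frame(unit = c(1, 1, 2, 2), day = c(0, 10, 0, 10),
                    fate = c(1, NA, 1, 1))
  expect_warning(out <- build_encounter_history(unk), "unknown fate")
  expect_equal(unique(out$unit), 2)
})

test_that("interval covariates come from the interval start", {
  v <- data.frame(unit = 1, day = c(0, 10, 20), fate = 1,
                  cov = c(5, 7, 9))
  eh <- build_encounter_history(v)
  expect_equal(eh$cov, c(5, 7))
})

test_that("simulated fates round-trip through the visit-log builder", {
  w <- small_world()
  units <- data.frame(unit = 1:120, elevation = rnorm(120))
  eh <- simulate_fates(units, w$truth, "nest", check_interval = 10)
  # reconstruct the visit log: a visit at each interval boundary
  visits <- do.call(rbind, lapply(split(eh, eh$unit), function(u) {
    u <- u[order(u$entry), ]
    data.frame(unit = u$unit[1], day = c(u$entry[1], u$exit),
               fate = c(1, u$y))
  }))
  back <- build_encounter_history(visits)
  back <- back[order(back$unit, back$entry), ]
  orig <- eh[order(eh$unit, eh$entry), c("unit", "entry", "exit", "t", "y")]
  rownames(back) <- rownames(orig) <- NULL
  expect_equal(back[, c("unit", "entry", "exit", "t", "y")], orig)
})

test_that("holdout splits by individual with no leakage", {
  df <- data.frame(animal = rep(1:60, each = 4), v = rnorm(240))
  sp <- holdout_split(df, "animal", n_withhold = 15, seed = 2)
  expect_length(sp$withheld_ids, 15)
  expect_equal(sort(unique(c(sp$train$animal, sp$test$animal))), 1:60)
  expect_length(intersect(sp$train$animal, sp$test$animal), 0)
  expect_error(holdout_split(df, "animal", n_withhold = 60), "withhold")
})

test_that("design assembly standardises every candidate column", {
  dt <- small_design()
  expect_equal(sort(unique(unlist(dt$groups))), sort(dt$covariates))
  for (cl in c(dt$covariates, "dist_anchor")) {
    expect_lt(abs(mean(dt$table[[cl]])), 1e-8)
    expect_equal(sqrt(mean((dt$table[[cl]] - mean(dt$table[[cl]]))^2)), 1,
                 tolerance = 1e-8)
  }
  expect_equal(sum(dt$table$used == 0) / sum(dt$table$used == 1), 5)
})
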