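# a stack of two constant-free bands with known values for map algebra
toy_stack <- function(a_vals, b_vals, res = 30) {
  ny <- nrow(a_vals)
  structure(list(nx = ncol(a_vals), ny = ny, res = res, xmin = 0,
                 ymin = 0,
                 bands = list(a = a_vals, b = b_vals),
                 features = list(), years = 2020,
                 covariates = list()),
            class = "landscape_stack")
}

toy_scaling <- data.frame(column = c("a", "b"), mean = c(0, 0),
                          sd = c(1, 1))

test_that("zero covariates give w = 1 and HSI = 0.5 everywhere", {
  st <- toy_stack(matrix(0, 4, 4), matrix(0, 4, 4))
  fit <- fake_fit(list(intercept = rnorm(200, -2),
                       a = rnorm(200, 0.8, 0.01),
                       b = rnorm(200, -0.5, 0.01)),
                  covariates = c("a", "b"))
  ss <- predict_selection(fit, st, toy_scaling)
  expect_equal(range(ss$w$values), c(1, 1))
  expect_equal(range(ss$hsi$values), c(0.5, 0.5))
})

test_that("a +1 SD step in one covariate multiplies the odds by exp(beta)", {
  a <- matrix(c(0, 1, 2, 0.3), 2, 2)
  st <- toy_stack(a, matrix(0, 2, 2))
  fit <- fake_fit(list(intercept = rep(-2, 200), a = rep(0.8, 200),
                       b = rep(-0.5, 200)), covariates = c("a", "b"))
  ss <- predict_selection(fit, st, toy_scaling)
  odds <- ss$hsi$values / (1 - ss$hsi$values)
  expect_equal(odds[2, 1] / odds[1, 1], exp(0.8), tolerance = 1e-9)
  # HSI strictly increasing in the positively selected covariate
  expect_true(all(order(a) == order(ss$hsi$values)))
  expect_true(all(ss$hsi$values > 0 & ss$hsi$values < 1))
})

test_that("missing bands are reported by covariate name", {
  st <- toy_stack(matrix(0, 2, 2), matrix(0, 2, 2))
  fit <- fake_fit(list(intercept = rep(0, 200), zz = rep(1, 200)),
                  covariates = "zz")
  expect_error(predict_selection(fit, st, toy_scaling), "zz")
})

test_that("isopleth thresholds sit at the 50/25/5 percent use levels", {
  set.seed(41)
  used_hsi <- runif(10000)
  surf <- grid_raster(matrix(runif(2500), 50, 50))
  cs <- categorize_selection(surf, used_hsi)
  expect_equal(unname(cs$thresholds), c(0.5, 0.75, 0.95), tolerance = 0.02)
  # by construction ~5% of used points are in the high class
  expect_equal(mean(used_hsi >= cs$thresholds[3]), 0.05, tolerance = 0.005)
  # classes partition the surface
  expect_false(any(is.na(cs$raster$values)))
  expect_setequal(unique(as.vector(cs$raster$values)), 0:3)
})

test_that("tied used values make the isopleths fail loudly", {
  surf <- grid_raster(matrix(runif(100), 10, 10))
  expect_error(categorize_selection(surf, rep(0.7, 100)), "non-monotone")
  expect_error(categorize_selection(surf, runif(10)), "at least 20")
})

test_that("survival categories split failed from successful values", {
  set.seed(42)
  failed <- rnorm(200, 0.2, 0.02)
  success <- rnorm(200, 0.8, 0.02)
  surf <- grid_raster(matrix(seq(0, 1, length.out = 100), 10, 10))
  cs <- categorize_survival(surf, failed, success)
  th <- unname(cs$thresholds)
  expect_equal(th[1], median(failed))
  expect_equal(th[3], median(success))
  expect_equal(th[2], (th[1] + th[3]) / 2)
  expect_true(all(diff(th) > 0))
  # boundaries fall between the clusters
  expect_true(th[2] > 0.3 && th[2] < 0.7)
  # classes partition the masked surface exactly
  expect_setequal(unique(as.vector(cs$raster$values)), 1:4)
  expect_error(suppressWarnings(
    categorize_survival(surf, rep(0.5, 10), rep(0.5, 10))))
  expect_error(categorize_survival(surf, numeric(0), success),
               "non-empty")
})

test_that("survival prediction is the exponentiated flat baseline", {
  st <- toy_stack(matrix(0, 3, 3), matrix(0, 3, 3))
  g0 <- qlogis(0.99)
  fit <- fake_fit(list(intercept = rep(g0, 200)), kind = "survival",
                  covariates = character(0))
  sv <- predict_survival(fit, st, toy_scaling[0, ], days = 38)
  expect_equal(range(sv$ds$values), c(0.99, 0.99), tolerance = 1e-9)
  expect_equal(range(sv$cumulative$values), rep(0.99^38, 2),
               tolerance = 1e-9)
})

test_that("survival surfaces stay in (0,1) and preserve pixel order", {
  a <- matrix(rnorm(16), 4, 4)
  st <- toy_stack(a, matrix(0, 4, 4))
  fit <- fake_fit(list(intercept = rep(3, 200), a = rep(0.5, 200)),
                  kind = "survival", covariates = "a")
  sv <- predict_survival(fit, st, toy_scaling, days = 21)
  expect_true(all(sv$ds$values > 0 & sv$ds$values < 1))
  expect_equal(order(sv$ds$values), order(sv$cumulative$values))
})

test_that("composite selection multiplies max-relativised stages", {
  s <- grid_raster(matrix(runif(64, 0.1, 0.9), 8, 8))
  comp <- composite_selection(list(s, s, s))
  expect_equal(comp$values, (s$values / max(s$values))^3, tolerance = 1e-12)
  expect_equal(max(comp$values), 1)
  expect_equal(order(comp$values), order(s$values))
  z <- s; z$values[3, 3] <- 0
  comp0 <- composite_selection(list(s, s, z))
  expect_equal(comp0$values[3, 3], 0)
  bad <- grid_raster(matrix(0.5, 4, 4))
  expect_error(composite_selection(list(s, bad)), "grid")
})

test_that("composite survival is a true product, masked to habitat", {
  v1 <- grid_raster(matrix(0.38, 2, 2))
  v2 <- grid_raster(matrix(0.9, 2, 2))
  v3 <- grid_raster(matrix(0.82, 2, 2))
  comp <- composite_survival(list(v1, v2, v3))
  expect_equal(comp$values[1, 1], 0.28044, tolerance = 1e-9)
  one <- grid_raster(matrix(1, 2, 2))
  expect_equal(composite_survival(list(v1, one))$values, v1$values)
  mask <- grid_raster(matrix(c(0L, 1L, 2L, NA), 2, 2))
  m <- composite_survival(list(v1, v2), mask)
  expect_true(is.na(m$values[1, 1])) # nonhabitat
  expect_true(is.na(m$values[2, 2])) # unclassified
  expect_equal(m$values[2, 1], 0.38 * 0.9)
})

# build categorized surfaces holding the full 3 x 4 combination table
overlay_fixture <- function() {
  sel <- matrix(rep(1:3, each = 4), 3, 4, byrow = TRUE)
  surv <- matrix(rep(1:4, 3), 3, 4, byrow = TRUE)
  list(
    sel = structure(list(raster = grid_raster(sel),
                         labels = c(`0` = "nonhabitat", `1` = "low",
                                    `2` = "moderate", `3` = "high"),
                         kind = "selection"),
                    class = "categorized_surface"),
    surv = structure(list(raster = grid_raster(surv),
                          labels = c(`1` = "very low", `2` = "low",
                                     `3` = "moderate", `4` = "high"),
                          kind = "survival"),
                     class = "categorized_surface"))
}

test_that("the overlay rank truth table is exact on all 12 cells", {
  fx <- overlay_fixture()
  rk <- rank_overlay(fx$sel, fx$surv)
  expected <- matrix(NA_integer_, 3, 4)
  for (s in 1:3) {
    for (v in 1:4) {
      expected[s, v] <- if (v >= 2) (v - 2) * 3 + s + 3 else 4 - s
    }
  }
  expect_equal(rk$raster$values, expected)
  expect_setequal(as.vector(rk$raster$values), 1:12)
  # extremes: high selection x high survival on top,
  # high selection x very low survival at the bottom
  expect_equal(rk$raster$values[3, 4], 12)
  expect_equal(rk$raster$values[3, 1], 1)
  expect_equal(rk$legend$rank[1], 12)
  expect_equal(rk$legend$selection_label[1], "high")
  expect_equal(rk$legend$survival_label[1], "high")
  expect_equal(sum(rk$area$percent), 100, tolerance = 1e-9)
})

test_that("nonhabitat carries no rank; unclassified habitat errors", {
  fx <- overlay_fixture()
  sel0 <- fx$sel
  sel0$raster$values[1, 1] <- 0L
  rk <- rank_overlay(sel0, fx$surv)
  expect_true(is.na(rk$raster$values[1, 1]))
  holes <- fx$surv
  holes$raster$values[2, 2] <- NA
  expect_error(rank_overlay(fx$sel, holes), "unclassified")
})

test_that("pixel areas convert at 900 square metres per pixel", {
  sel <- structure(list(raster = grid_raster(matrix(3L, 100, 100),
                                             res = 30),
                        labels = c(`3` = "high"), kind = "selection"),
                   class = "categorized_surface")
  surv <- structure(list(raster = grid_raster(matrix(4L, 100, 100),
                                              res = 30),
                         labels = c(`4` = "high"), kind = "survival"),
                    class = "categorized_surface")
  rk <- rank_overlay(sel, surv)
  expect_equal(sum(rk$area$km2), 10000 * 900 / 1e6) # 9 km2
})

test_that("management categories follow the rule table", {
  sel <- matrix(c(3L, 0L, 2L, 3L, 1L, 0L), 2, 3)
  surv <- matrix(c(4L, NA, 2L, 1L, 3L, NA), 2, 3)
  asui <- grid_raster(matrix(c(1, 1, 0, 0, 1, 0), 2, 3))
  selc <- structure(list(raster = grid_raster(sel),
                         labels = c(`0` = "nonhabitat", `1` = "low",
                                    `2` = "moderate", `3` = "high"),
                         kind = "selection"),
                    class = "categorized_surface")
  survc <- structure(list(raster = grid_raster(surv),
                          labels = c(`1` = "very low", `2` = "low",
                                     `3` = "moderate", `4` = "high"),
                          kind = "survival"),
                     class = "categorized_surface")
  mc <- management_categories(selc, survc, asui)
  v <- mc$raster$values
  expect_equal(v[1, 1], 1L) # high sel, high surv, high use -> priority+
  expect_equal(v[2, 1], 3L) # nonhabitat in high use -> general
  expect_equal(v[1, 2], 4L) # moderate sel, low use -> other
  expect_equal(v[2, 2], 3L) # high sel, low use -> general
  expect_equal(v[1, 3], 2L) # low sel in high use -> priority
  expect_equal(v[2, 3], NA_integer_) # nonhabitat, low use -> unclassified
  expect_message(out <- management_categories(selc, survc, NULL), "ASUI")
  expect_null(out)
})

test_that("area summaries report both denominators", {
  cs <- structure(list(raster = grid_raster(matrix(c(0L, 1L, 1L, NA),
                                                   2, 2)),
                       labels = c(`0` = "nonhabitat", `1` = "low"),
                       kind = "selection"),
                  class = "categorized_surface")
  a <- area_summary(cs)
  expect_equal(a$pixels, c(1, 2))
  expect_equal(sum(a$pct_of_classified), 100)
  expect_equal(sum(a$pct_of_region), 75)
})
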