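test_that("rank cross-validation calibrates on self-generated points", {
  w <- small_world()
  wmap <- truth_selection_weights(w$stack, w$truth, "nest")$values
  set.seed(6)
  pick <- sample.int(length(wmap), 2000, replace = TRUE, prob = wmap)
  cv <- rsf_cross_validate(wmap[pick], as.vector(wmap), bins = 10)
  expect_gte(cv$rho, 0.9)
  expect_gt(cv$slope, 0.7)
  expect_lt(cv$slope, 1.3)
  expect_equal(sum(cv$table$observed), 2000)
})

test_that("uninformative test points give a near-zero slope", {
  w <- small_world()
  wmap <- truth_selection_weights(w$stack, w$truth, "nest")$values
  set.seed(7)
  pick <- sample.int(length(wmap), 2000, replace = TRUE) # uniform use
  cv <- rsf_cross_validate(wmap[pick], as.vector(wmap), bins = 10)
  expect_lt(abs(cv$slope), 0.3)
})

test_that("perfect monotone bin ordering yields rho = 1", {
  ref <- rep(1:10, each = 100) + runif(1000, 0, 0.5)
  test <- rep(9.6, 50) # all in the top bin
  cv <- rsf_cross_validate(test, ref, bins = 10)
  expect_equal(cv$rho, stats::cor(cv$table$observed, 1:10,
                                  method = "spearman"))
  inc <- unlist(lapply(1:10, function(b) rep(b + 0.2, b * 10)))
  cv2 <- rsf_cross_validate(inc, ref, bins = 10)
  expect_equal(cv2$rho, 1)
})

test_that("rank cross-validation is invariant to monotone transforms", {
  w <- small_world()
  wmap <- truth_selection_weights(w$stack, w$truth, "nest")$values
  set.seed(8)
  pick <- sample.int(length(wmap), 1000, replace = TRUE, prob = wmap)
  cv_raw <- rsf_cross_validate(wmap[pick], as.vector(wmap))
  cv_log <- rsf_cross_validate(log(wmap[pick]), log(as.vector(wmap)))
  expect_equal(cv_raw$rho, cv_log$rho)
  expect_equal(cv_raw$table$observed, cv_log$table$observed)
})

test_that("a flat surface cannot be binned", {
  expect_error(rsf_cross_validate(rep(1, 10), rep(1, 100)), "bins")
})

make_uhc_fit <- function(beta, n_draws = 300) {
  set.seed(20)
  fake_fit(list(intercept = rnorm(n_draws, -1.6, 0.05),
                a = rnorm(n_draws, beta, 0.05)), covariates = "a")
}

test_that("calibration envelopes cover self-consistent test data", {
  set.seed(21)
  avail <- data.frame(a = rnorm(4000))
  fit <- make_uhc_fit(1.0)
  w <- exp(1.0 * avail$a)
  test <- data.frame(a = avail$a[sample.int(4000, 500, replace = TRUE,
                                            prob = w)])
  u <- uhc_envelope(fit, avail, test, n_draws = 150, seed = 2)
  expect_gte(u$coverage[["a"]], 0.9)
})

test_that("a shifted covariate distribution breaks calibration", {
  set.seed(22)
  avail <- data.frame(a = rnorm(4000))
  fit <- make_uhc_fit(1.0)
  test <- data.frame(a = rnorm(500, 3, 0.5)) # +3 SD shift
  u <- uhc_envelope(fit, avail, test, n_draws = 150, seed = 2)
  expect_lt(u$coverage[["a"]], 0.5)
})

test_that("a null model predicts the availability distribution", {
  set.seed(23)
  avail <- data.frame(a = rnorm(4000))
  fit <- make_uhc_fit(0)
  test <- data.frame(a = rnorm(500)) # fresh draw from availability
  u <- uhc_envelope(fit, avail, test, n_draws = 150, seed = 2)
  expect_gte(u$coverage[["a"]], 0.9)
})

test_that("degenerate covariates are skipped with a warning", {
  avail <- data.frame(a = rnorm(500), flat = 1)
  test <- data.frame(a = rnorm(100), flat = 1)
  fit <- make_uhc_fit(0.5)
  expect_warning(
    u <- uhc_envelope(fit, avail, test, covariates = c("a", "flat"),
                      n_draws = 120, seed = 2), "degenerate")
  expect_false("flat" %in% names(u$coverage))
})

make_surv_fit <- function(g0, n_draws = 400) {
  fake_fit(list(intercept = rnorm(n_draws, g0, 0.03)), kind = "survival",
           covariates = character(0))
}

sim_test_eh <- function(n, ds, duration = 38, check = 10, seed = 1) {
  set.seed(seed)
  checks <- unique(c(seq(check, duration, check), duration))
  entry <- c(0, checks[-length(checks)])
  fail <- rgeom(n, 1 - ds) + 1
  do.call(rbind, lapply(seq_len(n), function(i) {
    if (fail[i] > duration) {
      k <- seq_along(checks); y <- rep(1, length(k))
    } else {
      k <- seq_len(which(fail[i] <= checks)[1])
      y <- c(rep(1, length(k) - 1), 0)
    }
    data.frame(unit = i, entry = entry[k], exit = checks[k],
               t = checks[k] - entry[k], y = y)
  }))
}

test_that("the survival PPC is calibrated for well-specified data", {
  ds <- 0.975
  fit <- make_surv_fit(qlogis(ds))
  test <- sim_test_eh(300, ds, seed = 31)
  p <- survival_ppc(fit, test, n_draws = 300, seed = 3)
  expect_gte(p$p_value, 0.1)
  expect_lte(p$p_value, 0.9)
})

test_that("the survival PPC flags badly misspecified survival", {
  ds_model <- 0.99
  fit <- make_surv_fit(qlogis(ds_model))
  # truth two logits below the model
  test <- sim_test_eh(300, plogis(qlogis(ds_model) - 2), seed = 32)
  p <- survival_ppc(fit, test, n_draws = 300, seed = 3)
  expect_lt(p$p_value, 0.05)
})

test_that("an all-survive test set still yields a valid p-value", {
  fit <- make_surv_fit(qlogis(0.999))
  checks <- c(10, 20, 30, 38)
  test <- do.call(rbind, lapply(1:40, function(i) {
    data.frame(unit = i, entry = c(0, checks[-4]), exit = checks,
               t = diff(c(0, checks)), y = 1)
  }))
  p <- survival_ppc(fit, test, n_draws = 200, seed = 4)
  expect_gte(p$p_value, 0)
  expect_lte(p$p_value, 1)
  expect_error(survival_ppc(fit, test[0, ]), "empty")
})

test_that("the exposure curve estimator matches a hand computation", {
  eh <- data.frame(exit = c(10, 10, 10, 20, 20), y = c(1, 1, 0, 1, 0))
  km <- km_exposure(eh)
  expect_equal(km$surv, c(2 / 3, 2 / 3 * 1 / 2))
})
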