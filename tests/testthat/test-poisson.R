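test_that("intercept-only MLE is the log sample mean", {
  f <- fit_poisson(data.frame(y = c(2L, 4L, 6L)), "y")
  expect_equal(unname(coef(f)), log(4), tolerance = 1e-8)
  expect_equal(f$r2_dev, 0)
  expect_equal(f$k, 0)
})

test_that("coefficients are recovered from near-noiseless simulation", {
  set.seed(42)
  x <- as.numeric(scale(rnorm(2000)))
  # huge counts make the relative Poisson noise negligible
  y <- rpois(2000, exp(8 + 0.5 * x))
  f <- fit_poisson(data.frame(x = x, y = y), "y", "x")
  expect_equal(unname(coef(f)), c(8, 0.5), tolerance = 1e-2)
})

test_that("fit agrees with stats::glm on the same data", {
  set.seed(43)
  d <- std_design(200, 3)
  d <- sim_counts(d, c(`(Intercept)` = 2, x1 = 0.4, x2 = -0.3), 99)
  f <- fit_poisson(d, "y", c("x1", "x2", "x3"))
  ref <- glm(y ~ x1 + x2 + x3, data = d, family = poisson())
  sref <- summary(ref)$coefficients
  expect_equal(unname(coef(f)), unname(coef(ref)), tolerance = 1e-8)
  expect_equal(f$coefficients$std.error, unname(sref[, 2]), tolerance = 1e-6)
  expect_equal(f$coefficients$p.value, unname(sref[, 4]), tolerance = 1e-6)
  expect_equal(f$deviance, deviance(ref), tolerance = 1e-8)
  expect_equal(f$AIC, AIC(ref), tolerance = 1e-6)
  expect_equal(f$BIC, BIC(ref), tolerance = 1e-6)
})

test_that("deviance and adjusted pseudo-R2 behave like nested-model statistics", {
  set.seed(44)
  d <- std_design(300, 4)
  d <- sim_counts(d, c(`(Intercept)` = 3, x1 = 0.5), 7)
  fits <- lapply(0:4, function(k) fit_poisson(d, "y", head(paste0("x", 1:4), k)))
  devs <- vapply(fits, function(f) f$deviance, numeric(1))
  # adding a predictor never increases residual deviance
  expect_true(all(diff(devs) <= 1e-8))
  for (f in fits) {
    expect_lte(f$deviance, f$null.deviance + 1e-8)
    expect_gte(f$r2_dev, 0)
    expect_lte(f$r2_dev, 1)
    expect_lte(f$r2_adj, f$r2_dev + 1e-12)
    # the stated adjustment formula, recomputed directly
    expect_equal(f$r2_adj,
                 1 - (1 - f$r2_dev) * (f$n - 1) / (f$n - f$k - 1),
                 tolerance = 1e-12)
  }
})

test_that("significance codes follow the printed thresholds", {
  expect_equal(signif_code(c(0.0005, 0.005, 0.049, 0.09, 0.2)),
               c("***", "**", "*", "•", ""))
  set.seed(45)
  d <- std_design(500, 2)
  d <- sim_counts(d, c(`(Intercept)` = 3, x1 = 0.3), 5)
  f <- fit_poisson(d, "y", c("x1", "x2"))
  td <- tidy(f)
  expect_identical(td$signif, signif_code(td$p.value))
})

test_that("best subset agrees with a naive double-loop enumeration", {
  set.seed(46)
  d <- std_design(120, 4)
  d <- sim_counts(d, c(`(Intercept)` = 2.5, x1 = 0.6, x3 = -0.4), 13)
  cand <- paste0("x", 1:4)
  bs <- best_subset(d, "y", cand, criterion = "BIC")
  # oracle: loop all subsets via stats::glm and BIC()
  best_crit <- Inf
  best_set <- NULL
  for (k in 0:4) {
    for (s in utils::combn(cand, k, simplify = FALSE)) {
      fml <- if (k == 0) y ~ 1 else
        stats::reformulate(s, response = "y")
      crit <- BIC(glm(fml, data = d, family = poisson()))
      if (crit < best_crit - 1e-10) {
        best_crit <- crit
        best_set <- s
      }
    }
  }
  expect_setequal(bs$best$predictors, best_set)
  expect_equal(min(bs$results$criterion), best_crit, tolerance = 1e-6)
  # the selected criterion value is minimal over the explicit ranking
  expect_equal(bs$best$BIC, min(bs$results$criterion), tolerance = 1e-6)
})

test_that("best subset finds the signal and drops noise predictors", {
  set.seed(47)
  d <- std_design(500, 3)
  d <- sim_counts(d, c(`(Intercept)` = 3, x1 = 0.8), 21)
  bs <- best_subset(d, "y", paste0("x", 1:3))
  expect_identical(bs$best$predictors, "x1")
  # zero-signal: BIC should mostly pick the empty model
  empty <- vapply(1:20, function(s) {
    set.seed(s + 900)
    d0 <- std_design(200, 3)
    d0$y <- rpois(200, 30)
    length(best_subset(d0, "y", paste0("x", 1:3))$best$predictors) == 0
  }, logical(1))
  expect_gte(mean(empty), 0.6)
})

test_that("candidate cap and tie-breaks are enforced", {
  d <- std_design(50, 2)
  d$y <- rpois(50, 10)
  expect_error(
    best_subset(d, "y", paste0("x", 1:21)),
    "max_k",
    fixed = FALSE
  )
  # max_k caps subset size
  set.seed(48)
  d2 <- std_design(100, 4)
  d2 <- sim_counts(d2, c(`(Intercept)` = 3, x1 = 0.5, x2 = 0.5, x3 = 0.5), 3)
  bs <- best_subset(d2, "y", paste0("x", 1:4), max_k = 2)
  expect_lte(bs$best$k, 2)
})

test_that("report_table mirrors the cross-group layout", {
  set.seed(49)
  d <- std_design(200, 3)
  dA <- sim_counts(d, c(`(Intercept)` = 3, x1 = 0.5), 1)
  dB <- sim_counts(d, c(`(Intercept)` = 3, x3 = -0.5), 2)
  fits <- list(
    GroupA = fit_poisson(dA, "y", "x1"),
    GroupB = fit_poisson(dB, "y", "x3")
  )
  tbl <- report_table(fits, environment_vars = "x1",
                      landscape_vars = c("x2", "x3"))
  expect_named(tbl, c("section", "term", "GroupA", "GroupB"))
  expect_equal(tbl$term[1], "(Intercept)")
  expect_equal(tbl$term[nrow(tbl)], "R2_adj")
  # unselected cells are dashed
  expect_equal(tbl$GroupB[tbl$term == "x1"], "–")
  expect_equal(tbl$GroupA[tbl$term == "x3"], "–")
  # coefficient cells carry the significance code
  a_cell <- tbl$GroupA[tbl$term == "x1"]
  expect_match(a_cell, "^-?[0-9.]+")
  expect_equal(tbl$section[tbl$term == "x3"], "Landscape factors")
})
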