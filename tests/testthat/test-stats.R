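test_that("percent change follows the reference-denominator convention", {
  expect_identical(pct_change(1.6, 0.83), 48.1)
  expect_identical(pct_change(26.16, 5.94), 77.3)
  expect_identical(pct_change(3, 3), 0)
  expect_error(pct_change(0, 1), "positive")
  expect_error(pct_change(-2, 1), "positive")
  ## scale invariance: pct_change(ca, cb) == pct_change(a, b)
  set.seed(1)
  for (i in 1:20) {
    a <- runif(1, 0.1, 30); b <- runif(1, 0, 30); c <- runif(1, 0.1, 9)
    expect_equal(pct_change(c * a, c * b, digits = Inf),
                 pct_change(a, b, digits = Inf), tolerance = 1e-9)
  }
})

test_that("rank-sum p-values match full enumeration on small samples", {
  r <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p.value, 0.1)       # 2/20 labelings as extreme
  expect_equal(r$p.value, rank_sum_enum_p(c(1, 2, 3), c(4, 5, 6)))
  set.seed(2)
  for (i in 1:5) {
    x <- rnorm(8); y <- rnorm(8, 0.8)
    expect_lt(abs(compare_groups(x, y)$p.value - rank_sum_enum_p(x, y)),
              0.01)
  }
  ## identical samples -> p ~ 1 under the approximation
  z <- c(1, 2, 3, 4, 5)
  expect_gt(compare_groups(z, z)$p.value, 0.9)
  expect_error(compare_groups(numeric(0), 1:3), "non-empty")
})

test_that("OLS coefficients match the normal-equation oracle to 1e-8", {
  set.seed(3)
  for (i in 1:5) {
    tab <- simulate_roi_table(n = 60, seed = i)
    fit <- backward_stepwise(tab, alpha_remove = 1)  # keep the full model
    X <- cbind(1, tab$asl_um, tab$pcl_um, tab$cbf_hz, tab$ciliation_pct,
               tab$metachronous, tab$metachrony_proportion,
               tab$metachronous * tab$cbf_hz)
    beta <- solve(t(X) %*% X, t(X) %*% tab$mct_mm_min)
    expect_lt(max(abs(fit$coefficients$estimate - as.numeric(beta))), 1e-8)
  }
})

test_that("a perfectly linear single predictor is recovered exactly", {
  tab <- data.frame(asl_um = 1:30, mct_mm_min = 2 + 0.7 * (1:30))
  ## summary.lm warns about the essentially perfect fit; that is the point
  fit <- suppressWarnings(backward_stepwise(tab, predictors = "asl_um"))
  expect_equal(fit$coefficients["asl_um", "estimate"], 0.7, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1)
  expect_identical(fit$retained, "asl_um")
})

test_that("stepwise elimination keeps true effects and reports its trace", {
  tab <- simulate_roi_table(n = 200, beta_met = 5, beta_asl = 0.3,
                            sigma = 2, seed = 9)
  fit <- backward_stepwise(tab)
  expect_true(all(c("metachronous", "asl_um") %in% fit$retained))
  expect_true(all(fit$coefficients[-1, "p.value"] < 0.10))
  expect_setequal(c(fit$retained, fit$eliminated),
                  c("asl_um", "pcl_um", "cbf_hz", "ciliation_pct",
                    "metachronous", "metachrony_proportion",
                    "metachronous:cbf_hz"))
  ## retention is invariant to predictor column order
  fit2 <- backward_stepwise(tab, predictors = rev(c(
    "asl_um", "pcl_um", "cbf_hz", "ciliation_pct", "metachronous",
    "metachrony_proportion", "metachronous:cbf_hz")))
  expect_setequal(fit2$retained, fit$retained)
})

test_that("aliased predictors are dropped with a warning, not an error", {
  tab <- simulate_roi_table(n = 80, seed = 4)
  tab$dup <- tab$asl_um
  expect_warning(
    fit <- backward_stepwise(tab, predictors = c("asl_um", "dup",
                                                 "metachronous")),
    "aliased")
  expect_false("dup" %in% fit$retained)
})

test_that("null predictors are mostly eliminated at the 0.10 threshold", {
  set.seed(6)
  n_empty <- 0L
  for (i in 1:30) {
    tab <- simulate_roi_table(n = 100, beta_met = 0, beta_asl = 0,
                              sigma = 2, seed = 1000 + i)
    fit <- backward_stepwise(tab)
    if (length(fit$retained) == 0L) n_empty <- n_empty + 1L
  }
  ## with 7 null predictors tested at alpha = 0.10 the intercept-only
  ## model is recovered roughly (1 - 0.1)^7 ~ half the time; require a
  ## clear majority of eliminations overall rather than a spurious model
  expect_gte(n_empty / 30, 0.35)
})
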