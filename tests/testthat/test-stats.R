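test_that("replicate summary reproduces the healthy-serum triplets", {
  dcr3 <- replicate_summary(c(29.89, 24.95, 26.87))
  expect_equal(dcr3$mean, 27.23, tolerance = 0.01)
  expect_equal(dcr3$sd, 2.49, tolerance = 0.005)
  expect_equal(dcr3$cv_percent, 9.14, tolerance = 0.005)
  gdf15 <- replicate_summary(c(97.96, 98.66, 97.72))
  expect_equal(gdf15$mean, 98.11, tolerance = 0.005)
  expect_equal(gdf15$sd, 0.49, tolerance = 0.005)
  expect_equal(gdf15$cv_percent, 0.5, tolerance = 0.005)
})

test_that("replicate summary matches a two-pass oracle and edge cases", {
  set.seed(13)
  for (i in 1:10) {
    x <- rnorm(sample(2:20, 1), mean = 50, sd = 5)
    s <- replicate_summary(x)
    m <- sum(x) / length(x)
    v <- sum((x - m)^2) / (length(x) - 1)
    expect_equal(s$mean, m, tolerance = 1e-12)
    expect_equal(s$sd, sqrt(v), tolerance = 1e-12)
    expect_equal(s$cv_percent, 100 * sqrt(v) / m, tolerance = 1e-12)
  }
  same <- replicate_summary(c(3, 3, 3))
  expect_equal(same$sd, 0)
  expect_equal(same$cv_percent, 0)
  expect_warning(one <- replicate_summary(5), "fewer than 2")
  expect_true(is.na(one$sd))
})

test_that("sd-percent-of-mean reproduces the printed variability figures", {
  expect_equal(sd_percent_of_mean(79.31, 164.44), 48.2, tolerance = 0.05)
  expect_equal(sd_percent_of_mean(411.78, 378.1), 108.9, tolerance = 0.05)
  expect_equal(sd_percent_of_mean(39.25, 62.59), 62.7, tolerance = 0.05)
  expect_equal(sd_percent_of_mean(0, 10), 0)
})

test_that("enrichment bookkeeping reproduces stated and strict forms", {
  expect_equal(enrichment_factor(94.9, 97.6), 92.62, tolerance = 0.005)
  expect_equal(enrichment_factor(94.9, 100), 94.9)
  expect_equal(enrichment_factor(94.9, 100, mode = "strict"), 1 / 0.051,
               tolerance = 1e-9)
  # stated mode is linear in recovery
  r <- c(20, 40, 80)
  f <- vapply(r, function(x) enrichment_factor(94.9, x), 0)
  expect_equal(f[3] / f[1], 4)
  expect_warning(inf <- enrichment_factor(100, 50, mode = "strict"),
                 "infinite")
  expect_true(is.infinite(inf))
})

test_that("normalization rescaling reproduces the chromatogram factor", {
  expect_equal(apply_normalization(2000, 14.52), 137.74, tolerance = 0.005)
  expect_equal(apply_normalization(42, 1), 42)
  expect_equal(apply_normalization(apply_normalization(42, 14.52), 1 / 14.52),
               42, tolerance = 1e-12)
})

test_that("qPCR relative expression follows 2^(Ct_ref - Ct_target)", {
  expect_equal(delta_ct_expression(20, 20), 1)
  expect_equal(delta_ct_expression(20, 21), 2)
  expect_equal(delta_ct_expression(23.32, 20), 2^-3.32, tolerance = 1e-12)
  expect_equal(delta_ct_expression(23.32, 20), 0.1, tolerance = 0.002)
})

test_that("calibration fits recover exact lines and their signs", {
  lv <- c(10, 30, 100, 300)
  perfect <- fit_linearity(calibration_series(lv, lv / 50))
  expect_equal(perfect$r, 1)
  expect_equal(perfect$intercept, 0, tolerance = 1e-12)
  expect_equal(perfect$slope, 1 / 50, tolerance = 1e-12)
  anti <- fit_linearity(calibration_series(lv, -lv))
  expect_equal(anti$r, -1)
  expect_error(fit_linearity(calibration_series(c(1, 2), c(1, 2))),
               "3 distinct")
})

test_that("linearity r is invariant to sign-preserving affine rescaling", {
  set.seed(17)
  s <- calibration_series(c(10, 30, 100, 300),
                          c(10, 30, 100, 300) / 50 * rlnorm(4, 0, 0.03))
  r0 <- fit_linearity(s)$r
  s2 <- s; s2$level <- 3 * s2$level + 7; s2$ratio <- 0.5 * s2$ratio - 1
  expect_equal(fit_linearity(s2)$r, r0, tolerance = 1e-12)
})

test_that("method comparison returns rank and linear correlations", {
  x <- c(1, 2, 3, 4, 5)
  ident <- compare_methods(x, x, method = "pearson")
  expect_equal(ident$r, 1)
  mono <- compare_methods(x, exp(x))
  expect_equal(mono$r, 1)              # Spearman: rank invariance
  expect_lt(compare_methods(x, exp(x), "pearson")$r, 1)
  expect_error(compare_methods(x, rep(1, 5)), "constant")
  # paired signal + noise recovers a positive correlation
  set.seed(19)
  truth <- rnorm(30, 100, 30)
  a <- truth + rnorm(30, 0, 10); b <- truth + rnorm(30, 0, 10)
  cm <- compare_methods(a, b)
  expect_gt(cm$r, 0.5)
  expect_lt(cm$p_value, 0.05)
})

test_that("group stats follow box-plot semantics", {
  g <- group_stats(1:9)
  expect_equal(g$median, 5)
  expect_equal(g$q1, 3)
  expect_equal(g$q3, 7)
  expect_true(g$q1 <= g$median && g$median <= g$q3)
  expect_equal(g$whisker_high - g$mean, g$sd)
  single <- group_stats(4.2)
  expect_equal(single$median, 4.2)
  expect_equal(single$mean, 4.2)
  expect_true(is.na(single$sd))
})
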