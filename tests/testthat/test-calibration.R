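test_that("weighted fit matches the normal-equations oracle on random sets", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(3:12, 1)
    x <- exp(runif(n, log(0.03), log(100)))
    y <- runif(1, 10, 5000) * x * exp(rnorm(n, 0, 0.2)) + rnorm(n, 0, 5)
    for (wt in c("1/x", "1/x^2", "none")) {
      w <- switch(wt, "1/x" = 1 / x, "1/x^2" = 1 / x^2, "none" = rep(1, n))
      fit <- fit_weighted_line(x, y, wt)
      ora <- wls_oracle(x, y, w)
      expect_equal(fit$slope, ora$slope, tolerance = 1e-10)
      expect_equal(fit$intercept, ora$intercept, tolerance = 1e-10)
    }
  }
})

test_that("noiseless series gives the exact line and full R-squared", {
  pts <- make_points(slope = 1000, intercept = 0)
  fit <- fit_weighted_line(pts$nominal_concentration, pts$peak_area, "1/x")
  expect_equal(fit$slope, 1000, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  fit2 <- fit_weighted_line(c(1, 3), c(1, 3), "none")
  expect_equal(fit2$slope, 1, tolerance = 1e-12)
  expect_equal(fit2$intercept, 0, tolerance = 1e-12)
})

test_that("degenerate designs are rejected", {
  expect_error(fit_weighted_line(c(1, 1), c(0, 2), "none"),
               class = "rrfq_degenerate_design_error")
  expect_error(fit_weighted_line(c(0, 1), c(0, 1), "1/x"),
               class = "rrfq_value_error")
})

test_that("slope is invariant to permutation and replicate duplication", {
  set.seed(7)
  pts <- make_points(area_fun = function(c) 500 * c * exp(rnorm(length(c), 0, 0.05)))
  fit <- fit_weighted_line(pts$nominal_concentration, pts$peak_area, "1/x")
  perm <- sample(nrow(pts))
  fitp <- fit_weighted_line(pts$nominal_concentration[perm],
                            pts$peak_area[perm], "1/x")
  expect_equal(fitp$slope, fit$slope, tolerance = 1e-12)
  dup <- rbind(pts, pts)
  fitd <- fit_weighted_line(dup$nominal_concentration, dup$peak_area, "1/x")
  expect_equal(fitd$slope, fit$slope, tolerance = 1e-12)
  expect_equal(fitd$intercept, fit$intercept, tolerance = 1e-10)
})

test_that("1/x weighting shrinks low-end relative residuals on heteroscedastic data", {
  set.seed(11)
  reps <- 200
  rel_w <- rel_u <- numeric(reps)
  for (i in seq_len(reps)) {
    pts <- make_points(area_fun = function(c) {
      1000 * c * exp(rnorm(length(c), 0, 0.1))
    })
    fw <- fit_weighted_line(pts$nominal_concentration, pts$peak_area, "1/x")
    fu <- fit_weighted_line(pts$nominal_concentration, pts$peak_area, "none")
    low <- pts$nominal_concentration <= 0.3
    pred_w <- fw$intercept + fw$slope * pts$nominal_concentration[low]
    pred_u <- fu$intercept + fu$slope * pts$nominal_concentration[low]
    truth <- 1000 * pts$nominal_concentration[low]
    rel_w[i] <- mean(abs(pred_w - truth) / truth)
    rel_u[i] <- mean(abs(pred_u - truth) / truth)
  }
  expect_lt(median(rel_w), median(rel_u))
})

test_that("back-calculation accuracy is the stated arithmetic", {
  curve <- list(slope = 1000, intercept = 0)
  expect_equal(back_calc_accuracy(curve, 1000 * 10, 10), 100)
  expect_equal(back_calc_accuracy(curve, 9000, 10), 90)
  # 115% boundary case stays inside the default closed band
  expect_equal(back_calc_accuracy(curve, 115000, 100), 115)
  expect_error(back_calc_accuracy(list(slope = 0, intercept = 0), 1, 1),
               class = "rrfq_undefined_accuracy_error")
})

test_that("bias filter excludes saturated levels and the refit recovers the slope", {
  slope_true <- 2000
  pts <- make_points(area_fun = function(c) slope_true * c / (1 + c / 50))
  curve <- fit_calibration(pts, run_config(), "m", "positive")
  expect_true(100 %in% curve$excluded_levels$level)
  surv <- setdiff(unique(pts$nominal_concentration),
                  curve$excluded_levels$level)
  # oracle: refit on the surviving subset only
  keep <- pts$nominal_concentration %in% surv
  ora <- fit_weighted_line(pts$nominal_concentration[keep],
                           pts$peak_area[keep], "1/x")
  expect_equal(curve$slope, ora$slope, tolerance = 1e-12)
  expect_equal(curve$n_points_used, length(surv))
})

test_that("a top level at half its linear response is excluded and the slope recovered exactly", {
  pts <- make_points(area_fun = function(c) ifelse(c == 100, 50000, 1000 * c))
  curve <- fit_calibration(pts, run_config(), "m", "positive")
  expect_equal(curve$excluded_levels$level, 100)
  expect_equal(curve$slope, 1000, tolerance = 1e-9)
  expect_equal(curve$n_points_used, 7)
  expect_true(curve$quantifiable)
})

test_that("clean linear data passes the bias filter untouched", {
  pts <- make_points(slope = 1234, intercept = 0)
  curve <- fit_calibration(pts, run_config(), "m", "positive")
  expect_equal(nrow(curve$excluded_levels), 0)
  expect_true(curve$quantifiable)
  expect_equal(curve$r_squared, 1, tolerance = 1e-12)
  expect_equal(curve$slope, 1234, tolerance = 1e-9)
})

test_that("too few surviving levels yields a non-quantifiable curve, not an error", {
  # only the two lowest levels respond linearly; the rest are wildly biased
  pts <- make_points(area_fun = function(c) {
    ifelse(c <= 0.3, 1000 * c, 1000 * c * 0.2)
  })
  curve <- fit_calibration(pts, run_config(), "m", "positive")
  expect_false(curve$quantifiable)
  expect_match(curve$reason, "bias filter|level")
  # fewer distinct levels than min_points short-circuits the same way
  few <- make_points(levels = c(1, 10), slope = 100)
  curve2 <- fit_calibration(few, run_config(), "m", "positive")
  expect_false(curve2$quantifiable)
})

test_that("LOD follows the closed form and rejects non-positive solutions", {
  curve <- list(slope = 100, intercept = 0)
  expect_equal(estimate_lod(curve, noise_level = 50, sn_threshold = 2), 1.0)
  # intercept already above the noise threshold: extrapolates negative
  neg <- estimate_lod(list(slope = 100, intercept = 200), 50, 2)
  expect_true(is.na(neg))
  expect_match(attr(neg, "reason"), "non-positive")
  # degenerate threshold 0 with zero intercept -> LOD 0, undefined
  z <- estimate_lod(curve, noise_level = 50, sn_threshold = 0)
  expect_true(is.na(z))
  expect_true(is.na(estimate_lod(list(slope = -1, intercept = 0), 10)))
  # monotone non-decreasing in the noise level when defined
  lods <- vapply(seq(10, 500, by = 10),
                 function(nl) estimate_lod(curve, nl, 2), numeric(1))
  expect_true(all(diff(lods) >= 0))
})

test_that("LOQ is the lowest detected level", {
  pts <- make_points(slope = 1000)
  expect_equal(estimate_loq(pts, detection_threshold = 0), 0.03)
  expect_true(is.na(estimate_loq(pts, detection_threshold = 1e9)))
  # only the top level clears the threshold
  expect_equal(estimate_loq(pts, detection_threshold = 99000), 100)
  expect_error(estimate_loq(pts, detection_threshold = -1),
               class = "rrfq_value_error")
})
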