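test_that("calibration on an exact line returns exact coefficients", {
  conc <- seq(2.5, 20, by = 2.5)
  cur <- -5e-9 * conc + 3e-7
  fit <- calibration_fit(conc, cur)
  expect_equal(fit$slope, -5e-9, tolerance = 1e-12)
  expect_equal(fit$intercept, 3e-7, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$linear_range, c(2.5, 20))
  expect_error(calibration_fit(conc[1:4], cur[1:4]), "at least 5")
  expect_error(calibration_fit(rep(5, 6), rnorm(6)), "distinct")
})

test_that("an outlier is flagged by the studentized-residual rule", {
  conc <- seq(2.5, 20, by = 2.5)
  set.seed(21)
  cur <- -5e-9 * conc + 3e-7 + rnorm(8, 0, 1.155e-9)
  cur[4] <- cur[4] + 10 * 1.155e-9
  fit <- calibration_fit(conc, cur)
  expect_true(4 %in% fit$outlier_flags)
})

test_that("concentration prediction inverts the calibration line", {
  fit <- calibration_fit(seq(2.5, 20, 2.5), -5e-9 * seq(2.5, 20, 2.5) + 3e-7)
  expect_equal(predict(fit, -5e-9 * 10 + 3e-7), 10, tolerance = 1e-9)
  expect_warning(p <- predict(fit, 3.2e-7), "negative")
  expect_lt(p, 0)
})

test_that("LOD/LOQ keep their exact 10:3 ratio and algebra", {
  ll <- lod_loq(1.155e-9, -5e-9)
  expect_equal(ll[["loq"]] / ll[["lod"]], 10 / 3, tolerance = 1e-12)
  expect_equal(ll[["loq"]], 2.31, tolerance = 1e-9)
  expect_equal(lod_loq(0, 5e-9), c(lod = 0, loq = 0))
  expect_error(lod_loq(1e-9, 0), "nonzero")
  # sign of the slope is irrelevant
  expect_equal(lod_loq(1e-9, -2e-9), lod_loq(1e-9, 2e-9))
})

test_that("repeatability statistics use the n-1 standard deviation", {
  st <- repeatability_rsd(c(246, 247, 247, 251, 253))
  expect_equal(st$mean, 248.8)
  expect_equal(st$sd, sd(c(246, 247, 247, 251, 253)))
  expect_equal(round(st$sd, 2), 3.03)
  expect_equal(round(st$rsd_percent, 2), 1.22)
  same <- repeatability_rsd(c(5, 5, 5))
  expect_equal(same$sd, 0)
  expect_equal(same$rsd_percent, 0)
  expect_error(repeatability_rsd(c(1, 2)), "at least 3")
  expect_error(repeatability_rsd(c(-1, 0, 1)), "mean is zero")
})

test_that("tablet assay agrees with repeatability on the same list", {
  x <- c(246, 247, 247, 251, 253)
  a <- assay_tablet(x, 250)
  r <- repeatability_rsd(x)
  expect_equal(a$mean, r$mean)
  expect_equal(a$sd, r$sd)
  expect_equal(a$rsd_percent, r$rsd_percent)
  expect_equal(a$mean_percent_of_label, 100 * 248.8 / 250)
  # a zero-content tablet is kept, not silently excluded
  z <- assay_tablet(c(0, 250, 250), 250)
  expect_equal(z$n, 3L)
  expect_gt(z$sd, 100)
  expect_error(assay_tablet(x, -250), "positive")
})

test_that("recovery analysis computes per-sample recoveries and bias", {
  st <- recovery_analysis(rep(0.10, 5), c(0.09, 0.08, 0.08, 0.11, 0.12))
  expect_equal(st$recovery_percent, c(90, 80, 80, 110, 120))
  expect_equal(st$mean, 96)
  expect_equal(st$bias_percent, st$mean - 100)   # identity by construction
  perfect <- recovery_analysis(c(1, 2, 3), c(1, 2, 3))
  expect_equal(perfect$mean, 100)
  expect_equal(perfect$bias_percent, 0)
  over <- recovery_analysis(c(1, 2), c(1.1, 2.2))
  expect_equal(over$mean, 110, tolerance = 1e-12)
  expect_equal(over$sd, 0, tolerance = 1e-9)
  expect_equal(over$bias_percent, 10, tolerance = 1e-12)
  expect_error(recovery_analysis(c(1, 2), c(1, 2, 3)), "equal length")
})

test_that("current rescaling scales the line but not LOD/LOQ", {
  cal <- gen_calibration(tr_default, seed = 31)
  f1 <- calibration_fit(cal$conc_um, cal$current_a)
  f2 <- calibration_fit(cal$conc_um, cal$current_a * 50)
  expect_equal(f2$slope, f1$slope * 50, tolerance = 1e-12)
  expect_equal(f2$intercept, f1$intercept * 50, tolerance = 1e-12)
  expect_equal(f2$residual_sd, f1$residual_sd * 50, tolerance = 1e-12)
  expect_equal(f2$lod, f1$lod, tolerance = 1e-12)
  expect_equal(f2$loq, f1$loq, tolerance = 1e-12)
})

test_that("stochastic calibration reproduces its generating scatter", {
  # residual SD chosen so the population R^2 is 0.97 over 2.5-20 uM
  concs <- seq(2.5, 20, 2.5)
  sigma97 <- 5e-9 * sd(concs) * sqrt(0.03 / 0.97)
  tr97 <- ground_truth(calib = c(slope = -5e-9, intercept = 3e-7,
                                 residual_sd = sigma97))
  r2 <- vapply(1:200, function(s) {
    cal <- gen_calibration(tr97, seed = s)
    calibration_fit(cal$conc_um, cal$current_a)$r_squared
  }, numeric(1))
  expect_gt(median(r2), 0.94)
  expect_lt(median(r2), 0.99)
  # default residual SD: detection limit recovered within 5% (median;
  # the n-1 SD estimator is slightly low-biased at 6 residual df)
  lods <- vapply(1:200, function(s) {
    cal <- gen_calibration(tr_default, seed = s)
    calibration_fit(cal$conc_um, cal$current_a)$lod
  }, numeric(1))
  lod_true <- 3 * 1.155e-9 / 5e-9
  expect_lt(abs(median(lods) - lod_true) / lod_true, 0.05)
})

test_that("simulated replicates reproduce their generating %RSD", {
  rsds <- vapply(1:500, function(s) {
    set.seed(s)
    repeatability_rsd(rnorm(5, 100, 2))$rsd_percent
  }, numeric(1))
  expect_lt(abs(mean(rsds) - 2), 0.2)
})
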