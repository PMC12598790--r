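test_that("relative viscosity has the right closed forms", {
  # unchanged flow times: every value is exactly 1
  fl <- flow_time_series(100, rep(160, 5), seq(0, 4e-4, 1e-4), 1.2e-4)
  rv <- relative_viscosity_series(fl)
  expect_equal(rv$rel_visc, rep(1, 5))
  expect_equal(rv$r, seq(0, 4e-4, 1e-4) / 1.2e-4)
  # doubled specific viscosity: cube root of two
  fl2 <- flow_time_series(100, c(160, 220, 220), c(0, 1e-4, 2e-4), 1.2e-4)
  rv2 <- relative_viscosity_series(fl2)
  expect_equal(rv2$rel_visc[2:3], rep(2^(1/3), 2), tolerance = 1e-12)
})

test_that("relative viscosity error handling", {
  fl <- flow_time_series(100, c(95, 160, 165), c(0, 1e-4, 2e-4), 1.2e-4)
  expect_error(relative_viscosity_series(fl), "eta0")
  fl2 <- flow_time_series(100, c(160, 90, 165), c(0, 1e-4, 2e-4), 1.2e-4)
  expect_warning(rv <- relative_viscosity_series(fl2), "flagged")
  expect_true(is.nan(rv$rel_visc[2]))
})

test_that("relative viscosity is invariant to rescaling all flow times", {
  fl <- gen_flow_times(tr_default, noise_sd = 0.005, seed = 4)
  rv1 <- relative_viscosity_series(fl)
  fl2 <- flow_time_series(attr(fl, "t0") * 3, fl$t * 3, fl$ligand_conc,
                          attr(fl, "dna_conc"))
  rv2 <- relative_viscosity_series(fl2)
  expect_equal(rv2$rel_visc, rv1$rel_visc, tolerance = 1e-12)
})

test_that("viscosity trend test distinguishes flat from rising series", {
  r <- seq(0.25, 3, by = 0.25)
  expect_identical(
    viscosity_trend_test(data.frame(r = r, rel_visc = rep(1, 12)))$trend,
    "flat")
  # intercalator-like: ~20% rise over the r range
  intr <- ground_truth(visc_slope = 0.073)
  rv <- relative_viscosity_series(gen_flow_times(intr, noise_sd = 0.002,
                                                 seed = 8))
  expect_identical(viscosity_trend_test(rv)$trend, "increasing")
  # small (~0.7% in cube-root units) drift stays practically flat
  drift <- data.frame(r = r, rel_visc = 1 + 0.0023 * r)
  expect_identical(viscosity_trend_test(drift)$trend, "flat")
  expect_error(viscosity_trend_test(data.frame(r = 1:3,
                                               rel_visc = rep(1, 3))),
               "at least 4")
})

test_that("Herschel-Bulkley fit recovers noise-free parameters", {
  rh <- gen_rheogram(tr_default, noise_sd = 0)
  fit <- herschel_bulkley_fit(rh, shear_rate_eval = 500)
  expect_lt(rel_err(fit$tau0, 0.32), 1e-3)
  expect_lt(rel_err(fit$k, 5.95e-5), 1e-3)
  expect_lt(rel_err(fit$n, 1.57), 1e-3)
  # residuals essentially zero on model-consistent data
  expect_lt(fit$sse / sum(rh$shear_stress^2), 1e-16)
  # apparent viscosity from the fitted curve
  tau500 <- 0.32 + 5.95e-5 * 500^1.57
  expect_equal(fit$eta_app, tau500 / 500, tolerance = 1e-6)
})

test_that("Herschel-Bulkley reduces to Newtonian flow", {
  rates <- seq(50, 1000, length.out = 20)
  rh <- rheogram(rates, 0.016 * rates)   # tau0 = 0, n = 1
  fit <- herschel_bulkley_fit(rh)
  expect_lt(abs(fit$n - 1), 1e-6)
  expect_lt(rel_err(fit$k, 0.016), 1e-6)
  expect_lt(fit$tau0, 1e-8)
  expect_error(herschel_bulkley_fit(rheogram(rates, rep(0, 20))),
               "zero")
})
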