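test_that("baseline correction leaves flat and linear backgrounds at zero", {
  pot <- seq(0.8, 1.6, length.out = 401)
  zero <- voltammogram(pot, rep(0, 401))
  expect_equal(baseline_correct(zero, 21)$current, rep(0, 401))
  ramp <- voltammogram(pot, 1e-8 + 4e-8 * pot)
  corr <- baseline_correct(ramp, 21)$current
  expect_lt(max(abs(corr)) / diff(range(ramp$current)), 0.01)
})

test_that("baseline correction preserves peak height and is idempotent", {
  vg <- gen_voltammogram(tr_default, noise_sd = 0)
  bc <- baseline_correct(vg, 151)
  pk <- find_peak_current(bc, c(0.95, 1.25))
  expect_lt(rel_err(pk$ip, tr_default$peak_heights[["dGuo"]]), 0.02)
  bc2 <- baseline_correct(bc, 151)
  expect_lt(max(abs(bc2$current - bc$current)) / max(bc$current), 1e-3)
  expect_error(baseline_correct(vg, 20), "odd")
  expect_error(baseline_correct(vg, 1e5), "smaller")
})

test_that("peak finding locates both base-oxidation peaks", {
  bc <- baseline_correct(gen_voltammogram(tr_default, noise_sd = 0), 151)
  dguo <- find_peak_current(bc, c(0.95, 1.25))
  dado <- find_peak_current(bc, c(1.25, 1.50))
  expect_true(dguo$found && dado$found)
  expect_lt(abs(dguo$ep - 1.09), 0.002)   # within a grid step
  expect_lt(abs(dado$ep - 1.36), 0.002)
  # all-noise input: nothing above the noise floor
  set.seed(13)
  noise <- voltammogram(bc$potential, rnorm(nrow(bc), 0, 1e-9))
  expect_false(find_peak_current(noise, c(0.95, 1.25))$found)
  # zero peak heights: no peak either
  silent <- gen_voltammogram(ground_truth(peak_heights = c(dGuo = 0,
                                                           dAdo = 0)),
                             noise_sd = 0)
  expect_false(find_peak_current(baseline_correct(silent, 151),
                                 c(0.95, 1.25))$found)
  expect_error(find_peak_current(bc, c(2, 3)), "no data")
})

test_that("suppression regression inverts its generating model", {
  kb <- tr_default$kb_electro[["dGuo"]]
  concs <- seq(5e-6, 40e-6, by = 5e-6)
  s_free <- tr_default$peak_heights[["dGuo"]]
  s_complex <- s_free / (1 + kb * concs)
  fit <- electro_binding_fit(concs, s_complex, s_free)
  expect_lt(rel_err(fit$kb, kb), 1e-10)
  expect_equal(fit$slope, 1, tolerance = 1e-9)
  # half suppression at [drug] = 1/Kb sits exactly on the line
  expect_equal(10^(fit$intercept + fit$slope *
                     log10((s_free / 2) / (s_free - s_free / 2))),
               kb, tolerance = 1e-9)
})

test_that("suppression fit through the full peak pipeline stays within 1%", {
  concs <- seq(5e-6, 40e-6, by = 5e-6)
  ip_at <- function(L) {
    v <- gen_voltammogram(tr_default, drug_conc = L, noise_sd = 0)
    find_peak_current(baseline_correct(v, 151), c(0.95, 1.25))$ip
  }
  s_free <- ip_at(0)
  s_complex <- vapply(concs, ip_at, numeric(1))
  fit <- electro_binding_fit(concs, s_complex, s_free)
  expect_lt(rel_err(fit$kb, tr_default$kb_electro[["dGuo"]]), 0.01)
})

test_that("suppression fit validation and unit invariance", {
  concs <- c(5e-6, 1e-5, 2e-5, 4e-5)
  s_free <- 3e-7
  sc <- s_free / (1 + 6.02e4 * concs)
  f1 <- electro_binding_fit(concs, sc, s_free)
  f2 <- electro_binding_fit(concs, sc * 1e3, s_free * 1e3)
  expect_equal(f2$kb, f1$kb, tolerance = 1e-12)
  expect_warning(
    f3 <- electro_binding_fit(c(concs, 8e-5), c(sc, s_free * 1.1), s_free),
    "excluded")
  expect_equal(f3$n_points, 4L)
  expect_error(suppressWarnings(
    electro_binding_fit(concs[1:3], c(sc[1], s_free, s_free), s_free)),
    "fewer than 3")
})
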