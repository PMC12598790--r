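test_that("Stern-Volmer fit recovers the generating constant exactly", {
  qs <- gen_quench_series(tr_default, "hoechst", noise_sd = 0)
  fit <- stern_volmer_fit(qs)
  expect_lt(rel_err(fit$kb, 1.63e3), 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-10)
  et <- stern_volmer_fit(gen_quench_series(tr_default, "etbr",
                                           noise_sd = 0))
  expect_lt(rel_err(et$kb, 1.17e2), 1e-12)
})

test_that("Stern-Volmer input validation", {
  s <- titration_series(c(1e-5, 2e-5, 3e-5), c(900, 800, 700), 1.5e-4,
                        kind = "fluorescence")
  expect_error(stern_volmer_fit(s), "zero-quencher")
  s2 <- titration_series(c(0, 1e-5, 2e-5), c(1000, -5, 700), 1.5e-4,
                         kind = "fluorescence")
  expect_error(stern_volmer_fit(s2), "positive")
})

test_that("double-log fit returns n = 1 on Stern-Volmer data", {
  t1 <- ground_truth(n_true = 1, kb_quench = 1.63e3)
  qs <- gen_quench_series(t1, "hoechst", noise_sd = 0)
  fit <- double_log_fit(qs)
  expect_lt(abs(fit$n_stoichiometry - 1), 1e-6)
  expect_lt(rel_err(fit$kb, 1.63e3), 1e-6)
})

test_that("double-log fit recovers a non-unit stoichiometry", {
  qs <- gen_quench_series(tr_default, noise_sd = 0, model = "double_log")
  fit <- double_log_fit(qs)
  expect_lt(rel_err(fit$kb, 2.57e4), 1e-3)
  expect_lt(rel_err(fit$n_stoichiometry, 1.17), 1e-3)
})

test_that("unquenched interior points are excluded with a warning", {
  q <- c(0, 5e-5, 1e-4, 1.5e-4, 2e-4)
  i <- c(1000, 1005, 900, 850, 800)   # second point not quenched
  s <- titration_series(q, i, 1.5e-4, kind = "fluorescence")
  expect_warning(fit <- double_log_fit(s), "excluded")
  expect_equal(fit$n_points, 3L)
  # too few usable points is an error
  s2 <- titration_series(q[1:4], c(1000, 1005, 1010, 900), 1.5e-4,
                         kind = "fluorescence")
  expect_error(suppressWarnings(double_log_fit(s2)), "fewer than 3")
})

test_that("Ksv, Kb and n are invariant to intensity rescaling", {
  qs <- gen_quench_series(tr_default, "hoechst", noise_sd = 0.01, seed = 5)
  qs2 <- titration_series(qs$ligand_conc, qs$response * 321,
                          attr(qs, "macromolecule_conc"),
                          kind = "fluorescence")
  expect_equal(stern_volmer_fit(qs2)$kb, stern_volmer_fit(qs)$kb,
               tolerance = 1e-12)
  d1 <- double_log_fit(qs); d2 <- double_log_fit(qs2)
  expect_equal(d2$kb, d1$kb, tolerance = 1e-12)
  expect_equal(d2$n_stoichiometry, d1$n_stoichiometry, tolerance = 1e-12)
})

test_that("displacement comparison calls the displaced probe", {
  mk <- function(ksv) {
    t <- ground_truth(ksv_true = c(etbr = ksv[1], hoechst = ksv[2]))
    list(e = stern_volmer_fit(gen_quench_series(t, "etbr", noise_sd = 0)),
         h = stern_volmer_fit(gen_quench_series(t, "hoechst", noise_sd = 0)))
  }
  f <- mk(c(1.17e2, 1.63e3))
  out <- displacement_compare(f$e, f$h)
  expect_identical(as.character(out), "groove_probe_displaced")
  expect_equal(attr(out, "ratio"), 1.63e3 / 1.17e2, tolerance = 1e-9)
  f2 <- mk(c(1.63e3, 1.17e2))   # swapped
  expect_identical(as.character(displacement_compare(f2$e, f2$h)),
                   "intercalator_probe_displaced")
  f3 <- mk(c(5e2, 5e2))
  expect_identical(as.character(displacement_compare(f3$e, f3$h)),
                   "indeterminate")
})
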