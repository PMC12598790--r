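groove_evidence <- function() {
  list(
    kb_by_method = list(benesi_hildebrand = 3.22e4, double_log = 2.57e4,
                        electrochemical = 6.02e4),
    delta_tm = 5.4,
    viscosity_trend = "flat",
    displaced_probe = "groove_probe_displaced",
    spectral = list(change = "hyperchromic", peak_shift_nm = NA_real_),
    force_class = "electrostatic"
  )
}

intercalator_evidence <- function() {
  list(
    kb_by_method = list(electrochemical = 1e7),
    delta_tm = 11,
    viscosity_trend = "increasing",
    displaced_probe = "intercalator_probe_displaced"
  )
}

test_that("the full groove evidence set yields a minor-groove call", {
  rep <- aggregate_evidence(groove_evidence())
  expect_identical(rep$mode_call, "minor_groove")
  expect_equal(rep$votes[["groove"]], 5)
  expect_equal(rep$votes[["intercalation"]], 0)
  # every fired rule points at an evidence key actually present
  keys <- vapply(rep$rule_trace, `[[`, character(1), "evidence_key")
  expect_true(all(keys %in% names(rep$evidence)))
  # the force class is recorded but never votes
  r6 <- Filter(function(t) t$rule == "R6_force_class", rep$rule_trace)
  expect_identical(r6[[1]]$vote, "none")
})

test_that("the intercalator evidence set yields an intercalation call", {
  rep <- aggregate_evidence(intercalator_evidence())
  expect_identical(rep$mode_call, "intercalation")
  expect_gte(rep$votes[["intercalation"]], 4)
})

test_that("sparse or conflicting evidence is indeterminate", {
  expect_identical(aggregate_evidence(list(delta_tm = 11.6))$mode_call,
                   "indeterminate")   # a single vote is not enough
  tie <- aggregate_evidence(list(delta_tm = 5.4,
                                 viscosity_trend = "increasing"))
  expect_identical(tie$mode_call, "indeterminate")
  expect_error(aggregate_evidence(list()), "empty")
})

test_that("thermodynamic-only evidence can yield an electrostatic call", {
  rep <- aggregate_evidence(list(force_class = "electrostatic"))
  expect_identical(rep$mode_call, "electrostatic")
  # but never when structural evidence exists
  rep2 <- aggregate_evidence(list(force_class = "electrostatic",
                                  delta_tm = 5.4))
  expect_false(rep2$mode_call == "electrostatic")
})

test_that("adding groove evidence never flips a groove call", {
  base <- list(kb_by_method = list(double_log = 2.57e4), delta_tm = 5.4)
  expect_identical(aggregate_evidence(base)$mode_call, "minor_groove")
  more <- c(base, list(viscosity_trend = "flat",
                       displaced_probe = "groove_probe_displaced"))
  expect_identical(aggregate_evidence(more)$mode_call, "minor_groove")
})

test_that("calls are reproducible from the serialized evidence alone", {
  rep <- aggregate_evidence(groove_evidence())
  again <- aggregate_evidence(rep$evidence)
  expect_identical(again$mode_call, rep$mode_call)
  expect_identical(again$votes, rep$votes)
  expect_identical(again$rule_trace, rep$rule_trace)
})

test_that("run_report aggregates all stages into a groove call", {
  rep <- run_report(paper_like_config())
  expect_identical(rep$mode_call, "minor_groove")
  expect_gte(rep$votes[["groove"]], 4)
  expect_length(rep$stage_errors, 0)
  expect_equal(rep$stages$melting$delta_tm, 5.4, tolerance = 1e-3)
})

test_that("run_report handles subsets, failures and empty configs", {
  expect_error(run_report(list()), "no technique")
  # melting only: one vote, indeterminate call
  cfg <- paper_like_config()["melting"]
  rep <- run_report(cfg)
  expect_identical(names(rep$evidence), "delta_tm")
  expect_identical(rep$mode_call, "indeterminate")
  # a failing stage is recorded and the rest still runs
  cfg2 <- paper_like_config()[c("melting", "uv")]
  cfg2$uv <- "/nonexistent/titration.csv"
  rep2 <- run_report(cfg2)
  expect_named(rep2$stage_errors, "uv")
  expect_equal(rep2$evidence$delta_tm, 5.4, tolerance = 1e-3)
})

test_that("two runs on identical inputs write identical JSON", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg <- paper_like_config(noise = 0.01, seed = 99)
  run_report(cfg, out_dir = d1)
  run_report(cfg, out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d2, f)),
                     readLines(file.path(d1, f)))
  }
  expect_true("report.json" %in% list.files(d1))
  parsed <- jsonlite::read_json(file.path(d1, "report.json"))
  expect_equal(parsed$schema_version, 1L)
  expect_identical(parsed$mode_call, "minor_groove")
})
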