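#' Aggregate multi-technique evidence into a binding-mode call
#'
#' Formalises the narrative synthesis used to assign a binding mode from
#' orthogonal experiments. Each available evidence key fires one rule, in a
#' fixed order, and contributes a groove or intercalation vote:
#'
#' * R1 binding-constant magnitude: any method's Kb in
#'   `kb_groove_range` (default \[1e3, 1e5)) votes groove; any Kb at or
#'   above `kb_intercalation_min` (default 1e6) votes intercalation.
#' * R2 melting shift: [interpret_delta_tm()] on `delta_tm`.
#' * R3 viscosity trend: flat votes groove, increasing votes intercalation.
#' * R4 dye displacement: `"groove_probe_displaced"` votes groove,
#'   `"intercalator_probe_displaced"` votes intercalation.
#' * R5 spectral change: hyperchromism without a large red shift
#'   (> 15 nm) is a non-intercalative (groove) vote.
#' * R6 thermodynamic force class: recorded descriptively, never a vote
#'   (sign rules describe forces, not binding-site geometry).
#'
#' The call is the vote majority; ties or fewer than `min_votes` votes give
#' `"indeterminate"`. `"electrostatic"` is emitted only when the force
#' class is electrostatic and no structural evidence (binding constants,
#' melting shift, viscosity, displacement, spectra) is present at all.
#'
#' @param evidence Named list; recognised keys: `kb_by_method` (named
#'   numeric, 1/M), `delta_tm` (deg C), `viscosity_trend` (`"flat"`,
#'   `"increasing"`, `"decreasing"`), `displaced_probe` (a
#'   [displacement_compare()] result), `spectral` (list with `change` and
#'   optional `peak_shift_nm`, or the bare change string), `force_class`.
#'   Unknown keys are carried through untouched.
#' @param kb_groove_range,kb_intercalation_min,intercalation_min,groove_max
#'   Rule thresholds (see above and [interpret_delta_tm()]).
#' @param min_votes Minimum number of votes for a non-indeterminate call
#'   (default 2).
#' @return Object of class `binding_mode_report`: `evidence` (as given),
#'   `mode_call`, `votes` (named counts), `rule_trace` (one entry per fired
#'   rule: rule id, evidence key, input, vote), `schema_version`.
#' @export
aggregate_evidence <- function(evidence,
                               kb_groove_range = c(1e3, 1e5),
                               kb_intercalation_min = 1e6,
                               intercalation_min = 10,
                               groove_max = 6,
                               min_votes = 2L) {
  if (!is.list(evidence) || length(evidence) == 0L)
    stop("empty evidence", call. = FALSE)
  trace <- list()
  vote <- function(rule, key, input, v) {
    trace[[length(trace) + 1L]] <<- list(rule = rule, evidence_key = key,
                                         input = input, vote = v)
  }

  kb <- evidence$kb_by_method
  if (!is.null(kb)) {
    kb <- unlist(kb)
    if (any(kb >= kb_groove_range[1L] & kb < kb_groove_range[2L]))
      vote("R1_kb_magnitude", "kb_by_method",
           paste(signif(kb, 3), collapse = ", "), "groove")
    if (any(kb >= kb_intercalation_min))
      vote("R1_kb_magnitude", "kb_by_method",
           paste(signif(kb, 3), collapse = ", "), "intercalation")
  }
  if (!is.null(evidence$delta_tm)) {
    itp <- interpret_delta_tm(evidence$delta_tm,
                              intercalation_min = intercalation_min,
                              groove_max = groove_max)
    if (itp == "groove_consistent")
      vote("R2_delta_tm", "delta_tm", evidence$delta_tm, "groove")
    else if (itp == "intercalation_consistent")
      vote("R2_delta_tm", "delta_tm", evidence$delta_tm, "intercalation")
    else
      vote("R2_delta_tm", "delta_tm", evidence$delta_tm, "none")
  }
  if (!is.null(evidence$viscosity_trend)) {
    vt <- evidence$viscosity_trend
    if (vt == "flat")
      vote("R3_viscosity", "viscosity_trend", vt, "groove")
    else if (vt == "increasing")
      vote("R3_viscosity", "viscosity_trend", vt, "intercalation")
    else
      vote("R3_viscosity", "viscosity_trend", vt, "none")
  }
  if (!is.null(evidence$displaced_probe)) {
    dp <- as.character(evidence$displaced_probe)
    if (dp == "groove_probe_displaced")
      vote("R4_displacement", "displaced_probe", dp, "groove")
    else if (dp == "intercalator_probe_displaced")
      vote("R4_displacement", "displaced_probe", dp, "intercalation")
    else
      vote("R4_displacement", "displaced_probe", dp, "none")
  }
  if (!is.null(evidence$spectral)) {
    sp <- evidence$spectral
    change <- if (is.list(sp)) sp$change else as.character(sp)
    shift <- if (is.list(sp)) sp$peak_shift_nm %||% NA_real_ else NA_real_
    if (identical(change, "hyperchromic") &&
        (is.na(shift) || shift <= 15))
      vote("R5_spectral", "spectral", change, "groove")
    else
      vote("R5_spectral", "spectral", change, "none")
  }
  if (!is.null(evidence$force_class))
    vote("R6_force_class", "force_class",
         as.character(evidence$force_class), "none")

  votes <- vapply(trace, function(t) t$vote, character(1L))
  n_groove <- sum(votes == "groove")
  n_inter <- sum(votes == "intercalation")
  total <- n_groove + n_inter

  structural_keys <- c("kb_by_method", "delta_tm", "viscosity_trend",
                       "displaced_probe", "spectral")
  has_structural <- any(structural_keys %in% names(evidence))

  mode_call <-
    if (!has_structural &&
        identical(as.character(evidence$force_class), "electrostatic"))
      "electrostatic"
    else if (total < min_votes || n_groove == n_inter)
      "indeterminate"
    else if (n_groove > n_inter) "minor_groove"
    else "intercalation"

  structure(
    list(evidence = evidence, mode_call = mode_call,
         votes = c(groove = n_groove, intercalation = n_inter),
         rule_trace = trace, schema_version = 1L),
    class = "binding_mode_report")
}

#' @export
print.binding_mode_report <- function(x, ...) {
  cat(sprintf("<binding_mode_report> mode_call = %s (groove %d : intercalation %d)\n",
              x$mode_call, x$votes[["groove"]], x$votes[["intercalation"]]))
  for (t in x$rule_trace)
    cat(sprintf("  %-18s %-16s -> %s  [%s]\n", t$rule, t$evidence_key,
                t$vote, paste(format(t$input), collapse = " ")))
  invisible(x)
}
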