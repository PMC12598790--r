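#' Run the full multi-technique analysis and binding-mode report
#'
#' Orchestrates every configured stage — UV-vis Benesi-Hildebrand,
#' fluorescence quenching and dye displacement, van't Hoff thermodynamics,
#' thermal denaturation, relative viscosity, and voltammetric peak
#' suppression — collects the per-technique evidence, and hands it to
#' [aggregate_evidence()] for the rule-based binding-mode call. A failing
#' stage is recorded in `stage_errors` and its evidence simply omitted;
#' the remaining stages still run. Given fixed inputs the whole report is
#' deterministic.
#'
#' @param config Named list configuring any subset of stages. Each stage
#'   accepts either the in-memory domain object or a CSV path for
#'   [read_table()]:
#' * `uv`: a `"titration"` input (UV absorbance, zero-ligand point
#'   required).
#' * `fluorescence`: list with `etbr` and/or `hoechst` `"titration"`
#'   inputs (the Hoechst series also feeds the double-log analysis when
#'   present).
#' * `thermo`: list/data frame with `temperature_k` and `kb`.
#' * `melting`: list with `complex` and `reference` `"melting"` inputs.
#' * `viscosity`: a `"flow"` input.
#' * `voltammetry`: list with `drug_conc` (M), `s_complex` (A) and
#'   `s_free` (A), or a data frame plus `s_free`.
#' @param out_dir Optional directory: per-stage JSON files plus
#'   `report.json` are written there (schema_version 1).
#' @return The [aggregate_evidence()] report, with the per-stage fit
#'   objects in `$stages` and any failures in `$stage_errors`.
#' @export
run_report <- function(config, out_dir = NULL) {
  known <- c("uv", "fluorescence", "thermo", "melting", "viscosity",
             "voltammetry")
  if (!is.list(config) || !any(known %in% names(config)))
    stop("no technique configured: config must name at least one of ",
         paste(known, collapse = ", "), call. = FALSE)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  evidence <- list()
  stages <- list()
  stage_errors <- list()
  kb_by_method <- c()
  run_stage <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e) e)
    if (inherits(res, "error")) {
      stage_errors[[name]] <<- conditionMessage(res)
      NULL
    } else {
      stages[[name]] <<- res
      res
    }
  }

  if (!is.null(config$uv)) {
    res <- run_stage("uv", function() {
      s <- .as_input(config$uv, "titration")
      list(fit = benesi_hildebrand_fit(s),
           spectral = classify_spectral_change(s))
    })
    if (!is.null(res)) {
      kb_by_method["benesi_hildebrand"] <- res$fit$kb
      evidence$spectral <- res$spectral[c("change", "peak_shift_nm")]
    }
  }

  if (!is.null(config$fluorescence)) {
    res <- run_stage("fluorescence", function() {
      fl <- config$fluorescence
      out <- list()
      if (!is.null(fl$etbr))
        out$etbr <- stern_volmer_fit(.as_input(fl$etbr, "titration"))
      if (!is.null(fl$hoechst)) {
        hs <- .as_input(fl$hoechst, "titration")
        out$hoechst <- stern_volmer_fit(hs)
        out$double_log <- double_log_fit(hs)
      }
      if (!is.null(out$etbr) && !is.null(out$hoechst))
        out$displacement <- displacement_compare(out$etbr, out$hoechst)
      out
    })
    if (!is.null(res)) {
      if (!is.null(res$double_log))
        kb_by_method["double_log"] <- res$double_log$kb
      if (!is.null(res$displacement))
        evidence$displaced_probe <- as.character(res$displacement)
      evidence$ksv <- c(etbr = res$etbr$kb %||% NA_real_,
                        hoechst = res$hoechst$kb %||% NA_real_)
    }
  }

  if (!is.null(config$thermo)) {
    res <- run_stage("thermo", function() {
      th <- config$thermo
      vant_hoff_fit(th$temperature_k, th$kb)
    })
    if (!is.null(res)) evidence$force_class <- res$force_class
  }

  if (!is.null(config$melting)) {
    res <- run_stage("melting", function() {
      ml <- config$melting
      cx <- fit_melting_curve(.as_input(ml$complex, "melting"))
      rf <- fit_melting_curve(.as_input(ml$reference, "melting"))
      list(complex = cx, reference = rf,
           delta_tm = delta_tm(cx$tm, rf$tm))
    })
    if (!is.null(res)) evidence$delta_tm <- res$delta_tm
  }

  if (!is.null(config$viscosity)) {
    res <- run_stage("viscosity", function() {
      rv <- relative_viscosity_series(.as_input(config$viscosity, "flow"))
      list(series = rv, trend = viscosity_trend_test(rv))
    })
    if (!is.null(res)) evidence$viscosity_trend <- res$trend$trend
  }

  if (!is.null(config$voltammetry)) {
    res <- run_stage("voltammetry", function() {
      vt <- config$voltammetry
      electro_binding_fit(vt$drug_conc, vt$s_complex, vt$s_free)
    })
    if (!is.null(res)) kb_by_method["electrochemical"] <- res$kb
  }

  if (length(kb_by_method)) evidence$kb_by_method <- as.list(kb_by_method)
  if (!length(evidence))
    stop("every configured stage failed; no evidence collected: ",
         paste(names(stage_errors), stage_errors, collapse = "; "),
         call. = FALSE)

  report <- aggregate_evidence(evidence)
  report$stages <- stages
  report$stage_errors <- stage_errors

  if (!is.null(out_dir)) {
    for (nm in names(stages))
      jsonlite::write_json(.jsonable(stages[[nm]]),
                           file.path(out_dir, paste0(nm, ".json")),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           force = TRUE)
    jsonlite::write_json(
      .jsonable(report[c("schema_version", "mode_call", "votes",
                         "rule_trace", "evidence", "stage_errors")]),
      file.path(out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  }
  report
}

# resolve a stage input: path -> read_table, object -> validated pass-through
.as_input <- function(x, schema) {
  if (is.character(x) && length(x) == 1L) read_table(x, schema) else x
}

# strip fitted-value vectors and class attributes for compact JSON output
.jsonable <- function(x) {
  if (inherits(x, "binding_fit"))
    return(x[c("method", "kb", "kb_stderr", "n_stoichiometry", "slope",
               "intercept", "slope_se", "intercept_se", "r_squared",
               "n_points", "flags")])
  if (inherits(x, "melting_fit") || inherits(x, "thermo_result") ||
      inherits(x, "hb_fit") || inherits(x, "validation_stats"))
    return(unclass(x))
  if (is.list(x)) return(lapply(x, .jsonable))
  x
}
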