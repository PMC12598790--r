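#' Stern-Volmer quenching analysis
#'
#' Fits the Stern-Volmer relation \eqn{I_0/I = 1 + K_{sv}[Q]} by ordinary
#' least squares of \eqn{I_0/I} against quencher concentration. The
#' intercept is fitted freely; a deviation of more than 0.1 from the
#' theoretical value 1 raises a warning (it is diagnostic of curvature or a
#' mis-identified zero point, and is not silently forced away).
#'
#' @param series A [titration_series()] of kind `"fluorescence"` whose
#'   zero-quencher point defines \eqn{I_0}. All intensities must be > 0.
#' @return A `binding_fit` with `method = "stern_volmer"`; `kb` holds
#'   \eqn{K_{sv}} (the slope) and `kb_stderr` its standard error.
#' @export
stern_volmer_fit <- function(series) {
  stopifnot(inherits(series, "titration_series"))
  if (!any(series$ligand_conc == 0))
    stop("series must contain a zero-quencher point (defines I0)",
         call. = FALSE)
  if (any(series$response <= 0))
    stop("all intensities must be positive", call. = FALSE)
  i0 <- series$response[series$ligand_conc == 0][1L]
  x <- series$ligand_conc
  y <- i0 / series$response
  ols <- .ols(x, y)
  flags <- character()
  if (abs(ols$intercept - 1) > 0.1) {
    flags <- "intercept_far_from_1"
    warning(sprintf("Stern-Volmer intercept %.3f deviates from 1 by > 0.1",
                    ols$intercept), call. = FALSE)
  }
  if (ols$slope <= 0) flags <- c(flags, "non_quenching")
  new_binding_fit("stern_volmer", kb = ols$slope, kb_stderr = ols$slope_se,
                  ols = ols, x = x, y = y, flags = flags)
}

#' Double-logarithmic binding analysis of quenching data
#'
#' Fits \eqn{\log_{10}\frac{I_0 - I}{I} = \log_{10} K_b + n \log_{10} [Q]},
#' giving the binding constant from the intercept and the binding
#' stoichiometry from the slope. Base-10 logarithms are used throughout;
#' the recovered \eqn{K_b} is invariant to the base only because the same
#' base is applied to both sides.
#'
#' @param series A [titration_series()] with a zero-quencher point (defines
#'   \eqn{I_0}; excluded from the regression). Interior points with
#'   \eqn{I \ge I_0} (no quenching) are excluded with a warning.
#' @return A `binding_fit` with `method = "double_log"`, `kb = 10^intercept`
#'   and `n_stoichiometry = slope`.
#' @export
double_log_fit <- function(series) {
  stopifnot(inherits(series, "titration_series"))
  if (!any(series$ligand_conc == 0))
    stop("series must contain a zero-quencher point (defines I0)",
         call. = FALSE)
  if (any(series$response <= 0))
    stop("all intensities must be positive", call. = FALSE)
  i0 <- series$response[series$ligand_conc == 0][1L]
  keep <- series$ligand_conc > 0
  q <- series$ligand_conc[keep]
  i <- series$response[keep]
  usable <- i < i0
  if (any(!usable))
    warning(sprintf("%d point(s) with I >= I0 excluded", sum(!usable)),
            call. = FALSE)
  q <- q[usable]; i <- i[usable]
  if (length(q) < 3L)
    stop("fewer than 3 usable points with I < I0", call. = FALSE)
  x <- log10(q)
  y <- log10((i0 - i) / i)
  ols <- .ols(x, y)
  kb <- 10^ols$intercept
  kb_se <- kb * log(10) * ols$intercept_se
  new_binding_fit("double_log", kb = kb, kb_stderr = kb_se, ols = ols,
                  x = x, y = y,
                  n_stoichiometry = ols$slope,
                  n_stoichiometry_se = ols$slope_se)
}

#' Compare probe displacement between an intercalator and a groove probe
#'
#' In a dye-displacement experiment the test ligand quenches the probe whose
#' binding site it competes for. A much larger Stern-Volmer constant against
#' the minor-groove probe (Hoechst 33258) than against the intercalator
#' probe (ethidium bromide) indicates the groove probe is displaced, and
#' vice versa.
#'
#' @param fit_etbr,fit_hoechst `binding_fit`s from [stern_volmer_fit()] on
#'   the EtBr-dsDNA and Hoechst-dsDNA systems.
#' @param ratio_threshold Fold-difference needed for a call (default 5).
#' @return `"groove_probe_displaced"`, `"intercalator_probe_displaced"` or
#'   `"indeterminate"`, with the Ksv ratio as attribute `"ratio"`
#'   (Hoechst / EtBr).
#' @export
displacement_compare <- function(fit_etbr, fit_hoechst,
                                 ratio_threshold = 5) {
  stopifnot(inherits(fit_etbr, "binding_fit"),
            inherits(fit_hoechst, "binding_fit"))
  if (fit_etbr$method != "stern_volmer" ||
      fit_hoechst$method != "stern_volmer")
    stop("displacement_compare expects two stern_volmer fits", call. = FALSE)
  if (fit_etbr$kb <= 0 || fit_hoechst$kb <= 0)
    stop("non-positive Ksv", call. = FALSE)
  ratio <- fit_hoechst$kb / fit_etbr$kb
  out <- if (ratio >= ratio_threshold) "groove_probe_displaced"
         else if (1 / ratio >= ratio_threshold) "intercalator_probe_displaced"
         else "indeterminate"
  attr(out, "ratio") <- ratio
  out
}
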