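# Gas constant, J/(mol K). Kb is treated as dimensionless inside ln
# (implicit 1 M standard state), matching common practice for binding
# thermodynamics from titration data.
.R_GAS <- 8.314

#' van't Hoff analysis of temperature-dependent binding constants
#'
#' Ordinary least squares of \eqn{\ln K_b} against \eqn{1/T}:
#' \eqn{\Delta H = -R \cdot slope}, \eqn{\Delta S = R \cdot intercept}
#' (R = 8.314 J/(mol K)). Standard errors are propagated directly from the
#' regression. With four or more temperatures a quadratic term in
#' \eqn{1/T} is tested and a curvature warning raised when it is
#' significant at the 5% level (heat-capacity effects would bend the line).
#'
#' @param temperature_k Temperatures (K), distinct, >= 3.
#' @param kb Binding constants (1/M), positive, one per temperature.
#' @return An object of class `thermo_result`: `delta_h` (kJ/mol),
#'   `delta_s` (J/(mol K)), their standard errors, `delta_g` (kJ/mol, one
#'   per input temperature, from [gibbs()]), `force_class` (from
#'   [classify_forces()]), and regression diagnostics.
#' @export
vant_hoff_fit <- function(temperature_k, kb) {
  temperature_k <- as.numeric(temperature_k)
  kb <- as.numeric(kb)
  if (length(temperature_k) != length(kb))
    stop("temperature_k and kb must have equal length", call. = FALSE)
  if (length(kb) < 3L)
    stop("van't Hoff analysis needs at least 3 temperature points",
         call. = FALSE)
  if (anyDuplicated(temperature_k))
    stop("duplicate temperatures", call. = FALSE)
  if (any(kb <= 0))
    stop("all kb must be positive", call. = FALSE)
  x <- 1 / temperature_k
  y <- log(kb)
  ols <- .ols(x, y)
  delta_h <- -.R_GAS * ols$slope / 1000          # kJ/mol
  delta_s <- .R_GAS * ols$intercept              # J/(mol K)
  delta_h_se <- .R_GAS * ols$slope_se / 1000
  delta_s_se <- .R_GAS * ols$intercept_se
  curvature <- FALSE
  if (length(x) >= 4L) {
    qfit <- stats::lm(y ~ x + I(x^2))
    pq <- suppressWarnings(
      stats::coef(summary(qfit))["I(x^2)", "Pr(>|t|)"])
    if (is.finite(pq) && pq < 0.05) {
      curvature <- TRUE
      warning("significant curvature in ln Kb vs 1/T (quadratic term p < 0.05)",
              call. = FALSE)
    }
  }
  structure(
    list(
      delta_h = delta_h, delta_s = delta_s,
      delta_h_se = delta_h_se, delta_s_se = delta_s_se,
      delta_g = gibbs(delta_h, delta_s, temperature_k),
      temperature_k = temperature_k,
      force_class = classify_forces(delta_h, delta_s),
      r_squared = ols$r_squared,
      slope = ols$slope, intercept = ols$intercept,
      curvature_warning = curvature,
      n_points = length(x)
    ),
    class = "thermo_result"
  )
}

#' @export
print.thermo_result <- function(x, ...) {
  cat("<thermo_result> van't Hoff analysis\n")
  cat(sprintf("  dH = %.3f kJ/mol (SE %.3g)\n", x$delta_h, x$delta_h_se))
  cat(sprintf("  dS = %.3f J/(mol K) (SE %.3g)\n", x$delta_s, x$delta_s_se))
  for (i in seq_along(x$temperature_k))
    cat(sprintf("  dG(%.2f K) = %.3f kJ/mol\n",
                x$temperature_k[i], x$delta_g[i]))
  cat(sprintf("  dominant forces: %s\n", x$force_class))
  if (x$curvature_warning) cat("  warning: curvature detected\n")
  invisible(x)
}

#' Gibbs free energy from enthalpy and entropy
#'
#' \eqn{\Delta G = \Delta H - T \Delta S / 1000} (kJ/mol), evaluated at each
#' supplied temperature. The division by 1000 converts the entropy term
#' from J/mol to kJ/mol.
#'
#' @param delta_h Enthalpy change (kJ/mol).
#' @param delta_s Entropy change (J/(mol K)).
#' @param temperature_k Temperatures (K).
#' @return Numeric vector of \eqn{\Delta G} (kJ/mol), one per temperature.
#' @export
gibbs <- function(delta_h, delta_s, temperature_k) {
  stopifnot(is.finite(delta_h), is.finite(delta_s),
            all(is.finite(temperature_k)))
  delta_h - temperature_k * delta_s / 1000
}

#' Classify dominant binding forces from thermodynamic signs
#'
#' The standard sign rules for ligand-macromolecule association:
#' both positive = hydrophobic; both negative = van der Waals or hydrogen
#' bonding; negative enthalpy with positive entropy = electrostatic.
#' Exact signs of the point estimates are used; a zero on either axis (or
#' the remaining quadrant, positive enthalpy with negative entropy, which
#' implies no spontaneous binding at any temperature) is classified
#' `"indeterminate"` with an explanation attribute.
#'
#' @param delta_h Enthalpy change (kJ/mol).
#' @param delta_s Entropy change (J/(mol K)).
#' @return One of `"hydrophobic"`, `"vdw_or_hbond"`, `"electrostatic"`,
#'   `"indeterminate"` (with attribute `"explanation"` in the last case).
#' @export
classify_forces <- function(delta_h, delta_s) {
  if (delta_h > 0 && delta_s > 0) return("hydrophobic")
  if (delta_h < 0 && delta_s < 0) return("vdw_or_hbond")
  if (delta_h < 0 && delta_s > 0) return("electrostatic")
  out <- "indeterminate"
  attr(out, "explanation") <-
    if (delta_h == 0 || delta_s == 0)
      "a sign is exactly zero; the sign rules do not apply"
    else
      "dH > 0 with dS < 0: binding never spontaneous, outside the sign rules"
  out
}
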