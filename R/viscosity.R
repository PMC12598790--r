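#' Relative-viscosity titration series
#'
#' Converts viscometer flow times into the cube-root relative viscosity
#' used for binding-mode diagnosis. With buffer flow time \eqn{t_0}, the
#' specific viscosity at each point is \eqn{\eta = (t - t_0)/t_0}; the
#' zero-ligand (dsDNA only) point defines \eqn{\eta_0}; the reported value
#' is \eqn{(\eta/\eta_0)^{1/3}} against the mixing ratio
#' \eqn{r = [ligand]/[DNA]}. The cube root tracks contour-length changes of
#' a rodlike polymer, so intercalation (which lengthens the helix) raises
#' it while groove binding leaves it flat.
#'
#' @param flow A [flow_time_series()] whose first point is the zero-ligand
#'   dsDNA solution.
#' @return Data frame with columns `r`, `rel_visc`
#'   (\eqn{(\eta/\eta_0)^{1/3}}) and `flagged` (flow time below the buffer
#'   reference; value reported as `NaN`).
#' @export
relative_viscosity_series <- function(flow) {
  stopifnot(inherits(flow, "flow_time_series"))
  t0 <- attr(flow, "t0")
  dna <- attr(flow, "dna_conc")
  if (flow$ligand_conc[1L] != 0)
    stop("flow series must start at a zero-ligand (dsDNA only) point",
         call. = FALSE)
  eta0 <- (flow$t[1L] - t0) / t0
  if (eta0 <= 0)
    stop("DNA flow time not above buffer; eta0 <= 0", call. = FALSE)
  eta <- (flow$t - t0) / t0
  flagged <- flow$t < t0
  if (any(flagged))
    warning(sprintf("%d flow time(s) below the buffer reference flagged",
                    sum(flagged)), call. = FALSE)
  val <- ifelse(flagged, NaN, (eta / eta0)^(1 / 3))
  data.frame(r = flow$ligand_conc / dna, rel_visc = val, flagged = flagged)
}

#' Trend test on a relative-viscosity series
#'
#' Ordinary least squares of \eqn{(\eta/\eta_0)^{1/3}} against r with a 95%
#' confidence interval on the slope. The trend is `"flat"` when the interval
#' contains zero or when the predicted change over the observed r range is
#' below `flat_threshold` (in cube-root units; small changes are physically
#' inconsequential even when statistically detectable); otherwise
#' `"increasing"`/`"decreasing"` by the slope sign.
#'
#' @param series Data frame from [relative_viscosity_series()] (columns `r`,
#'   `rel_visc`), >= 4 unflagged points.
#' @param flat_threshold Predicted-change threshold for practical flatness
#'   (default 0.05).
#' @return List with `slope`, `ci` (95%), `trend`, and the predicted
#'   `change_over_range`.
#' @export
viscosity_trend_test <- function(series, flat_threshold = 0.05) {
  stopifnot(is.data.frame(series), all(c("r", "rel_visc") %in% names(series)))
  ok <- is.finite(series$rel_visc)
  r <- series$r[ok]; v <- series$rel_visc[ok]
  if (length(r) < 4L)
    stop("trend test needs at least 4 points", call. = FALSE)
  fit <- stats::lm(v ~ r)
  slope <- unname(stats::coef(fit)[2L])
  # confint -> vcov -> summary.lm warns on exactly constant input
  ci <- unname(suppressWarnings(stats::confint(fit, "r", level = 0.95)))
  change <- slope * diff(range(r))
  trend <- if ((ci[1L] <= 0 && ci[2L] >= 0) || abs(change) < flat_threshold)
    "flat" else if (slope > 0) "increasing" else "decreasing"
  list(slope = slope, ci = c(ci), trend = trend,
       change_over_range = change)
}

#' Herschel-Bulkley fit to a flow curve
#'
#' Nonlinear least squares of the yield-stress power-law model
#' \eqn{\tau = \tau_0 + K \dot\gamma^n} with \eqn{\tau_0 \ge 0},
#' \eqn{K > 0}, \eqn{n > 0} enforced by box constraints. Three starts
#' (n = 0.5, 1, 1.5, with K matched to the data at each) are run through
#' Levenberg-Marquardt and the lowest-SSE convergent fit wins.
#'
#' @param rheo A [rheogram()] with >= 5 points.
#' @param shear_rate_eval Optional shear rate (1/s) at which to report the
#'   apparent viscosity \eqn{\eta_{app} = \tau(\dot\gamma^*)/\dot\gamma^*}
#'   (Pa s).
#' @return Object of class `hb_fit`: `tau0` (Pa), `k` (Pa s^n), `n`, their
#'   standard errors, `sse`, `r_squared`, and `eta_app` when requested.
#' @export
herschel_bulkley_fit <- function(rheo, shear_rate_eval = NULL) {
  stopifnot(inherits(rheo, "rheogram"))
  if (nrow(rheo) < 5L)
    stop("Herschel-Bulkley fit needs at least 5 points", call. = FALSE)
  rate <- rheo$shear_rate
  stress <- rheo$shear_stress
  if (all(stress == 0))
    stop("all stresses are zero; no flow curve to fit", call. = FALSE)

  best <- NULL
  for (n0 in c(0.5, 1, 1.5)) {
    t00 <- max(0, min(stress) - 1e-3 * diff(range(stress)))
    k0 <- max((stats::median(stress) - t00) / stats::median(rate)^n0, 1e-12)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        stress ~ tau0 + k * rate^n,
        start = list(tau0 = t00, k = k0, n = n0),
        lower = c(0, 1e-300, 1e-6),
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::residuals(fit)^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
  }
  if (is.null(best))
    stop("Herschel-Bulkley fit did not converge from any start",
         call. = FALSE)
  fit <- best$fit
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e)
    stats::setNames(rep(NA_real_, 3L), names(cf)))
  r2 <- 1 - best$sse / sum((stress - mean(stress))^2)
  eta_app <- if (!is.null(shear_rate_eval)) {
    tau <- cf[["tau0"]] + cf[["k"]] * shear_rate_eval^cf[["n"]]
    tau / shear_rate_eval
  } else NA_real_
  structure(
    list(tau0 = cf[["tau0"]], k = cf[["k"]], n = cf[["n"]],
         tau0_se = se[["tau0"]], k_se = se[["k"]], n_se = se[["n"]],
         sse = best$sse, r_squared = r2,
         eta_app = eta_app, shear_rate_eval = shear_rate_eval %||% NA_real_),
    class = "hb_fit")
}

#' @export
print.hb_fit <- function(x, ...) {
  cat(sprintf(
    "<hb_fit> tau0 = %.4g Pa, K = %.4g Pa.s^n, n = %.4g (R^2 %.5f)\n",
    x$tau0, x$k, x$n, x$r_squared))
  if (is.finite(x$eta_app))
    cat(sprintf("  apparent viscosity at %.4g 1/s: %.4g Pa s\n",
                x$shear_rate_eval, x$eta_app))
  invisible(x)
}
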