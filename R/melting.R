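#' Fit a DNA melting curve and extract the melting temperature
#'
#' The 260 nm absorbance of dsDNA rises sigmoidally through the
#' helix-to-coil transition; the melting temperature Tm is the midpoint.
#' A four-parameter logistic
#' \deqn{A(T) = lower + \frac{upper - lower}{1 + e^{-(T - T_m)/w}}}
#' is fitted by Levenberg-Marquardt least squares. If the logistic fit
#' fails to converge, the fallback is linear interpolation of the
#' temperature at the absorbance halfway between the plateau means (means
#' of the lowest and highest 15% of temperatures); the method actually used
#' is recorded.
#'
#' @param curve A [melting_curve()].
#' @return Object of class `melting_fit`: `tm` (deg C), `width` (deg C),
#'   `lower`, `upper`, `tm_se`, `method` (`"logistic"` or `"half_height"`),
#'   and `r_squared`.
#'
#' @section Failure modes:
#' A curve with no transition (flat, or amplitude below 2% of the mean
#' absorbance and below 4 residual SDs) raises a `"no transition"` error;
#' so does a fitted Tm outside the temperature range of the data.
#' @export
fit_melting_curve <- function(curve) {
  stopifnot(inherits(curve, "melting_curve"))
  temp <- curve$temperature
  ab <- curve$absorbance
  amp <- diff(range(ab))
  if (amp == 0)
    stop("no transition: absorbance is constant", call. = FALSE)

  # plateau means from the coolest / hottest 15% of temperatures
  n <- length(temp)
  k <- max(2L, ceiling(0.15 * n))
  low_mean <- mean(ab[seq_len(k)])
  high_mean <- mean(ab[seq.int(n - k + 1L, n)])
  half <- (low_mean + high_mean) / 2

  start <- list(lower = min(ab), upper = max(ab),
                tm = .half_height_tm(temp, ab, half),
                w = diff(range(temp)) / 15)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      ab ~ lower + (upper - lower) / (1 + exp(-(temp - tm) / w)),
      start = start,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)

  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    resid_sd <- sqrt(sum(stats::residuals(fit)^2) / max(1L, n - 4L))
    fitted_amp <- abs(cf[["upper"]] - cf[["lower"]])
    if (fitted_amp < 4 * resid_sd && fitted_amp < 0.02 * mean(abs(ab)))
      stop("no transition: fitted amplitude not distinguishable from noise",
           call. = FALSE)
    tm <- cf[["tm"]]
    if (tm < min(temp) || tm > max(temp))
      stop("fitted Tm outside the data temperature range", call. = FALSE)
    se <- tryCatch(sqrt(diag(stats::vcov(fit)))[["tm"]],
                   error = function(e) NA_real_)
    r2 <- 1 - sum(stats::residuals(fit)^2) / sum((ab - mean(ab))^2)
    out <- list(tm = tm, width = cf[["w"]], lower = cf[["lower"]],
                upper = cf[["upper"]], tm_se = se, method = "logistic",
                r_squared = r2)
  } else {
    tm <- .half_height_tm(temp, ab, half)
    if (!is.finite(tm))
      stop("no transition: half-height level never crossed", call. = FALSE)
    out <- list(tm = tm, width = NA_real_, lower = low_mean,
                upper = high_mean, tm_se = NA_real_,
                method = "half_height", r_squared = NA_real_)
  }
  structure(out, class = "melting_fit")
}

# temperature at which the curve crosses `level`, by linear interpolation
# between the bracketing points (first upward crossing)
.half_height_tm <- function(temp, ab, level) {
  s <- ab - level
  idx <- which(s[-length(s)] * s[-1L] <= 0 & s[-length(s)] != s[-1L])
  if (!length(idx)) return(NA_real_)
  i <- idx[1L]
  temp[i] + (level - ab[i]) * (temp[i + 1L] - temp[i]) / (ab[i + 1L] - ab[i])
}

#' @export
print.melting_fit <- function(x, ...) {
  cat(sprintf("<melting_fit> Tm = %.2f degC (SE %.3g, %s fit)\n",
              x$tm, x$tm_se, x$method))
  if (is.finite(x$width))
    cat(sprintf("  width %.2f degC, plateaus %.4g -> %.4g AU\n",
                x$width, x$lower, x$upper))
  invisible(x)
}

#' Melting-temperature shift
#'
#' @param tm_complex Tm of the ligand-dsDNA complex (deg C).
#' @param tm_free Tm of free dsDNA (deg C).
#' @return `tm_complex - tm_free` (deg C).
#' @export
delta_tm <- function(tm_complex, tm_free) {
  stopifnot(is.finite(tm_complex), is.finite(tm_free))
  tm_complex - tm_free
}

#' Interpret a melting-temperature shift
#'
#' Intercalators stabilise the duplex strongly (shifts of roughly 10-12 deg
#' C or more), whereas groove binders leave Tm nearly unchanged. Shifts of
#' at least `intercalation_min` are called intercalation-consistent, of at
#' most `groove_max` groove-consistent, in between ambiguous.
#'
#' @param dtm Melting-temperature shift (deg C).
#' @param intercalation_min Lower bound for an intercalation call (default
#'   10 deg C).
#' @param groove_max Upper bound for a groove call (default 6 deg C).
#' @return `"intercalation_consistent"`, `"groove_consistent"` or
#'   `"ambiguous"`.
#' @export
interpret_delta_tm <- function(dtm, intercalation_min = 10, groove_max = 6) {
  if (!(groove_max < intercalation_min))
    stop("thresholds must satisfy groove_max < intercalation_min",
         call. = FALSE)
  if (dtm >= intercalation_min) "intercalation_consistent"
  else if (dtm <= groove_max) "groove_consistent"
  else "ambiguous"
}
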