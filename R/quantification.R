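#' Calibration-curve fit for voltammetric quantification
#'
#' Ordinary least squares of peak current (A) against concentration (uM):
#' the reporting layer of the quantification workflow keeps the
#' micromolar axis because validated figures of merit (LOD, LOQ, linear
#' range) are conventionally quoted per uM. The residual standard
#' deviation (n - 2 denominator) feeds [lod_loq()]; points with
#' externally studentized residuals beyond 3 are flagged as outliers but
#' never silently dropped.
#'
#' @param conc_um Concentrations (uM), >= 5 distinct values.
#' @param current_a Peak currents (A).
#' @return Object of class `calibration_result`: `slope` (A/uM),
#'   `intercept` (A), `r_squared`, `residual_sd` (A), `lod`/`loq` (uM),
#'   `linear_range` (uM), `outlier_flags`.
#' @export
calibration_fit <- function(conc_um, current_a) {
  conc_um <- as.numeric(conc_um); current_a <- as.numeric(current_a)
  if (length(conc_um) != length(current_a))
    stop("conc_um and current_a must have equal length", call. = FALSE)
  if (length(conc_um) < 5L)
    stop("calibration needs at least 5 points", call. = FALSE)
  if (length(unique(conc_um)) < 2L)
    stop("calibration needs at least two distinct concentrations",
         call. = FALSE)
  fit <- stats::lm(current_a ~ conc_um)
  cf <- stats::coef(fit)
  vc <- suppressWarnings(stats::vcov(fit))
  n <- length(conc_um)
  residual_sd <- sqrt(sum(stats::residuals(fit)^2) / (n - 2L))
  rst <- tryCatch(suppressWarnings(stats::rstudent(fit)),
                  error = function(e) rep(0, n))
  ll <- lod_loq(residual_sd, unname(cf[2L]))
  structure(
    list(
      slope = unname(cf[2L]), intercept = unname(cf[1L]),
      slope_se = sqrt(vc[2L, 2L]),
      intercept_se = sqrt(vc[1L, 1L]),
      r_squared = {
        sst <- sum((current_a - mean(current_a))^2)
        if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 1
      },
      residual_sd = residual_sd,
      lod = ll[["lod"]], loq = ll[["loq"]],
      linear_range = range(conc_um),
      outlier_flags = which(abs(rst) > 3),
      n_points = n,
      conc_um = conc_um, current_a = current_a,
      fitted = unname(stats::fitted(fit))
    ),
    class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result>\n")
  cat(sprintf("  I (A) = %.4g C (uM) + %.4g,  R^2 = %.4f (%d points)\n",
              x$slope, x$intercept, x$r_squared, x$n_points))
  cat(sprintf("  residual SD %.4g A; LOD %.3g uM; LOQ %.3g uM; range %g-%g uM\n",
              x$residual_sd, x$lod, x$loq,
              x$linear_range[1L], x$linear_range[2L]))
  if (length(x$outlier_flags))
    cat("  outlier point(s):", paste(x$outlier_flags, collapse = ", "), "\n")
  invisible(x)
}

#' Predict concentrations from a calibration line
#'
#' Inverts the calibration: `C = (I - intercept) / slope`. Negative
#' predictions are reported as-is with a warning rather than clipped.
#'
#' @param object A `calibration_result`.
#' @param current_a Currents (A) to convert.
#' @param ... Unused.
#' @return Concentrations (uM).
#' @export
predict.calibration_result <- function(object, current_a, ...) {
  conc <- (as.numeric(current_a) - object$intercept) / object$slope
  if (any(conc < 0))
    warning("negative predicted concentration(s) reported as-is",
            call. = FALSE)
  conc
}

#' Limits of detection and quantification
#'
#' ICH-style regression-based limits: `LOD = 3 SD / |slope|`,
#' `LOQ = 10 SD / |slope|`, so `loq / lod = 10/3` identically. `SD` is
#' normally the calibration residual SD; a blank-replicate SD may be passed
#' instead.
#'
#' @param residual_sd Standard deviation of the response (A), >= 0.
#' @param slope Calibration slope (A/uM), nonzero.
#' @return Named numeric: `lod`, `loq` (uM).
#' @export
lod_loq <- function(residual_sd, slope) {
  if (!is.finite(slope) || slope == 0)
    stop("slope must be nonzero", call. = FALSE)
  if (residual_sd < 0)
    stop("residual_sd must be non-negative", call. = FALSE)
  c(lod = 3 * residual_sd / abs(slope),
    loq = 10 * residual_sd / abs(slope))
}

new_validation_stats <- function(per_sample, bias_percent = NA_real_,
                                 extra = list()) {
  m <- mean(per_sample)
  s <- stats::sd(per_sample)           # n - 1 denominator
  structure(
    c(list(mean = m, sd = s,
           rsd_percent = 100 * s / m,
           bias_percent = bias_percent,
           n = length(per_sample),
           per_sample = per_sample),
      extra),
    class = "validation_stats")
}

#' @export
print.validation_stats <- function(x, ...) {
  cat(sprintf("<validation_stats> n = %d: mean %.4g, SD %.4g, %%RSD %.4g",
              x$n, x$mean, x$sd, x$rsd_percent))
  if (is.finite(x$bias_percent))
    cat(sprintf(", %%bias %.4g", x$bias_percent))
  cat("\n")
  invisible(x)
}

#' Repeatability statistics
#'
#' Mean, sample standard deviation (n - 1 denominator) and percent
#' relative standard deviation of replicate measurements.
#'
#' @param replicates Numeric vector, >= 3 values, nonzero mean.
#' @return A `validation_stats` object.
#' @export
repeatability_rsd <- function(replicates) {
  replicates <- as.numeric(replicates)
  if (length(replicates) < 3L)
    stop("need at least 3 replicates", call. = FALSE)
  if (mean(replicates) == 0)
    stop("%RSD undefined: mean is zero", call. = FALSE)
  new_validation_stats(replicates)
}

#' Tablet assay statistics
#'
#' Replicate determinations of drug content in a tablet against the label
#' claim. No measurement is silently excluded.
#'
#' @param measured_mg Measured contents (mg), >= 3 tablets.
#' @param label_mg Nominal (label) content (mg), positive.
#' @return A `validation_stats` with extra fields `percent_of_label`
#'   (per tablet) and `mean_percent_of_label`.
#' @export
assay_tablet <- function(measured_mg, label_mg) {
  measured_mg <- as.numeric(measured_mg)
  if (length(measured_mg) < 3L)
    stop("need at least 3 tablets", call. = FALSE)
  if (!is.finite(label_mg) || label_mg <= 0)
    stop("label_mg must be positive", call. = FALSE)
  pct <- 100 * measured_mg / label_mg
  new_validation_stats(measured_mg,
                       extra = list(percent_of_label = pct,
                                    mean_percent_of_label = mean(pct),
                                    label_mg = label_mg))
}

#' Recovery (spike) analysis
#'
#' Per-sample percent recovery `100 * found / added`; the summary reports
#' the mean, sample SD and %RSD of the recoveries and the bias
#' `mean recovery - 100`.
#'
#' @param added_mg Spiked amounts (mg), positive.
#' @param found_mg Recovered amounts (mg), same length.
#' @return A `validation_stats` over the percent recoveries with
#'   `bias_percent` populated and `recovery_percent` per sample.
#' @export
recovery_analysis <- function(added_mg, found_mg) {
  added_mg <- as.numeric(added_mg); found_mg <- as.numeric(found_mg)
  if (length(added_mg) != length(found_mg))
    stop("added_mg and found_mg must have equal length", call. = FALSE)
  if (any(added_mg <= 0))
    stop("added amounts must be positive", call. = FALSE)
  rec <- 100 * found_mg / added_mg
  out <- new_validation_stats(rec,
                              extra = list(recovery_percent = rec))
  out$bias_percent <- out$mean - 100
  out
}
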