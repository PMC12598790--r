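# Shared result class for the four binding-constant estimators. Every
# estimator reduces to a straight-line regression in transformed coordinates,
# so the object carries the regression alongside the derived constant.

# Internal OLS wrapper: returns coefficients, their SEs, covariance, R^2 and
# residual SD in one flat list. All linearized fits in the package go
# through lm() via this helper.
.ols <- function(x, y) {
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  # vcov calls summary.lm, which warns on numerically perfect fits;
  # those are routine here (noise-free synthetic data)
  vc <- suppressWarnings(stats::vcov(fit))
  n <- length(x)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 1
  list(
    intercept = unname(cf[1L]), slope = unname(cf[2L]),
    intercept_se = sqrt(vc[1L, 1L]), slope_se = sqrt(vc[2L, 2L]),
    cov_si = vc[1L, 2L],
    r_squared = r2,
    residual_sd = if (n > 2L) sqrt(sum(stats::residuals(fit)^2) / (n - 2L))
                  else NA_real_,
    fitted = unname(stats::fitted(fit)),
    residuals = unname(stats::residuals(fit)),
    n = n
  )
}

new_binding_fit <- function(method, kb, kb_stderr, ols, x, y,
                            n_stoichiometry = NA_real_,
                            n_stoichiometry_se = NA_real_,
                            flags = character()) {
  stopifnot(is.character(method), length(method) == 1L)
  structure(
    list(
      kb = kb, kb_stderr = kb_stderr,
      n_stoichiometry = n_stoichiometry,
      n_stoichiometry_se = n_stoichiometry_se,
      slope = ols$slope, intercept = ols$intercept,
      slope_se = ols$slope_se, intercept_se = ols$intercept_se,
      r_squared = ols$r_squared,
      n_points = ols$n,
      x = x, y = y, fitted = ols$fitted, residuals = ols$residuals,
      method = method, flags = flags
    ),
    class = "binding_fit"
  )
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("<binding_fit> method = %s\n", x$method))
  cat(sprintf("  Kb = %.4g 1/M (SE %.2g), R^2 = %.4f, n = %d points\n",
              x$kb, x$kb_stderr, x$r_squared, x$n_points))
  if (!is.na(x$n_stoichiometry))
    cat(sprintf("  stoichiometry n = %.3f (SE %.2g)\n",
                x$n_stoichiometry, x$n_stoichiometry_se))
  if (length(x$flags))
    cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.binding_fit <- function(object, ...) {
  cat(sprintf("Binding-constant fit (%s)\n", object$method))
  cat(sprintf("  Kb        : %.6g 1/M  (SE %.3g)\n",
              object$kb, object$kb_stderr))
  if (!is.na(object$n_stoichiometry))
    cat(sprintf("  n         : %.4f      (SE %.3g)\n",
                object$n_stoichiometry, object$n_stoichiometry_se))
  cat(sprintf("  slope     : %.6g  (SE %.3g)\n",
              object$slope, object$slope_se))
  cat(sprintf("  intercept : %.6g  (SE %.3g)\n",
              object$intercept, object$intercept_se))
  cat(sprintf("  R^2       : %.6f   (%d points)\n",
              object$r_squared, object$n_points))
  if (length(object$flags))
    cat("  flags     :", paste(object$flags, collapse = ", "), "\n")
  invisible(object)
}

#' @export
coef.binding_fit <- function(object, ...) {
  c(kb = object$kb, n = object$n_stoichiometry,
    slope = object$slope, intercept = object$intercept)
}

#' @export
residuals.binding_fit <- function(object, ...) object$residuals

#' @export
plot.binding_fit <- function(x, ...) {
  graphics::plot(x$x, x$y,
                 xlab = "transformed concentration",
                 ylab = "transformed response",
                 main = sprintf("%s fit (Kb = %.3g 1/M)", x$method, x$kb),
                 ...)
  graphics::abline(x$intercept, x$slope, col = "steelblue")
  invisible(x)
}
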