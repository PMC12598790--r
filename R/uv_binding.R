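#' Benesi-Hildebrand binding constant from a UV-vis titration
#'
#' Double-reciprocal analysis of a 1:1 complexation isotherm. With the
#' apparent extinction coefficient at each point,
#' `eps_a = response / (path * [dsDNA])`, and the free-chromophore
#' coefficient `eps_f` taken from the zero-titrant point, the model
#' \deqn{\frac{C}{\varepsilon_a-\varepsilon_f} =
#'       \frac{C}{\varepsilon_b-\varepsilon_f} +
#'       \frac{1}{K_b(\varepsilon_b-\varepsilon_f)}}
#' is linear in the varied concentration \eqn{C}; the binding constant is the
#' slope/intercept ratio of the ordinary-least-squares line.
#'
#' The classical equation is written in terms of the dsDNA concentration,
#' while in a drug-titration experiment the concentration actually varied is
#' the ligand's. `mode` selects which reading the abscissa is given: both use
#' the series' varied-concentration column as x; the choice is recorded in
#' the fit so reports state which species the axis was interpreted as.
#'
#' @param series A [titration_series()] of kind `"uv_absorbance"` containing
#'   a zero-titrant point (defines `eps_f`).
#' @param mode `"vary_ligand"` (default: x is the titrant = drug axis) or
#'   `"vary_dna"` (the literal double-reciprocal reading, x interpreted as
#'   the dsDNA axis).
#' @return A `binding_fit` with `method = "benesi_hildebrand"`. `kb_stderr`
#'   is first-order error propagation of the slope/intercept ratio including
#'   their covariance. Flag `"kb_unreliable"` is set when the intercept is
#'   statistically indistinguishable from zero (|intercept| < 2 SE).
#' @export
benesi_hildebrand_fit <- function(series,
                                  mode = c("vary_ligand", "vary_dna")) {
  mode <- match.arg(mode)
  stopifnot(inherits(series, "titration_series"))
  dna <- attr(series, "macromolecule_conc")
  path <- attr(series, "path_cm") %||% 1
  if (!any(series$ligand_conc == 0))
    stop("series must contain a zero-titrant point to define eps_f",
         call. = FALSE)
  eps_a <- series$response / (path * dna)
  eps_f <- eps_a[series$ligand_conc == 0][1L]

  keep <- series$ligand_conc > 0
  x <- series$ligand_conc[keep]
  denom <- eps_a[keep] - eps_f
  bad <- denom <= 0
  if (any(bad)) {
    warning(sprintf(
      "%d point(s) with eps_a - eps_f <= 0 excluded from hyperchromic fit",
      sum(bad)), call. = FALSE)
    x <- x[!bad]; denom <- denom[!bad]
  }
  if (length(x) < 3L)
    stop("fewer than 3 usable points with eps_a - eps_f > 0", call. = FALSE)

  y <- x / denom
  ols <- .ols(x, y)
  kb <- ols$slope / ols$intercept
  # var(s/i) ~ (1/i)^2 var_s + (s/i^2)^2 var_i - 2 (s/i^3) cov
  kb_se <- sqrt((ols$slope_se / ols$intercept)^2 +
                (ols$slope * ols$intercept_se / ols$intercept^2)^2 -
                2 * ols$slope / ols$intercept^3 * ols$cov_si)
  flags <- character()
  if (abs(ols$intercept) < 2 * ols$intercept_se) {
    flags <- "kb_unreliable"
    warning("intercept indistinguishable from 0; Kb flagged unreliable",
            call. = FALSE)
  }
  fit <- new_binding_fit("benesi_hildebrand", kb, kb_se, ols, x, y,
                         flags = flags)
  fit$mode <- mode
  fit$eps_f <- eps_f
  fit$eps_b <- eps_f + 1 / ols$slope  # slope = 1/(eps_b - eps_f)
  fit
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Theil-Sen slope with a rank-based confidence interval (Sen's method with
# the normal approximation to the Kendall statistic). Small-n tool for trend
# direction only.
theil_sen <- function(x, y, conf = 0.95) {
  n <- length(x)
  ij <- utils::combn(n, 2L)
  slopes <- (y[ij[2L, ]] - y[ij[1L, ]]) / (x[ij[2L, ]] - x[ij[1L, ]])
  slopes <- sort(slopes[is.finite(slopes)])
  m <- length(slopes)
  est <- stats::median(slopes)
  var_s <- n * (n - 1) * (2 * n + 5) / 18
  c_alpha <- stats::qnorm(1 - (1 - conf) / 2) * sqrt(var_s)
  lo <- max(1L, floor((m - c_alpha) / 2))
  hi <- min(m, ceiling((m + c_alpha) / 2) + 1L)
  list(slope = est, lower = slopes[lo], upper = slopes[hi])
}

#' Classify the direction of spectral change along a titration
#'
#' Hyperchromism (absorbance increase at the observation wavelength as the
#' ligand is added) signals perturbation of base stacking without
#' intercalative stabilisation; hypochromism the opposite. The direction is
#' the sign of the Theil-Sen slope of response against ligand concentration,
#' with `"none"` when the slope's confidence interval spans zero.
#'
#' @param series A [titration_series()], ordered by ligand concentration.
#' @param conf Confidence level for the trend interval (default 0.95).
#' @return A list with `change` (`"hyperchromic"`, `"hypochromic"` or
#'   `"none"`), the Theil-Sen `slope` with its interval, and
#'   `peak_shift_nm` (`NA` here: single-wavelength series carry no peak
#'   position; full-spectrum input would be needed).
#' @export
classify_spectral_change <- function(series, conf = 0.95) {
  stopifnot(inherits(series, "titration_series"))
  if (nrow(series) < 3L)
    stop("need at least 3 points to classify a trend", call. = FALSE)
  ts <- theil_sen(series$ligand_conc, series$response, conf = conf)
  change <- if (ts$lower <= 0 && ts$upper >= 0) "none"
            else if (ts$slope > 0) "hyperchromic"
            else "hypochromic"
  list(change = change, slope = ts$slope,
       slope_ci = c(ts$lower, ts$upper), peak_shift_nm = NA_real_)
}
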