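#' Moving-average baseline correction of a voltammogram
#'
#' Iterative moving-average baseline stripping: the baseline estimate
#' starts at the raw current and on each of 50 fixed passes is replaced by
#' the pointwise minimum of itself and its centred moving average
#' (edges padded with the end values). Peaks are progressively carved out
#' of the estimate while the slowly varying background is retained; the
#' baseline is then subtracted. Because the estimate can only decrease, the
#' corrected current is non-negative wherever the raw signal sits on its
#' baseline. The pass count is fixed for determinism.
#'
#' @param v A [voltammogram()].
#' @param window_points Moving-average window (odd, >= 3, < length of the
#'   sweep). Choose it large relative to the peak width and small relative
#'   to the baseline drift scale.
#' @return A [voltammogram()] with corrected current and the removed
#'   baseline in attribute `"baseline"`.
#' @export
baseline_correct <- function(v, window_points = 21L) {
  stopifnot(inherits(v, "voltammogram"))
  w <- as.integer(window_points)
  n <- nrow(v)
  if (w < 3L || w %% 2L == 0L || w >= n)
    stop("window_points must be odd, >= 3 and smaller than the sweep",
         call. = FALSE)
  b <- v$current
  for (pass in seq_len(50L)) {
    b <- pmin(b, .movavg(b, w))
  }
  out <- voltammogram(v$potential, v$current - b,
                      metadata = attr(v, "metadata"))
  attr(out, "baseline") <- b
  out
}

# centred moving average with reflective padding (2*end - mirror), which
# continues a locally linear signal exactly and so leaves straight
# baselines untouched at the edges
.movavg <- function(x, w) {
  h <- (w - 1L) %/% 2L
  n <- length(x)
  xp <- c(2 * x[1L] - x[seq.int(h + 1L, 2L)],
          x,
          2 * x[n] - x[seq.int(n - 1L, n - h)])
  as.numeric(stats::filter(xp, rep(1 / w, w), sides = 2L))[
    seq.int(h + 1L, h + length(x))]
}

#' Locate a peak in a voltammogram window
#'
#' The peak current Ip is the maximum (baseline-corrected) current inside
#' the search window; the peak potential Ep refines the grid maximum by a
#' parabola through the maximum and its two neighbours. A maximum below
#' 3 times the median absolute deviation of the whole corrected sweep is
#' reported as no peak.
#'
#' @param v A (typically baseline-corrected) [voltammogram()].
#' @param search_window Numeric length-2: potential window (V) to search.
#' @return List with `found` (logical), `ep` (V), `ip` (A), and
#'   `noise_floor` (A, the 3-MAD threshold). `ep`/`ip` are `NA` when no
#'   peak clears the floor.
#' @export
find_peak_current <- function(v, search_window) {
  stopifnot(inherits(v, "voltammogram"), length(search_window) == 2L)
  lo <- min(search_window); hi <- max(search_window)
  idx <- which(v$potential >= lo & v$potential <= hi)
  if (!length(idx))
    stop("search window contains no data points", call. = FALSE)
  floor3 <- 3 * stats::mad(v$current, center = 0)
  i_max <- idx[which.max(v$current[idx])]
  ip <- v$current[i_max]
  if (ip <= floor3)
    return(list(found = FALSE, ep = NA_real_, ip = NA_real_,
                noise_floor = floor3))
  ep <- v$potential[i_max]
  if (i_max > 1L && i_max < nrow(v)) {
    y1 <- v$current[i_max - 1L]; y2 <- ip; y3 <- v$current[i_max + 1L]
    denom <- y1 - 2 * y2 + y3
    if (denom < 0) {  # concave: refine vertex
      delta <- 0.5 * (y1 - y3) / denom
      step <- (v$potential[i_max + 1L] - v$potential[i_max - 1L]) / 2
      ep <- ep + delta * step
      ip <- y2 - 0.25 * (y1 - y3) * delta
    }
  }
  list(found = TRUE, ep = ep, ip = ip, noise_floor = floor3)
}

#' Electrochemical binding constant from peak-current suppression
#'
#' Ligand binding to dsDNA suppresses the base-oxidation peak currents; the
#' suppression obeys
#' \deqn{\log \frac{1}{[drug]} = \log K_b +
#'       \log \frac{S_{complex}}{S_{free} - S_{complex}}}
#' where \eqn{S_{free}} is the peak current of dsDNA alone and
#' \eqn{S_{complex}} the current at each drug concentration. Ordinary least
#' squares of \eqn{\log_{10}(1/[drug])} against
#' \eqn{\log_{10}(S_{complex}/(S_{free}-S_{complex}))} puts \eqn{\log K_b}
#' in the intercept; the slope is expected near 1 and a deviation beyond
#' 0.25 raises a warning.
#'
#' @param drug_conc Drug concentrations (mol/L), positive.
#' @param s_complex Peak currents (A) in the presence of the drug,
#'   `0 < s_complex < s_free`; violating points are excluded with a warning.
#' @param s_free Peak current (A) of the dsDNA solution alone.
#' @return A `binding_fit` with `method = "electrochemical"`,
#'   `kb = 10^intercept`.
#' @export
electro_binding_fit <- function(drug_conc, s_complex, s_free) {
  drug_conc <- as.numeric(drug_conc); s_complex <- as.numeric(s_complex)
  if (length(drug_conc) != length(s_complex))
    stop("drug_conc and s_complex must have equal length", call. = FALSE)
  if (any(drug_conc <= 0))
    stop("drug_conc must be positive", call. = FALSE)
  if (!is.finite(s_free) || s_free <= 0)
    stop("s_free must be a positive current", call. = FALSE)
  usable <- s_complex > 0 & s_complex < s_free
  if (any(!usable))
    warning(sprintf("%d point(s) with s_complex outside (0, s_free) excluded",
                    sum(!usable)), call. = FALSE)
  drug_conc <- drug_conc[usable]; s_complex <- s_complex[usable]
  if (length(drug_conc) < 3L)
    stop("fewer than 3 usable suppression points", call. = FALSE)
  x <- log10(s_complex / (s_free - s_complex))
  y <- log10(1 / drug_conc)
  ols <- .ols(x, y)
  kb <- 10^ols$intercept
  kb_se <- kb * log(10) * ols$intercept_se
  flags <- character()
  if (abs(ols$slope - 1) > 0.25) {
    flags <- "slope_far_from_1"
    warning(sprintf("suppression slope %.3f deviates from 1 by > 0.25",
                    ols$slope), call. = FALSE)
  }
  new_binding_fit("electrochemical", kb = kb, kb_stderr = kb_se, ols = ols,
                  x = x, y = y, flags = flags)
}
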