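#' Titration series
#'
#' Container for the optical response of a fixed dsDNA solution as the ligand
#' (or quencher) concentration is varied: either UV-vis absorbance or
#' fluorescence emission intensity at a single observation wavelength.
#'
#' @param ligand_conc Numeric vector of titrant concentrations (mol/L),
#'   non-negative. Reordered (with a warning) if not already increasing.
#' @param response Numeric vector of the same length: absorbance (AU) for
#'   `kind = "uv_absorbance"`, emission intensity (arbitrary units) for
#'   `kind = "fluorescence"`.
#' @param macromolecule_conc Fixed dsDNA concentration (mol/L, per
#'   nucleotide), strictly positive.
#' @param wavelength_nm Observation wavelength (nm).
#' @param kind `"uv_absorbance"` or `"fluorescence"`.
#' @param path_cm Optical path length (cm); default 1.
#'
#' @return An object of class `titration_series`: a data frame with columns
#'   `ligand_conc` and `response` and attributes holding the fixed-solution
#'   metadata.
#' @export
titration_series <- function(ligand_conc, response, macromolecule_conc,
                             wavelength_nm = 260,
                             kind = c("uv_absorbance", "fluorescence"),
                             path_cm = 1) {
  kind <- match.arg(kind)
  ligand_conc <- as.numeric(ligand_conc)
  response <- as.numeric(response)
  if (length(ligand_conc) != length(response))
    stop("ligand_conc and response must have equal length", call. = FALSE)
  if (length(ligand_conc) < 3L)
    stop("a titration series needs at least 3 points", call. = FALSE)
  if (anyNA(ligand_conc) || any(!is.finite(ligand_conc)))
    stop("ligand_conc must be finite", call. = FALSE)
  if (any(!is.finite(response)))
    stop("response must be finite", call. = FALSE)
  if (any(ligand_conc < 0))
    stop("ligand_conc must be non-negative", call. = FALSE)
  if (is.unsorted(ligand_conc, strictly = TRUE)) {
    if (anyDuplicated(ligand_conc))
      stop("ligand_conc must be strictly increasing (duplicates found)",
           call. = FALSE)
    warning("ligand_conc not increasing; points reordered", call. = FALSE)
    ord <- order(ligand_conc)
    ligand_conc <- ligand_conc[ord]
    response <- response[ord]
  }
  if (!is.numeric(macromolecule_conc) || length(macromolecule_conc) != 1L ||
      !is.finite(macromolecule_conc) || macromolecule_conc <= 0)
    stop("macromolecule_conc must be a single positive number (mol/L)",
         call. = FALSE)
  structure(
    data.frame(ligand_conc = ligand_conc, response = response),
    macromolecule_conc = macromolecule_conc,
    wavelength_nm = wavelength_nm,
    kind = kind,
    path_cm = path_cm,
    class = c("titration_series", "data.frame")
  )
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf("<titration_series> %s, %d points, dsDNA %.4g M, %g nm\n",
              attr(x, "kind"), nrow(x), attr(x, "macromolecule_conc"),
              attr(x, "wavelength_nm")))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Melting curve
#'
#' Absorbance at 260 nm versus temperature for one sample, the raw record of
#' a thermal-denaturation experiment.
#'
#' @param temperature Temperatures (deg C), strictly increasing, >= 5 points.
#' @param absorbance Absorbance at 260 nm (AU), finite.
#' @param label Sample identifier.
#' @return Object of class `melting_curve` (a data frame).
#' @export
melting_curve <- function(temperature, absorbance, label = "sample") {
  temperature <- as.numeric(temperature)
  absorbance <- as.numeric(absorbance)
  if (length(temperature) != length(absorbance))
    stop("temperature and absorbance must have equal length", call. = FALSE)
  if (length(temperature) < 5L)
    stop("a melting curve needs at least 5 points", call. = FALSE)
  if (any(!is.finite(temperature)))
    stop("temperature must be finite", call. = FALSE)
  if (is.unsorted(temperature, strictly = TRUE))
    stop("temperature not increasing", call. = FALSE)
  if (any(!is.finite(absorbance)))
    stop("absorbance must be finite", call. = FALSE)
  structure(
    data.frame(temperature = temperature, absorbance = absorbance),
    label = as.character(label),
    class = c("melting_curve", "data.frame")
  )
}

#' @export
print.melting_curve <- function(x, ...) {
  cat(sprintf("<melting_curve> '%s', %d points, %.1f-%.1f degC\n",
              attr(x, "label"), nrow(x), min(x$temperature),
              max(x$temperature)))
  invisible(x)
}

#' Voltammogram
#'
#' Current versus applied potential for one differential-pulse-voltammetry
#' sweep.
#'
#' @param potential Potentials (V vs reference), strictly monotonic,
#'   >= 20 points.
#' @param current Currents (A), finite.
#' @param metadata Named list of scan parameters (scan rate V/s, step
#'   potential V, modulation amplitude V, modulation time s, interval time s).
#' @return Object of class `voltammogram` (a data frame).
#' @export
voltammogram <- function(potential, current, metadata = list()) {
  potential <- as.numeric(potential)
  current <- as.numeric(current)
  if (length(potential) != length(current))
    stop("potential and current must have equal length", call. = FALSE)
  if (length(potential) < 20L)
    stop("a voltammogram needs at least 20 points", call. = FALSE)
  d <- diff(potential)
  if (!(all(d > 0) || all(d < 0)))
    stop("potential must be strictly monotonic", call. = FALSE)
  if (any(!is.finite(current)))
    stop("current must be finite", call. = FALSE)
  structure(
    data.frame(potential = potential, current = current),
    metadata = metadata,
    class = c("voltammogram", "data.frame")
  )
}

#' @export
print.voltammogram <- function(x, ...) {
  cat(sprintf("<voltammogram> %d points, %.3f to %.3f V\n",
              nrow(x), x$potential[1L], x$potential[nrow(x)]))
  invisible(x)
}

#' Flow-time series
#'
#' Viscometer flow times of a dsDNA solution at increasing ligand
#' concentrations, together with the buffer reference flow time, as used for
#' relative-viscosity binding-mode analysis.
#'
#' @param t0 Buffer (reference) flow time (s), > 0.
#' @param t Flow times (s), one per ligand addition (the zero-ligand point is
#'   the plain dsDNA solution).
#' @param ligand_conc Ligand concentrations (mol/L), non-negative increasing.
#' @param dna_conc dsDNA concentration (mol/L), > 0.
#' @return Object of class `flow_time_series`.
#' @export
flow_time_series <- function(t0, t, ligand_conc, dna_conc) {
  t0 <- as.numeric(t0); t <- as.numeric(t)
  ligand_conc <- as.numeric(ligand_conc)
  if (length(t0) != 1L || !is.finite(t0) || t0 <= 0)
    stop("t0 must be a single positive flow time (s)", call. = FALSE)
  if (length(t) != length(ligand_conc))
    stop("t and ligand_conc must have equal length", call. = FALSE)
  if (any(!is.finite(t)))
    stop("flow times must be finite", call. = FALSE)
  if (any(ligand_conc < 0) || is.unsorted(ligand_conc, strictly = TRUE))
    stop("ligand_conc must be non-negative and strictly increasing",
         call. = FALSE)
  if (!is.numeric(dna_conc) || dna_conc <= 0)
    stop("dna_conc must be positive", call. = FALSE)
  structure(
    data.frame(ligand_conc = ligand_conc, t = t,
               below_t0 = t < t0),  # flagged, not dropped
    t0 = t0, dna_conc = dna_conc,
    class = c("flow_time_series", "data.frame")
  )
}

#' @export
print.flow_time_series <- function(x, ...) {
  cat(sprintf("<flow_time_series> %d points, t0 = %.3g s, DNA %.4g M\n",
              nrow(x), attr(x, "t0"), attr(x, "dna_conc")))
  invisible(x)
}

#' Rheogram
#'
#' Shear stress versus shear rate for one sample, the raw record used to fit
#' the Herschel-Bulkley flow model.
#'
#' @param shear_rate Shear rates (1/s), strictly increasing, positive.
#' @param shear_stress Shear stresses (Pa), finite.
#' @param label Sample identifier.
#' @return Object of class `rheogram` (a data frame).
#' @export
rheogram <- function(shear_rate, shear_stress, label = "sample") {
  shear_rate <- as.numeric(shear_rate)
  shear_stress <- as.numeric(shear_stress)
  if (length(shear_rate) != length(shear_stress))
    stop("shear_rate and shear_stress must have equal length", call. = FALSE)
  if (any(shear_rate <= 0) || is.unsorted(shear_rate, strictly = TRUE))
    stop("shear_rate must be positive and strictly increasing", call. = FALSE)
  if (any(!is.finite(shear_stress)))
    stop("shear_stress must be finite", call. = FALSE)
  structure(
    data.frame(shear_rate = shear_rate, shear_stress = shear_stress),
    label = as.character(label),
    class = c("rheogram", "data.frame")
  )
}

#' @export
print.rheogram <- function(x, ...) {
  cat(sprintf("<rheogram> '%s', %d points, %.3g-%.3g 1/s\n",
              attr(x, "label"), nrow(x), min(x$shear_rate),
              max(x$shear_rate)))
  invisible(x)
}
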