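#' Ground-truth parameter set for synthetic instrument data
#'
#' Collects every parameter the signal generators draw on, with defaults
#' set to the study conditions the package's worked examples reproduce:
#' UV binding constant 3.22e4 1/M; Stern-Volmer constants 1.17e2 (EtBr
#' probe) and 1.63e3 1/M (Hoechst probe); double-log binding constant
#' 2.57e4 1/M with stoichiometry 1.17; melting midpoints 72.2 (free dsDNA)
#' and 77.6 deg C (complex); voltammetric base-oxidation peaks at +1.09
#' and +1.36 V with electrochemical binding constants 6.02e4 and 5.75e3
#' 1/M; Herschel-Bulkley flow parameters (0.32 Pa, 5.95e-5 Pa s^n, 1.57);
#' calibration line I = -5e-9 C + 3e-7 A over 2.5-20 uM with residual SD
#' 1.155e-9 A (the value consistent with a 2.31 uM quantification limit).
#' Extinction coefficients and intensity scales, which the instruments do
#' not constrain, use round spectroscopically plausible values (dsDNA
#' 6600 1/(M cm) per nucleotide free, 30% hyperchromic when saturated).
#'
#' @param ... Named overrides of any default listed above.
#' @return A list of class `ground_truth`.
#' @export
ground_truth <- function(...) {
  truth <- list(
    kb_true = 3.22e4,             # 1/M, UV isotherm
    ksv_true = c(etbr = 1.17e2, hoechst = 1.63e3),  # 1/M
    kb_quench = 2.57e4,           # 1/M, double-log model
    n_true = 1.17,                # binding stoichiometry
    i0 = 1000,                    # a.u., unquenched intensity
    eps_f = 6600,                 # 1/(M cm), free chromophore
    eps_b = 8580,                 # 1/(M cm), fully bound (hyperchromic)
    tm_true = 77.6,               # deg C, complex midpoint
    tm_free = 72.2,               # deg C, free dsDNA midpoint
    transition_width = 2.5,       # deg C, logistic width
    melt_lower = 0.60,            # AU, folded plateau
    melt_upper = 0.85,            # AU, denatured plateau
    peak_centers = c(dGuo = 1.09, dAdo = 1.36),   # V
    peak_heights = c(dGuo = 3.0e-7, dAdo = 1.5e-7),  # A
    peak_widths = c(dGuo = 0.04, dAdo = 0.04),    # V (Gaussian sigma)
    kb_electro = c(dGuo = 6.02e4, dAdo = 5.75e3), # 1/M
    baseline_coef = c(1.0e-8, 4.0e-8),  # A, A/V: linear background
    hb_params = c(tau0 = 0.32, k = 5.95e-5, n = 1.57),
    flow_t0 = 100,                # s, buffer flow time
    flow_eta0 = 0.60,             # specific viscosity of plain dsDNA
    visc_slope = 0,               # cube-root units per r (0 = groove-like)
    calib = c(slope = -5e-9, intercept = 3e-7, residual_sd = 1.155e-9),
    noise_sd = 0.01               # relative noise, shared default
  )
  override <- list(...)
  unknown <- setdiff(names(override), names(truth))
  if (length(unknown))
    stop("unknown ground-truth parameter(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  truth[names(override)] <- override
  structure(truth, class = "ground_truth")
}

# Run `expr` under a locally seeded RNG, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a UV-vis titration of dsDNA with a ligand
#'
#' The apparent extinction coefficient interpolates between the free and
#' bound values with the bound fraction of a 1:1 complexation isotherm:
#' `eps_a = eps_f + f (eps_b - eps_f)`, response
#' `= eps_a * path * dna_conc`, plus Gaussian noise of standard deviation
#' `noise_sd * response`. `mass_action = "ideal"` (default) takes
#' `f = Kb L / (1 + Kb L)` with L the total ligand concentration — the
#' assumption under which the Benesi-Hildebrand linearization is exact, so
#' noise-free fits recover `kb_true` identically. `"exact"` solves 1:1
#' mass action (quadratic root) with ligand depletion, letting the
#' linearization bias of the double-reciprocal analysis be measured.
#'
#' @param truth A [ground_truth()].
#' @param dna_conc Fixed dsDNA concentration (M per nucleotide).
#' @param ligand_concs Ligand concentrations (M), non-negative increasing;
#'   include 0 so downstream fits can anchor `eps_f`.
#' @param noise_sd Relative noise (0 reproduces the model exactly).
#' @param seed Optional integer seed recorded in the output metadata.
#' @param mass_action `"ideal"` or `"exact"` (see above).
#' @return A [titration_series()] of kind `"uv_absorbance"` with attribute
#'   `"seed"`.
#' @export
gen_uv_titration <- function(truth = ground_truth(),
                             dna_conc = 150e-6,
                             ligand_concs = c(0, seq(25e-6, 300e-6,
                                                     by = 25e-6)),
                             noise_sd = truth$noise_sd, seed = NULL,
                             mass_action = c("ideal", "exact")) {
  mass_action <- match.arg(mass_action)
  if (any(ligand_concs < 0))
    stop("ligand concentrations must be non-negative", call. = FALSE)
  kb <- truth$kb_true
  l <- ligand_concs
  f <- if (mass_action == "ideal") {
    kb * l / (1 + kb * l)
  } else {
    b <- dna_conc + l + 1 / kb
    cplx <- (b - sqrt(b^2 - 4 * dna_conc * l)) / 2
    cplx / dna_conc
  }
  eps_a <- truth$eps_f + f * (truth$eps_b - truth$eps_f)
  resp <- eps_a * 1 * dna_conc
  resp <- .with_seed(seed,
    resp + stats::rnorm(length(resp), 0, noise_sd * resp))
  out <- titration_series(l, resp, macromolecule_conc = dna_conc,
                          wavelength_nm = 260, kind = "uv_absorbance")
  attr(out, "seed") <- seed
  out
}

#' Simulate a fluorescence-quenching titration
#'
#' With `model = "stern_volmer"` the intensity follows
#' `I = I0 / (1 + Ksv Q)` (Ksv selected by `probe`); with
#' `model = "double_log"` it follows the stoichiometric generalisation
#' `I = I0 / (1 + Kb Q^n)`, from which [double_log_fit()] recovers
#' (`kb_quench`, `n_true`) exactly in the noise-free case (and the two
#' models coincide when n = 1).
#'
#' @param truth A [ground_truth()].
#' @param probe `"hoechst"` or `"etbr"` (chooses the Stern-Volmer constant).
#' @param ligand_concs Quencher concentrations (M) including 0.
#' @param noise_sd Relative noise.
#' @param seed Optional integer seed.
#' @param model `"stern_volmer"` (default) or `"double_log"`.
#' @return A [titration_series()] of kind `"fluorescence"`.
#' @export
gen_quench_series <- function(truth = ground_truth(),
                              probe = c("hoechst", "etbr"),
                              ligand_concs = c(0, seq(50e-6, 300e-6,
                                                      by = 50e-6)),
                              noise_sd = truth$noise_sd, seed = NULL,
                              model = c("stern_volmer", "double_log")) {
  probe <- match.arg(probe)
  model <- match.arg(model)
  if (any(ligand_concs < 0))
    stop("quencher concentrations must be non-negative", call. = FALSE)
  q <- ligand_concs
  i <- if (model == "stern_volmer") {
    truth$i0 / (1 + truth$ksv_true[[probe]] * q)
  } else {
    truth$i0 / (1 + truth$kb_quench * q^truth$n_true)
  }
  i <- .with_seed(seed, i + stats::rnorm(length(i), 0, noise_sd * i))
  out <- titration_series(q, i, macromolecule_conc = 150e-6,
                          wavelength_nm = 460, kind = "fluorescence")
  attr(out, "seed") <- seed
  attr(out, "probe") <- probe
  out
}

#' Simulate an absorbance-vs-temperature melting curve
#'
#' Four-parameter logistic in temperature: plateaus `melt_lower` and
#' `melt_upper`, midpoint `tm`, width `transition_width`, plus relative
#' Gaussian noise.
#'
#' @param truth A [ground_truth()].
#' @param temp_grid Temperatures (deg C), increasing.
#' @param tm Midpoint (deg C); defaults to the complex midpoint
#'   `truth$tm_true` (pass `truth$tm_free` for the reference curve).
#' @param noise_sd Relative noise.
#' @param seed Optional integer seed.
#' @param label Sample label.
#' @return A [melting_curve()].
#' @export
gen_melting_curve <- function(truth = ground_truth(),
                              temp_grid = seq(20, 100, by = 0.5),
                              tm = truth$tm_true,
                              noise_sd = truth$noise_sd, seed = NULL,
                              label = "synthetic") {
  ab <- truth$melt_lower + (truth$melt_upper - truth$melt_lower) /
    (1 + exp(-(temp_grid - tm) / truth$transition_width))
  ab <- .with_seed(seed, ab + stats::rnorm(length(ab), 0, noise_sd * ab))
  out <- melting_curve(temp_grid, ab, label = label)
  attr(out, "seed") <- seed
  out
}

#' Simulate a differential pulse voltammogram
#'
#' Sum of Gaussian oxidation peaks on a linear background. At drug
#' concentration L each peak height is scaled by the binding-suppression
#' factor `S(L) = 1 / (1 + Kb L)` (Kb per peak from `kb_electro`), so a
#' noise-free concentration series satisfies the logarithmic suppression
#' model of [electro_binding_fit()] exactly. Noise is Gaussian with SD
#' `noise_sd * max(peak_heights)`.
#'
#' @param truth A [ground_truth()].
#' @param potential_grid Potentials (V), increasing.
#' @param drug_conc Drug concentration (M) controlling peak suppression.
#' @param noise_sd Relative noise (relative to the tallest peak).
#' @param seed Optional integer seed.
#' @return A [voltammogram()].
#' @export
gen_voltammogram <- function(truth = ground_truth(),
                             potential_grid = seq(0.8, 1.6, by = 0.002),
                             drug_conc = 0,
                             noise_sd = truth$noise_sd, seed = NULL) {
  if (drug_conc < 0) stop("drug_conc must be non-negative", call. = FALSE)
  cur <- truth$baseline_coef[1L] + truth$baseline_coef[2L] * potential_grid
  for (p in seq_along(truth$peak_centers)) {
    supp <- 1 / (1 + truth$kb_electro[[p]] * drug_conc)
    cur <- cur + truth$peak_heights[[p]] * supp *
      exp(-(potential_grid - truth$peak_centers[[p]])^2 /
            (2 * truth$peak_widths[[p]]^2))
  }
  cur <- .with_seed(seed,
    cur + stats::rnorm(length(cur), 0,
                       noise_sd * max(truth$peak_heights)))
  out <- voltammogram(potential_grid, cur,
                      metadata = list(scan_rate_v_s = 0.01,
                                      step_potential_v = 0.008,
                                      modulation_amplitude_v = 0.05,
                                      modulation_time_s = 0.05,
                                      interval_time_s = 0.5,
                                      drug_conc_m = drug_conc))
  attr(out, "seed") <- seed
  out
}

#' Simulate a shear-stress/shear-rate flow curve
#'
#' Herschel-Bulkley model `tau = tau0 + K rate^n` plus relative Gaussian
#' noise.
#'
#' @param truth A [ground_truth()] (`hb_params` used).
#' @param shear_rates Shear rates (1/s), increasing, positive.
#' @param noise_sd Relative noise.
#' @param seed Optional integer seed.
#' @return A [rheogram()].
#' @export
gen_rheogram <- function(truth = ground_truth(),
                         shear_rates = seq(50, 1000, length.out = 25),
                         noise_sd = truth$noise_sd, seed = NULL) {
  p <- truth$hb_params
  tau <- p[["tau0"]] + p[["k"]] * shear_rates^p[["n"]]
  tau <- .with_seed(seed, tau + stats::rnorm(length(tau), 0,
                                             noise_sd * tau))
  out <- rheogram(shear_rates, tau, label = "synthetic")
  attr(out, "seed") <- seed
  out
}

#' Simulate viscometer flow times along a ligand titration
#'
#' Target relative viscosities follow
#' `(eta/eta0)^(1/3) = 1 + visc_slope * r` with `r = [ligand]/[DNA]`:
#' `visc_slope = 0` emulates a groove binder (flat), a positive slope an
#' intercalator (helix lengthening). Flow times are back-computed as
#' `t = t0 (1 + eta)` plus relative Gaussian noise on `t - t0`.
#'
#' @param truth A [ground_truth()].
#' @param ligand_concs Ligand concentrations (M) starting at 0.
#' @param dna_conc dsDNA concentration (M).
#' @param noise_sd Relative noise on the specific flow-time increment.
#' @param seed Optional integer seed.
#' @return A [flow_time_series()].
#' @export
gen_flow_times <- function(truth = ground_truth(),
                           ligand_concs = seq(0, 360e-6, by = 30e-6),
                           dna_conc = 120e-6,
                           noise_sd = truth$noise_sd, seed = NULL) {
  r <- ligand_concs / dna_conc
  eta <- truth$flow_eta0 * (1 + truth$visc_slope * r)^3
  dt <- truth$flow_t0 * eta
  dt <- .with_seed(seed, dt * (1 + stats::rnorm(length(dt), 0, noise_sd)))
  out <- flow_time_series(truth$flow_t0, truth$flow_t0 + dt,
                          ligand_concs, dna_conc)
  attr(out, "seed") <- seed
  out
}

#' Simulate a concentration-response calibration table
#'
#' Linear response `I = slope C + intercept` with homoscedastic Gaussian
#' residuals of SD `truth$calib["residual_sd"]` (in amperes, not relative:
#' a regression residual SD is what the LOD/LOQ formulas consume).
#'
#' @param truth A [ground_truth()].
#' @param concs_um Calibration concentrations (uM).
#' @param replicates Replicates per concentration.
#' @param seed Optional integer seed.
#' @return Data frame with columns `conc_um`, `current_a` and attribute
#'   `"seed"`.
#' @export
gen_calibration <- function(truth = ground_truth(),
                            concs_um = seq(2.5, 20, by = 2.5),
                            replicates = 1L, seed = NULL) {
  conc <- rep(concs_um, each = replicates)
  cal <- truth$calib
  cur <- cal[["slope"]] * conc + cal[["intercept"]]
  cur <- .with_seed(seed,
    cur + stats::rnorm(length(cur), 0, cal[["residual_sd"]]))
  structure(data.frame(conc_um = conc, current_a = cur), seed = seed)
}
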