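---
title: "Models and methods behind dnabind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dnabind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnabind)
```

`dnabind` estimates how a small molecule binds double-stranded DNA from
six orthogonal experiments and synthesises the evidence into an explicit
binding-mode call. This vignette documents the models, the choices made
where the methodology is genuinely open, the numerical details, and the
limits of what the test suite can demonstrate.

Units are mol/L, kelvin, amperes and volts internally; degrees Celsius
appear at melting-curve boundaries and micromolar in the quantification
reporting layer, where figures of merit are conventionally quoted per µM.

## Binding-constant estimators

### Benesi–Hildebrand (UV–vis)

For a 1:1 complex monitored through an apparent extinction coefficient
`eps_a = A/(path * [dsDNA])`, the double-reciprocal form

$$\frac{C}{\varepsilon_a-\varepsilon_f} =
  \frac{C}{\varepsilon_b-\varepsilon_f} +
  \frac{1}{K_b(\varepsilon_b-\varepsilon_f)}$$

is linear in the varied concentration $C$, and $K_b$ is the
slope/intercept ratio. Three deliberate choices:

* **Which axis is $C$.** The classical equation is written in the dsDNA
  concentration, but in a drug-titration experiment the axis actually
  varied is the ligand's. `benesi_hildebrand_fit(mode =)` offers both
  readings (`"vary_ligand"` default, `"vary_dna"` for the literal one);
  numerically the regression is the same, and the mode is recorded in the
  fit so reports are unambiguous.
* **$\varepsilon_f$ from the zero-ligand point**, not a literature value:
  the analysis stays self-contained, at the cost of propagating that
  single point's noise into every denominator.
* **Unweighted OLS**, matching double-reciprocal plot practice. The fit is
  flagged `kb_unreliable` when the intercept is statistically
  indistinguishable from zero (|intercept| < 2 SE), which is what a
  fully saturated series produces.

The generator (`gen_uv_titration`) exposes the estimator's central
assumption. With `mass_action = "ideal"` the bound fraction is
$K_bL/(1+K_bL)$ in the *total* ligand concentration — the regime in which
the linearization is exact, so noise-free fits recover the generating
constant identically. With `mass_action = "exact"` the 1:1 mass-action
quadratic is solved with ligand depletion; at the default conditions
(150 µM dsDNA, 25–300 µM ligand, $K_b = 3.22\times10^4$ 1/M) the fixed
DNA consumes most of the titrant at the low end, free and total ligand
diverge grossly, and the double-reciprocal fit is biased low by roughly
an order of magnitude. The test suite measures that bias explicitly; it
is the reason modern practice prefers nonlinear isotherm fits.

### Stern–Volmer and double-log (fluorescence)

`stern_volmer_fit` regresses $I_0/I$ on $[Q]$ with a *free* intercept:
forcing it through 1 would hide curvature and zero-point errors, so a
deviation beyond 0.1 warns instead. `double_log_fit` fits
$\log_{10}\frac{I_0-I}{I} = \log_{10}K_b + n\log_{10}[Q]$, excluding the
zero-quencher point (it defines $I_0$) and any interior point with
$I \ge I_0$ (with a warning). Base-10 logarithms are applied to both
sides; $K_b$ depends on that consistency, not on the base. No
inner-filter correction is applied by default, appropriate for absorbances
low enough that the effect does not perturb linearity.

`displacement_compare` calls the displaced probe from the ratio of the
two Stern–Volmer constants with a default fold-threshold of 5: an order
of magnitude is the unambiguous regime, 5 keeps moderate but clear
contrasts decisive while sending near-equal quenching to
`"indeterminate"`.

### Voltammetric suppression

Ligand binding lowers the dGuo (+1.09 V) and dAdo (+1.36 V) base-oxidation
peak currents. `electro_binding_fit` regresses $\log_{10}(1/[drug])$ on
$\log_{10}(S_{complex}/(S_{free}-S_{complex}))$, so $\log K_b$ is the
intercept and the theoretical slope is 1 (a deviation beyond 0.25 warns).
The source methodology states only that "slope and intercept" were used;
this orientation is the one consistent with the model equation as usually
printed, and is documented here as a choice.

Peak measurement: `baseline_correct` runs exactly 50 passes of
pointwise-minimum moving-average stripping (pass count fixed for
determinism; the estimate can only decrease, so corrected currents are
non-negative where the raw sweep sits on its baseline). Edges are padded
by reflection (`2*end − mirror`), which continues a locally linear
background exactly — with constant padding the edge error compounds over
the iterations. `find_peak_current` takes the window maximum, refines the
potential by a parabola through the maximum and its neighbours, and
declares "no peak" below 3× the MAD of the corrected sweep. The window
should be wide relative to the peak (at the default synthetic grid of
2 mV and 0.04 V Gaussian peaks, 151 points = 0.3 V keeps height error
under 2% and double application changes the result by <0.1%).

## Thermodynamics

`vant_hoff_fit` uses $R = 8.314$ J/(mol K) and treats $K_b$ as
dimensionless inside the logarithm (implicit 1 M standard state). With
four or more temperatures a quadratic term in $1/T$ is tested and
significant curvature (5% level) warns — a linear van't Hoff analysis
assumes temperature-independent $\Delta H$. Force classification uses the
exact signs of the point estimates, as the qualitative sign rules are
conventionally applied; zero on either axis, or the
$\Delta H>0,\Delta S<0$ quadrant (no spontaneous binding at any
temperature), returns `"indeterminate"` with an explanation.

Worth recording: applying $\Delta G = \Delta H - T\Delta S$ with the
*rounded* tabulated $\Delta H$/$\Delta S$ reproduces a published-style
ΔG table at the highest temperature exactly and is 0.01 kJ/mol off at the
two lower ones — the difference between deriving the column from rounded
inputs and from unrounded ones. The tests assert the identity at 2 dp
with a 0.02 kJ/mol allowance for exactly this reason.

## Melting

`fit_melting_curve` fits a four-parameter logistic (two plateaus,
midpoint, width) by Levenberg–Marquardt; if that fails it falls back to
interpolating the temperature at the absorbance halfway between plateau
means (means of the coolest and hottest 15% of points) and records which
path produced the answer. A fitted amplitude indistinguishable from noise
(below 4 residual SDs *and* below 2% of the mean absorbance), or a
midpoint outside the data range, raises a "no transition" error rather
than returning a number.

`interpret_delta_tm` uses `intercalation_min = 10` °C (the canonical
~10–12 °C intercalator stabilisation) and `groove_max = 6` °C, chosen so
the 5–6 °C shifts typical of groove binders classify as such while
leaving an explicit ambiguous band; both are arguments, not constants.
One known source-data quirk: a published ΔTm column can disagree with the
subtraction of its own Tm entries (11.6 vs 83.4 − 72.2 = 11.2);
`delta_tm` always reports the subtraction.

## Viscometry and rheology

Relative viscosity uses flow times: $\eta = (t - t_0)/t_0$ against the
buffer time, $\eta_0$ from the zero-ligand (dsDNA-only) point, and the
cube root $(\eta/\eta_0)^{1/3}$ plotted against $r = [ligand]/[DNA]$ —
the exponent that tracks contour-length change of a rodlike polymer.
`viscosity_trend_test` is an OLS slope with 95% CI; the trend is flat
when the CI spans zero *or* the predicted change over the observed
r-range is under 0.05 cube-root units, a practical-significance floor
(at ~1, a 5% change) below which length change is not credible —
statistically detectable microdrifts should not flip a binding-mode call.

The Herschel–Bulkley model $\tau = \tau_0 + K\dot\gamma^n$ is fitted by
Levenberg–Marquardt with box constraints ($\tau_0 \ge 0$, $K, n > 0$) and
three starts ($n_0 = 0.5, 1, 1.5$, spanning shear-thinning through
shear-thickening), keeping the lowest-SSE convergent fit. The functional
form itself is inferred from the standard meaning of yield-stress /
consistency / flow-index parameter tables; the source never writes the
equation. Because the reference shear rate behind a tabulated "viscosity"
column is generally unstated, apparent viscosity is only reported at a
user-supplied rate.

## Quantification and validation

Calibration is unweighted OLS of current on concentration (µM), residual
SD on $n-2$ degrees of freedom, and LOD/LOQ = 3 and 10 × SD/|slope| — so
LOQ/LOD = 10/3 identically. The SD is the calibration residual SD (the
usual ICH reading of the formulas); a blank-replicate SD can be passed to
`lod_loq` directly. Note the arithmetic consequence: published LOD/LOQ
pairs rounded to 2 dp are rarely in an exact 3:10 ratio (0.693 prints as
0.70); `dnabind` reports unrounded values. Outliers are flagged at
|studentized residual| > 3 but never dropped. All validation statistics
use the $n-1$ sample SD, `%RSD = 100·SD/mean`, and recovery bias = mean
recovery − 100 by construction.

## The synthetic-data generator

`ground_truth()` fixes every generator parameter; defaults are the
package's reference study conditions (binding constants 3.22 × 10⁴ UV,
1.17 × 10²/1.63 × 10³ Stern–Volmer, 2.57 × 10⁴ with n = 1.17 double-log,
6.02 × 10⁴/5.75 × 10³ electrochemical; Tm 72.2/77.6 °C; peaks at
+1.09/+1.36 V; Herschel–Bulkley (0.32, 5.95 × 10⁻⁵, 1.57); calibration
−5 × 10⁻⁹ C + 3 × 10⁻⁷ A over 2.5–20 µM). Values the signals do not
constrain are set once to spectroscopically plausible round numbers:
ε_f = 6600 1/(M cm) per nucleotide (the canonical dsDNA 260 nm
coefficient) with a 30% hyperchromic bound form, unquenched intensity
1000 a.u., melting plateaus 0.60→0.85 AU with a 2.5 °C logistic width,
Gaussian peak widths 0.04 V on a linear 10–40 nA background, buffer flow
time 100 s with dsDNA specific viscosity 0.6. The default relative noise
is 1%, set so the calibration's residual SD (1.155 × 10⁻⁹ A) is the value
consistent with a 2.31 µM quantification limit; the same source also
prints R² = 0.9700, which would demand ~4.7× more scatter and a ~3 µM
LOD — the two published figures are mutually inconsistent, and the
LOD/LOQ-consistent value was chosen.

Each generator takes an integer seed, restores the caller's RNG state,
and records the seed in the object so written files are byte-reproducible.
Noise is Gaussian: relative to the signal for optical data, relative to
the tallest peak for voltammograms, absolute (in amperes) for calibration
residuals, since a regression residual SD is what the LOD formulas
consume.

What the generator does *not* emulate: spectral lineshapes and wavelength
structure (titrations are single-wavelength), electrode kinetics (peaks
are Gaussians, not Butler–Volmer responses), multi-domain melting,
temperature-dependent rheology, and any heteroscedasticity beyond the
simple relative-noise model. Passing recovery tests therefore demonstrate
estimator correctness under the stated models, not robustness to every
instrumental artifact of real data.

## Precision at realistic noise: what recovery tests show

The suite verifies two regimes. Noise-free, every estimator inverts its
generating model to ≤0.1% (the linearized fits to machine precision,
checked against closed-form least squares at 10⁻¹² relative). At 1%
relative noise, the acceptance test measures median recovery error over
200 seeded replicates. Most quantities sit comfortably under 5%
(Stern–Volmer ~2.6%, electrochemical ~0.7%, Tm ~0.08%, stoichiometry
~1.7%, yield stress ~1.4%, flow index ~0.8%). Three do not, and the suite
reports them honestly rather than relaxing the check:

* **Benesi–Hildebrand $K_b$ (~12%)** — the constant is a slope/intercept
  ratio whose intercept is small and noise-limited, and the zero-ligand
  anchor point's noise enters every denominator.
* **Double-log $K_b$ (~16%)** — $\log K_b$ is the intercept at
  $\log_{10}[Q] = 0$, an extrapolation roughly four decades beyond the
  measured concentration range, so slope noise is amplified ~fivefold.
* **Herschel–Bulkley $K$ (~8%)** — $K$ and $n$ are nearly collinear over
  a finite shear-rate window.

In each case the median error scales linearly with the noise level (at
0.1% noise: ~1.2%, ~1.6%, ~0.8% respectively), i.e. the estimators are
unbiased and the spread is intrinsic variance amplification of the
linearizations — a quantified reminder of why reported binding constants
from double-reciprocal and double-log analyses carry large uncertainties.

## Mode inference

`aggregate_evidence` fires at most six rules in a fixed order; R1–R5 vote
groove or intercalation (Kb magnitude in [10³, 10⁵) vs ≥10⁶; ΔTm; flat vs
rising viscosity; which probe was displaced; hyperchromism without a
large red shift as a non-intercalative vote) and R6 records the
thermodynamic force class without voting, because sign rules describe
forces, not binding-site geometry. The call is the vote majority with a
two-vote minimum; ties are `"indeterminate"`; `"electrostatic"` is
emitted only when the force class says so *and* no structural evidence
exists at all. The thresholds formalise a narrative practice and are all
arguments; the defaults reproduce the reference evidence pattern (five
groove votes) and an intercalator pattern (strong binder, ~11 °C shift,
rising viscosity, intercalator probe displaced) correctly, which the
end-to-end tests assert. The rule trace makes every call reproducible
from the serialized evidence alone.

## Problem sizes and runtime

Test problem sizes are chosen to keep the full suite fast while leaving
the statistics stable: 12-point UV titrations, 7-point quench series,
161-point melting curves, 401-point voltammograms, 25-point rheograms,
8-point calibrations, and 200 seeded replicates for every stochastic
envelope. The acceptance script averages titration-derived constants over
three replicate runs, mirroring the triplicate protocol validated assays
use.

## Known limitations

* The Benesi–Hildebrand and double-log analyses inherit the classical
  linearization pathologies quantified above; the package measures them
  but deliberately does not replace the methods with nonlinear fits.
* Stern–Volmer analysis cannot separate static from dynamic quenching
  without lifetime data.
* `classify_spectral_change` reports no peak shift for single-wavelength
  series; full-spectrum input would be required.
* Baseline correction assumes peaks are narrow relative to the chosen
  window and background drift is smooth on that scale; overlapping-peak
  deconvolution is out of scope.
* The binding-mode rules are a transparent formalisation of qualitative
  literature criteria, not a probabilistic model; conflicting evidence
  yields `"indeterminate"`, never a weighted compromise.
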