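# dnabind

Multi-technique analysis of small-molecule binding to double-stranded DNA.

Whether a drug sits in a DNA groove, intercalates between base pairs, or
associates electrostatically with the backbone determines both its
pharmacology and its usefulness as a biosensor recognition element. No
single experiment settles the question; practitioners combine UV–vis and
fluorescence titrations, thermal denaturation, viscometry and
electrochemistry, and argue from the pattern. `dnabind` implements that
whole workflow as tested, reusable estimators plus an explicit, rule-based
synthesis of the evidence, together with a synthetic-data generator that
emulates every supported signal type with known ground truth, so each
estimator is verifiable by parameter recovery.

## What it computes

**Binding constants**, by four classical routes:

- *Benesi–Hildebrand* (UV–vis): for a 1:1 complex,
  `C/(εa − εf) = C/(εb − εf) + 1/(Kb (εb − εf))` is linear in the varied
  concentration `C`; `Kb = slope/intercept` of the double-reciprocal plot
  (`benesi_hildebrand_fit`).
- *Stern–Volmer* (fluorescence quenching): `I0/I = 1 + Ksv [Q]`
  (`stern_volmer_fit`), and the double-logarithmic form
  `log((I0 − I)/I) = log Kb + n log [Q]` giving the binding constant and
  stoichiometry (`double_log_fit`). A dye-displacement comparison between
  an intercalator probe (ethidium bromide) and a minor-groove probe
  (Hoechst 33258) identifies which site class the ligand competes for
  (`displacement_compare`).
- *Voltammetric suppression*: ligand binding suppresses the dGuo/dAdo
  base-oxidation peak currents of dsDNA;
  `log(1/[drug]) = log Kb + log(S_complex/(S_free − S_complex))`
  (`electro_binding_fit`), with moving-average baseline correction and
  peak location (`baseline_correct`, `find_peak_current`).

**Thermodynamics**: van't Hoff regression of `ln Kb` on `1/T` gives
ΔH = −R·slope and ΔS = R·intercept; ΔG = ΔH − TΔS; the (ΔH, ΔS) sign rules
classify the dominant forces (`vant_hoff_fit`, `gibbs`,
`classify_forces`).

**Melting**: four-parameter logistic fit of the 260 nm
absorbance-vs-temperature transition; Tm is the midpoint, and the shift
ΔTm against free dsDNA separates intercalators (≳10 °C) from groove
binders (small shifts) (`fit_melting_curve`, `delta_tm`,
`interpret_delta_tm`).

**Viscometry**: cube-root relative viscosity `(η/η0)^(1/3)` against
`r = [ligand]/[DNA]` with a trend test (intercalation lengthens the helix
and raises viscosity; groove binding leaves it flat), plus
Herschel–Bulkley rheology `τ = τ0 + K·γ̇ⁿ`
(`relative_viscosity_series`, `viscosity_trend_test`,
`herschel_bulkley_fit`).

**Quantification & validation**: calibration regression, LOD/LOQ
(3·SD/slope and 10·SD/slope), repeatability %RSD, tablet assay and
spike-recovery statistics (`calibration_fit`, `lod_loq`,
`repeatability_rsd`, `assay_tablet`, `recovery_analysis`).

**Mode inference**: `aggregate_evidence` applies six explicit rules (Kb
magnitude, ΔTm, viscosity trend, displaced probe, spectral change
direction, recorded force class) to the collected evidence and emits a
binding-mode call with a full rule trace; `run_report` orchestrates all
stages from in-memory objects or CSV files and writes versioned JSON
reports.

## Worked example

```r
library(dnabind)
truth <- ground_truth()                      # defaults: see ?ground_truth

uv  <- gen_uv_titration(truth, noise_sd = 0.005, seed = 42)
fit <- benesi_hildebrand_fit(uv)
summary(fit)
#> Binding-constant fit (benesi_hildebrand)
#>   Kb        : 31056.2 1/M  (SE 5.15e+03)
#>   slope     : 0.000509134  (SE 1.28e-05)
#>   intercept : 1.63939e-08  (SE 2.35e-09)
#>   R^2       : 0.993763   (12 points)
```

The fitted 3.1 × 10⁴ 1/M (generated from 3.22 × 10⁴ at 0.5% noise) sits in
the 10³–10⁵ range typical of groove binders, far from the 10⁶–10⁷ of
classical intercalators. Feeding all six techniques to the orchestrator:

```r
th <- vant_hoff_fit(c(288.15, 298.15, 308.15), c(3.71e4, 3.22e4, 3.12e4))
th
#> <thermo_result> van't Hoff analysis
#>   dH = -6.436 kJ/mol (SE 2.22)
#>   dS = 64.999 J/(mol K) (SE 7.46)
#>   dG(288.15 K) = -25.166 kJ/mol
#>   dG(298.15 K) = -25.816 kJ/mol
#>   dG(308.15 K) = -26.466 kJ/mol
#>   dominant forces: electrostatic

report <- run_report(list(
  uv = uv,
  fluorescence = list(
    etbr    = gen_quench_series(truth, "etbr",    noise_sd = 0.005, seed = 43),
    hoechst = gen_quench_series(truth, "hoechst", noise_sd = 0.005, seed = 42)),
  thermo  = list(temperature_k = c(288.15, 298.15, 308.15),
                 kb = c(3.71e4, 3.22e4, 3.12e4)),
  melting = list(
    complex   = gen_melting_curve(truth, tm = truth$tm_true,
                                  noise_sd = 0.005, seed = 42),
    reference = gen_melting_curve(truth, tm = truth$tm_free,
                                  noise_sd = 0.005, seed = 43)),
  viscosity = gen_flow_times(truth, noise_sd = 0.005, seed = 42)))
report
#> <binding_mode_report> mode_call = minor_groove (groove 5 : intercalation 0)
#>   R1_kb_magnitude    kb_by_method     -> groove  [31100, 1000]
#>   R2_delta_tm        delta_tm         -> groove  [5.48803]
#>   R3_viscosity       viscosity_trend  -> groove  [flat]
#>   R4_displacement    displaced_probe  -> groove  [groove_probe_displaced]
#>   R5_spectral        spectral         -> groove  [hyperchromic]
#>   R6_force_class     force_class      -> none  [electrostatic]
```

Five independent lines of evidence vote groove; the melting shift of
~5.5 °C is far below the ~10–12 °C an intercalator produces, viscosity is
flat over the titration, and the minor-groove probe — not the
intercalator probe — is displaced. The thermodynamic sign pattern
(ΔH < 0, ΔS > 0) is recorded as electrostatic *forces* but deliberately
never votes on binding-site *geometry*.

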