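# Closed-form simple-linear-regression oracle, independent of lm():
# slope = Sxy/Sxx, intercept = ybar - slope*xbar. Used to cross-check every
# linearized fit in the package.
ols_oracle <- function(x, y) {
  xbar <- sum(x) / length(x)
  ybar <- sum(y) / length(y)
  sxx <- sum((x - xbar)^2)
  sxy <- sum((x - xbar) * (y - ybar))
  slope <- sxy / sxx
  c(intercept = ybar - slope * xbar, slope = slope)
}

rel_err <- function(est, truth) abs(est - truth) / abs(truth)

# default ground truth shared across tests
tr_default <- ground_truth()

# a full six-technique configuration built from the default ground truth,
# the fixture behind the end-to-end report tests
paper_like_config <- function(noise = 0, seed = NULL) {
  tr <- tr_default
  concs <- seq(5e-6, 40e-6, by = 5e-6)
  s_free <- tr$peak_heights[["dGuo"]]
  s_complex <- s_free / (1 + tr$kb_electro[["dGuo"]] * concs)
  list(
    uv = gen_uv_titration(tr, noise_sd = noise, seed = seed),
    fluorescence = list(
      etbr = gen_quench_series(tr, "etbr", noise_sd = noise, seed = seed),
      hoechst = gen_quench_series(tr, "hoechst", noise_sd = noise,
                                  seed = seed)),
    thermo = list(temperature_k = c(288.15, 298.15, 308.15),
                  kb = c(3.71e4, 3.22e4, 3.12e4)),
    melting = list(
      complex = gen_melting_curve(tr, tm = tr$tm_true, noise_sd = noise,
                                  seed = seed),
      reference = gen_melting_curve(tr, tm = tr$tm_free, noise_sd = noise,
                                    seed = seed)),
    viscosity = gen_flow_times(tr, noise_sd = noise, seed = seed),
    voltammetry = list(drug_conc = concs, s_complex = s_complex,
                       s_free = s_free))
}
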