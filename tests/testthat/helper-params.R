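# Shared fixtures: the package's default calibration and the Fig-1-style
# spectroscopic parameter set used in the model-comparison scans
# (zero coil contribution).
table1_spectro <- function() spectro_params(-41000, 100, 3.4, 2100, -45)
table1_thermo <- function() thermo_params(v = 0.07, dG0 = -0.22,
                                          dH0 = -1.3, dCp = 0.006)
scan_spectro <- function() spectro_params(-40000, 0, 4, 0, 0)

# Independent Gibbs-Helmholtz evaluation used as an oracle for
# propagation_at_T (kept deliberately separate from the package's code path).
oracle_w <- function(dG0, dH0, dCp, T_K, T0 = 273.15, R = 1.987e-3) {
  dS0 <- (dH0 - dG0) / T0
  dG_T <- dH0 + dCp * (T_K - T0) - T_K * (dS0 + dCp * log(T_K / T0))
  exp(-dG_T / (R * T_K))
}
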