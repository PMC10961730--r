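# helixcd

Ensemble estimation of peptide helix content from circular dichroism (CD)
at 222 nm, for peptide biophysicists analysing helix–coil transitions.

The standard ("linear") way to turn a measured mean molar ellipticity
`[θ]222` into a fractional helicity applies one helix baseline — the
ellipticity of the maximal-length helix — to every conformer. But the
per-unit helix ellipticity depends on the length of the helical segment it
sits in, and a peptide in solution is an ensemble of conformers with
different segment lengths. `helixcd` implements the ensemble treatment:

* an exact **Lifson–Roig helix–coil engine** resolved by helical-segment
  composition. Conformer classes (multisets of helical-run lengths) get
  weight `Ω v^n w^m`, with closed-form degeneracies `Ω`; a `2^N`
  brute-force enumerator serves as an independent oracle. The propagation
  constant follows Gibbs–Helmholtz: `w(T) = exp(−ΔG(T)/RT)` with `ΔG`,
  `ΔH`, `ΔCp` given at 0 °C.
* three **spectroscopic models** mapping compositions to `[θ]222` per
  peptide unit: *empirical* (`[θ]H∞(1 − k/n_H)` per segment), *dichroic*
  (interior units at `[θ]H∞`, the six singly hydrogen-bonded end units at
  `[θ]H1 = [θ]H∞(1 − k/6)`), and *linear* (the approximation under test),
  plus temperature-dependent helix/coil baselines and raw-signal
  conversion `[θ] = θ/(10 l c N_pep)`.
* **inversion** of a measured signal to helicity (unique because the
  signal is strictly monotone in `w`) and **global fitting** of melt
  curves plus fully-helical reference series under a Gaussian noise model,
  with a deterministic multi-start ML backend and an affine-invariant
  MCMC backend.
* a **synthetic-data module** generating (AAKAA)n-GY-style melt suites and
  reference series for end-to-end testing, and a **CLI**
  (`exec/helixcd`: `helicity`, `simulate`, `fit`, `compare-models`).

## Worked example

What helicity does `[θ]222 = −12,000 deg cm² dmol⁻¹` at 0 °C imply for a
blocked 32-residue peptide (33 peptide units)?

```r
library(helixcd)
sp <- spectro_params()                     # default calibration
est <- helicity_from_signal_ensemble(-12000, T = 0, chain_spec(32), sp,
                                     v = 0.07)
est$mean_helicity              # 0.416  -- ensemble (dichroic) helicity
est$w_hat                      # 1.149  -- fitted propagation constant
est$helical_conformer_fraction # 0.807  -- P(>= 1 helical segment)
helicity_from_signal_linear(-12000, 0, chain_spec(32), sp)
                               # 0.363  -- the linear model's estimate
```

The ensemble model reads 41.6% helicity from this signal; the linear
closed form reads 36.3% — the systematic underestimate the package
quantifies. The same computation from the shell:

```
$ helixcd helicity --theta -12000 --n-res 32
theta_222 = -12000.0 deg cm^2/dmol at 0.0 degC (33 units)
ensemble (dichroic): helicity = 0.416, w_hat = 1.1488, P(>=1 segment) = 0.807
linear model:        helicity = 0.363
```

Forward modelling and fitting:

```r
th <- thermo_params(v = 0.07, dG0 = -0.22, dH0 = -1.3, dCp = 0.006)
propagation_at_T(th, 273.15)   # 1.50 at 0 degC
melt <- predict_melt(sp, th, chain_spec(32), T_grid = 0:95)

sets <- simulate_study(sim_config(seed = 1))   # synthetic study, sigma = 300
fit  <- helix_fit(sets, model = "dichroic", seed = 1)
summary(fit)                   # nine parameters with 2-sigma intervals
```

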