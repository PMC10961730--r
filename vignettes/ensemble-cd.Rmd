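---
title: "Estimating peptide helicity from CD with an ensemble model"
author: "helixcd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating peptide helicity from CD with an ensemble model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helixcd)
```

## The problem

Circular dichroism at 222 nm is the standard probe of alpha-helix content
in peptides: helical peptide units produce a strongly negative mean molar
ellipticity, coil units a weakly positive one. The common practice is the
*linear* spectroscopic model,

$$[\theta]_{222} = f_H\,[\theta]_H(N_{pep}, T) + (1 - f_H)\,[\theta]_C(T),$$

which converts a measured signal into a mean fractional helicity $f_H$
using one helix baseline — the ellipticity of the maximal-length helix —
for every conformer. Real peptides, however, populate an ensemble of
conformers whose helical segments have different lengths, and the per-unit
helix ellipticity depends on segment length. `helixcd` implements an
ensemble treatment: exact Lifson–Roig statistics resolved by helical
segment composition, combined with segment-specific helix-length
corrections, so that each conformer class contributes its own ellipticity.
The linear model is retained side by side, because quantifying its bias is
half the point.

## Helix–coil model

Each of the $N_{res}$ residues is helical (h) or coil (c). A run of $m$
consecutive helical residues has Lifson–Roig weight $v^2 w^{m-2}$ for
$m \ge 2$ and $v$ for $m = 1$; coil residues have weight 1. $v$ is the
nucleation constant (entropic, temperature-independent), and the
propagation constant follows the Gibbs–Helmholtz relation

$$\Delta G(T) = \Delta H + \Delta C_p (T - T_0)
  - T\left[\frac{\Delta H - \Delta G_0}{T_0} + \Delta C_p \ln(T/T_0)\right],
  \qquad w(T) = e^{-\Delta G(T)/RT},$$

with all parameters given at $T_0 = 273.15$ K and
$R = 1.987\times10^{-3}$ kcal mol$^{-1}$ K$^{-1}$. With $\Delta C_p = 0$
this reduces to the van 't Hoff two-parameter form.

Three conventions had to be fixed where the classical model meets the
peptide-unit (chromophore) picture:

* **Residue-to-unit mapping.** A run of $m \ge 3$ helical residues forms a
  helical segment of $n_H = m + 1$ peptide units (the minimal helix with
  one backbone hydrogen bond spans four units). Runs of one or two
  helical residues carry their statistical weight but are *spectroscopic
  coil*: their units contribute the coil ellipticity.
* **Boundary convention.** The two terminal residues are held in the coil
  state and carry neither $v$ nor $w$. This is the standard end treatment
  and, with the default calibration, reproduces the few-percent
  helical-conformer fraction expected for a short AAKAA peptide at 0 °C,
  whereas free ends would roughly double it. Its price is that the maximal
  single helix spans $n_{res} - 1$ units rather than all $N_{pep}$.
* **Peptide units.** Blocked peptides (N-acetyl, C-amide) have
  $N_{pep} = N_{res} + 1$ chromophores; all ellipticities in the package
  are per mole of peptide unit.

### Composition-resolved enumeration

`composition_weights()` enumerates conformer *classes* — multisets of
helical-run lengths — instead of individual states. A class with runs
$\{m_1, \dots, m_j\}$ occupying $M$ of the $L = n_{res} - 2$ interior
positions has degeneracy

$$\Omega = \frac{j!}{\prod_r c_r!} \binom{L - M + 1}{j},$$

the number of distinct orderings times the stars-and-bars placement count
(runs separated by at least one coil residue). Class weight is
$\Omega\, v^n w^m$ with the exponents summed over runs. This is exact for
any number of segments — no truncation at two segments is used; the
often-quoted claim that three or more simultaneous segments are negligible
(< 3%) is *verified* by `segment_count_distribution()` over the studied
parameter box rather than assumed. A $2^{N}$ brute-force enumerator
(`enumerate_bruteforce()`) is kept as an independent oracle and the test
suite requires class-by-class agreement to $10^{-12}$ for all
$n_{res} \le 14$.

The number of classes is the number of restricted partitions (6,842 for
$n_{res} = 32$; about 173,000 for $n_{res} = 50$), so the enumeration is
exact yet cheap. For the forward signal the classes are further collapsed
onto distinct $(n, m)$ exponent pairs, against which all spectroscopic
quantities are linear; this reduces the hot path of the global fit to a
few-hundred-row matrix product per melt curve.

## Spectroscopic models

All three models share the coil baseline
$[\theta]_C(T) = [\theta]_C + \partial_T[\theta]_C \cdot T$ and the
infinite-helix baseline
$[\theta]_{H\infty}(T) = [\theta]_{H\infty} + \partial_T[\theta]_{H\infty}\cdot T$:

* **Empirical**: each segment of $n_H$ units contributes
  $[\theta]_{H\infty}(T)(1 - k/n_H)$ per unit; $k$ is the dimensionless
  end-effect parameter.
* **Dichroic**: the (up to) six singly hydrogen-bonded units of a segment
  — three at each end — contribute $[\theta]_{H1}(T)$, doubly bonded
  interior units $[\theta]_{H\infty}(T)$. Requiring agreement with the
  empirical form for $n_H > 6$ forces
  $[\theta]_{H1} = [\theta]_{H\infty}(1 - k/6)$, the closed form used
  throughout; equivalently $k = 6(1 - [\theta]_{H1}/[\theta]_{H\infty})$.
  Segments of $n_H \le 6$ units are all-end: their per-unit value is
  constant at $[\theta]_{H1}$, which is where the two ensemble models
  genuinely differ.
* **Linear**: every helical unit contributes
  $[\theta]_{H\infty}(T)(1 - k/N_{pep})$ — the maximal-length-helix value
  — applied once to the *total* helical unit count, deliberately ignoring
  segmentation. This reproduces the approximation under scrutiny,
  including its mistreatment of multi-segment conformers.

$k$ is treated as temperature-independent, so $[\theta]_{H1}$ inherits its
slope as $\partial_T[\theta]_{H1} = \partial_T[\theta]_{H\infty}(1-k/6)$
(43.3 deg cm² dmol⁻¹ °C⁻¹ at the default calibration). Whether $k$ should
itself drift with temperature is an open question in the field; the
constant-$k$ assumption is an explicit extension point.

The ensemble signal is
$[\theta]_{222} = \sum_i p_i\,(\theta_{helix,i} + n_{C,i}[\theta]_C)/N_{pep}$.
When the three models are compared (`compare-models`, and the scan used in
the acceptance analysis) the coil contribution is set to zero and the
difference between the linear and dichroic signals is reported *on the
helicity scale*, i.e. divided by $|[\theta]_H(N_{pep})|$. With zero coil
this quantity equals the amount by which the linear inversion
underestimates the true ensemble helicity — the scientifically meaningful
number — whereas a ratio to the (small, intermediate-helicity) ensemble
signal itself would overstate the effect roughly twofold.

## Parameters

| parameter | units | default | role |
|---|---|---|---|
| $[\theta]_{H\infty}$ | deg cm² dmol⁻¹ | −41,000 | infinite-helix ellipticity at 0 °C |
| $\partial_T[\theta]_{H\infty}$ | deg cm² dmol⁻¹ °C⁻¹ | 100 | helix baseline slope |
| $k$ | — | 3.4 | end-effect (helix-length) correction |
| $[\theta]_C$ | deg cm² dmol⁻¹ | 2,100 | coil ellipticity at 0 °C |
| $\partial_T[\theta]_C$ | deg cm² dmol⁻¹ °C⁻¹ | −45 | coil baseline slope |
| $\Delta G_0$ | kcal mol⁻¹ | −0.22 | propagation free energy at 0 °C ($w_0 = 1.50$) |
| $\Delta H_0$ | kcal mol⁻¹ | −1.3 | propagation enthalpy |
| $\Delta C_p$ | kcal mol⁻¹ K⁻¹ | 0.006 | heat capacity of propagation |
| $v$ | — | 0.07 | nucleation constant |

The defaults are the package's calibration for alanine-rich
(AAKAA)$_n$-GY-style peptides with the dichroic model; model-comparison
scans instead use the conventional illustration values
($[\theta]_{H\infty} = -40{,}000$, $k = 4$, zero coil).

## Inversion and global fitting

`helicity_from_signal_ensemble()` solves
$[\theta]_{222}(w) = \theta_{obs}$ for $w$ by bisection on $\log w$
(tolerance $10^{-12}$); the signal is strictly monotone in $w$, which the
test suite asserts over the parameter box, so the root is unique. Signals
outside the attainable interval are refused with the interval stated.
The linear closed form is provided alongside; for any mixed ensemble the
linear estimate is at most the ensemble estimate.

`helix_fit()` estimates all nine parameters jointly from: thermal melts
(full forward model), fully-helical reference series (direct observations
of $[\theta]_H(N_{pep}, 0\,°C)$, which pin $[\theta]_{H\infty}$ and $k$
through the curvature in $1/N_{pep}$), and pre-transition slope series
(observations of $\partial_T[\theta]_{H\infty}(1 - k/N_{pep})$). The noise
model is Gaussian; datasets carrying a noise scale enter with it, others
share a single scale profiled out analytically.

Numerical choices:

* Parameters are rescaled to order one before optimization (they span
  nine orders of magnitude); `nlminb` runs under sign-preserving box
  constraints spanning 1/5 to 5 times the starting values — also the
  uniform-prior support of the MCMC backend.
* Five optimization starts by default (the nominal start plus seeded
  ±40% jitter); ties broken by the lowest objective. Uncertainties are
  2-sigma curvature (observed-information) intervals; the reported
  correlation matrix is the Gaussian-approximation correlation for the ML
  backend and the Spearman rank correlation of posterior draws for MCMC.
* The MCMC backend is an affine-invariant stretch-move ensemble sampler
  (default 3,000 steps, 1,000 burn-in) — affine invariance sidesteps the
  scale disparity without hand tuning. It is intended for uncertainty
  exploration; the deterministic backend is what the tests pin down.
* A configuration with fewer observations than free parameters is refused
  up front with the list of unconstrained parameters.

## The synthetic generator

`sim_config()` + `simulate_study()` emulate the study design the
estimator is meant for: blocked chains of 7, 17, 22, 27 and 32 residues,
melts over 0–95 °C in 1 °C steps, Gaussian scatter of
$\sigma_{222} = 300$ deg cm² dmol⁻¹ (the order of visible scatter in real
melt data), a fully-helical series over $N_{pep} = 7\dots60$ with the same
scatter, and a slope series with scatter 10 deg cm² dmol⁻¹ °C⁻¹ (slopes
are two orders of magnitude smaller than ellipticities, and published
slope compilations scatter at about the ten-percent level). Generators are
pure functions of the configuration and its recorded seed.

What the generator does *not* emulate: instrument artifacts (lamp drift,
absorbance flattening, high-tension cutoffs), concentration errors,
aggregation, heteropolymer sequence effects, or any deviation from the
Gaussian noise model. Parameter-recovery tests passing on these data
therefore demonstrate the estimator's correctness and conditioning under
its own assumptions — not robustness to the failure modes of real CD
acquisition.

For routine testing the recovery studies use reduced problem sizes
(three chains, 5 °C steps, thinned reference series); the full-design
study is exercised once in the acceptance suite.

## Known limitations

* Homopolymer model only: one $w$ for all residues, no capping or
  side-chain terms. Heteropolymer extensions would change the composition
  enumeration only through per-run weights.
* The terminal-coil convention truncates the maximal helix at
  $n_{res} - 1$ units, so at saturation the three spectroscopic models
  agree only to within the residual end effect (≈ 1–2% for short chains)
  at the ensemble level; exact three-way convergence holds at the
  conformer level for a full-chain segment.
* $k$ constant in temperature (see above).
* The linear-model bias quantified here depends on $k$ and on the
  ensemble composition; the ~5%-of-scale figure is specific to the
  33-unit chain at $v = 0.048$.
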