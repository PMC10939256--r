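---
title: "Models, parameters and design choices in arexcest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, parameters and design choices in arexcest}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the science inside `arexcest`: the models, the
tunable parameters and their defaults, the numerical choices, what the
synthetic-data generator does and does not emulate, and the known
limitations a user should weigh before interpreting results.

## 1. The Bloch-McConnell simulator

### Model

Each proton pool $i$ (water, solute pools, semisolid MT) contributes three
magnetization components $(M_x^i, M_y^i, M_z^i)$.  Under continuous-wave
irradiation at offset $\Delta\omega$ the coupled system is linear and
time-invariant,

$$\frac{dM}{dt} = A\,M + b,$$

where $A$ holds relaxation ($R_1 = 1/T_1$, $R_2 = 1/T_2$), off-resonance
precession at $(\delta_i - \Delta\omega)\,\gamma B_0 \cdot 10^{-6}$ rad/s,
the nutation term $\omega_1 = \gamma B_1$, and mass-balanced two-site
exchange routed through water (solute loses magnetization at $k_i$, water
loses to solute $i$ at $f_i k_i$, with $f_i$ the proton fraction).  The
drive $b$ contains $R_1^i M_0^i$.

Propagation uses the exact affine solution via the exponential of the
augmented matrix $\left[\begin{smallmatrix}A & b\\ 0 & 0\end{smallmatrix}\right]$,
which is valid even when $A$ is singular; a stiff ODE integrator is the
fallback if the exponential fails, and an independent adaptive-step ODE
integration serves as the test oracle (agreement is at the $10^{-9}$ level
over random pool systems and protocols).

### Assumptions and their rationale

* **Single-shot saturation.**  Every offset starts from thermal
  equilibrium.  With the simulation TR of 8 s and tissue $T_1 \le 2.2$ s,
  steady-state cycling would change Z by under 2%, and the acquisition TRs
  (5 s) are also several $T_1$.
* **CW block pulse only.**  Shaped or pulsed saturation is out of scope.
* **Lorentzian lineshape for every pool, including semisolid MT.**  A
  super-Lorentzian MT lineshape would be more realistic for myelinated
  tissue, but a single consistent 3-component propagator keeps the
  simulator exactly consistent with the Lorentzian fitting stage; the MT
  pool's very short $T_2$ (10 µs) reproduces the broad baseline.
* **Sign convention.**  Positive offsets are downfield of water;
  $\omega(\text{rad/s}) = \Delta\omega_{\text{ppm}} \cdot 10^{-6}\gamma B_0$.

### The default pool library

The shipped nine-pool library (`inst/extdata/pool_library.yaml`) is
configuration, not ground truth: literature-typical 9.4 T brain values
chosen once.  Water ($T_1$ 2.0 s, $T_2$ 45 ms); glutamate amine at 3.0 ppm
($f = 9\times10^{-4}$, $k = 5500\,\mathrm{s^{-1}}$ — a fast exchanger);
creatine guanidinium at 2.0 ppm ($k = 950\,\mathrm{s^{-1}}$);
phosphocreatine guanidinium at 2.64 ppm ($k = 140\,\mathrm{s^{-1}}$);
amide at 3.5 ppm ($k = 30\,\mathrm{s^{-1}}$); a GABA amine contaminant at
2.91 ppm; NOE pools at −3.5 and −1.6 ppm; and a semisolid MT pool
($f = 0.05$, $T_2 = 10\,\mu s$, centered at 0 or −2.3 ppm depending on
`mt_mode`).  The ninth pool is placed at 2.91 ppm (GABA) rather than at an
upfield hydroxyl position deliberately: every solute of the library then
lies inside the default solute-exclusion band of the background fit
(section 3), keeping the shipped simulation and processing defaults
mutually consistent.  A solute left inside the fitted band would be
absorbed by the background model and destabilize it.

### Protocols

Defaults mirror the acquisition they emulate: high-power glutamate-weighted
CEST (B1 5.9 µT, 1000 ms, 57 offsets evenly spanning −8…8 ppm, reference at
−300 ppm), low-power creatine-weighted CEST (B1 1.47 µT, 3500 ms, piecewise
asymmetric offset list whose printed segment boundaries enumerate to 87
offsets — the count is recorded in study sidecars), WASSR (0.05 µT,
1000 ms, 81 offsets −1…1 ppm in 0.025 ppm steps), a 30°/60° double-angle
pair, and a variable-TR series at {0.25, 0.5, 1, 1.5, 2, 3.5, 5, 8} s.
The 57-offset list is not published pointwise; a uniform grid is the
default and is configurable.  Where sources disagree on the low-power B1
(1.47 vs 1.4 µT) the package uses 1.47 µT, and 2.64 ppm is used for PCr
throughout.

## 2. Field mapping

* **WASSR B0.**  The water frequency is the argmin of a cubic-spline
  interpolant of the low-power Z-spectrum on a 0.001 ppm grid.  A
  symmetry-matching algorithm would be equivalent on symmetric dips; the
  spline argmin is simpler and robust at SNR 50 (at least 95% of random
  shifts in ±0.4 ppm are recovered within ±0.01 ppm in the acceptance
  run).  A
  minimum at the sampled boundary means the water line is out of range and
  the voxel is masked.
* **B0 resampling.**  Spectra are resampled onto nominal offsets with a
  cubic spline; values on locally monotone runs are clamped into their
  bracketing-sample range (no spline overshoot), while local extrema are
  left unclamped because the true curve there genuinely passes beyond its
  bracketing samples — clamping at a dip bottom would bias the minimum by
  the full curvature error.  Offsets shifted outside the measured range
  become `NA`; they are never extrapolated.  Note that losing an endpoint
  this way is not free: the fitted MT baseline responds to the −8/+8 ppm
  anchors, so corrected and uncorrected analyses should be compared on
  their common offset support.
* **Double-angle B1.**  $\theta = \arccos(S_{2\alpha}/2S_\alpha)$,
  ratio $=\theta/\alpha$; the arccos argument is clamped to $[-1, 1]$ and
  clamped voxels are flagged rather than erroring, because at ratio noise
  the argument legitimately strays above 1.
* **Variable-TR T1.**  Pure saturation recovery
  $S = S_0(1 - e^{-TR/T_1})$; TE decay is constant across TRs and absorbed
  into $S_0$.  Because $S_0$ is linear in the model it is profiled out in
  closed form and $T_1$ is found by bounded 1-D minimization on
  $[0.05, 10]$ s — deterministic, and equivalent to the joint bounded
  least-squares fit.  Estimates at a bound are flagged and excluded from
  the analysis mask (intersection semantics across all field maps).

## 3. Multi-pool Lorentzian background fitting

The Z-spectrum is modeled as
$Z(\Delta\omega) = 1 - \sum_i A_i \,/\, \bigl(1 + 4\bigl((\Delta\omega - \Delta\omega_i)/\sigma_i\bigr)^2\bigr)$
with $\sigma_i$ the FWHM in ppm.  The constant is fixed at 1 (a free
baseline would trade against the water amplitude).  Two component sets are
shipped: `threepool_sym` (water + NOE$_{-3.5}$ + symmetric MT, used with
the high-power protocol) and `fourpool_asym` (water + both NOE pools +
asymmetric MT, low-power protocol), each with published starting values and
box bounds loaded from `inst/extdata/lorentzian_defaults.yaml`.

Solute resonances are **not** fitted components; the default objective
excludes the 1.6–4.0 ppm band containing the guanidinium, amine and amide
lines, the standard Lorentzian-difference practice.  The window is
configurable.

Numerical choices:

* Bounded Levenberg-Marquardt (`minpack.lm`) with an analytic Jacobian,
  `ftol = ptol = 1e-10`, at most 2000 evaluations.
* A deterministic multi-start: the user's initializer (if any) plus the
  published starting values, followed by one polish pass from the best
  candidate.  Bounded LM can park a small component at a bound (amplitude
  zero with collapsed width has a degenerate, delta-shaped amplitude
  gradient); the published-SV start and the 0.05 ppm floor on width lower
  bounds remove that failure mode.  The fit is deterministic: identical
  inputs give identical results.
* Z-values are clipped at $10^{-6}$ before any inversion.

**Identifiability under noise.**  With free centers and widths the 9- or
12-parameter fit is nearly collinear between the broad components.  At
SNR 100 the Fisher information at the default truth bounds the relative
standard error of the NOE$_{-3.5}$ amplitude ($A = 0.02$) at roughly 50%,
and the fitted estimator sits at that bound; only the water amplitude is
recoverable at the few-percent level.  Per-parameter accuracy claims for
small amplitudes at realistic SNR are therefore not meaningful — fitted
small-amplitude components should be read as baseline absorbers, not as
quantitative pool estimates.  This is a property of the model class, not of
the optimizer.

## 4. AREX quantification

Inverse subtraction removes spillover and MT multiplicatively:
$1/Z_\mathrm{corr}(\Delta\omega) = 1/Z(\Delta\omega) - 1/Z_\mathrm{fit}(\Delta\omega)$,
and the asymmetry scaled by $1/T_1$ gives
$\mathrm{AREX}(\Delta\omega) = \bigl(1/Z_\mathrm{corr}(+\Delta\omega) - 1/Z_\mathrm{corr}(-\Delta\omega)\bigr)/T_1$
in s⁻¹, read out at 3.0 (Glu), 2.64 (PCr) and 2.0 (Cr) ppm.  Design
choices:

* The baseline $Z_\mathrm{fit}$ includes **all** fitted background
  components (water + MT + NOE), not MT alone, so the fitted NOE dips at
  −3.5/−1.6 ppm do not leak into the asymmetry.  The include-set is an
  argument.
* On the asymmetric low-power grid, $-\Delta\omega$ counterparts are
  obtained by monotone cubic interpolation over the negative branch;
  positive offsets whose mirror falls outside the sampled range are
  dropped.
* Metabolite read-out: an offset coinciding with the target (±0.005 ppm)
  is returned directly; interior targets are linearly interpolated between
  bracketing samples; at the range boundary the nearest sample within
  0.05 ppm is accepted.
* B1 correction divides by the actual/nominal ratio (first-order inverse
  scaling of labeling efficiency), clamped to $[0.5, 1.5]$ to avoid noise
  blow-up; clamped voxels are flagged.

**Known limitation — the baseline-mismatch floor.**  A sum of three or
four Lorentzians cannot represent a deeply saturated Bloch-McConnell
spectrum exactly.  At 5.9 µT / 1 s, where $Z \approx 0.17$ near ±2 ppm,
the representation error is of order $10^{-2}$ in Z, and the inverse
metric amplifies misfit by $1/Z^2$: a solute-free phantom that still
contains NOE pools shows spurious AREX of order 0.1 s⁻¹ at the metabolite
offsets (the acceptance script reports this floor).  The same phantom
through the low-power protocol stays below 0.005 s⁻¹, and a fully
symmetric phantom (water + symmetric MT) is null to within $10^{-4}$
at high power — i.e. the pipeline itself introduces no
asymmetry; the floor is model mismatch.  Quantitative comparisons between
groups are unaffected as long as both groups share the background, but
absolute high-power AREX values carry this systematic.

## 5. The synthetic-data generator

`make_phantom()` builds a single-slice phantom (disc of tissue with a
centered square "hippocampus" ROI) with per-class pool systems and T1,
smooth Gaussian-blob B0 (≤ 0.4 ppm) and multiplicative B1 (0.8–1.2) fields;
`simulate_study()` renders the five acquisitions (two CEST stacks with
−300 ppm references, WASSR, double-angle pair, variable-TR series), adding
the voxel's B0 shift to every nominal offset, scaling B1 by the voxel's
ratio, and applying Rician noise (magnitude of a complex Gaussian
perturbation).  All randomness is seeded explicitly; identical seeds give
bitwise-identical studies.  Spectra are memoized over unique
(class, B0, B1) voxel keys — an exact optimization.

`make_roi_table()` draws per-animal Gaussian measures for two groups of 10
(means/SDs shaped to the magnitude of the study contrasts it emulates, as
configuration) plus covariates, for exercising the statistics layer.

What the generator does **not** emulate: anatomy (no atlas, no partial
volume), k-space/readout effects (RARE blurring, motion), spatially
correlated noise, multi-slice geometry, and drift.  Passing tests
therefore demonstrate correctness of the processing chain under its own
forward model, not robustness to everything an in-vivo acquisition can do.

## 6. Statistics layer

* `glm_group_difference()`: OLS of measure on group + covariates; the
  reported mean difference is the adjusted WT − ARTE10 contrast; with no
  covariates this reduces exactly to the pooled two-sample t-test.  The
  degenerate 3-row case (one animal in a group) still yields the OLS
  contrast, with Cohen's d reported as `NA`.
* `cohens_d_ci()`: d is (ARTE10 − WT)/pooled SD, bias-uncorrected (not
  Hedges' g); the CI inverts the noncentral-t distribution, with a
  normal-approximation fallback that is flagged in the return value.
* `bh_fdr()`: Benjamini-Hochberg step-up; each results table is one
  family.
* `partial_corr()`: Pearson correlation of OLS residuals with
  $df = n - 2 - k$; covariates default to the same adjustment variables as
  the group tables (ROI volume for CEST measures, water linewidth for MRS
  measures) and are configurable, since the choice is a modeling decision.

## 7. Problem sizes and determinism

The shipped tests run the simulator-vs-ODE comparison on 100 random
systems, WASSR recovery on 1000 noisy voxels, Lorentzian noise recovery on
500 voxels, T1 recovery on 500 replicates, effect-size recovery on 2000
replicates, and the end-to-end phantom chain on 10–12 voxel grids — sizes
chosen so the whole suite completes in minutes on one CPU while keeping
Monte-Carlo standard errors well below the asserted margins.  Every
stochastic step takes an explicit seed; pipeline artifacts embed the seed
and a configuration hash so a run can be reproduced from its sidecars
alone.
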