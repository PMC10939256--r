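# arexcest

Simulation and quantification of chemical exchange saturation transfer
(CEST) MRI Z-spectra, with AREX (apparent exchange-dependent relaxation)
metabolite mapping and a two-group statistics layer.

## The problem

CEST MRI detects dilute metabolites — glutamate (amine protons at 3.0 ppm),
creatine and phosphocreatine (guanidinium protons at 2.0 and 2.64 ppm) —
by saturating their exchangeable protons with an off-resonance RF pulse and
reading out the transferred saturation as a reduction of the water signal.
The normalized water signal as a function of saturation offset,
`Z(Δω) = S(Δω)/S₀`, mixes the metabolite signal with direct water
saturation (spillover), the broad semisolid magnetization-transfer (MT)
baseline, relayed NOE resonances and T1 relaxation.  `arexcest` implements
the full quantification chain used in preclinical neuro-CEST at 9.4 T, for
researchers who want a tested, scriptable reference implementation with a
matched synthetic-data generator:

1. **Bloch-McConnell simulation** (`simulate_zspectrum()`,
   `pool_contrast()`, `protocol_sweep()`): multi-pool continuous-wave
   saturation propagated with the closed-form matrix-exponential solution of
   `dM/dt = A·M + b`; with/without-pool contrast maps over B1 and
   saturation-duration grids.
2. **Field mapping** (`estimate_b0_wassr()`, `estimate_b1_double_angle()`,
   `fit_t1_variable_tr()`): per-voxel B0 from a WASSR sweep, B1 from a
   30°/60° double-angle pair, T1 from a variable-TR saturation-recovery
   series.
3. **Multi-pool Lorentzian background fitting** (`fit_multipool()`):
   bounded nonlinear least squares of
   `Z(Δω) = 1 − Σᵢ Aᵢ / (1 + 4((Δω − Δωᵢ)/σᵢ)²)`
   with published starting values and box bounds for the water, NOE and MT
   components; solute bands are excluded from the objective.
4. **AREX quantification** (`arex_quantify()`, `arex_maps()`): inverse
   subtraction `1/Z_corr = 1/Z − 1/Z_fit`, asymmetry analysis
   `AREX(Δω) = (1/Z_corr(+Δω) − 1/Z_corr(−Δω)) / T1` (units s⁻¹), read-out
   at 3.0 / 2.64 / 2.0 ppm, and linear B1 correction.
5. **Group statistics** (`roi_group_stats()`, `cohens_d_ci()`,
   `partial_corr()`): covariate-adjusted GLM group contrasts,
   Benjamini-Hochberg FDR, Cohen's d with noncentral-t confidence
   intervals, partial correlations.
6. **Synthetic studies** (`make_phantom()`, `simulate_study()`,
   `make_roi_table()`): digital phantoms with per-tissue pool systems,
   smooth B0/B1 inhomogeneity fields and Rician noise, plus group-structured
   ROI tables — no external data needed anywhere in the tests.

## Worked example

```r
library(arexcest)
sys <- default_pool_system()          # 9-pool brain model at 9.4 T

## high-power (5.9 uT, 1 s) glutamate-weighted acquisition
zg  <- simulate_zspectrum(sys, glu_protocol())
fit <- fit_multipool(zg, "threepool_sym")
print(fit)
#> Multi-pool Lorentzian fit (threepool_sym)
#>   48 offsets fitted, residual norm 0.0158, converged in 31 iterations
#>                   A   sigma  center
#> Water        0.4071  5.7631  1.0000
#> NOE_-3.5     0.2702  4.4538 -1.0196
#> MT_symmetric 0.4132 60.3233 -2.3230

arex_quantify(zg, t1 = 2.0, fit = fit, targets = arex_targets()["Glu"])$values
#>    Glu
#> 0.3874

## low-power (1.47 uT, 3.5 s) creatine-weighted acquisition
zc <- simulate_zspectrum(sys, cr_protocol())
arex_quantify(zc, t1 = 2.0, model = "fourpool_asym",
              targets = arex_targets()[c("PCr", "Cr")])$values
#>    PCr     Cr
#> 0.0749 0.0846
```

The fitted table gives the background components: the dip depth `A`
(unitless), FWHM `sigma` (ppm) and center (ppm) of the water direct
saturation, the −3.5 ppm NOE and the semisolid MT pool.  The AREX values
are exchange-weighted relaxation rates (s⁻¹) at the metabolite resonances
after spillover/MT removal and T1 normalization: here the 3 ppm amine pool
of the simulated tissue produces a Glu-AREX of about 0.39 s⁻¹, and the
guanidinium pools PCr/Cr-AREX of 0.075/0.085 s⁻¹ under the low-power
protocol.

A two-group synthetic cohort and its comparison table:

```r
set.seed(42)
tbl <- make_roi_table(effects_spec(seed = 42))   # 10 WT vs 10 ARTE10
roi_group_stats(tbl, c("AREX_Glu", "AREX_PCr", "AREX_Cr", "qT1"),
                covariates = "roi_volume")
#>    measure mean_difference   p_fdr cohens_d d_ci_low d_ci_high
#> 1 AREX_Glu         0.08729 0.00971   -1.560    -2.56    -0.532
#> 2 AREX_PCr         0.01107 0.00692   -1.736    -2.76    -0.677
#> 3  AREX_Cr         0.00886 0.08526   -0.986    -1.91    -0.041
#> 4      qT1        15.02992 0.45236   -0.226    -1.10     0.657
```

`mean_difference` is the covariate-adjusted WT − ARTE10 contrast in the
measure's units; `cohens_d` is the standardized ARTE10 − WT difference with
its 95% noncentral-t interval; `p_fdr` applies Benjamini-Hochberg across
the four measures as one family.

A staged command-line pipeline (phantom → simulate → b0map → b1map →
t1map → fitz → arex → roistats) is available via

```sh
Rscript inst/cli/arexcest.R all --dir run1 --seed 7
```

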