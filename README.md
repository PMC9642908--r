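# odaciti

Estimation of the cerebral metabolic rate of oxygen (CMRO2) from
periarteriolar tissue pO2 maps measured by two-photon phosphorescence
lifetime microscopy (2PLM).

Around a diving cortical arteriole, the steady-state radial pO2 profile
encodes how fast the surrounding tissue consumes oxygen. The classical
Krogh–Erlang cylinder model assumes the arteriole is the *only* O2 source
within a tissue radius R_t; in mouse cortex the capillary-free space is
narrow and the capillary bed contributes, which that model cannot express.
The ODACITI model (O2 Delivery from Arterioles and Capillaries Into
Tissue) adds a capillary-supplied transitional annulus: on
R_ves ≤ r ≤ R_t,

    pO2(r) = p_ves + (CMRO2 / 4Dα) (r² − R_ves² − 2 R_ves² ln(r/R_ves))
             + β ln(r/R_ves),

with a smooth log continuation beyond R_t and constant p_ves inside the
vessel. The coefficient β = CMRO2 (R_ves² − R0²) / (2Dα) encodes the
arteriole's share of delivery via the zero-net-flux radius R0 ≤ R_t; when
R0 = R_t the model reduces exactly to Krogh–Erlang. Fitting pO2(r) for
(CMRO2, p_ves, β) given R_ves and R_t (80 µm in mouse cortex) yields the
local oxygen consumption rate in µmol cm⁻³ min⁻¹.

The package is aimed at microscopists and modellers working with
point-scanned tissue pO2 data. It provides, as pipeable functions over
tibbles:

- **phosphorescence decays → pO2**: single-exponential decay fitting
  (`fit_decay()`, `fit_decays()`), biexponential lifetime calibration
  (`lifetime_to_po2()`), residual QC and the ≥ 500-cycle motion filter;
- **diffusion models**: `krogh_po2()`, `odaciti_po2()` and their flux
  relations, with a single µm/mmHg/µmol-min unit layer;
- **forward simulation**: a finite-difference Poisson solver for arbitrary
  circular-vessel geometries (`solve_poisson_2d()`), the reference
  multi-vessel scene (`fig2d_geometry()`), grid sampling and seeded
  Gaussian noise — the validation substrate;
- **ROI segmentation**: radial interpolation, cubic smoothing splines
  (csaps convention, p = 0.001), derivative-based cutoffs and low-35%-tail
  augmentation (`segment_grid()`);
- **fitting and experiments**: `fit_odaciti()`, `fit_krogh()`,
  `rt_sensitivity()`, `estimate_rves()` (FWHM), plane averaging;
- **laminar summaries**: layer assignment by depth, distribution tails,
  per-layer tables (`layer_summary()`).

Fitted objects support `tidy()`, `glance()`, `predict()` and `autoplot()`.

## Worked example

Simulate a noisy 400-point measurement grid around an arteriole with known
CMRO2 = 2 µmol cm⁻³ min⁻¹, segment it, and fit:

```r
library(odaciti)

truth <- krogh_params(cmro2 = 2, p_ves = 60, r_ves = 10, r_t = 80)
grid <- generate_krogh_synthetic_grid(truth) |>
  add_gaussian_noise(sigma = 2, seed = 42)

seg <- segment_grid(grid)
seg
#> Segmentation: 202 / 400 points included (76 derivative, 126 low-tail)
#>   direction flags: ok=20

fit <- fit_odaciti(seg$profile, r_ves = 10, r_t = 80)
fit
#> ODACITI fit: CMRO2 = 1.8140 umol cm^-3 min^-1, p_ves = 59.49 mmHg, beta = -18.678 mmHg (r0 = 83.5 um)
#>   SSE 395.1 over 202 points (Rves 10.0, Rt 80.0 um)
```

All 20 directions found a derivative zero-crossing near the capillary-bed
plateau; the low-tail rule re-admitted the plateau points beyond it. The
fit recovers the generating rate within ~9% under σ = 2 mmHg noise
(noiseless data are recovered exactly), with the vessel-wall pO2 (59.5 vs
60 mmHg) and β (−18.7 mmHg, i.e. R0 ≈ R_t: the arteriole supplies
essentially the whole cylinder) alongside.

Sensitivity to a misjudged capillary-free radius, on noiseless data:

```r
sens <- rt_sensitivity(generate_krogh_synthetic(truth), r_ves = 10, true_cmro2 = 2)
attr(sens, "summary")
#> # A tibble: 2 × 3
#>   model   mean_error_pct max_error_pct
#>   <chr>            <dbl>         <dbl>
#> 1 krogh             45.7         104.
#> 2 odaciti           15.7          37.3
```

Sweeping the assumed R_t over 60–80 µm costs the capillary-aware model a
mean CMRO2 error of ~16%, against ~46% for the Krogh–Erlang fit — the
practical argument for modelling capillary delivery.

`reproduce_validation(out_dir, seed)` reruns the whole validation battery
(noisy recovery at CMRO2 ∈ {1, 2, 3}, the multi-vessel simulated scene
with segmentation, and the R_t sweep) and writes a results file that is
byte-identical for identical seeds.

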