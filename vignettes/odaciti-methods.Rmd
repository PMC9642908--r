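---
title: "Estimating CMRO2 from periarteriolar oxygen gradients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating CMRO2 from periarteriolar oxygen gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odaciti)
```

## The problem

Two-photon phosphorescence lifetime microscopy (2PLM) measures tissue pO2
point by point around a diving (penetrating) cortical arteriole. Because
oxygen moves by diffusion and is consumed at a volumetric rate CMRO2
(umol cm^-3 min^-1), the steady-state radial pO2 profile around the
arteriole encodes that rate: the steeper the curvature of pO2(r), the more
oxygen the tissue burns. This package turns raw photon-count decays into
pO2, turns pO2 maps into radial profiles, and fits a diffusion model to
those profiles to estimate CMRO2 — plus a complete synthetic-data stack to
validate every step without any experimental input.

## The two diffusion models

Both models describe a cylindrical arteriole of radius $R_{ves}$ whose wall
is held at $p_{ves}$, embedded in tissue with uniform consumption, in 2-D
steady state: $\nabla^2 P = \mathrm{CMRO_2}/(D\alpha)$, with
$D = 4\times10^{-5}\,\mathrm{cm^2\,s^{-1}}$ and
$\alpha = 1.39\,\mathrm{\mu M\,mmHg^{-1}}$ (`tissue_constants()`).

**Krogh–Erlang** assumes the arteriole is the *sole* source for a tissue
cylinder of radius $R_t$, with zero flux through $r = R_t$:

$$P(r) = p_{ves} + \frac{\mathrm{CMRO_2}}{4D\alpha}
  \left(r^2 - R_{ves}^2 - 2R_t^2 \ln\frac{r}{R_{ves}}\right),
  \qquad R_{ves} \le r \le R_t.$$

Beyond $R_t$ the expression rises unphysically and is therefore not defined
there (`krogh_po2()` refuses such radii).

**ODACITI** (O2 Delivery from Arterioles and Capillaries Into Tissue)
relaxes the sole-source assumption: the capillary bed supplies the tissue
beyond a zero-net-flux radius $R_0 \le R_t$, where $R_t$ is the radius of
the capillary-*free* periarteriolar space (fixed at 80 um in mouse cortex).
On $[R_{ves}, R_t]$:

$$P(r) = p_{ves} + \frac{\mathrm{CMRO_2}}{4D\alpha}
  \left(r^2 - R_{ves}^2 - 2R_{ves}^2 \ln\frac{r}{R_{ves}}\right)
  + \beta \ln\frac{r}{R_{ves}},$$

with a log continuation beyond $R_t$ chosen so that $P$ is continuous
everywhere and differentiable at $R_t$, and constant $p_{ves}$ inside the
vessel (perivascular dye shows no gradient). The fitted coefficient
$\beta = \mathrm{CMRO_2}(R_{ves}^2 - R_0^2)/(2D\alpha)$ encodes the
arteriole's share of delivery; `beta_to_r0()`/`r0_to_beta()` interconvert.
When $R_0 = R_t$ the model reduces *exactly* to Krogh–Erlang (a tested
identity). Total-flux relations (`krogh_flux()`, `odaciti_flux()`) are
cross-checked against numerical derivatives of the closed forms in the test
suite.

Units are a deliberate design point: every interface uses um, mmHg and
umol cm^-3 min^-1; a single internal coefficient
(CMRO2/(4 D alpha), mmHg um^-2) performs the conversion, so no call site
ever multiplies by a power of ten.

## Fitting

Both model predictions are *linear* in their free parameters
($p_{ves}$, CMRO2, $\beta$). `fit_odaciti()` and `fit_krogh()` therefore
compute the global least-squares optimum directly by QR decomposition
instead of iterating a nonlinear optimizer; the physical bound
$\mathrm{CMRO_2} \ge 0$ is enforced by one active-set step (refit with the
rate pinned at zero, with a warning). This is exact, deterministic, and
removes initialisation and convergence failures by construction. The fit
reports the design-matrix condition number and warns above $10^6$: with no
data beyond $R_0$, $\beta$ and CMRO2 trade off and the problem becomes
practically unidentifiable. The Krogh fit uses only points inside
$[R_{ves}, R_t]$ (its domain of validity); the ODACITI fit uses *all*
points, including the intravascular plateau and the capillary bed — that is
its point. Fits are unweighted and unbinned by default (`bin_um` reproduces
2-um binned fitting); measurement noise is homoscedastic, so unweighted
least squares is the natural choice.

$R_{ves}$ is measured from a fluorescence intensity profile across the
vessel as half the full width at half maximum (`estimate_rves()`), with the
half-max level midway between the profile's minimum and maximum.

## From photon counts to pO2

A gated acquisition accumulates photon counts in 2-us bins over a 287-us
window for up to 1000 excitation cycles per point. `fit_decay()` fits
$N(t) = N_0 e^{-t/\tau} + x$ by bounded Levenberg–Marquardt
(minpack.lm), using only bins at least 5 us after gate closure (earlier
bins carry the instrument response), with $\tau$ initialised from the
log-linear slope of background-subtracted counts and one restart from
$\tau = 30$ us before failing loudly. Bins are equally weighted — the
plain reading of a nonlinear least-squares fit of count data; a
Poisson-weighted variant was considered and rejected as an undocumented
deviation. `fractional_residual()` ($\sum |data - fit|/fit$) tracks fit
quality versus accumulated cycles; points with fewer than 500 usable cycles
(motion) are dropped by `filter_points_by_cycles()` — the boundary is
inclusive. The lifetime-to-pO2 map is the empirical biexponential
$A_1 e^{-\tau/t_1} + A_2 e^{-\tau/t_2} + y_0$; its constants are
instrument-specific and must be supplied (`read_calibration()`). The
shipped `default_calibration()` is a clearly-labelled synthetic stand-in
spanning 0–160 mmHg over lifetimes of roughly 8–92 us, for simulation and
testing only. `simulate_decay()` draws per-bin Poisson counts, matching
photon-counting detection.

## ROI segmentation

Real capillary geometry is not radially symmetric, and a nearby oxygenated
vessel can push pO2 back up along some directions. `segment_grid()`
implements the automated selection:

1. 20 equally spaced radii (18 degrees apart) are drawn from the arteriole
   center and pO2 is interpolated along each at 2-um steps
   (`extract_radial_vectors()`). Interpolation is bilinear on the
   measurement lattice, with an inverse-distance fallback for scattered
   layouts (no Delaunay interpolation exists in the dependency set; for
   lattice grids bilinear is the same piecewise-linear idea).
2. Each vector is smoothed with a cubic smoothing spline with parameter
   $p = 0.001$ in the MATLAB `csaps` convention
   ($p\sum(y-s)^2 + (1-p)\int s''^2$), mapped internally onto
   `stats::smooth.spline` via $\lambda = (1-p)/p\,/\,\mathrm{range}(r)^3$;
   $p = 1$ interpolates, $p \to 0$ tends to a straight line
   (`smooth_vector()`).
3. Points are included from the vessel wall outward until the smoothed
   derivative $dP/dr$ first crosses zero from below
   (`roi_from_derivative()`). Two textual readings of this criterion
   conflict (include while *descending* versus include where the derivative
   is *positive*); physically pO2 falls away from an arteriole, so the
   descending/zero-crossing rule is the default and the positive-derivative
   reading is available as `rule = "literal"` for comparison. Directions
   whose derivative never crosses zero are kept in full and flagged
   (`no_crossing`); strictly rising directions are cut at the first radius
   and flagged (`degenerate`) — the fallback is not specified anywhere, so
   it is explicit and reported.
4. All points in the bottom 35% of the map's pO2 distribution are added
   back (`augment_with_low_tail()`) — these are inter-capillary tissue, the
   data that anchor the capillary-bed plateau. Quantiles are
   linear-interpolation quantiles; ties at the threshold are included, so a
   constant map is included in its entirety. The union reading is used: the
   tail can re-admit points beyond a derivative cutoff.
5. Included points are collapsed to $(r, \mathrm{pO_2})$ pairs by Euclidean
   distance (`collapse_to_radial_profile()`), optionally binned.

Grid points map to direction sectors by nearest angle; a point is inside
the derivative ROI when its radius is within its sector's cutoff.

## Synthetic data: what it emulates and what it does not

Two generators regenerate the validation inputs.

`generate_krogh_synthetic()` / `generate_krogh_synthetic_grid()` build the
idealised dataset: $p_{ves}$ inside the vessel, the Krogh solution on
$[R_{ves}, R_t]$, and a constant capillary-bed level $P(R_t)$ beyond — on a
radial vector (default 0–100 um in 2-um steps, the binning and radial
extent of the experimental profiles) or on the experimental 20 x 20 grid
over a 300 x 300 um field of view. Gaussian noise of $\sigma = 2$ mmHg
(`add_gaussian_noise()`) represents measurement error; the reference
conditions use CMRO2 of 1, 2 and 3 umol cm^-3 min^-1 with
$p_{ves} = 60$ mmHg, $R_{ves} = 10$ um, $R_t = 80$ um. A deterministic
`literal_mu_plus_sigma` mode (every value shifted by exactly $+\sigma$) is
kept for comparison with that alternative construction.

`solve_poisson_2d()` handles arbitrary circular-vessel geometries: a
5-point finite-difference Laplacian with Shortley–Weller corrected arms
where a stencil crosses a vessel wall (the Dirichlet value is imposed on
the true circle, keeping second-order accuracy), vessel interiors clamped
to their intravascular pO2, and a reflective outer boundary in the
finite-volume sense (the zero-flux face lies half a cell beyond the last
node — empirically an order of magnitude more accurate at the rim than the
mirrored-node alternative). The single-vessel disk solve matches the Krogh
closed form within 0.07 mmHg at a 1-um mesh (asserted at 0.5 mmHg in the
tests, the same verification strategy used for the original finite-element
implementation). The solver demands at least 4 nodes across the smallest
vessel diameter, refuses source-free (singular) problems, and *allows*
negative solved pO2 with a warning, since the linear model permits
over-consumption geometries.

`fig2d_geometry()` is the reference multi-vessel scene: a 15-um central
arteriole at 70 mmHg, seven 5-um capillaries at 35 mmHg at distances 80,
88, 97, 105, 113, 122 and 130 um (angles evenly spaced, offset half a
sector), and an extra arteriole at 60 mmHg 110 um away on the +x axis.
Exact coordinates are not published, so this layout is representative, not
exact. The default domain is a disk whose zero-flux rim sits at the outer
edge of the capillary shell (133 um): the scene describes only the
periarteriolar region out to the first capillaries, and the reflective rim
stands for the symmetric continuation of the bed (delivery balancing
consumption). On a 300 x 300 um box (`shape = "rect"`) the tissue beyond
the shell has no source at all and the field decays toward the corners —
useful for stress-testing, wrong as a stand-in for cortex.

**A known limitation, quantified.** With only seven discrete capillaries,
the azimuthal *mean* of the solved field obeys the radial consumption
equation exactly — the fit on all grid points recovers CMRO2 = 2 within
~2–3% — but the *segmented* fit recovers ~1.3–1.7 (15–35% low). The
derivative criterion cuts directions where pO2 rises toward a capillary,
excising the high side of the bed annulus, while the bottom-35% tail
re-admits only the low side; the included capillary-bed data then sit
systematically below the plateau the model needs. In real maps the bed is
dense, the bottom-35% tail essentially *is* the bed plateau, and the
excision is unbiased — which is why the procedure works on tissue but
under-recovers on this deliberately sparse synthetic ring. The end-to-end
suite asserts both numbers so the behaviour stays visible; passing the
symmetric-grid recoveries says nothing about segmentation bias on sparse
scenes, and vice versa.

## The Rt-sensitivity experiment

The capillary-free radius cannot be measured in every experiment, so its
misspecification matters. `rt_sensitivity()` refits both models while the
assumed $R_t$ sweeps 60–80 um (5-um steps) on the noiseless
Krogh-with-plateau dataset, whose true $R_t$ is 80 um, and reports the
error curve plus two summaries: the mean absolute CMRO2 error over the
range (the headline robustness number — ODACITI ~16%, Krogh ~46%) and the
worst case, attained at 60 um (~37% vs ~104%). ODACITI's robustness has a
clean explanation: its middle branch can represent Krogh data *exactly* on
$[R_{ves}, R_t^{assumed}]$ via $\beta$, so only the data beyond the assumed
radius are mis-modelled, whereas the Krogh fit is structurally wrong
everywhere once $R_t$ is misjudged. Because of this, the reported error
depends on the sampled radial extent; the 0–100-um default is the
measurement-like choice, fixed once.

## Laminar summaries

`assign_layer()` maps depth to cortical layers — I: 50–100 um, II/III:
150–300 um, IV: 320–500 um, surface at 0 — with closed band edges (a
shared boundary resolves to the shallower layer) and explicit `unassigned`
gaps. `distribution_tails()` returns the means of the bottom- and
top-35% of a pO2 distribution (inter-capillary vs periarteriolar pools).
`layer_summary()` gives per-layer mean ± SE and, on request, per-subject
means: repeated planes within an animal are dependent, so inferential
modelling (e.g. a mixed-effects model with subject as a random effect)
is intentionally left to dedicated tools outside this package.
`depth_profile()` flags its output as periarteriolar-biased — grids are
centered on arterioles, so these means overstate bulk tissue pO2.

## Problem sizes and reproducibility

The test suite and `reproduce_validation()` run at the study's native
sizes: 400-point measurement grids, 1-um solver meshes for the reference
scene (0.5 um only in the mesh-convergence check), 9–50 noise replicates
per recovery property. All randomness is seeded; `reproduce_validation()`
writes byte-identical results for identical seeds, and file writers render
numerics at fixed 15-significant-digit precision so write–read–write
round-trips are byte-stable. `scripts/acceptance.R` recomputes the
Rt-misspecification errors from scratch; see the README for how to run it.
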