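---
title: "Adaptive iterative hard thresholding for limited-angle CT: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive iterative hard thresholding for limited-angle CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(aihtct)
```

## The reconstruction model

Limited-angle CT measures line integrals `l` of an unknown attenuation
image `h` over an angular range shorter than the 180 degrees required for
exact inversion. The package reconstructs by minimizing

$$\operatorname*{argmin}_{h \in \Omega}\; \|Zh - l\|_B^2 \;+\;
  \sum_i \beta_i \,\|(Ah)_i\|_0,$$

where `Z` is the parallel-beam projection operator over the available
views, `B` the diagonal matrix of inverse ray sums (so every ray
contributes on the same scale regardless of its intersection length), `A`
the spline-framelet analysis operator, and `Ω` the non-negative orthant
(attenuation cannot be negative). The `l0` term counts nonzero detail
coefficients: it encodes the working assumption that the object is close to
piecewise constant, so that its framelet detail coefficients are sparse and
concentrated on edges. Limited-angle artifacts — smooth streaks aligned
with the missing directions — are *not* sparse in this frame, which is what
lets thresholding separate them from anatomy.

The iteration interleaves three exact, individually testable stages:

1. a SART data-fidelity sweep `h* = h + g\,V^{-1} Z^T B (l - Zh)`,
   `g ∈ (0,2]`, where `V` holds per-pixel column sums;
2. hard thresholding of the eight detail subbands of `Ah*` followed by
   exact synthesis (`A` is a Parseval frame, `A^T A = I`);
3. projection onto `Ω` by clipping negatives (on by default).

With all thresholds zero and the clip disabled, stages 2–3 are the
identity and the algorithm *is* SART — a property the test suite asserts to
`1e-10` and a useful debugging lever.

## Geometry and projector

The acquisition is parallel-beam: the algorithm under study is agnostic to
beam geometry, and parallel beams make the adjoint, the FBP weighting and
analytic checks (chord lengths of a disk) simplest, while limited-angle
artifacts keep the same character. Angles are in degrees, `0°` runs along
image rows, counter-clockwise positive; views are uniform on the half-open
range `[start, end)`. The detector row must cover the image diagonal
(`default_n_detectors(size)` gives `ceil(size * sqrt(2)) + 1` bins at pixel
spacing), since detector truncation is a different problem deliberately not
modeled.

Rays are discretized by Joseph's method — stepping along the dominant axis
with linear interpolation across it — and the discretization is realized
once per (geometry, grid) pair as a sparse matrix. The backprojector is its
exact transpose, so the adjoint identity `⟨Zh, y⟩ = ⟨h, Zᵀy⟩` holds to
machine precision; iterative reconstruction with an unmatched
projector/backprojector pair can diverge in ways that are hard to
diagnose, which is why the package never approximates the adjoint. The
matrix is cached per session, trading ~100 MB of memory at `128²`/120
views for projections that cost one sparse mat-vec.

One discretization caveat found while validating rotation invariance: a
hard-rasterized disk is *not* rotationally symmetric, and Joseph
interpolation has a small angle-dependent blur (worst near 45°). Projection
profiles of a smooth radial bump agree across angles to well under 1%, but
for hard-edged objects per-bin deviations at the edge reach ~2–3%. Tests of
rotation invariance therefore use a smooth disk.

## SART sweep order

Two sweep orders are provided. `sweep = "sequential"` (the default) is
classical SART: views are applied one at a time in ascending-angle order,
each with its own per-view row/column sums. `sweep = "simultaneous"`
applies all views at once with global weights; it is a Landweber-type
scheme for which the weighted residual `‖Zh − l‖_B` decreases provably and
monotonically for `g ∈ (0,1]` (asserted in the tests), but it converges an
order of magnitude more slowly: on a clean full-range `64²` problem the
sequential sweep reaches RMSE 0.008 in 100 sweeps where the simultaneous
one needs thousands. Sequential is the right default for practical use and
for the packaged comparisons; simultaneous is retained because its
monotonicity makes it the better object for convergence analysis. Both are
deterministic. Iteration starts from the zero image — reproducible and,
under non-negativity, a sensible prior-free choice.

## The framelet stage

The filter bank is the piecewise-linear B-spline tight framelet: low-pass
`[1,2,1]/4`, gradient-like `√2[1,0,−1]/4`, curvature-like `[−1,2,−1]/4`.
Its defining property, verified at construction to `1e-12`, is
`|k̂0(ω)|² + |k̂1(ω)|² + |k̂2(ω)|² = 1` at every frequency; this single
condition is what makes synthesis-after-analysis exact, which the
thresholding step silently relies on. The 2-D transform is separable,
single-level, undecimated, with periodic boundary extension — the unique
combination under which perfect reconstruction is exact on every image
shape (including odd sizes) rather than approximate near borders. Subbands
are ordered row-filter-major (`s00, s01, …, s22`); `s00` is the
approximation band and is never thresholded, because the approximation
carries the bulk image intensity and thresholding it would bias the
reconstruction toward zero.

Hard thresholding compares magnitudes: `y ↦ 0` if `|y| ≤ β*`, else `y`. A
signed comparison would annihilate all negative coefficients, which cannot
be the intent of an l0 proximal step. The boundary case `|y| = β*` maps to
0 so the operator is deterministic. The algorithm is parameterized directly
by the threshold `β*` (a single value for all eight detail subbands by
default; per-subband vectors are supported) rather than by the penalty
weights `β_i`, since the threshold is what the proximal operator actually
consumes.

## Adaptive threshold selection

The threshold trades data fidelity against sparsity, and the right value
depends on the noise level, the angular range and the iterate itself. The
package selects it on a discrete L-curve: for each candidate `t` in a grid,
threshold the current iterate's coefficients at `t`, synthesize, and plot
`log10 ‖Z h_t − l‖₂` against `log10` of the surviving detail-coefficient
count. The curve is L-shaped — killing noise-floor coefficients barely
moves the misfit, killing edge coefficients moves it a lot — and the corner
is found as the candidate of maximum three-point Menger curvature. Ties
break toward the smaller threshold (less regularization when indifferent);
a degenerate flat curve (e.g. no detail coefficients at all) returns the
smallest candidate. The default grid is `10^seq(-3.5, -0.5, length = 8)`,
spanning noise-floor to edge-scale coefficients for images in `[0,1]`, and
the selection is refreshed every 10 iterations (`lcurve_every`) — each
refresh costs one forward projection per candidate, and between refreshes
the iterate changes little. The selected threshold is always a grid
element, making runs exactly reproducible.

The fixed-threshold variant (`run_wf_baseline()`, default `β* = 0.05`)
serves as the wavelet-frame comparator: same loop, no adaptation. The
packaged default deliberately uses one mid-scale value rather than a
per-problem tuned one, since its role is to show what adaptation buys.

## Stopping and iteration budget

Iterations stop at `n_iters` (default 200) or when the relative image
change drops below `stop_tol` (default `1e-6`). The model offers no
intrinsic stopping rule; 200 sweeps is comfortably past the point of
diminishing returns for `128²` problems in pilot runs, and the change-based
criterion mostly matters for the fixed-threshold variant, which can reach
its fixed point early.

## Phantoms and metrics

Phantoms are additive compositions of ellipses and rectangles rasterized by
the centre-point rule (a pixel belongs to a shape iff its centre is
inside). This keeps pixel-count identities exact and images exactly
piecewise constant — the model class the regularizer targets — at the price
of aliased edges: consistency across resolutions holds on average but not
pixelwise at contrast-1 boundaries, and objects meant to be rotationally
symmetric should be given smooth profiles instead. The standard ten-ellipse
Shepp-Logan head phantom is included, as is a packaged abdominal-like
default; both live in `[0,1]` with no Hounsfield calibration, since the
reconstruction experiments are unitless.

Quality is scored by `RMSE = sqrt(Σ(P−Q)²/M)` with `M` the total pixel
count, and `PSNR = 10 log10(max|Q|²/RMSE²)` with the peak taken from the
reference image — one global value per reconstruction, no sliding window.
PSNR of a perfect reconstruction is `Inf` by convention.

## The packaged comparison

`run_experiment()` reproduces the comparison protocol end to end: phantom →
projection over each scan range (`[0,90]` and `[0,120]`, one view per
degree) → optional Gaussian noise → FBP / SART / WF / AIHT → RMSE/PSNR
table. Defaults: `128²` default phantom, clean data, 200 iterations, `g =
1`, non-negativity on. The packaged sizes keep the full comparison under a
minute on one CPU while being large enough for the limited-angle artifacts
to dominate discretization effects. Noise enters only through `add_noise()`
(i.i.d. Gaussian, the conventional reading of an unspecified "noise
level"); Poisson/transmission statistics are out of scope.

```{r experiment}
tab <- run_experiment(experiment_spec())
plot_experiment(tab, "rmse")
```

## The spectral-CT module

No patient data accompany the diagnostic analysis, so the module pairs the
*statistics* (slope, curve typing, ROC) with a synthetic cohort generator
whose role is structural realism, not clinical fidelity. Each subject draws
five parameters — curve slope (HU/keV), mixed-energy CT value (HU),
water(iodine) and water(calcium) concentrations (mg/mL, truncated at 0),
effective atomic number — independently from per-group normal models, and
the monoenergetic curve on the 40–100 keV grid is an exponential-like decay
anchored at the high-energy value and matched exactly to the drawn slope.

The slope convention is the radiology one, `(CT(E_low) − CT(E_high)) /
(E_high − E_low)`: descending attenuation curves — the hepatic-ascites
signature — have positive slope. Under this convention the curve-type
proportions (about 94% descending among hepatic subjects, 88% ascending
among carcinomatous ones) force the hepatic group's mean slope *above* the
carcinomatous group's; a report of "lower slope" for the hepatic group is
consistent only under the opposite sign convention, and the package follows
the quantitative proportions. Default group means and SDs were set once:
slope means ±SDs chosen so the slope-sign probabilities match those
proportions (`1.20 ± 0.77` vs `−0.85 ± 0.72` HU/keV), group sizes 50/42,
and the remaining means following the reported direction of each group
difference with magnitudes typical of effusion spectral CT. Independence
between parameters is a stated simplification — real spectral parameters
are correlated — so the generator supports testing the statistical
machinery, not estimating clinical operating points.

ROC analysis is empirical: every observed marker value is a candidate
threshold, AUC is the Mann-Whitney statistic (ties counted 1/2, invariant
under monotone transforms), and the operating point maximizes Youden's
`J = sensitivity + specificity − 1` with ties broken toward higher
sensitivity. The implementation is cross-checked against pROC in the test
suite.

## What the tests do and do not show

The suite verifies exact algebraic identities (tight-frame reconstruction,
projector adjointness, the scalar SART closed form, metric identities),
distributional properties of the generators at large `n`, and the headline
ordering — AIHT beating SART and fixed-threshold WF on both limited ranges
of the packaged clean-data experiment, with more angular data never
hurting. Passing them shows the algorithm behaves as designed on
piecewise-constant synthetic objects under Gaussian noise and a matched
forward model. It does not show performance on real scanner data, where
the forward model is approximate, noise is not Gaussian, objects are not
piecewise constant, and the spectral parameters are correlated — those
claims would need data the package deliberately does not pretend to have.

## Known limitations

- Parallel-beam only; no fan/cone geometry, no detector truncation.
- Single-level framelet decomposition; a multi-level transform might
  separate large-scale streaks better but breaks the exact-synthesis
  argument used here.
- The L-curve grid is global across subbands by default; genuinely
  per-subband adaptation is supported mechanically but has no selection
  rule of its own.
- The comparator set contains FBP, SART and fixed-threshold WF; a
  multiplicative-regularization comparator is not implemented (no defining
  equations available to implement it faithfully).
- The spectral cohort is synthetic; its ROC numbers characterize the
  generator, not patients.
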