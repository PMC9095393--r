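# aihtct

Limited-angle CT reconstruction by **adaptive iterative hard thresholding
(AIHT)**, with the evaluation protocol and spectral-CT diagnostic statistics
that go with it.

## The problem

When a CT gantry can only cover part of the half-turn needed for exact
tomography — common in thoracic and interventional imaging — the measured
sinogram misses a wedge of frequency space. Filtered backprojection (FBP)
then produces the characteristic slope and streak artifacts, and purely
algebraic methods (SART) converge to one of many data-consistent images,
leaving the null-space component unresolved. The package targets users who
study such limited-angle protocols: it provides the forward model, the
reconstruction algorithms, phantoms with known ground truth, and the
image-quality metrics to compare them.

## The algorithm

The reconstruction solves the regularized model

    argmin_{h >= 0}  || Z h - l ||_B^2  +  sum_i beta_i || (A h)_i ||_0

where `Z` is the limited-angle projection operator, `l` the measured
sinogram, `B` the diagonal inverse-ray-sum weighting, and `A` the
undecimated piecewise-linear B-spline tight-frame (framelet) transform with
filters `k0 = [1,2,1]/4`, `k1 = sqrt(2)[1,0,-1]/4`, `k2 = [-1,2,-1]/4`. The
l0 penalty on the 8 detail subbands encodes the assumption that the object
is approximately piecewise constant. Each outer iteration performs three
steps:

1. **SART sweep** — `h* = h + g V^-1 Z^T B (l - Z h)` with relaxation
   `g` in (0, 2];
2. **framelet hard thresholding** — analyze `h*`, zero every detail
   coefficient with magnitude at or below the threshold `beta*`, synthesize
   (exact, since `A^T A = I`);
3. **non-negativity projection** — clip negative pixels.

The threshold is not hand-tuned: every few iterations the algorithm sweeps a
candidate grid, traces the discrete L-curve of
(log data misfit, log surviving-coefficient count), and selects the corner
of maximum three-point curvature. Fixing the threshold instead gives the
wavelet-frame (WF) comparator; `beta* = 0` recovers plain SART; FBP is the
analytic baseline.

The spectral module generates synthetic two-group effusion cohorts (hepatic
vs. carcinomatous) with per-subject monoenergetic CT-value curves, computes
energy-spectrum curve slopes `(CT(E_low) - CT(E_high)) / (E_high - E_low)`,
classifies curves as ascending/descending, and evaluates markers by
empirical ROC analysis (Mann-Whitney AUC, Youden operating point).

## Worked example

```r
library(aihtct)
ph   <- default_phantom(64)                                  # ground truth
geom <- limited_angle_geometry(c(0, 90), 90, default_n_detectors(64))
sino <- forward_project(ph, geom)                            # 90-view sinogram

fit  <- run_aiht(sino, 64, aiht_config(n_iters = 100))
sart <- run_sart(sino, 64, n_iters = 100, nonneg = TRUE)

metrics_report(fit$image, ph)
metrics_report(sart, ph)
glance(fit)
```

```
# A tibble: 1 × 4
    rmse  psnr n_pixels peak_value
   <dbl> <dbl>    <int>      <dbl>
1 0.0158  33.5     4096       0.75
# A tibble: 1 × 4
    rmse  psnr n_pixels peak_value
   <dbl> <dbl>    <int>      <dbl>
1 0.0412  25.2     4096       0.75
# A tibble: 1 × 5
  n_iters final_misfit final_threshold detail_sparsity converged
    <int>        <dbl>           <dbl>           <dbl> <lgl>    
1     100         2.12         0.00611           0.148 FALSE
```

On this 90-degree scan AIHT reaches RMSE 0.016 (PSNR 33.5 dB) against
ground truth where unregularized SART stops at RMSE 0.041 (25.2 dB): the
thresholding suppresses the limited-angle streaks while keeping the
piecewise-constant structure. The fit summary shows the adaptively selected
threshold (0.0061) and that only 15% of detail coefficients survive it.
`autoplot(fit$image)`, `autoplot(fit)` and `plot_experiment()` visualize
reconstructions, convergence traces and comparison tables; `tidy()` /
`glance()` return them as tibbles.

A command-line front end with `phantom`, `project`, `reconstruct`,
`evaluate`, `experiment`, `cohort` and `roc` subcommands is installed at
`inst/cli/aihtct.R` (TIFF images, CSV sinograms/cohorts/tables, JSON
configs and ROC results).

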