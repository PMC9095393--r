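test_that("hard thresholding follows the magnitude case table", {
  bk <- build_filter_bank()
  cf <- framelet_analyze(rand_image(6, 6, seed = 1), bk)
  cf$subbands$s01 <- matrix(c(0.5, 2, -2, 1, -1, 0.99), 2, 3)
  out <- hard_threshold(cf, 1)
  expect_equal(out$subbands$s01, matrix(c(0, 2, -2, 0, 0, 0), 2, 3))
  expect_identical(out$subbands$s00, cf$subbands$s00)  # low-pass untouched
  expect_error(hard_threshold(cf, -0.1), ">= 0")
})

test_that("zero threshold is the identity and thresholding is idempotent", {
  bk <- build_filter_bank()
  for (seed in 1:5) {
    cf <- framelet_analyze(rand_image(9, 7, seed = seed), bk)
    z <- hard_threshold(cf, 0)
    for (nm in names(cf$subbands)) {
      expect_identical(z$subbands[[nm]], cf$subbands[[nm]])
    }
    t1 <- hard_threshold(cf, 0.4)
    t2 <- hard_threshold(t1, 0.4)
    for (nm in names(cf$subbands)) {
      expect_identical(t2$subbands[[nm]], t1$subbands[[nm]])
    }
  }
})

test_that("per-subband threshold vectors are honoured", {
  bk <- build_filter_bank()
  cf <- framelet_analyze(rand_image(8, 8, seed = 2), bk)
  beta <- c(Inf, 0, 0, 0, 0, 0, 0, 0)  # kill only the first detail subband
  out <- hard_threshold(cf, beta)
  expect_true(all(out$subbands$s01 == 0))
  expect_identical(out$subbands$s22, cf$subbands$s22)
})

test_that("the L-curve corner separates a bimodal coefficient field", {
  # strong edges (detail coefficients ~0.25) over a weak texture (~0.005):
  # the corner threshold must fall strictly between the modes
  n <- 48
  sp <- phantom_spec(n, background = 0, shapes = list(
    list(kind = "rectangle", center = c(n / 2, n / 2), extent = c(n / 2, n / 2),
         intensity = 1)
  ))
  set.seed(31)
  px <- make_piecewise_phantom(sp)$pixels + matrix(rnorm(n * n, sd = 0.005), n)
  h <- ct_image(pmin(pmax(px, 0), 1))
  g <- tiny_geometry(c(0, 90), 45, n)
  sino <- forward_project(h, g)
  grid <- 10^seq(-3, -0.3, length.out = 9)
  sel <- select_threshold_lcurve(h, sino, grid = grid)
  expect_true(sel %in% grid)
  # noise-mode detail coefficients have sd ~0.0015 (image sd 0.005 times the
  # largest detail-kernel norm); the edge mode sits at ~0.25
  expect_gt(sel, 0.003)
  expect_lt(sel, 0.1)
  expect_identical(sel, select_threshold_lcurve(h, sino, grid = grid))
})

test_that("degenerate L-curves fall back to the documented tie-breaks", {
  n <- 16
  g <- tiny_geometry(c(0, 90), 10, n)
  flat <- ct_image(matrix(0.5, n, n))
  sino <- forward_project(flat, g)
  grid <- c(0.01, 0.1, 1)
  # constant image: no detail coefficients at all -> flat curve -> smallest
  expect_identical(select_threshold_lcurve(flat, sino, grid = grid), 0.01)
  # 3-point grid with a genuine corner: only the middle point has a defined
  # curvature, so it is returned
  set.seed(5)
  tex <- ct_image(pmin(pmax(0.5 + matrix(rnorm(n * n, sd = 0.02), n), 0), 1))
  sel <- select_threshold_lcurve(tex, forward_project(tex, g),
                                 grid = c(0.001, 0.01, 0.1))
  expect_identical(sel, 0.01)
  expect_error(select_threshold_lcurve(flat, sino, grid = c(0.1, 0.2)), "3")
})

test_that("AIHT with zero thresholds and no clipping reproduces SART", {
  n <- 32
  g <- tiny_geometry(c(0, 90), 45, n)
  sino <- forward_project(default_phantom(n), g)
  cfg <- aiht_config(n_iters = 30, threshold_mode = "fixed", beta_star = 0,
                     nonneg = FALSE, stop_tol = 0)
  fit <- run_aiht(sino, n, cfg)
  ref <- run_sart(sino, n, n_iters = 30, g = 1, nonneg = FALSE)
  expect_lt(max(abs(fit$image$pixels - ref$pixels)), 1e-10)
})

test_that("AIHT runs are deterministic with a sane trace", {
  n <- 32
  g <- tiny_geometry(c(0, 90), 45, n)
  sino <- forward_project(default_phantom(n), g)
  cfg <- aiht_config(n_iters = 15, lcurve_every = 5)
  f1 <- run_aiht(sino, n, cfg)
  f2 <- run_aiht(sino, n, cfg)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$image$pixels, f2$image$pixels)
  expect_true(all(f1$trace$n_surviving <= f1$trace$n_detail_total))
  expect_true(all(f1$trace$threshold %in% cfg$lcurve_grid))
  expect_s3_class(tidy(f1), "tbl_df")
  expect_identical(nrow(glance(f1)), 1L)
})

test_that("the WF baseline is fixed-threshold AIHT", {
  n <- 32
  g <- tiny_geometry(c(0, 90), 45, n)
  sino <- forward_project(default_phantom(n), g)
  cfg <- aiht_config(n_iters = 10, threshold_mode = "fixed", beta_star = 0.05)
  wf <- run_wf_baseline(sino, n, cfg)
  ai <- run_aiht(sino, n, cfg)
  expect_identical(wf$image$pixels, ai$image$pixels)
  # absurdly large threshold: every detail coefficient dies
  big <- run_wf_baseline(sino, n, aiht_config(n_iters = 5, threshold_mode = "fixed",
                                              beta_star = 1e6))
  expect_true(all(big$trace$n_surviving == 0))
})

test_that("regularization improves limited-angle reconstruction quality", {
  n <- 64
  ph <- default_phantom(n)
  g <- tiny_geometry(c(0, 90), 90, n)
  sino <- forward_project(ph, g)
  sart <- run_sart(sino, n, n_iters = 100, nonneg = TRUE)
  wf <- run_wf_baseline(sino, n, aiht_config(n_iters = 100, threshold_mode = "fixed",
                                             beta_star = 0.05))
  ai <- run_aiht(sino, n, aiht_config(n_iters = 100))
  expect_lt(image_rmse(wf$image, ph), image_rmse(sart, ph) * 2)  # same ballpark
  expect_lt(image_rmse(ai$image, ph), image_rmse(sart, ph))
  expect_gt(image_psnr(ai$image, ph), image_psnr(sart, ph))
})
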