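test_that("limited-angle geometries space views uniformly on a half-open range", {
  g <- limited_angle_geometry(c(0, 90), 90, 95)
  expect_equal(g$angles, 0:89)
  g2 <- limited_angle_geometry(c(0, 120), 120, 95)
  expect_equal(g2$angles[1], 0)
  expect_equal(g2$angles[120], 119)
  expect_error(limited_angle_geometry(c(0, 181), 90, 95), "180")
  expect_error(limited_angle_geometry(c(90, 90), 10, 95), "end > start")
})

test_that("rays through a uniform disk integrate to the chord length", {
  n <- 64; r <- 20; v <- 0.5
  img <- disk_image(n, r, v)
  g <- tiny_geometry(c(0, 180), 36, n)
  s <- forward_project(img, g)
  ctr_bin <- (g$n_detectors + 1) / 2  # detector offset 0 passes the centre
  chords <- s$values[, ctr_bin]
  expect_true(all(abs(chords - 2 * r * v) / (2 * r * v) < 0.02))
})

test_that("forward projection is linear and maps zero to zero", {
  g <- tiny_geometry(c(0, 120), 20, 16)
  z <- forward_project(ct_image(matrix(0, 16, 16)), g)
  expect_true(all(z$values == 0))
  a <- rand_image(16, seed = 4); b <- rand_image(16, seed = 5)
  sa <- forward_project(ct_image(a), g)$values
  sb <- forward_project(ct_image(b), g)$values
  sab <- forward_project(ct_image(2 * a - 3 * b), g)$values
  expect_equal(sab, 2 * sa - 3 * sb, tolerance = 1e-12)
})

test_that("a single pixel projects onto hand-enumerated interpolation weights", {
  # 4x4 image, pixel (2,3) = 1; 7 detector bins at offsets -3..3.
  px <- matrix(0, 4, 4); px[2, 3] <- 1
  # angle 0: rays run along rows at height t; pixel row coordinate 2 lies
  # halfway between the rays at t = 0 (row coord 2.5) and t = 1 (1.5),
  # so each receives weight 1/2
  g0 <- limited_angle_geometry(c(0, 90), 1, 7)
  s0 <- forward_project(ct_image(px), g0)$values[1, ]
  expect_equal(s0, c(0, 0, 0, 0.5, 0.5, 0, 0), tolerance = 1e-12)
  # angle 90: rays run along columns; pixel column 3 sits between the rays
  # at t = 0 (col coord 2.5) and t = -1 (3.5)
  g90 <- limited_angle_geometry(c(90, 180), 1, 7)
  s90 <- forward_project(ct_image(px), g90)$values[1, ]
  expect_equal(s90, c(0, 0, 0.5, 0.5, 0, 0, 0), tolerance = 1e-12)
})

test_that("back projection is the exact adjoint of forward projection", {
  g <- tiny_geometry(c(0, 150), 25, 16)
  z <- ct_sinogram(matrix(0, 25, g$n_detectors), g)
  expect_true(all(back_project(z, 16)$pixels == 0))
  for (k in 1:50) {
    h <- rand_image(16, seed = 100 + k)
    y <- matrix(rnorm(25 * g$n_detectors), 25)
    lhs <- sum(forward_project(ct_image(h), g)$values * y)
    rhs <- sum(h * back_project(ct_sinogram(y, g), 16)$pixels)
    expect_equal(lhs, rhs, tolerance = 1e-6)
  }
})

test_that("a single-view single-bin backprojection is supported only on that ray", {
  g <- limited_angle_geometry(c(0, 90), 1, 12)
  y <- matrix(0, 1, 12)
  y[1, 7] <- 1  # detector offset +0.5 at angle 0: a horizontal ray
  img <- back_project(ct_sinogram(y, g), 8)$pixels
  hit_rows <- which(rowSums(abs(img)) > 0)
  # ray at height 0.5 crosses row coordinate 4.0: rows 4 only (weight 1)
  expect_true(all(hit_rows %in% c(4, 5)))
  expect_true(all(abs(img[setdiff(1:8, hit_rows), ]) == 0))
})

test_that("projections of a symmetric disk agree across angles", {
  img <- smooth_disk(48, 16, 1)
  g <- tiny_geometry(c(0, 180), 18, 48)
  s <- forward_project(img, g)
  ref <- s$values[1, ]
  scale <- max(ref)
  for (a in 2:18) {
    expect_lt(max(abs(s$values[a, ] - ref)) / scale, 0.02)
  }
})

test_that("non-negative images give non-negative sinograms", {
  img <- default_phantom(32)
  s <- forward_project(img, tiny_geometry(c(0, 90), 30, 32))
  expect_gte(min(s$values), 0)
})

test_that("detector rows that truncate the image are rejected", {
  expect_error(
    forward_project(ct_image(matrix(1, 32, 32)),
                    limited_angle_geometry(c(0, 90), 10, 20)),
    "diagonal"
  )
})

test_that("additive noise has the requested distribution and is reproducible", {
  g <- tiny_geometry(c(0, 180), 120, 96)
  s <- forward_project(make_shepp_logan(96), g)
  expect_identical(add_noise(s, 0, seed = 1)$values, s$values)
  n1 <- add_noise(s, 1, seed = 7)
  n2 <- add_noise(s, 1, seed = 7)
  expect_identical(n1$values, n2$values)
  expect_equal(n1$noise_level, 1)
  resid <- n1$values - s$values
  expect_gt(length(resid), 1e4)
  expect_lt(abs(sd(resid) - 1), 0.05)
  expect_error(add_noise(s, -1), "sigma")
})

test_that("FBP matches the standard imaging-library oracle on full-range data", {
  # frozen oracle: scikit-image radon/iradon (ramp filter, linear
  # interpolation) end-to-end on the same 128^2 phantom at 180 views
  # gives RMSE 0.05899 against ground truth
  ph <- make_shepp_logan(128)
  g <- tiny_geometry(c(0, 180), 180, 128)
  s <- forward_project(ph, g)
  expect_true(all(fbp_reconstruct(ct_sinogram(matrix(0, 180, g$n_detectors), g),
                                  128)$pixels == 0))
  r_full <- image_rmse(fbp_reconstruct(s, 128), ph)
  expect_lt(abs(r_full - 0.05899) / 0.05899, 0.20)
  expect_lt(r_full, 0.08)
  # limited-angle data degrade FBP
  g90 <- tiny_geometry(c(0, 90), 90, 128)
  r_lim <- image_rmse(fbp_reconstruct(forward_project(ph, g90), 128), ph)
  expect_gt(r_lim, r_full)
})
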