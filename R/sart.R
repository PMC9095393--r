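# Internal projector handle: the sparse system matrix plus bookkeeping.
# Public entry points build it from a geometry; tests may construct tiny
# systems directly (e.g. the 1-pixel/1-ray scalar recurrence).
new_projector <- function(Z, image_shape, n_angles, n_detectors) {
  structure(
    list(Z = Z, image_shape = as.integer(image_shape),
         n_angles = as.integer(n_angles), n_detectors = as.integer(n_detectors)),
    class = "ct_projector"
  )
}

projector_for <- function(geometry, size, pixel_spacing = 1) {
  shp <- c(size, size)
  check_coverage(geometry, shp, pixel_spacing)
  Z <- get_system_matrix(geometry, shp, pixel_spacing)
  new_projector(Z, shp, length(geometry$angles), geometry$n_detectors)
}

#' SART diagonal weights
#'
#' The SART update `h <- h + g * V^-1 Z^T B (l - Z h)` uses two diagonal
#' weight matrices: `B` holds inverse ray (row) sums of the system matrix
#' and `V^-1` inverse pixel (column) sums. They are computed operationally
#' by projecting an all-ones image and backprojecting an all-ones sinogram.
#' Rays that miss the image, and pixels hit by no ray, get weight 0 (not
#' infinity) and drop out of the update. These are the weights of the
#' simultaneous (all views at once) sweep; the view-sequential sweep uses
#' the analogous per-view sums internally.
#'
#' @param geometry a [limited_angle_geometry()].
#' @param size image side in pixels.
#' @param pixel_spacing physical length per pixel.
#' @return A `sart_weights` object with fields `row_weights` (per ray) and
#'   `col_weights` (per pixel, matrix-shaped).
#' @export
compute_sart_weights <- function(geometry, size, pixel_spacing = 1) {
  prj <- projector_for(geometry, size, pixel_spacing)
  sart_weights_for(prj)
}

sart_weights_for <- function(prj) {
  row_sums <- as.numeric(prj$Z %*% rep(1, prod(prj$image_shape)))
  col_sums <- as.numeric(Matrix::crossprod(prj$Z, rep(1, nrow(prj$Z))))
  inv0 <- function(s) ifelse(s > 0, 1 / s, 0)
  structure(
    list(
      row_weights = inv0(row_sums),
      col_weights = matrix(inv0(col_sums), nrow = prj$image_shape[1]),
      image_shape = prj$image_shape
    ),
    class = "sart_weights"
  )
}

# Per-view blocks for the view-sequential sweep: each view's rows of Z with
# its own inverse row/column sums. Cached alongside the system matrix.
view_blocks_for <- function(prj, geometry, pixel_spacing = 1) {
  key <- paste0(projector_key(geometry, prj$image_shape, pixel_spacing), "|blocks")
  if (!is.null(.projector_cache[[key]])) return(.projector_cache[[key]])
  nd <- prj$n_detectors
  inv0 <- function(s) ifelse(s > 0, 1 / s, 0)
  blocks <- lapply(seq_len(prj$n_angles), function(a) {
    idx <- ((a - 1L) * nd + 1L):(a * nd)
    Za <- prj$Z[idx, , drop = FALSE]
    rs <- as.numeric(Za %*% rep(1, ncol(Za)))
    cs <- as.numeric(Matrix::crossprod(Za, rep(1, nrow(Za))))
    list(Z = Za, idx = idx, bw = inv0(rs), vw = inv0(cs))
  })
  .projector_cache[[key]] <- blocks
  blocks
}

# One simultaneous sweep (all views at once) on raw vectors.
sart_sweep_simultaneous <- function(hvec, lvec, prj, weights, g) {
  resid <- lvec - as.numeric(prj$Z %*% hvec)
  corr <- as.numeric(Matrix::crossprod(prj$Z, weights$row_weights * resid))
  hvec + g * as.vector(weights$col_weights) * corr
}

# One classical SART sweep: views updated one at a time in ascending-angle
# order (deterministic), each with its own per-view weights.
sart_sweep_sequential <- function(hvec, lvec, blocks, g) {
  for (b in blocks) {
    resid <- lvec[b$idx] - as.numeric(b$Z %*% hvec)
    hvec <- hvec + g * b$vw * as.numeric(Matrix::crossprod(b$Z, b$bw * resid))
  }
  hvec
}

# dispatch on sweep order; blocks/weights may be NULL and are then built
sart_sweep_raw <- function(hvec, lvec, prj, g, sweep, weights = NULL, blocks = NULL) {
  if (sweep == "simultaneous") {
    if (is.null(weights)) weights <- sart_weights_for(prj)
    sart_sweep_simultaneous(hvec, lvec, prj, weights, g)
  } else {
    sart_sweep_sequential(hvec, lvec, blocks, g)
  }
}

#' One SART sweep
#'
#' Performs one sweep of the SART update
#' `h + g * V^-1 Z^T B (l - Z h)` with relaxation `g` in `(0, 2]`. The
#' default sweep order is the classical view-sequential one (views applied
#' one at a time in ascending-angle order, each with its own per-view
#' weights); `sweep = "simultaneous"` applies all views at once with the
#' global weights of [compute_sart_weights()]. Either way the sweep is
#' deterministic, and images consistent with the data (`Z h = l`) are fixed
#' points.
#'
#' @param h current image estimate, a [ct_image()] or matrix.
#' @param sino measured [ct_sinogram()].
#' @param weights a [compute_sart_weights()] result (simultaneous sweep
#'   only; computed on the fly if `NULL`).
#' @param g relaxation factor in `(0, 2]`.
#' @param sweep `"sequential"` (classical SART) or `"simultaneous"`.
#' @return A [ct_image()] after one sweep.
#' @export
sart_step <- function(h, sino, weights = NULL, g = 1,
                      sweep = c("sequential", "simultaneous")) {
  sweep <- match.arg(sweep)
  if (g <= 0 || g > 2) stop("relaxation `g` must lie in (0, 2]", call. = FALSE)
  h <- as_ct_image(h)
  size <- nrow(h$pixels)
  prj <- projector_for(sino$geometry, size, h$pixel_spacing)
  blocks <- if (sweep == "sequential") {
    view_blocks_for(prj, sino$geometry, h$pixel_spacing)
  }
  newv <- sart_sweep_raw(as.vector(h$pixels), sino_to_ray_vector(sino), prj,
                         g, sweep, weights = weights, blocks = blocks)
  ct_image(matrix(newv, nrow = size), pixel_spacing = h$pixel_spacing)
}

#' Plain SART reconstruction
#'
#' Iterates [sart_step()] from the zero image for `n_iters` sweeps,
#' optionally clipping negative pixels to zero after each sweep (projection
#' onto the non-negative orthant). The baseline algebraic method the
#' regularized reconstruction is compared against.
#'
#' @param sino a [ct_sinogram()].
#' @param size image side in pixels.
#' @param n_iters number of sweeps (`>= 1`).
#' @param g relaxation factor in `(0, 2]`.
#' @param nonneg clip negatives after each sweep?
#' @param sweep `"sequential"` (classical SART, default) or
#'   `"simultaneous"`.
#' @param pixel_spacing physical length per pixel.
#' @return A [ct_image()].
#' @examples
#' ph <- make_shepp_logan(32)
#' g <- limited_angle_geometry(c(0, 180), 60, default_n_detectors(32))
#' rec <- run_sart(forward_project(ph, g), 32, n_iters = 20)
#' @export
run_sart <- function(sino, size, n_iters = 100, g = 1, nonneg = FALSE,
                     sweep = c("sequential", "simultaneous"),
                     pixel_spacing = 1) {
  sweep <- match.arg(sweep)
  if (n_iters < 1) stop("`n_iters` must be >= 1", call. = FALSE)
  if (g <= 0 || g > 2) stop("relaxation `g` must lie in (0, 2]", call. = FALSE)
  prj <- projector_for(sino$geometry, size, pixel_spacing)
  weights <- if (sweep == "simultaneous") sart_weights_for(prj)
  blocks <- if (sweep == "sequential") {
    view_blocks_for(prj, sino$geometry, pixel_spacing)
  }
  lvec <- sino_to_ray_vector(sino)
  hvec <- rep(0, prod(prj$image_shape))
  for (m in seq_len(n_iters)) {
    hvec <- sart_sweep_raw(hvec, lvec, prj, g, sweep, weights, blocks)
    if (nonneg) hvec <- pmax(hvec, 0)
  }
  ct_image(matrix(hvec, nrow = size), pixel_spacing = pixel_spacing)
}

# weighted residual norm ||Z h - l||_B used by convergence diagnostics
weighted_residual_norm <- function(hvec, lvec, prj, weights) {
  r <- as.numeric(prj$Z %*% hvec) - lvec
  sqrt(sum(weights$row_weights * r^2))
}
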