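#' Limited-angle parallel-beam acquisition geometry
#'
#' Views are uniformly spaced on the half-open interval
#' `[range_deg[1], range_deg[2])` with step `(end - start) / n_angles`.
#' Angles are in degrees; at 0 degrees rays run along image rows, and angles
#' increase counter-clockwise. The detector row must cover the image
#' diagonal, so the default detector count for an `n x n` image is
#' `ceil(n * sqrt(2)) + 1`.
#'
#' @param range_deg length-2 numeric `(start, end)` with
#'   `0 < end - start <= 180`.
#' @param n_angles number of views.
#' @param n_detectors number of detector bins.
#' @param detector_spacing physical length per detector bin.
#' @return A `ct_geometry` object.
#' @examples
#' g <- limited_angle_geometry(c(0, 90), 90, 95)
#' head(g$angles)
#' @export
limited_angle_geometry <- function(range_deg, n_angles, n_detectors,
                                   detector_spacing = 1) {
  if (length(range_deg) != 2 || range_deg[2] <= range_deg[1]) {
    stop("`range_deg` must satisfy end > start", call. = FALSE)
  }
  if (range_deg[2] - range_deg[1] > 180) {
    stop("angular span must be at most 180 degrees", call. = FALSE)
  }
  if (n_angles < 1 || n_detectors < 1) {
    stop("`n_angles` and `n_detectors` must be positive", call. = FALSE)
  }
  step <- (range_deg[2] - range_deg[1]) / n_angles
  angles <- range_deg[1] + step * (seq_len(n_angles) - 1)
  structure(
    list(
      angles = angles,
      n_detectors = as.integer(n_detectors),
      detector_spacing = as.numeric(detector_spacing),
      angular_range = as.numeric(range_deg)
    ),
    class = "ct_geometry"
  )
}

#' Default detector count for an image size
#'
#' @param size image side in pixels.
#' @return `ceil(size * sqrt(2)) + 1`, enough bins to cover the diagonal.
#' @export
default_n_detectors <- function(size) {
  as.integer(ceiling(size * sqrt(2)) + 1L)
}

#' @export
print.ct_geometry <- function(x, ...) {
  cat(sprintf(
    "<ct_geometry> %d views on [%g, %g) deg, %d detectors (spacing %g)\n",
    length(x$angles), x$angular_range[1], x$angular_range[2],
    x$n_detectors, x$detector_spacing
  ))
  invisible(x)
}

# Detector-bin offsets, centred on the rotation axis.
detector_offsets <- function(geometry) {
  n <- geometry$n_detectors
  (seq_len(n) - (n + 1) / 2) * geometry$detector_spacing
}

# ---------------------------------------------------------------------------
# Joseph-discretized system matrix.
#
# The projector is realized as an explicit sparse matrix over pixels
# (column-major vectorization), built by stepping each ray along its dominant
# axis with linear interpolation across the transverse axis. back_project is
# the exact transpose, so the pair is a matched adjoint by construction.
# ---------------------------------------------------------------------------
build_system_matrix <- function(geometry, image_shape, pixel_spacing = 1) {
  nr <- image_shape[1]; nc <- image_shape[2]
  sp <- pixel_spacing
  t_off <- detector_offsets(geometry)
  n_det <- geometry$n_detectors
  trip_i <- vector("list", length(geometry$angles))
  trip_j <- trip_i
  trip_x <- trip_i
  for (a in seq_along(geometry$angles)) {
    th <- geometry$angles[a] * pi / 180
    u <- c(cos(th), sin(th))    # ray direction
    nvec <- c(-sin(th), cos(th))  # detector axis
    if (abs(u[1]) >= abs(u[2])) {
      # x-dominant: step across columns, interpolate between rows
      xk <- (seq_len(nc) - (nc + 1) / 2) * sp
      # y(t, x) = t * (n_y - n_x u_y / u_x) + x * (u_y / u_x)
      slope_t <- nvec[2] - nvec[1] * u[2] / u[1]
      y <- outer(t_off * slope_t, xk * (u[2] / u[1]), `+`)  # n_det x nc
      # continuous row coordinate (row 1 top, y up)
      rpix <- (nr + 1) / 2 - y / sp
      r0 <- floor(rpix)
      w1 <- rpix - r0          # weight of row r0 + 1
      step_w <- sp / abs(u[1])
      ray <- rep(seq_len(n_det), times = nc)
      col_idx <- rep(seq_len(nc), each = n_det)
      r0v <- as.vector(r0); w1v <- as.vector(w1)
      ok0 <- r0v >= 1 & r0v <= nr
      ok1 <- (r0v + 1) >= 1 & (r0v + 1) <= nr
      i <- c(ray[ok0], ray[ok1])
      j <- c((col_idx[ok0] - 1L) * nr + r0v[ok0],
             (col_idx[ok1] - 1L) * nr + r0v[ok1] + 1L)
      x <- c((1 - w1v[ok0]) * step_w, w1v[ok1] * step_w)
    } else {
      # y-dominant: step across rows, interpolate between columns
      yr <- ((nr + 1) / 2 - seq_len(nr)) * sp
      # x(t, y) = t * (n_x - n_y u_x / u_y) + y * (u_x / u_y)
      slope_t <- nvec[1] - nvec[2] * u[1] / u[2]
      x <- outer(t_off * slope_t, yr * (u[1] / u[2]), `+`)  # n_det x nr
      cpix <- x / sp + (nc + 1) / 2
      c0 <- floor(cpix)
      w1 <- cpix - c0
      step_w <- sp / abs(u[2])
      ray <- rep(seq_len(n_det), times = nr)
      row_idx <- rep(seq_len(nr), each = n_det)
      c0v <- as.vector(c0); w1v <- as.vector(w1)
      ok0 <- c0v >= 1 & c0v <= nc
      ok1 <- (c0v + 1) >= 1 & (c0v + 1) <= nc
      i <- c(ray[ok0], ray[ok1])
      j <- c((c0v[ok0] - 1L) * nr + row_idx[ok0],
             (c0v[ok1]) * nr + row_idx[ok1])
      x <- c((1 - w1v[ok0]) * step_w, w1v[ok1] * step_w)
    }
    keep <- x > 0
    trip_i[[a]] <- i[keep] + (a - 1L) * n_det
    trip_j[[a]] <- j[keep]
    trip_x[[a]] <- x[keep]
  }
  Matrix::sparseMatrix(
    i = unlist(trip_i), j = unlist(trip_j), x = unlist(trip_x),
    dims = c(length(geometry$angles) * n_det, nr * nc)
  )
}

# Per-session cache of system matrices keyed by geometry + image shape.
.projector_cache <- new.env(parent = emptyenv())

projector_key <- function(geometry, image_shape, pixel_spacing) {
  paste(
    paste(format(geometry$angles, digits = 12), collapse = ","),
    geometry$n_detectors, geometry$detector_spacing,
    image_shape[1], image_shape[2], pixel_spacing,
    sep = "|"
  )
}

get_system_matrix <- function(geometry, image_shape, pixel_spacing = 1) {
  key <- projector_key(geometry, image_shape, pixel_spacing)
  if (is.null(.projector_cache[[key]])) {
    .projector_cache[[key]] <- build_system_matrix(geometry, image_shape, pixel_spacing)
  }
  .projector_cache[[key]]
}

check_coverage <- function(geometry, image_shape, pixel_spacing) {
  diag_len <- sqrt(sum(image_shape^2)) * pixel_spacing
  det_len <- geometry$n_detectors * geometry$detector_spacing
  if (det_len < diag_len) {
    stop(sprintf(
      "detector row (%g) does not cover the image diagonal (%g); truncation is not modeled",
      det_len, diag_len
    ), call. = FALSE)
  }
}

#' Sinogram container
#'
#' Projection data indexed by (view angle, detector bin) together with the
#' acquisition geometry and the standard deviation of any noise added.
#'
#' @param values numeric matrix, `n_angles x n_detectors`.
#' @param geometry a [limited_angle_geometry()].
#' @param noise_level standard deviation of added noise (0 if clean).
#' @return A `ct_sinogram` object.
#' @export
ct_sinogram <- function(values, geometry, noise_level = 0) {
  values <- as.matrix(values)
  stopifnot(inherits(geometry, "ct_geometry"))
  if (nrow(values) != length(geometry$angles) || ncol(values) != geometry$n_detectors) {
    stop("sinogram shape inconsistent with geometry", call. = FALSE)
  }
  if (!all(is.finite(values))) stop("sinogram values must be finite", call. = FALSE)
  if (noise_level < 0) stop("`noise_level` must be >= 0", call. = FALSE)
  structure(
    list(values = unname(values), geometry = geometry,
         noise_level = as.numeric(noise_level)),
    class = "ct_sinogram"
  )
}

#' @export
print.ct_sinogram <- function(x, ...) {
  cat(sprintf(
    "<ct_sinogram> %d x %d (views x detectors), noise sd %g\n",
    nrow(x$values), ncol(x$values), x$noise_level
  ))
  invisible(x)
}

#' Forward projection (discrete Radon transform)
#'
#' Computes the line integral of the image along every (angle, detector
#' offset) ray of the geometry, using Joseph linear interpolation along each
#' ray's dominant axis. The operator is linear in the image and its exact
#' transpose is [back_project()].
#'
#' @param image a [ct_image()] (or matrix).
#' @param geometry a [limited_angle_geometry()]; its detector row must cover
#'   the image diagonal.
#' @return A [ct_sinogram()] with `noise_level = 0`.
#' @export
forward_project <- function(image, geometry) {
  image <- as_ct_image(image)
  shp <- dim(image$pixels)
  check_coverage(geometry, shp, image$pixel_spacing)
  Z <- get_system_matrix(geometry, shp, image$pixel_spacing)
  v <- as.numeric(Z %*% as.vector(image$pixels))
  ct_sinogram(ray_vector_to_sino_values(v, geometry), geometry)
}

# Rays are laid out detector-fastest within each view; sinogram matrices are
# n_angles x n_detectors, so the ray vector is t(values) flattened.
sino_to_ray_vector <- function(sino) as.vector(t(sino$values))
ray_vector_to_sino_values <- function(v, geometry) {
  matrix(v, nrow = length(geometry$angles), byrow = TRUE)
}

#' Backprojection (exact adjoint of the forward projector)
#'
#' Applies the transpose of the Joseph system matrix, so that
#' `<Zh, y> == <h, t(Z) y>` to machine precision for all images `h` and
#' sinograms `y`.
#'
#' @param sino a [ct_sinogram()].
#' @param size image side in pixels of the target grid.
#' @param pixel_spacing physical length per pixel.
#' @return A [ct_image()].
#' @export
back_project <- function(sino, size, pixel_spacing = 1) {
  stopifnot(inherits(sino, "ct_sinogram"))
  shp <- c(size, size)
  check_coverage(sino$geometry, shp, pixel_spacing)
  Z <- get_system_matrix(sino$geometry, shp, pixel_spacing)
  v <- as.numeric(Matrix::crossprod(Z, sino_to_ray_vector(sino)))
  ct_image(matrix(v, nrow = size), pixel_spacing = pixel_spacing)
}

#' Add measurement noise to a sinogram
#'
#' Adds i.i.d. zero-mean Gaussian noise of standard deviation `sigma` to
#' every bin and records `sigma` in the `noise_level` field. Deterministic
#' for a fixed seed.
#'
#' @param sino a [ct_sinogram()].
#' @param sigma noise standard deviation, `>= 0`.
#' @param seed integer seed.
#' @return A [ct_sinogram()].
#' @export
add_noise <- function(sino, sigma, seed = 1) {
  stopifnot(inherits(sino, "ct_sinogram"))
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma < 0) {
    stop("`sigma` must be a single number >= 0", call. = FALSE)
  }
  if (sigma == 0) return(sino)
  set.seed(seed)
  noisy <- sino$values + matrix(
    stats::rnorm(length(sino$values), sd = sigma),
    nrow = nrow(sino$values)
  )
  ct_sinogram(noisy, sino$geometry, noise_level = sigma)
}

#' Filtered backprojection baseline
#'
#' Ramp (Ram-Lak) filtering in the frequency domain, zero-padded to the next
#' power of two, followed by the matched backprojector scaled by the angular
#' step. The classical analytic baseline; on limited-angle data it produces
#' the characteristic slope/streak artifacts that iterative methods are
#' designed to suppress.
#'
#' @param sino a [ct_sinogram()].
#' @param size output image side in pixels.
#' @param pixel_spacing physical length per pixel.
#' @return A [ct_image()]; negative values are retained (no clipping).
#' @export
fbp_reconstruct <- function(sino, size, pixel_spacing = 1) {
  stopifnot(inherits(sino, "ct_sinogram"))
  g <- sino$geometry
  n_det <- g$n_detectors
  npad <- 2^ceiling(log2(2 * n_det))
  # frequency axis in cycles per physical unit
  k <- c(0:(npad / 2), -(npad / 2 - 1):-1)
  nu <- abs(k) / (npad * g$detector_spacing)
  filtered <- t(apply(sino$values, 1, function(p) {
    pad <- c(p, rep(0, npad - n_det))
    q <- Re(stats::fft(stats::fft(pad) * nu, inverse = TRUE)) / npad
    q[seq_len(n_det)]
  }))
  dtheta <- (g$angular_range[2] - g$angular_range[1]) / length(g$angles) * pi / 180
  fsino <- ct_sinogram(filtered, g)
  bp <- back_project(fsino, size, pixel_spacing)
  ct_image(bp$pixels * dtheta / pixel_spacing, pixel_spacing = pixel_spacing)
}
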