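# Analytic ellipse table of the standard (low-contrast) Shepp-Logan head
# phantom on the [-1,1]^2 square: additive intensity, semi-axes (a horizontal,
# b vertical), centre (x0, y0), rotation phi in degrees (counter-clockwise).
shepp_logan_ellipses <- function() {
  tibble::tribble(
    ~intensity, ~a,     ~b,     ~x0,   ~y0,    ~phi,
    1.00,       0.6900, 0.9200,  0.00,  0.0000,   0,
    -0.98,      0.6624, 0.8740,  0.00, -0.0184,   0,
    -0.02,      0.1100, 0.3100,  0.22,  0.0000, -18,
    -0.02,      0.1600, 0.4100, -0.22,  0.0000,  18,
    0.01,       0.2100, 0.2500,  0.00,  0.3500,   0,
    0.01,       0.0460, 0.0460,  0.00,  0.1000,   0,
    0.01,       0.0460, 0.0460,  0.00, -0.1000,   0,
    0.01,       0.0460, 0.0230, -0.08, -0.6050,   0,
    0.01,       0.0230, 0.0230,  0.00, -0.6060,   0,
    0.01,       0.0230, 0.0460,  0.06, -0.6050,   0
  )
}

# Evaluate the additive ellipse sum at continuous points (x, y) on [-1,1]^2.
shepp_logan_value <- function(x, y) {
  ell <- shepp_logan_ellipses()
  val <- numeric(length(x))
  for (i in seq_len(nrow(ell))) {
    phi <- ell$phi[i] * pi / 180
    dx <- x - ell$x0[i]
    dy <- y - ell$y0[i]
    xr <- dx * cos(phi) + dy * sin(phi)
    yr <- -dx * sin(phi) + dy * cos(phi)
    inside <- (xr / ell$a[i])^2 + (yr / ell$b[i])^2 <= 1
    val <- val + ell$intensity[i] * inside
  }
  val
}

#' Shepp-Logan head phantom
#'
#' Rasterizes the standard ten-ellipse Shepp-Logan phantom on a square grid.
#' A pixel takes the sum of the intensities of all ellipses whose interior
#' contains the pixel centre (centre-point rasterization, no anti-aliasing),
#' so the image is exactly piecewise constant. Values lie in `[0, 1]`.
#'
#' @param size image side in pixels (`size >= 16`).
#' @return A [ct_image()] of dimension `size x size`.
#' @examples
#' ph <- make_shepp_logan(64)
#' range(ph$pixels)
#' @export
make_shepp_logan <- function(size) {
  if (!is.numeric(size) || length(size) != 1 || size != round(size) || size < 16) {
    stop("`size` must be a single integer >= 16", call. = FALSE)
  }
  size <- as.integer(size)
  # pixel centres on [-1, 1]: half-integer offsets, row 1 at the top
  cs <- ((seq_len(size) - 0.5) / size) * 2 - 1
  x <- rep(cs, each = size)
  y <- rep(rev(cs), times = size)
  px <- matrix(shepp_logan_value(x, y), nrow = size, ncol = size)
  ct_image(px)
}

#' Specify a piecewise-constant phantom
#'
#' A phantom is a constant background plus additive shapes (ellipses and
#' rectangles). Shapes are given in pixel coordinates: `center = c(row, col)`
#' (fractional allowed), ellipse `axes = c(semi_r, semi_c)` in pixels,
#' rectangle `extent = c(height, width)` in pixels, `rotation` in degrees
#' counter-clockwise. A pixel belongs to a shape iff its centre point lies
#' inside; overlapping shapes add.
#'
#' @param size square image side in pixels.
#' @param background scalar background intensity.
#' @param shapes list of shape lists, each with fields `kind`
#'   (`"ellipse"` or `"rectangle"`), `center`, `axes` or `extent`,
#'   optional `rotation` (default 0) and `intensity`.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(size, background = 0, shapes = list()) {
  if (!is.numeric(size) || size < 2) stop("`size` must be >= 2", call. = FALSE)
  for (s in shapes) {
    if (!is.list(s) || is.null(s$kind) || !s$kind %in% c("ellipse", "rectangle")) {
      stop("each shape needs kind 'ellipse' or 'rectangle'", call. = FALSE)
    }
    if (is.null(s$center) || length(s$center) != 2) {
      stop("each shape needs a length-2 center (row, col)", call. = FALSE)
    }
    ext <- if (s$kind == "ellipse") s$axes else s$extent
    if (is.null(ext) || length(ext) != 2 || any(ext <= 0)) {
      stop("each shape needs positive axes/extent of length 2", call. = FALSE)
    }
    # at least partly inside the image support
    if (any(s$center - ext > size + 0.5) || any(s$center + ext < 0.5)) {
      stop("shape lies entirely outside the image support", call. = FALSE)
    }
  }
  structure(
    list(size = as.integer(size), background = as.numeric(background), shapes = shapes),
    class = "phantom_spec"
  )
}

#' Rasterize a piecewise-constant phantom
#'
#' Deterministic for a fixed spec (and seed; the seed is reserved for specs
#' produced by random generators and does not perturb rasterization). Pixel
#' membership follows the centre-point rule, so the image is constant on each
#' shape interior minus overlaps and the set of distinct values is at most
#' `2^k + 1` for `k` shapes. Final values outside `[0, 1]` are clipped with a
#' warning.
#'
#' @param spec a [phantom_spec()].
#' @param seed optional integer, recorded for provenance only.
#' @return A [ct_image()].
#' @examples
#' sp <- phantom_spec(32, background = 0.2,
#'   shapes = list(list(kind = "rectangle", center = c(16.5, 16.5),
#'                      extent = c(16, 16), intensity = 0.5)))
#' img <- make_piecewise_phantom(sp)
#' table(img$pixels)
#' @export
make_piecewise_phantom <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$size
  px <- matrix(spec$background, n, n)
  r <- rep(seq_len(n), times = n)   # pixel-centre row coordinate
  cc <- rep(seq_len(n), each = n)   # pixel-centre col coordinate
  for (s in spec$shapes) {
    rot <- if (is.null(s$rotation)) 0 else s$rotation * pi / 180
    dr <- r - s$center[1]
    dc <- cc - s$center[2]
    # rotate pixel offsets into the shape frame (CCW rotation of the shape)
    ur <- dr * cos(rot) - dc * sin(rot)
    uc <- dr * sin(rot) + dc * cos(rot)
    inside <- if (s$kind == "ellipse") {
      (ur / s$axes[1])^2 + (uc / s$axes[2])^2 <= 1
    } else {
      abs(ur) < s$extent[1] / 2 & abs(uc) < s$extent[2] / 2
    }
    px <- px + s$intensity * matrix(inside, n, n)
  }
  if (any(px < 0) || any(px > 1)) {
    warning("phantom intensities outside [0, 1]; clipping", call. = FALSE)
    px <- pmin(pmax(px, 0), 1)
  }
  ct_image(px)
}

#' Random piecewise-constant phantom specification
#'
#' Draws a reproducible collection of ellipses and rectangles inside a
#' circular field of view. Useful for stress-testing reconstruction on
#' phantoms other than the packaged defaults.
#'
#' @param size image side in pixels.
#' @param n_shapes number of shapes.
#' @param seed integer seed.
#' @return A [phantom_spec()].
#' @export
random_phantom_spec <- function(size, n_shapes = 5, seed = 1) {
  set.seed(seed)
  shapes <- purrr::map(seq_len(n_shapes), function(i) {
    kind <- sample(c("ellipse", "rectangle"), 1)
    ctr <- stats::runif(2, 0.3 * size, 0.7 * size)
    ext <- stats::runif(2, 0.05 * size, 0.2 * size)
    list(
      kind = kind,
      center = ctr,
      axes = ext, extent = ext,
      rotation = stats::runif(1, 0, 180),
      intensity = stats::runif(1, 0.05, 0.15)
    )
  })
  phantom_spec(size, background = 0, shapes = shapes)
}

#' Packaged default phantom
#'
#' The piecewise-constant test object used by the packaged limited-angle
#' experiment: an elliptical body containing a few constant-intensity
#' structures, loosely imitating an abdominal cross-section. All values in
#' `[0, 1]`.
#'
#' @param size image side in pixels (default 128).
#' @return A [ct_image()].
#' @export
default_phantom <- function(size = 128) {
  s <- size
  spec <- phantom_spec(
    s,
    background = 0,
    shapes = list(
      list(kind = "ellipse", center = c(0.50, 0.50) * s, axes = c(0.42, 0.36) * s,
           intensity = 0.40),
      list(kind = "ellipse", center = c(0.42, 0.38) * s, axes = c(0.16, 0.12) * s,
           rotation = 20, intensity = 0.25),
      list(kind = "ellipse", center = c(0.45, 0.66) * s, axes = c(0.10, 0.08) * s,
           intensity = 0.15),
      list(kind = "rectangle", center = c(0.68, 0.50) * s, extent = c(0.12, 0.22) * s,
           rotation = 0, intensity = 0.20),
      list(kind = "ellipse", center = c(0.70, 0.32) * s, axes = c(0.05, 0.05) * s,
           intensity = 0.35),
      list(kind = "ellipse", center = c(0.28, 0.58) * s, axes = c(0.045, 0.045) * s,
           intensity = 0.30)
    )
  )
  make_piecewise_phantom(spec)
}

#' Read and write phantom specifications as JSON
#'
#' Schema: `{"size": int, "background": float, "shapes": [{"kind": "...",
#' "center": [r, c], "axes"/"extent": [..], "rotation": deg,
#' "intensity": float}]}`.
#'
#' @param spec a [phantom_spec()].
#' @param path file path.
#' @return `write_phantom_spec()` returns `path` invisibly;
#'   `read_phantom_spec()` returns a `phantom_spec`.
#' @export
write_phantom_spec <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  shapes <- purrr::map(x$shapes, function(s) {
    s$center <- as.numeric(s$center)
    if (!is.null(s$axes)) s$axes <- as.numeric(s$axes)
    if (!is.null(s$extent)) s$extent <- as.numeric(s$extent)
    s
  })
  phantom_spec(x$size, background = x$background, shapes = shapes)
}
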