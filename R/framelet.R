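#' Piecewise-linear B-spline tight-framelet filter bank
#'
#' Three length-3 filters: the low-pass `k0 = c(1, 2, 1)/4`, the first-order
#' detail `k1 = sqrt(2) * c(1, 0, -1)/4`, and the second-order detail
#' `k2 = c(-1, 2, -1)/4`. They satisfy the unitary (tight-frame) condition
#' `|k0^(w)|^2 + |k1^(w)|^2 + |k2^(w)|^2 = 1` at every frequency, which makes
#' the undecimated separable 2D transform a Parseval frame: synthesis after
#' analysis is the identity.
#'
#' @return A `framelet_bank` with field `filters` (list of the three
#'   filters, taps at offsets -1, 0, 1).
#' @examples
#' bk <- build_filter_bank()
#' sum(bk$filters[[1]])  # low-pass preserves constants
#' @export
build_filter_bank <- function() {
  filters <- list(
    k0 = c(1, 2, 1) / 4,
    k1 = sqrt(2) * c(1, 0, -1) / 4,
    k2 = c(-1, 2, -1) / 4
  )
  bank <- structure(list(filters = filters), class = "framelet_bank")
  # verify the unitary condition at construction
  w <- seq(0, 2 * pi, length.out = 17)[-17]
  s <- framelet_frequency_response(bank, w)
  if (max(abs(s - 1)) > 1e-12) {
    stop("filter bank violates the unitary tight-frame condition", call. = FALSE)
  }
  bank
}

#' Squared frequency response sum of the filter bank
#'
#' Evaluates `sum_i |ki^(w)|^2` by the discrete-time Fourier transform of the
#' three filters; equals 1 identically for a tight frame.
#'
#' @param bank a [build_filter_bank()].
#' @param omega numeric vector of angular frequencies.
#' @return Numeric vector the length of `omega`.
#' @export
framelet_frequency_response <- function(bank, omega) {
  taps <- c(-1, 0, 1)
  out <- numeric(length(omega))
  for (k in bank$filters) {
    h <- vapply(omega, function(w) sum(k * exp(-1i * w * taps)), complex(1))
    out <- out + Mod(h)^2
  }
  out
}

# circular 1D convolution along rows / cols with a centred length-3 filter:
# (k * x)[n] = k[-1] x[n+1] + k[0] x[n] + k[1] x[n-1]  (periodic extension)
conv_rows <- function(x, k) {
  n <- nrow(x)
  up <- x[c(2:n, 1), , drop = FALSE]    # x[n+1]
  down <- x[c(n, 1:(n - 1)), , drop = FALSE]  # x[n-1]
  k[1] * up + k[2] * x + k[3] * down
}
conv_cols <- function(x, k) {
  n <- ncol(x)
  left <- x[, c(2:n, 1), drop = FALSE]
  right <- x[, c(n, 1:(n - 1)), drop = FALSE]
  k[1] * left + k[2] * x + k[3] * right
}
# adjoints: circular correlation
corr_rows <- function(x, k) conv_rows(x, rev(k))
corr_cols <- function(x, k) conv_cols(x, rev(k))

subband_names <- function() {
  as.vector(t(outer(0:2, 0:2, function(i, j) paste0("s", i, j))))
}

#' Undecimated tight-frame analysis
#'
#' Decomposes an image into 9 subbands, one per filter pair `(i, j)`:
#' circular convolution with the separable kernel `ki` (rows) x `kj` (cols),
#' periodic boundary, single level, no decimation. Subband `(0,0)` is the
#' low-pass approximation; the other 8 are detail subbands. Ordering is
#' row-filter-major: `s00, s01, s02, s10, ..., s22`.
#'
#' @param image a [ct_image()] or matrix, at least 3 x 3.
#' @param bank a [build_filter_bank()].
#' @return A `framelet_coefficients` object with fields `subbands` (named
#'   list of 9 matrices) and `source_shape`.
#' @export
framelet_analyze <- function(image, bank = build_filter_bank()) {
  px <- if (inherits(image, "ct_image")) image$pixels else as.matrix(image)
  if (nrow(px) < 3 || ncol(px) < 3) {
    stop("image must be at least 3 x 3 for framelet analysis", call. = FALSE)
  }
  f <- bank$filters
  subbands <- list()
  for (i in 0:2) {
    rowpass <- conv_rows(px, f[[i + 1]])
    for (j in 0:2) {
      subbands[[paste0("s", i, j)]] <- conv_cols(rowpass, f[[j + 1]])
    }
  }
  structure(
    list(subbands = subbands, source_shape = dim(px)),
    class = "framelet_coefficients"
  )
}

#' Tight-frame synthesis (exact transpose of analysis)
#'
#' Applies the adjoint of each analysis kernel (circular correlation) to its
#' subband and sums. Because the bank is a Parseval frame,
#' `framelet_synthesize(framelet_analyze(x))` recovers `x` exactly (to
#' floating-point roundoff).
#'
#' @param coeffs a [framelet_analyze()] result.
#' @param bank a [build_filter_bank()].
#' @param pixel_spacing spacing for the reconstructed [ct_image()].
#' @return A [ct_image()].
#' @export
framelet_synthesize <- function(coeffs, bank = build_filter_bank(),
                                pixel_spacing = 1) {
  stopifnot(inherits(coeffs, "framelet_coefficients"))
  shp <- coeffs$source_shape
  for (nm in subband_names()) {
    sb <- coeffs$subbands[[nm]]
    if (is.null(sb) || !identical(dim(sb), as.integer(shp))) {
      stop("inconsistent subband shapes", call. = FALSE)
    }
  }
  f <- bank$filters
  out <- matrix(0, shp[1], shp[2])
  for (i in 0:2) {
    for (j in 0:2) {
      sb <- coeffs$subbands[[paste0("s", i, j)]]
      out <- out + corr_rows(corr_cols(sb, f[[j + 1]]), f[[i + 1]])
    }
  }
  ct_image(out, pixel_spacing = pixel_spacing)
}

#' @export
print.framelet_coefficients <- function(x, ...) {
  cat(sprintf(
    "<framelet_coefficients> 9 subbands of %d x %d\n",
    x$source_shape[1], x$source_shape[2]
  ))
  invisible(x)
}

# stack the 8 detail subbands as a named list (everything except s00)
detail_names <- function() setdiff(subband_names(), "s00")
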