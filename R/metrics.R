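#' Root-mean-square error between two images
#'
#' `sqrt(sum((P - Q)^2) / M)` with `M` the total pixel count (one global
#' value per image pair, no sliding window). Symmetric in its arguments.
#'
#' @param P reconstructed image ([ct_image()] or matrix).
#' @param Q reference image of the same shape.
#' @return Non-negative scalar.
#' @examples
#' image_rmse(matrix(0, 2, 2), matrix(c(3, 0, 0, 4), 2, 2))  # 2.5
#' @export
image_rmse <- function(P, Q) {
  p <- if (inherits(P, "ct_image")) P$pixels else as.matrix(P)
  q <- if (inherits(Q, "ct_image")) Q$pixels else as.matrix(Q)
  if (!identical(dim(p), dim(q))) stop("images must have the same shape", call. = FALSE)
  sqrt(sum((p - q)^2) / length(p))
}

#' Peak signal-to-noise ratio in dB
#'
#' `10 * log10(max(|Q|)^2 / rmse^2)` with the peak taken from the reference
#' image `Q` (so the metric is intentionally asymmetric). Identical images
#' give `Inf`.
#'
#' @inheritParams image_rmse
#' @return Scalar in dB (`Inf` when the images coincide).
#' @export
image_psnr <- function(P, Q) {
  q <- if (inherits(Q, "ct_image")) Q$pixels else as.matrix(Q)
  peak <- max(abs(q))
  if (peak == 0) stop("reference image is identically zero; PSNR undefined", call. = FALSE)
  r <- image_rmse(P, Q)
  if (r == 0) return(Inf)
  10 * log10(peak^2 / r^2)
}

#' Image-quality report
#'
#' @inheritParams image_rmse
#' @return A one-row tibble with `rmse`, `psnr`, `n_pixels`, `peak_value`.
#' @export
metrics_report <- function(P, Q) {
  q <- if (inherits(Q, "ct_image")) Q$pixels else as.matrix(Q)
  tibble::tibble(
    rmse = image_rmse(P, Q),
    psnr = image_psnr(P, Q),
    n_pixels = length(q),
    peak_value = max(abs(q))
  )
}
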