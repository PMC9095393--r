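#' 2D CT image container
#'
#' A `ct_image` is a real-valued pixel grid: the reconstruction target, a
#' phantom, or a reconstruction result. Pixel values are attenuation on an
#' arbitrary linear scale (phantoms live in `[0, 1]`; no Hounsfield
#' calibration). Row 1 is the top of the image; in continuous coordinates the
#' image centre sits at the origin with y increasing upward and pixel centres
#' at half-integer offsets from the image edge.
#'
#' @param pixels numeric matrix of attenuation values; all values must be
#'   finite and the matrix at least 2 x 2.
#' @param pixel_spacing physical length per pixel (arbitrary units).
#' @return A `ct_image` object.
#' @examples
#' img <- ct_image(matrix(0, 8, 8))
#' dim(img)
#' @export
ct_image <- function(pixels, pixel_spacing = 1) {
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels)) stop("`pixels` must be a numeric matrix", call. = FALSE)
  if (nrow(pixels) < 2 || ncol(pixels) < 2) {
    stop("a ct_image must be at least 2 x 2", call. = FALSE)
  }
  if (!all(is.finite(pixels))) stop("all pixel values must be finite", call. = FALSE)
  if (!is.numeric(pixel_spacing) || length(pixel_spacing) != 1 || pixel_spacing <= 0) {
    stop("`pixel_spacing` must be a single positive number", call. = FALSE)
  }
  structure(
    list(pixels = unname(pixels), pixel_spacing = as.numeric(pixel_spacing)),
    class = "ct_image"
  )
}

#' Coerce to a CT image
#'
#' @param x a matrix or `ct_image`.
#' @param ... passed to [ct_image()].
#' @return A `ct_image`.
#' @export
as_ct_image <- function(x, ...) {
  if (inherits(x, "ct_image")) return(x)
  ct_image(x, ...)
}

#' @export
dim.ct_image <- function(x) dim(x$pixels)

#' @export
print.ct_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "<ct_image> %d x %d, spacing %g, range [%.4g, %.4g]\n",
    d[1], d[2], x$pixel_spacing, min(x$pixels), max(x$pixels)
  ))
  invisible(x)
}

#' Read and write CT images as single-page float TIFF
#'
#' Images are stored as 32-bit float single-page TIFF so that attenuation
#' values round-trip without 8-bit quantisation.
#'
#' @param image a [ct_image()].
#' @param path file path.
#' @param pixel_spacing spacing to attach on read (TIFF carries none here).
#' @return `write_image_tiff()` returns `path` invisibly; `read_image_tiff()`
#'   returns a `ct_image`.
#' @export
write_image_tiff <- function(image, path) {
  image <- as_ct_image(image)
  tiff::writeTIFF(image$pixels, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path, pixel_spacing = 1) {
  px <- tiff::readTIFF(path, as.is = FALSE)
  if (is.list(px)) px <- px[[1]]
  if (length(dim(px)) == 3) px <- px[, , 1]
  ct_image(px, pixel_spacing = pixel_spacing)
}

#' Tabulate an image as a tibble
#'
#' Long format suitable for ggplot2: one row per pixel with its matrix row,
#' column and value.
#'
#' @param x a `ct_image`.
#' @param ... unused.
#' @return A tibble with columns `row`, `col`, `value`.
#' @method tidy ct_image
#' @export
tidy.ct_image <- function(x, ...) {
  px <- x$pixels
  tibble::tibble(
    row = rep(seq_len(nrow(px)), times = ncol(px)),
    col = rep(seq_len(ncol(px)), each = nrow(px)),
    value = as.vector(px)
  )
}

#' Plot a CT image
#'
#' @param object a `ct_image`.
#' @param title optional plot title.
#' @param ... unused.
#' @return A ggplot object (grey-scale raster, radiological orientation).
#' @method autoplot ct_image
#' @export
autoplot.ct_image <- function(object, title = NULL, ...) {
  df <- tidy.ct_image(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, x = NULL, y = NULL, fill = "value") +
    ggplot2::theme_minimal()
}
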