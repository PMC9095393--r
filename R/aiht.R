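#' AIHT configuration
#'
#' All iteration, relaxation, thresholding and constraint parameters of the
#' adaptive iterative hard-threshold reconstruction.
#'
#' @param n_iters outer iteration cap.
#' @param g SART relaxation factor in `(0, 2]`.
#' @param threshold_mode `"adaptive_lcurve"` (threshold re-selected at the
#'   L-curve corner) or `"fixed"`.
#' @param beta_star detail-subband threshold(s) used in `"fixed"` mode:
#'   a single value applied to all 8 detail subbands, or one value per
#'   detail subband. The low-pass subband is never thresholded.
#' @param lcurve_grid strictly increasing candidate thresholds for the
#'   adaptive mode (at least 3).
#' @param lcurve_every re-select the threshold every this many iterations.
#' @param nonneg clip negative pixels after each synthesis (projection onto
#'   the non-negative orthant)?
#' @param stop_tol stop when the relative image change drops below this.
#' @param sweep SART sweep order, `"sequential"` (classical, default) or
#'   `"simultaneous"`; see [sart_step()].
#' @return An `aiht_config` object.
#' @export
aiht_config <- function(n_iters = 200,
                        g = 1,
                        threshold_mode = c("adaptive_lcurve", "fixed"),
                        beta_star = 0.05,
                        lcurve_grid = 10^seq(-3.5, -0.5, length.out = 8),
                        lcurve_every = 10,
                        nonneg = TRUE,
                        stop_tol = 1e-6,
                        sweep = c("sequential", "simultaneous")) {
  threshold_mode <- match.arg(threshold_mode)
  sweep <- match.arg(sweep)
  if (g <= 0 || g > 2) stop("relaxation `g` must lie in (0, 2]", call. = FALSE)
  if (n_iters < 1) stop("`n_iters` must be >= 1", call. = FALSE)
  if (any(beta_star < 0)) stop("thresholds must be >= 0", call. = FALSE)
  if (!length(beta_star) %in% c(1, 8)) {
    stop("`beta_star` must have length 1 or 8 (one per detail subband)", call. = FALSE)
  }
  if (threshold_mode == "adaptive_lcurve") {
    if (length(lcurve_grid) < 3 || any(diff(lcurve_grid) <= 0)) {
      stop("`lcurve_grid` must be strictly increasing with >= 3 candidates", call. = FALSE)
    }
    if (any(lcurve_grid < 0)) stop("thresholds must be >= 0", call. = FALSE)
  }
  structure(
    list(
      n_iters = as.integer(n_iters), g = g, threshold_mode = threshold_mode,
      beta_star = beta_star, lcurve_grid = lcurve_grid,
      lcurve_every = as.integer(lcurve_every), nonneg = nonneg,
      stop_tol = stop_tol, sweep = sweep
    ),
    class = "aiht_config"
  )
}

#' Hard thresholding of framelet detail coefficients
#'
#' The l0 proximal operator applied per detail subband: a coefficient `y`
#' maps to 0 when `|y| <= beta_star` and passes unchanged otherwise (the tie
#' `|y| = beta_star` resolves to 0 for determinism). The low-pass subband
#' `s00` always passes unchanged.
#'
#' @param coeffs a [framelet_analyze()] result.
#' @param beta_star scalar threshold, or one threshold per detail subband
#'   (length 8, in the row-filter-major order `s01, s02, s10, ..., s22`).
#' @return A `framelet_coefficients` object.
#' @export
hard_threshold <- function(coeffs, beta_star) {
  stopifnot(inherits(coeffs, "framelet_coefficients"))
  if (any(beta_star < 0)) stop("thresholds must be >= 0", call. = FALSE)
  dn <- detail_names()
  if (length(beta_star) == 1) beta_star <- rep(beta_star, length(dn))
  if (length(beta_star) != length(dn)) {
    stop("`beta_star` must have length 1 or 8", call. = FALSE)
  }
  out <- coeffs
  for (k in seq_along(dn)) {
    sb <- coeffs$subbands[[dn[k]]]
    sb[abs(sb) <= beta_star[k]] <- 0
    out$subbands[[dn[k]]] <- sb
  }
  out
}

# number of nonzero detail coefficients
count_surviving <- function(coeffs) {
  sum(vapply(detail_names(), function(nm) sum(coeffs$subbands[[nm]] != 0), 0))
}

# Menger curvature of three points (4 * area / product of side lengths);
# NA when any two points coincide.
menger_curvature <- function(p1, p2, p3) {
  a <- sqrt(sum((p1 - p2)^2))
  b <- sqrt(sum((p2 - p3)^2))
  cc <- sqrt(sum((p1 - p3)^2))
  if (a == 0 || b == 0 || cc == 0) return(NA_real_)
  cross <- (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1])
  2 * abs(cross) / (a * b * cc)
}

#' Adaptive threshold selection at the L-curve corner
#'
#' For each candidate threshold `t` the current image is thresholded in the
#' framelet domain, re-synthesized, and scored by the point
#' `(log10 ||Z h_t - l||_2, log10 #{surviving detail coefficients})`. The
#' selected threshold is the candidate of maximum discrete (three-point
#' Menger) curvature along this L-shaped trade-off curve; ties break toward
#' the smaller threshold, and a degenerate flat curve returns the smallest
#' candidate. The result is always an element of `grid`.
#'
#' @param h current image estimate ([ct_image()] or matrix).
#' @param sino measured [ct_sinogram()].
#' @param bank a [build_filter_bank()].
#' @param grid strictly increasing candidate thresholds (at least 3).
#' @return A single threshold value from `grid`.
#' @export
select_threshold_lcurve <- function(h, sino, bank = build_filter_bank(), grid) {
  if (length(grid) < 3 || any(diff(grid) <= 0)) {
    stop("`grid` must be strictly increasing with >= 3 candidates", call. = FALSE)
  }
  h <- as_ct_image(h)
  size <- nrow(h$pixels)
  prj <- projector_for(sino$geometry, size, h$pixel_spacing)
  lvec <- sino_to_ray_vector(sino)
  coeffs <- framelet_analyze(h, bank)
  pts <- matrix(NA_real_, length(grid), 2)
  for (k in seq_along(grid)) {
    ct <- hard_threshold(coeffs, grid[k])
    n_surv <- count_surviving(ct)
    ht <- framelet_synthesize(ct, bank, pixel_spacing = h$pixel_spacing)
    misfit <- sqrt(sum((as.numeric(prj$Z %*% as.vector(ht$pixels)) - lvec)^2))
    pts[k, ] <- c(log10(max(misfit, .Machine$double.xmin)),
                  log10(max(n_surv, 1)))
  }
  curv <- rep(NA_real_, length(grid))
  for (k in 2:(length(grid) - 1)) {
    curv[k] <- menger_curvature(pts[k - 1, ], pts[k, ], pts[k + 1, ])
  }
  if (all(is.na(curv)) || max(curv, na.rm = TRUE) <= 0) {
    return(grid[1])  # flat or degenerate curve: smallest candidate
  }
  grid[which.max(curv)]  # which.max breaks ties toward the smaller threshold
}

run_aiht_engine <- function(sino, size, config, pixel_spacing = 1) {
  stopifnot(inherits(config, "aiht_config"))
  bank <- build_filter_bank()
  prj <- projector_for(sino$geometry, size, pixel_spacing)
  weights <- if (config$sweep == "simultaneous") sart_weights_for(prj)
  blocks <- if (config$sweep == "sequential") {
    view_blocks_for(prj, sino$geometry, pixel_spacing)
  }
  lvec <- sino_to_ray_vector(sino)
  hvec <- rep(0, prod(prj$image_shape))
  beta <- config$beta_star
  trace <- vector("list", config$n_iters)
  n_total_detail <- 8 * prod(prj$image_shape)
  for (m in seq_len(config$n_iters)) {
    hstar <- sart_sweep_raw(hvec, lvec, prj, config$g, config$sweep,
                            weights, blocks)
    hstar_img <- ct_image(matrix(hstar, nrow = size), pixel_spacing = pixel_spacing)
    coeffs <- framelet_analyze(hstar_img, bank)
    if (config$threshold_mode == "adaptive_lcurve" &&
        (m == 1 || (m - 1) %% config$lcurve_every == 0)) {
      beta <- select_threshold_lcurve(hstar_img, sino, bank, config$lcurve_grid)
    }
    ct <- hard_threshold(coeffs, beta)
    n_surv <- count_surviving(ct)
    hnew <- as.vector(framelet_synthesize(ct, bank)$pixels)
    if (config$nonneg) hnew <- pmax(hnew, 0)
    misfit <- sqrt(sum((as.numeric(prj$Z %*% hnew) - lvec)^2))
    rel_change <- sqrt(sum((hnew - hvec)^2)) / max(sqrt(sum(hnew^2)), .Machine$double.eps)
    hvec <- hnew
    trace[[m]] <- tibble::tibble(
      iteration = m, misfit = misfit, n_surviving = n_surv,
      n_detail_total = n_total_detail,
      threshold = beta[1], rel_change = rel_change
    )
    if (rel_change < config$stop_tol) break
  }
  structure(
    list(
      image = ct_image(matrix(hvec, nrow = size), pixel_spacing = pixel_spacing),
      trace = dplyr::bind_rows(trace),
      config = config,
      geometry = sino$geometry
    ),
    class = "aiht_fit"
  )
}

#' Adaptive iterative hard-threshold (AIHT) reconstruction
#'
#' The full three-stage loop, started from the zero image: a SART
#' data-fidelity sweep, framelet analysis, hard thresholding of the detail
#' subbands (with the threshold re-selected periodically at the L-curve
#' corner when `threshold_mode = "adaptive_lcurve"`), framelet synthesis,
#' and an optional non-negativity clip. Stops at `n_iters` sweeps or when
#' the relative image change falls below `stop_tol`. Deterministic for fixed
#' inputs and configuration.
#'
#' @param sino a [ct_sinogram()].
#' @param size image side in pixels.
#' @param config an [aiht_config()].
#' @param pixel_spacing physical length per pixel.
#' @return An `aiht_fit` with fields `image` ([ct_image()]), `trace`
#'   (per-iteration tibble: misfit, surviving-coefficient count, threshold,
#'   relative change), `config`, `geometry`.
#' @examples
#' ph <- default_phantom(32)
#' g <- limited_angle_geometry(c(0, 90), 45, default_n_detectors(32))
#' fit <- run_aiht(forward_project(ph, g), 32, aiht_config(n_iters = 20))
#' glance(fit)
#' @export
run_aiht <- function(sino, size, config = aiht_config(), pixel_spacing = 1) {
  run_aiht_engine(sino, size, config, pixel_spacing)
}

#' Fixed-threshold wavelet-frame (WF) baseline
#'
#' The same loop as [run_aiht()] with a fixed, non-adaptive detail
#' threshold: the wavelet-frame comparator used alongside plain SART and
#' FBP. Identical to `run_aiht()` with `threshold_mode = "fixed"`.
#'
#' @inheritParams run_aiht
#' @param config an [aiht_config()]; its `threshold_mode` is forced to
#'   `"fixed"`.
#' @return An `aiht_fit`.
#' @export
run_wf_baseline <- function(sino, size, config = aiht_config(threshold_mode = "fixed"),
                            pixel_spacing = 1) {
  config$threshold_mode <- "fixed"
  run_aiht_engine(sino, size, config, pixel_spacing)
}

#' @export
print.aiht_fit <- function(x, ...) {
  n <- nrow(x$trace)
  cat(sprintf(
    "<aiht_fit> %d x %d image after %d iterations (%s threshold), final misfit %.4g\n",
    nrow(x$image$pixels), ncol(x$image$pixels), n,
    x$config$threshold_mode, x$trace$misfit[n]
  ))
  invisible(x)
}

#' Per-iteration trace of an AIHT fit
#'
#' @param x an `aiht_fit`.
#' @param ... unused.
#' @return The per-iteration tibble (`iteration`, `misfit`, `n_surviving`,
#'   `n_detail_total`, `threshold`, `rel_change`).
#' @method tidy aiht_fit
#' @export
tidy.aiht_fit <- function(x, ...) x$trace

#' One-row summary of an AIHT fit
#'
#' @param x an `aiht_fit`.
#' @param ... unused.
#' @return A one-row tibble: iterations run, final misfit, final threshold,
#'   final detail sparsity (surviving / total).
#' @method glance aiht_fit
#' @export
glance.aiht_fit <- function(x, ...) {
  n <- nrow(x$trace)
  tibble::tibble(
    n_iters = n,
    final_misfit = x$trace$misfit[n],
    final_threshold = x$trace$threshold[n],
    detail_sparsity = x$trace$n_surviving[n] / x$trace$n_detail_total[n],
    converged = x$trace$rel_change[n] < x$config$stop_tol
  )
}

#' Plot the convergence trace of an AIHT fit
#'
#' @param object an `aiht_fit`.
#' @param ... unused.
#' @return A ggplot of data misfit and surviving-coefficient count per
#'   iteration (free y scales).
#' @method autoplot aiht_fit
#' @export
autoplot.aiht_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$trace[, c("iteration", "misfit", "n_surviving")],
    -"iteration", names_to = "quantity", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "iteration", y = NULL) +
    ggplot2::theme_minimal()
}
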