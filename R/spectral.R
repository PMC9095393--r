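#' Slope of an energy-spectrum attenuation curve
#'
#' The change of monoenergetic CT value per keV between the curve's lowest
#' and highest sampled energies, with the low-energy value first:
#' `(CT(E_low) - CT(E_high)) / (E_high - E_low)` (HU/keV). Under this
#' radiology convention a descending attenuation curve — CT value falling
#' with energy, the hepatic-ascites signature — has positive slope.
#'
#' @param curve named numeric vector of CT values (HU); names are the
#'   monoenergies in keV (e.g. `c(keV_40 = 100, keV_100 = 40)`), or a
#'   numeric vector with `energies` supplied separately.
#' @param energies optional numeric vector of energies (keV) matching
#'   `curve`.
#' @return Scalar slope in HU/keV.
#' @examples
#' spectral_slope(c(100, 40), energies = c(40, 100))  # 1
#' @export
spectral_slope <- function(curve, energies = NULL) {
  if (is.null(energies)) energies <- curve_energies(curve)
  if (length(curve) < 2 || length(energies) != length(curve)) {
    stop("curve needs at least 2 energy samples with matching energies", call. = FALSE)
  }
  if (any(diff(order(energies)) < 0) || any(duplicated(energies))) {
    stop("energies must be distinct", call. = FALSE)
  }
  lo <- which.min(energies)
  hi <- which.max(energies)
  (curve[[lo]] - curve[[hi]]) / (energies[hi] - energies[lo])
}

curve_energies <- function(curve) {
  nm <- names(curve)
  if (is.null(nm)) stop("supply `energies` or name the curve values 'keV_<E>'", call. = FALSE)
  as.numeric(sub("^keV_", "", nm))
}

#' Classify an energy-spectrum curve
#'
#' `"descending"` when the CT value falls with energy (positive
#' [spectral_slope()]), `"ascending"` when it rises, `"flat"` at exactly
#' zero slope.
#'
#' @inheritParams spectral_slope
#' @return One of `"ascending"`, `"descending"`, `"flat"`.
#' @export
classify_curve <- function(curve, energies = NULL) {
  s <- spectral_slope(curve, energies)
  if (s > 0) "descending" else if (s < 0) "ascending" else "flat"
}

#' Specify a synthetic two-group spectral-CT cohort
#'
#' The statistical stand-in for a hepatic-ascites (S1) versus carcinomatous
#' effusion (D0) cohort. Each spectral parameter is drawn independently per
#' group from a normal model; per-subject monoenergetic curves are
#' exponential-like decays anchored at the high-energy CT value and matched
#' to the drawn slope. Default group means follow the reported direction of
#' the group differences: S1 has lower mixed-energy CT value, lower
#' water(iodine) and water(calcium) concentrations, higher effective atomic
#' number, and predominantly descending curves (positive slope), with
#' slope-sign probabilities matching the reported curve-type proportions
#' (about 94% descending in S1 and 88% ascending in D0).
#'
#' @param n_per_group integer vector `c(S1, D0)`; default the study's 50/42.
#' @param means named list of group means, each a length-2 vector
#'   `c(S1, D0)`, for `slope` (HU/keV), `mixed_ct` (HU), `water_iodine`
#'   (mg/mL), `water_calcium` (mg/mL), `zeff`.
#' @param sds named list of matching standard deviations (all `> 0`).
#' @param energy_grid monoenergies (keV) at which curves are sampled.
#' @param seed integer seed.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_per_group = c(50, 42),
                        means = list(
                          slope = c(1.20, -0.85),
                          mixed_ct = c(8, 15),
                          water_iodine = c(1.2, 3.1),
                          water_calcium = c(6, 13),
                          zeff = c(7.80, 7.45)
                        ),
                        sds = list(
                          slope = c(0.77, 0.72),
                          mixed_ct = c(4, 4),
                          water_iodine = c(0.9, 1.0),
                          water_calcium = c(3, 3.5),
                          zeff = c(0.25, 0.25)
                        ),
                        energy_grid = seq(40, 100, by = 10),
                        seed = 1) {
  if (length(n_per_group) != 2 || any(n_per_group < 2)) {
    stop("`n_per_group` must be two integers >= 2", call. = FALSE)
  }
  pars <- c("slope", "mixed_ct", "water_iodine", "water_calcium", "zeff")
  for (p in pars) {
    if (is.null(means[[p]]) || length(means[[p]]) != 2) {
      stop(sprintf("`means$%s` must have length 2", p), call. = FALSE)
    }
    if (is.null(sds[[p]]) || length(sds[[p]]) != 2 || any(sds[[p]] <= 0)) {
      stop(sprintf("`sds$%s` must be two positive values", p), call. = FALSE)
    }
  }
  if (length(energy_grid) < 2 || any(diff(energy_grid) <= 0)) {
    stop("`energy_grid` must be strictly increasing with >= 2 points", call. = FALSE)
  }
  structure(
    list(n_per_group = as.integer(n_per_group), means = means, sds = sds,
         energy_grid = as.numeric(energy_grid), seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# Exponential-like monoenergetic curve through (E_lo, ct_lo) and (E_hi, ct_hi)
# with fixed decay constant; two free parameters per subject (level, slope).
spectral_curve_values <- function(ct_hi, slope, energies, decay = 1 / 30) {
  e_lo <- min(energies); e_hi <- max(energies)
  ct_lo <- ct_hi + slope * (e_hi - e_lo)
  shape <- (exp(-decay * (energies - e_lo)) - exp(-decay * (e_hi - e_lo))) /
    (1 - exp(-decay * (e_hi - e_lo)))
  ct_hi + (ct_lo - ct_hi) * shape
}

#' Generate a synthetic spectral-CT cohort
#'
#' Draws every parameter independently from the per-group normal model of
#' the [cohort_spec()] (concentrations truncated at 0) and synthesizes each
#' subject's monoenergetic curve. Deterministic per seed.
#'
#' @param spec a [cohort_spec()].
#' @return A tibble with one row per subject: `subject_id`, `group`
#'   (`"S1_hepatic"` / `"D0_carcinomatous"`), `water_iodine`,
#'   `water_calcium`, `zeff`, `mixed_ct`, `slope`, then one `keV_<E>` column
#'   per energy-grid point.
#' @examples
#' co <- generate_cohort(cohort_spec(seed = 7))
#' dplyr::count(co, group)
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  groups <- c("S1_hepatic", "D0_carcinomatous")
  rows <- purrr::map2(groups, seq_along(groups), function(gname, gi) {
    n <- spec$n_per_group[gi]
    draw <- function(p) stats::rnorm(n, spec$means[[p]][gi], spec$sds[[p]][gi])
    tibble::tibble(
      group = gname,
      water_iodine = pmax(draw("water_iodine"), 0),
      water_calcium = pmax(draw("water_calcium"), 0),
      zeff = draw("zeff"),
      mixed_ct = draw("mixed_ct"),
      slope = draw("slope")
    )
  })
  co <- dplyr::bind_rows(rows)
  co$subject_id <- sprintf("subj_%03d", seq_len(nrow(co)))
  # per-subject monoenergetic curve anchored at the high-energy CT value
  curves <- purrr::map2(co$mixed_ct, co$slope, function(cthi, sl) {
    spectral_curve_values(cthi, sl, spec$energy_grid)
  })
  cm <- do.call(rbind, curves)
  colnames(cm) <- sprintf("keV_%g", spec$energy_grid)
  dplyr::bind_cols(
    co[, c("subject_id", "group", "water_iodine", "water_calcium",
           "zeff", "mixed_ct", "slope")],
    tibble::as_tibble(cm)
  )
}

#' Read and write cohorts as CSV
#'
#' One row per subject with the columns produced by [generate_cohort()].
#'
#' @param cohort a cohort tibble.
#' @param path file path.
#' @return `write_cohort_csv()` returns `path` invisibly;
#'   `read_cohort_csv()` returns a tibble.
#' @export
write_cohort_csv <- function(cohort, path) {
  readr::write_csv(cohort, path)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Empirical ROC analysis of a scalar diagnostic marker
#'
#' Sweeps every observed marker value as a threshold, computes sensitivity
#' and specificity for the positive group, the area under the ROC curve by
#' the trapezoidal rule (equivalently the Mann-Whitney statistic, counting
#' ties as 1/2), and the operating point maximizing Youden's
#' `J = sensitivity + specificity - 1` (ties broken toward higher
#' sensitivity). With `direction = "lesser_is_positive"` lower marker values
#' indicate the positive class.
#'
#' @param values numeric marker values, one per subject.
#' @param labels logical or two-level vector; `positive` identifies the
#'   positive class.
#' @param direction `"greater_is_positive"` or `"lesser_is_positive"`.
#' @param positive the label treated as positive (defaults to the first
#'   level encountered when `labels` is not logical).
#' @return A `roc_result` with `auc`, `best_threshold`, `sensitivity`,
#'   `specificity`, `direction`, and the full `curve` tibble
#'   (`threshold`, `sensitivity`, `specificity`, `youden_j`).
#' @examples
#' r <- roc_metrics(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE),
#'                  direction = "lesser_is_positive")
#' r$auc
#' @export
roc_metrics <- function(values, labels,
                        direction = c("greater_is_positive", "lesser_is_positive"),
                        positive = NULL) {
  direction <- match.arg(direction)
  if (length(values) != length(labels)) {
    stop("`values` and `labels` must have the same length", call. = FALSE)
  }
  if (is.logical(labels)) {
    pos <- labels
  } else {
    lv <- unique(as.character(labels))
    if (length(lv) != 2) stop("`labels` must contain exactly two classes", call. = FALSE)
    if (is.null(positive)) positive <- lv[1]
    pos <- as.character(labels) == positive
  }
  if (sum(pos) < 2 || sum(!pos) < 2) {
    stop("need at least 2 subjects in each class", call. = FALSE)
  }
  score <- if (direction == "greater_is_positive") values else -values
  # AUC via the Mann-Whitney rank statistic (ties count 1/2)
  rk <- rank(score)
  n1 <- sum(pos); n0 <- sum(!pos)
  auc <- (sum(rk[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  # sensitivity/specificity at every observed threshold: predict positive
  # when score >= threshold
  thr <- sort(unique(score), decreasing = TRUE)
  sens <- vapply(thr, function(t) mean(score[pos] >= t), 0)
  spec <- vapply(thr, function(t) mean(score[!pos] < t), 0)
  j <- sens + spec - 1
  best <- which(j == max(j))
  if (length(best) > 1) best <- best[which.max(sens[best])]
  curve <- tibble::tibble(
    threshold = if (direction == "greater_is_positive") thr else -thr,
    sensitivity = sens, specificity = spec, youden_j = j
  )
  structure(
    list(
      auc = auc,
      best_threshold = curve$threshold[best],
      sensitivity = sens[best],
      specificity = spec[best],
      direction = direction,
      curve = curve
    ),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "<roc_result> AUC %.3f; Youden point: threshold %.4g, sensitivity %.3f, specificity %.3f (%s)\n",
    x$auc, x$best_threshold, x$sensitivity, x$specificity, x$direction
  ))
  invisible(x)
}

#' Full ROC curve of a fitted ROC result
#'
#' @param x a [roc_metrics()] result.
#' @param ... unused.
#' @return The per-threshold tibble (`threshold`, `sensitivity`,
#'   `specificity`, `youden_j`).
#' @export
tidy.roc_result <- function(x, ...) x$curve

#' One-row summary of a ROC result
#'
#' @param x a [roc_metrics()] result.
#' @param ... unused.
#' @return A one-row tibble: `auc`, `best_threshold`, `sensitivity`,
#'   `specificity`, `direction`.
#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(
    auc = x$auc, best_threshold = x$best_threshold,
    sensitivity = x$sensitivity, specificity = x$specificity,
    direction = x$direction
  )
}

#' Plot a ROC curve
#'
#' @param object a [roc_metrics()] result.
#' @param ... unused.
#' @return A ggplot of sensitivity against 1 - specificity with the Youden
#'   operating point marked.
#' @export
autoplot.roc_result <- function(object, ...) {
  df <- object$curve
  ggplot2::ggplot(df, ggplot2::aes(x = 1 - .data$specificity, y = .data$sensitivity)) +
    ggplot2::geom_path() +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::annotate(
      "point",
      x = 1 - object$specificity, y = object$sensitivity,
      colour = "red", size = 2
    ) +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = "1 - specificity", y = "sensitivity",
      title = sprintf("AUC = %.3f", object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Write a ROC result as JSON
#'
#' @param roc a [roc_metrics()] result.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_roc_json <- function(roc, path) {
  jsonlite::write_json(
    list(
      auc = roc$auc, best_threshold = roc$best_threshold,
      sensitivity = roc$sensitivity, specificity = roc$specificity,
      direction = roc$direction
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Spectral diagnostic summary of a cohort
#'
#' Computes, from a cohort tibble, the per-group mean curve slope, the
#' curve-type proportions, and ROC analyses for the three quantitative
#' markers (water(iodine), water(calcium), curve slope) with the hepatic
#' group as positive class. Marker directions follow the group-difference
#' directions of the generator: concentrations are lower in the hepatic
#' group (`lesser_is_positive`), the slope higher (`greater_is_positive`).
#'
#' @param cohort a [generate_cohort()] tibble (or one read from CSV).
#' @param positive_group group label treated as positive.
#' @return A list with `curve_types` (tibble of per-group curve-type
#'   proportions), `slope_by_group` (tibble of group slope means), and
#'   `roc` (named list of `roc_result`s for `water_iodine`,
#'   `water_calcium`, `slope`).
#' @export
spectral_summary <- function(cohort, positive_group = "S1_hepatic") {
  kev <- grep("^keV_", names(cohort), value = TRUE)
  energies <- as.numeric(sub("^keV_", "", kev))
  slopes <- apply(as.matrix(cohort[, kev]), 1, spectral_slope, energies = energies)
  types <- vapply(
    slopes, function(s) if (s > 0) "descending" else if (s < 0) "ascending" else "flat",
    ""
  )
  df <- dplyr::mutate(cohort, curve_slope = slopes, curve_type = types)
  curve_types <- df |>
    dplyr::count(.data$group, .data$curve_type) |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(proportion = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  slope_by_group <- df |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      mean_slope = mean(.data$curve_slope),
      sd_slope = stats::sd(.data$curve_slope),
      .groups = "drop"
    )
  labels <- df$group == positive_group
  roc <- list(
    water_iodine = roc_metrics(df$water_iodine, labels, "lesser_is_positive"),
    water_calcium = roc_metrics(df$water_calcium, labels, "lesser_is_positive"),
    slope = roc_metrics(df$curve_slope, labels, "greater_is_positive")
  )
  list(curve_types = curve_types, slope_by_group = slope_by_group, roc = roc)
}
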