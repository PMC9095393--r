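test_that("curve slopes use the low-minus-high endpoint convention", {
  expect_equal(spectral_slope(c(50, 50, 50), energies = c(40, 70, 100)), 0)
  expect_equal(spectral_slope(c(100, 40), energies = c(40, 100)), 1)
  expect_lt(spectral_slope(c(10, 20, 30), energies = c(40, 70, 100)), 0)
  # named-vector interface
  expect_equal(spectral_slope(c(keV_40 = 100, keV_70 = 60, keV_100 = 40)), 1)
  expect_error(spectral_slope(c(keV_40 = 1)), "2 energy samples")
})

test_that("curves classify by slope sign", {
  expect_identical(classify_curve(c(100, 40), energies = c(40, 100)), "descending")
  expect_identical(classify_curve(c(40, 100), energies = c(40, 100)), "ascending")
  expect_identical(classify_curve(c(7, 7), energies = c(40, 100)), "flat")
})

test_that("cohort generation is deterministic and matches its normal model", {
  co1 <- generate_cohort(cohort_spec(seed = 42))
  co2 <- generate_cohort(cohort_spec(seed = 42))
  expect_identical(co1, co2)
  expect_identical(nrow(co1), 92L)
  expect_identical(unname(table(co1$group)["S1_hepatic"]), 50L)

  big <- cohort_spec(n_per_group = c(10000, 10000), seed = 7)
  co <- generate_cohort(big)
  for (p in c("zeff", "mixed_ct", "slope")) {
    for (gi in 1:2) {
      gname <- c("S1_hepatic", "D0_carcinomatous")[gi]
      xs <- co[[p]][co$group == gname]
      se <- big$sds[[p]][gi] / sqrt(10000)
      expect_lt(abs(mean(xs) - big$means[[p]][gi]), 3 * se)
    }
  }
})

test_that("per-subject curves honour the drawn slope and anchor", {
  co <- generate_cohort(cohort_spec(seed = 3))
  kev <- grep("^keV_", names(co), value = TRUE)
  energies <- as.numeric(sub("^keV_", "", kev))
  slopes <- apply(as.matrix(co[, kev]), 1, spectral_slope, energies = energies)
  expect_equal(slopes, co$slope, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(co[[sprintf("keV_%g", max(energies))]], co$mixed_ct,
               tolerance = 1e-10)
})

test_that("curve-type proportions follow the generator's slope-sign probabilities", {
  spec <- cohort_spec(n_per_group = c(4000, 4000), seed = 12)
  co <- generate_cohort(spec)
  sm <- spectral_summary(co)
  p_desc_s1 <- stats::pnorm(spec$means$slope[1] / spec$sds$slope[1])
  p_asc_d0 <- stats::pnorm(-spec$means$slope[2] / spec$sds$slope[2])
  got_s1 <- sm$curve_types$proportion[sm$curve_types$group == "S1_hepatic" &
                                        sm$curve_types$curve_type == "descending"]
  got_d0 <- sm$curve_types$proportion[sm$curve_types$group == "D0_carcinomatous" &
                                        sm$curve_types$curve_type == "ascending"]
  tol <- 3 * sqrt(0.25 / 4000)
  expect_lt(abs(got_s1 - p_desc_s1), tol)
  expect_lt(abs(got_d0 - p_asc_d0), tol)
  # hepatic curves predominantly descending, carcinomatous ascending
  expect_gt(got_s1, 0.85)
  expect_gt(got_d0, 0.8)
})

test_that("exchangeable groups give chance-level discrimination", {
  eq <- cohort_spec(
    n_per_group = c(2000, 2000),
    means = list(slope = c(0, 0), mixed_ct = c(10, 10),
                 water_iodine = c(2, 2), water_calcium = c(8, 8),
                 zeff = c(7.6, 7.6)),
    seed = 9
  )
  co <- generate_cohort(eq)
  r <- roc_metrics(co$water_iodine, co$group == "S1_hepatic", "lesser_is_positive")
  expect_lt(abs(r$auc - 0.5), 0.03)
})

test_that("ROC handles separation, anti-separation and validation", {
  r <- roc_metrics(c(5, 6, 7, 1, 2, 3), rep(c(TRUE, FALSE), each = 3))
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  r0 <- roc_metrics(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r0$auc, 0)
  expect_error(roc_metrics(1:4, rep(TRUE, 4)), "class")
  expect_error(roc_metrics(1:3, c(TRUE, FALSE, TRUE)), "2 subjects")
})

test_that("AUC is invariant under strictly monotone transforms", {
  set.seed(21)
  x <- rnorm(60)
  lab <- rep(c(TRUE, FALSE), 30)
  a0 <- roc_metrics(x, lab)$auc
  expect_equal(roc_metrics(exp(x), lab)$auc, a0)
  expect_equal(roc_metrics(x^3 + 5 * x, lab)$auc, a0)
})

test_that("the Youden point dominates every observed threshold", {
  set.seed(33)
  vals <- c(rnorm(15, 1), rnorm(15))
  lab <- rep(c(TRUE, FALSE), each = 15)
  r <- roc_metrics(vals, lab)
  best_j <- r$sensitivity + r$specificity - 1
  expect_true(all(r$curve$youden_j <= best_j + 1e-12))
})

test_that("ROC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(14)
  vals <- c(rnorm(40, 1.1), rnorm(35))
  lab <- rep(c(1, 0), c(40, 35))
  ours <- roc_metrics(vals, lab == 1)
  ref <- pROC::roc(lab, vals, direction = "<", quiet = TRUE)
  expect_equal(ours$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-10)
  yj <- pROC::coords(ref, "best", best.method = "youden",
                     ret = c("sensitivity", "specificity"))
  expect_equal(ours$sensitivity + ours$specificity,
               yj$sensitivity + yj$specificity, tolerance = 1e-10)
})

test_that("cohorts and ROC results round-trip through CSV and JSON", {
  co <- generate_cohort(cohort_spec(seed = 2))
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(co, f)
  co2 <- read_cohort_csv(f)
  expect_equal(as.data.frame(co2), as.data.frame(co), tolerance = 1e-12)

  r <- roc_metrics(co$water_iodine, co$group == "S1_hepatic", "lesser_is_positive")
  jf <- withr::local_tempfile(fileext = ".json")
  write_roc_json(r, jf)
  back <- jsonlite::read_json(jf, simplifyVector = TRUE)
  expect_equal(back$auc, r$auc)
  expect_equal(back$sensitivity, r$sensitivity)
  expect_s3_class(tidy(r), "tbl_df")
  expect_identical(nrow(glance(r)), 1L)
})

test_that("the cohort summary reports group differences in the right direction", {
  co <- generate_cohort(cohort_spec(seed = 5))
  sm <- spectral_summary(co)
  s1 <- sm$slope_by_group$mean_slope[sm$slope_by_group$group == "S1_hepatic"]
  d0 <- sm$slope_by_group$mean_slope[sm$slope_by_group$group == "D0_carcinomatous"]
  expect_gt(s1, 0)
  expect_lt(d0, 0)
  for (nm in names(sm$roc)) expect_gt(sm$roc[[nm]]$auc, 0.5)
})
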