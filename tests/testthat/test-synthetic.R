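test_that("cohort_config validates the study design", {
  expect_s3_class(cohort_config(), "cohort_config")
  expect_error(cohort_config(n_patients = 1), "n_patients")
  expect_error(cohort_config(n_observers = 1), "n_observers")
  expect_error(cohort_config(sigma2_patient = -1), "sigma2_patient")
  expect_error(cohort_config(spacing_mm = 0), "positive")
  expect_error(cohort_config(beta0_dsc = c(0.9, 0.8)), "per organ")
  cm <- default_confidence_model <- cohort_config()$confidence_model
  cm[1, 1, ] <- c(2, 0, 0, 0, 0)
  expect_error(cohort_config(confidence_model = cm), "sum to 1")
})

test_that("config round-trips through YAML", {
  cfg <- cohort_config(n_patients = 4, seed = 9, sigma2_patient = 0.007)
  f <- tempfile(fileext = ".yaml")
  write_cohort_config(cfg, f)
  cfg2 <- read_cohort_config(f)
  expect_equal(cfg2$n_patients, 4L)
  expect_equal(cfg2$seed, 9L)
  expect_equal(cfg2$sigma2_patient, 0.007)
  expect_equal(cfg2$beta0_dsc, cfg$beta0_dsc)
  writeLines("nonsense_field: 3", f)
  expect_error(read_cohort_config(f), "unknown config field")
  unlink(f)
})

test_that("cohort has the design arithmetic of the study", {
  cfg <- cohort_config(n_patients = 3, seed = 5)
  coh <- generate_cohort(cfg)
  expect_equal(length(coh$records), 3 * 2 * 5 * 3)
  expect_equal(nrow(coh$scans), 6)
  meta <- cohort_metadata(coh)
  expect_equal(nrow(meta), 90)
  expect_true(all(table(meta$organ) == 18))
  expect_true(all(meta$confidence %in% 1:5))
  expect_true(all(meta$correction_time_s > 0))
  # every record's three masks share one grid
  r <- coh$records[[1]]
  expect_identical(dim(r$truth_mask$voxels), dim(r$ai_mask$voxels))
  expect_identical(dim(r$truth_mask$voxels), dim(r$corrected_mask$voxels))
})

test_that("identical config and seed give bit-identical cohorts", {
  cfg <- function() cohort_config(n_patients = 2, seed = 7)
  c1 <- generate_cohort(cfg())
  c2 <- generate_cohort(cfg())
  expect_identical(c1$records, c2$records)
  expect_identical(cohort_metadata(c1), cohort_metadata(c2))
})

test_that("zero deformation and zero variance give perfect agreement", {
  cfg <- cohort_config(n_patients = 2, sigma2_patient = 0, sigma2_observer = 0,
                       sigma2_residual = 0, deformation_scale = 0, seed = 3)
  coh <- generate_cohort(cfg)
  for (r in coh$records[seq(1, 60, by = 7)]) {
    expect_identical(r$ai_mask$voxels, r$truth_mask$voxels)
    expect_identical(r$corrected_mask$voxels, r$truth_mask$voxels)
  }
  m <- metrics_for_cohort(coh)
  expect_true(all(m$dsc == 1))
  expect_true(all(m$hd95 == 0))
})

test_that("a grid too small for the organs fails naming the organ", {
  expect_error(generate_cohort(cohort_config(grid_shape = 24, seed = 1)),
               "grid too small to contain organ")
})

test_that("generate_metric_table realises the linear model", {
  # no noise: arm values are exactly beta0 and beta0 + beta1
  d0 <- generate_metric_table(0.9, -0.35, 0, 0, 0, n_patients = 4, seed = 1)
  expect_true(all(d0$value[d0$x == 0] == 0.9))
  expect_true(all(d0$value[d0$x == 1] == 0.9 - 0.35))
  expect_equal(nrow(d0), 4 * 3 * 2)

  # large n: the arm-mean difference recovers beta1 within 3 MC SEs
  d <- generate_metric_table(0.9, -0.35, 3e-3, 4e-4, 2.5e-3,
                             n_patients = 2000, seed = 42)
  diff <- mean(d$value[d$x == 1]) - mean(d$value[d$x == 0])
  mc_se <- sqrt(2 * 2.5e-3 / (2000 * 3))
  expect_lt(abs(diff - (-0.35)), 3 * mc_se)

  expect_error(generate_metric_table(0.9, 0, -0.1, 0, 1), ">= 0")
})

test_that("variance decomposition of a huge metric table recovers each component", {
  a <- 10000L; b <- 50L
  truth <- c(patient = 3e-3, observer = 4e-4, residual = 2.5e-3)
  d <- generate_metric_table(0.85, -0.02, truth[1], truth[2], truth[3],
                             n_patients = a, n_observers = b, seed = 99)
  est <- mom_oracle(d)
  n <- nrow(d)
  # the patient/residual strata have thousands of df (<5% recovery); the
  # observer stratum has only b - 1, so its tolerance is its own MC error
  expect_lt(abs(est["patient"] / truth["patient"] - 1), 0.05)
  expect_lt(abs(est["residual"] / truth["residual"] - 1), 0.05)
  se_obs <- sqrt(2 / (b - 1)) * (truth["observer"] + truth["residual"] / (n / b))
  expect_lt(abs(est["observer"] - truth["observer"]), 3 * se_obs)
})

test_that("outlier scenario degrades exactly the flagged patient's conventional bladder", {
  cfg <- cohort_config(n_patients = 3, seed = 11,
                       outlier_scenario = list(enabled = TRUE, patient = 2))
  m <- metrics_for_cohort(generate_cohort(cfg))
  bad <- m[m$dsc < 0.2, ]
  expect_true(all(bad$organ == "bladder"))
  expect_true(all(bad$patient_id == "p02"))
  expect_true(all(bad$imaging_system == "conventional"))
  expect_equal(nrow(bad), 3)  # all observers of that scan
  expect_true(all(bad$hd95 > 60))

  # arm isolation: high-performance metrics identical to the no-outlier run
  m0 <- metrics_for_cohort(generate_cohort(cohort_config(n_patients = 3, seed = 11)))
  hp <- m$imaging_system == "high_performance"
  expect_identical(m[hp, c("dsc", "hd95")], m0[hp, c("dsc", "hd95")])
})

test_that("outlier scenario fails loudly when the grid cannot hold the separation", {
  cfg <- cohort_config(organs = "bladder", grid_shape = 75, spacing_mm = 2,
                       beta0_dsc = 0.95, beta1_dsc = -0.03,
                       beta0_hd95 = 4.5, beta1_hd95 = 2,
                       n_patients = 2, seed = 2)
  coh <- generate_cohort(cfg)
  expect_error(apply_outlier_scenario(coh, 1), "grid too small")
})

test_that("estimated variance components track the configured ones across a sweep", {
  # levels spread widely enough to dominate the geometric noise floor of the
  # displacement calibration (~1e-3 on the Dice variance scale)
  res_levels <- c(1e-4, 2e-3, 2e-2)
  est <- vapply(seq_along(res_levels), function(i) {
    cfg <- cohort_config(n_patients = 8, organs = "prostate",
                         beta0_dsc = 0.86, beta1_dsc = 0,
                         beta0_hd95 = 5, beta1_hd95 = 0.3,
                         sigma2_patient = 1e-3, sigma2_observer = 1e-4,
                         sigma2_residual = res_levels[i], seed = 500 + i)
    m <- metrics_for_cohort(generate_cohort(cfg))
    f <- fit_crossed_model(m, response = "dsc", reference = "conventional")
    f$sigma2_residual
  }, numeric(1))
  expect_gt(cor(est, res_levels, method = "spearman"), 0.9)
})

test_that("cohort masks export to NIfTI and read back into identical metrics", {
  cfg <- cohort_config(n_patients = 2, organs = c("prostate", "bladder"),
                       beta0_dsc = c(0.86, 0.95), beta1_dsc = c(0, -0.03),
                       beta0_hd95 = c(5, 4.5), beta1_hd95 = c(0.3, 2), seed = 21)
  coh <- generate_cohort(cfg)
  dir <- file.path(tempdir(), "nifti_export")
  meta_csv <- export_cohort_nifti(coh, dir)
  expect_true(file.exists(meta_csv))
  coh2 <- read_delineations(meta_csv)
  m1 <- metrics_for_cohort(coh)
  m2 <- metrics_for_cohort(coh2)
  expect_equal(m1$dsc, m2$dsc, tolerance = 1e-12)
  expect_equal(m1$hd95, m2$hd95, tolerance = 1e-12)
  unlink(dir, recursive = TRUE)
})
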