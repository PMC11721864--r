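test_that("zero observer variance gives ICC exactly 0", {
  a <- 8; b <- 3
  set.seed(5)
  pat_vals <- rnorm(a)
  tab <- data.frame(patient_id = rep(sprintf("p%02d", 1:a), b),
                    observer_id = rep(sprintf("o%d", 1:b), each = a),
                    value = rep(pat_vals, b))  # identical across observers
  est <- icc_point(tab)
  expect_equal(est$icc, 0)
  expect_equal(est$sigma2_observer, 0)
  expect_false(est$degenerate)
})

test_that("the ICC is the observer share of the total variance", {
  set.seed(77)
  comp <- icc_point(sim_arm_table(12, 3, 0.8, 0.1, 0.1))
  manual <- comp$sigma2_observer /
    (comp$sigma2_observer + comp$sigma2_patient + comp$sigma2_systematic)
  expect_equal(comp$icc, manual)
  expect_gte(comp$icc, 0); expect_lte(comp$icc, 1)
})

test_that("simulated tables recover a true ICC of 0.22 on average", {
  # with 3 observers the observer stratum has 2 df whatever the patient count,
  # so single estimates scatter widely; the mean over replicates is the
  # meaningful recovery check
  tot <- 6e-3
  s2o <- 0.22 * tot; rest <- tot - s2o
  set.seed(88)
  est <- replicate(200, icc_point(sim_arm_table(500, 3, 0.55 * rest, s2o,
                                                0.45 * rest))$icc)
  expect_lt(abs(mean(est) - 0.22), 0.03)
})

test_that("constant data is flagged degenerate with ICC 0", {
  tab <- data.frame(patient_id = rep(c("a", "b"), 2),
                    observer_id = rep(c("o1", "o2"), each = 2), value = 1)
  est <- icc_point(tab)
  expect_equal(est$icc, 0)
  expect_true(est$degenerate)
})

test_that("the unbalanced REML fallback agrees with the closed form near balance", {
  set.seed(9)
  tab <- sim_arm_table(15, 3, 0.5, 0.1, 0.2)
  bal <- icc_point(tab)
  # force the REML path by duplicating-then-dropping nothing: drop one row
  unb <- icc_point(tab[-1, ])
  expect_lt(abs(bal$icc - unb$icc), 0.05)
  # and on balanced data the REML engine itself matches the closed form
  f <- autosegeval:::reml_crossed(tab$value, NULL, tab$patient_id, tab$observer_id)
  expect_equal(f$sigma2_observer, bal$sigma2_observer, tolerance = 1e-6)
  expect_equal(f$sigma2_patient, bal$sigma2_patient, tolerance = 1e-6)
  expect_equal(f$sigma2_residual, bal$sigma2_systematic, tolerance = 1e-6)
})

test_that("bootstrap replicates are deterministic, in range, and honour degeneracy", {
  set.seed(12)
  tab <- sim_arm_table(10, 3, 0.5, 0.1, 0.2)
  b1 <- stratified_bootstrap_icc(tab, B = 100, seed = 4)
  b2 <- stratified_bootstrap_icc(tab, B = 100, seed = 4)
  expect_identical(b1, b2)
  expect_true(all(b1 >= 0 & b1 <= 1))

  const <- data.frame(patient_id = rep(sprintf("p%d", 1:5), 2),
                      observer_id = rep(c("o1", "o2"), each = 5), value = 3)
  bc <- stratified_bootstrap_icc(const, B = 50, seed = 1)
  expect_true(all(bc == 0))
  expect_equal(attr(bc, "n_degenerate"), 50L)
  expect_equal(unname(diff(quantile(bc, c(0.025, 0.975)))), 0)
})

test_that("the bootstrap mean approaches the point estimate for many patients", {
  set.seed(31)
  tab <- sim_arm_table(1500, 3, 3e-3, 6e-4, 2.5e-3)
  pt <- icc_point(tab)
  bt <- stratified_bootstrap_icc(tab, B = 300, seed = 6)
  expect_lt(abs(mean(bt) - pt$icc), 0.01)
})

test_that("compare_icc reproduces the closed-form Welch test", {
  set.seed(14)
  x <- rnorm(400, 0.10, 0.03); y <- rnorm(400, 0.13, 0.05)
  cmp <- compare_icc(boot_hp = x, boot_conv = y)
  oracle <- welch_oracle(y, x)  # conventional minus high-performance
  expect_equal(cmp$welch_t, oracle$t, tolerance = 1e-9)
  expect_equal(cmp$welch_df, oracle$df, tolerance = 1e-9)
  expect_equal(cmp$p_value, oracle$p, tolerance = 1e-9)
  expect_equal(cmp$delta_ci,
               unname(quantile(y - x, c(0.025, 0.975), type = 7)),
               tolerance = 1e-12)

  same <- rnorm(100, 0.1, 0.01)
  cmp2 <- compare_icc(same, same)
  expect_equal(cmp2$welch_t, 0)
  expect_equal(cmp2$p_value, 1)
  expect_equal(cmp2$delta_ci, c(0, 0))

  cmp3 <- compare_icc(rep(0.1, 50), rep(0.1, 50))
  expect_true(cmp3$degenerate)
  expect_equal(cmp3$p_value, 1)
})

test_that("icc_point rejects malformed tables", {
  tab <- sim_arm_table(4, 2, 1, 1, 1)
  tab2 <- rbind(tab, tab[1, ])
  expect_error(icc_point(tab2), "more than one observation")
  tab$imaging_system <- rep(c("a", "b"), length.out = nrow(tab))
  expect_error(icc_point(tab), "single imaging-system")
})
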