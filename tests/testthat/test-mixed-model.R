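test_that("under balance the arm coefficient is the arm-mean difference", {
  for (s in 1:5) {
    d <- generate_metric_table(0.85, -0.02, 3e-3, 4e-4, 2.5e-3, seed = 200 + s)
    f <- fit_crossed_model(d, response = "value", reference = "high_performance")
    diff <- mean(d$value[d$x == 1]) - mean(d$value[d$x == 0])
    expect_equal(f$beta1, diff, tolerance = 1e-9)
  }
})

test_that("REML components equal the expected-mean-squares closed form under balance", {
  for (s in 1:5) {
    d <- generate_metric_table(0.85, -0.02, 0.02, 0.01, 0.01, seed = 300 + s)
    f <- fit_crossed_model(d, response = "value", reference = "high_performance")
    mo <- mom_oracle(d)
    expect_equal(f$sigma2_patient, unname(mo["patient"]), tolerance = 1e-6)
    expect_equal(f$sigma2_observer, unname(mo["observer"]), tolerance = 1e-6)
    expect_equal(f$sigma2_residual, unname(mo["residual"]), tolerance = 1e-6)
  }
})

test_that("with both random components truncated the fit is ordinary two-group regression", {
  # seed chosen so both method-of-moments estimates are negative (truncation path)
  d <- generate_metric_table(0.5, 0.1, 0, 0, 0.04, n_patients = 8, seed = 1)
  f <- fit_crossed_model(d, response = "value", reference = "high_performance")
  expect_equal(f$sigma2_patient, 0)
  expect_equal(f$sigma2_observer, 0)
  ols <- summary(stats::lm(value ~ x, data = d))$coefficients
  expect_equal(f$beta1, unname(ols[2, 1]), tolerance = 1e-9)
  expect_equal(f$se_beta1, unname(ols[2, 2]), tolerance = 1e-9)
})

test_that("fit matches lmerTest's REML and Satterthwaite inference", {
  skip_if_not_installed("lmerTest")
  for (s in c(4, 17)) {
    d <- generate_metric_table(0.85, -0.02, 3e-3, 4e-4, 2.5e-3, seed = s)
    f <- fit_crossed_model(d, response = "value", reference = "high_performance")
    lf <- lmerTest::lmer(value ~ x + (1 | patient_id) + (1 | observer_id),
                         data = d)
    co <- summary(lf)$coefficients
    expect_equal(f$beta1, unname(co[2, 1]), tolerance = 1e-7)
    expect_equal(f$se_beta1, unname(co[2, 2]), tolerance = 1e-5)
    expect_equal(f$df, unname(co[2, 3]), tolerance = 1e-2)
    expect_equal(f$p_value, unname(co[2, 5]), tolerance = 1e-4)
    vc <- as.data.frame(lme4::VarCorr(lf))
    expect_equal(f$sigma2_residual,
                 vc$vcov[vc$grp == "Residual"], tolerance = 1e-6)
  }
})

test_that("the REML criterion at the optimum dominates the ANOVA starting point", {
  for (s in 1:3) {
    d <- generate_metric_table(0.85, -0.02, 3e-3, 4e-4, 2.5e-3, seed = 400 + s)
    f <- fit_crossed_model(d, response = "value", reference = "high_performance")
    mo <- pmax(mom_oracle(d), 1e-8)
    ll_start <- -0.5 * autosegeval:::reml_dev_sigma(f, unname(mo[c("patient", "observer", "residual")]))
    expect_gte(f$reml_loglik + 1e-8, ll_start)
  }
})

test_that("exactly symmetric arms give t = 0 and p = 1", {
  base <- expand.grid(patient_id = sprintf("p%02d", 1:6),
                      observer_id = sprintf("o%d", 1:3),
                      stringsAsFactors = FALSE)
  set.seed(8)
  base$cell <- rnorm(nrow(base))
  d <- rbind(transform(base, imaging_system = "high_performance", value = cell),
             transform(base, imaging_system = "conventional", value = cell))
  f <- fit_crossed_model(d, response = "value", reference = "conventional")
  expect_equal(f$beta1, 0, tolerance = 1e-12)
  tst <- test_fixed_effect(f)
  expect_equal(tst$t_statistic, 0, tolerance = 1e-9)
  expect_equal(tst$p_value, 1, tolerance = 1e-9)
})

test_that("sign convention follows the reference-arm choice", {
  d <- generate_metric_table(5, 1.2, 0.01, 0.01, 0.05, seed = 31)
  f_conv_ref <- fit_crossed_model(d, response = "value", reference = "conventional")
  f_hp_ref <- fit_crossed_model(d, response = "value", reference = "high_performance")
  expect_equal(f_conv_ref$beta1, -f_hp_ref$beta1, tolerance = 1e-9)
  expect_gt(f_hp_ref$beta1, 0)  # conventional minus high-performance, beta1 = +1.2
})

test_that("degenerate and malformed tables fail loudly", {
  d <- generate_metric_table(1, 0, 0, 0, 0, n_patients = 4, seed = 1)
  f <- fit_crossed_model(d, response = "value")
  expect_true(f$degenerate)
  tst <- test_fixed_effect(f)
  expect_true(tst$degenerate)
  expect_equal(tst$p_value, 1)  # beta1 = 0 exactly

  d2 <- generate_metric_table(1, 0, 0, 0, 0.1, n_patients = 4, seed = 1)
  expect_error(fit_crossed_model(d2[d2$x == 0, ], response = "value"),
               "both imaging systems")
  d3 <- d2[d2$observer_id == "obs1", ]
  expect_error(fit_crossed_model(d3, response = "value"), "2 observers")
})
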