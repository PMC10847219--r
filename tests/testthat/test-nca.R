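test_that("NCA matches the analytic one-compartment oracle", {
  grid <- list(c(1, 0.1), c(2, 0.2), c(0.5, 0.05), c(1.5, 0.07))
  for (p in grid) {
    ka <- p[1]; ke <- p[2]
    prof <- one_compartment_profile(ka, ke)
    nca <- run_nca(prof)
    expect_lt(abs(nca$auc_0_inf_ng_h_ml - one_compartment_auc_inf(ka, ke)) /
                one_compartment_auc_inf(ka, ke), 0.005)
    expect_lt(abs(nca$lambda_z_per_h - ke) / ke, 0.01)
    # Tmax oracle: log(ka/ke)/(ka-ke), within one grid step
    expect_lt(abs(nca$tmax_h - log(ka / ke) / (ka - ke)), 0.051)
    expect_gte(nca$auc_0_inf_ng_h_ml, nca$auc_0_t_ng_h_ml)
    expect_true(nca$extrapolated_fraction >= 0 &&
                  nca$extrapolated_fraction < 1)
  }
})

test_that("degenerate profiles are rejected", {
  expect_error(run_nca(list(times = 1, concentrations = 5)), "3 points")
  expect_error(run_nca(list(times = c(1, 1, 2), concentrations = c(1, 2, 3))),
               "strictly increasing")
})

test_that("NCA is linear: scaling the profile scales Cmax and AUC only", {
  prof <- one_compartment_profile(1, 0.1)
  prof2 <- prof
  prof2$concentrations <- 2 * prof$concentrations
  a <- run_nca(prof)
  b <- run_nca(prof2)
  expect_equal(b$cmax_ng_ml, 2 * a$cmax_ng_ml)
  expect_equal(b$auc_0_t_ng_h_ml, 2 * a$auc_0_t_ng_h_ml)
  expect_equal(b$auc_0_inf_ng_h_ml, 2 * a$auc_0_inf_ng_h_ml)
  expect_equal(b$lambda_z_per_h, a$lambda_z_per_h)
})

test_that("a non-estimable terminal phase flags AUC_0-inf missing", {
  t <- 1:12
  rising <- list(times = t, concentrations = t^1.5)
  expect_warning(nca <- run_nca(rising), "not estimable")
  expect_true(is.na(nca$auc_0_inf_ng_h_ml))
  expect_true(is.na(nca$lambda_z_per_h))
  expect_gt(nca$auc_0_t_ng_h_ml, 0)
})

test_that("average fold error is the geometric mean fold deviation", {
  obs <- c(10, 20, 40, 80)
  expect_equal(average_fold_error(obs, obs), 1)
  expect_equal(average_fold_error(2 * obs, obs), 2)
  expect_equal(average_fold_error(c(2, 0.5), c(1, 1)), 1)
  expect_message(
    afe <- average_fold_error(c(1, 2, 0), c(1, 2, 3)), "excluding 1")
  expect_equal(afe, 1)
  expect_error(average_fold_error(1:3, 1:4), "paired")
})

test_that("AFE against 10% proportional noise is unbiased for n >= 50", {
  set.seed(11)
  pred <- one_compartment_profile(1, 0.1, dt = 1)$concentrations
  pred <- pred[seq_len(55)]
  sdlog <- sqrt(log(1 + 0.1^2))
  obs <- pred * exp(rnorm(length(pred), -sdlog^2 / 2, sdlog))
  afe <- average_fold_error(pred, obs)
  expect_gt(afe, 0.9)
  expect_lt(afe, 1.1)
})

test_that("fold changes reproduce the published elderly exposure ratios", {
  fc <- fold_change(list(auc_0_inf_ng_h_ml = 2933, cmax_ng_ml = 254),
                    list(auc_0_inf_ng_h_ml = 2062, cmax_ng_ml = 189.5))
  expect_equal(round_half_up(fc$auc_ratio, 2), 1.42)
  fc2 <- fold_change(4151, 2062)
  expect_equal(round_half_up(fc2$auc_ratio, 2), 2.01)
  same <- fold_change(1234, 1234)
  expect_equal(same$auc_ratio, 1)
  expect_error(fold_change(100, 0), "positive")
})

test_that("dose fractions follow exposure matching with half-up rounding", {
  expect_equal(recommend_dose_fraction(2062, 2933), 70L)
  expect_equal(recommend_dose_fraction(2933, 5059), 58L)
  expect_equal(recommend_dose_fraction(500, 500), 100L)
  expect_equal(recommend_dose_fraction_from_ratio(1.87), 53L)
  expect_equal(recommend_dose_fraction_from_ratio(1.86), 54L)
  expect_equal(recommend_dose_fraction_from_ratio(1), 100L)
  expect_error(recommend_dose_fraction_from_ratio(0), "positive")
})

test_that("the two dose-fraction routes agree exactly", {
  set.seed(5)
  ref <- runif(25, 500, 5000)
  spc <- runif(25, 500, 9000)
  for (i in seq_along(ref)) {
    expect_identical(recommend_dose_fraction(ref[i], spc[i]),
                     recommend_dose_fraction_from_ratio(spc[i] / ref[i]))
  }
})

test_that("interval NCA computes AUC_tau over the requested window", {
  prof <- one_compartment_profile(1, 0.1, t_end = 48)
  full <- run_nca(prof)
  tau <- run_nca(prof, interval = c(12, 24))
  expect_lt(tau$auc_tau_ng_h_ml, full$auc_0_t_ng_h_ml)
  expect_gte(tau$tmax_h, 12)
  expect_error(run_nca(prof, interval = c(24, 12)))
})

test_that("the dose-recommendation table reproduces the published numbers", {
  tab <- dose_recommendation_table()
  expect_equal(
    tab$auc_ratio_vs_adult,
    c(1.00, 1.42, 1.61, 2.01, 1.59, 1.48, 1.75, 2.45))
  expect_equal(
    tab$dose_fraction_percent,
    c(100L, 70L, 88L, 71L, 89L, 96L, 81L, 58L))
})
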