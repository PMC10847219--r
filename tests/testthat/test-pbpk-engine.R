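# Engine tests run on a shortened grid (0-72 h, 0.1 h steps) to keep the
# suite quick; the acceptance tests exercise the full default grid.
eng_grid <- seq(0, 72, by = 0.1)

test_that("a zero dose yields an identically zero profile", {
  prof <- simulate_individual(ref_adult(), apix(), dosing_regimen(0),
                              t_grid = eng_grid)
  expect_true(all(prof$concentrations == 0))
})

test_that("the model is dose-linear and keeps a stable terminal slope", {
  phys <- ref_adult()
  cmp <- apix()
  p10 <- simulate_individual(phys, cmp, dosing_regimen(10), t_grid = eng_grid)
  p25 <- simulate_individual(phys, cmp, dosing_regimen(25), t_grid = eng_grid)
  nz <- p10$concentrations > 0
  expect_equal(p25$concentrations[nz] / p10$concentrations[nz],
               rep(2.5, sum(nz)), tolerance = 1e-6)

  l10 <- suppressWarnings(run_nca(p10))$lambda_z_per_h
  l25 <- suppressWarnings(run_nca(p25))$lambda_z_per_h
  expect_equal(l10, l25, tolerance = 1e-3)
})

test_that("mass is conserved at every output time", {
  prof <- simulate_individual(ref_adult(), apix(), dosing_regimen(10),
                              t_grid = eng_grid, full_output = TRUE)
  mb <- attr(prof, "mass_balance")
  expect_true(all(abs(mb - 1) < 1e-3))
})

test_that("multiple dosing obeys superposition of shifted single doses", {
  phys <- ref_adult()
  cmp <- apix()
  tg <- seq(0, 48, by = 0.1)
  single <- simulate_individual(phys, cmp, dosing_regimen(10), t_grid = tg)
  double <- simulate_individual(phys, cmp,
                                dosing_regimen(10, n_doses = 2,
                                               interval_h = 12),
                                t_grid = tg)
  shift <- approx(single$times + 12, single$concentrations, xout = tg,
                  yleft = 0)$y
  expected <- single$concentrations + shift
  sel <- tg > 12.5 # away from the dose discontinuity
  expect_equal(double$concentrations[sel], expected[sel], tolerance = 2e-3)
})

test_that("population summaries collapse correctly for identical individuals", {
  pop <- rep(list(ref_adult()), 3)
  res <- simulate_population(pop, apix(), dosing_regimen(10),
                             t_grid = seq(0, 24, 0.5))
  expect_equal(res$p5_profile$concentrations, res$mean_profile$concentrations)
  expect_equal(res$p95_profile$concentrations, res$mean_profile$concentrations)
  expect_equal(res$mean_profile$concentrations,
               res$individual_profiles[[1]]$concentrations)
})

test_that("population simulation is deterministic and spreads with variability", {
  base <- ref_adult()
  pop <- sample_population(population_spec(8, seed = 3), base)
  tg <- seq(0, 24, 0.5)
  r1 <- simulate_population(pop, apix(), dosing_regimen(10), t_grid = tg)
  r2 <- simulate_population(pop, apix(), dosing_regimen(10), t_grid = tg)
  expect_identical(r1$mean_profile$concentrations,
                   r2$mean_profile$concentrations)
  i_cmax <- which.max(r1$mean_profile$concentrations)
  expect_gt(r1$p95_profile$concentrations[i_cmax],
            r1$p5_profile$concentrations[i_cmax])
  # pointwise mean equals the arithmetic mean of the individuals
  cmat <- sapply(r1$individual_profiles, `[[`, "concentrations")
  expect_equal(r1$mean_profile$concentrations, rowMeans(cmat))
})

test_that("calibration recovers a known absorption area from engine output", {
  phys <- ref_adult()
  truth <- apix()
  target <- simulate_individual(phys, truth, dosing_regimen(10),
                                t_grid = c(0, 0.5, 1, 2, 3, 4, 6, 9, 12,
                                           24, 48, 72))
  target$times <- target$times[-1]
  target$concentrations <- target$concentrations[-1]
  start <- apixaban_parameters(
    intestinal_area_cm2 = truth$intestinal_area_cm2 * 3)
  fit <- calibrate_absorption(start, phys, target, dosing_regimen(10))
  expect_lt(abs(fit$effective_area_cm2 - truth$intestinal_area_cm2) /
              truth$intestinal_area_cm2, 0.05)
  expect_lt(fit$objective, fit$objective_start)
})

test_that("calibration is invariant to dose under linear kinetics", {
  phys <- ref_adult()
  truth <- apix()
  tpts <- c(0.5, 1, 2, 4, 8, 12, 24, 48)
  mk_target <- function(dose) {
    pr <- simulate_individual(phys, truth, dosing_regimen(dose),
                              t_grid = c(0, tpts))
    concentration_time_profile(tpts, pr$concentrations[-1],
                               dosing_regimen(dose))
  }
  start <- apixaban_parameters(
    intestinal_area_cm2 = truth$intestinal_area_cm2 * 2)
  f10 <- calibrate_absorption(start, phys, mk_target(10))
  f20 <- calibrate_absorption(start, phys, mk_target(20))
  expect_equal(f10$effective_area_cm2, f20$effective_area_cm2,
               tolerance = 1e-3)
})

test_that("a flat zero prediction aborts calibration with a clear error", {
  phys <- ref_adult()
  dead <- apixaban_parameters(peff_cm_min = 1e-30)
  target <- simulate_individual(phys, apix(), dosing_regimen(10),
                                t_grid = c(0, 1, 2, 4, 8, 12))
  target$times <- target$times[-1]
  target$concentrations <- target$concentrations[-1]
  expect_error(
    calibrate_absorption(dead, phys, target, dosing_regimen(10),
                         area_bounds = c(1e-2, 1e2)),
    "flat")
})

test_that("the time grid must cover the dosing regimen", {
  expect_error(
    simulate_individual(ref_adult(), apix(),
                        dosing_regimen(10, n_doses = 4, interval_h = 12),
                        t_grid = seq(0, 24, 0.5)),
    "cover")
})
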