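test_that("renal clearance scales linearly with creatinine clearance", {
  expect_equal(scale_renal_clearance(1.2053, 120, 120), 1.2053)
  expect_equal(scale_renal_clearance(1.2053, 120, 40), 1.2053 * 40 / 120)
  expect_equal(round(scale_renal_clearance(1.2053, 120, 40), 4), 0.4018)
  expect_equal(scale_renal_clearance(5, 120, 0), 0)
  expect_error(scale_renal_clearance(1, 0, 40), "positive")
  # linearity: doubling CLcr doubles CL_R; additivity in CLcr
  clcr <- c(15, 40, 65, 120)
  expect_equal(scale_renal_clearance(1.7, 120, 2 * clcr),
               2 * scale_renal_clearance(1.7, 120, clcr))
  expect_equal(scale_renal_clearance(1.7, 120, 40 + 25),
               scale_renal_clearance(1.7, 120, 40) +
                 scale_renal_clearance(1.7, 120, 25))
})

test_that("renal impairment scales CL_R through GFR and touches nothing else", {
  phys <- ref_adult()
  cmp <- apix()
  cl_ref <- renal_plasma_clearance(cmp, phys)

  norm <- apply_renal_impairment(phys, cmp, renal_impairment_spec("normal"))
  expect_equal(renal_plasma_clearance(norm$cmp, norm$phys), cl_ref)

  sev <- apply_renal_impairment(phys, cmp, renal_impairment_spec("severe"))
  expect_equal(renal_plasma_clearance(sev$cmp, sev$phys), cl_ref * 15 / 120)
  mild <- apply_renal_impairment(phys, cmp, renal_impairment_spec("mild"))
  expect_equal(renal_plasma_clearance(mild$cmp, mild$phys), cl_ref * 65 / 120)

  expect_equal(sev$phys$organ_volumes_l, phys$organ_volumes_l)
  expect_equal(sev$phys$organ_blood_flows_l_min, phys$organ_blood_flows_l_min)
  expect_equal(sev$phys$hematocrit, phys$hematocrit)
  expect_equal(sev$cmp$fu, cmp$fu)
  expect_equal(sev$cmp$cl_h_l_h, cmp$cl_h_l_h)
})

test_that("Child-Pugh overlays reproduce every published cell exactly", {
  phys <- ref_adult()
  cmp <- apix()
  cells <- list(
    `CP-A` = c(hep = 0.45, ren = 0.94, oth = 1.75, liv = 1.32, hct = 0.39,
               alb = 0.81, agp = 0.60),
    `CP-B` = c(hep = 0.79, ren = 0.69, oth = 2.25, liv = 1.05, hct = 0.37,
               alb = 0.68, agp = 0.56),
    `CP-C` = c(hep = 0.15, ren = 0.51, oth = 2.75, liv = 0.53, hct = 0.35,
               alb = 0.50, agp = 0.30)
  )
  for (cls in names(cells)) {
    want <- cells[[cls]]
    out <- apply_hepatic_impairment(phys, cmp,
                                    hepatic_impairment_modifiers(cls))
    q <- out$phys$organ_blood_flows_l_min
    expect_identical(q[["liver"]], want[["hep"]])
    expect_identical(q[["kidney"]], want[["ren"]])
    expect_identical(out$phys$organ_volumes_l[["liver"]], want[["liv"]])
    expect_identical(out$phys$hematocrit, want[["hct"]])
    expect_identical(out$phys$albumin_ontogeny, want[["alb"]])
    expect_identical(out$phys$agp_ontogeny, want[["agp"]])
    # all non-hepatic, non-renal flows carry the class multiplier exactly
    rest_organs <- setdiff(names(phys$organ_blood_flows_l_min),
                           c("lung", "liver", "kidney"))
    expect_identical(q[rest_organs],
                     phys$organ_blood_flows_l_min[rest_organs] * want[["oth"]])
    # cardiac output re-closed
    expect_equal(q[["lung"]], sum(q[setdiff(names(q), "lung")]))
    # unbound fraction rescaled through the ontogeny factor
    expect_equal(out$cmp$fu, scale_fu_for_binding(cmp, want[["alb"]]))
  }
})

test_that("hepatic overlay scales CL_H with functional liver volume by default", {
  phys <- ref_adult()
  cmp <- apix()
  cpc <- apply_hepatic_impairment(phys, cmp, hepatic_impairment_modifiers("CP-C"))
  expect_equal(cpc$cmp$cl_h_l_h, 2.4 * 0.53 / 2.44)
  fixed <- apply_hepatic_impairment(phys, cmp,
                                    hepatic_impairment_modifiers("CP-C"),
                                    cl_h_scaling = "none")
  expect_equal(fixed$cmp$cl_h_l_h, 2.4)
  custom <- apply_hepatic_impairment(
    phys, cmp, hepatic_impairment_modifiers("CP-C", cl_h_multiplier = 0.25))
  expect_equal(custom$cmp$cl_h_l_h, 0.6)
})

test_that("the identity modifier set leaves the physiology unchanged", {
  phys <- ref_adult()
  cmp <- apix()
  out <- apply_hepatic_impairment(phys, cmp,
                                  hepatic_impairment_modifiers("healthy"))
  for (f in c("organ_volumes_l", "organ_blood_flows_l_min", "hematocrit",
              "albumin_ontogeny", "agp_ontogeny", "gfr_ml_min")) {
    expect_equal(out$phys[[f]], phys[[f]], info = f)
  }
  expect_equal(out$cmp$fu, cmp$fu)
  expect_equal(out$cmp$cl_h_l_h, cmp$cl_h_l_h)
})

test_that("impairment overlays refuse a non-healthy baseline", {
  phys <- ref_adult()
  cmp <- apix()
  once <- apply_hepatic_impairment(phys, cmp,
                                   hepatic_impairment_modifiers("CP-A"))
  expect_error(
    apply_hepatic_impairment(once$phys, once$cmp,
                             hepatic_impairment_modifiers("CP-B")),
    "healthy baseline")
})

test_that("elderly scaling is the identity at the baseline age", {
  phys <- chn_adult()
  same <- scale_to_elderly(phys, 30)
  expect_equal(same, phys)
  expect_warning(scale_to_elderly(phys, 25), "below the baseline age")
})

test_that("elderly scaling is monotone in the published directions", {
  phys <- chn_adult()
  ages <- c(60, 70, 81)
  scaled <- lapply(ages, function(a) scale_to_elderly(phys, a))
  gfr <- vapply(scaled, `[[`, numeric(1), "gfr_ml_min")
  hep <- vapply(scaled, function(p)
    p$organ_blood_flows_l_min[["liver"]], numeric(1))
  mus <- vapply(scaled, function(p) p$organ_volumes_l[["muscle"]], numeric(1))
  adi_frac <- vapply(scaled, function(p)
    p$organ_volumes_l[["adipose"]] / sum(p$organ_volumes_l), numeric(1))
  expect_lt(gfr[2], 120)
  expect_true(all(diff(gfr) < 0))
  expect_true(all(diff(hep) < 0))
  expect_true(all(diff(mus) < 0))
  expect_true(all(diff(adi_frac) > 0))
  for (p in scaled) expect_silent(validate_physiology(p))
})

test_that("renal and elderly scalings commute", {
  phys <- chn_adult()
  cmp <- apix()
  spec <- renal_impairment_spec("moderate")
  a <- scale_to_elderly(apply_renal_impairment(phys, cmp, spec)$phys, 70)
  b <- apply_renal_impairment(scale_to_elderly(phys, 70), cmp, spec)$phys
  expect_equal(a$gfr_ml_min, b$gfr_ml_min)
  expect_equal(a$organ_volumes_l, b$organ_volumes_l)
  expect_equal(a$organ_blood_flows_l_min, b$organ_blood_flows_l_min)
})
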