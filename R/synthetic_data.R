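# Synthetic "observed" clinical datasets. The published clinical profiles
# being emulated were digitized from figures and are not reproduced here;
# instead, every study design (doses, impairment groups, sparse sampling
# schedules, group sizes) is re-created by simulating virtual subjects with
# log-normally perturbed physiology and adding proportional log-normal
# residual noise, so every pipeline stage is testable without downloads.

# Group designs: single doses 5/10/25/50 mg; multiple doses 2.5/5/10/25 mg
# twice daily for 7 days; renal groups at CLcr 120/65/40/15 mL/min (n = 8,
# 10, 7, 7); hepatic groups healthy/CP-A/CP-B/CP-C (n = 16, 8, 8, 8);
# elderly 60-81 y, 50% women (n = 6). Sparse sampling, 8-14 points.
.study_designs <- function() {
  t_single <- c(0.5, 1, 2, 3, 4, 6, 9, 12, 24, 48, 72)
  t_multi <- c(0.5, 1, 2, 4, 8, 12, 144.5, 145, 146, 148, 150, 152, 156, 168)
  list(
    healthy_single = list(doses = c(5, 10, 25, 50), n = 6,
                          regimen = function(d) dosing_regimen(d),
                          times = t_single, window_h = 168),
    healthy_multi = list(doses = c(2.5, 5, 10, 25), n = 6,
                         regimen = function(d)
                           dosing_regimen(d, n_doses = 14, interval_h = 12),
                         times = t_multi, window_h = 264),
    renal = list(arms = c(normal = 120, mild = 65, moderate = 40, severe = 15),
                 n = c(8, 10, 7, 7), dose = 10,
                 regimen = function(d) dosing_regimen(d),
                 times = t_single, window_h = 168),
    hepatic = list(arms = c("healthy", "CP-A", "CP-B", "CP-C"),
                   n = c(16, 8, 8, 8), dose = 10,
                   regimen = function(d) dosing_regimen(d),
                   times = t_single, window_h = 168),
    elderly = list(n = 6, dose = 10, age_range = c(60, 81),
                   proportion_female = 0.5,
                   regimen = function(d) dosing_regimen(d),
                   times = t_single, window_h = 168)
  )
}

#' Specify a synthetic observed-data study
#'
#' @param group `"healthy_single"`, `"healthy_multi"`, `"renal"`,
#'   `"hepatic"` or `"elderly"`; fixes the dosing arms, group sizes and
#'   default sparse sampling schedule of the emulated study.
#' @param n_subjects per-arm group size override (single number, recycled).
#' @param sampling_times override of the sparse sampling times (hours),
#'   8 to 14 points within the study window.
#' @param noise_cv proportional residual noise CV (fraction, default 0.10).
#' @param parameter_perturbation_cv log-normal CV on organ volumes, flows
#'   and GFR across subjects (default 0.16).
#' @param clearance_cv log-normal CV on hepatic clearance and permeability
#'   across subjects (default 0.30).
#' @param seed integer seed.
#' @return an object of class `synthetic_study_spec`.
#' @export
synthetic_study_spec <- function(group = c("healthy_single", "healthy_multi",
                                           "renal", "hepatic", "elderly"),
                                 n_subjects = NULL, sampling_times = NULL,
                                 noise_cv = 0.10,
                                 parameter_perturbation_cv = 0.16,
                                 clearance_cv = 0.30, seed = 1L) {
  group <- match.arg(group)
  if (noise_cv < 0) stop("'noise_cv' must be >= 0")
  if (parameter_perturbation_cv < 0 || clearance_cv < 0) {
    stop("perturbation CVs must be >= 0")
  }
  design <- .study_designs()[[group]]
  if (!is.null(n_subjects)) design$n <- rep(n_subjects, length(design$n))
  if (!is.null(sampling_times)) {
    if (length(sampling_times) < 3) stop("too few sampling times")
    if (max(sampling_times) > design$window_h) {
      stop("sampling times extend beyond the study simulation window (",
           design$window_h, " h)")
    }
    design$times <- sort(sampling_times)
  }
  structure(list(group = group, design = design, noise_cv = noise_cv,
                 parameter_perturbation_cv = parameter_perturbation_cv,
                 clearance_cv = clearance_cv, seed = as.integer(seed)),
            class = "synthetic_study_spec")
}

.perturbed_compounds <- function(cmp, n, cv) {
  lapply(seq_len(n), function(i) {
    cm <- cmp
    cm$cl_h_l_h <- cm$cl_h_l_h * .lognormal_factor(1, cv)
    cm$peff_cm_min <- cm$peff_cm_min * .lognormal_factor(1, cv)
    cm
  })
}

.simulate_arm <- function(base_phys, base_cmp, spec, regimen, arm_label,
                          n, pop_spec_extra = list()) {
  ps <- do.call(population_spec, c(list(
    n = n, seed = spec$seed + abs(sum(utf8ToInt(arm_label))),
    variability_cv = list(organ_volumes = spec$parameter_perturbation_cv,
                          organ_blood_flows = spec$parameter_perturbation_cv,
                          gfr = spec$parameter_perturbation_cv)),
    pop_spec_extra))
  pop <- sample_population(ps, base_phys)
  cmps <- .perturbed_compounds(base_cmp, n, spec$clearance_cv)

  times <- spec$design$times
  t_grid <- sort(unique(c(0, times)))
  sim <- simulate_population(pop, cmps, regimen, t_grid = t_grid)
  cmat <- vapply(sim$individual_profiles, function(p)
    p$concentrations[match(times, p$times)], numeric(length(times)))
  if (spec$noise_cv > 0) {
    noise <- matrix(.lognormal_factor(length(cmat), spec$noise_cv),
                    nrow = nrow(cmat))
    cmat <- cmat * noise
  }
  data.frame(
    group = spec$group, arm = arm_label, time_h = times,
    conc_ng_per_ml = rowMeans(cmat), sd_ng_per_ml = apply(cmat, 1, stats::sd),
    n_subjects = n, stringsAsFactors = FALSE
  )
}

#' Generate synthetic observed mean concentration profiles
#'
#' Emulates the digitized group-mean clinical profiles: for each arm of the
#' study design, samples virtual subjects around the preset baseline
#' (European adult for the healthy/renal/hepatic studies, Chinese adult
#' aged into the elderly range for the elderly study), applies the arm's
#' impairment overlay, simulates each subject, samples the sparse
#' schedule, applies mean-preserving proportional log-normal residual
#' noise, and returns the per-arm mean (+/- sd) concentrations. Identical
#' seeds give identical datasets; the caller's random state is restored.
#'
#' @param spec a [synthetic_study_spec].
#' @param cmp compound parameters (default the packaged apixaban set).
#' @return data.frame with columns `group`, `arm`, `time_h`,
#'   `conc_ng_per_ml`, `sd_ng_per_ml`, `n_subjects`.
#' @export
generate_observed_profiles <- function(spec, cmp = apixaban_parameters()) {
  stopifnot(inherits(spec, "synthetic_study_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(spec$seed)

  d <- spec$design
  out <- list()
  if (spec$group %in% c("healthy_single", "healthy_multi")) {
    base <- demographic_preset("european_adult")
    for (dose in d$doses) {
      out[[length(out) + 1]] <- .simulate_arm(
        base, cmp, spec, d$regimen(dose), paste0(dose, "mg"), d$n)
    }
  } else if (spec$group == "renal") {
    base <- demographic_preset("european_adult")
    for (i in seq_along(d$arms)) {
      ovl <- apply_renal_impairment(
        base, cmp, renal_impairment_spec(clcr_ml_min = d$arms[[i]]))
      out[[length(out) + 1]] <- .simulate_arm(
        ovl$phys, ovl$cmp, spec, d$regimen(d$dose), names(d$arms)[i], d$n[i])
    }
  } else if (spec$group == "hepatic") {
    base <- demographic_preset("european_adult")
    for (i in seq_along(d$arms)) {
      cls <- d$arms[[i]]
      if (cls == "healthy") {
        ph <- base; cm <- cmp
      } else {
        ovl <- apply_hepatic_impairment(base, cmp,
                                        hepatic_impairment_modifiers(cls))
        ph <- ovl$phys; cm <- ovl$cmp
      }
      out[[length(out) + 1]] <- .simulate_arm(
        ph, cm, spec, d$regimen(d$dose), cls, d$n[i])
    }
  } else { # elderly
    base <- demographic_preset("chinese_adult")
    out[[length(out) + 1]] <- .simulate_arm(
      base, cmp, spec, d$regimen(d$dose), "elderly", d$n,
      pop_spec_extra = list(age_range = d$age_range,
                            proportion_female = d$proportion_female))
  }
  do.call(rbind, out)
}

#' Parameter-recovery study for the calibration stage
#'
#' Acceptance harness for the middle-out calibration: generates a
#' synthetic healthy single-dose dataset from known "true" values of the
#' effective absorption area and the lumped hepatic clearance (subjects'
#' physiology perturbed, clearances held at truth, proportional residual
#' noise added), then re-calibrates both parameters against the group mean
#' profile starting from deliberately displaced values, and reports the
#' relative recovery errors.
#'
#' @param seed integer seed.
#' @param n_subjects group size (default 12).
#' @param noise_cv residual noise CV (default 0.10).
#' @param parameter_perturbation_cv between-subject physiology CV
#'   (default 0.16; set 0 for a noise-free self-consistency check).
#' @param true_area_cm2,true_cl_h_l_h the known truth (defaults: packaged
#'   apixaban values).
#' @param dose_mg single oral dose (default 10).
#' @return data.frame with one row per parameter: `parameter`, `true`,
#'   `recovered`, `rel_error`.
#' @export
parameter_recovery_study <- function(seed = 1L, n_subjects = 12,
                                     noise_cv = 0.10,
                                     parameter_perturbation_cv = 0.16,
                                     true_area_cm2 = NULL,
                                     true_cl_h_l_h = NULL, dose_mg = 10) {
  truth <- apixaban_parameters()
  if (!is.null(true_area_cm2)) truth$intestinal_area_cm2 <- true_area_cm2
  if (!is.null(true_cl_h_l_h)) truth$cl_h_l_h <- true_cl_h_l_h

  spec <- synthetic_study_spec(
    "healthy_single", n_subjects = n_subjects, noise_cv = noise_cv,
    parameter_perturbation_cv = parameter_perturbation_cv,
    clearance_cv = 0, seed = seed)
  spec$design$doses <- dose_mg
  obs <- generate_observed_profiles(spec, cmp = truth)
  regimen <- dosing_regimen(dose_mg)
  target <- concentration_time_profile(obs$time_h, obs$conc_ng_per_ml,
                                       regimen, "group_mean")

  start <- truth
  start$intestinal_area_cm2 <- truth$intestinal_area_cm2 * 2
  start$cl_h_l_h <- truth$cl_h_l_h * 0.5
  phys <- demographic_preset("european_adult")
  fit <- calibrate_absorption(start, phys, target, regimen, fit_clh = TRUE)

  data.frame(
    parameter = c("intestinal_area_cm2", "cl_h_l_h"),
    true = c(truth$intestinal_area_cm2, truth$cl_h_l_h),
    recovered = c(fit$effective_area_cm2, fit$cl_h_l_h),
    rel_error = c(
      abs(fit$effective_area_cm2 - truth$intestinal_area_cm2) /
        truth$intestinal_area_cm2,
      abs(fit$cl_h_l_h - truth$cl_h_l_h) / truth$cl_h_l_h),
    stringsAsFactors = FALSE
  )
}
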