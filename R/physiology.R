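# Reference-human physiology and virtual-population sampling.
#
# The body is represented by 18 compartments: 16 organs (including a "rest"
# compartment that absorbs unassigned mass and flow so that totals close)
# plus arterial and venous blood. Baseline organ volumes and blood flows are
# compiled from standard reference-human tables for a resting European adult
# male (30 y, 82 kg, 180 cm) and scaled allometrically to body weight
# (volumes linearly, flows with exponent 0.75). The healthy hepatic arterial
# flow (0.44 L/min), renal flow (1.35 L/min), liver volume (2.44 L) and
# hematocrit (0.47) are pinned to the published healthy column of the
# hepatic-impairment physiology table so that impairment overlays are
# internally consistent.

#' @keywords internal
PERFUSED_ORGANS <- c(
  "heart", "brain", "muscle", "adipose", "skin", "bone", "liver", "kidney",
  "spleen", "pancreas", "stomach", "small_intestine", "large_intestine",
  "gonads", "rest"
)

#' @keywords internal
SPLANCHNIC_ORGANS <- c(
  "spleen", "pancreas", "stomach", "small_intestine", "large_intestine"
)

#' @keywords internal
ALL_ORGANS <- c("lung", PERFUSED_ORGANS, "arterial_blood", "venous_blood")

# Reference tables at 82 kg. Volumes in L; flows in L/min. The liver flow is
# the hepatic *arterial* flow; portal inflow from the splanchnic organs is
# added by the simulation engine. "rest" volume is derived at build time so
# total body volume equals body_weight / 1.05 (mean tissue density kg/L).
.ref_body_weight_kg <- 82

.ref_volumes_l <- c(
  lung = 1.00, heart = 0.37, brain = 1.45, muscle = 30.0, adipose = 15.0,
  skin = 3.40, bone = 9.80, liver = 2.44, kidney = 0.34, spleen = 0.19,
  pancreas = 0.15, stomach = 0.17, small_intestine = 0.70,
  large_intestine = 0.40, gonads = 0.04,
  arterial_blood = 1.80, venous_blood = 3.70
)

.ref_flows_l_min <- c(
  heart = 0.26, brain = 0.78, muscle = 1.10, adipose = 0.33, skin = 0.33,
  bone = 0.33, liver = 0.44, kidney = 1.35, spleen = 0.077, pancreas = 0.065,
  stomach = 0.065, small_intestine = 0.65, large_intestine = 0.26,
  gonads = 0.003, rest = 0.46
)

#' Demographic presets
#'
#' Named anthropometric presets used throughout the analyses. The European
#' adult matches the reference individual of the model (30 y, 82 kg,
#' 180 cm). The Chinese adult preset (30 y, 63 kg, 168 cm) is a documented
#' implementer choice, since no Chinese anthropometrics are published for
#' the cohorts being emulated.
#'
#' @param preset one of `"european_adult"`, `"chinese_adult"`.
#' @return a [physiology_parameters] object.
#' @export
demographic_preset <- function(preset = c("european_adult", "chinese_adult")) {
  preset <- match.arg(preset)
  switch(preset,
    european_adult = build_reference_individual(30, "male", 82, 180),
    chinese_adult  = build_reference_individual(30, "male", 63, 168)
  )
}

#' Build the reference individual's physiology
#'
#' Constructs a complete [physiology_parameters] set for a healthy adult:
#' 18-compartment organ volumes and blood flows scaled to the requested
#' body size, hematocrit 0.47, glomerular filtration rate 120 mL/min, and
#' binding-protein ontogeny factors at their healthy value of 1.
#'
#' @param age years, in \[18, 100\].
#' @param sex `"male"` or `"female"`. Females carry a modestly larger
#'   adipose and smaller muscle fraction; the difference is absorbed by the
#'   "rest" compartment so total body volume is preserved.
#' @param body_weight kg, positive.
#' @param height cm, positive.
#' @return an object of class `physiology_parameters`: a list with
#'   demographics, `organ_volumes_l` (named over all 18 compartments),
#'   `organ_blood_flows_l_min` (perfused organs plus `lung`, whose flow is
#'   the cardiac output), `hematocrit`, `gfr_ml_min`, and the two ontogeny
#'   factors.
#' @export
build_reference_individual <- function(age = 30, sex = c("male", "female"),
                                       body_weight = 82, height = 180) {
  sex <- match.arg(sex)
  if (!is.numeric(age) || length(age) != 1 || age < 18 || age > 100) {
    stop("'age' must be a single number in [18, 100]")
  }
  if (!is.numeric(body_weight) || length(body_weight) != 1 || body_weight <= 0) {
    stop("'body_weight' must be a single positive number (kg)")
  }
  if (!is.numeric(height) || length(height) != 1 || height <= 0) {
    stop("'height' must be a single positive number (cm)")
  }

  wfrac <- body_weight / .ref_body_weight_kg
  vols <- .ref_volumes_l * wfrac
  flows <- .ref_flows_l_min * wfrac^0.75

  if (sex == "female") {
    vols["adipose"] <- vols["adipose"] * 1.30
    vols["muscle"] <- vols["muscle"] * 0.85
  }

  body_volume <- body_weight / 1.05
  rest_vol <- body_volume - sum(vols)
  if (rest_vol <= 0) {
    stop("demographics imply a non-positive 'rest' compartment volume; ",
         "check 'body_weight'")
  }
  vols <- c(vols, rest = unname(rest_vol))
  vols <- vols[ALL_ORGANS]

  cardiac_output <- sum(flows)
  flows <- c(lung = unname(cardiac_output), flows)

  phys <- structure(
    list(
      age = age,
      sex = sex,
      body_weight_kg = body_weight,
      height_cm = height,
      bmi_kg_m2 = body_weight / (height / 100)^2,
      hematocrit = if (sex == "male") 0.47 else 0.42,
      gfr_ml_min = 120,
      organ_volumes_l = vols,
      organ_blood_flows_l_min = flows,
      albumin_ontogeny = 1,
      agp_ontogeny = 1
    ),
    class = "physiology_parameters"
  )
  validate_physiology(phys)
  phys
}

#' Validate a physiology parameter set
#'
#' Checks the structural invariants: all volumes and flows strictly
#' positive, hematocrit in (0, 1), ontogeny factors in (0, 3\], BMI
#' consistent with weight and height, and flow balance (the sum of the
#' perfused-organ flows must equal the pulmonary flow, i.e. cardiac output,
#' to within 1e-6 relative).
#'
#' @param phys a `physiology_parameters` object.
#' @return `phys`, invisibly; errors describe the violated invariant.
#' @export
validate_physiology <- function(phys) {
  stopifnot(inherits(phys, "physiology_parameters"))
  v <- phys$organ_volumes_l
  q <- phys$organ_blood_flows_l_min
  if (!all(ALL_ORGANS %in% names(v))) {
    stop("organ_volumes_l must cover all 18 compartments")
  }
  if (!all(c("lung", PERFUSED_ORGANS) %in% names(q))) {
    stop("organ_blood_flows_l_min must cover lung and all perfused organs")
  }
  if (any(v <= 0)) stop("all organ volumes must be strictly positive")
  if (any(q <= 0)) stop("all organ blood flows must be strictly positive")
  if (phys$hematocrit <= 0 || phys$hematocrit >= 1) {
    stop("hematocrit must lie in (0, 1)")
  }
  for (f in c("albumin_ontogeny", "agp_ontogeny")) {
    if (phys[[f]] <= 0 || phys[[f]] > 3) stop(f, " must lie in (0, 3]")
  }
  if (phys$gfr_ml_min <= 0) stop("gfr_ml_min must be positive")
  bmi <- phys$body_weight_kg / (phys$height_cm / 100)^2
  if (abs(bmi - phys$bmi_kg_m2) > 1e-9) {
    stop("bmi_kg_m2 inconsistent with body_weight_kg and height_cm")
  }
  co <- q[["lung"]]
  ret <- sum(q[PERFUSED_ORGANS])
  if (abs(ret - co) / co > 1e-6) {
    stop("flow balance violated: venous return ", signif(ret, 8),
         " L/min vs cardiac output ", signif(co, 8), " L/min")
  }
  invisible(phys)
}

#' @export
print.physiology_parameters <- function(x, ...) {
  cat(sprintf(
    "<physiology_parameters> %s, %.0f y, %.1f kg, %.0f cm (BMI %.2f)\n",
    x$sex, x$age, x$body_weight_kg, x$height_cm, x$bmi_kg_m2))
  cat(sprintf("  cardiac output %.2f L/min | GFR %.1f mL/min | hct %.2f\n",
              x$organ_blood_flows_l_min[["lung"]], x$gfr_ml_min, x$hematocrit))
  cat(sprintf("  liver %.2f L @ %.2f L/min (arterial) | ontogeny alb %.2f / agp %.2f\n",
              x$organ_volumes_l[["liver"]],
              x$organ_blood_flows_l_min[["liver"]],
              x$albumin_ontogeny, x$agp_ontogeny))
  invisible(x)
}

#' Specify a virtual population
#'
#' @param n number of individuals (>= 1).
#' @param age_range two ages in years, low to high; individuals are drawn
#'   uniformly.
#' @param proportion_female fraction of females in \[0, 1\].
#' @param variability_cv named list of coefficients of variation (fractions,
#'   >= 0) for the log-normally perturbed parameter groups. Recognized
#'   names: `organ_volumes`, `organ_blood_flows`, `gfr`. Defaults are 16%
#'   on volumes and flows and 16% on GFR.
#' @param seed integer seed giving reproducible sampling.
#' @return an object of class `population_spec`.
#' @export
population_spec <- function(n, age_range = c(25, 35), proportion_female = 0,
                            variability_cv = list(), seed = 1L) {
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n)) {
    stop("'n' must be a positive whole number")
  }
  if (length(age_range) != 2 || any(!is.finite(age_range)) ||
      age_range[1] > age_range[2]) {
    stop("'age_range' must be two finite ages, low <= high")
  }
  if (proportion_female < 0 || proportion_female > 1) {
    stop("'proportion_female' must lie in [0, 1]")
  }
  cv <- utils::modifyList(
    list(organ_volumes = 0.16, organ_blood_flows = 0.16, gfr = 0.16),
    variability_cv
  )
  if (any(unlist(cv) < 0)) stop("coefficients of variation must be >= 0")
  structure(
    list(n = as.integer(n), age_range = as.numeric(age_range),
         proportion_female = proportion_female, variability_cv = cv,
         seed = as.integer(seed)),
    class = "population_spec"
  )
}

# Mean-preserving log-normal multiplier: E[x * m] = x for any cv >= 0.
.lognormal_factor <- function(k, cv) {
  if (cv == 0) return(rep(1, k))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(k, mean = -sdlog^2 / 2, sd = sdlog))
}

#' Sample a virtual population around a base individual
#'
#' Draws `spec$n` individuals by perturbing the base physiology with
#' mean-preserving log-normal factors (so that parameter means converge to
#' the base values), drawing age uniformly over the spec's range and sex by
#' the female proportion. When the sampled age exceeds the base age and
#' `apply_age_scaling` is `TRUE`, each individual is first passed through
#' [scale_to_elderly()] at their sampled age. Cardiac output is recomputed
#' from the perturbed organ flows, so flow balance holds for every
#' individual. Sampling is fully determined by `spec$seed`; the caller's
#' random-number state is left untouched.
#'
#' @param spec a [population_spec].
#' @param base a `physiology_parameters` object to perturb.
#' @param apply_age_scaling apply age-decline scaling before perturbation
#'   when the sampled age is above the base age (default: only when the
#'   whole age range is at or above 60).
#' @return a list of `physiology_parameters`, length `spec$n`.
#' @export
sample_population <- function(spec, base,
                              apply_age_scaling = all(spec$age_range >= 60)) {
  stopifnot(inherits(spec, "population_spec"),
            inherits(base, "physiology_parameters"))

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(spec$seed)

  cv <- spec$variability_cv
  out <- vector("list", spec$n)
  for (i in seq_len(spec$n)) {
    age_i <- stats::runif(1, spec$age_range[1], spec$age_range[2])
    sex_i <- if (stats::runif(1) < spec$proportion_female) "female" else "male"
    ind <- base
    ind$age <- age_i
    ind$sex <- sex_i
    if (apply_age_scaling && age_i > base$age) {
      ind <- scale_to_elderly(ind, age_i)
    }
    nv <- length(ind$organ_volumes_l)
    nq <- length(PERFUSED_ORGANS)
    ind$organ_volumes_l <- ind$organ_volumes_l *
      .lognormal_factor(nv, cv$organ_volumes)
    qp <- ind$organ_blood_flows_l_min[PERFUSED_ORGANS] *
      .lognormal_factor(nq, cv$organ_blood_flows)
    ind$organ_blood_flows_l_min <- c(lung = unname(sum(qp)), qp)
    ind$gfr_ml_min <- ind$gfr_ml_min * .lognormal_factor(1, cv$gfr)
    ind$body_weight_kg <- 1.05 * sum(ind$organ_volumes_l)
    ind$bmi_kg_m2 <- ind$body_weight_kg / (ind$height_cm / 100)^2
    validate_physiology(ind)
    out[[i]] <- ind
  }
  out
}
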