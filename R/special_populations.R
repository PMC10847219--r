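# Pathophysiological overlays: renal impairment (creatinine-clearance
# scaling of renal elimination), hepatic impairment (Child-Pugh classes A-C
# as published physiology modifiers), and elderly age-decline scaling.

REFERENCE_CLCR_ML_MIN <- 120

.renal_categories <- c(normal = 120, mild = 65, moderate = 40, severe = 15)

#' Specify renal impairment by creatinine clearance
#'
#' @param category one of `"normal"` (CLcr 120 mL/min), `"mild"` (65),
#'   `"moderate"` (40), `"severe"` (15); ignored if `clcr_ml_min` is given.
#' @param clcr_ml_min creatinine clearance, mL/min (> 0).
#' @return an object of class `renal_impairment_spec`.
#' @export
renal_impairment_spec <- function(category = c("normal", "mild", "moderate",
                                               "severe"),
                                  clcr_ml_min = NULL) {
  if (is.null(clcr_ml_min)) {
    category <- match.arg(category)
    clcr_ml_min <- .renal_categories[[category]]
  } else {
    category <- NA_character_
  }
  if (!is.numeric(clcr_ml_min) || clcr_ml_min <= 0) {
    stop("'clcr_ml_min' must be positive")
  }
  structure(list(category = category, clcr_ml_min = clcr_ml_min,
                 clcr_ref_ml_min = REFERENCE_CLCR_ML_MIN),
            class = "renal_impairment_spec")
}

#' Scale renal clearance by creatinine clearance
#'
#' `CL_R,i = CL_R,ref * CLcr_i / CLcr_ref` — renal drug clearance is taken
#' proportional to renal function as measured by creatinine clearance.
#'
#' @param cl_r_ref reference renal clearance, L/h.
#' @param clcr_ref reference creatinine clearance, mL/min (> 0).
#' @param clcr_i target creatinine clearance, mL/min (>= 0).
#' @return scaled renal clearance, L/h.
#' @export
scale_renal_clearance <- function(cl_r_ref, clcr_ref, clcr_i) {
  if (!is.numeric(clcr_ref) || clcr_ref <= 0) {
    stop("'clcr_ref' must be positive")
  }
  cl_r_ref * clcr_i / clcr_ref
}

#' Apply renal impairment to a physiology/compound pair
#'
#' Implements creatinine-clearance scaling of renal elimination by scaling
#' the individual's GFR by `CLcr_i / CLcr_ref`, which (through
#' [renal_plasma_clearance()]) scales CL_R by exactly the same factor while
#' leaving every non-renal parameter untouched.
#'
#' @param phys `physiology_parameters`.
#' @param cmp `compound_parameters` (returned unchanged; kept in the
#'   signature so impairment overlays compose uniformly).
#' @param spec a [renal_impairment_spec].
#' @return list with elements `phys` and `cmp`.
#' @export
apply_renal_impairment <- function(phys, cmp, spec) {
  stopifnot(inherits(phys, "physiology_parameters"),
            inherits(cmp, "compound_parameters"),
            inherits(spec, "renal_impairment_spec"))
  phys$gfr_ml_min <- phys$gfr_ml_min * spec$clcr_ml_min / spec$clcr_ref_ml_min
  attr(phys, "renal_impairment") <- spec$category
  list(phys = phys, cmp = cmp)
}

# Published Child-Pugh physiology modifiers. Flows in L/min, liver volume
# in L; "other_organ_flow_fraction" multiplies the blood flow of every
# organ except liver and kidney (hyperdynamic circulation).
.hepatic_modifier_table <- list(
  healthy = list(hepatic_flow_l_min = 0.44, renal_flow_l_min = 1.35,
                 other_organ_flow_fraction = 1, liver_volume_l = 2.44,
                 hematocrit = 0.47, albumin_ontogeny = 1, agp_ontogeny = 1),
  `CP-A` = list(hepatic_flow_l_min = 0.45, renal_flow_l_min = 0.94,
                other_organ_flow_fraction = 1.75, liver_volume_l = 1.32,
                hematocrit = 0.39, albumin_ontogeny = 0.81,
                agp_ontogeny = 0.60),
  `CP-B` = list(hepatic_flow_l_min = 0.79, renal_flow_l_min = 0.69,
                other_organ_flow_fraction = 2.25, liver_volume_l = 1.05,
                hematocrit = 0.37, albumin_ontogeny = 0.68,
                agp_ontogeny = 0.56),
  `CP-C` = list(hepatic_flow_l_min = 0.15, renal_flow_l_min = 0.51,
                other_organ_flow_fraction = 2.75, liver_volume_l = 0.53,
                hematocrit = 0.35, albumin_ontogeny = 0.50,
                agp_ontogeny = 0.30)
)

#' Child-Pugh hepatic impairment modifiers
#'
#' Returns the published physiology changes for a Child-Pugh class:
#' hepatic (arterial) and renal blood flow, the multiplicative flow factor
#' for all other organs, liver volume, hematocrit, and the albumin and
#' alpha-1-acid-glycoprotein ontogeny factors. `"healthy"` returns the
#' identity modifier set.
#'
#' @param cp_class `"CP-A"`, `"CP-B"`, `"CP-C"`, or `"healthy"`.
#' @param ... named overrides of individual modifier fields (e.g. a custom
#'   `cl_h_multiplier` for sensitivity analysis).
#' @return an object of class `hepatic_impairment_modifiers`.
#' @export
hepatic_impairment_modifiers <- function(cp_class = c("CP-A", "CP-B", "CP-C",
                                                      "healthy"), ...) {
  cp_class <- match.arg(cp_class)
  mods <- .hepatic_modifier_table[[cp_class]]
  mods$cp_class <- cp_class
  mods <- utils::modifyList(mods, list(...))
  stopifnot(mods$hepatic_flow_l_min > 0, mods$renal_flow_l_min > 0,
            mods$other_organ_flow_fraction > 0, mods$liver_volume_l > 0,
            mods$hematocrit > 0, mods$hematocrit < 1,
            mods$albumin_ontogeny > 0, mods$agp_ontogeny > 0)
  structure(mods, class = "hepatic_impairment_modifiers")
}

#' Apply Child-Pugh hepatic impairment
#'
#' Overlays the published Child-Pugh physiology changes on a healthy
#' baseline: hepatic and renal blood flows, liver volume and hematocrit are
#' set to the class values; every other organ flow is multiplied by the
#' class's flow fraction; cardiac output is recomputed from the new organ
#' flows so flow balance is re-established; the ontogeny factors are set
#' and the compound's unbound fraction is re-derived via
#' [scale_fu_for_binding()].
#'
#' Hepatic clearance: the lumped plasma clearance is scaled by the
#' functional liver-volume ratio (`liver_volume_class / 2.44`) by default,
#' reflecting the loss of metabolizing tissue; set
#' `cl_h_scaling = "none"` to hold CL_H at its healthy value, or pass an
#' explicit `cl_h_multiplier` through the modifier object. See the methods
#' vignette for the rationale.
#'
#' Applying an impairment overlay twice is an error (the baseline must be
#' healthy, i.e. ontogeny factors of 1).
#'
#' @param phys healthy `physiology_parameters`.
#' @param cmp `compound_parameters`.
#' @param mods a [hepatic_impairment_modifiers] object.
#' @param cl_h_scaling `"liver_volume"` (default) or `"none"`.
#' @return list with elements `phys` and `cmp` (both transformed).
#' @export
apply_hepatic_impairment <- function(phys, cmp, mods,
                                     cl_h_scaling = c("liver_volume", "none")) {
  stopifnot(inherits(phys, "physiology_parameters"),
            inherits(cmp, "compound_parameters"),
            inherits(mods, "hepatic_impairment_modifiers"))
  cl_h_scaling <- match.arg(cl_h_scaling)
  if (phys$albumin_ontogeny != 1 || phys$agp_ontogeny != 1) {
    stop("hepatic impairment must be applied to a healthy baseline ",
         "(ontogeny factors of 1); it cannot be applied twice")
  }

  q <- phys$organ_blood_flows_l_min
  others <- setdiff(PERFUSED_ORGANS, c("liver", "kidney"))
  q[others] <- q[others] * mods$other_organ_flow_fraction
  q["liver"] <- mods$hepatic_flow_l_min
  q["kidney"] <- mods$renal_flow_l_min
  q["lung"] <- sum(q[PERFUSED_ORGANS])
  phys$organ_blood_flows_l_min <- q

  phys$organ_volumes_l["liver"] <- mods$liver_volume_l
  phys$hematocrit <- mods$hematocrit
  phys$albumin_ontogeny <- mods$albumin_ontogeny
  phys$agp_ontogeny <- mods$agp_ontogeny
  attr(phys, "hepatic_impairment") <- mods$cp_class

  cmp$fu <- scale_fu_for_binding(cmp, mods$albumin_ontogeny)
  mult <- mods$cl_h_multiplier %||% {
    if (cl_h_scaling == "liver_volume") {
      mods$liver_volume_l / .hepatic_modifier_table$healthy$liver_volume_l
    } else 1
  }
  cmp$cl_h_l_h <- cmp$cl_h_l_h * mult

  validate_physiology(phys)
  list(phys = phys, cmp = cmp)
}

# Age-decline multipliers relative to the 30-year reference. Published-style
# linear declines (fractions per year past age 30), recorded here as the
# model's documented ageing functions.
.age_decline_rates <- list(
  gfr = 0.008,           # ~1 mL/min/year from 120 mL/min
  flows = 0.005,         # cardiac output and regional flows
  muscle_volume = 0.006,
  liver_volume = 0.005,
  lean_volume = 0.002,   # remaining lean organs and blood
  adipose_gain = 0.010   # adipose fraction rises with age
)

#' Scale a physiology to an elderly target age
#'
#' Applies documented linear age-decline functions relative to the
#' 30-year-old reference: GFR, organ blood flows, muscle and liver volumes
#' and the remaining lean organ volumes fall with age, while adipose volume
#' rises; body weight is recomputed from the new total volume. At the
#' baseline age the transform is the identity; a target age below the
#' baseline age produces a warning and no change.
#'
#' @param phys `physiology_parameters`.
#' @param target_age years (typically >= 60 for elderly cohorts).
#' @return transformed `physiology_parameters` with `age = target_age`.
#' @export
scale_to_elderly <- function(phys, target_age) {
  stopifnot(inherits(phys, "physiology_parameters"))
  if (target_age < phys$age) {
    warning("target_age (", target_age, ") is below the baseline age (",
            phys$age, "); returning the physiology unchanged")
    return(phys)
  }
  dy <- target_age - max(phys$age, 30)
  if (target_age <= 30 || dy <= 0) {
    phys$age <- target_age
    return(phys)
  }
  r <- .age_decline_rates
  f <- function(rate) max(1 - rate * dy, 0.2)

  phys$gfr_ml_min <- phys$gfr_ml_min * f(r$gfr)
  q <- phys$organ_blood_flows_l_min
  q[PERFUSED_ORGANS] <- q[PERFUSED_ORGANS] * f(r$flows)
  q["lung"] <- sum(q[PERFUSED_ORGANS])
  phys$organ_blood_flows_l_min <- q

  v <- phys$organ_volumes_l
  lean <- setdiff(names(v), c("muscle", "liver", "adipose"))
  v["muscle"] <- v["muscle"] * f(r$muscle_volume)
  v["liver"] <- v["liver"] * f(r$liver_volume)
  v[lean] <- v[lean] * f(r$lean_volume)
  v["adipose"] <- v["adipose"] * (1 + r$adipose_gain * dy)
  phys$organ_volumes_l <- v

  phys$body_weight_kg <- 1.05 * sum(v)
  phys$bmi_kg_m2 <- phys$body_weight_kg / (phys$height_cm / 100)^2
  phys$age <- target_age
  validate_physiology(phys)
  phys
}
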