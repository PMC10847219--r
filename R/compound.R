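# Drug-specific parameters and derived quantities: tissue:plasma partition
# coefficients, renal plasma clearance, and binding-protein adjustment of
# the unbound fraction.

#' Apixaban compound parameters
#'
#' The packaged apixaban parameter set: log P 2.22, plasma fraction unbound
#' 0.93 (albumin), molecular weight 459 g/mol, acid pKa 13.07 (effectively
#' neutral at physiological pH), specific intestinal permeability
#' 9e-7 cm/min, lumped hepatic plasma clearance 2.4 L/h, and glomerular
#' filtration fraction 0.18. The blood:plasma ratio defaults to 1 and the
#' model is written against plasma concentrations. The effective intestinal
#' surface area is the single middle-out calibrated constant of the model
#' (see the methods vignette); it multiplies the specific permeability to
#' give the absorptive uptake clearance.
#'
#' Any field can be overridden, e.g. `apixaban_parameters(fu = 0.13)`.
#'
#' @param ... named overrides of the default fields.
#' @return an object of class `compound_parameters`.
#' @export
apixaban_parameters <- function(...) {
  defaults <- list(
    name = "apixaban",
    log_p = 2.22,
    fu = 0.93,
    mw_g_mol = 459,
    pka_acid = 13.07,
    peff_cm_min = 9e-7,
    cl_h_l_h = 2.4,
    f_gfr = 0.18,
    bp_ratio = 1.0,
    intestinal_area_cm2 = 1.0748e7
  )
  cmp <- utils::modifyList(defaults, list(...))
  compound_parameters(cmp)
}

#' Construct and validate compound parameters
#'
#' @param x a named list with at least `log_p`, `fu`, `mw_g_mol`,
#'   `peff_cm_min`, `cl_h_l_h`, `f_gfr`; see [apixaban_parameters()] for
#'   the full field set.
#' @return an object of class `compound_parameters`.
#' @export
compound_parameters <- function(x) {
  req <- c("log_p", "fu", "mw_g_mol", "peff_cm_min", "cl_h_l_h", "f_gfr")
  miss <- setdiff(req, names(x))
  if (length(miss)) stop("missing compound fields: ", paste(miss, collapse = ", "))
  if (x$fu <= 0 || x$fu > 1) stop("'fu' must lie in (0, 1]")
  if (x$peff_cm_min <= 0) stop("'peff_cm_min' must be positive")
  if (x$cl_h_l_h < 0) stop("'cl_h_l_h' must be >= 0")
  if (x$f_gfr < 0) stop("'f_gfr' must be >= 0")
  if (x$f_gfr > 1) warning("'f_gfr' exceeds 1 (net secretion implied)")
  if (is.null(x$bp_ratio)) x$bp_ratio <- 1.0
  if (is.null(x$intestinal_area_cm2)) x$intestinal_area_cm2 <- 1.0748e7
  structure(x, class = "compound_parameters")
}

#' @export
print.compound_parameters <- function(x, ...) {
  cat(sprintf("<compound_parameters> %s\n", x$name %||% "unnamed"))
  cat(sprintf("  log P %.2f | fu %.3f | MW %.0f g/mol | Peff %.2g cm/min\n",
              x$log_p, x$fu, x$mw_g_mol, x$peff_cm_min))
  cat(sprintf("  CL_H %.2f L/h | f_GFR %.2f | effective area %.3g cm2\n",
              x$cl_h_l_h, x$f_gfr, x$intestinal_area_cm2))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Fractional tissue composition (volume fractions of water, neutral lipid
# and phospholipid) for the tissue-composition partitioning methods,
# compiled from standard homogenate tables. Organs without their own entry
# map onto a chemically similar tissue (gut for the GI organs, muscle for
# gonads and the rest compartment).
.tissue_composition <- function() {
  tc <- rbind(
    adipose = c(0.180, 0.7900, 0.0020),
    bone    = c(0.439, 0.0740, 0.0011),
    brain   = c(0.770, 0.0510, 0.0565),
    gut     = c(0.718, 0.0487, 0.0163),
    heart   = c(0.758, 0.0115, 0.0166),
    kidney  = c(0.783, 0.0207, 0.0162),
    liver   = c(0.751, 0.0348, 0.0252),
    lung    = c(0.811, 0.0030, 0.0090),
    muscle  = c(0.760, 0.0238, 0.0072),
    skin    = c(0.718, 0.0284, 0.0111),
    spleen  = c(0.788, 0.0201, 0.0198),
    plasma  = c(0.945, 0.0035, 0.00225)
  )
  colnames(tc) <- c("f_water", "f_nlipid", "f_plipid")
  tc
}

.organ_tissue_map <- c(
  lung = "lung", heart = "heart", brain = "brain", muscle = "muscle",
  adipose = "adipose", skin = "skin", bone = "bone", liver = "liver",
  kidney = "kidney", spleen = "spleen", pancreas = "gut", stomach = "gut",
  small_intestine = "gut", large_intestine = "gut", gonads = "muscle",
  rest = "muscle"
)

#' Tissue:plasma partition coefficients
#'
#' Computes perfusion-model partition coefficients (Kp) for all 16 organ
#' compartments from tissue composition and the compound's lipophilicity
#' and plasma binding, treating the compound as neutral (appropriate for a
#' very weak acid such as apixaban).
#'
#' Two methods are available:
#' \describe{
#'   \item{`pksim_standard`}{a standard tissue-homogenate calculation:
#'     each tissue partitions into water, neutral lipid and phospholipid;
#'     non-adipose tissues use the octanol:water partition coefficient
#'     `10^log_p` for the lipid phases with a tissue-binding correction
#'     `fu_t = 1 / (1 + 0.5 (1 - fu) / fu)`, while adipose uses the
#'     vegetable-oil:water coefficient from the regression
#'     `log D_vo:w = 1.115 log P - 1.35` and `fu_t = 1`.}
#'   \item{`rodgers_rowland`}{a simplified neutral-compound form,
#'     `Kp = fu * (f_water + P f_nlipid + (0.3 P + 0.7) f_plipid)`.}
#' }
#'
#' @param cmp `compound_parameters`.
#' @param phys `physiology_parameters` (fixes the organ set).
#' @param method `"pksim_standard"` (default) or `"rodgers_rowland"`.
#' @return an object of class `partition_coefficients`: list with `kp`
#'   (named positive vector over the 16 organs) and `method`.
#' @export
compute_partition_coefficients <- function(cmp, phys,
                                           method = c("pksim_standard",
                                                      "rodgers_rowland")) {
  stopifnot(inherits(cmp, "compound_parameters"),
            inherits(phys, "physiology_parameters"))
  if (is.character(method) && length(method) == 1 &&
      !method %in% c("pksim_standard", "rodgers_rowland")) {
    stop("unknown partition method '", method,
         "'; supported methods: pksim_standard, rodgers_rowland")
  }
  method <- match.arg(method)
  tc <- .tissue_composition()
  p_ow <- 10^cmp$log_p
  fu <- cmp$fu
  organs <- names(.organ_tissue_map)

  kp <- vapply(organs, function(org) {
    t <- tc[.organ_tissue_map[[org]], ]
    pl <- tc["plasma", ]
    if (method == "pksim_standard") {
      is_adipose <- identical(org, "adipose")
      p_t <- if (is_adipose) 10^(1.115 * cmp$log_p - 1.35) else p_ow
      fu_t <- if (is_adipose) 1 else 1 / (1 + 0.5 * (1 - fu) / fu)
      num <- p_t * (t[["f_nlipid"]] + 0.3 * t[["f_plipid"]]) +
        (t[["f_water"]] + 0.7 * t[["f_plipid"]])
      den <- p_t * (pl[["f_nlipid"]] + 0.3 * pl[["f_plipid"]]) +
        (pl[["f_water"]] + 0.7 * pl[["f_plipid"]])
      num / den * fu / fu_t
    } else {
      fu * (t[["f_water"]] + p_ow * t[["f_nlipid"]] +
              (0.3 * p_ow + 0.7) * t[["f_plipid"]])
    }
  }, numeric(1))

  stopifnot(all(kp > 0))
  structure(list(kp = kp, method = method), class = "partition_coefficients")
}

#' Renal plasma clearance from the glomerular filtration fraction
#'
#' `CL_R = f_GFR * fu * GFR`, with GFR converted from mL/min to L/h.
#' Inverting the relation recovers `f_GFR = CL_R / (fu * GFR)`.
#'
#' @param cmp `compound_parameters` (uses `f_gfr` and `fu`).
#' @param phys `physiology_parameters` (uses `gfr_ml_min`).
#' @return renal plasma clearance, L/h.
#' @export
renal_plasma_clearance <- function(cmp, phys) {
  stopifnot(inherits(cmp, "compound_parameters"),
            inherits(phys, "physiology_parameters"))
  if (phys$gfr_ml_min <= 0) stop("GFR must be positive")
  gfr_l_h <- phys$gfr_ml_min * 60 / 1000
  cmp$f_gfr * cmp$fu * gfr_l_h
}

#' Adjust the unbound fraction for binding-protein abundance
#'
#' Rescales the plasma fraction unbound when the abundance of the binding
#' protein changes by a multiplicative ontogeny factor: the bound:unbound
#' ratio `(1 - fu)/fu` scales with protein abundance, giving
#' `fu' = 1 / (1 + ontogeny * (1 - fu) / fu)`. At ontogeny 1 the unbound
#' fraction is unchanged; as the factor falls toward 0 (protein loss) the
#' unbound fraction rises toward 1.
#'
#' @param cmp `compound_parameters` (uses `fu`), or a bare numeric fu.
#' @param albumin_ontogeny positive multiplicative factor.
#' @return adjusted unbound fraction in (0, 1\].
#' @export
scale_fu_for_binding <- function(cmp, albumin_ontogeny) {
  fu <- if (inherits(cmp, "compound_parameters")) cmp$fu else cmp
  if (!is.numeric(fu) || fu <= 0 || fu > 1) stop("'fu' must lie in (0, 1]")
  if (albumin_ontogeny <= 0) stop("'albumin_ontogeny' must be positive")
  1 / (1 + albumin_ontogeny * (1 - fu) / fu)
}

#' Read or write compound parameters as YAML
#'
#' Flat YAML with unit-suffixed field names, mirroring the packaged
#' apixaban fixture at `system.file("extdata", "apixaban.yaml",
#' package = "apixpbpk")`.
#'
#' @param path file path.
#' @return `read_compound_config` returns `compound_parameters`;
#'   `write_compound_config` returns `path` invisibly.
#' @export
read_compound_config <- function(path) {
  x <- yaml::read_yaml(path)
  compound_parameters(x)
}

#' @rdname read_compound_config
#' @param cmp `compound_parameters` to serialize.
#' @export
write_compound_config <- function(cmp, path) {
  stopifnot(inherits(cmp, "compound_parameters"))
  yaml::write_yaml(unclass(cmp), path)
  invisible(path)
}
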