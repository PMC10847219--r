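# Non-compartmental analysis, average-fold-error model evaluation, and
# exposure-matched dose normalization.

# Half-up rounding (R's round() is round-half-even); reported percentages
# and ratios use the conventional half-up rule.
round_half_up <- function(x, digits = 0) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Non-compartmental analysis of a concentration-time profile
#'
#' Computes Cmax and Tmax from the grid maximum, AUC by the linear
#' trapezoidal rule, the terminal elimination rate constant lambda_z by
#' log-linear regression over the terminal points (the window of the last
#' 3 to 10 post-peak points with the best adjusted r-squared), and
#' AUC extrapolated to infinity as `AUC_0-t + C_last / lambda_z`.
#'
#' When no terminal window achieves adjusted r-squared >= 0.8 with a
#' negative slope, lambda_z (and quantities derived from it) are returned
#' as `NA` with a warning, while `auc_0_t`, `cmax` and `tmax` are still
#' reported.
#'
#' For multiple-dose data, pass `interval = c(t1, t2)` to compute the
#' steady-state metrics over one dosing interval: `auc_tau` over
#' \[t1, t2\] plus Cmax/Tmax within the interval.
#'
#' @param profile a [concentration_time_profile], or anything with `times`
#'   and `concentrations` fields.
#' @param interval optional two-element window (hours) for interval-based
#'   (AUC_tau) analysis.
#' @return an object of class `pk_parameters`: `cmax_ng_ml`, `tmax_h`,
#'   `auc_0_t_ng_h_ml`, `auc_0_inf_ng_h_ml`, `lambda_z_per_h`, `t_half_h`,
#'   `extrapolated_fraction`; with `interval`, also `auc_tau_ng_h_ml`.
#' @export
run_nca <- function(profile, interval = NULL) {
  t <- profile$times
  c_ <- profile$concentrations
  if (length(t) < 3) stop("NCA requires at least 3 points")
  if (any(diff(t) <= 0)) stop("'times' must be strictly increasing")

  trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

  imax <- which.max(c_)
  cmax <- c_[imax]
  tmax <- t[imax]
  auc_0_t <- trapz(t, c_)

  # terminal slope: last 3..10 points strictly after Tmax, best adjusted r2
  post <- which(t > tmax & c_ > 0)
  lambda_z <- NA_real_
  best_r2 <- -Inf
  n_lambda <- NA_integer_
  if (length(post) >= 3) {
    for (k in 3:min(10, length(post))) {
      idx <- utils::tail(post, k)
      fit <- stats::lm(log(c_[idx]) ~ t[idx])
      slope <- unname(stats::coef(fit)[2])
      # suppress the "essentially perfect fit" note on noise-free grids
      r2 <- suppressWarnings(summary(fit)$adj.r.squared)
      if (!is.na(slope) && slope < 0 && r2 > best_r2) {
        best_r2 <- r2
        lambda_z <- -slope
        n_lambda <- k
      }
    }
  }
  if (!is.finite(lambda_z) || best_r2 < 0.8) {
    warning("terminal slope not estimable (best adjusted r2 ",
            signif(max(best_r2, 0), 3), "); AUC_0-inf flagged missing")
    lambda_z <- NA_real_
  }

  c_last <- utils::tail(c_[c_ > 0], 1)
  auc_inf <- if (is.na(lambda_z)) NA_real_ else auc_0_t + c_last / lambda_z

  out <- list(
    cmax_ng_ml = cmax,
    tmax_h = tmax,
    auc_0_t_ng_h_ml = auc_0_t,
    auc_0_inf_ng_h_ml = auc_inf,
    lambda_z_per_h = lambda_z,
    t_half_h = if (is.na(lambda_z)) NA_real_ else log(2) / lambda_z,
    extrapolated_fraction =
      if (is.na(auc_inf)) NA_real_ else 1 - auc_0_t / auc_inf,
    n_lambda_points = n_lambda,
    lambda_z_adj_r2 = if (is.finite(best_r2)) best_r2 else NA_real_
  )

  if (!is.null(interval)) {
    stopifnot(length(interval) == 2, interval[1] < interval[2])
    sel <- t >= interval[1] & t <= interval[2]
    if (sum(sel) < 3) stop("fewer than 3 points inside 'interval'")
    out$auc_tau_ng_h_ml <- trapz(t[sel], c_[sel])
    out$cmax_ng_ml <- max(c_[sel])
    out$tmax_h <- t[sel][which.max(c_[sel])]
  }
  structure(out, class = "pk_parameters")
}

#' @export
print.pk_parameters <- function(x, ...) {
  cat("<pk_parameters>\n")
  cat(sprintf("  Cmax %.4g ng/mL at %.2f h\n", x$cmax_ng_ml, x$tmax_h))
  cat(sprintf("  AUC_0-t %.5g | AUC_0-inf %.5g ng.h/mL (%.1f%% extrapolated)\n",
              x$auc_0_t_ng_h_ml, x$auc_0_inf_ng_h_ml,
              100 * x$extrapolated_fraction))
  cat(sprintf("  lambda_z %.4g /h (t1/2 %.3g h)\n",
              x$lambda_z_per_h, x$t_half_h))
  if (!is.null(x$auc_tau_ng_h_ml)) {
    cat(sprintf("  AUC_tau %.5g ng.h/mL\n", x$auc_tau_ng_h_ml))
  }
  invisible(x)
}

#' Average fold error between predicted and observed concentrations
#'
#' `AFE = 10^mean(log10(pred/obs))` over paired, positive values: the
#' geometric mean of the fold deviations. AFE equals 1 exactly when the
#' predictions are unbiased in log space; the conventional acceptance band
#' is 0.5 to 2.
#'
#' @param predicted,observed paired positive numeric vectors at matched
#'   times; pairs with a non-positive member are excluded with a message.
#' @return the average fold error (dimensionless scalar).
#' @export
average_fold_error <- function(predicted, observed) {
  if (length(predicted) != length(observed)) {
    stop("'predicted' and 'observed' must be paired (equal length)")
  }
  ok <- predicted > 0 & observed > 0 & is.finite(predicted) & is.finite(observed)
  if (sum(!ok)) {
    message("excluding ", sum(!ok), " pairs with non-positive or ",
            "non-finite concentrations")
  }
  if (!sum(ok)) stop("no usable prediction/observation pairs")
  10^mean(log10(predicted[ok] / observed[ok]))
}

.auc_of <- function(x) {
  if (inherits(x, "pk_parameters") || is.list(x)) {
    x$auc_0_inf_ng_h_ml %||% x$auc_0_inf %||% stop("no AUC_0-inf field")
  } else {
    as.numeric(x)
  }
}
.cmax_of <- function(x) {
  if (inherits(x, "pk_parameters") || is.list(x)) {
    x$cmax_ng_ml %||% x$cmax %||% NA_real_
  } else {
    NA_real_
  }
}

#' Exposure fold change of a special population versus reference
#'
#' @param pk_special,pk_reference `pk_parameters` objects (or bare AUC
#'   values); the reference AUC must be positive.
#' @return list with `auc_ratio` and `cmax_ratio` (exact; reports round to
#'   2 decimals via [round_half_up()]).
#' @export
fold_change <- function(pk_special, pk_reference) {
  auc_ref <- .auc_of(pk_reference)
  if (!is.finite(auc_ref) || auc_ref <= 0) {
    stop("reference AUC must be positive")
  }
  list(auc_ratio = .auc_of(pk_special) / auc_ref,
       cmax_ratio = .cmax_of(pk_special) / .cmax_of(pk_reference))
}

#' Exposure-matched dose fraction
#'
#' The dose fraction (percent of the reference dose) that matches the
#' special population's exposure to the reference exposure under linear
#' kinetics: `round(100 * AUC_reference / AUC_special)` (half-up).
#'
#' @param auc_reference,auc_special positive exposures, ng.h/mL.
#' @return integer percent.
#' @export
recommend_dose_fraction <- function(auc_reference, auc_special) {
  if (auc_reference <= 0 || auc_special <= 0) stop("AUCs must be positive")
  as.integer(round_half_up(100 * auc_reference / auc_special))
}

#' @rdname recommend_dose_fraction
#' @param auc_ratio positive AUC ratio (special / reference).
#' @export
recommend_dose_fraction_from_ratio <- function(auc_ratio) {
  if (auc_ratio <= 0) stop("'auc_ratio' must be positive")
  as.integer(round_half_up(100 / auc_ratio))
}

#' Published apixaban exposure and fold-change inputs
#'
#' `reported_exposure()` returns the published predicted exposures for a
#' 10 mg oral dose (AUC_0-inf in ng.h/mL, Cmax in ng/mL where reported)
#' for the healthy Chinese adult, the healthy Chinese elderly and the
#' elderly renal-/hepatic-impaired populations.
#' `reported_fold_changes()` returns the published predicted Cmax and AUC
#' ratios for adult renal and hepatic impairment versus normal function.
#' Both are packaged inputs for the dose-normalization stage.
#'
#' @return a data.frame.
#' @export
reported_exposure <- function() {
  path <- system.file("extdata", "reported_exposure.csv",
                      package = "apixpbpk", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname reported_exposure
#' @export
reported_fold_changes <- function() {
  path <- system.file("extdata", "reported_fold_changes.csv",
                      package = "apixpbpk", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Dose-normalization table for the elderly special populations
#'
#' Builds the full dose-recommendation table from an exposure table (by
#' default the packaged published exposures): AUC fold change of every
#' population versus the healthy adult, and the exposure-matched dose
#' fraction versus the stated reference of each row (the healthy adult for
#' the healthy elderly; the healthy elderly for the impaired-elderly
#' populations, matching how the recommendations are quoted).
#'
#' @param exposure data.frame with columns `population`,
#'   `auc_0_inf_ng_h_ml`, `dose_reference` (a population label); defaults
#'   to [reported_exposure()].
#' @return data.frame with `population`, `auc_ratio_vs_adult` (2 dp),
#'   `dose_reference`, `dose_fraction_percent`.
#' @export
dose_recommendation_table <- function(exposure = reported_exposure()) {
  stopifnot(all(c("population", "auc_0_inf_ng_h_ml", "dose_reference") %in%
                  names(exposure)))
  adult <- exposure$auc_0_inf_ng_h_ml[exposure$population == "chinese_adult"]
  if (length(adult) != 1) stop("exposure table must contain 'chinese_adult'")
  ref_auc <- exposure$auc_0_inf_ng_h_ml[
    match(exposure$dose_reference, exposure$population)]
  data.frame(
    population = exposure$population,
    auc_0_inf_ng_h_ml = exposure$auc_0_inf_ng_h_ml,
    auc_ratio_vs_adult = round_half_up(
      exposure$auc_0_inf_ng_h_ml / adult, 2),
    dose_reference = exposure$dose_reference,
    dose_fraction_percent = ifelse(
      is.na(ref_auc), NA_integer_,
      mapply(function(r, s) if (is.na(r)) NA_integer_ else
        recommend_dose_fraction(r, s),
        ref_auc, exposure$auc_0_inf_ng_h_ml)),
    stringsAsFactors = FALSE
  )
}
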