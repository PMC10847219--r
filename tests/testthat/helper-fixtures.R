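# Shared fixtures: reference individuals, compound sets, and an analytic
# one-compartment oral curve used as the NCA oracle.

ref_adult <- function() demographic_preset("european_adult")
chn_adult <- function() demographic_preset("chinese_adult")
apix <- function(...) apixaban_parameters(...)

# C(t) = A (exp(-ke t) - exp(-ka t)); closed forms:
#   AUC_0-inf = A (1/ke - 1/ka), terminal slope ke (for ka > ke),
#   Tmax = log(ka/ke) / (ka - ke).
one_compartment_profile <- function(ka, ke, A = 100, t_end = NULL,
                                    dt = 0.05) {
  if (is.null(t_end)) t_end <- 8 * log(2) / ke
  t <- seq(0, t_end, by = dt)
  concentration_time_profile(t[-1], A * (exp(-ke * t[-1]) - exp(-ka * t[-1])),
                             dosing_regimen(1), "analytic")
}

one_compartment_auc_inf <- function(ka, ke, A = 100) A * (1 / ke - 1 / ka)
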