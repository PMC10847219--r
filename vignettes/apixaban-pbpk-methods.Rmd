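---
title: "Methods: whole-body PBPK modelling of apixaban in special populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: whole-body PBPK modelling of apixaban in special populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apixpbpk)
```

## The problem

Apixaban is an oral direct factor Xa inhibitor eliminated by hepatic
metabolism (lumped plasma clearance CL~H~ = 2.4 L/h) and renal filtration
(glomerular filtration fraction f~GFR~ = 0.18). Clinical exposure data in
renally impaired, hepatically impaired and elderly patients are sparse, so
dosing in these groups is extrapolated from healthy adults. This package
implements that extrapolation as a mechanistic pipeline: a whole-body
physiologically based pharmacokinetic (PBPK) model parameterized for
apixaban, pathophysiological overlays for the special populations,
non-compartmental analysis (NCA) of the simulated profiles, and
exposure-matched dose normalization.

## Model structure

The body is represented by 18 compartments: lung, heart, brain, muscle,
adipose, skin, bone, liver, kidney, spleen, pancreas, stomach, small and
large intestine, gonads, a residual "rest" compartment that closes the mass
and flow balances, and arterial and venous blood. All organs are
perfusion-limited: for a non-eliminating organ with blood flow $Q_i$,
volume $V_i$ and tissue:plasma partition coefficient $K_{p,i}$,

$$\frac{dA_i}{dt} = Q_i\left(C_{art} - \frac{A_i/V_i}{K_{p,i}}\right).$$

Venous blood collects the organ outflows, passes through the lung, and
returns as arterial blood. The liver receives its arterial supply
(0.44 L/min in the healthy adult) plus the portal outflow of the
splanchnic organs (spleen, pancreas, stomach, intestines). Elimination is
hepatic, $CL_H \cdot C_{liver}/K_{p,liver}$, and renal,
$CL_R \cdot C_{kidney}/K_{p,kidney}$, with

$$CL_R = f_{GFR} \cdot f_u \cdot GFR.$$

The blood:plasma ratio defaults to 1 and all reported concentrations are
venous plasma in ng/mL. Because no printed blood:plasma value exists for
the parameter set, unity is the neutral choice; with it, hematocrit is
carried as a physiological state (its impairment overlay values are
reproduced exactly) but does not alter the kinetics.

Oral absorption uses three gastrointestinal lumen transit compartments:
first-order stomach emptying (half-life 15 min), small-intestinal transit
(mean 3.3 h) and colonic transit (mean 13 h) into a fecal sink. The
absorptive flux from the small-intestinal lumen into the portal inflow is
$P_{eff} \times A_{eff} \times C_{lumen}$ with a lumen volume of 0.65 L. No
solubility limit is modelled: apixaban doses are small and the emulated
studies used immediate-release formulations.

The system is linear, which the pipeline exploits and verifies: profiles
scale proportionally with dose, multiple dosing superposes time-shifted
single doses, and the steady-state AUC over one dosing interval equals the
single-dose AUC extrapolated to infinity.

### Numerical choices

The ODE system is solved with `deSolve::lsoda` (stiff-capable) at relative
tolerance 1e-8 and absolute tolerance 1e-10 mg, with doses administered as
solver events at the exact dose times. The default output grid has 0.05 h
spacing, chosen so that the trapezoidal AUC and the terminal-slope
regression of the NCA stage are grid-converged (the NCA oracle tests hold
them to 0.5% and 1%). Mass balance (amount in body + eliminated +
unabsorbed = administered) is checked to 0.1% of dose at every output
time. Negative states or solver non-convergence raise errors rather than
being clipped silently.

## Parameters

| Parameter | Value | Units | Meaning |
|---|---|---|---|
| log P | 2.22 | — | lipophilicity, drives tissue partitioning |
| f~u~ | 0.93 | — | plasma fraction unbound (albumin) |
| MW | 459 | g/mol | molecular weight |
| pKa (acid) | 13.07 | — | effectively neutral at physiological pH |
| P~eff~ | 9e-7 | cm/min | specific intestinal permeability |
| CL~H~ | 2.4 | L/h | lumped hepatic plasma clearance |
| f~GFR~ | 0.18 | — | fraction of GFR contributing to renal clearance |
| A~eff~ | 1.0748e7 | cm² | effective absorptive area (calibrated, below) |
| GFR | 120 | mL/min | healthy adult glomerular filtration rate |

The packaged f~u~ of 0.93 follows the parameter table being reproduced;
public references for apixaban give ~0.13. We ship the printed value for
fidelity and allow an override (`apixaban_parameters(fu = 0.13)`). A
consequence of the high unbound fraction is a large distribution volume
and a terminal half-life (~78 h in the reference adult) well above the
clinical ~12 h; AUC — the quantity dose normalization rests on — is
unaffected, since in a linear model AUC depends only on bioavailable dose
and clearance.

### Partition coefficients

Two neutral-compound tissue-composition methods are provided.
`pksim_standard` (default) is a homogenate calculation: tissues partition
into water, neutral lipid and phospholipid; non-adipose tissues use the
octanol:water coefficient with a tissue-binding correction
$f_{u,t} = 1/(1 + 0.5(1-f_u)/f_u)$, adipose uses the vegetable-oil:water
regression $\log D_{vo:w} = 1.115\log P - 1.35$. `rodgers_rowland` is the
simplified neutral-class composition formula. Both satisfy the expected
limits (a neutral, unbound, log P = 0 compound partitions like tissue
water; adipose K~p~ rises monotonically with log P; the f~u~ dependence is
closed-form and is tested as such).

### Absorption calibration (middle-out)

The only fitted constant is the effective absorptive surface area
multiplying P~eff~. Specific permeability and anatomical surface area are
not separately identifiable from plasma data, so their product is
calibrated: `calibrate_absorption()` minimizes the squared
log-concentration error against a target profile, optionally
co-estimating CL~H~. The packaged default (1.0748e7 cm²) was calibrated
once so that the reference Chinese adult receiving 10 mg reproduces the
published adult AUC~0–∞~ of 2062 ng·h/mL, the exposure all dose
normalization is anchored to. `parameter_recovery_study()` verifies the
calibration machinery: with 12 virtual subjects and 10% residual noise it
recovers known area and CL~H~ values within 10%.

## Special-population overlays

**Renal impairment.** Renal drug clearance is scaled in proportion to
creatinine clearance, $CL_{R,i} = CL_{R,ref} \cdot CL_{cr,i}/CL_{cr,ref}$,
with CLcr categories 120 (normal), 65 (mild), 40 (moderate) and
15 mL/min (severe) against the reference 120 mL/min. The implementation
scales GFR by the same factor, which keeps the filtration-fraction
relation and the CLcr scaling mutually consistent and leaves every
non-renal parameter untouched.

**Hepatic impairment.** Child-Pugh classes A/B/C are physiology overlays
reproducing the published parameter table exactly: hepatic arterial flow
0.45/0.79/0.15 L/min, renal flow 0.94/0.69/0.51 L/min, all other organ
flows multiplied by 1.75/2.25/2.75 (hyperdynamic circulation), liver
volume 1.32/1.05/0.53 L, hematocrit 0.39/0.37/0.35, albumin ontogeny
0.81/0.68/0.50 and α1-acid-glycoprotein ontogeny 0.60/0.56/0.30. Cardiac
output is recomputed so flow balance holds, and f~u~ is re-derived from
the albumin ontogeny factor via the bound-ratio law
$f_u' = 1/(1 + ont \cdot (1-f_u)/f_u)$. The CP-B hepatic flow exceeding
the healthy value is reproduced as published, without reinterpretation.

A design choice was genuinely open here: the source table lists no change
in hepatic clearance itself. Holding the lumped CL~H~ fixed, however,
provably cannot reproduce the published direction of hepatic-impairment
exposure (AUC rising with severity): in this model the oral AUC is
$F_a D / (CL_H + CL_{R,eff}/F_h)$, so reducing hepatic flow cancels out of
the hepatic term and the fu rise only increases renal clearance —
exposure would *fall* with severity. We therefore scale CL~H~ by the
functional liver-volume ratio (2.44 → 1.32/1.05/0.53 L gives multipliers
0.54/0.43/0.22), a standard loss-of-functional-mass assumption that the
overlay exposes as a configurable knob (`cl_h_scaling = "none"` restores
the fixed-CL~H~ variant; an explicit `cl_h_multiplier` supports
sensitivity analysis). With it, the simulated AUC ratios rise
monotonically CP-A → CP-B → CP-C (1.44/1.62/2.10 at 10 mg), matching the
published direction (1.04/1.13/1.86).

**Elderly.** Ageing is a set of documented linear decline functions
relative to the 30-year reference: GFR −0.8%/y, organ blood flows
−0.5%/y, muscle −0.6%/y, liver −0.5%/y, other lean organs −0.2%/y, and
adipose +1.0%/y; body weight is recomputed from the new total volume.
These are implementer-chosen published-style rates (the emulated workflow
delegated them to proprietary software internals); they produce the
expected directions — lower GFR and hepatic flow, higher adipose
fraction, and higher AUC than the adult at any fixed dose — and commute
with the renal overlay (both act multiplicatively on disjoint parameters
or on GFR multiplicatively).

The Chinese adult preset (30 y, 63 kg, 168 cm) and the European reference
(30 y, 82 kg, 180 cm) differ only in anthropometry; organ volumes scale
linearly and flows allometrically (exponent 0.75) with body weight.

## Virtual populations

`sample_population()` perturbs a base individual with mean-preserving
log-normal factors, by default CV 16% on organ volumes, flows and GFR;
the synthetic-data generator additionally perturbs CL~H~ and P~eff~ with
CV 30%. Cardiac output is recomputed per individual so flow balance holds
for everyone sampled. The defaults reflect typical between-subject
physiological variability; the sources being emulated state that Monte
Carlo population simulation was used but print no CVs, so these values
were chosen once and are not tuned.

## NCA and model evaluation

`run_nca()` computes Cmax/Tmax from the grid maximum, AUC~0–t~ by the
linear trapezoidal rule, and the terminal rate constant λ~z~ by log-linear
regression over the best window (by adjusted r²) of the last 3–10
post-peak points — the conventional "best fit" rule of standard PK
software, which names no selection rule of record. AUC~0–∞~ adds
C~last~/λ~z~; when no window achieves adjusted r² ≥ 0.8 with a negative
slope, λ~z~-derived quantities are flagged missing rather than guessed.
For multiple dosing, metrics are computed over the final dosing interval
(AUC~τ~). Model fit against observed data uses the average fold error,
$AFE = 10^{\mathrm{mean}(\log_{10}(pred/obs))}$, with the conventional
0.5–2 acceptance band.

Dose normalization assumes dose-linear kinetics (an engine invariant):
the exposure-matched dose fraction is
$100 \cdot AUC_{ref}/AUC_{special}$, rounded half-up to integer percent;
fold-change ratios are reported to two decimals. The packaged published
exposure table (10 mg in Chinese adult, elderly and impaired-elderly
populations) is an *input* to this stage; the elderly fraction is quoted
against the healthy adult and the impaired-elderly fractions against the
healthy elderly, matching how the recommendations are stated.

## Synthetic observed data

The clinical profiles the emulated studies digitized from figures are not
redistributable, so `generate_observed_profiles()` reproduces the study
*designs* — single doses of 5/10/25/50 mg (n = 6), twice-daily
2.5/5/10/25 mg for 7 days, renal groups at CLcr 120/65/40/15 (n = 8/10/7/7),
hepatic groups healthy/CP-A/B/C (n = 16/8/8/8), and an elderly cohort
(60–81 y, 50% women) — with sparse 8–14-point sampling, log-normally
perturbed subjects and mean-preserving proportional residual noise
(CV 10% default, a typical assay-plus-digitization error). All generation
is seeded and bit-reproducible.

What passing against synthetic data shows — and what it does not: the
closure tests (simulate → NCA → AFE within 0.5–2; parameter recovery
within 10%) establish that the pipeline is self-consistent, unbiased in
log space and identifiable at realistic noise, not that the engine
reproduces real clinical profiles. Real data differ in ways the generator
does not emulate: absorption variability beyond a single area parameter,
non-proportional assay error, dropout/BLQ handling, and the true
between-subject covariance structure.

## Problem sizes

The shipped analyses and tests use an individual 0.05 h output grid over
168 h for single doses, a 60-dose twice-daily run for the steady-state
identity, populations of 6 (healthy and elderly cohorts, matching the
emulated designs) and 1000 only for the sampling-moment checks, and 12
subjects for the recovery study — sizes chosen so each stage completes in
seconds while keeping the statistical checks well-powered.

## Known limitations

- The terminal half-life is overpredicted (see the f~u~ note): terminal
  phase and Cmax-sensitive conclusions should not be read off this
  parameterization, while AUC-based fold changes and dose fractions are
  robust to it.
- Absolute exposures in the impaired and elderly groups depend on
  population physiology databases and group covariates that are not
  public; the pipeline reproduces the published fold-change and
  dose-fraction *arithmetic* exactly, and the simulated ratios match the
  published ones in direction and ordering, not cell-by-cell.
- Mechanistic enzyme kinetics (CYP3A4/5), transporters, enterohepatic
  recirculation, food and formulation effects, dialysis and combined
  renal+hepatic calibration are out of scope.
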