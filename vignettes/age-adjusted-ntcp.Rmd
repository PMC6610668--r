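---
title: "Age-adjusted NTCP models for chronic radiation-associated dysphagia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Age-adjusted NTCP models for chronic radiation-associated dysphagia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radntcp)
```

## The modelling problem

Chronic radiation-associated dysphagia (RAD) — aspiration, stricture, or
gastrostomy dependence at one year or later after head-and-neck
chemoradiation — depends on the dose received by non-target swallowing
muscles. Classic NTCP models describe a population-average dose–response;
this package fits a logistic dose–response in which patient age enters as a
dose-response-modifying covariate, on the hypothesis that presbyphagia (the
normal age-related loss of swallowing reserve) leaves older muscles less
able to compensate for the same radiation insult. The practical output is
twofold: per-muscle diagnostics of how much dose and age each contribute,
and per-muscle, per-age-stratum mean-dose constraints at a fixed predicted
risk.

## From DVH to a summary dose

Each region of interest (ROI) enters the regression as a single summary
dose, produced in three steps.

1. **Parsing and validation.** A DVH arrives as a two-column (dose, volume)
   delimited table, cumulative or differential, in percent or fractional
   volume. Volumes are normalised to fractions; any volume above 1.5 is
   taken to indicate the percent dialect (a legitimate fractional volume
   cannot exceed 1, and percent tables essentially always contain values
   well above 1.5). Cumulative tables must be non-increasing, differential
   masses must sum to 1 within `1e-6`.
2. **EQD2 correction.** Doses are converted to 2-Gy-fraction equivalents
   bin by bin under the linear-quadratic model,
   $D_i \cdot (d_i + \alpha/\beta)/(2 + \alpha/\beta)$ with
   $d_i = D_i/n$. The whole ROI is assumed delivered in the plan's $n$
   fractions (standard DVH-level practice; no per-bin fractionation data
   exist in a DVH). The default $\alpha/\beta$ is 3 Gy, a conventional
   value for late-responding muscle; it is a configuration knob
   (`alpha_beta`) because the appropriate value for deglutitive muscle is
   genuinely uncertain, and the run log records the value used.
3. **gEUD reduction.** The generalized mean
   $\left(\sum_i v_i D_i^a\right)^{1/a}$ collapses the histogram to one
   number. The default exponent is $a = 1$ — the arithmetic mean dose —
   because the constraints this package produces are stated in mean-dose
   units; the exponent is configurable per ROI (`geud_a`) for
   serial-behaving structures where a larger $a$ is defensible. The
   power-mean inequality guarantees the reduction is non-decreasing in $a$
   and bounded by the minimum and maximum bin dose, which the test suite
   checks property-style. Computation runs in log space so large exponents
   (e.g. $a = 50$) remain stable.

A differential bin's representative dose is the midpoint of its cumulative
interval — unbiased when dose is uniform within the bin, which is the only
assumption a binned histogram supports.

## The dose–response fit

The binary outcome is modelled as
$P(\mathrm{RAD}) = \mathrm{logit}^{-1}(\beta_0 + \beta_D D + \beta_{age}\,
\mathrm{age} + \sum_x \beta_x x)$, fitted by maximum likelihood with a
Newton–Raphson iteration written for this package (observed-information
covariance, two-sided Wald tests, Mann–Whitney AUC of the linear
predictor). Age is continuous, in years; decade strata are used only for
reporting, represented at ages 45, 55, 65 and 75 — the stratum midpoints
(75 for the open-ended `>=70` stratum, matching its observed center in
cohorts of this kind). Numerical choices:

- predictors are standardized internally, so convergence and the
  separation cap are scale-free; coefficients are back-transformed exactly;
- convergence requires the score's max-norm below `1e-8`, with step-halving
  and a Nelder–Mead restart as fallback;
- probabilities are clipped to `[1e-12, 1 - 1e-12]` inside likelihoods so
  `log(0)` never occurs;
- complete separation is reported as a classed error, detected two ways:
  a standardized coefficient exceeding 50 while the deviance is still
  falling, or a converged fit that predicts every outcome perfectly (the
  wide-margin case, where clipping flattens the score before the cap is
  reached). Both mean the likelihood is unbounded and no finite MLE exists.

The fit re-parameterizes, at any covariate profile, into $D_{50} =
-(\beta_0 + \sum \beta_x x)/\beta_D$ and normalized slope
$\gamma_{50} = \beta_D D_{50}/4$, the conventional two-parameter
description of an NTCP curve.

An ordinal (proportional-odds) variant is provided for a graded outcome.
The grade is coded as the number of distinct RAD criteria met (0, 1, 2+) —
one defensible choice among several, since event multiplicity and severity
are both plausible orderings; it is documented as an assumption, not a
finding. With two levels the model *is* the binary fit and is fitted as
such; with three or more it is fitted by `MASS::polr`.

## Covariate selection and diagnostics

Forward-stepwise selection starts from the dose-only base model and
greedily adds the candidate covariate that lowers BIC
($k\ln n - 2\ln L$) the most, stopping when none does. Ties break by
lowest BIC, then candidate-list order — deterministic by construction.
BIC rather than AIC because the goal is a parsimonious clinical model, and
BIC's $\ln n$ penalty is consistent for variable selection.

The per-ROI diagnostics table reports Wald p-values for the dose and age
coefficients, FDR-adjusted by Benjamini–Hochberg with the dose p-values of
all ROIs as one family and the age p-values as another — mirroring a
two-column, eight-muscle report. Wald (not likelihood-ratio) p-values are
used here because the table is per-coefficient; the stepwise path itself
compares whole models through BIC. Both the p-value type and the family
structure are configurable in the sense that the building blocks
(`benjamini_hochberg()`, `tidy()`) are exported.

## Bootstrap and constraints

Uncertainty comes from case resampling: `B` resamples of patients with
replacement (default `B = 2000`; the bundled pipeline demo uses 200 to
keep a laptop run short), refitting on each, flagging non-converged or
separated replicates, and excluding them from percentile (2.5/97.5) bands.
If more than half the replicates fail, the ensemble itself errors — a
model that unstable should not be summarised by bands. Percentile rather
than normal-theory intervals because replicate coefficient distributions
are skewed at low event counts.

Constraint inversion is closed-form,
$D(r) = (\mathrm{logit}(r) - \beta_0 - \beta_{age}\,\mathrm{age})/\beta_D$,
with a bisection solver available as a cross-check (`method =
"bisection"`); the two agree to well under `1e-6` Gy. When the model's
baseline risk at 0 Gy already exceeds the target, the closed form is
negative: the function warns with a dedicated condition class and the table
layer prints the cell as `"<10"`, the same floor convention used for any
constraint under 10 Gy — below that the model is extrapolating far outside
the observed dose range and a numeric value would feign precision. Tables
round to integer Gy for display and keep full precision in `dose_gy`.
Whether such a table should come from the point fit or a bootstrap summary
is an open design question; the package uses the point fit (the bootstrap
is attached to curves, where band width is interpretable) — the two
converge as the cohort grows.

## What the synthetic generator does and does not emulate

`simulate_cohort()` reproduces the *statistical structure* the analysis
assumes: decade-of-age proportions 19/49/23/9% with uniform ages within
strata (40–49, 50–59, 60–69, 70–80); eight deglutitive-muscle ROIs with
truncated-normal summary doses spanning roughly 10–75 Gy; coded clinical
covariates with marginal frequencies typical of a chemo-IMRT oropharynx
cohort (91% male, 65% cisplatin, 91% N2b–3); and a Bernoulli outcome driven
by one designated ROI's dose (default the mylo/geniohyoid complex, the
submental structure most strongly implicated in chronic RAD) through true
coefficients `(-7.3, 0.06/Gy, 0.033/yr)`. Those defaults put overall
prevalence near 11% at typical doses and give a ~2.7-fold odds increase
from age 45 to 75 — the qualitative regime of interest; they are
illustrative, not estimates of any real cohort.

What it does **not** emulate: multi-ROI causal structure (the outcome
depends on a single driver ROI, not a weighted combination); realistic
inter-ROI dose correlation beyond an optional shared patient-level shift
(`shared_dose_sd`); spatial or sub-ROI dose information; covariate–dose
confounding (larger tumors drive both nodal stage and constrictor dose in
real plans); or censoring and follow-up asymmetry. Passing tests therefore
demonstrate that the estimation and inversion machinery is correct under
the stated model, not that the model is correct for any real cohort.

`simulate_dvh()` produces a smooth sigmoidal cumulative DVH anchored at
exactly (0 Gy, 1) and (max, 0); it emulates the shape of a uniformly
irradiated ROI with penumbra, not the multimodal DVHs of structures
straddling a field edge.

## Test problem sizes

The suite exercises parameter recovery on 20 cohorts of n = 3000,
bootstrap band coverage on 100 cohorts of n = 1000 with B = 200, stepwise
selection on n = 1000–3000, and convergence of fitted constraints to their
generating values from n = 1000 to n = 4000 — sizes chosen so the whole
suite runs in a couple of minutes on one core while keeping Monte Carlo
error well inside the asserted margins (e.g. ≥ 88/100 nominal-95% coverage,
≥ 18/20 recovery within 3 SE).

## Known limitations

- The gEUD exponent and $\alpha/\beta$ are assumptions, not estimates; both
  are logged with every run because constraints shift with them.
- Mean-dose constraints inherit every limitation of DVH-level analysis: no
  sub-ROI spatial information, no account of which part of a muscle is
  spared.
- The logistic-with-covariates form implies a non-zero baseline risk at
  0 Gy; that is deliberate (chronic dysphagia has non-radiation causes) but
  it means very low constraint targets can be unreachable for older
  patients, which the `"<10"` flag makes explicit rather than hiding.
- Wald p-values are first-order; at 34 events across 300 patients they are
  adequate for ranking, less so for calibrated inference in the tails.
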