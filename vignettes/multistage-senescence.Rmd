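---
title: "Methods: the multistage-senescence model of cancer incidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the multistage-senescence model of cancer incidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stagesen)
```

## The model

Adult cancer incidence is modeled as the completion of `k` sequential,
discrete, stable cellular changes ("stages"), each occurring at the same
small annual rate `u`. The hazard of completing the last stage at age `t`
is then the Armitage–Doll power law `u^k t^(k-1) / Γ(k)`; generalizing
the factorial to the gamma function lets `k` be any positive real, which
matters because fitted stage numbers are rarely integers (e.g. 6.44 for
male adrenocortical cancer). The observed decline of incidence in the
oldest old is captured by one further parameter: a linear senescence
tumor-suppression term `(1 - b t)`, unity at the time origin and zero at
age `1/b`, giving

ASR(t) = (u^k / Γ(k)) · t^(k−1) · (1 − b t),  0 ≤ t ≤ 1/b.

For cancers of reproductive organs the stage clock is taken to start at
puberty, so `t` is age − 15 years (`onset_offset = 15` in
`model_params()`); for all other cancers `t` is age. Everything the
package derives — the peak of the curve at `(k−1)/(b k)`, the lifetime
cumulative probability `Pc = (u^k/Γ(k)) b^(−k) (1/k − 1/(k+1))`, the
`k/(k+1)` share of lifetime risk removed by the senescence term — follows
from this single expression.

Assumptions worth keeping in view: the stages are sequential and equally
fast (so `u` is a geometric mean if the real per-stage rates differ); the
data are cross-sectional rates, so period and cohort effects are folded
into the parameters; there is no competing-mortality correction, so `Pc`
is the lifetime risk a person would accumulate if they lived to age `1/b`.

## Two peak-age expressions

Two closed forms for the age of peak incidence are in circulation for
this model, and they disagree: `k/(b(k+1))` (exposed as
`peak_age_formula()`) is the maximizer of `t^k (1−bt)`, i.e. of the curve
with one extra power of `t`, while the true argmax of the incidence rate
`t^(k−1)(1−bt)` is `(k−1)/(bk)` (`peak_age_argmax()`). The illustrative
stage-vs-peak-age sequence (67, 76, 81, 87, 90 years for k = 2, 3, 4, 6,
8 at b = 0.0099) follows the first form; per-cancer tabulated model peak
ages follow the second (male bladder cancer: k = 9, b = 0.0098 gives
90.7 ≈ the tabulated 91.0). Both are exported; derived statistics in
`fit_series()` use the argmax form because they describe the fitted
curve itself.

## Rates and their standard errors

`compute_crude_rates()` forms crude rates per 100,000 person-years per
5-year bin. The standard error is Poisson, `sqrt(n)/PY × 1e5`; registry
tabulations rarely state more, and the inverse-variance weights of the
fit need exactly this. Two edge rules:

* zero-case bins get a *weighting* SE computed as if one case had been
  observed — otherwise their weight `1/SE²` is infinite — so they stay in
  the fit with low influence;
* bins with zero person-years are flagged invalid and excluded.

Aggregate "85+" populations are split into 5-year bins with
census-derived fractions (`infer_oldage_populations()`), conserving the
total exactly. The bin list includes 95–99: omitting it would leave a
hole in the pyramid. Observed peaks (`observed_peak()`) are restricted to
ages below 105, where single-digit populations make rates erratic, with
ties resolved toward the younger bin.

## Fitting

`fit_series()` minimizes the inverse-variance-weighted squared error
between observed rates and `1e5 · ASR(t)` over bins at or above the start
age, using Levenberg–Marquardt (`minpack.lm::nls.lm`). Choices that
matter:

* **Window.** Default start age 50, where case counts begin to rise;
  early-peaking exceptions THCA and CESC start at 30 and TGCT at 20
  (`default_start_age()`). All bins through 110+ are used: the old-age
  bins are what identify `b`.
* **Parameterization.** The amplitude is fit as `log a` (positivity for
  free, and it decorrelates the scale from `k`); `k` is bounded to
  (0.5, 20); `b` is unconstrained in sign — degenerate fits with `b ≤ 0`
  are real outcomes (male PCPG) and are reported, with `Pc` returned as
  NaN.
* **Support truncation in the objective.** The model rate is evaluated
  as `a t^(k−1) · max(1 − bt, 0)`. Without the truncation, bins beyond
  `1/b` — which in clean data hold zero cases and therefore carry the
  small substitute SE — would compare against large *negative* rates and
  dominate the objective, dragging `k` to its lower bound. A negative
  hazard is meaningless; zero is the model's statement there.
* **Multi-start.** The objective is multimodal in `(a, k)`. The initial
  `k` comes from the log-log slope of rate against time plus one, and the
  optimizer is restarted from that guess and ±2 (deterministic, so fits
  are exactly reproducible); the best deviance wins.
* **Inference.** Covariance is the Jacobian-based `(JᵀJ)⁻¹ · RSS/(n−3)`;
  `u = (a Γ(k))^(1/k)` and its SE follow by the delta method from
  `(log a, k)`; parameter P-values are two-sided Wald tests on `n−3`
  degrees of freedom (the fitting literature states no test; Wald on the
  NLS covariance is the minpack convention). Fits with P(u) or P(k)
  above 0.1 are flagged excluded (`apply_inclusion_rules()`), which also
  implements the colorectal substitution: the combined COADREAD row is
  dropped whenever COAD and READ enter separately, so colorectal cases
  are never double-counted.

Noise-free curves are refit to ≈1e-6 relative error; multiplying all SEs
by a constant leaves point estimates unchanged (only the reported
uncertainties scale).

## Cross-cancer statistics and inclusion sets

Every published summary depends on an exact row set, so the sets are
named data, not ad hoc filters (`select_subset()`): the core pooled
non-reproductive set drops LGG and PCPG (fits excluded by the P > 0.1
rule) and COADREAD (double-counting), leaving n = 21 with READ and
n = 20 without; the lifetime-risk sets additionally drop READ for
females only. Statistics are standard and delegated to base R: paired
and Welch t-tests, Spearman and Pearson correlations, unweighted OLS of
`u` on `k` (whose slope and negated intercept are the two-variable
constants `c` and `d`), ANCOVA slope/intercept comparisons, and Holm
step-down correction where a family of tests is requested together.

The combined "at least one cancer" lifetime risk uses the independence
complement rule `1 − Π(1 − Pc_i)` — the standard choice for an
"any" event, and it reproduces the published 41% (female) / 55% (male)
to within half a point on the packaged tables.

## The two-variable model and rounding sensitivity

With `b` nearly constant across non-reproductive cancers and `u` tightly
linear in `k` (`u = c·k − d`, c = 0.0046, d = 0.0087), incidence becomes
a function of age and stage number alone (`asr_two_variable()`). One
numerical caveat documented here because it shapes the tests: at `k = 2`
the transition rate `2c − d = 0.0005` is a near-cancellation, so the
±5e-5 rounding of the printed constants moves the predicted lifetime
probability by tens of percent. The package therefore checks the
two-variable lifetime probabilities at k = 3, 4, 6 (5% tolerance) and
k = 8 (13%, the propagated-rounding bound) and does not treat the k = 2
value as reproducible. For the same reason the refitted intercept `d`
is only expected to match to ~5%, while the slope `c` is stable.

## Driver-gene decomposition

`build_driver_table()` joins mean driver-mutation counts per tumor from
two published catalogs against fitted `k` (pooled-sex for
non-reproductive cancers, sex-specific for reproductive ones) and takes
the difference as "non-driver stages"; negative values are kept — they
are informative (endometrial cancer reports more driver mutations than
fitted stages). The driver-vs-k regression is unweighted OLS after
removing points whose *studentized* (leave-one-out standardized)
residual from a preliminary all-points fit is ≥ 3.0; on the packaged
table this removes exactly UCEC and reproduces the published line
y = 0.14 k + 0.86 with r = 0.42 (n = 26). The 95% interval reported by
`driver_fraction_summary()` is a population interval (mean ± 1.96 SD of
the per-cancer percentages), describing spread across cancer types, not
estimation error of the mean.

## The synthetic-registry generator

`simulate_registry()` draws per-bin case counts independently as
Poisson with mean `ASR(t) · PY`, per cancer, sex and 5-year bin, over a
census-like pyramid (`population_template()`: flat to age 60,
exponential decline to 85, and an 85+ aggregate split by old-age
fractions so the population-inference path is exercised). This matches
the cross-sectional structure the analysis assumes. It deliberately does
**not** emulate cohort or period effects, overdiagnosis dynamics,
shared-cohort correlation between bins, competing mortality, or a
susceptible subpopulation — so passing recovery tests demonstrates that
the estimation pipeline is faithful to its own model, not that the model
is true of any real registry.

Validation problem sizes, chosen as the regime the analysis targets: the
recovery experiments use ten million person-years per bin (the scale of
a pooled multi-registry extract), truth parameters across the fitted
range (k from 4 to 9, u on the `c·k − d` trend, b near 0.01), and 20
seeded replicates per cell; at that scale the median bias of `k` is
below 0.05 stages (the acceptance bound is 0.5), `b` is recovered to
±5e-6, and the full simulate → rates → fit → peak-age pipeline lands
within two years of the truth. At 1e5 person-years per bin the RMSE of
`k` is roughly ten times larger, which the tests assert as a sanity
check on the noise model.

## Known limitations

* Cross-sectional rates only: no age–period–cohort separation.
* Poisson SEs ignore the uncertainty of the inferred 85+ populations.
* `Pc` ignores competing mortality and so overstates attainable lifetime
  risk for late-peaking cancers.
* The equal-rate-per-stage assumption makes `u` a geometric mean; the
  strong `u`–`k` association admits other readings (e.g. slower early
  stages) that this package cannot distinguish.
* The packaged tables are transcriptions of printed, rounded values;
  statistics that amplify rounding (near-cancellations, high powers) are
  flagged above rather than asserted to printed precision.
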