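---
title: "From streetscape composition to physical-activity inference: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From streetscape composition to physical-activity inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem this package addresses

Urban-health studies increasingly score how neighbourhoods *look* — wealthy,
safe, lively, depressing, boring, beautiful — from street-view imagery, and
relate those perception scores to residents' physical activity (PA). The
measurement chain has three stages: (1) a human–machine scoring system in
which a regression model recommends a 0–10 score for an image and volunteers
correct it until the model's rolling error is small; (2) spatial aggregation
of image scores to sampling points (mean over camera headings) and then to
neighbourhood exposures (mean within a circular buffer around the
neighbourhood centroid); (3) a two-level random-intercept linear model of
weekly PA minutes on the six exposures plus individual covariates.

Real deployments of this chain rest on non-redistributable imagery and
private survey data, so nothing downstream is independently checkable.
`perceptPA` rebuilds the whole chain as tested, reusable code and couples it
to a synthetic-world generator whose every parameter is recorded, so each
stage can be validated by parameter recovery rather than by trusting printed
numbers.

## The synthetic world

**Scenes.** Each of `K = 12` object classes (a stand-in for the 150+ classes
a semantic segmentation would produce) gets a proportion of the image. Each
neighbourhood draws a mean composition from a symmetric Dirichlet with total
concentration 55; each image draws its composition from a Dirichlet centred
on the mean of its nearest centroid with total concentration 6.5. These two
constants were fixed once, from the Dirichlet moment formula, so that the
latent score SD is about 0.4 between neighbourhood means and about 1.1
between images — the between-neighbourhood figure matches the descriptive
neighbourhood-level spreads (0.2–0.4) reported for this kind of data, and
the image-level spread is large enough that a regressor can demonstrably
learn the score (a world with no image contrast would make every downstream
test vacuous).

**Latent perception.** Score = `clip(intercept + w·proportions, 0, 10)`.
The six weight vectors are orthonormal zero-sum contrasts scaled to
`sum(w^2) = 9K`; intercepts are set to the reported descriptive means (4.9,
4.7, 4.8, 6.3, 5.7, 3.9). Orthogonality keeps the six indicators jointly
identifiable from 35 neighbourhoods; real indicators are more collinear
(which is why the package always attaches a VIF report to Model 1).

**Raters.** A volunteer rating is the latent score plus Gaussian noise
(`rater_sd`, default 0.25 score units), clipped to [0, 10]. Ratings are kept
continuous; rounding to integers is a documented option we did not take, as
the source text is silent.

**Survey.** 35 neighbourhoods, Poisson(23) respondents each (~805 total).
Covariates are drawn independently at the published margins (51% female,
mean age 42.5, 82% married, income concentrated at 10–20k CNY/month, 4.1%
functionally restricted); no covariance structure is imposed because only
margins are reported. The outcome is generated from
`eta_ij = x_ij' beta + u_j + e_ij` with `u ~ N(0, 0.022)`,
`e ~ N(0, 0.141)` — the printed random part of the fitted total-PA model —
using each neighbourhood's TRUE (noise-free) perception scores.

**The outcome transform.** The published coefficients (perception effects
~1.0–1.6, constant 1.252) are numerically incompatible with raw weekly
minutes (mean 198.7): the fitted values would be two orders of magnitude off.
On the `log1p` scale, the same coefficients evaluated at the mean scores give
`eta ≈ 5.6`, i.e. `expm1(5.6) ≈ 260` weekly minutes — the right scale. The
generator and the models therefore default to `log1p`, with `identity`
available; this is a package design choice, the source never states its
transform.

**Fixed effects.** The generating coefficients are the published total-PA
estimates, with one deliberate exception: the non-significant "wealthy"
effect is set to an exact zero so that the type-I behaviour of the inference
machinery is testable. Five nonzero perception effects (+safe, +lively,
+beautiful, −depressing, −boring) carry the sign pattern of interest.

**IPAQ items.** Total weekly minutes are split into light/moderate/vigorous
shares (Dirichlet with means 0.51/0.22/0.26, matching the reported intensity
means) and each intensity is factored into (days/week, minutes/day): days
are truncated-Poisson on 1..7 (rate 4) for active intensities, minutes/day
is the rounded quotient. `days × minutes/day` reconstructs the intensity's
minutes to within `days/2 ≤ 3.5` minutes, preserving the questionnaire's
product identity.

## The scoring system

One independent bagged regression-tree ensemble (random forest; implemented
in C++ inside the package, since the deployment image carries no forest
library) per indicator, trained on an initial batch of oracle-rated scenes
(default 300). Calibration then alternates: the model recommends a score for
the next scene, the oracle corrects it, the pair joins the training set, and
the forest is refit every 25 corrections (a runtime compromise with the same
limiting behaviour as refitting each time; configurable down to 1). The loop
stops when the rolling RMSE between recommended and corrected scores over
the last 100 images drops below the threshold, or after
`max_calibration_images`.

The deployed system's printed stopping rule — RMSE below 5 on a 0–10 scale —
would accept a near-random model; whether the underlying scale was 0–100 is
unknowable from the text. We therefore default the synthetic threshold to
0.5 (twice the rater noise) and keep the printed value available in
configuration as the documented "paper mode". Predictions are always clipped
to [0, 10], the declared scale. Validation scores a disjoint holdout
(default 100 images) against fresh oracle ratings and reports Pearson r with
its p-value; in the synthetic default world r is typically 0.94–0.97,
the qualitative analogue of the r = 0.96–0.98 reported on real imagery.

## Aggregation

Point score = arithmetic mean of the (up to four) heading scores; missing
headings are averaged over what exists and flagged rather than dropped.
Neighbourhood exposure = mean of point scores within a circular buffer of
the configured radius (default 1 km, sensitivity 1.5 km) around the
centroid. Distances are planar Euclidean — the synthetic world lives in
projected metres — and the boundary is inclusive ("within" read inclusively;
measure-zero decision). Points may serve several overlapping buffers, as
real buffers do. One consequence worth knowing: with 1 km buffers over a
~900 m neighbourhood layout, adjacent neighbourhoods share many points, so
the *aggregated* true scores have between-neighbourhood SD ~0.15–0.2 rather
than the 0.4 of the underlying neighbourhood means. This spatial smoothing
is exactly the modifiable-areal-unit problem the design inherits; the
recovery experiments condition on the aggregated truth, so it does not bias
the coefficient checks.

## The mixed model

`y_ij = x_ij' beta + u_j + e_ij`, `u_j ~ N(0, sigma2_u)`,
`e_ij ~ N(0, sigma2_e)`. Estimation profiles the (restricted) log-likelihood
over the variance ratio `lambda = sigma2_u / sigma2_e`: all group-wise
quantities reduce to closed-form cross products because
`V^{-1}` is block diagonal with `W_j = I − lambda/(1 + lambda n_j) 11'`;
a one-dimensional bounded optimisation on `log(lambda)` plus an explicit
`lambda = 0` boundary candidate gives the optimum (so no negative variance
estimates ever arise), GLS gives `beta`, and standard errors come from the
inverse weighted cross-product. The implementation agrees with `lme4` and
with a dense brute-force oracle to ~1e-6 in log-likelihood on test
instances.

Inference is by normal (z) Wald tests with stars at p < 0.10 / 0.05 / 0.01
(strict inequalities), matching the reporting convention of the field; no
Satterthwaite correction is applied. A consequence the tests quantify: with
35 clusters the 0.05 test of a neighbourhood-level coefficient has true size
around 0.065–0.08 (z ignores the ~28 effective degrees of freedom). The
acceptance suite checks the type-I rate against a central 99% binomial
region around 0.05, which the observed rate meets, but users analysing
few-cluster data should know the z convention is mildly anti-conservative.

`AIC = −2 logLik + 2 (p_fixed + 2)`: both variance components are counted,
a stated convention since the source's is unrecoverable — AIC values are
comparable within this package only. Missing rows are deleted listwise with
the count recorded on the fit. Rank-deficient designs raise an error naming
the aliased columns; a corollary the tests exercise is that the full
six-indicator model needs at least eight neighbourhoods (intercept plus six
group-level columns from J groups).

`ICC = sigma2_u / (sigma2_u + sigma2_e)`; `VIF_k = 1/(1 − R²_k)` per
predictor, with exact collinearity reported as a flagged `Inf` rather than
an exception, and both the maximum and mean reported because the source's
single printed VIF is not attributable to either.

## The analysis suite and the recovery experiments

`run_model_suite()` fits seven REML models, all with the six indicators
jointly plus the full covariate set: Model 1 (total PA, 1 km), Model 2
(excluding functionally restricted respondents), Model 3 (excluding age >
70), Model 4 (1.5 km buffers), Models 5–7 (light/moderate/vigorous PA).
When a filter removes all contrast from a covariate (e.g. Model 2 and the
restriction indicator) the term is dropped and recorded, which also makes
the no-op-filter identities (`Model2 ≡ Model1` when nobody is restricted,
etc.) hold exactly.

`parameter_recovery_experiment()` regenerates world → truth → survey per
replicate and refits Model 1 with TRUE exposures: per-coefficient bias,
RMSE, 95% CI coverage, sign recovery among estimates significant at 0.10,
and the type-I rate of the true-zero wealthy effect. With
`use_scoring = TRUE` the exposures instead pass through the full adversarial
scoring pipeline, making the experiment end-to-end; the acceptance suite
runs 100 such replicates at reduced image counts (spacing 150 m, initial
batch 150, calibration cap 600, 60 trees) — a pure runtime reduction; noise
levels and effect sizes stay at their defaults. A separate
`icc_recovery_experiment()` uses a null-effect world (intercept
`log1p(198.7)`, variance components at ICC 0.137) so the ICC target is not
contaminated by neighbourhood-level fixed effects.

A further monitored property: raising `rater_sd` over {0.25, 1.5, 3} never
increases the average standardised perception effect — the classical
attenuation of regression coefficients under exposure measurement error,
demonstrated end-to-end. Standardised (not raw) effects are compared
because the forest's regression-to-the-mean compresses the exposure scale,
which would confound raw-coefficient comparisons.

## Determinism

Every pipeline stage derives its seed from the single master seed via a
fixed integer schedule; `run_all()` with the same seed writes byte-identical
output trees (wall-clock timings go to stderr only, never into files).

## What a green test does and does not establish

Green tests establish that the chain is internally correct: the estimator
matches independent oracles, aggregation is exact, the scoring loop learns a
learnable world, and generated parameters are recovered without material
bias. They do not establish anything about real streetscapes: the synthetic
compositions are Dirichlet (real segmentations have spatial and semantic
structure), covariates are independent (real ones are not), the latent
perception function is linear, raters are exchangeable with homoscedastic
Gaussian noise, and the causal questions (self-selection, ecological
fallacy) are untouched, as they are in the source design. Known limitations
beyond these: no respondent-specific buffers, planar geometry only, no
random slopes or non-Gaussian outcomes.
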