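---
title: "Longitudinal breast density: model, estimation and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal breast density: model, estimation and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longdens)
```

## Why a longitudinal density measure

BI-RADS breast composition is recorded at essentially every screening
mammogram, making it the density measure most widely available for risk
models. It is also coarse (four categories) and noisy (inter- and
intra-reader variability). A woman's screening history therefore contains
repeated, error-prone measurements of a slowly evolving trait. `longdens`
treats them exactly that way: a linear mixed model describes the
population trajectory of density over age and BMI, and each woman's
current density is predicted by combining her own reading history with the
population surface through empirical Bayes. The result is a continuous,
per-screen density estimate that is more stable between visits than any
single reading and usable wherever a BI-RADS value would be.

## The mixed model

For woman $i$ at screen $j$, the reading $y_{ij}\in\{1,2,3,4\}$ is
modelled as a continuous Gaussian outcome

$$y_{ij} = x_{ij}^\top\beta + z_{ij}^\top b_i + \varepsilon_{ij},
\qquad b_i \sim N(0, G),\qquad \varepsilon_{ij}\sim N(0,\sigma^2),$$

with fixed-effect design
$x_{ij} = (1, a, a^2, a^3, a^4, \mathrm{BMI}, a\cdot \mathrm{BMI})$, where
$a = \mathrm{age}/5 - c$ is age in 5-year units centred at a constant $c$,
and random-effect design $z_{ij} = (1, a)$ — a per-woman intercept and age
slope with unstructured covariance $G$. The quartic age polynomial lets
the population curve bend through the menopausal transition; the age×BMI
interaction (linear age only) lets the BMI gradient change with age.

Treating an ordinal reading as continuous is a deliberate approximation:
it makes the empirical-Bayes predictor linear and closed-form, and the
evaluation layer never uses the Gaussian likelihood for inference about
individual women, only the point predictions. An ordinal-probit variant is
out of scope.

**Tunable parameters.**

* `centering` ($c$, default 10, i.e. age 50): has no effect on fitted
  values (tested to $10^{-6}$), only on conditioning of the quartic; 50 is
  mid-cohort.
* Winsorization bounds 15 and 35 kg/m²: BMI outside this range is capped
  so extreme adiposity does not extrapolate the linear BMI effect.
* BMI imputation: baseline missingness is filled with the mean observed
  baseline BMI in 5-year baseline-age bins (the bin width is a package
  choice; results are insensitive to it at widths 2–10), follow-up
  missingness by last observation carried forward.
* Eligibility: baseline age 40–73 and at least 6 months of follow-up,
  applied after dropping screens without a reading.

## Estimation

The marginal likelihood is maximised directly. For each woman
$V_i = Z_i G Z_i^\top + \sigma^2 I$; all per-woman quantities reduce to
sufficient statistics ($Z_i^\top Z_i$, $Z_i^\top X_i$, $Z_i^\top y_i$,
totals of $X^\top X$, $X^\top y$, $y^\top y$), so one likelihood
evaluation is $O(\text{women})$ with closed-form 2×2 algebra via the
Woodbury identity. $\beta$ is profiled out by GLS at every
variance-component candidate; $G$ is parameterised by its Cholesky factor
(so $G \succeq 0$ by construction, including the boundary $G = 0$), and
$\sigma^2$ by its logarithm. The four-dimensional profile surface is
maximised by BFGS with an analytic gradient (envelope theorem: the
$\beta$-score vanishes at the GLS solution), then polished by Newton steps
until the gradient is below $10^{-10}$. The tight polish is what makes
fitted values agree across centering constants to $10^{-6}$ — the flat
directions of the variance surface otherwise leave parameterisation-sized
wobble in predictions. If every woman has a single screen, $G$ is
unidentified; the fit proceeds and flags it.

Standard errors for $\beta$ use the cluster-robust sandwich
$A^{-1} B A^{-1}$ with $A=\sum_i X_i^\top V_i^{-1}X_i$ and
$B=\sum_i s_i s_i^\top$, $s_i = X_i^\top V_i^{-1} r_i$; a full 11-parameter
version (β, the three Cholesky parameters, $\log\sigma^2$) is available by
numerical differentiation of per-woman log-likelihoods.

## The empirical-Bayes density and its categories

With parameters in hand, the posterior of $b_i$ given screens $1..k$ is
$\hat b = G Z^\top V^{-1}(y - X\beta)$ with covariance
$G - GZ^\top V^{-1}ZG$; computationally both are evaluated through
$L = \mathrm{chol}(G)$ and $K = I + L^\top Z^\top Z L/\sigma^2$ as
$\hat b = \sigma^{-2} L K^{-1} L^\top Z^\top r$, which is exact for
singular $G$. The sequential estimates for a whole cohort use within-woman
cumulative sufficient statistics, so the entire pass is vectorised.

Decisions worth stating explicitly:

* The estimate at screen $k$ **includes** that screen's reading ("data
  observed so far" reads as inclusive); an exclusive variant is available
  (`inclusive = FALSE`) for sensitivity.
* Predictions are **not clipped** to [1, 4]; the top and bottom categories
  are open-ended, so the categorical measure absorbs the tails.
* The fixed part is evaluated at the **current** (imputed/winsorized) BMI;
  historical rows use their own contemporaneous BMI. A forecast of the BMI
  trajectory would be an alternative; current-BMI is the convention here.
* Categories are left-closed, right-open: a value exactly on a cut point
  goes up. Cut points are derived from the baseline distribution so that
  category pairs 1–2, 3–4, 5–6, 7–8 reproduce the baseline BI-RADS A–D
  proportions with an equal split inside each pair, using type-1
  (inverse-ECDF) quantiles. If a baseline category is empty the derived
  cuts contain ties; this degenerate output is flagged with a warning. The
  bundled reference cuts (1.5, 2.0, 2.2, 2.6, 2.9, 3.2, 3.6) are only
  meaningful together with a parameter file on the same scale, and are
  re-derived whenever the model is refit.

## Survival evaluation

Risk intervals are counting-process rows on the follow-up time scale
(years since baseline exam). Women enter 6 months after baseline (the lag
guards against prevalent disease); covariates are piecewise constant,
updated at each screen (left-closed attribution: at time $t$ the latest
screen at or before $t$ applies); the last interval carries the event
indicator. Follow-up time, not attained age, is the time scale, with
baseline age as a covariate — consistent with adjusting for age at entry.

Three density models are fitted, each adjusted for age at the entry screen
(per year) and time-varying BMI (per kg/m²):

1. BI-RADS as a 4-level factor, reference "Scattered" (level 2) — 3 df;
2. continuous longitudinal density, linear + quadratic — 2 df;
3. the eight-category measure as a factor, reference category 3 — 7 df.

Density terms enter uncentred so hazard ratios read "per unit"; centring
them changes no likelihood (tested). The partial likelihood is maximised
by Newton–Raphson with step halving; Efron tie handling is the default
(continuous simulated times make ties rare), Breslow is available.
Directions with no information (e.g. a covariate that never varies in any
risk set) are handled by a pseudo-inverse step rather than an error; a
coefficient diverging past ±30 is reported as separation, naming the
covariate. Information gain is $\Delta LR\text{-}\chi^2 = 2(\ell_{\text{model}}
- \ell_{\text{age+BMI}})$. A secondary analysis starts follow-up at the
third mammogram (`start_at_screen = 3`; age at the third mammogram becomes
the age adjustment; women with fewer screens drop out), optionally with
covariates frozen at their entry-screen values (`frozen_at_entry`) — the
non-updated variant.

**Concordance.** The yearly at-risk concordance yC uses windows
$[t, t+1)$ starting at $t = 0.5$: every event in the window is compared
with every woman at risk at the event time without an event then, using
current linear predictors; ties count ½ (which keeps the noise limit at
exactly 0.5). Windows are summarised by the pair-weighted mean (an
equal-weight variant exists behind `weight = "equal"`); per-window
standard errors come from the per-event clustered U-statistic variance.
This windowed incident/dynamic definition with current covariate values is
this package's definition, stated here because "concordance" admits many
variants. Model comparison bootstraps whole women (intervals within a
woman are dependent), with a percentile interval; resampling is
deterministic under a fixed seed.

**Stability.** For women with ≥3 screens, the density contribution to the
linear predictor at screens 2 and 3 (factor hazard ratios for BI-RADS;
linear+quadratic terms for the longitudinal measure, both from the
full-cohort fits) gives each woman a relative risk at each screen. Each
screen's risks are normalised to mean 1 across women, and the measure of
instability is the fraction of women whose ratio (screen 3 / screen 2)
leaves $[4/5, 5/4]$ — the band within which a 10-year risk classification
would typically not change.

## The simulator

`simulate_cohort()` generates cohorts whose observable statistics match a
large US screening population: baseline ages uniform on 40–73; inter-screen
gaps ~N(1.8, 0.5²) years; a 5% per-visit stopping probability combined
with a right-skewed potential-follow-up draw (19 yr administrative horizon
scaled by Beta(1, 2.2), censored at age 75) gives a median of 3 screens
per woman, roughly a quarter with a baseline screen only, and a median
follow-up near 5 years; BMI starts near 27 kg/m², drifts upward, and is
missing for ~5% of baseline and ~16% of follow-up screens (exercising the
imputation path). Latent density is $x^\top\beta + z^\top b$ with defaults
(intercept 3.7, BMI gradient −0.04, age decline, intercept SD 0.67, total
SD ≈ 0.8) chosen so that rounded-and-clipped readings give approximately
8/35/43/14% A/B/C/D at baseline. Event times are piecewise-exponential
with hazard $0.003\,e^{1.71(d-2.6) - 0.19(d^2-2.6^2) + 0.05(\text{age}_0-50)
+ 0.005(\text{BMI}-27)}$ driven by the **true latent** density $d$ — the
regime in which smoothing noisy readings should pay off — yielding ~2%
cumulative incidence.

What the simulator does *not* emulate: calendar effects, radiologist or
machine random effects, hormone-therapy dynamics, menopause as an event
(age enters smoothly), DCIS or death as competing risks, and real
BI-RADS reader behaviour (readings are a rounded Gaussian, so the
discretisation error is symmetric and homoscedastic, which real readers
are not). Passing tests on simulated cohorts therefore demonstrates
correctness of the machinery and the qualitative measurement-error
phenomenon, not clinical performance on any real population.

## Validation design and problem sizes

The test suite validates every layer against an independent route:
marginal log-likelihoods against dense multivariate-normal evaluation;
posteriors against dense BLUP algebra (100 randomized women, 1–10
screens, agreement to $10^{-8}$) and a two-dimensional grid-integration
Bayes oracle ($10^{-4}$); ML fits against parameter recovery on
continuous-outcome cohorts (20 replicates of 2000 women; every parameter
within 3 Monte-Carlo standard errors) and against `nlme::lme`; the Cox
fitter against a grid-search maximizer and `survival::coxph`
(20 randomized datasets, $10^{-6}$); concordance against an explicit
double-loop count (exact equality) and the 0.5 noise limit; the simulator
against closed-form exponential event fractions and rounding-cell
probabilities. The model-comparison study uses 20 replicates of 5000
women. At ~2% incidence that is roughly 95 events per replicate, and a
caveat belongs here: with so few events the *difference* in information
between two density models is itself noisy (its between-replicate spread
is comparable to its mean, and even an oracle handed the true latent
density does not win every replicate), so single-replicate comparisons of
ΔLR-χ² should be read qualitatively. The stability contrast, by contrast,
uses every woman with three screens (~2700 per replicate) and is sharp:
the longitudinal measure's instability fraction is consistently a third
to a half of the BI-RADS one.

## Known limitations

* The Gaussian treatment of an ordinal outcome attenuates variance
  components when readings are discretised (visible and expected in the
  simulator's recovery checks with discretisation on).
* The measure assumes the mixed model's age–BMI surface is transportable
  to the woman being scored; a parameter file fitted on one population
  applied to another inherits that population's calibration.
* Absolute risk (baseline hazard) is deliberately out of scope; all
  survival outputs are relative.
* The stability band $[4/5, 5/4]$ is a convention, not an estimate.
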