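# longdens

Longitudinal breast density estimation from serial BI-RADS readings, with a
full predictive-evaluation suite for breast cancer risk.

## The problem

BI-RADS breast composition (A = almost entirely fat … D = extremely dense,
coded 1–4) is one of the strongest routinely collected breast cancer risk
factors, but a single reading is noisy: radiologists disagree with each
other and with themselves, and a woman's density also drifts with age, BMI
and menopause. Risk models that plug in the latest reading inherit that
noise — a woman whose reading flips between B and C flips risk category
with it.

`longdens` implements a longitudinal alternative: treat the reading
history as repeated measurements of a smooth underlying trajectory and
estimate, at every screen, the woman's current density from *all* readings
observed so far, borrowing strength from the population age–BMI surface.

## The model

Readings are modelled with a linear mixed model on the 1–4 scale,

y_ij = x_ij' β + z_ij' b_i + ε_ij,&emsp;b_i ~ N(0, G),&emsp;ε_ij ~ N(0, σ²),

where x_ij = (1, a, a², a³, a⁴, BMI, a·BMI) with a = age/5 centred
(a quartic age polynomial, BMI per kg/m², and an age×BMI interaction),
and z_ij = (1, a) gives each woman a random intercept and age slope with
unstructured 2×2 covariance G. The model is fitted by maximum likelihood
(β profiled out by GLS; G through its Cholesky factor; analytic-gradient
quasi-Newton), with cluster-robust sandwich standard errors.

The **continuous longitudinal density** at screen k is the empirical-Bayes
(BLUP) prediction using screens 1..k:

d̂_ik = x_ik' β̂ + z_ik' b̂_i(k),&emsp; b̂_i(k) = G Z' V⁻¹ (y − Xβ̂),

which shrinks noisy histories toward the population surface — a woman's
first screen is informed by every other woman of her age and BMI. An
eight-category version is derived with cut points chosen so the baseline
proportions in category pairs 1–2, 3–4, 5–6, 7–8 match baseline BI-RADS
A–D, split equally within each pair.

Predictive value is assessed exactly as a screening-cohort analysis would:

* time-varying-covariate Cox models (counting-process form, Efron ties) for
  three density measures — BI-RADS as a 4-level factor, continuous
  longitudinal density (linear + quadratic), and the eight-category
  measure — each adjusted for baseline age and time-varying BMI;
* likelihood-ratio information gain ΔLR-χ² over the age+BMI-only model;
* a yearly at-risk concordance index (yC) with cluster bootstrap;
* a stability analysis: the fraction of women whose normalised relative
  risk ratio from second to third mammogram leaves the stable range
  [4/5, 5/4].

Because real screening cohorts of this kind are access-restricted, the
package ships a cohort simulator with known generative truth (latent
density trajectories, rounded-and-clipped readings, proportional hazards
driven by the *true* latent density) so every stage is testable end to end.

## Worked example

```r
library(longdens)

sim    <- simulate_cohort(sim_config(n_women = 2000, seed = 42))
cohort <- preprocess_cohort(sim$cohort)   # eligibility, BMI imputation, winsorization
fit    <- fit_lmm_ml(cohort)
print(fit)
#> Linear mixed model for BI-RADS density (ML)
#>   1884 women, 6186 screens, log-likelihood -5908.862
#>   beta: 3.5102 -0.0764 -0.0067 0.0061 -0.0009 -0.0335 0.0004
#>   G: [0.4090 -0.0089; -0.0089 0.0063], sigma2 = 0.2255

est  <- sequential_estimates(cohort, fit$params)
cuts <- derive_cutpoints(est$value[est$n_obs_used == 1],
                         cohort$screens$birads[!duplicated(cohort$screens$woman_id)])
est$category8 <- categorize(est$value, cuts)

dm <- density_models(cohort, est)
dm$delta
#>        model delta_lr df
#> 1     birads 17.68905  3
#> 2 continuous 20.43416  2
#> 3  category8 20.22786  7
```

The `delta` table is the information gain of each density model over the
age+BMI-only Cox model: here the continuous longitudinal measure adds more
likelihood-ratio information (20.4 on 2 df) than raw BI-RADS (17.7 on
3 df) even though it spends fewer degrees of freedom — the qualitative
signature of measurement-error smoothing. Concordance follows the same
pattern:

```r
lp_b <- cox_linear_predictor(dm$birads, dm$intervals)
lp_c <- cox_linear_predictor(dm$continuous, dm$intervals)
yearly_concordance(dm$intervals, lp_b)$mean_yC   # 0.756
yearly_concordance(dm$intervals, lp_c)$mean_yC   # 0.764
```

A command-line pipeline (`simulate | fit | predict | evaluate | report`)
over YAML configs is at `inst/cli/longdens.R`.

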