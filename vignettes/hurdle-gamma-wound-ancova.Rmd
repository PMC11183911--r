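---
title: "A Bayesian hurdle-Gamma ANCOVA for wound-closure endpoints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Bayesian hurdle-Gamma ANCOVA for wound-closure endpoints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(woundhurdle)
```

## The problem

Chronic-wound studies (for instance diabetic foot ulcers treated with
amnion–chorion allografts) typically record a baseline wound area and an
endpoint area around 12 weeks. The endpoint is *semicontinuous*: a point mass
at exactly zero (the wound closed) and a right-skewed positive distribution
for wounds still open. Two clinically meaningful summaries are

* **Ψ**, the marginal probability of full closure, and
* **xPAR**, the expected percent area reduction,
  $100 \cdot E[(\mathrm{pre} - Y)/\mathrm{pre}]$, where a closed wound
  contributes a 100% reduction and a grown wound a negative one.

`woundhurdle` estimates both, per treatment arm and as an arm contrast, from
a Bayesian hurdle-Gamma analysis of covariance.

## The model

For subject $i$ with arm indicator $g_i \in \{0, 1\}$ (1 =
retention-processed graft), baseline area $\mathrm{pre}_i$ (standardized to
$z_i$ by the sample mean and SD) and endpoint area $y_i \ge 0$:

$$
I(y_i > 0) \sim \mathrm{Bernoulli}(\pi_i), \qquad
\operatorname{logit}(\pi_i) = \alpha + \beta g_i + \gamma z_i
$$

$$
y_i \mid y_i > 0 \sim \mathrm{Gamma}(k,\, k/\mu_i), \qquad
\log(\mu_i) = \theta + \delta g_i + \varepsilon z_i
$$

$\pi_i$ is the probability the wound is *open*; Ψ is one minus its
baseline-averaged value. The Gamma is parameterized by its mean $\mu_i$ and
shape $k$ (rate $k/\mu_i$), so $E[Y \mid \text{open}] = \mu_i$ exactly — this
makes the xPAR computation closed-form per posterior draw. The ANCOVA
structure (baseline as covariate in both components) is what gives the
comparison its precision: the baseline explains part of the endpoint
variance, shrinking the posterior of the group effect $\delta$, a property
the test suite checks directly against the unadjusted two-group model.

Note the model describes the *endpoint area itself*, not the pre–post
difference: a Gamma cannot support the negative differences produced by
healing wounds, so percent reduction is always a derived quantity, never the
response.

### Priors

"Uninformative, scaled to the data" is made concrete as: Normal(0, 2.5)
on all standardized-scale slopes (logit and log), intercepts anchored at
empirical values — the logit of the observed open fraction, and the mean log
positive area with scale $2.5 \times \mathrm{SD}(\log y^+)$ — and
half-Normal(10) on $k$. On standardized predictors these are weakly
informative in the usual sense; prior-predictive closure probabilities span
essentially (0, 1). All scales are overridable through `prior_spec()`.

### Sampling

The posterior is sampled with an adaptive random-walk Metropolis sampler
written for this package: a BFGS search locates the posterior mode and the
inverse Hessian (Laplace approximation) seeds the proposal covariance and
disperses the chain starts; during warmup the covariance is refined from the
chain history (Haario-style) and a global scale follows a Robbins–Monro
recursion toward an acceptance rate of 0.3, near-optimal for random-walk
proposals; after warmup the kernel is frozen, so retained draws come from a
fixed, valid Metropolis chain. Defaults are 4 chains × 1000 retained draws
(4000 total) after 1000 warmup iterations, with 5 post-warmup transitions per
retained draw (`thin`) to keep autocorrelation modest — the diagnostics report on a
study-scale fit shows bulk ESS of several hundred per parameter out of 4000
retained draws and split-R̂ close to 1. "Divergences" here
count post-warmup proposals at which the log posterior was non-finite
(normally zero); they are reported, never filtered.

Because the sampler is seeded explicitly and chains run sequentially from
one RNG stream, a fixed `fit_config(seed=)` reproduces a fit bit-for-bit.

## Marginal effects by g-computation

Ψ and xPAR are population-level quantities, so per posterior draw the model
predictions are averaged over the **pooled** empirical baseline distribution
(both arms) under a counterfactual arm assignment:

$$
\Psi(\text{draw}, g) = 1 - \tfrac1n \sum_i \pi_i(g), \qquad
\mathrm{xPAR}(\text{draw}, g) = \tfrac{100}{n} \sum_i
  \left[(1 - \pi_i(g)) + \pi_i(g)\,(1 - \mu_i(g)/\mathrm{pre}_i)\right]
$$

Standardizing over the pooled baselines means an arm's value depends on the
arm only through the parameters — baseline imbalance between arms cannot leak
into the contrast, which is the point of adjusting for baseline in the first
place. Intervals are equal-tailed central 95% posterior intervals (not HPD).
Per draw, xPAR is bounded above by 100 and may be negative; it is never
truncated. `expected_par(mc_per_draw = )` switches to simulating endpoint
areas instead of the closed form; it exists purely as a Monte-Carlo
cross-check and agrees within simulation error.

## The synthetic cohort generator

The EHR data behind the motivating study are not available, so validation is
simulation-based. `generate_cohort()` draws from exactly the model above plus:

* **Baseline areas**: Gamma with mean 15.5 cm² and shape 1.6 (right-skewed,
  upper tail into the tens of cm², matching the reported per-arm means of
  14–17 cm²), *left-truncated at 1 cm²*. The truncation has a clinical
  reading — wounds below a square centimeter would not receive graft
  therapy — and a numerical one: xPAR divides by the baseline area, and an
  untruncated shape-1.6 Gamma occasionally yields areas near zero whose
  $\mu/\mathrm{pre}$ terms reach thousands of percent, making the empirical
  g-computation average meaninglessly heavy-tailed. Linear predictors use the
  truncated distribution's own mean and SD as standardization constants.
* **Counts**: applications and treatment days are negative binomial
  (variance $\mu + \mu^2/\phi$) with arm means (7.9, 10.6) and (68.2, 77.3)
  and dispersions 20 and 10, independent of the area process (the motivating
  analysis models them by separate ANOVAs; no joint model is described
  anywhere). Zero draws are floored at one — every treated subject has at
  least one application — which shifts the means by under 0.2% at these
  parameter values.
* **Demographics**: age and sex are generated as passthrough columns and
  never modeled.
* Closure is an exact zero endpoint area; there is no "almost closed"
  threshold. Areas are recorded to $10^{-4}$ cm² so CSV round trips are
  exact; open wounds are floored at $10^{-4}$ so rounding cannot silently
  close them.

`calibrate_to_targets()` solves $(\alpha, \beta)$ and then $(\theta,
\delta)$ by one-dimensional root finding so that the *population* closure
probability and xPAR per arm (computed by a deterministic 4096-node
quantile-midpoint quadrature over the truncated baseline distribution) hit
requested targets; `default_calibration_targets()` carries the published
point estimates — closure 0.740 / 0.738 and xPAR 52.6% / 67.3% for the
lamination- and retention-processed arms. Both marginal quantities are
monotone in their intercepts, so the solves are well posed; infeasible
targets (e.g. closure indistinguishable from 1) raise an error naming the
offending target. The remaining generator parameters — hurdle and area
baseline slopes 0.5 and 0.4 per baseline SD, Gamma shape 1.2 — were chosen
once as plausible for chronic-wound data: sizeable but not dominant baseline
effects, and strongly right-skewed open-wound areas.

## What the simulations do and do not show

Parameter-recovery and calibrated-recovery tests demonstrate that the
pipeline is *self-consistent*: data generated from the model, at sample
sizes (500/arm) where the posterior is informative, give back the generating
parameters and the calibrated population targets. They cannot show that real
EHR wound data follow a hurdle-Gamma law, that the 12-week endpoint is
measured without error, or that treatment assignment in a retrospective
cohort is unconfounded beyond the baseline-area adjustment. The generator
also simulates counts independently of areas, so it cannot probe violations
of that independence.

## Numerical choices and problem sizes

* Calibration quadrature: 4096 nodes; root finding by `uniroot` on
  $[-25, 25]$ with tolerance $10^{-10}$; achieved targets re-verified to
  $10^{-4}$.
* Degenerate diagnostics inputs: zero-variance chains report R̂ = 1 and
  ESS = total draw count by convention rather than erroring, so constant
  (pinned) parameters in unadjusted fits do not crash reporting; ESS is
  clipped at 1.25 × total draws with a warning.
* Validation of cohort files is fail-fast with row/column references;
  missing endpoint areas are an error, never imputed.
* Test problem sizes were chosen as the smallest that make each property
  sharply testable: 500–2000 subjects/arm for recovery, $10^5$ subjects for
  generator marginals, 20 replicate fits for interval calibration, 10 seeds
  at 200/arm for the ANCOVA precision property.

## Known limitations

* The sampler is a random-walk Metropolis: adequate for this 7-parameter
  posterior (verified by R̂/ESS), but not a general-purpose replacement for
  gradient-based samplers in higher dimensions.
* Single endpoint per subject; no trajectory modeling between baseline and
  endpoint, no censoring, and no covariates beyond arm and baseline area.
* The count ANOVAs share one dispersion across arms (a per-arm option is the
  obvious extension; the shared form is the simplest reading of "similarly
  fit" ANOVA structure).
* The published "Variance" rows for the auxiliary models are reported here
  as the model dispersion parameter, clearly labeled — their original
  definition is ambiguous (the printed values are impossible as raw-scale
  variances under the stated likelihoods).

## A worked run

```{r example, eval = FALSE}
params <- default_generative_params()
cohort <- generate_cohort(params, n_per_arm = c(23, 18), seed = 7)
design <- build_design(cohort)
fit <- fit_hurdle_ancova(design, config = fit_config(seed = 1))
mcmc_report(fit)
expected_par(fit, design, arm = 1)
closure_probability(fit, design, arm = 1)
group_contrast(fit, design, "xPAR")
report <- run_report(cohort, config = fit_config(seed = 1), draws = fit)
write_report(report, "report.txt", "text")
```
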