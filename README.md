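# woundhurdle

Bayesian comparison of two wound-care treatments on a semicontinuous
wound-area endpoint. Chronic-wound studies record a baseline area (cm²) and
an endpoint area at ~12 weeks that is either exactly zero (closed) or a
right-skewed positive value — a shape no single standard likelihood fits.
`woundhurdle` implements the hurdle-Gamma analysis of covariance for this
endpoint, for biostatisticians analyzing two-arm wound cohorts and for
methodologists who want a fully simulatable, testable version of the model.

## The model

For subject *i* with arm *gᵢ* ∈ {0, 1} (1 = retention-processed graft,
0 = lamination-processed), standardized baseline *zᵢ*, endpoint area
*yᵢ* ≥ 0:

```
I(yᵢ > 0) ~ Bernoulli(πᵢ),        logit(πᵢ) = α + β gᵢ + γ zᵢ
yᵢ | yᵢ>0 ~ Gamma(k, k/μᵢ),       log(μᵢ)  = θ + δ gᵢ + ε zᵢ
```

Posterior draws (adaptive-Metropolis MCMC, 4 chains × 1000 draws, Laplace
preconditioning, rank-normalized split-R̂ / bulk-ESS diagnostics) are turned
into the clinical quantities by g-computation over the pooled empirical
baselines:

* **Ψ** — marginal probability of full closure, `1 − mean(πᵢ)` per draw;
* **xPAR** — expected percent area reduction,
  `100 · mean[(1−πᵢ) + πᵢ(1 − μᵢ/preᵢ)]` per draw (closed wound = 100%);
* arm contrasts of both, each with equal-tailed 95% credible intervals.

Auxiliary one-way Bayesian ANOVAs (Gamma for starting area,
negative-binomial for product applications and treatment days) complete a
Table-style cohort report. A calibrated synthetic-cohort generator — the
same generative model, with intercepts solved by deterministic quadrature so
population Ψ and xPAR hit prescribed targets — stands in for the unavailable
EHR data and drives parameter-recovery validation end to end.

## Worked example

```r
library(woundhurdle)

params <- default_generative_params()          # calibrated generative model
cohort <- generate_cohort(params, n_per_arm = c(23, 18), seed = 7)
design <- build_design(cohort)
fit    <- fit_hurdle_ancova(design, config = fit_config(seed = 1))

expected_par(fit, design, arm = 1)
#> xPAR [arm 1]: 51.36% (95% CrI -65.23%–89.04%), 4000 draws
closure_probability(fit, design, arm = 1)
#> Psi [arm 1]: 0.7339 (95% CrI 0.5568–0.8793), 4000 draws
group_contrast(fit, design, "xPAR")
#> xPAR contrast [arm 1 - arm 0]: 26.15% (95% CrI -96.65%–196.7%), 4000 draws
```

At 41 subjects the point estimates sit near the generator's population
values (xPAR 67.3% / 52.6%, closure ≈ 0.74 in both arms) but the credible
intervals are wide — exactly the small-sample uncertainty such cohorts carry.
At 500 subjects per arm the same pipeline recovers the population values to
within a few percentage points (see `tests/testthat/test-acceptance.R`).
`mcmc_report(fit)` here gives max split-R̂ 1.010, min bulk ESS 505, and no
divergent proposals.

A shell interface wraps the same functions:

```sh
inst/cli/woundhurdle simulate --n-arm1 23 --n-arm0 18 --seed 7 -o cohort.csv
inst/cli/woundhurdle fit cohort.csv --chains 4 --draws 1000 -o draws.csv
inst/cli/woundhurdle report cohort.csv --draws-csv draws.csv -o report.txt
```

## Package layout

* `R/likelihoods.R` — hurdle-Gamma, mean/shape Gamma, mean/dispersion
  negative-binomial densities and conversions
* `R/cohort.R` — generative model, calibration, synthetic cohorts
* `R/mcmc.R`, `R/ancova.R`, `R/anova.R` — sampler, hurdle ANCOVA, auxiliary
  ANOVAs
* `R/effects.R` — Ψ, xPAR and contrasts by g-computation
* `R/diagnostics.R` — split-R̂, bulk ESS, convergence report
* `R/io.R`, `R/report.R`, `R/cli.R` — cohort CSV validation, report writer,
  CLI
* `vignettes/hurdle-gamma-wound-ancova.Rmd` — the methods vignette: model,
  priors, sampler, calibration, design choices and limitations
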