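# Shared fixtures: small sampler configurations and hand-built posterior
# draws / designs for oracle checks.

quick_cfg <- function(seed = 1L, chains = 2L, draws = 500L) {
  fit_config(n_chains = chains, n_draws_per_chain = draws,
             n_warmup = 500L, seed = seed, thin = 2L)
}

# tiny cohort with fixed values for exact arithmetic checks
toy_cohort <- function() {
  data.frame(
    subject_id = paste0("T", 1:5),
    arm = c(1L, 1L, 0L, 0L, 1L),
    pre_area_cm2 = c(10, 20, 15, 5, 8),
    post_area_cm2 = c(0, 4.5, 0, 2.25, 0),
    n_applications = c(7L, 9L, 11L, 10L, 6L),
    treatment_days = c(60L, 70L, 80L, 75L, 55L),
    age = c(70, 65, 60, 58, 72),
    sex = c("F", "M", "F", "M", "F"),
    stringsAsFactors = FALSE
  )
}

# posterior_draws object with draws fixed by hand: `theta` is a matrix with
# one row per draw and the 7 named ANCOVA parameters as columns
manual_draws <- function(theta) {
  stopifnot(ncol(theta) == 7L)
  dd <- array(theta, dim = c(nrow(theta), 1L, 7L),
              dimnames = list(iteration = NULL, chain = NULL,
                              parameter = c("hurdle_intercept", "hurdle_group",
                                            "hurdle_baseline", "area_intercept",
                                            "area_group", "area_baseline", "shape")))
  woundhurdle:::new_posterior_draws(dd, 0L, fit_config(n_chains = 1L,
                                                       n_draws_per_chain = nrow(theta)),
                                    model = "manual")
}

# design with two subjects whose baselines are chosen by the caller
two_subject_design <- function(pre = c(10, 20)) {
  cohort <- data.frame(
    subject_id = c("A", "B"),
    arm = c(1L, 0L),
    pre_area_cm2 = pre,
    post_area_cm2 = c(3, 0),
    n_applications = c(5L, 8L),
    treatment_days = c(50L, 60L),
    stringsAsFactors = FALSE
  )
  build_design(validate_cohort(cohort))
}
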