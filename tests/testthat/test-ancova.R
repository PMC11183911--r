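test_that("design standardizes the baseline and back-transforms exactly", {
  co <- toy_cohort()
  co$pre_area_cm2 <- c(2, 4, 6, 3, 5)
  d <- build_design(validate_cohort(co))
  expect_equal(mean(d$pre_std), 0, tolerance = 1e-12)
  expect_equal(sd(d$pre_std), 1, tolerance = 1e-12)
  expect_equal(design_pre_raw(d), co$pre_area_cm2, tolerance = 1e-12)
  expect_equal(sum(d$group == 1), 3)

  one_arm <- toy_cohort(); one_arm$arm <- 1L
  expect_error(build_design(validate_cohort(one_arm)), "both arms")
  flat <- toy_cohort(); flat$pre_area_cm2 <- rep(7, 5)
  expect_error(build_design(validate_cohort(flat)), "zero variance")
})

test_that("log_posterior equals the per-record hurdle-Gamma sum plus the log prior", {
  d <- build_design(validate_cohort(toy_cohort()))
  pr <- default_priors(d)
  theta <- c(-0.4, 0.3, 0.2, 1.1, -0.25, 0.15, log(1.7))
  k <- exp(theta[7])
  # term-by-term oracle
  ll <- 0
  for (i in seq_len(d$n)) {
    pi_i <- 1 / (1 + exp(-(theta[1] + theta[2] * d$group[i] + theta[3] * d$pre_std[i])))
    mu_i <- exp(theta[4] + theta[5] * d$group[i] + theta[6] * d$pre_std[i])
    ll <- ll + dhurdle_gamma(d$y[i], pi_i, mu_i, k)
  }
  lp_prior <- dnorm(theta[1], pr$hurdle_intercept[1], pr$hurdle_intercept[2], log = TRUE) +
    dnorm(theta[2], pr$hurdle_group[1], pr$hurdle_group[2], log = TRUE) +
    dnorm(theta[3], pr$hurdle_baseline[1], pr$hurdle_baseline[2], log = TRUE) +
    dnorm(theta[4], pr$area_intercept[1], pr$area_intercept[2], log = TRUE) +
    dnorm(theta[5], pr$area_group[1], pr$area_group[2], log = TRUE) +
    dnorm(theta[6], pr$area_baseline[1], pr$area_baseline[2], log = TRUE) +
    log(2) + dnorm(k, 0, pr$shape_scale, log = TRUE) + theta[7]
  expect_equal(log_posterior(theta, d, pr), ll + lp_prior, tolerance = 1e-10)
  expect_error(log_posterior(c(theta[-7], Inf), d, pr), "finite")
})

test_that("a closed wound isolates the hurdle branch of the likelihood", {
  co <- toy_cohort()[c(1, 4), ]          # one closed (arm 1), one open (arm 0)
  d <- build_design(validate_cohort(co))
  pr <- prior_spec()
  theta <- c(0.2, -0.5, 0.3, 1.0, 0.0, 0.0, log(2))
  # subtract the open subject's contribution and the prior: what remains is
  # log(1 - pi) for the closed subject
  closed <- which(d$y == 0)
  open <- which(d$y > 0)
  pi_o <- plogis(theta[1] + theta[2] * d$group[open] + theta[3] * d$pre_std[open])
  mu_o <- exp(theta[4] + theta[5] * d$group[open] + theta[6] * d$pre_std[open])
  lp_prior <- sum(dnorm(theta[1:6],
                        c(pr$hurdle_intercept[1], pr$hurdle_group[1], pr$hurdle_baseline[1],
                          pr$area_intercept[1], pr$area_group[1], pr$area_baseline[1]),
                        c(pr$hurdle_intercept[2], pr$hurdle_group[2], pr$hurdle_baseline[2],
                          pr$area_intercept[2], pr$area_group[2], pr$area_baseline[2]),
                        log = TRUE)) +
    log(2) + dnorm(exp(theta[7]), 0, pr$shape_scale, log = TRUE) + theta[7]
  rest <- dhurdle_gamma(d$y[open], pi_o, mu_o, exp(theta[7]))
  pi_c <- plogis(theta[1] + theta[2] * d$group[closed] + theta[3] * d$pre_std[closed])
  expect_equal(log_posterior(theta, d, pr) - lp_prior - rest, log(1 - pi_c),
               tolerance = 1e-10)
})

test_that("with diffuse priors the likelihood maximizer recovers the positive-area mean", {
  set.seed(5)
  n <- 400
  co <- data.frame(subject_id = as.character(1:n),
                   arm = rep(0:1, each = n / 2),
                   pre_area_cm2 = rgamma(n, 4, 0.3),
                   post_area_cm2 = 0,
                   n_applications = 5L, treatment_days = 50L,
                   stringsAsFactors = FALSE)
  open <- rbinom(n, 1, 0.7) == 1
  co$post_area_cm2[open] <- rgamma(sum(open), shape = 2, rate = 2 / 6)  # flat: no arm/baseline effect
  d <- build_design(validate_cohort(co))
  diffuse <- prior_spec(hurdle_intercept = c(0, 50), hurdle_group = c(0, 50),
                        hurdle_baseline = c(0, 50), area_intercept = c(0, 50),
                        area_group = c(0, 50), area_baseline = c(0, 50),
                        shape_scale = 50)
  opt <- optim(c(1, 0, 0, log(6), 0, 0, log(2)),
               function(th) -log_posterior(th, d, diffuse), method = "BFGS")
  ref_mean <- mean(d$y[d$y > 0 & d$group == 0])
  expect_equal(exp(opt$par[4]), ref_mean, tolerance = 0.05)
})

test_that("the fit returns the configured draw count, reports divergences, and is seed-deterministic", {
  p <- default_generative_params()
  co <- generate_cohort(p, c(60, 60), seed = 2)
  d <- build_design(co)
  fit <- fit_hurdle_ancova(d, config = fit_config(seed = 9))
  dm <- draws_matrix(fit)
  expect_equal(dim(fit$draws), c(1000L, 4L, 7L))
  expect_equal(nrow(dm), 4000L)
  expect_true(all(is.finite(dm)))
  expect_true(all(dm[, "shape"] > 0))
  expect_true(is.numeric(fit$divergences) && fit$divergences >= 0)
  fit2 <- fit_hurdle_ancova(d, config = fit_config(seed = 9))
  expect_identical(fit$draws, fit2$draws)
  fit3 <- fit_hurdle_ancova(d, config = fit_config(seed = 10))
  expect_false(identical(fit$draws, fit3$draws))
})

test_that("the posterior recovers known generative parameters at large n", {
  p <- default_generative_params()
  co <- generate_cohort(p, c(2000, 2000), seed = 21)
  d <- build_design(co)
  fit <- fit_hurdle_ancova(d, config = quick_cfg(seed = 22))
  dm <- draws_matrix(fit)
  truth <- c(hurdle_intercept = p$hurdle_intercept,
             hurdle_group = p$hurdle_group,
             hurdle_baseline = p$hurdle_baseline,
             area_intercept = p$area_intercept,
             area_group = p$area_group,
             area_baseline = p$area_baseline,
             shape = p$gamma_shape)
  for (nm in names(truth)) {
    z <- abs(mean(dm[, nm]) - truth[nm]) / sd(dm[, nm])
    expect_lt(z, 3)
  }
})

test_that("the posterior SD of the group effect contracts as n grows", {
  p <- default_generative_params()
  sds <- sapply(c(50, 200, 800), function(n) {
    co <- generate_cohort(p, c(n, n), seed = 31)
    fit <- fit_hurdle_ancova(build_design(co), config = quick_cfg(seed = 32))
    sd(draws_matrix(fit)[, "area_group"])
  })
  expect_true(all(diff(sds) < 0))
})

test_that("default priors are data-scaled, arm-exchangeable, and prior-predictively wide", {
  co <- generate_cohort(default_generative_params(), c(50, 50), seed = 41)
  d <- build_design(co)
  pr <- default_priors(d)
  spread <- sd(log(d$y[d$y > 0]))
  expect_gte(pr$area_intercept[2], spread)
  # swapping arm labels leaves the priors untouched
  co_sw <- co; co_sw$arm <- 1L - co_sw$arm
  expect_identical(pr, default_priors(build_design(co_sw)))
  # prior predictive closure probability spans (0.05, 0.95)
  set.seed(43)
  a <- rnorm(4000, pr$hurdle_intercept[1], pr$hurdle_intercept[2])
  g <- rnorm(4000, pr$hurdle_baseline[1], pr$hurdle_baseline[2])
  psi <- 1 - sapply(seq_len(4000), function(i) mean(plogis(a[i] + g[i] * d$pre_std)))
  qs <- quantile(psi, c(0.025, 0.975))
  expect_lt(qs[1], 0.05)
  expect_gt(qs[2], 0.95)
})

test_that("true parameters fall inside 99% posterior intervals at nominal frequency", {
  p <- default_generative_params()
  hits <- 0L; total <- 0L; per_par <- integer(7)
  n_rep <- 20L
  for (r in seq_len(n_rep)) {
    co <- generate_cohort(p, c(500, 500), seed = 100 + r)
    fit <- fit_hurdle_ancova(build_design(co), config = quick_cfg(seed = 200 + r))
    dm <- draws_matrix(fit)
    truth <- c(p$hurdle_intercept, p$hurdle_group, p$hurdle_baseline,
               p$area_intercept, p$area_group, p$area_baseline, p$gamma_shape)
    for (j in 1:7) {
      ci <- quantile(dm[, j], c(0.005, 0.995))
      inside <- truth[j] >= ci[1] && truth[j] <= ci[2]
      hits <- hits + inside; total <- total + 1L
      per_par[j] <- per_par[j] + inside
    }
  }
  expect_gte(hits / total, 0.95)
  expect_true(all(per_par >= 0.9 * n_rep))
})
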