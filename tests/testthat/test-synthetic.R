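test_that("generate_cohort respects sizes, arms and seed determinism", {
  p <- generative_params()
  co <- generate_cohort(p, c(23, 18), seed = 7)
  expect_s3_class(co, "cohort_table")
  expect_equal(nrow(co), 41L)
  expect_equal(sum(co$arm == 1), 23L)
  expect_equal(sum(co$arm == 0), 18L)
  expect_false(any(duplicated(co$subject_id)))
  expect_true(all(co$pre_area_cm2 > 0))
  expect_true(all(co$post_area_cm2 >= 0))
  expect_true(all(co$n_applications >= 1 & co$treatment_days >= 1))
  co2 <- generate_cohort(p, c(23, 18), seed = 7)
  expect_identical(co, co2)
  co3 <- generate_cohort(p, c(23, 18), seed = 8)
  expect_false(identical(co$pre_area_cm2, co3$pre_area_cm2))
  expect_error(generate_cohort(p, c(0, 5), seed = 1), "positive integers")
  expect_error(generative_params(gamma_shape = -1), "positive")
})

test_that("degenerate hurdle parameters close every wound", {
  p <- generative_params(hurdle_intercept = -40, hurdle_group = 0,
                         hurdle_baseline = 0)
  co <- generate_cohort(p, c(30, 30), seed = 3)
  expect_true(all(co$post_area_cm2 == 0))
})

test_that("empirical closure fraction and baseline mean match the analytic marginals", {
  p <- default_generative_params()
  n <- 5e4L
  co <- generate_cohort(p, c(n, n), seed = 11)
  for (a in 0:1) {
    psi_true <- woundhurdle:::marginal_closure_quad(p, a)
    emp <- mean(co$post_area_cm2[co$arm == a] == 0)
    se <- sqrt(psi_true * (1 - psi_true) / n)
    expect_lt(abs(emp - psi_true), 3 * se)
  }
  bm <- woundhurdle:::baseline_moments(p)
  se_pre <- bm["scale"] / sqrt(2 * n)
  expect_lt(abs(mean(co$pre_area_cm2) - bm["center"]), 3 * se_pre)
})

test_that("population_xpar agrees with an independent brute-force simulation and the quadrature closed form", {
  p <- default_generative_params()
  # independent test-side simulation of the generative model
  set.seed(991)
  n <- 5e5
  k <- p$baseline_shape; r <- p$baseline_shape / p$baseline_mean
  p0 <- pgamma(p$baseline_min, k, r)
  pre <- qgamma(p0 + runif(n) * (1 - p0), k, r)
  bm <- woundhurdle:::baseline_moments(p)
  z <- (pre - bm["center"]) / bm["scale"]
  for (a in 0:1) {
    pi_open <- plogis(p$hurdle_intercept + p$hurdle_group * a + p$hurdle_baseline * z)
    open <- rbinom(n, 1, pi_open) == 1
    y <- numeric(n)
    mu <- exp(p$area_intercept + p$area_group * a + p$area_baseline * z[open])
    y[open] <- rgamma(sum(open), shape = p$gamma_shape, rate = p$gamma_shape / mu)
    oracle <- 100 * mean((pre - y) / pre)
    mc_se <- 100 * sd((pre - y) / pre) / sqrt(n)
    est <- population_xpar(p, a, mc_draws = 5e5, seed = 17)
    expect_lt(abs(est - oracle), 6 * mc_se)           # two independent MC runs
    expect_lt(abs(est - woundhurdle:::marginal_xpar_quad(p, a)), 4 * mc_se)
  }
  expect_error(population_xpar(p, 2), "arm")
})

test_that("calibration hits the published endpoint targets and round-trips", {
  tg <- default_calibration_targets()
  p <- calibrate_to_targets(tg, base = generative_params(), tol = 1e-4)
  for (a in 0:1) {
    expect_equal(woundhurdle:::marginal_closure_quad(p, a),
                 tg$closure_by_arm[a + 1], tolerance = 1e-4)
    expect_equal(woundhurdle:::marginal_xpar_quad(p, a),
                 tg$xpar_by_arm[a + 1], tolerance = 1e-4)
  }
  # the Monte-Carlo population quantities agree with the calibrated targets
  expect_equal(population_closure(p, 1, 2e5, seed = 5), tg$closure_by_arm[2],
               tolerance = 0.01)
  expect_equal(population_xpar(p, 1, 2e5, seed = 5), tg$xpar_by_arm[2],
               tolerance = 0.02)
})

test_that("symmetric targets give vanishing group coefficients and infeasible targets error", {
  tg <- calibration_targets(closure_by_arm = c(0.5, 0.5), xpar_by_arm = c(50, 50))
  p <- calibrate_to_targets(tg, base = generative_params())
  expect_lt(abs(p$hurdle_group), 1e-6)
  expect_lt(abs(p$area_group), 1e-6)
  expect_error(calibration_targets(c(1, 0.5), c(50, 50)), "\\(0, 1\\)")
  expect_error(calibration_targets(c(0.5, 0.5), c(101, 50)), "< 100")
  near1 <- calibration_targets(c(1 - 1e-16, 0.5), c(50, 50))
  expect_error(calibrate_to_targets(near1, base = generative_params()),
               "not attainable")
})
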