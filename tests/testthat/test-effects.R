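test_that("closure probability and xPAR match a hand-computed toy oracle", {
  d <- two_subject_design(pre = c(10, 20))
  theta <- rbind(
    c(-0.5, 0.4, 0.2, 1.2, -0.3, 0.1, 1.5),
    c(-1.0, 0.1, 0.0, 1.0, -0.1, 0.2, 2.0),
    c(0.3, -0.2, 0.4, 1.4, 0.2, -0.1, 1.0))
  draws <- manual_draws(theta)
  pre <- design_pre_raw(d)
  for (a in 0:1) {
    psi_hand <- xpar_hand <- numeric(3)
    for (m in 1:3) {
      pi_m <- mu_m <- numeric(2)
      for (i in 1:2) {
        pi_m[i] <- 1 / (1 + exp(-(theta[m, 1] + theta[m, 2] * a + theta[m, 3] * d$pre_std[i])))
        mu_m[i] <- exp(theta[m, 4] + theta[m, 5] * a + theta[m, 6] * d$pre_std[i])
      }
      psi_hand[m] <- 1 - mean(pi_m)
      xpar_hand[m] <- 100 * mean((1 - pi_m) + pi_m * (1 - mu_m / pre))
    }
    psi <- closure_probability(draws, d, a)
    xpar <- expected_par(draws, d, a)
    expect_equal(psi$per_draw, psi_hand, tolerance = 1e-12)
    expect_equal(psi$mean, mean(psi_hand), tolerance = 1e-12)
    expect_equal(xpar$per_draw, xpar_hand, tolerance = 1e-12)
    expect_equal(xpar$n_draws, 3L)
  }
  ct <- group_contrast(draws, d, "xPAR")
  x1 <- expected_par(draws, d, 1); x0 <- expected_par(draws, d, 0)
  expect_equal(ct$per_draw, x1$per_draw - x0$per_draw, tolerance = 1e-12)
  expect_equal(ct$mean, x1$mean - x0$mean, tolerance = 1e-12)
})

test_that("constant draws give exact degenerate summaries", {
  d <- two_subject_design()
  # pi_open = 0.26 for every subject and arm -> Psi = 0.74, zero-width interval
  th <- c(qlogis(0.26), 0, 0, 1, 0, 0, 1)
  draws <- manual_draws(rbind(th, th, th))
  psi <- closure_probability(draws, d, 1)
  expect_equal(psi$mean, 0.74, tolerance = 1e-12)
  expect_equal(psi$upper - psi$lower, 0, tolerance = 1e-14)
  # always-open wounds: Psi = 0
  draws_open <- manual_draws(rbind(c(40, 0, 0, 1, 0, 0, 1)))
  expect_equal(closure_probability(draws_open, d, 0)$mean, 0, tolerance = 1e-12)
  # certain closure: xPAR = 100%
  draws_closed <- manual_draws(rbind(c(-40, 0, 0, 1, 0, 0, 1)))
  expect_equal(expected_par(draws_closed, d, 1)$mean, 100, tolerance = 1e-9)
})

test_that("never-closing wounds with conditional mean equal to baseline give xPAR 0", {
  d <- two_subject_design(pre = c(10, 20))
  pre <- design_pre_raw(d)
  # solve theta, epsilon so exp(theta + eps * z_i) = pre_i for both subjects
  z <- d$pre_std
  eps <- (log(pre[2]) - log(pre[1])) / (z[2] - z[1])
  th0 <- log(pre[1]) - eps * z[1]
  draws <- manual_draws(rbind(c(40, 0, 0, th0, 0, eps, 2)))
  expect_equal(expected_par(draws, d, 1)$mean, 0, tolerance = 1e-9)
})

test_that("per-draw effect bounds hold and arm-symmetric draws give a null contrast", {
  set.seed(8)
  theta <- cbind(rnorm(200), 0, rnorm(200), rnorm(200, 1), 0, rnorm(200, 0, 0.5),
                 rexp(200) + 0.2)
  d <- two_subject_design()
  draws <- manual_draws(theta)
  for (a in 0:1) {
    psi <- closure_probability(draws, d, a)
    xpar <- expected_par(draws, d, a)
    expect_true(all(psi$per_draw >= 0 & psi$per_draw <= 1))
    expect_true(all(xpar$per_draw <= 100))
    expect_true(psi$lower <= psi$mean && psi$mean <= psi$upper)
  }
  # group coefficients identically zero in every draw -> contrast exactly 0
  expect_equal(group_contrast(draws, d, "xPAR")$per_draw, rep(0, 200),
               tolerance = 1e-12)
  expect_equal(group_contrast(draws, d, "Psi")$mean, 0, tolerance = 1e-12)
})

test_that("simulation-based xPAR agrees with the closed form within Monte-Carlo error", {
  set.seed(12)
  theta <- cbind(rnorm(40, -0.5, 0.2), 0.3, 0.2, rnorm(40, 1.5, 0.1), -0.2, 0.1,
                 runif(40, 1, 3))
  d <- two_subject_design(pre = c(8, 25))
  draws <- manual_draws(theta)
  closed <- expected_par(draws, d, 1)
  sim <- expected_par(draws, d, 1, mc_per_draw = 4000, seed = 99)
  expect_equal(sim$mean, closed$mean, tolerance = 0.02)
  expect_error(expected_par(draws, d, 2), "arm")
  expect_error(group_contrast(draws, d, "nope"))
})
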