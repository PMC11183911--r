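#' MCMC sampler configuration
#'
#' Settings for the adaptive random-walk Metropolis sampler used by every
#' Bayesian fit in the package. The defaults retain 4 chains x 1000 draws =
#' 4000 posterior draws after discarding warmup. `thin` controls how many
#' post-warmup transitions are run per retained draw; it reduces
#' autocorrelation in the retained sample without changing the retained-draw
#' count. `target_accept` is the acceptance rate the warmup scale adaptation
#' aims for; 0.3 is near-optimal for a multivariate random-walk proposal.
#'
#' @param n_chains Positive integer number of chains (default 4).
#' @param n_draws_per_chain Retained draws per chain after warmup (default 1000).
#' @param n_warmup Warmup (adaptation) iterations per chain, discarded
#'   (default 1000).
#' @param seed Integer seed; fixing it makes the fit bit-reproducible.
#' @param target_accept Acceptance-rate target in (0, 1) for scale adaptation.
#' @param thin Post-warmup transitions per retained draw (default 5).
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(n_chains = 4L, n_draws_per_chain = 1000L,
                       n_warmup = 1000L, seed = 1L,
                       target_accept = 0.3, thin = 5L) {
  stopifnot(n_chains >= 1, n_draws_per_chain >= 1, n_warmup >= 1,
            thin >= 1, target_accept > 0, target_accept < 1)
  structure(list(n_chains = as.integer(n_chains),
                 n_draws_per_chain = as.integer(n_draws_per_chain),
                 n_warmup = as.integer(n_warmup),
                 seed = as.integer(seed),
                 target_accept = target_accept,
                 thin = as.integer(thin)),
            class = "fit_config")
}

# Adaptive random-walk Metropolis over an arbitrary log-posterior.
#
# Warmup uses Haario-style adaptation: the proposal covariance is the running
# empirical covariance of the chain (ridge-regularized) and a global scale
# follows a Robbins-Monro recursion toward `target_accept`. The kernel is
# frozen at the end of warmup, so the retained draws come from a fixed,
# correct Metropolis chain. Proposals with non-finite log posterior are
# rejected; post-warmup occurrences are counted as divergences.
#
# Returns list(draws = array[iter, chain, par], divergences, accept_rate).
adaptive_metropolis <- function(log_post, init, par_names,
                                config = fit_config(),
                                init_jitter = 0.5) {
  d <- length(init)
  set.seed(config$seed)

  # Laplace preconditioning: locate the posterior mode and use the local
  # inverse Hessian as the initial proposal covariance; warmup adaptation
  # then only has to refine it. Falls back to a diagonal proposal if the
  # Hessian is not positive definite.
  neg_lp <- function(th) {
    # overflow en route to an explored extreme is handled by the -Inf guard;
    # keep optim's finite-difference probing quiet about it
    v <- suppressWarnings(-log_post(th))
    if (!is.finite(v)) 1e10 else v
  }
  opt <- tryCatch(
    stats::optim(init, neg_lp, method = "BFGS",
                 hessian = TRUE, control = list(maxit = 500)),
    error = function(e) NULL)
  chol_lap <- NULL
  if (!is.null(opt) && is.finite(opt$value)) {
    init <- opt$par
    cov_lap <- tryCatch(solve(opt$hessian), error = function(e) NULL)
    if (!is.null(cov_lap)) {
      ch <- tryCatch(chol(cov_lap + diag(1e-10, d)), error = function(e) NULL)
      if (!is.null(ch)) chol_lap <- t(ch)
    }
  }
  n_keep <- config$n_draws_per_chain
  n_sample_iter <- n_keep * config$thin
  draws <- array(NA_real_,
                 dim = c(n_keep, config$n_chains, d),
                 dimnames = list(iteration = NULL, chain = NULL,
                                 parameter = par_names))
  divergences <- 0L
  acc_post <- 0L

  jitter_draw <- function() {
    if (!is.null(chol_lap))
      init + 2 * as.vector(chol_lap %*% stats::rnorm(d))   # overdispersed
    else
      init + stats::rnorm(d, 0, init_jitter)
  }
  for (ch in seq_len(config$n_chains)) {
    x <- jitter_draw()
    lx <- log_post(x)
    tries <- 0L
    while (!is.finite(lx) && tries < 50L) {   # re-jitter until a finite start
      x <- jitter_draw()
      lx <- log_post(x)
      tries <- tries + 1L
    }
    if (!is.finite(lx))
      stop("adaptive_metropolis: could not find a finite starting point", call. = FALSE)

    log_lambda <- log(2.38^2 / d)
    run_mean <- x
    run_m2 <- matrix(0, d, d)
    n_seen <- 1L
    chol_prop <- if (!is.null(chol_lap)) chol_lap else diag(0.1, d)

    total_iter <- config$n_warmup + n_sample_iter
    keep_idx <- 0L
    for (i in seq_len(total_iter)) {
      step <- exp(0.5 * log_lambda) * as.vector(chol_prop %*% stats::rnorm(d))
      prop <- x + step
      lp <- log_post(prop)
      accepted <- FALSE
      if (is.finite(lp)) {
        alpha <- min(1, exp(lp - lx))
        if (stats::runif(1) < alpha) { x <- prop; lx <- lp; accepted <- TRUE }
      } else {
        alpha <- 0
        if (i > config$n_warmup) divergences <- divergences + 1L
      }
      if (i <= config$n_warmup) {
        # Robbins-Monro on the global scale
        log_lambda <- log_lambda + (alpha - config$target_accept) / i^0.7
        # running covariance of the warmup trajectory
        n_seen <- n_seen + 1L
        delta <- x - run_mean
        run_mean <- run_mean + delta / n_seen
        run_m2 <- run_m2 + tcrossprod(delta, x - run_mean)
        if (i >= 250L && i %% 25L == 0L) {
          S <- run_m2 / (n_seen - 1L) + diag(1e-8, d)
          ch_try <- tryCatch(chol(S), error = function(e) NULL)
          if (!is.null(ch_try)) chol_prop <- t(ch_try)
        }
      } else {
        if (accepted) acc_post <- acc_post + 1L
        if ((i - config$n_warmup) %% config$thin == 0L) {
          keep_idx <- keep_idx + 1L
          draws[keep_idx, ch, ] <- x
        }
      }
    }
    keep_idx <- 0L
  }
  accept_rate <- acc_post / (config$n_chains * n_sample_iter)
  list(draws = draws, divergences = divergences, accept_rate = accept_rate)
}

#' Posterior draws container
#'
#' @param draws 3-d array `[iteration, chain, parameter]` with named
#'   parameters.
#' @param divergences Integer count of post-warmup proposals with non-finite
#'   log posterior.
#' @param config The [fit_config()] used.
#' @param model Character label of the fitted model.
#' @return An object of class `posterior_draws`.
#' @keywords internal
new_posterior_draws <- function(draws, divergences, config, model,
                                accept_rate = NA_real_) {
  structure(list(draws = draws,
                 divergences = divergences,
                 config = config,
                 model = model,
                 accept_rate = accept_rate,
                 parameters = dimnames(draws)$parameter),
            class = "posterior_draws")
}

#' Flatten posterior draws to a matrix
#'
#' @param x A `posterior_draws` object.
#' @return Numeric matrix with one row per retained draw (chains stacked) and
#'   one named column per parameter.
#' @export
draws_matrix <- function(x) {
  stopifnot(inherits(x, "posterior_draws"))
  dd <- x$draws
  out <- matrix(dd, nrow = dim(dd)[1] * dim(dd)[2], ncol = dim(dd)[3])
  colnames(out) <- dimnames(dd)$parameter
  out
}

#' @export
print.posterior_draws <- function(x, ...) {
  dm <- draws_matrix(x)
  cat(sprintf("Posterior draws: %s\n", x$model))
  cat(sprintf("  %d chains x %d draws = %d retained draws; %d divergent proposals\n",
              dim(x$draws)[2], dim(x$draws)[1], nrow(dm), x$divergences))
  qs <- t(apply(dm, 2, function(v)
    c(mean = mean(v), sd = stats::sd(v),
      stats::quantile(v, c(0.025, 0.975)))))
  print(round(qs, 4))
  invisible(x)
}

#' Write posterior draws to CSV (long format)
#'
#' Columns: `chain`, `iteration`, `parameter`, `value`.
#'
#' @param x A `posterior_draws` object.
#' @param path Output file path.
#' @export
write_draws_csv <- function(x, path) {
  stopifnot(inherits(x, "posterior_draws"))
  dd <- x$draws
  n_it <- dim(dd)[1]; n_ch <- dim(dd)[2]; pars <- dimnames(dd)$parameter
  long <- data.frame(
    chain = rep(rep(seq_len(n_ch), each = n_it), times = length(pars)),
    iteration = rep(rep(seq_len(n_it), times = n_ch), times = length(pars)),
    parameter = rep(pars, each = n_it * n_ch),
    value = as.vector(dd)
  )
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Read posterior draws from a long-format CSV
#'
#' @param path CSV written by [write_draws_csv()].
#' @param model Optional model label to attach.
#' @return A `posterior_draws` object (divergence count unknown, set to 0).
#' @export
read_draws_csv <- function(path, model = "restored from CSV") {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("chain", "iteration", "parameter", "value")
  if (!all(need %in% names(long)))
    stop("read_draws_csv: file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  pars <- unique(long$parameter)
  n_ch <- max(long$chain); n_it <- max(long$iteration)
  dd <- array(NA_real_, dim = c(n_it, n_ch, length(pars)),
              dimnames = list(iteration = NULL, chain = NULL, parameter = pars))
  for (p in seq_along(pars)) {
    sub <- long[long$parameter == pars[p], ]
    dd[cbind(sub$iteration, sub$chain, p)] <- sub$value
  }
  if (anyNA(dd)) stop("read_draws_csv: incomplete draw grid", call. = FALSE)
  new_posterior_draws(dd, 0L, fit_config(n_chains = n_ch, n_draws_per_chain = n_it),
                      model)
}
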