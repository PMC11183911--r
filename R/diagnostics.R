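split_halves <- function(x) {
  # x: iterations x chains -> first/second chain halves side by side
  n <- nrow(x)
  h <- n %/% 2L
  cbind(x[seq_len(h), , drop = FALSE],
        x[seq.int(n - h + 1L, n), , drop = FALSE])
}

rank_normalize <- function(x) {
  # fractional-offset normal scores over the pooled draws
  r <- rank(x, ties.method = "average")
  z <- stats::qnorm((r - 3 / 8) / (length(x) + 1 / 4))
  matrix(z, nrow(x), ncol(x))
}

rhat_basic <- function(z) {
  n <- nrow(z); m <- ncol(z)
  W <- mean(apply(z, 2, stats::var))
  B <- n * stats::var(colMeans(z))
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Rank-normalized split R-hat
#'
#' Convergence diagnostic for one parameter: each chain is split in half,
#' the pooled draws are replaced by fractional-offset normal scores, and the
#' classic between/within variance ratio is computed on the split,
#' rank-normalized chains. Values near 1 indicate convergence. Chains with
#' zero variance return 1 by convention.
#'
#' @param chains Numeric matrix of draws, iterations x chains (at least 2
#'   chains of at least 4 draws), or a list of equal-length numeric vectors.
#' @return The split R-hat value.
#' @export
split_rhat <- function(chains) {
  x <- as_chain_matrix(chains, min_draws = 4L, caller = "split_rhat")
  if (stats::sd(x) == 0) return(1)
  rhat_basic(rank_normalize(split_halves(x)))
}

as_chain_matrix <- function(chains, min_draws, caller) {
  if (is.list(chains)) {
    len <- unique(lengths(chains))
    if (length(len) != 1L)
      stop(caller, ": chains must have equal length", call. = FALSE)
    chains <- do.call(cbind, chains)
  }
  if (!is.matrix(chains) || ncol(chains) < 2L)
    stop(caller, ": need at least 2 chains", call. = FALSE)
  if (nrow(chains) < min_draws)
    stop(caller, ": need at least ", min_draws, " draws per chain", call. = FALSE)
  if (anyNA(chains)) stop(caller, ": draws contain NA", call. = FALSE)
  chains
}

# biased (1/n) autocovariance sequence via FFT
autocov_fft <- function(v) {
  n <- length(v)
  vc <- v - mean(v)
  L <- 2^ceiling(log2(2 * n))
  f <- stats::fft(c(vc, rep(0, L - n)))
  ac <- Re(stats::fft(Conj(f) * f, inverse = TRUE)) / L
  ac[seq_len(n)] / n
}

#' Bulk effective sample size
#'
#' Autocorrelation-based effective sample size on rank-normalized split
#' chains, combining within-chain autocovariances with the between-chain
#' variance and truncating the autocorrelation sum by Geyer's initial
#' monotone positive-pair sequence. For independent draws the result is close
#' to the total draw count; it is clipped at 1.25 x the total (with a
#' warning) to bound estimator noise. Constant chains return the total draw
#' count by convention.
#'
#' @param chains Numeric matrix of draws, iterations x chains (at least 2
#'   chains of at least 8 draws), or a list of equal-length numeric vectors.
#' @return The bulk ESS estimate.
#' @export
ess_bulk <- function(chains) {
  x <- as_chain_matrix(chains, min_draws = 8L, caller = "ess_bulk")
  n_total <- length(x)
  if (stats::sd(x) == 0) return(n_total)
  z <- rank_normalize(split_halves(x))
  n <- nrow(z); m <- ncol(z)
  acov <- sapply(seq_len(m), function(j) autocov_fft(z[, j]))
  mean_acov <- rowMeans(acov)
  chain_var <- acov[1, ] * n / (n - 1)
  W <- mean(chain_var)
  var_plus <- (n - 1) / n * W + stats::var(colMeans(z))
  rho <- 1 - (W - mean_acov) / var_plus          # rho[t + 1] is lag t
  rho[1] <- 1
  # Geyer initial positive, monotone-decreasing sequence over (even, odd) pairs
  max_pairs <- floor(n / 2) - 1L
  pair_sum <- rho[1] + rho[2]                    # P_0 = rho_0 + rho_1
  for (k in seq_len(max_pairs)) {
    p <- rho[2 * k + 1] + rho[2 * k + 2]         # P_k = rho_{2k} + rho_{2k+1}
    if (is.na(p) || p <= 0) break
    pair_sum <- c(pair_sum, p)
  }
  pair_sum <- cummin(pair_sum)
  tau <- -1 + 2 * sum(pair_sum)
  tau <- max(tau, 1 / log10(n_total + 10))       # guard against tiny/negative tau
  ess <- n_total / tau
  if (ess > 1.25 * n_total) {
    warning("ess_bulk: estimate exceeded 1.25x the draw count; clipped",
            call. = FALSE)
    ess <- 1.25 * n_total
  }
  ess
}

#' Convergence report for a posterior fit
#'
#' Applies [split_rhat()] and [ess_bulk()] to every sampled parameter and
#' combines them with the divergence count into a pass/fail report: pass if
#' the maximum R-hat is at most `rhat_threshold`, the minimum ESS is at least
#' `ess_threshold`, and no divergent transitions occurred. Parameters held
#' constant (e.g. slopes pinned at zero in an unadjusted fit) get R-hat 1 and
#' ESS equal to the draw count by the degenerate-chain convention.
#'
#' @param draws A `posterior_draws` object.
#' @param rhat_threshold Maximum acceptable split R-hat (default 1.05).
#' @param ess_threshold Minimum acceptable bulk ESS (default 400).
#' @return An object of class `diagnostics_report` with per-parameter
#'   `rhat` and `ess`, `divergences`, `pass`, and the names of any failing
#'   parameters.
#' @export
mcmc_report <- function(draws, rhat_threshold = 1.05, ess_threshold = 400) {
  stopifnot(inherits(draws, "posterior_draws"))
  pars <- dimnames(draws$draws)$parameter
  rhat <- vapply(pars, function(p) split_rhat(draws$draws[, , p]), numeric(1))
  ess <- vapply(pars, function(p) ess_bulk(draws$draws[, , p]), numeric(1))
  fail <- unique(c(names(rhat)[rhat > rhat_threshold],
                   names(ess)[ess < ess_threshold]))
  structure(list(rhat = rhat,
                 ess = ess,
                 divergences = draws$divergences,
                 rhat_threshold = rhat_threshold,
                 ess_threshold = ess_threshold,
                 failing = fail,
                 pass = length(fail) == 0L && draws$divergences == 0L),
            class = "diagnostics_report")
}

#' @export
print.diagnostics_report <- function(x, ...) {
  cat("MCMC diagnostics\n")
  tab <- data.frame(rhat = round(x$rhat, 4), ess = round(x$ess, 1))
  print(tab)
  cat(sprintf("  divergent proposals: %d\n", x$divergences))
  cat(sprintf("  %s (thresholds: R-hat <= %.3f, ESS >= %g, divergences == 0)\n",
              if (x$pass) "PASS" else paste("FAIL:", paste(x$failing, collapse = ", ")),
              x$rhat_threshold, x$ess_threshold))
  invisible(x)
}
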