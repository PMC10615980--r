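#' Split-chain potential scale reduction (R-hat)
#'
#' Gelman-Rubin convergence statistic computed on split chains: each chain
#' is halved (dropping the middle draw when the length is odd), the
#' between- and within-half variances are combined, and
#' `sqrt(var_plus / W)` is returned with `var_plus = (n-1)/n W + B/n`.
#'
#' @param chains Numeric matrix of draws, iterations in rows, chains in
#'   columns (at least 2 chains of at least 4 draws).
#' @return A single number `>= 1` up to estimator noise; `Inf` when the
#'   within-chain variance is zero but chains disagree, `NaN` when all
#'   draws are identical.
#' @export
rhat <- function(chains) {
  chains <- as.matrix(chains)
  if (ncol(chains) < 2L) stop("need at least 2 chains")
  if (nrow(chains) < 4L) stop("need at least 4 draws per chain")
  halves <- split_chains(chains)
  n <- nrow(halves)
  W <- mean(apply(halves, 2L, stats::var))
  B <- n * stats::var(colMeans(halves))
  if (W == 0) {
    return(if (B == 0) NaN else Inf)
  }
  var_plus <- (n - 1) / n * W + B / n
  sqrt(var_plus / W)
}

split_chains <- function(chains) {
  n <- nrow(chains)
  half <- n %/% 2L
  do.call(cbind, lapply(seq_len(ncol(chains)), function(m) {
    cbind(chains[seq_len(half), m],
          chains[(n - half + 1L):n, m])
  }))
}

#' Effective sample size
#'
#' Autocorrelation-adjusted effective number of draws, computed on split
#' chains from the multi-chain autocorrelation estimate
#' `rho_t = 1 - (W - mean autocovariance_t) / var_plus`, truncated by
#' Geyer's initial positive sequence (summation stops before the first
#' negative paired sum `rho_{2k} + rho_{2k+1}`).
#'
#' @inheritParams rhat
#' @return Effective sample size; 0 when the draws are constant.
#' @export
ess <- function(chains) {
  chains <- as.matrix(chains)
  if (ncol(chains) < 2L) stop("need at least 2 chains")
  if (nrow(chains) < 4L) stop("need at least 4 draws per chain")
  halves <- split_chains(chains)
  n <- nrow(halves)
  m <- ncol(halves)
  acov <- vapply(seq_len(m), function(i) autocov_fft(halves[, i]), numeric(n))
  chain_var <- acov[1L, ] * n / (n - 1)
  W <- mean(chain_var)
  B_over_n <- stats::var(colMeans(halves))
  var_plus <- (n - 1) / n * W + B_over_n
  if (var_plus == 0) return(0)
  rho <- 1 - (W - rowMeans(acov)) / var_plus
  # Geyer initial positive sequence: tau = 2 * sum of positive paired
  # autocorrelations (rho_{2k} + rho_{2k+1}) minus rho_0.
  tau <- -rho[1L]
  t <- 0L
  while (t + 2L <= n) {
    pair <- rho[t + 1L] + rho[t + 2L]
    if (!is.finite(pair) || pair < 0) break
    tau <- tau + 2 * pair
    t <- t + 2L
  }
  max(n * m / max(tau, 1e-12), 0)
}

# Autocovariance sequence (biased, divisor n) via FFT.
autocov_fft <- function(x) {
  n <- length(x)
  x <- x - mean(x)
  nfft <- 2L^ceiling(log2(2L * n))
  f <- stats::fft(c(x, rep(0, nfft - n)))
  ac <- Re(stats::fft(f * Conj(f), inverse = TRUE))[seq_len(n)] / nfft
  ac / n
}

#' Convergence diagnostics for a fit
#'
#' Per-parameter split-chain R-hat and effective sample size, plus the
#' divergent-transition count as a fraction of post-warmup transitions.
#' Customary thresholds (R-hat below 1.1, ESS above 400) are reported as
#' pass/fail flags, never enforced.
#'
#' @param fit A [fit_drift()] result.
#' @param rhat_threshold,ess_threshold Thresholds used for the summary flags.
#' @return A list of class `drift_diagnostics`: data.frame `parameters`
#'   (columns `parameter`, `rhat`, `ess`), `divergent` count, `divergent_fraction`,
#'   and logical flags `rhat_ok`, `ess_ok`.
#' @export
diagnostics <- function(fit, rhat_threshold = 1.1, ess_threshold = 400) {
  stopifnot(inherits(fit, "drift_fit"))
  nm <- fit$param_names
  per_param <- vapply(seq_along(nm), function(p) {
    x <- vapply(fit$draws, function(ch) ch[, p], numeric(nrow(fit$draws[[1L]])))
    c(rhat(x), ess(x))
  }, numeric(2))
  total <- sum(vapply(fit$draws, nrow, integer(1)))
  rh <- per_param[1L, ]
  es <- per_param[2L, ]
  structure(list(
    parameters = data.frame(parameter = nm, rhat = rh, ess = es,
                            stringsAsFactors = FALSE),
    divergent = sum(fit$divergent),
    divergent_fraction = sum(fit$divergent) / max(1L, total),
    rhat_ok = all(is.finite(rh) & rh < rhat_threshold),
    ess_ok = all(es > ess_threshold)
  ), class = "drift_diagnostics")
}

#' @export
print.drift_diagnostics <- function(x, ...) {
  rh <- x$parameters$rhat
  es <- x$parameters$ess
  cat(sprintf("R-hat:  max %.3f (threshold 1.1) -> %s\n",
              max(rh[is.finite(rh)]), if (x$rhat_ok) "ok" else "CHECK"))
  cat(sprintf("ESS:    min %.0f (threshold 400) -> %s\n",
              min(es), if (x$ess_ok) "ok" else "CHECK"))
  cat(sprintf("Divergent transitions: %d (%.2f%%)\n",
              x$divergent, 100 * x$divergent_fraction))
  invisible(x)
}
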