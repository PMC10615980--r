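#' Sampler configuration
#'
#' Settings for the No-U-Turn sampler: number of chains, total iterations
#' per chain, warmup iterations (adaptation; discarded), the dual-averaging
#' target acceptance statistic, and the master seed from which per-chain
#' seeds are derived. Defaults mirror routine practice for this model
#' family: 3 chains of 5000 iterations with 2000 warmup (9000 retained
#' draws) and a high 0.98 acceptance target to suppress divergent
#' transitions in the funnel-prone drift-scale geometry.
#'
#' @param chains Number of independent chains.
#' @param iterations Total iterations per chain (including warmup).
#' @param warmup Warmup iterations per chain; must be `< iterations`.
#' @param target_acceptance Dual-averaging target in (0, 1).
#' @param seed Master integer seed.
#' @param max_treedepth Maximum tree doublings per iteration.
#' @return An object of class `sampler_config`.
#' @export
sampler_config <- function(chains = 3L, iterations = 5000L, warmup = 2000L,
                           target_acceptance = 0.98, seed = 1L,
                           max_treedepth = 10L) {
  if (warmup >= iterations) stop("warmup must be smaller than iterations")
  if (warmup < 1L) stop("warmup must be positive")
  if (target_acceptance <= 0 || target_acceptance >= 1) {
    stop("target_acceptance must lie strictly between 0 and 1")
  }
  structure(list(chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 warmup = as.integer(warmup),
                 target_acceptance = target_acceptance,
                 seed = as.integer(seed),
                 max_treedepth = as.integer(max_treedepth)),
            class = "sampler_config")
}

MODEL_VARIANTS <- c("proposed", "proposed_no_markov", "baseline", "baseline_markov")

variant_opts <- function(variant, hyper, temperature = 1) {
  variant <- match.arg(variant, MODEL_VARIANTS)
  list(rater_steps = variant %in% c("proposed", "proposed_no_markov"),
       markov = variant %in% c("proposed", "baseline_markov"),
       mu_sigma = hyper$mu_sigma,
       D = 1.7,
       temperature = temperature)
}

data_payload <- function(data) {
  d <- dims(data)
  list(J = d$J, R = d$R, T = d$T, K = d$K,
       examinee = data$examinee, rater = data$rater,
       time = data$time, score = data$score)
}

# Parameter bookkeeping for the unconstrained vector used by the sampler.
param_layout <- function(J, R, T, K, opts) {
  nfree <- K - 2L
  nblocks <- if (opts$rater_steps) R else 1L
  list(J = J, R = R, T = T, K = K, nfree = nfree, nblocks = nblocks,
       off_beta = J, off_lsig = J + R * T,
       off_d = J + R * T + if (opts$markov) R else 0L,
       P = J + R * T + (if (opts$markov) R else 0L) + nblocks * nfree)
}

constrained_names <- function(lay, opts) {
  nm <- c(paste0("theta[", seq_len(lay$J), "]"),
          as.vector(t(outer(seq_len(lay$R), seq_len(lay$T),
                            function(r, t) paste0("beta[", r, ",", t, "]")))))
  if (opts$markov) nm <- c(nm, paste0("sigma[", seq_len(lay$R), "]"))
  if (lay$K > 2L) {
    if (opts$rater_steps) {
      for (r in seq_len(lay$R)) {
        nm <- c(nm, paste0("d[", r, ",", 2:lay$K, "]"))
      }
    } else {
      nm <- c(nm, paste0("d[", 2:lay$K, "]"))
    }
  }
  nm
}

# Map a matrix of unconstrained draws to the constrained scale: for Markov
# variants the severity block is non-centered (beta_r1 followed by the
# standardised innovations), so beta is rebuilt by the cumulative-sum
# transform; sigma is exponentiated; each free step block gains its forced
# final entry. beta for rater r, time t sits at column
# off_beta + (r-1)*T + t.
constrain_draws <- function(u, lay, opts) {
  out <- u[, seq_len(lay$off_lsig), drop = FALSE]
  if (opts$markov) {
    sig <- exp(u[, lay$off_lsig + seq_len(lay$R), drop = FALSE])
    if (lay$T > 1L) {
      for (r in seq_len(lay$R)) {
        cols <- lay$off_beta + (r - 1L) * lay$T + seq_len(lay$T)
        bl <- out[, cols, drop = FALSE]
        bl[, -1L] <- bl[, -1L] * sig[, r]
        out[, cols] <- t(apply(bl, 1L, cumsum))
      }
    }
    out <- cbind(out, sig)
  }
  if (lay$nfree >= 0L && lay$K > 2L) {
    for (b in seq_len(lay$nblocks)) {
      cols <- lay$off_d + (b - 1L) * lay$nfree + seq_len(lay$nfree)
      free <- u[, cols, drop = FALSE]
      out <- cbind(out, free, -rowSums(free))
    }
  }
  # K == 2: the step vector is fully determined as (0, 0); nothing to add
  out
}

prior_init <- function(lay, opts) {
  # prior draws on the sampler's own (non-centered) coordinates: initial
  # severities and innovations are standard normal, log drift scales come
  # from their N(mu_sigma, 1) prior
  q <- stats::rnorm(lay$P)
  if (opts$markov) {
    q[lay$off_lsig + seq_len(lay$R)] <- stats::rnorm(lay$R, opts$mu_sigma, 1)
  }
  q
}

#' Fit a drift model by NUTS
#'
#' Samples the joint posterior of one of four model variants with a
#' No-U-Turn Hamiltonian Monte Carlo sampler (analytic gradients; drift
#' scales sampled on the log scale with the Jacobian included):
#'
#' * `proposed`: rater-specific steps, Markov severity chain with
#'   rater-specific drift scales.
#' * `proposed_no_markov`: rater-specific steps, i.i.d. standard-normal
#'   severities (the temporal-independence ablation).
#' * `baseline`: shared steps, i.i.d. standard-normal severities.
#' * `baseline_markov`: shared steps, Markov severity chain.
#'
#' Non-convergence is never an error; inspect [diagnostics()] for R-hat,
#' ESS and divergent-transition counts.
#'
#' @param data A [rating_data()] object.
#' @param variant One of `"proposed"`, `"proposed_no_markov"`, `"baseline"`,
#'   `"baseline_markov"`.
#' @param hyper A [hyperparameters()] object (drift-scale prior).
#' @param config A [sampler_config()].
#' @param temperature Likelihood power; 1 targets the posterior. Values
#'   below 1 target the tempered posterior used by [wbic()].
#' @return An object of class `drift_fit` with per-chain constrained draws,
#'   sampler diagnostics, and the model description.
#' @export
fit_drift <- function(data, variant = "proposed", hyper = hyperparameters(),
                      config = sampler_config(), temperature = 1) {
  stopifnot(inherits(data, "rating_data"))
  stopifnot(inherits(hyper, "hyperparameters"))
  stopifnot(inherits(config, "sampler_config"))
  variant <- match.arg(variant, MODEL_VARIANTS)
  opts <- variant_opts(variant, hyper, temperature)
  d <- dims(data)
  lay <- param_layout(d$J, d$R, d$T, d$K, opts)
  payload <- data_payload(data)

  chain_seeds <- derive_seeds(config$seed, config$chains)
  draws <- vector("list", config$chains)
  unconstrained <- vector("list", config$chains)
  divergent <- integer(config$chains)
  stepsize <- numeric(config$chains)
  accept <- numeric(config$chains)
  nm <- constrained_names(lay, opts)
  for (ch in seq_len(config$chains)) {
    init <- withr::with_seed(chain_seeds[ch], prior_init(lay, opts))
    res <- rd_nuts(payload, opts, init, config$iterations, config$warmup,
                   config$target_acceptance, config$max_treedepth,
                   chain_seeds[ch])
    u <- res$draws
    unconstrained[[ch]] <- u
    cd <- constrain_draws(u, lay, opts)
    colnames(cd) <- nm
    draws[[ch]] <- cd
    divergent[ch] <- res$divergent
    stepsize[ch] <- res$stepsize
    accept[ch] <- res$mean_accept
  }
  structure(list(draws = draws, unconstrained = unconstrained,
                 variant = variant, hyper = hyper, config = config,
                 opts = opts, layout = lay, data = data,
                 divergent = divergent, stepsize = stepsize,
                 mean_accept = accept, param_names = nm),
            class = "drift_fit")
}

# Independent per-chain seeds below 2^31, reproducibly derived from the
# master seed.
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max, n))
}

#' @export
print.drift_fit <- function(x, ...) {
  d <- dims(x$data)
  ndraw <- sum(vapply(x$draws, nrow, integer(1)))
  cat(sprintf("drift_fit: variant '%s', %d chains x %d draws (%d total)\n",
              x$variant, x$config$chains,
              x$config$iterations - x$config$warmup, ndraw))
  cat(sprintf("  data: n = %d (J = %d, R = %d, T = %d, K = %d)\n",
              d$n, d$J, d$R, d$T, d$K))
  cat(sprintf("  divergent transitions: %d (%.2f%% of post-warmup)\n",
              sum(x$divergent),
              100 * sum(x$divergent) / max(1L, ndraw)))
  invisible(x)
}

#' Expected a posteriori estimates
#'
#' Posterior means over all chains and post-warmup draws, returned as a
#' [parameter_set()] (or [baseline_parameter_set()] for the shared-step
#' variants). Step estimates satisfy the identification constraints exactly
#' because the constraint map is linear in the free coordinates.
#'
#' @param fit A `drift_fit`.
#' @return A parameter set of posterior means.
#' @export
eap <- function(fit) {
  stopifnot(inherits(fit, "drift_fit"))
  if (length(fit$draws) == 0L || nrow(fit$draws[[1L]]) == 0L) {
    stop("fit contains no draws")
  }
  m <- unname(colMeans(do.call(rbind, fit$draws)))
  lay <- fit$layout
  opts <- fit$opts
  theta <- m[seq_len(lay$J)]
  beta <- matrix(m[lay$off_beta + seq_len(lay$R * lay$T)],
                 nrow = lay$R, ncol = lay$T, byrow = TRUE)
  idx <- lay$off_beta + lay$R * lay$T
  sigma <- NULL
  if (opts$markov) {
    sigma <- m[idx + seq_len(lay$R)]
    idx <- idx + lay$R
  }
  per_block <- if (lay$K > 2L) lay$K - 1L else 0L
  if (opts$rater_steps) {
    dmat <- matrix(0, lay$R, lay$K)
    if (per_block > 0L) {
      for (r in seq_len(lay$R)) {
        dmat[r, 2:lay$K] <- m[idx + (r - 1L) * per_block + seq_len(per_block)]
      }
    }
    parameter_set(theta, beta, sigma, dmat)
  } else {
    dvec <- if (per_block > 0L) c(0, m[idx + seq_len(per_block)]) else c(0, 0)
    baseline_parameter_set(theta, beta, dvec, sigma = sigma)
  }
}
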