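#' Log-likelihood of rating data
#'
#' Sum over observations of the log category probability of the observed
#' score, with rater `r`'s step vector (or the shared step vector for a
#' `baseline_parameter_set`). This reference implementation is plain R and
#' deliberately independent of the compiled density used by the sampler; the
#' two are cross-checked in the test suite.
#'
#' @param data A [rating_data()] object.
#' @param params A [parameter_set()] or [baseline_parameter_set()].
#' @return A single finite number (0 for an empty dataset).
#' @export
log_likelihood <- function(data, params) {
  stopifnot(inherits(data, "rating_data"))
  d <- dims(data)
  check_param_dims(params, d)
  if (d$n == 0L) return(0)
  baseline <- inherits(params, "baseline_parameter_set")
  ll <- 0
  for (i in seq_len(d$n)) {
    j <- data$examinee[i]; r <- data$rater[i]; t <- data$time[i]; k <- data$score[i]
    steps <- if (baseline) params$d else params$d[r, ]
    p <- category_probabilities(params$theta[j], params$beta[r, t], steps,
                                params$scaling_D)
    ll <- ll + log(p[k])
  }
  ll
}

check_param_dims <- function(params, d) {
  if (length(params$theta) != d$J) {
    stop("theta length ", length(params$theta), " does not match J = ", d$J)
  }
  if (nrow(params$beta) != d$R) {
    stop("beta has ", nrow(params$beta), " rows but R = ", d$R)
  }
  if (ncol(params$beta) != d$T) {
    stop("beta has ", ncol(params$beta), " columns but T = ", d$T)
  }
  K <- if (inherits(params, "baseline_parameter_set")) length(params$d) else ncol(params$d)
  if (K != d$K) stop("step parameters imply K = ", K, " but data declare K = ", d$K)
  invisible(TRUE)
}

#' Log prior density of a parameter set
#'
#' Evaluates the joint log prior: standard-normal terms for abilities and
#' initial severities, the first-order Markov chain
#' `beta[r,t] ~ N(beta[r,t-1], sigma[r])` for `t > 1`, the log-normal
#' drift-scale prior `sigma[r] ~ LN(mu_sigma, 1)`, and the step prior:
#' independent standard normals on `d[2:K]` conditioned on the zero-sum
#' identification constraint (evaluated on all constrained entries, the
#' last of which is determined by the free coordinates; `d[1] = 0` carries
#' no density).
#' When `params$sigma` is `NULL` (independent-severity ablation), all
#' severities get i.i.d. standard-normal terms instead of the chain.
#'
#' @inheritParams log_likelihood
#' @param hyper A [hyperparameters()] object.
#' @return A single number.
#' @export
log_prior <- function(params, hyper = hyperparameters()) {
  stopifnot(inherits(params, c("parameter_set", "baseline_parameter_set")))
  stopifnot(inherits(hyper, "hyperparameters"))
  baseline <- inherits(params, "baseline_parameter_set")
  beta <- params$beta
  R <- nrow(beta); T <- ncol(beta)
  lp <- sum(stats::dnorm(params$theta, 0, 1, log = TRUE))
  if (is.null(params$sigma)) {
    lp <- lp + sum(stats::dnorm(beta, 0, 1, log = TRUE))
  } else {
    if (any(params$sigma <= 0)) stop("sigma must be strictly positive")
    lp <- lp + sum(stats::dnorm(beta[, 1L], 0, 1, log = TRUE))
    if (T > 1L) {
      for (t in 2:T) {
        lp <- lp + sum(stats::dnorm(beta[, t], beta[, t - 1L], params$sigma,
                                    log = TRUE))
      }
    }
    lp <- lp + sum(stats::dlnorm(params$sigma, hyper$mu_sigma,
                                 hyper$prior_sd_sigma, log = TRUE))
  }
  dmat <- if (baseline) matrix(params$d, nrow = 1L) else params$d
  K <- ncol(dmat)
  if (K >= 3L) {
    lp <- lp + sum(stats::dnorm(dmat[, 2:K, drop = FALSE], 0, 1, log = TRUE))
  }
  lp
}

#' Unnormalised log posterior
#'
#' `log_likelihood(data, params) + log_prior(params, hyper)`: the target of
#' the MCMC sampler, exposed for direct evaluation and for cross-checking
#' the compiled sampler density.
#'
#' @inheritParams log_likelihood
#' @inheritParams log_prior
#' @return A single number.
#' @export
log_posterior <- function(data, params, hyper = hyperparameters()) {
  log_likelihood(data, params) + log_prior(params, hyper)
}
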