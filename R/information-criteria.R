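#' Pointwise log-likelihood matrix
#'
#' Log probability of every observation under every posterior draw,
#' computed with the same category-probability kernel as the model. Rows
#' are draws (all chains stacked), columns are observations in the row
#' order of `fit$data`.
#'
#' @param fit A [fit_drift()] result.
#' @return Numeric matrix, draws x observations; all entries are log
#'   probabilities of ordinal categories, hence `<= 0`.
#' @export
pointwise_loglik <- function(fit) {
  stopifnot(inherits(fit, "drift_fit"))
  u <- do.call(rbind, fit$unconstrained)
  rd_pointwise_loglik(data_payload(fit$data), fit$opts, u)
}

#' Widely applicable information criterion
#'
#' WAIC on the deviance scale: `-2 * (lppd - p_waic)`, where `lppd` is the
#' sum over observations of the log of the mean posterior likelihood
#' (log-sum-exp stabilised) and the effective-parameter penalty `p_waic` is
#' the sum of per-observation sample variances of the log-likelihood
#' (`n - 1` denominator). Lower is better.
#'
#' @param ll A pointwise log-likelihood matrix (draws x observations), as
#'   returned by [pointwise_loglik()], or a `drift_fit` (in which case the
#'   matrix is computed first).
#' @return A single number of class `waic_result` with attributes `lppd`
#'   and `p_waic`.
#' @export
waic <- function(ll) {
  if (inherits(ll, "drift_fit")) ll <- pointwise_loglik(ll)
  ll <- as.matrix(ll)
  S <- nrow(ll)
  if (S < 1L) stop("need at least one draw")
  if (S == 1L) warning("single draw: p_waic is 0 and WAIC is -2 * log-likelihood")
  lppd <- sum(apply(ll, 2L, function(x) logsumexp(x) - log(S)))
  p_waic <- if (S > 1L) sum(apply(ll, 2L, stats::var)) else 0
  structure(-2 * (lppd - p_waic), lppd = lppd, p_waic = p_waic,
            class = "waic_result")
}

#' @export
print.waic_result <- function(x, ...) {
  cat(sprintf("WAIC = %.2f (lppd = %.2f, p_waic = %.2f); lower is better\n",
              unclass(x), attr(x, "lppd"), attr(x, "p_waic")))
  invisible(x)
}

#' Widely applicable Bayesian information criterion
#'
#' WBIC approximates the negative log marginal likelihood as the expectation
#' of the negative log-likelihood under the tempered posterior
#' `prior x likelihood^(1/log n)`. A dedicated sampling pass at that
#' temperature is run; the returned value is in nats and is not on the
#' deviance scale of [waic()] — the two are reported side by side, not
#' compared to each other.
#'
#' @inheritParams fit_drift
#' @param temperature Likelihood power for the tempered run. The default
#'   `NULL` uses `1 / log(n)` (the WBIC temperature); passing 1 is a testing
#'   hook that reduces WBIC to the posterior mean of the negative
#'   log-likelihood from an ordinary fit.
#' @return A single number (nats) of class `wbic_result`, with the tempered
#'   `drift_fit` attached as attribute `fit`.
#' @export
wbic <- function(data, variant = "proposed", hyper = hyperparameters(),
                 config = sampler_config(), temperature = NULL) {
  stopifnot(inherits(data, "rating_data"))
  n <- nrow(data)
  if (n < 2L) stop("WBIC requires at least 2 observations (log n must be nonzero)")
  if (is.null(temperature)) temperature <- 1 / log(n)
  fit <- fit_drift(data, variant = variant, hyper = hyper, config = config,
                   temperature = temperature)
  ll <- pointwise_loglik(fit)
  structure(mean(-rowSums(ll)), fit = fit, temperature = temperature,
            class = "wbic_result")
}

#' @export
print.wbic_result <- function(x, ...) {
  cat(sprintf("WBIC = %.2f nats (likelihood temperature %.4f); lower is better\n",
              unclass(x), attr(x, "temperature")))
  invisible(x)
}

#' Compare model variants by WAIC and WBIC
#'
#' Fits the requested variants on one dataset and tabulates WAIC (ordinary
#' posterior) and WBIC (tempered run) per variant, flagging the minima.
#'
#' @inheritParams fit_drift
#' @param variants Character vector of variants to compare.
#' @return A data.frame with columns `variant`, `waic`, `wbic`,
#'   `waic_best`, `wbic_best`.
#' @export
compare_models <- function(data, variants = MODEL_VARIANTS,
                           hyper = hyperparameters(),
                           config = sampler_config()) {
  rows <- lapply(variants, function(v) {
    f <- fit_drift(data, variant = v, hyper = hyper, config = config)
    w <- waic(f)
    wb <- wbic(data, variant = v, hyper = hyper, config = config)
    data.frame(variant = v, waic = as.numeric(w), wbic = as.numeric(wb),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$waic_best <- out$waic == min(out$waic)
  out$wbic_best <- out$wbic == min(out$wbic)
  out
}
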