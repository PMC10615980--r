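#' Score-category probabilities
#'
#' Probability of each ordinal score category for one examinee-rater-time
#' combination under the adjacent-categories (partial-credit style) kernel of
#' the many-facet Rasch model:
#' \deqn{P_k \propto \exp \sum_{m=1}^{k} D(\theta - \beta - d_m),}
#' normalised over `k = 1..K`. Computation is done in log-space with a
#' log-sum-exp normaliser so large `|theta - beta|` cannot overflow.
#'
#' @param theta Examinee ability (scalar).
#' @param beta Rater severity at the relevant time point (scalar).
#' @param d Step vector of length `K` with `d[1] = 0`.
#' @param D Logistic scaling constant (default 1.7).
#' @return Numeric probability vector of length `K` summing to 1.
#' @examples
#' category_probabilities(0, 0, rep(0, 5))        # uniform over 5 categories
#' category_probabilities(1, 0, c(0, 0))          # two-category logistic
#' @export
category_probabilities <- function(theta, beta, d, D = 1.7) {
  if (!all(is.finite(c(theta, beta, d, D)))) stop("non-finite model parameters")
  K <- length(d)
  if (K < 2L) stop("step vector must have length K >= 2")
  if (abs(d[1L]) > 1e-12) stop("step vector must have d[1] = 0")
  k <- seq_len(K)
  logits <- k * D * (theta - beta) - D * cumsum(d)
  exp(logits - logsumexp(logits))
}

#' @rdname category_probabilities
#' @details `baseline_category_probabilities` is the identical kernel; it
#'   exists so code reads correctly when a single step vector is shared by
#'   all raters (the baseline model) rather than being rater-specific.
#' @export
baseline_category_probabilities <- function(theta, beta, d, D = 1.7) {
  category_probabilities(theta, beta, d, D)
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}
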