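#' Mixture specification for true drift scales
#'
#' In the simulation protocol the rater drift scales are drawn from a
#' two-component log-normal mixture: a "stable" component `LN(-3, 1)` for
#' 60% of raters and a "drifting" component `LN(-1, 1)` for the remaining
#' 40%, emulating a pool in which most raters hold their severity steady
#' while a minority drift markedly.
#'
#' @param stable_fraction Proportion of raters in the stable component.
#' @param stable_logmean,drifting_logmean Log-scale means of the components.
#' @param logsd Log-scale standard deviation, shared by both components.
#' @return An object of class `sigma_mixture`.
#' @export
sigma_mixture <- function(stable_fraction = 0.6, stable_logmean = -3,
                          drifting_logmean = -1, logsd = 1) {
  if (!is.numeric(stable_fraction) || stable_fraction < 0 || stable_fraction > 1) {
    stop("stable_fraction must lie in [0, 1]")
  }
  if (!all(is.finite(c(stable_logmean, drifting_logmean, logsd))) || logsd <= 0) {
    stop("invalid mixture specification")
  }
  structure(list(stable_fraction = stable_fraction,
                 stable_logmean = stable_logmean,
                 drifting_logmean = drifting_logmean,
                 logsd = logsd),
            class = "sigma_mixture")
}

#' Draw true model parameters
#'
#' Generates a ground-truth [parameter_set()] from the generative
#' distributions: `theta ~ N(0,1)`, `beta[,1] ~ N(0,1)`,
#' `beta[,t] ~ N(beta[,t-1], sigma)` for `t > 1`, steps `d[r,2:K]` drawn
#' as iid standard normals conditioned on the zero-sum identification
#' constraint (centered normals), and `sigma` from the
#' two-component mixture in `mix`: `floor(stable_fraction * R)` raters take
#' the stable component, the rest the drifting component, and the component
#' labels are then randomly permuted over raters.
#'
#' @param J,R,T,K Numbers of examinees, raters, time points, categories.
#' @param mix A [sigma_mixture()] specification.
#' @param seed Optional integer seed; when given, the draw is reproducible
#'   and the caller's RNG state is left untouched.
#' @return A [parameter_set()]; attribute `sigma_component` records which
#'   mixture component ("stable" or "drifting") generated each rater's
#'   drift scale.
#' @export
draw_parameters <- function(J, R, T, K = 5L, mix = sigma_mixture(), seed = NULL) {
  stopifnot(inherits(mix, "sigma_mixture"))
  if (J < 1L || R < 1L || T < 1L || K < 2L) stop("invalid dimensions")
  run_seeded(seed, {
    n_stable <- floor(mix$stable_fraction * R)
    component <- sample(rep(c("stable", "drifting"), c(n_stable, R - n_stable)))
    logmean <- ifelse(component == "stable", mix$stable_logmean, mix$drifting_logmean)
    sigma <- stats::rlnorm(R, logmean, mix$logsd)
    theta <- stats::rnorm(J)
    beta <- matrix(0, R, T)
    beta[, 1L] <- stats::rnorm(R)
    if (T > 1L) {
      for (t in 2:T) beta[, t] <- stats::rnorm(R, beta[, t - 1L], sigma)
    }
    # steps: iid standard normals conditioned on the zero-sum constraint
    # (equivalently, centered normals), d[1] = 0
    d <- t(vapply(seq_len(R), function(r) {
      if (K == 2L) return(c(0, 0))
      g <- stats::rnorm(K - 1L)
      c(0, g - mean(g))
    }, numeric(K)))
    out <- parameter_set(theta, beta, sigma, d)
    attr(out, "sigma_component") <- component
    out
  })
}

run_seeded <- function(seed, expr) {
  if (is.null(seed)) eval.parent(substitute(expr)) else
    withr::with_seed(as.integer(seed), eval.parent(substitute(expr)))
}

#' Rating designs
#'
#' `fully_crossed_design()` assigns every rater to every examinee.
#' `systematic_link_design()` assigns each examinee a small set of cyclically
#' consecutive raters (examinee `j` gets raters `((j-1+i) mod R)+1` for
#' `i = 0..n_raters-1`), the overlapping-chain pattern that keeps the
#' examinee-rater graph connected so all raters can be linked to a common
#' scale. In both designs each rater scores each assigned examinee exactly
#' once: for every rater independently, the assigned examinees are randomly
#' permuted and split into `T` contiguous blocks (sizes differing by at most
#' one, larger blocks first), one block per time point — mirroring a rater
#' grading an even share of their workload per session in randomised order.
#'
#' @param J,R,T Numbers of examinees, raters and time points.
#' @param n_raters Raters per examinee for the link design (typically 2 or 3).
#' @param seed Optional integer seed for the time-blocking permutations.
#' @return A data.frame of class `assignment_design` with integer columns
#'   `examinee`, `rater`, `time`.
#' @examples
#' fully_crossed_design(6, 5, T = 1)
#' systematic_link_design(6, 5, n_raters = 2, T = 1)
#' @export
fully_crossed_design <- function(J, R, T, seed = NULL) {
  pairs <- expand.grid(examinee = seq_len(J), rater = seq_len(R))
  build_design(pairs, J, R, T, seed)
}

#' @rdname fully_crossed_design
#' @export
systematic_link_design <- function(J, R, n_raters, T, seed = NULL) {
  if (n_raters < 1L || n_raters > R) stop("n_raters must lie in 1..R")
  pairs <- do.call(rbind, lapply(seq_len(J), function(j) {
    data.frame(examinee = j,
               rater = ((j - 1L + seq_len(n_raters) - 1L) %% R) + 1L)
  }))
  build_design(pairs, J, R, T, seed)
}

build_design <- function(pairs, J, R, T, seed) {
  if (T < 1L) stop("T must be positive")
  J <- as.integer(J); R <- as.integer(R); T <- as.integer(T)
  run_seeded(seed, {
    pairs$examinee <- as.integer(pairs$examinee)
    pairs$rater <- as.integer(pairs$rater)
    pairs$time <- NA_integer_
    for (r in seq_len(R)) {
      idx <- which(pairs$rater == r)
      n <- length(idx)
      if (n == 0L) next
      sizes <- block_sizes(n, T)
      pairs$time[sample(idx)] <- rep(seq_len(T), sizes)
    }
    pairs <- pairs[order(pairs$examinee, pairs$rater), ]
    rownames(pairs) <- NULL
    structure(pairs, J = J, R = R, T = T,
              class = c("assignment_design", "data.frame"))
  })
}

# n items into T contiguous blocks, sizes ceiling(n/T) for the first
# n %% T blocks and floor(n/T) for the rest.
block_sizes <- function(n, T) {
  base <- n %/% T
  extra <- n %% T
  rep(c(base + 1L, base), c(extra, T - extra))
}

#' Simulate score data from the drift model
#'
#' For each assigned (examinee, rater) pair, draws one ordinal score at the
#' pair's time point from the category distribution implied by `params`.
#'
#' @param params A [parameter_set()] (the generating truth).
#' @param design An assignment design from [fully_crossed_design()] or
#'   [systematic_link_design()].
#' @param seed Optional integer seed.
#' @return A [rating_data()] object with one row per assigned pair.
#' @export
simulate_scores <- function(params, design, seed = NULL) {
  stopifnot(inherits(design, "assignment_design"))
  J <- attr(design, "J"); R <- attr(design, "R"); T <- attr(design, "T")
  K <- ncol(params$d)
  if (length(params$theta) < J || nrow(params$beta) < R || ncol(params$beta) < T) {
    stop("design indices exceed parameter dimensions")
  }
  run_seeded(seed, {
    score <- integer(nrow(design))
    for (i in seq_len(nrow(design))) {
      p <- category_probabilities(params$theta[design$examinee[i]],
                                  params$beta[design$rater[i], design$time[i]],
                                  params$d[design$rater[i], ],
                                  params$scaling_D)
      score[i] <- sample.int(K, 1L, prob = p)
    }
    rating_data(data.frame(examinee = design$examinee, rater = design$rater,
                           time = design$time, score = score),
                J = J, R = R, T = T, K = K)
  })
}
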