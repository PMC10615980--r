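# Shared fixtures and independent oracles for the test suite.

# Direct (non-log-space) evaluation of the category probabilities, kept
# deliberately naive so it can serve as an oracle for the log-space
# implementation.
naive_category_probabilities <- function(theta, beta, d, D = 1.7) {
  K <- length(d)
  num <- vapply(seq_len(K), function(k) {
    exp(sum(D * (theta - beta - d[seq_len(k)])))
  }, numeric(1))
  num / sum(num)
}

naive_log_likelihood <- function(data, params) {
  baseline <- inherits(params, "baseline_parameter_set")
  total <- 0
  for (i in seq_len(nrow(data))) {
    steps <- if (baseline) params$d else params$d[data$rater[i], ]
    p <- naive_category_probabilities(params$theta[data$examinee[i]],
                                      params$beta[data$rater[i], data$time[i]],
                                      steps, params$scaling_D)
    total <- total + log(p[data$score[i]])
  }
  total
}

# Random valid parameter set of given dimensions.
random_parameters <- function(J, R, T, K = 5L, markov = TRUE) {
  theta <- rnorm(J)
  beta <- matrix(rnorm(R * T), R, T)
  sigma <- if (markov) rlnorm(R, -2, 1) else NULL
  d <- t(vapply(seq_len(R),
                function(r) constrain_steps(if (K > 2) rnorm(K - 2) else numeric(0)),
                numeric(K)))
  parameter_set(theta, beta, sigma, d)
}

# Tiny deterministic dataset used across files.
tiny_dataset <- function() {
  rating_data(data.frame(
    examinee = c(1L, 1L, 2L, 2L, 3L),
    rater = c(1L, 2L, 1L, 2L, 1L),
    time = c(1L, 1L, 2L, 1L, 2L),
    score = c(2L, 5L, 1L, 3L, 4L)),
    J = 3L, R = 2L, T = 2L, K = 5L)
}

# Map a constrained parameter set to the sampler's unconstrained vector.
# Markov variants use the non-centered severity block: beta_r1 followed by
# the standardised innovations z_rt = (beta_rt - beta_{r,t-1}) / sigma_r.
unconstrained_vector <- function(params, markov = !is.null(params$sigma)) {
  baseline <- inherits(params, "baseline_parameter_set")
  K <- if (baseline) length(params$d) else ncol(params$d)
  dmat <- if (baseline) matrix(params$d, nrow = 1L) else params$d
  free <- if (K > 2) as.vector(t(dmat[, 2:(K - 1L), drop = FALSE])) else numeric(0)
  sev <- params$beta
  if (markov && ncol(sev) > 1L) {
    sev[, -1L] <- (sev[, -1L, drop = FALSE] - sev[, -ncol(sev), drop = FALSE]) /
      params$sigma
  }
  c(params$theta, as.vector(t(sev)),
    if (markov) log(params$sigma), free)
}

# log |det| of the map from the sampler's coordinates to the constrained
# (beta, sigma) scale: sigma_r per innovation (T - 1 of them) plus sigma_r
# for the log-scale transform itself.
sampler_jacobian <- function(params) {
  if (is.null(params$sigma)) return(0)
  ncol(params$beta) * sum(log(params$sigma))
}

# Session-level cache so expensive fits are shared between test files.
.fit_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fit_cache)) {
    assign(key, force(expr), envir = .fit_cache)
  }
  get(key, envir = .fit_cache)
}

# Reference fit: one simulated dataset at the routine desk scale
# (J = 100, R = 5, T = 3, fully crossed) fitted with 3 chains of
# 1000 warmup + 1000 retained draws.
reference_fit <- function() {
  cached("reference_fit", {
    truth <- draw_parameters(100L, 5L, 3L, 5L, seed = 811L)
    des <- fully_crossed_design(100L, 5L, 3L, seed = 812L)
    dat <- simulate_scores(truth, des, seed = 813L)
    fit <- fit_drift(dat, "proposed",
                     config = sampler_config(chains = 3L, iterations = 2000L,
                                             warmup = 1000L, seed = 814L))
    list(truth = truth, data = dat, fit = fit)
  })
}

# Bipartite examinee-rater connectivity by breadth-first search.
design_connected <- function(design) {
  J <- attr(design, "J"); R <- attr(design, "R")
  adj_e <- split(design$rater, design$examinee)
  adj_r <- split(design$examinee, design$rater)
  seen_e <- logical(J); seen_r <- logical(R)
  queue <- list(c("r", 1L))
  seen_r[1L] <- TRUE
  while (length(queue) > 0L) {
    node <- queue[[1L]]; queue <- queue[-1L]
    if (node[1L] == "r") {
      for (e in adj_r[[as.character(node[2L])]]) {
        if (!seen_e[e]) { seen_e[e] <- TRUE; queue[[length(queue) + 1L]] <- c("e", e) }
      }
    } else {
      for (r in adj_e[[as.character(node[2L])]]) {
        if (!seen_r[r]) { seen_r[r] <- TRUE; queue[[length(queue) + 1L]] <- c("r", r) }
      }
    }
  }
  all(seen_e) && all(seen_r)
}
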