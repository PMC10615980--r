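#' Root mean square error and bias
#'
#' Accuracy summaries for one parameter family within one replication:
#' entities of the family are pooled, so `rmse` is
#' `sqrt(mean((estimates - truths)^2))` and `bias` is
#' `mean(estimates - truths)`. Averaging across replications happens at the
#' reporting layer.
#'
#' @param estimates,truths Equal-length numeric vectors.
#' @return A single number.
#' @export
rmse <- function(estimates, truths) {
  if (length(estimates) != length(truths)) stop("length mismatch")
  if (length(estimates) < 1L) stop("need at least one value")
  sqrt(mean((estimates - truths)^2))
}

#' @rdname rmse
#' @export
bias <- function(estimates, truths) {
  if (length(estimates) != length(truths)) stop("length mismatch")
  if (length(estimates) < 1L) stop("need at least one value")
  mean(estimates - truths)
}

#' Configuration of a parameter-recovery experiment
#'
#' Defines the condition grid and per-replication settings of the
#' simulation study: truth is drawn from the generative model (drift scales
#' from the stable/drifting mixture), scores are simulated under the chosen
#' rating design, the model is refitted, and RMSE/bias per parameter family
#' are recorded. The default grid crosses `J` in {100, 200, 500},
#' `R` in {5, 10} and `T` in {3, 5} with `K = 5`.
#'
#' @param grid Data.frame with integer columns `J`, `R`, `T` (one row per
#'   condition). Defaults to the full 12-condition grid.
#' @param K Number of score categories.
#' @param replications Replications per condition.
#' @param design `"crossed"`, `"link2"` or `"link3"`.
#' @param fit_mu_sigma Drift-scale prior log-mean used when fitting.
#' @param mix True drift-scale mixture ([sigma_mixture()]).
#' @param seed Master seed; every draw in the experiment derives from it.
#' @param sampler A [sampler_config()] template (its seed field is ignored;
#'   per-fit seeds derive from `seed`).
#' @return An object of class `recovery_config`.
#' @export
recovery_config <- function(grid = expand.grid(J = c(100L, 200L, 500L),
                                               R = c(5L, 10L),
                                               T = c(3L, 5L)),
                            K = 5L, replications = 50L,
                            design = c("crossed", "link2", "link3"),
                            fit_mu_sigma = -2, mix = sigma_mixture(),
                            seed = 1L,
                            sampler = sampler_config()) {
  design <- match.arg(design)
  if (replications < 1L) stop("replications must be at least 1")
  grid <- as.data.frame(grid)[c("J", "R", "T")]
  grid <- grid[order(grid$J, grid$R, grid$T), , drop = FALSE]
  rownames(grid) <- NULL
  structure(list(grid = grid, K = as.integer(K),
                 replications = as.integer(replications), design = design,
                 fit_mu_sigma = fit_mu_sigma, mix = mix,
                 seed = as.integer(seed), sampler = sampler),
            class = "recovery_config")
}

build_design_for <- function(design, J, R, T, seed) {
  switch(design,
         crossed = fully_crossed_design(J, R, T, seed = seed),
         link2 = systematic_link_design(J, R, 2L, T, seed = seed),
         link3 = systematic_link_design(J, R, 3L, T, seed = seed))
}

# Per-(condition, replication) seeds: four independent streams (truth,
# design, scores, fit), identical across model variants so ablations are
# fitted to the very same datasets.
recovery_seeds <- function(config) {
  n <- nrow(config$grid) * config$replications * 4L
  s <- withr::with_seed(config$seed, sample.int(.Machine$integer.max, n))
  array(s, dim = c(4L, config$replications, nrow(config$grid)))
}

#' Run a parameter-recovery experiment
#'
#' Executes the full loop for one model variant: per condition and
#' replication, draw truth, build the rating design, simulate scores, fit
#' by NUTS, take EAP estimates, and record pooled RMSE and bias per
#' parameter family (`theta`, `beta`, `d`, and `sigma` for Markov
#' variants), together with convergence diagnostics. Fully reproducible
#' from the master seed; the same master seed yields identical simulated
#' datasets for every variant.
#'
#' @param config A [recovery_config()].
#' @param variant Model variant passed to [fit_drift()].
#' @param progress Print one line per completed fit.
#' @param estimator `"eap"` runs the full sampler; `"oracle"` substitutes
#'   the true parameters for the estimates (a plumbing hook that bypasses
#'   sampling and must produce all-zero errors).
#' @return An object of class `recovery_report`: `results` (one row per
#'   condition x replication x family), `by_condition` (RMSE/bias averaged
#'   over replications), `grand` (averages over all conditions), plus the
#'   config, variant and a count of failed replications.
#' @export
run_recovery <- function(config, variant = "proposed", progress = FALSE,
                         estimator = c("eap", "oracle")) {
  stopifnot(inherits(config, "recovery_config"))
  variant <- match.arg(variant, MODEL_VARIANTS)
  estimator <- match.arg(estimator)
  seeds <- recovery_seeds(config)
  hyper <- hyperparameters(config$fit_mu_sigma)
  rows <- list()
  failures <- 0L
  for (ci in seq_len(nrow(config$grid))) {
    J <- config$grid$J[ci]; R <- config$grid$R[ci]; T <- config$grid$T[ci]
    for (rep in seq_len(config$replications)) {
      s <- seeds[, rep, ci]
      truth <- draw_parameters(J, R, T, config$K, mix = config$mix, seed = s[1L])
      des <- build_design_for(config$design, J, R, T, seed = s[2L])
      dat <- simulate_scores(truth, des, seed = s[3L])
      t_fit <- Sys.time()
      if (estimator == "oracle") {
        fam <- family_errors(truth, truth,
                             variant_opts(variant, hyper, 1))
        for (f in names(fam)) {
          rows[[length(rows) + 1L]] <- data.frame(
            J = J, R = R, T = T, design = config$design, rep = rep,
            family = f, rmse = fam[[f]]["rmse"], bias = fam[[f]]["bias"],
            max_rhat = NA_real_, min_ess = NA_real_, divergent = NA_integer_,
            seconds = as.numeric(Sys.time() - t_fit, units = "secs"),
            stringsAsFactors = FALSE)
        }
        next
      }
      fit <- tryCatch(
        fit_drift(dat, variant = variant, hyper = hyper,
                  config = sampler_config(
                    chains = config$sampler$chains,
                    iterations = config$sampler$iterations,
                    warmup = config$sampler$warmup,
                    target_acceptance = config$sampler$target_acceptance,
                    seed = s[4L],
                    max_treedepth = config$sampler$max_treedepth)),
        error = function(e) e)
      if (inherits(fit, "error")) {
        failures <- failures + 1L
        warning(sprintf("replication failed (J=%d R=%d T=%d rep %d): %s",
                        J, R, T, rep, conditionMessage(fit)), call. = FALSE)
        next
      }
      est <- eap(fit)
      diag <- diagnostics(fit)
      fam <- family_errors(est, truth, fit$opts)
      for (f in names(fam)) {
        rows[[length(rows) + 1L]] <- data.frame(
          J = J, R = R, T = T, design = config$design, rep = rep,
          family = f, rmse = fam[[f]]["rmse"], bias = fam[[f]]["bias"],
          max_rhat = max(diag$parameters$rhat[is.finite(diag$parameters$rhat)]),
          min_ess = min(diag$parameters$ess),
          divergent = diag$divergent,
          seconds = as.numeric(Sys.time() - t_fit, units = "secs"),
          stringsAsFactors = FALSE)
      }
      if (progress) {
        message(sprintf("J=%d R=%d T=%d rep %d/%d done (%s)",
                        J, R, T, rep, config$replications, variant))
      }
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  by_condition <- stats::aggregate(cbind(rmse, bias) ~ J + R + T + family,
                                   data = results, FUN = mean)
  grand <- stats::aggregate(cbind(rmse, bias) ~ family, data = by_condition,
                            FUN = mean)
  structure(list(results = results, by_condition = by_condition,
                 grand = grand, config = config, variant = variant,
                 failures = failures),
            class = "recovery_report")
}

# Pooled estimate/truth vectors per parameter family.
family_errors <- function(est, truth, opts) {
  K <- ncol(truth$d)
  out <- list(
    theta = c(rmse = rmse(est$theta, truth$theta),
              bias = bias(est$theta, truth$theta)),
    beta = c(rmse = rmse(as.vector(est$beta), as.vector(truth$beta)),
             bias = bias(as.vector(est$beta), as.vector(truth$beta))))
  est_d <- if (is.matrix(est$d)) est$d else
    matrix(est$d, nrow = nrow(truth$d), ncol = K, byrow = TRUE)
  out$d <- c(rmse = rmse(as.vector(est_d[, -1L]), as.vector(truth$d[, -1L])),
             bias = bias(as.vector(est_d[, -1L]), as.vector(truth$d[, -1L])))
  if (!is.null(est$sigma)) {
    out$sigma <- c(rmse = rmse(est$sigma, truth$sigma),
                   bias = bias(est$sigma, truth$sigma))
  }
  out
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("recovery_report: variant '%s', design '%s', %d condition(s) x %d replication(s)\n",
              x$variant, x$config$design, nrow(x$config$grid),
              x$config$replications))
  if (x$failures > 0L) cat(sprintf("  %d failed replication(s) excluded\n", x$failures))
  cat("Grand averages:\n")
  print(x$grand, row.names = FALSE)
  invisible(x)
}

#' Paired comparison of two recovery reports
#'
#' Pairs the per-condition averaged RMSEs of two reports run on the same
#' condition grid (typically the same data fitted with and without the
#' Markov severity prior) and performs a two-sided paired t-test per
#' parameter family shared by both reports.
#'
#' @param report_a,report_b `recovery_report` objects on identical grids.
#' @return Data.frame with one row per shared family: mean RMSE under each
#'   report, mean difference (`a - b`), `t`, `df`, `p_value`, and a
#'   `degenerate` flag for zero within-pair variance.
#' @export
paired_comparison <- function(report_a, report_b) {
  stopifnot(inherits(report_a, "recovery_report"),
            inherits(report_b, "recovery_report"))
  ga <- report_a$by_condition
  gb <- report_b$by_condition
  fams <- intersect(unique(ga$family), unique(gb$family))
  rows <- lapply(fams, function(f) {
    a <- ga[ga$family == f, ]
    b <- gb[gb$family == f, ]
    key_a <- paste(a$J, a$R, a$T)
    key_b <- paste(b$J, b$R, b$T)
    if (!identical(sort(key_a), sort(key_b))) {
      stop("condition grids of the two reports do not match")
    }
    b <- b[match(key_a, key_b), ]
    diff <- a$rmse - b$rmse
    degenerate <- length(diff) < 2L ||
      stats::sd(diff) < 1e-10 * max(1, abs(mean(diff)))
    tt <- if (!degenerate) {
      tryCatch(stats::t.test(a$rmse, b$rmse, paired = TRUE),
               error = function(e) NULL)
    }
    if (is.null(tt)) {
      degenerate <- TRUE
      tt <- list(statistic = NA_real_, parameter = NA_real_,
                 p.value = if (all(diff == 0)) 1 else NA_real_)
    }
    data.frame(family = f, mean_a = mean(a$rmse), mean_b = mean(b$rmse),
               mean_difference = mean(diff),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_value = tt$p.value, degenerate = degenerate,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Prior-sensitivity sweep for the drift-scale prior
#'
#' Fits the proposed model at each requested `mu_sigma` plus the
#' independent-severity ablation on the same dataset, and returns the EAP
#' severity trajectories per rater under each setting, suitable for
#' trajectory plots.
#'
#' @param data A [rating_data()] object.
#' @param mu_values Numeric vector of drift-scale prior log-means.
#' @param config A [sampler_config()].
#' @param include_no_markov Also fit the independent-severity ablation.
#' @return Data.frame with columns `setting`, `rater`, `time`, `beta_hat`;
#'   attribute `data_hash` records an MD5 of the input data for provenance.
#' @export
prior_sensitivity_sweep <- function(data, mu_values = c(-5, -2, 0),
                                    config = sampler_config(),
                                    include_no_markov = TRUE) {
  stopifnot(inherits(data, "rating_data"))
  settings <- c(paste0("mu_sigma=", mu_values),
                if (include_no_markov) "no_markov")
  rows <- list()
  for (s in seq_along(settings)) {
    if (settings[s] == "no_markov") {
      fit <- fit_drift(data, variant = "proposed_no_markov", config = config)
    } else {
      fit <- fit_drift(data, variant = "proposed",
                       hyper = hyperparameters(mu_values[s]), config = config)
    }
    b <- eap(fit)$beta
    rows[[s]] <- data.frame(setting = settings[s],
                            rater = rep(seq_len(nrow(b)), ncol(b)),
                            time = rep(seq_len(ncol(b)), each = nrow(b)),
                            beta_hat = as.vector(b),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "data_hash") <- data_md5(data)
  out
}

data_md5 <- function(data) {
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  utils::write.csv(as.data.frame(data), f, row.names = FALSE)
  unname(tools::md5sum(f))
}
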