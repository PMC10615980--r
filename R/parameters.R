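#' Step-parameter identification constraints
#'
#' Map a free coordinate vector of length `K - 2` to a full step vector of
#' length `K` satisfying the identification constraints `d[1] = 0` and
#' `sum(d[2:K]) = 0`: the result is `(0, free, -sum(free))`. For `K = 2` the
#' step vector is fully determined as `(0, 0)` and `free` must be empty.
#'
#' @param free Numeric vector of free step coordinates (length `K - 2`).
#' @return Numeric step vector of length `length(free) + 2`.
#' @seealso [unconstrain_steps()] for the inverse map.
#' @examples
#' constrain_steps(c(-0.8, -0.2, 0.3))  # K = 5
#' @export
constrain_steps <- function(free) {
  if (length(free) == 0L) return(c(0, 0))
  if (!is.numeric(free) || anyNA(free)) stop("free step coordinates must be finite numerics")
  c(0, free, -sum(free))
}

#' @rdname constrain_steps
#' @param d A full step vector of length `K` satisfying both constraints.
#' @return For `unconstrain_steps`, the `K - 2` free coordinates.
#' @export
unconstrain_steps <- function(d) {
  K <- length(d)
  if (K < 2L) stop("step vector must have length >= 2")
  if (abs(d[1L]) > 1e-8) stop("step vector must have d[1] = 0")
  if (abs(sum(d[-1L])) > 1e-8) stop("step vector must satisfy sum(d[2:K]) = 0")
  if (K == 2L) return(numeric(0))
  d[2:(K - 1L)]
}

#' Parameter set for the drift model
#'
#' Bundle of the model parameters: examinee abilities `theta` (length `J`),
#' time-specific rater severities `beta` (`R x T` matrix), rater drift scales
#' `sigma` (length `R`, strictly positive; `NULL` for the ablation whose
#' severities are a priori independent), and rater-specific step parameters
#' `d` (`R x K` matrix, each row satisfying `d[r,1] = 0`,
#' `sum(d[r,2:K]) = 0`).
#'
#' @param theta Numeric vector of abilities.
#' @param beta Numeric matrix of severities, raters in rows, time in columns.
#' @param sigma Positive numeric vector of drift scales, or `NULL`.
#' @param d Numeric matrix of step parameters (`R x K`).
#' @param scaling_D Logistic scaling constant; 1.7 throughout.
#' @return An object of class `parameter_set`.
#' @export
parameter_set <- function(theta, beta, sigma, d, scaling_D = 1.7) {
  beta <- as.matrix(beta)
  d <- as.matrix(d)
  R <- nrow(beta)
  if (nrow(d) != R) stop("beta and d must have one row per rater")
  if (!is.null(sigma)) {
    if (length(sigma) != R) stop("sigma must have one entry per rater")
    if (any(!is.finite(sigma)) || any(sigma <= 0)) stop("sigma must be strictly positive")
  }
  if (any(!is.finite(theta)) || any(!is.finite(beta)) || any(!is.finite(d))) {
    stop("parameters must be finite")
  }
  check_step_rows(d)
  structure(list(theta = as.numeric(theta), beta = beta, sigma = sigma,
                 d = d, scaling_D = scaling_D),
            class = "parameter_set")
}

check_step_rows <- function(d, tol = 1e-8) {
  if (any(abs(d[, 1L]) > tol)) stop("step parameters must have d[r,1] = 0")
  if (ncol(d) >= 2L && any(abs(rowSums(d[, -1L, drop = FALSE])) > tol)) {
    stop("step parameters must satisfy sum(d[r,2:K]) = 0")
  }
  invisible(TRUE)
}

#' Parameter set for the shared-step (baseline) model
#'
#' As [parameter_set()] but with a single step vector `d` of length `K`
#' shared by all raters, following the classical many-facet Rasch
#' parameterisation with time-specific severities.
#'
#' @inheritParams parameter_set
#' @param d Numeric step vector of length `K` (`d[1] = 0`,
#'   `sum(d[2:K]) = 0`).
#' @return An object of class `baseline_parameter_set`.
#' @export
baseline_parameter_set <- function(theta, beta, d, sigma = NULL, scaling_D = 1.7) {
  beta <- as.matrix(beta)
  R <- nrow(beta)
  if (!is.null(sigma)) {
    if (length(sigma) != R) stop("sigma must have one entry per rater")
    if (any(!is.finite(sigma)) || any(sigma <= 0)) stop("sigma must be strictly positive")
  }
  if (any(!is.finite(theta)) || any(!is.finite(beta)) || any(!is.finite(d))) {
    stop("parameters must be finite")
  }
  check_step_rows(matrix(d, nrow = 1L))
  structure(list(theta = as.numeric(theta), beta = beta, sigma = sigma,
                 d = as.numeric(d), scaling_D = scaling_D),
            class = "baseline_parameter_set")
}

#' @export
print.parameter_set <- function(x, ...) {
  cat(sprintf("parameter_set: J = %d, R = %d, T = %d, K = %d%s\n",
              length(x$theta), nrow(x$beta), ncol(x$beta), ncol(x$d),
              if (is.null(x$sigma)) " (no drift scales)" else ""))
  invisible(x)
}

#' @export
print.baseline_parameter_set <- function(x, ...) {
  cat(sprintf("baseline_parameter_set: J = %d, R = %d, T = %d, K = %d%s\n",
              length(x$theta), nrow(x$beta), ncol(x$beta), length(x$d),
              if (is.null(x$sigma)) " (no drift scales)" else ""))
  invisible(x)
}

#' Hyperparameters of the drift-scale prior
#'
#' The rater drift scales follow a log-normal prior `LN(mu_sigma, 1)`. The
#' log-scale mean `mu_sigma` encodes prior belief about how common severity
#' drift is across raters (smaller = drift believed rare); its default -2 is
#' the moderate setting recommended for routine use. The log-scale standard
#' deviation is fixed at 1 to keep the prior's shape interpretable in terms
#' of `mu_sigma` alone.
#'
#' @param mu_sigma Log-scale mean of the drift-scale prior.
#' @return An object of class `hyperparameters`.
#' @export
hyperparameters <- function(mu_sigma = -2) {
  if (!is.numeric(mu_sigma) || length(mu_sigma) != 1L || !is.finite(mu_sigma)) {
    stop("mu_sigma must be a single finite number")
  }
  structure(list(mu_sigma = mu_sigma, prior_sd_sigma = 1), class = "hyperparameters")
}

#' Serialise a parameter set to JSON
#'
#' Writes explicit dimensions and the full (constrained) step matrix so the
#' file round-trips without reference to the free-coordinate convention.
#'
#' @param params A `parameter_set` or `baseline_parameter_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, c("parameter_set", "baseline_parameter_set")))
  baseline <- inherits(params, "baseline_parameter_set")
  K <- if (baseline) length(params$d) else ncol(params$d)
  obj <- list(
    model = if (baseline) "baseline" else "proposed",
    J = length(params$theta), R = nrow(params$beta),
    T = ncol(params$beta), K = K,
    theta = params$theta,
    beta = params$beta,
    sigma = params$sigma,
    d = params$d,
    scaling_D = params$scaling_D
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_parameters
#' @return For `read_parameters`, the reconstructed parameter set.
#' @export
read_parameters <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sigma <- if (is.null(obj$sigma)) NULL else as.numeric(obj$sigma)
  beta <- matrix(as.numeric(obj$beta), nrow = obj$R, ncol = obj$T)
  if (identical(obj$model, "baseline")) {
    baseline_parameter_set(as.numeric(obj$theta), beta, as.numeric(obj$d),
                           sigma = sigma, scaling_D = obj$scaling_D)
  } else {
    parameter_set(as.numeric(obj$theta), beta, sigma,
                  matrix(as.numeric(obj$d), nrow = obj$R, ncol = obj$K),
                  scaling_D = obj$scaling_D)
  }
}
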