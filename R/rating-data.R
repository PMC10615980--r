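#' Long-format rating data
#'
#' Construct a validated container for longitudinal polytomous rating data.
#' Each row records one ordinal score given by one rater to one examinee at
#' one time point (a contiguous rating period: a session, an hour, a day).
#'
#' @param scores A data.frame with integer columns `examinee`, `rater`,
#'   `time`, `score` (all 1-based).
#' @param J,R,T,K Declared numbers of examinees, raters, time points and
#'   score categories. Defaults are taken from the maxima observed in
#'   `scores` (with `K >= 2` enforced).
#'
#' @return An object of class `rating_data`: the data.frame with attributes
#'   `J`, `R`, `T`, `K`.
#'
#' @details Scores must lie in `1..K`; indices must lie within the declared
#'   ranges; at most one observation may exist per (examinee, rater, time)
#'   triple. Violations are errors, never silently repaired.
#'
#' @examples
#' d <- rating_data(data.frame(examinee = 1:2, rater = 1L, time = 1L,
#'                             score = c(3L, 5L)), K = 5)
#' dims(d)
#' @export
rating_data <- function(scores, J = NULL, R = NULL, T = NULL, K = NULL) {
  required <- c("examinee", "rater", "time", "score")
  missing_cols <- setdiff(required, names(scores))
  if (length(missing_cols) > 0L) {
    stop("rating data is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  scores <- as.data.frame(scores)[required]
  for (col in required) {
    v <- scores[[col]]
    if (!is.numeric(v) || anyNA(v) || any(v != as.integer(v))) {
      stop("column '", col, "' must be integer-valued with no missing entries")
    }
    scores[[col]] <- as.integer(v)
  }
  n <- nrow(scores)
  J <- if (is.null(J)) if (n) max(scores$examinee) else 1L else as.integer(J)
  R <- if (is.null(R)) if (n) max(scores$rater) else 1L else as.integer(R)
  T <- if (is.null(T)) if (n) max(scores$time) else 1L else as.integer(T)
  K <- if (is.null(K)) if (n) max(2L, max(scores$score)) else 2L else as.integer(K)
  if (K < 2L) stop("K must be at least 2")
  if (J < 1L || R < 1L || T < 1L) stop("J, R and T must be positive")
  if (n > 0L) {
    check_range <- function(v, hi, what) {
      if (any(v < 1L) || any(v > hi)) {
        stop(what, " index out of declared range 1..", hi)
      }
    }
    check_range(scores$examinee, J, "examinee")
    check_range(scores$rater, R, "rater")
    check_range(scores$time, T, "time")
    if (any(scores$score < 1L) || any(scores$score > K)) {
      stop("score out of range 1..", K)
    }
    key <- paste(scores$examinee, scores$rater, scores$time)
    if (anyDuplicated(key)) {
      stop("duplicate observation for the same (examinee, rater, time) triple")
    }
  }
  structure(scores,
            J = J, R = R, T = T, K = K,
            class = c("rating_data", "data.frame"))
}

#' Dimensions of a rating dataset
#'
#' @param x A `rating_data` object.
#' @return Named list with elements `J`, `R`, `T`, `K` and `n` (observations).
#' @export
dims <- function(x) {
  stopifnot(inherits(x, "rating_data"))
  list(J = attr(x, "J"), R = attr(x, "R"), T = attr(x, "T"),
       K = attr(x, "K"), n = nrow(x))
}

#' @export
print.rating_data <- function(x, ...) {
  d <- dims(x)
  cat(sprintf(
    "rating_data: %d observations (J = %d examinees, R = %d raters, T = %d time points, K = %d categories)\n",
    d$n, d$J, d$R, d$T, d$K))
  if (d$n > 0L) {
    print(utils::head(as.data.frame(x), 6L))
    if (d$n > 6L) cat("...\n")
  }
  invisible(x)
}

#' Read rating data from CSV
#'
#' The file must have header `examinee,rater,time,score` with 1-based integer
#' columns. Parsing is strict: out-of-range scores are an error, not a clamp.
#'
#' @param path Path to the CSV file.
#' @inheritParams rating_data
#' @return A `rating_data` object.
#' @export
read_ratings <- function(path, J = NULL, R = NULL, T = NULL, K = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  rating_data(df, J = J, R = R, T = T, K = K)
}

#' Write rating data to CSV
#'
#' @param x A `rating_data` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ratings <- function(x, path) {
  stopifnot(inherits(x, "rating_data"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
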