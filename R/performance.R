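#' Accuracy: median signed final error
#'
#' @param errors signed final errors, meters.
#' @return Sample median, sign preserved.
#' @export
accuracy <- function(errors) {
  errors <- errors[!is.na(errors)]
  if (length(errors) == 0L) stop("empty input")
  stats::median(errors)
}

#' Precision: interquartile range of the signed final error
#'
#' Q3 - Q1 under the linear-interpolation quantile convention
#' ([stats::quantile()] type 7). Smaller is better; translation-invariant.
#'
#' @param errors signed final errors, meters (>= 2 values).
#' @return IQR in meters.
#' @export
precision_iqr <- function(errors) {
  errors <- errors[!is.na(errors)]
  if (length(errors) < 2L) stop("need at least 2 values")
  unname(diff(stats::quantile(errors, c(0.25, 0.75), type = 7)))
}

# sup distance between the ECDF and the normal CDF with estimated moments
lilliefors_statistic <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / stats::sd(x))
  p <- stats::pnorm(z)
  max(pmax(seq_len(n) / n - p, p - (seq_len(n) - 1) / n))
}

#' Lilliefors normality test with Monte-Carlo p-value
#'
#' Kolmogorov-Smirnov-type sup distance between the empirical CDF and a
#' normal CDF with mean and SD estimated from the sample; because the
#' parameters are estimated, the null distribution is obtained by seeded
#' Monte-Carlo simulation of standard-normal samples of the same size
#' (the statistic is affine-invariant, so the simulated null is exact up to
#' Monte-Carlo error).
#'
#' @param x numeric sample, n >= 4, non-degenerate.
#' @param n_mc Monte-Carlo replicates for the null.
#' @param seed RNG seed for the null simulation.
#' @return List `statistic`, `p`, `n`, `n_mc`.
#' @export
lilliefors <- function(x, n_mc = 10000, seed = 1L) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 4L) stop("need at least 4 observations")
  if (stats::sd(x) == 0) stop("degenerate input: zero variance")
  d <- lilliefors_statistic(x)
  null <- local({
    set.seed(seed)
    vapply(seq_len(n_mc),
           function(i) lilliefors_statistic(stats::rnorm(n)), numeric(1))
  })
  list(statistic = d, p = (sum(null >= d) + 1) / (n_mc + 1), n = n, n_mc = n_mc)
}

#' Per-condition performance summaries
#'
#' @param measures per-trial measures with `signed_error_m` (see
#'   [cohort_measures()]).
#' @return data.frame: one row per participant x direction x coordination
#'   with `accuracy` (median signed error, m), `precision` (IQR, m) and
#'   `n_trials`.
#' @export
condition_performance <- function(measures) {
  key <- interaction(measures$participant_id, measures$direction,
                     measures$coordination, drop = TRUE)
  rows <- lapply(split(measures, key), function(cell) {
    data.frame(participant_id = cell$participant_id[1], group = cell$group[1],
               direction = cell$direction[1],
               coordination = cell$coordination[1],
               accuracy = accuracy(cell$signed_error_m),
               precision = precision_iqr(cell$signed_error_m),
               n_trials = sum(!is.na(cell$signed_error_m)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$participant_id, out$direction, out$coordination), ]
}
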