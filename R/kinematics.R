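#' Resample a jittered yaw series onto a uniform grid
#'
#' Compensates for sampling jitter and missing data points by linear
#' interpolation onto a uniform grid at `rate_hz` spanning the observed time
#' range (no extrapolation).
#'
#' @param timestamps_s strictly increasing sample times, seconds.
#' @param values_deg yaw samples, degrees.
#' @param rate_hz target rate, Hz (default 90).
#' @return A `uniform_trace` list: `start_time_s`, `rate_hz`, `values_deg`.
#' @export
resample_uniform <- function(timestamps_s, values_deg, rate_hz = 90) {
  n <- length(timestamps_s)
  if (n < 2L) stop("need at least 2 samples")
  if (length(values_deg) != n) stop("timestamps and values lengths differ")
  if (any(diff(timestamps_s) <= 0))
    stop("timestamps must be strictly increasing")
  if (any(!is.finite(values_deg))) stop("values must be finite")
  grid <- seq(timestamps_s[1], timestamps_s[n], by = 1 / rate_hz)
  v <- stats::approx(timestamps_s, values_deg, xout = grid)$y
  structure(list(start_time_s = grid[1], rate_hz = rate_hz, values_deg = v),
            class = "uniform_trace")
}

#' Construct a uniform trace from already-gridded values
#'
#' @param values_deg yaw values on a uniform grid, degrees.
#' @param rate_hz grid rate, Hz.
#' @param start_time_s time of the first sample, seconds.
#' @return A `uniform_trace` list.
#' @export
uniform_trace <- function(values_deg, rate_hz = 90, start_time_s = 0) {
  structure(list(start_time_s = start_time_s, rate_hz = rate_hz,
                 values_deg = values_deg),
            class = "uniform_trace")
}

#' Moving-average smoothing of a uniform trace
#'
#' Centered moving average over exactly `window` samples; only positions
#' with a full window are retained, so the output is shorter by
#' `window - 1`. With the default even window of 18 the alignment is
#' asymmetric (9 samples left of the assigned center, 8 right); the induced
#' half-sample delay is identical across channels filtered with the same
#' window, so relative head-trunk timing is preserved.
#'
#' @param trace a `uniform_trace`.
#' @param window window length in samples (>= 1).
#' @return Smoothed `uniform_trace` with updated `start_time_s`.
#' @export
smooth_ma <- function(trace, window = 18) {
  stopifnot(inherits(trace, "uniform_trace"))
  x <- trace$values_deg
  n <- length(x)
  if (window < 1) stop("window must be >= 1")
  if (n < window) stop("degenerate trace: shorter than the smoothing window")
  cs <- cumsum(c(0, x))
  sm <- (cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) / window
  left <- floor(window / 2)  # samples to the left of the assigned center
  uniform_trace(sm, trace$rate_hz,
                trace$start_time_s + left / trace$rate_hz)
}

# one central-difference pass; loses one sample at each boundary
central_diff <- function(x, rate_hz) {
  n <- length(x)
  (x[3:n] - x[1:(n - 2)]) * rate_hz / 2
}

#' Angular jerk of a yaw trace
#'
#' Third time derivative via three successive central differences on the
#' uniform grid; the three boundary samples on each side lacking a full
#' stencil are dropped. Exact for cubic polynomials in time.
#'
#' @param trace a `uniform_trace` of yaw in degrees.
#' @return A `jerk_trace` list: `start_time_s`, `rate_hz`, `values` in
#'   deg/s^3.
#' @export
jerk <- function(trace) {
  stopifnot(inherits(trace, "uniform_trace"))
  x <- trace$values_deg
  if (length(x) < 7L) stop("degenerate trace: need >= 7 samples for jerk")
  r <- trace$rate_hz
  v <- central_diff(central_diff(central_diff(x, r), r), r)
  structure(list(start_time_s = trace$start_time_s + 3 / r, rate_hz = r,
                 values = v),
            class = "jerk_trace")
}

#' Root mean square
#'
#' @param values non-empty numeric vector.
#' @return `sqrt(mean(values^2))`.
#' @export
rms <- function(values) {
  if (length(values) == 0L) stop("empty input")
  sqrt(mean(values^2))
}

#' Fit an autoregressive prewhitening model
#'
#' Fits AR(p) by ordinary least squares for p = 0..`max_order` and selects
#' the order by AIC (via [stats::ar()]); the fitted AR polynomial is checked
#' for stationarity (all roots outside the unit circle).
#'
#' @param x numeric series (typically a jerk trace's values).
#' @param max_order maximum AR order considered.
#' @return A `prewhiten_model` list: `order`, `ar` (coefficients), `mean`,
#'   `aic` (AIC trace relative to the minimum).
#' @export
fit_prewhitener <- function(x, max_order = 20) {
  if (inherits(x, "jerk_trace")) x <- x$values
  n <- length(x)
  if (n < 10 * max(1, max_order)) stop("series too short for the requested max order")
  if (stats::sd(x) == 0) stop("degenerate series: zero variance")
  fit <- stats::ar(x, aic = TRUE, order.max = max_order, method = "ols",
                   demean = TRUE, intercept = FALSE)
  coefs <- as.numeric(fit$ar)
  if (length(coefs)) {
    roots <- polyroot(c(1, -coefs))
    if (any(Mod(roots) <= 1 + 1e-8))
      stop(sprintf("non-stationary AR fit: min root modulus %.4f", min(Mod(roots))))
  }
  structure(list(order = fit$order, ar = coefs, mean = mean(x), aic = fit$aic),
            class = "prewhiten_model")
}

# AR innovation filter: e_t = (x_t - mu) - sum phi_i (x_{t-i} - mu)
ar_residuals <- function(x, model) {
  xc <- x - mean(x)
  p <- length(model$ar)
  if (p == 0L) return(xc)
  e <- stats::filter(xc, c(1, -model$ar), method = "convolution", sides = 1)
  as.numeric(e[(p + 1):length(e)])
}

#' Prewhiten a head-trunk jerk pair with one AR filter
#'
#' Both series are passed through the same AR innovation filter (by default
#' the model fitted on the head series), so that their relative timing is
#' preserved while the autocorrelation that would bias cross-correlation
#' inference is removed.
#'
#' @param head,trunk `jerk_trace` objects (or numeric vectors) of equal
#'   length and rate.
#' @param model a `prewhiten_model`, e.g. from [fit_prewhitener()] on the
#'   head series.
#' @return List of two filtered numeric vectors, `head` and `trunk`.
#' @export
prewhiten_pair <- function(head, trunk, model) {
  hv <- if (inherits(head, "jerk_trace")) head$values else head
  tv <- if (inherits(trunk, "jerk_trace")) trunk$values else trunk
  if (length(hv) != length(tv)) stop("head and trunk series lengths differ")
  h <- ar_residuals(hv, model)
  t <- ar_residuals(tv, model)
  if (length(h) != length(t)) stop("length mismatch after filtering")
  list(head = h, trunk = t)
}

#' Peak of the normalized cross-correlation between two series
#'
#' Mean-removed, unit-variance normalized cross-correlation (the
#' [stats::ccf()] convention: denominator `n * sd(x) * sd(y)`), scanned over
#' lags up to `max_lag_s`; returns the maximum of `|r|` and its lag, ties
#' resolved toward the smallest `|lag|`.
#'
#' @param x,y equal-length numeric series (or `jerk_trace`s).
#' @param rate_hz sampling rate (taken from the traces when present).
#' @param max_lag_s lag search half-window, seconds.
#' @param signed if `TRUE` the signed maximum is used instead of `|r|`.
#' @return List `peak` (in [0, 1], or signed r), `lag_s`.
#' @export
cross_peak <- function(x, y, rate_hz = NULL, max_lag_s = 0.5, signed = FALSE) {
  if (inherits(x, "jerk_trace")) { rate_hz <- x$rate_hz; x <- x$values }
  if (inherits(y, "jerk_trace")) { if (is.null(rate_hz)) rate_hz <- y$rate_hz; y <- y$values }
  if (is.null(rate_hz)) stop("rate_hz required for numeric inputs")
  n <- length(x)
  if (length(y) != n) stop("series lengths differ")
  if (n < 30L) stop("series too short for cross-correlation")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate signal: zero variance")
  max_lag <- floor(max_lag_s * rate_hz)
  if (max_lag >= n) stop("max_lag_s exceeds the trace duration")
  xc <- x - mean(x); yc <- y - mean(y)
  denom <- n * stats::sd(x) * stats::sd(y) * (n - 1) / n
  lags <- -max_lag:max_lag
  r <- vapply(lags, function(k) {
    if (k >= 0) sum(xc[1:(n - k)] * yc[(1 + k):n]) else
      sum(xc[(1 - k):n] * yc[1:(n + k)])
  }, numeric(1)) / denom
  score <- if (signed) r else abs(r)
  best <- which(score == max(score))
  if (length(best) > 1L) best <- best[which.min(abs(lags[best]))]
  list(peak = if (signed) r[best] else abs(r[best]), lag_s = lags[best] / rate_hz)
}

#' Per-trial kinematic measures
#'
#' Runs the full measure chain on one execution-step trace: resample both
#' yaw channels at `rate_hz`, smooth with an `window`-sample moving
#' average, differentiate three times to jerk, take the trunk jerk RMS,
#' prewhiten the pair with an AR model fitted (by default) on the head
#' jerk, and locate the cross-correlation peak. A zero-variance trunk jerk
#' yields `trunk_rms` as computed (0 for a constant channel) and a missing
#' cross-peak (`NA`, never imputed as 0) with the reason recorded.
#'
#' @param trace data.frame with `t_s, head_yaw_deg, trunk_yaw_deg`.
#' @param rate_hz resampling rate, Hz.
#' @param window moving-average window, samples.
#' @param max_lag_s cross-correlation search half-window, seconds.
#' @param ar_max_order maximum prewhitening AR order.
#' @param fit_on which series drives the AR fit: `"head"`, `"trunk"`, or
#'   `"each"` (each series filtered by its own model).
#' @return List `trunk_rms`, `cross_peak`, `peak_lag_s`, `note`
#'   (`NA_character_` or the degeneracy reason).
#' @export
trial_measures <- function(trace, rate_hz = 90, window = 18, max_lag_s = 0.5,
                           ar_max_order = 20, fit_on = c("head", "trunk", "each")) {
  fit_on <- match.arg(fit_on)
  chain <- function(v) jerk(smooth_ma(resample_uniform(trace$t_s, v, rate_hz),
                                      window))
  hj <- chain(trace$head_yaw_deg)
  tj <- chain(trace$trunk_yaw_deg)
  trunk_rms <- rms(tj$values)
  if (stats::sd(tj$values) == 0 || stats::sd(hj$values) == 0) {
    return(list(trunk_rms = trunk_rms, cross_peak = NA_real_,
                peak_lag_s = NA_real_,
                note = "zero-variance jerk channel; cross-peak missing"))
  }
  mo <- min(ar_max_order, floor(length(hj$values) / 10))
  pw <- if (fit_on == "each") {
    mh <- fit_prewhitener(hj$values, mo)
    mt <- fit_prewhitener(tj$values, mo)
    h <- ar_residuals(hj$values, mh)
    t <- ar_residuals(tj$values, mt)
    k <- min(length(h), length(t))
    list(head = h[(length(h) - k + 1):length(h)],
         trunk = t[(length(t) - k + 1):length(t)])
  } else {
    ref <- if (fit_on == "head") hj$values else tj$values
    prewhiten_pair(hj, tj, fit_prewhitener(ref, mo))
  }
  if (stats::sd(pw$trunk) == 0 || stats::sd(pw$head) == 0)
    return(list(trunk_rms = trunk_rms, cross_peak = NA_real_,
                peak_lag_s = NA_real_,
                note = "zero-variance prewhitened channel; cross-peak missing"))
  cp <- cross_peak(pw$head, pw$trunk, rate_hz = rate_hz, max_lag_s = max_lag_s)
  list(trunk_rms = trunk_rms, cross_peak = cp$peak, peak_lag_s = cp$lag_s,
       note = NA_character_)
}

#' Measures for every trace of a cohort
#'
#' @param traces named list of trace data.frames as produced by
#'   [generate_cohort()] (each carrying `participant_id, group, direction,
#'   coordination, trial` columns).
#' @param metadata cohort metadata (for the signed final error), or `NULL`.
#' @param ... passed to [trial_measures()].
#' @return data.frame: one row per trial with identifiers, `trunk_rms`,
#'   `cross_peak`, `peak_lag_s`, `signed_error_m`, `note`.
#' @export
cohort_measures <- function(traces, metadata = NULL, ...) {
  rows <- lapply(names(traces), function(key) {
    tr <- traces[[key]]
    m <- trial_measures(tr, ...)
    err <- NA_real_
    if (!is.null(metadata)) {
      hit <- metadata$participant_id == tr$participant_id[1] &
        metadata$direction == tr$direction[1] &
        metadata$coordination == tr$coordination[1] &
        metadata$trial == tr$trial[1]
      if (any(hit)) err <- metadata$signed_final_error_m[which(hit)[1]]
    }
    data.frame(participant_id = tr$participant_id[1], group = tr$group[1],
               direction = tr$direction[1], coordination = tr$coordination[1],
               trial = tr$trial[1], trunk_rms = m$trunk_rms,
               cross_peak = m$cross_peak, peak_lag_s = m$peak_lag_s,
               signed_error_m = err, note = m$note, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aggregate per-trial measures to participant-condition medians
#'
#' The median aggregates by-trial measures within each participant x
#' direction x coordination cell; missing values (degenerate trials) are
#' excluded and counted.
#'
#' @param measures per-trial measures data.frame (see [cohort_measures()]).
#' @param value_cols measure columns to aggregate.
#' @return data.frame: one row per participant x direction x coordination
#'   with the cell medians, `n_trials` and `n_excluded_<col>` counts.
#' @export
aggregate_participant <- function(measures,
                                  value_cols = c("trunk_rms", "cross_peak",
                                                 "signed_error_m")) {
  key <- interaction(measures$participant_id, measures$direction,
                     measures$coordination, drop = TRUE)
  cells <- split(measures, key)
  rows <- lapply(cells, function(cell) {
    out <- data.frame(participant_id = cell$participant_id[1],
                      group = cell$group[1], direction = cell$direction[1],
                      coordination = cell$coordination[1],
                      n_trials = nrow(cell), stringsAsFactors = FALSE)
    for (col in value_cols) {
      v <- cell[[col]]
      if (all(is.na(v))) stop(sprintf(
        "empty cell after exclusions: %s %s/%s, measure %s",
        out$participant_id, out$direction, out$coordination, col))
      out[[col]] <- stats::median(v, na.rm = TRUE)
      out[[paste0("n_excluded_", col)]] <- sum(is.na(v))
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$participant_id, out$direction, out$coordination), ]
}
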