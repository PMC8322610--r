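#' Parameters of a synthetic head-trunk agent
#'
#' The agent stands in for a human steering the arrow toward the target: the
#' head is driven by a delayed proportional command smoothed by a
#' second-order (two cascaded first-order stages) low-pass, and the trunk
#' follows a fraction of each head increment. `coupling_kappa` is the
#' fraction of head rotation mirrored by the trunk (1 = rigid "en-bloc",
#' 0 = fully articulated); `damping_gamma` multiplies the trunk motion under
#' forced coordination (the "damping" behavior: reduced-amplitude trunk
#' rotations rather than none).
#'
#' @param coupling_kappa head-to-trunk coupling fraction, in [0, 1].
#' @param damping_gamma forced-coordination trunk multiplier, in [0, 1].
#' @param head_gain proportional steering gain toward the goal azimuth, 1/s.
#' @param head_tau_s smoothing time constant of each low-pass stage, seconds.
#' @param motor_noise_sd_deg SD of white Gaussian noise added to each yaw
#'   increment, degrees per tick.
#' @param reaction_delay_s delay before the steering error is acted on.
#' @param drift_rate_deg_per_s trunk-sensor drift rate (IMU-like), deg/s.
#' @param quantization_deg sensor resolution, degrees.
#' @return An `agent_params` list.
#' @export
agent_params <- function(coupling_kappa = 0.5, damping_gamma = 1,
                         head_gain = 3, head_tau_s = 0.12,
                         motor_noise_sd_deg = 0.2, reaction_delay_s = 0.15,
                         drift_rate_deg_per_s = 0, quantization_deg = 0.1) {
  if (coupling_kappa < 0 || coupling_kappa > 1) stop("coupling_kappa must lie in [0, 1]")
  if (damping_gamma < 0 || damping_gamma > 1) stop("damping_gamma must lie in [0, 1]")
  if (head_gain <= 0) stop("head_gain must be positive")
  if (head_tau_s <= 0) stop("head_tau_s must be positive")
  if (motor_noise_sd_deg < 0) stop("motor_noise_sd_deg must be non-negative")
  structure(list(coupling_kappa = coupling_kappa, damping_gamma = damping_gamma,
                 head_gain = head_gain, head_tau_s = head_tau_s,
                 motor_noise_sd_deg = motor_noise_sd_deg,
                 reaction_delay_s = reaction_delay_s,
                 drift_rate_deg_per_s = drift_rate_deg_per_s,
                 quantization_deg = quantization_deg),
            class = "agent_params")
}

#' Trunk increment following a head increment
#'
#' Under free coordination the trunk mirrors `coupling_kappa` of each head
#' increment; under forced coordination the mirrored fraction is further
#' scaled by `damping_gamma` (voluntary trunk damping).
#'
#' @param agent an [agent_params()].
#' @param head_increment_deg head yaw increment this tick, degrees.
#' @param coordination `"free"` or `"forced"`.
#' @param noise_deg additive trunk motor noise for this tick, degrees.
#' @return Trunk yaw increment, degrees.
#' @export
trunk_follower <- function(agent, head_increment_deg,
                           coordination = c("free", "forced"), noise_deg = 0) {
  coordination <- match.arg(coordination)
  gain <- if (coordination == "free") agent$coupling_kappa
          else agent$damping_gamma * agent$coupling_kappa
  gain * head_increment_deg + noise_deg
}

#' Closed-loop agent controller for [run_trial()]
#'
#' Builds the stateful controller callback: each tick the steering error
#' (goal azimuth minus arrow heading, observed `reaction_delay_s` ago) is
#' turned into a velocity command `head_gain * error`, smoothed by two
#' cascaded first-order stages with time constant `head_tau_s`, and
#' integrated into the head yaw with additive Gaussian motor noise; the
#' trunk follows via [trunk_follower()]. Randomness comes from the R RNG
#' stream in effect when the controller is called.
#'
#' @param agent an [agent_params()].
#' @param coordination `"free"` or `"forced"` (fixes the trunk rule).
#' @param head_yaw0_deg,trunk_yaw0_deg initial yaws, degrees.
#' @return A controller function suitable for [run_trial()].
#' @export
agent_controller <- function(agent, coordination = c("free", "forced"),
                             head_yaw0_deg = 0, trunk_yaw0_deg = 0) {
  coordination <- match.arg(coordination)
  head <- head_yaw0_deg
  trunk <- trunk_yaw0_deg
  v1 <- 0; v2 <- 0
  gain <- agent$head_gain
  tau <- agent$head_tau_s
  noise_sd <- agent$motor_noise_sd_deg
  trunk_gain <- if (coordination == "free") agent$coupling_kappa
                else agent$damping_gamma * agent$coupling_kappa
  buf <- NULL; bn <- 0L; pos <- 0L; filled <- 0L   # circular delay line
  noise <- numeric(0); ni <- 0L                    # chunked noise draws
  function(phase, t_s, arrow_heading_deg, goal_azimuth_deg, dt_s) {
    if (is.null(buf)) {
      bn <<- max(1L, as.integer(round(agent$reaction_delay_s / dt_s)) + 1L)
      buf <<- numeric(bn)
    }
    pos <<- pos %% bn + 1L
    cur <- goal_azimuth_deg - arrow_heading_deg
    # read the slot holding the error from bn - 1 ticks ago before overwriting
    err <- if (filled >= bn) buf[pos] else 0
    buf[pos] <<- cur
    filled <<- filled + 1L
    a <- dt_s / (tau + dt_s)
    v1 <<- v1 + a * (gain * err - v1)
    v2 <<- v2 + a * (v1 - v2)
    if (noise_sd > 0) {
      if (ni + 2L > length(noise)) { noise <<- stats::rnorm(512, 0, noise_sd); ni <<- 0L }
      head_inc <- v2 * dt_s + noise[ni + 1L]
      # independent trunk tremor: smaller than the head's (larger inertia)
      trunk_noise <- noise[ni + 2L] * 0.25
      ni <<- ni + 2L
    } else {
      head_inc <- v2 * dt_s
      trunk_noise <- 0
    }
    head <<- head + head_inc
    trunk <<- trunk + trunk_gain * head_inc + trunk_noise
    c(head, trunk)
  }
}

#' Cohort specification for the synthetic study
#'
#' Defaults reproduce the study layout: 10 blind and 11 sighted
#' participants, 2 direction x 2 coordination conditions, 20 trials per
#' condition, nominal 90 Hz sampling with timestamp jitter, 0.1 deg sensor
#' quantization and optional slow trunk-sensor drift with recalibration
#' every 10 trials. Group parameter distributions encode the qualitative
#' group contrast: blind agents are high-coupling ("en-bloc") with strong
#' forced-condition damping, sighted agents are low-coupling
#' ("articulated") with no condition-dependent change.
#'
#' @param n_blind,n_sighted group sizes.
#' @param trials_per_condition trials per participant per condition.
#' @param sampling_rate_hz nominal sampling rate, Hz.
#' @param jitter_sd_ms timestamp jitter SD, milliseconds.
#' @param dropout_prob per-sample drop probability.
#' @param drift_rate_deg_per_s trunk-sensor drift rate, deg/s.
#' @param recalibrate_every trials between drift recalibrations.
#' @param blind,sighted per-group parameter distributions: lists with
#'   `kappa_mean, kappa_sd, gamma_mean, gamma_sd` (normal, truncated to
#'   [0, 1]).
#' @param rng_seed master seed; per-participant/per-trial sub-seeds are
#'   derived from it by an integer hash of the (participant, condition,
#'   trial) indices.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_blind = 10, n_sighted = 11,
                        trials_per_condition = 20,
                        sampling_rate_hz = 90, jitter_sd_ms = 2,
                        dropout_prob = 0.02,
                        drift_rate_deg_per_s = 0.05,
                        recalibrate_every = 10,
                        blind = list(kappa_mean = 0.85, kappa_sd = 0.1,
                                     gamma_mean = 0.3, gamma_sd = 0.1),
                        sighted = list(kappa_mean = 0.15, kappa_sd = 0.1,
                                       gamma_mean = 1, gamma_sd = 0),
                        rng_seed = 1L) {
  if (n_blind <= 0 || n_sighted <= 0 || trials_per_condition <= 0)
    stop("counts must be positive")
  if (dropout_prob < 0 || dropout_prob > 1) stop("dropout_prob must lie in [0, 1]")
  structure(list(n_blind = n_blind, n_sighted = n_sighted,
                 trials_per_condition = trials_per_condition,
                 sampling_rate_hz = sampling_rate_hz,
                 jitter_sd_ms = jitter_sd_ms, dropout_prob = dropout_prob,
                 drift_rate_deg_per_s = drift_rate_deg_per_s,
                 recalibrate_every = recalibrate_every,
                 blind = blind, sighted = sighted, rng_seed = rng_seed),
            class = "cohort_spec")
}

#' Derive a reproducible sub-seed from a master seed and integer ids
#'
#' Splitting rule for per-participant and per-trial RNG streams: a
#' multiplicative-congruential hash of the master seed and the id sequence,
#' always below 2^31.
#'
#' @param master master seed.
#' @param ... integer ids (participant, condition, trial, ...).
#' @return A single integer seed.
#' @export
derive_seed <- function(master, ...) {
  ids <- c(...)
  h <- as.double(master) %% 2147483647
  for (v in ids) h <- (h * 48271 + as.double(v) + 1) %% 2147483647
  as.integer(h)
}

#' Degrade a kinematic trace like the acquisition chain
#'
#' Emulates the acquisition path: Gaussian timestamp jitter (asynchronous
#' collection), per-sample dropout, slow linear drift on the trunk channel
#' (IMU-like, starting from `drift_offset_s` since the last recalibration),
#' and quantization of both channels to the sensor resolution.
#'
#' @param trace data.frame with `t_s, head_yaw_deg, trunk_yaw_deg`.
#' @param jitter_sd_ms timestamp jitter SD, ms.
#' @param dropout_prob per-sample drop probability.
#' @param drift_rate_deg_per_s trunk drift rate, deg/s.
#' @param drift_offset_s time already elapsed since the last recalibration.
#' @param quantization_deg sensor resolution (0 disables).
#' @return The degraded trace (strictly increasing timestamps preserved by
#'   sorting after jitter).
#' @export
degrade_sensors <- function(trace, jitter_sd_ms = 2, dropout_prob = 0.02,
                            drift_rate_deg_per_s = 0, drift_offset_s = 0,
                            quantization_deg = 0.1) {
  n <- nrow(trace)
  if (is.null(n) || n < 2L) stop("trace must have at least 2 samples")
  t <- trace$t_s
  if (jitter_sd_ms > 0)
    t <- sort(t + stats::rnorm(n, 0, jitter_sd_ms / 1000))
  head <- trace$head_yaw_deg
  trunk <- trace$trunk_yaw_deg
  if (drift_rate_deg_per_s != 0)
    trunk <- trunk + drift_rate_deg_per_s * (drift_offset_s + t)
  if (quantization_deg > 0) {
    head <- round(head / quantization_deg) * quantization_deg
    trunk <- round(trunk / quantization_deg) * quantization_deg
  }
  keep <- if (dropout_prob > 0) stats::runif(n) >= dropout_prob else rep(TRUE, n)
  out <- trace
  out$t_s <- t; out$head_yaw_deg <- head; out$trunk_yaw_deg <- trunk
  out <- out[keep, , drop = FALSE]
  if (nrow(out) < 10L) stop("degenerate trace: fewer than 10 samples survive degradation")
  rownames(out) <- NULL
  out
}

# truncated-normal draw on [0, 1] by resampling
rtnorm01 <- function(n, mean, sd) {
  if (sd == 0) return(rep(pmin(1, pmax(0, mean)), n))
  x <- stats::rnorm(n, mean, sd)
  bad <- x < 0 | x > 1
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- x < 0 | x > 1
  }
  x
}

#' Sample per-participant agent parameters for a cohort
#'
#' @param spec a [cohort_spec()].
#' @return data.frame with one row per participant: `participant_id, group,
#'   coupling_kappa, damping_gamma`.
#' @export
sample_cohort_params <- function(spec) {
  set.seed(derive_seed(spec$rng_seed, 101L))
  n <- spec$n_blind + spec$n_sighted
  group <- c(rep("blind", spec$n_blind), rep("sighted", spec$n_sighted))
  kappa <- c(rtnorm01(spec$n_blind, spec$blind$kappa_mean, spec$blind$kappa_sd),
             rtnorm01(spec$n_sighted, spec$sighted$kappa_mean, spec$sighted$kappa_sd))
  gamma <- c(rtnorm01(spec$n_blind, spec$blind$gamma_mean, spec$blind$gamma_sd),
             rtnorm01(spec$n_sighted, spec$sighted$gamma_mean, spec$sighted$gamma_sd))
  data.frame(participant_id = sprintf("P%02d", seq_len(n)), group = group,
             coupling_kappa = kappa, damping_gamma = gamma,
             stringsAsFactors = FALSE)
}

#' Generate a full synthetic cohort
#'
#' Samples one agent per participant from its group distribution, then runs
#' every participant x direction x coordination x trial through
#' [run_trial()] with the side randomly alternated between leftward and
#' rightward and the dwell time drawn uniformly from [1, 3] s, degrades the
#' execution-step traces through [degrade_sensors()] (trunk drift is reset
#' every `recalibrate_every` trials), and collects trial metadata. Fully
#' reproducible from `spec$rng_seed`.
#'
#' @param spec a [cohort_spec()].
#' @param progress print progress lines every participant.
#' @return A list with `traces` (named list of data.frames, one per valid
#'   trial, names `P<participant>_<coordination>_<direction>_<trial>`),
#'   `metadata` (data.frame: one row per trial with config and outcome
#'   fields) and `params` (the sampled per-participant parameters).
#' @export
generate_cohort <- function(spec, progress = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  params <- sample_cohort_params(spec)
  dirs <- c("central", "lateral")
  coords <- c("free", "forced")
  traces <- list()
  meta <- vector("list", nrow(params) * 4L * spec$trials_per_condition)
  m <- 0L
  for (p in seq_len(nrow(params))) {
    agent <- agent_params(coupling_kappa = params$coupling_kappa[p],
                          damping_gamma = params$damping_gamma[p],
                          drift_rate_deg_per_s = spec$drift_rate_deg_per_s)
    for (di in dirs) for (co in coords) {
      ci <- (match(di, dirs) - 1L) * 2L + match(co, coords)
      drift_clock <- 0
      for (tr in seq_len(spec$trials_per_condition)) {
        seed <- derive_seed(spec$rng_seed, p, ci, tr)
        set.seed(seed)
        if ((tr - 1L) %% spec$recalibrate_every == 0L) drift_clock <- 0
        side <- if (stats::runif(1) < 0.5) "left" else "right"
        cfg <- trial_config(direction_level = di, coordination_level = co,
                            side = side,
                            dwell_time_s = stats::runif(1, 1, 3),
                            rng_seed = seed)
        ctrl <- agent_controller(agent, coordination = co)
        res <- run_trial(cfg, ctrl, tick_rate_hz = spec$sampling_rate_hz)
        key <- sprintf("%s_%s_%s_%02d", params$participant_id[p], co, di, tr)
        if (res$outcome$valid) {
          tr_deg <- degrade_sensors(res$trace[, c("t_s", "head_yaw_deg",
                                                  "trunk_yaw_deg")],
                                    jitter_sd_ms = spec$jitter_sd_ms,
                                    dropout_prob = spec$dropout_prob,
                                    drift_rate_deg_per_s = spec$drift_rate_deg_per_s,
                                    drift_offset_s = drift_clock,
                                    quantization_deg = agent$quantization_deg)
          drift_clock <- drift_clock + max(res$trace$t_s)
          tr_deg$participant_id <- params$participant_id[p]
          tr_deg$group <- params$group[p]
          tr_deg$direction <- di
          tr_deg$coordination <- co
          tr_deg$trial <- tr
          traces[[key]] <- tr_deg
        }
        m <- m + 1L
        meta[[m]] <- data.frame(
          participant_id = params$participant_id[p], group = params$group[p],
          direction = di, coordination = co, trial = tr, side = side,
          target_azimuth_deg = cfg$target_azimuth_deg,
          start_arrow_azimuth_deg = cfg$start_arrow_azimuth_deg,
          dwell_time_s = cfg$dwell_time_s, rng_seed = seed,
          valid = res$outcome$valid,
          endpoint_x_m = res$outcome$endpoint_x_m,
          endpoint_y_m = res$outcome$endpoint_y_m,
          hit = res$outcome$hit,
          signed_final_error_m = res$outcome$signed_final_error_m,
          stringsAsFactors = FALSE
        )
      }
    }
    if (progress) message(sprintf("participant %s done", params$participant_id[p]))
  }
  list(traces = traces, metadata = do.call(rbind, meta[seq_len(m)]),
       params = params)
}
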