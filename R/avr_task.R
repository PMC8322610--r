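#' Trial configuration for the acoustic-VR arrow-steering task
#'
#' Describes the geometry and factor levels of a single trial of the
#' archery-like steering game. The playing field is a horizontal plane; the
#' arrow starts loaded at the origin, the target is a sound source at
#' `target_distance_m` along azimuth `target_azimuth_deg`. Trigger-window and
#' target centers are always 15 degrees apart: in `central` trials the target
#' sits straight ahead (0 deg) and the arrow is aimed from +/-15 deg, in
#' `lateral` trials the target sits at +/-15 deg and the arrow starts at
#' 0 deg. Yaw and azimuth are in degrees, 0 = calibrated straight-ahead,
#' positive = rightward (clockwise seen from above).
#'
#' @param direction_level `"central"` or `"lateral"`.
#' @param coordination_level `"free"` (arrow follows head yaw) or `"forced"`
#'   (arrow follows head minus trunk yaw).
#' @param side `"left"` or `"right"`: which side the +/-15 deg offset (start
#'   azimuth for central, target azimuth for lateral) falls on.
#' @param dwell_time_s time in seconds the arrow must stay inside the trigger
#'   window before the shot fires; drawn uniformly from [1, 3] in the task,
#'   must lie in that interval.
#' @param target_distance_m distance to the target center, meters.
#' @param arrow_speed_mps arrow speed once shot, meters/second.
#' @param trigger_halfwidth_deg half-width of the trigger window, degrees;
#'   must be positive and below 15 so window and target never overlap.
#' @param hit_radius_m radius around the target center counting as a hit.
#' @param positioning_timeout_s positioning-step duration after which the
#'   trial is flagged invalid.
#' @param rng_seed integer seed recorded with the trial.
#'
#' @return An object of class `trial_config` (a list with the fields above
#'   plus derived `target_azimuth_deg`, `start_arrow_azimuth_deg`,
#'   `trigger_center_deg`).
#' @export
trial_config <- function(direction_level = c("central", "lateral"),
                         coordination_level = c("free", "forced"),
                         side = c("right", "left"),
                         dwell_time_s = 2,
                         target_distance_m = 60,
                         arrow_speed_mps = 10,
                         trigger_halfwidth_deg = 2.5,
                         hit_radius_m = 1,
                         positioning_timeout_s = 30,
                         rng_seed = NA_integer_) {
  direction_level <- match.arg(direction_level)
  coordination_level <- match.arg(coordination_level)
  side <- match.arg(side)
  if (!is.finite(dwell_time_s) || dwell_time_s < 1 || dwell_time_s > 3)
    stop("dwell_time_s must lie in [1, 3]")
  if (!is.finite(target_distance_m) || target_distance_m <= 0)
    stop("target_distance_m must be positive")
  if (!is.finite(arrow_speed_mps) || arrow_speed_mps <= 0)
    stop("arrow_speed_mps must be positive")
  if (!is.finite(trigger_halfwidth_deg) || trigger_halfwidth_deg <= 0 ||
      trigger_halfwidth_deg >= 15)
    stop("trigger_halfwidth_deg must lie in (0, 15)")
  sgn <- if (side == "right") 1 else -1
  if (direction_level == "central") {
    target_azimuth_deg <- 0
    start_arrow_azimuth_deg <- 15 * sgn
  } else {
    target_azimuth_deg <- 15 * sgn
    start_arrow_azimuth_deg <- 0
  }
  cfg <- list(
    direction_level = direction_level,
    coordination_level = coordination_level,
    side = side,
    target_azimuth_deg = target_azimuth_deg,
    start_arrow_azimuth_deg = start_arrow_azimuth_deg,
    trigger_center_deg = start_arrow_azimuth_deg,
    trigger_halfwidth_deg = trigger_halfwidth_deg,
    dwell_time_s = dwell_time_s,
    target_distance_m = target_distance_m,
    arrow_speed_mps = arrow_speed_mps,
    hit_radius_m = hit_radius_m,
    positioning_timeout_s = positioning_timeout_s,
    rng_seed = rng_seed
  )
  stopifnot(abs(cfg$target_azimuth_deg - cfg$trigger_center_deg) == 15)
  class(cfg) <- "trial_config"
  cfg
}

#' Arrow direction under a coordination mapping
#'
#' Under `free` coordination the arrow rotation mimics the head yaw alone;
#' under `forced` coordination the trunk anchors the reference frame and the
#' arrow rotation mimics the difference between head and trunk yaws.
#'
#' @param head_yaw_deg,trunk_yaw_deg yaw angles in degrees (finite).
#' @param coordination `"free"` or `"forced"`.
#' @return Arrow heading in degrees (vectorized over the yaw inputs).
#' @export
arrow_direction <- function(head_yaw_deg, trunk_yaw_deg,
                            coordination = c("free", "forced")) {
  coordination <- match.arg(coordination)
  if (!all(is.finite(head_yaw_deg)) || !all(is.finite(trunk_yaw_deg)))
    stop("yaw inputs must be finite")
  if (coordination == "free") head_yaw_deg else head_yaw_deg - trunk_yaw_deg
}

#' Earliest shot time for a trigger-window dwell rule
#'
#' The shot fires at the earliest time `t` such that the arrow orientation
#' stayed inside `[center - halfwidth, center + halfwidth]` continuously over
#' `[t - dwell_s, t]`. Containment is evaluated on the sampled orientations;
#' between samples the orientation is considered inside only if both
#' endpoints are inside.
#'
#' @param time_s,orientation_deg time-ordered samples of the arrow
#'   orientation.
#' @param window_center_deg,halfwidth_deg trigger-window geometry, degrees.
#' @param dwell_s required continuous containment, seconds.
#' @return Shot time in seconds, or `NA_real_` if the dwell is never met.
#' @export
check_trigger <- function(time_s, orientation_deg, window_center_deg,
                          halfwidth_deg, dwell_s) {
  if (length(time_s) == 0L) stop("empty orientation history")
  if (length(time_s) != length(orientation_deg))
    stop("time and orientation lengths differ")
  if (is.unsorted(time_s, strictly = FALSE)) stop("history must be time-ordered")
  inside <- abs(orientation_deg - window_center_deg) <= halfwidth_deg
  entry <- NA_real_
  for (i in seq_along(time_s)) {
    if (inside[i]) {
      if (is.na(entry)) entry <- time_s[i]
      if (time_s[i] - entry >= dwell_s) return(entry + dwell_s)
    } else {
      entry <- NA_real_
    }
  }
  NA_real_
}

#' Create a loaded arrow state
#'
#' @param heading_deg initial heading, degrees.
#' @return An `arrow_state` list: position (m), heading (deg), phase
#'   (`loaded`/`shot`/`landed`), elapsed time and path length.
#' @export
arrow_state <- function(heading_deg = 0) {
  structure(list(x_m = 0, y_m = 0, heading_deg = heading_deg,
                 phase = "loaded", elapsed_s = 0, path_m = 0),
            class = "arrow_state")
}

#' Advance a shot arrow by one tick
#'
#' The arrow advances `speed * dt` along its current heading in the
#' horizontal plane; path length grows by exactly that amount.
#'
#' @param state an `arrow_state` with `phase == "shot"`.
#' @param heading_deg heading during this tick, degrees.
#' @param dt_s tick duration, seconds (> 0).
#' @param speed_mps arrow speed, m/s.
#' @return Updated `arrow_state`.
#' @export
step_arrow <- function(state, heading_deg, dt_s, speed_mps = 10) {
  if (!identical(state$phase, "shot")) stop("arrow must be in the 'shot' phase")
  if (!is.finite(dt_s) || dt_s <= 0) stop("dt_s must be positive")
  rad <- heading_deg * pi / 180
  d <- speed_mps * dt_s
  state$x_m <- state$x_m + d * sin(rad)
  state$y_m <- state$y_m + d * cos(rad)
  state$heading_deg <- heading_deg
  state$elapsed_s <- state$elapsed_s + dt_s
  state$path_m <- state$path_m + d
  state
}

#' Signed final error of an arrow endpoint
#'
#' Magnitude is the Euclidean distance between the arrow endpoint and the
#' target center. The line joining the origin and the target center splits
#' the plane into two hemispaces; under the `"hemispace_positive"` convention
#' the error is positive when the endpoint lies in the same hemispace as the
#' initial arrow trajectory and negative otherwise (endpoints exactly on the
#' line are positive). `"hemispace_negative"` flips the sign, matching the
#' reading in which a negative value means a bias toward the initial
#' hemifield.
#'
#' @param endpoint_x_m,endpoint_y_m arrow endpoint, meters.
#' @param target_azimuth_deg,target_distance_m target center in polar form.
#' @param initial_arrow_azimuth_deg azimuth of the initial arrow trajectory;
#'   must not coincide with the target azimuth (the reference side would be
#'   undefined).
#' @param sign_convention `"hemispace_positive"` (default) or
#'   `"hemispace_negative"`.
#' @return Signed error in meters.
#' @export
signed_final_error <- function(endpoint_x_m, endpoint_y_m,
                               target_azimuth_deg, target_distance_m,
                               initial_arrow_azimuth_deg,
                               sign_convention = c("hemispace_positive",
                                                   "hemispace_negative")) {
  sign_convention <- match.arg(sign_convention)
  if (!is.finite(target_distance_m) || target_distance_m <= 0)
    stop("target_distance_m must be positive")
  trad <- target_azimuth_deg * pi / 180
  tx <- target_distance_m * sin(trad)
  ty <- target_distance_m * cos(trad)
  irad <- initial_arrow_azimuth_deg * pi / 180
  # cross product of the target direction with a second direction: sign tells
  # which hemispace the second direction points into
  cross2 <- function(ax, ay, bx, by) ax * by - ay * bx
  ref <- cross2(sin(trad), cos(trad), sin(irad), cos(irad))
  if (abs(ref) < 1e-12)
    stop("initial arrow azimuth lies on the origin-target line; reference side undefined")
  side <- cross2(sin(trad), cos(trad), endpoint_x_m, endpoint_y_m)
  magnitude <- sqrt((endpoint_x_m - tx)^2 + (endpoint_y_m - ty)^2)
  s <- if (side * ref >= 0) 1 else -1
  if (sign_convention == "hemispace_negative") s <- -s
  s * magnitude
}

#' Positioning-step feedback pitch
#'
#' During positioning an intermittent pure tone guides the participant: the
#' shorter the angular distance between arrow and trigger window, the higher
#' the pitch. Exponential interpolation between `f_min` (at 180 deg and
#' beyond) and `f_max` (at 0 deg).
#'
#' @param angular_distance_deg non-negative angular distance, degrees.
#' @param f_min_hz,f_max_hz pitch bounds, Hz.
#' @return Pitch in Hz, strictly decreasing in distance, bounded in
#'   `[f_min_hz, f_max_hz]`.
#' @export
positioning_feedback_pitch <- function(angular_distance_deg,
                                       f_min_hz = 220, f_max_hz = 880) {
  if (any(!is.finite(angular_distance_deg)) || any(angular_distance_deg < 0))
    stop("angular distance must be finite and non-negative")
  d <- pmin(angular_distance_deg, 180)
  f_max_hz * (f_min_hz / f_max_hz)^(d / 180)
}

#' Isotropic logarithmic source attenuation
#'
#' Gain of the target sound source relative to the reference distance;
#' azimuth-independent.
#'
#' @param distance_m listener-to-source distance, meters (> 0).
#' @param ref_m reference distance, meters (> 0).
#' @return Gain in dB: `-20 * log10(distance / ref)`.
#' @export
source_gain_db <- function(distance_m, ref_m = 1) {
  if (any(!is.finite(distance_m)) || any(distance_m <= 0))
    stop("distance_m must be positive")
  if (!is.finite(ref_m) || ref_m <= 0) stop("ref_m must be positive")
  -20 * log10(distance_m / ref_m)
}

#' Run one trial of the steering task
#'
#' Executes the two trial steps on a single 90 Hz clock. In the positioning
#' step the arrow is loaded at the origin and only rotates; the shot fires
#' once the arrow orientation has dwelt inside the trigger window for
#' `dwell_time_s` (see [check_trigger()]). In the execution step the arrow
#' advances at `arrow_speed_mps` along the heading commanded each tick and
#' the trial terminates when the cumulative path length reaches
#' `target_distance_m` (the final tick is truncated so path length lands
#' exactly on it). If positioning exceeds `positioning_timeout_s` the trial
#' is flagged invalid instead of being dropped.
#'
#' @param config a [trial_config()].
#' @param controller a function `function(phase, t_s, arrow_heading_deg,
#'   goal_azimuth_deg, dt_s)` returning `c(head_yaw_deg, trunk_yaw_deg)` for
#'   the next tick; called with `phase` `"positioning"` (goal = trigger
#'   center) or `"execution"` (goal = target azimuth). It may keep its own
#'   state.
#' @param tick_rate_hz simulation and sampling rate, Hz.
#' @return A list with `trace` (data.frame `t_s, head_yaw_deg, trunk_yaw_deg,
#'   arrow_heading_deg, arrow_x_m, arrow_y_m, phase`, execution step only),
#'   `outcome` (list `endpoint_x_m, endpoint_y_m, hit, signed_final_error_m,
#'   valid, shot_time_s`) and `config`.
#' @export
run_trial <- function(config, controller, tick_rate_hz = 90) {
  stopifnot(inherits(config, "trial_config"))
  dt <- 1 / tick_rate_hz
  coord <- config$coordination_level

  # positioning: rotate-only, dwell tracking inline
  n_max <- ceiling(config$positioning_timeout_s * tick_rate_hz)
  entry <- NA_real_
  t <- 0
  shot_time <- NA_real_
  heading <- config$start_arrow_azimuth_deg
  for (i in seq_len(n_max)) {
    yaws <- controller("positioning", t, heading, config$trigger_center_deg, dt)
    heading <- arrow_direction(yaws[1], yaws[2], coord)
    t <- t + dt
    if (abs(heading - config$trigger_center_deg) <= config$trigger_halfwidth_deg) {
      if (is.na(entry)) entry <- t
      if (t - entry >= config$dwell_time_s) { shot_time <- t; break }
    } else {
      entry <- NA_real_
    }
  }
  if (is.na(shot_time)) {
    outcome <- list(endpoint_x_m = NA_real_, endpoint_y_m = NA_real_,
                    hit = FALSE, signed_final_error_m = NA_real_,
                    valid = FALSE, shot_time_s = NA_real_)
    return(list(trace = NULL, outcome = outcome, config = config))
  }

  # execution: advance until path length reaches target distance
  n_exec <- ceiling(config$target_distance_m /
                      (config$arrow_speed_mps * dt)) + 1L
  ts <- numeric(n_exec); hy <- numeric(n_exec); ty <- numeric(n_exec)
  hd <- numeric(n_exec); ax <- numeric(n_exec); ay <- numeric(n_exec)
  x <- 0; y <- 0; path <- 0; te <- 0; k <- 0L
  while (path < config$target_distance_m - 1e-12) {
    yaws <- controller("execution", te, heading, config$target_azimuth_deg, dt)
    heading <- arrow_direction(yaws[1], yaws[2], coord)
    step_dt <- min(dt, (config$target_distance_m - path) / config$arrow_speed_mps)
    rad <- heading * pi / 180
    d <- config$arrow_speed_mps * step_dt
    x <- x + d * sin(rad); y <- y + d * cos(rad)
    path <- path + d; te <- te + step_dt
    k <- k + 1L
    ts[k] <- te; hy[k] <- yaws[1]; ty[k] <- yaws[2]
    hd[k] <- heading; ax[k] <- x; ay[k] <- y
  }
  trace <- data.frame(
    t_s = ts[seq_len(k)], head_yaw_deg = hy[seq_len(k)],
    trunk_yaw_deg = ty[seq_len(k)], arrow_heading_deg = hd[seq_len(k)],
    arrow_x_m = ax[seq_len(k)], arrow_y_m = ay[seq_len(k)],
    phase = rep("execution", k)
  )
  err <- signed_final_error(x, y, config$target_azimuth_deg,
                            config$target_distance_m,
                            config$start_arrow_azimuth_deg)
  outcome <- list(endpoint_x_m = x, endpoint_y_m = y,
                  hit = abs(err) <= config$hit_radius_m,
                  signed_final_error_m = err,
                  valid = TRUE, shot_time_s = shot_time)
  list(trace = trace, outcome = outcome, config = config)
}
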