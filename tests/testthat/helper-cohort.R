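# shared small synthetic cohorts, memoized so several test files can reuse
# one simulation
.cohort_cache <- new.env(parent = emptyenv())

cached_cohort <- function(key, spec) {
  if (!exists(key, envir = .cohort_cache)) {
    assign(key, generate_cohort(spec), envir = .cohort_cache)
  }
  get(key, envir = .cohort_cache)
}

small_cohort <- function() {
  cached_cohort("small", cohort_spec(n_blind = 4, n_sighted = 4,
                                     trials_per_condition = 3, rng_seed = 42))
}

# one noiseless agent trial, handy as a clean kinematic fixture
clean_agent_trace <- function(kappa = 0.8, coordination = "free", seed = 5) {
  set.seed(seed)
  agent <- agent_params(coupling_kappa = kappa, motor_noise_sd_deg = 0.2)
  cfg <- trial_config("central", coordination, "right", dwell_time_s = 1.5)
  run_trial(cfg, agent_controller(agent, coordination))
}

# median cross-peak of a few free-coordination trials for one agent
agent_median_crosspeak <- function(kappa, n_trials = 2, seed = 1) {
  set.seed(seed)
  agent <- agent_params(coupling_kappa = kappa)
  cps <- vapply(seq_len(n_trials), function(i) {
    cfg <- trial_config(sample(c("central", "lateral"), 1), "free",
                        sample(c("left", "right"), 1), dwell_time_s = 1.2)
    res <- run_trial(cfg, agent_controller(agent, "free"))
    tr <- degrade_sensors(res$trace[, c("t_s", "head_yaw_deg", "trunk_yaw_deg")],
                          jitter_sd_ms = 2, dropout_prob = 0.02,
                          quantization_deg = 0.1)
    trial_measures(tr)$cross_peak
  }, numeric(1))
  stats::median(cps, na.rm = TRUE)
}

# simulate one null 2x2x2 long table: iid responses, no true effects
null_long_table <- function(n_blind = 10, n_sighted = 11) {
  n <- n_blind + n_sighted
  grid <- expand.grid(direction = c("central", "lateral"),
                      coordination = c("free", "forced"),
                      participant_id = sprintf("P%02d", seq_len(n)),
                      stringsAsFactors = FALSE)
  grid$group <- ifelse(as.integer(sub("P", "", grid$participant_id)) <= n_blind,
                       "blind", "sighted")
  grid$value <- rnorm(nrow(grid)) + rep(rnorm(n), each = 4)  # subject effect
  grid
}
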