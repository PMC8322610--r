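test_that("uniform resampling interpolates exactly where it should", {
  # already uniform at 90 Hz -> identity
  t <- seq(0, 2, by = 1 / 90)
  v <- sin(t)
  u <- resample_uniform(t, v, 90)
  expect_equal(u$values_deg, v, tolerance = 1e-12)
  # affine signals are reproduced exactly despite jitter
  set.seed(1)
  tj <- sort(t + rnorm(length(t), 0, 0.002))
  va <- 3 + 2 * tj
  ua <- resample_uniform(tj, va, 90)
  grid <- ua$start_time_s + (seq_along(ua$values_deg) - 1) / 90
  expect_equal(ua$values_deg, 3 + 2 * grid, tolerance = 1e-10)
  # jittered sine recovered within 1% of amplitude
  ts <- sort(seq(0, 2, by = 1 / 90) + rnorm(181, 0, 0.002))
  us <- resample_uniform(ts, sin(2 * pi * 2 * ts), 90)
  gs <- us$start_time_s + (seq_along(us$values_deg) - 1) / 90
  expect_lt(max(abs(us$values_deg - sin(2 * pi * 2 * gs))), 0.01)
  expect_error(resample_uniform(c(0, 0, 1), 1:3), "increasing")
  expect_error(resample_uniform(0.5, 1), "2 samples")
})

test_that("moving average preserves constants and affine slopes", {
  const <- uniform_trace(rep(4, 50))
  expect_equal(smooth_ma(const)$values_deg, rep(4, 33))
  ramp <- uniform_trace(2 * (0:49))
  sm <- smooth_ma(ramp)
  # averaging an affine ramp gives the ramp at the window mean position
  expect_equal(sm$values_deg, 2 * ((0:32) + 8.5), tolerance = 1e-9)
  expect_equal(diff(sm$values_deg), rep(2, 32), tolerance = 1e-9)
  # unit impulse spreads to 1/18 over 18 output positions
  imp <- uniform_trace(c(rep(0, 30), 1, rep(0, 30)))
  smi <- smooth_ma(imp)$values_deg
  expect_equal(sum(smi > 1e-12), 18)
  expect_equal(unique(round(smi[smi > 1e-12], 12)), round(1 / 18, 12))
  expect_error(smooth_ma(uniform_trace(1:5)), "window")
})

test_that("jerk is the exact third derivative on cubics", {
  t <- (0:300) / 90
  expect_equal(jerk(uniform_trace(rep(2, 100)))$values, rep(0, 94))
  j <- jerk(uniform_trace(t^3))
  expect_equal(j$values, rep(6, length(j$values)), tolerance = 1e-6)
  # sine amplitude: (2*pi)^3 within 1% at 90 Hz
  js <- jerk(uniform_trace(sin(2 * pi * t)))
  expect_equal(max(abs(js$values)), (2 * pi)^3, tolerance = 0.01)
  expect_error(jerk(uniform_trace(1:5)), "7 samples")
})

test_that("rms follows its definition", {
  expect_equal(rms(rep(0, 10)), 0)
  expect_equal(rms(rep(-3, 7)), 3)
  expect_equal(rms(c(3, 4)), sqrt(12.5))
  expect_error(rms(numeric(0)), "empty")
})

test_that("AR prewhitener recovers known generators", {
  set.seed(10)
  # white noise: selected order 0 or negligible coefficients (3/sqrt(n)
  # allows for AIC selection bias on a true null coefficient)
  fw <- fit_prewhitener(rnorm(540), max_order = 10)
  expect_true(fw$order == 0 || all(abs(fw$ar) < 3 / sqrt(540)))
  # AR(1) phi = 0.8 recovered within 0.1
  x <- as.numeric(arima.sim(list(ar = 0.8), 540))
  f1 <- fit_prewhitener(x, max_order = 10)
  expect_gte(f1$order, 1)
  expect_lt(abs(f1$ar[1] - 0.8), 0.1)
  expect_error(fit_prewhitener(rep(1, 200), 5), "zero variance")
})

test_that("prewhitening whitens and preserves relative lag", {
  set.seed(11)
  x <- as.numeric(arima.sim(list(ar = 0.8), 540))
  model <- fit_prewhitener(x, max_order = 10)
  pw <- prewhiten_pair(x, x, model)
  n <- length(pw$head)
  ac <- acf(pw$head, lag.max = 5, plot = FALSE)$acf[2:6]
  expect_true(all(abs(ac) < 2 / sqrt(n)))
  # order-0 model is the identity (up to centering)
  m0 <- structure(list(order = 0L, ar = numeric(0), mean = 0), class = "prewhiten_model")
  pw0 <- prewhiten_pair(x, 2 * x, m0)
  expect_equal(pw0$head, x - mean(x))
  # trunk = head delayed by k samples: peak stays at lag k after prewhitening
  k <- 9
  y <- c(rep(0, k), x[1:(540 - k)])
  pwk <- prewhiten_pair(x[(k + 1):540], y[(k + 1):540],
                        fit_prewhitener(x[(k + 1):540], 10))
  cp <- cross_peak(pwk$head, pwk$trunk, rate_hz = 90, max_lag_s = 0.5)
  expect_equal(cp$lag_s, k / 90, tolerance = 1e-9)
})

test_that("cross-correlation peak has its boundary and symmetry properties", {
  set.seed(12)
  x <- rnorm(200)
  expect_equal(cross_peak(x, x, rate_hz = 90)$peak, 1, tolerance = 1e-9)
  expect_equal(cross_peak(x, x, rate_hz = 90)$lag_s, 0)
  expect_equal(cross_peak(x, -x, rate_hz = 90)$peak, 1, tolerance = 1e-9)
  # swapping inputs keeps the amplitude and flips the lag
  y <- c(rnorm(5), x[1:195]) + rnorm(200, 0, 0.3)
  a <- cross_peak(x, y, rate_hz = 90)
  b <- cross_peak(y, x, rate_hz = 90)
  expect_equal(a$peak, b$peak, tolerance = 1e-12)
  expect_equal(a$lag_s, -b$lag_s, tolerance = 1e-12)
  expect_error(cross_peak(rep(1, 100), rnorm(100), rate_hz = 90), "zero variance")
})

test_that("cross-correlation values agree with the ccf oracle", {
  set.seed(13)
  x <- rnorm(400); y <- rnorm(400) + 0.5 * x
  oracle <- ccf(x, y, lag.max = 45, plot = FALSE, demean = TRUE)
  mine <- cross_peak(x, y, rate_hz = 90, max_lag_s = 0.5)
  expect_equal(mine$peak, max(abs(oracle$acf)), tolerance = 1e-10)
})

test_that("independent noises stay below the permutation null ceiling", {
  set.seed(14)
  x <- rnorm(540); y <- rnorm(540)
  obs <- cross_peak(x, y, rate_hz = 90, max_lag_s = 0.5)$peak
  null <- vapply(1:1000, function(i)
    cross_peak(x, sample(y), rate_hz = 90, max_lag_s = 0.5)$peak, numeric(1))
  expect_lt(obs, quantile(null, 0.99))
})

test_that("trial measures handle degenerate and coupled trunks", {
  res <- clean_agent_trace()
  tr <- res$trace
  # constant trunk: rms 0 and missing (never zero) cross-peak
  tc <- tr; tc$trunk_yaw_deg <- 3
  m <- trial_measures(tc)
  expect_equal(m$trunk_rms, 0)
  expect_true(is.na(m$cross_peak))
  expect_match(m$note, "zero-variance")
  # trunk identical to head: near-perfect cross-peak
  th <- tr; th$trunk_yaw_deg <- tr$head_yaw_deg
  expect_gt(trial_measures(th)$cross_peak, 0.9)
  # determinism given the trace
  expect_identical(trial_measures(tr), trial_measures(tr))
})

test_that("scaling yaw scales trunk RMS and leaves cross-peak invariant", {
  res <- clean_agent_trace()
  tr <- res$trace
  sc <- tr
  sc$head_yaw_deg <- 2.5 * tr$head_yaw_deg
  sc$trunk_yaw_deg <- 2.5 * tr$trunk_yaw_deg
  m1 <- trial_measures(tr); m2 <- trial_measures(sc)
  expect_equal(m2$trunk_rms, 2.5 * m1$trunk_rms, tolerance = 1e-9)
  expect_equal(m2$cross_peak, m1$cross_peak, tolerance = 1e-6)
})

test_that("participant aggregation takes robust cell medians", {
  base <- data.frame(participant_id = "P01", group = "blind",
                     direction = "central", coordination = "free",
                     trial = 1:3, stringsAsFactors = FALSE)
  base$trunk_rms <- c(1, 2, 100)
  base$cross_peak <- c(0.5, 0.5, 0.5)
  base$signed_error_m <- c(-1, 0, 1)
  agg <- aggregate_participant(base)
  expect_equal(agg$trunk_rms, 2)
  expect_equal(agg$cross_peak, 0.5)
  # even count: mean of the two middle order statistics
  b2 <- do.call(rbind, replicate(2, base, simplify = FALSE))
  b2$trial <- 1:6
  set.seed(15)
  b2$trunk_rms <- rnorm(6)
  agg2 <- aggregate_participant(b2)
  s <- sort(b2$trunk_rms)
  expect_equal(agg2$trunk_rms, mean(s[3:4]))
  # NA measures are excluded and counted, never imputed
  b3 <- base; b3$cross_peak <- c(0.4, NA, 0.6)
  agg3 <- aggregate_participant(b3)
  expect_equal(agg3$cross_peak, 0.5)
  expect_equal(agg3$n_excluded_cross_peak, 1)
  b4 <- base; b4$cross_peak <- NA_real_
  expect_error(aggregate_participant(b4), "empty cell")
})
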