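test_that("zero-diffusion, zero-noise track is constant and seeded runs are identical", {
  m0 <- diffusion_state_model(D_values = c(non = 0), mean_lifetimes = c(non = 5))
  sim <- simulate_switching_track(m0, CFG, duration = 5, seed = 11)
  expect_true(all(sim$track$positions == sim$track$positions[1L]))

  m <- diffusion_state_model()
  a <- simulate_switching_track(m, CFG, duration = 10, seed = 42)
  b <- simulate_switching_track(m, CFG, duration = 10, seed = 42)
  expect_identical(a$track$positions, b$track$positions)
  expect_identical(a$truth$state, b$truth$state)
})

test_that("Brownian increments have variance 2 D dt (plus 2 sigma^2 under noise)", {
  n <- 1e4
  for (ns in c(0, 0.02)) {
    cfg <- sim_config(noise_sigma = ns)
    m <- diffusion_state_model(D_values = c(s = 0.05), mean_lifetimes = c(s = 1e6))
    sim <- simulate_switching_track(m, cfg, duration = n * cfg$line_time, seed = 7)
    v <- stats::var(diff(sim$track$positions))
    expect_v <- 2 * 0.05 * cfg$line_time + 2 * ns^2
    se <- expect_v * sqrt(2 / (n - 2))
    expect_lt(abs(v - expect_v), 3 * se)
  }
})

test_that("state labels align with frames and reflecting bounds hold", {
  m <- diffusion_state_model(D_values = c(a = 0.2, b = 0.01),
                             mean_lifetimes = c(a = 0.5, b = 0.5))
  cfg <- sim_config(tether_length_bp = 3000)  # ~1 um tether forces reflections
  sim <- simulate_switching_track(m, cfg, duration = 100, seed = 3)
  expect_length(sim$truth$state, length(sim$track$times))
  expect_true(all(sim$truth$positions_true >= 0))
  expect_true(all(sim$truth$positions_true <= bp_to_um(3000, cfg)))
  expect_true(all(sim$truth$state %in% c("a", "b")))
})

test_that("invalid model or duration is rejected", {
  expect_error(diffusion_state_model(
    D_values = c(a = 0.1, b = 0.1), mean_lifetimes = c(1, 1),
    transition_matrix = matrix(c(0, 0.5, 1, 0.2), 2, 2)), "sum to 1")
  m <- diffusion_state_model()
  expect_error(simulate_switching_track(m, CFG, duration = 0.01),
               "shorter than one frame")
})

test_that("bypass encounters cross; recoil stays on one side", {
  sim <- simulate_encounter_pair(CFG, "bypass", seed = 5)
  d <- sim$track1$positions - sim$track2$positions
  ev <- sim$truth$event_frames
  expect_lt(mean(d[1:(ev[1] - 2)]), 0)
  expect_gt(mean(d[(ev[2] + 2):length(d)]), 0)

  # zero diffusion after contact: deterministic recoil, same side throughout
  simr <- simulate_encounter_pair(CFG, "recoil", params = list(D = 0), seed = 5)
  dr <- simr$track1$positions - simr$track2$positions
  evf <- simr$truth$event_frames
  expect_true(all(dr[-(evf[1]:evf[2])] < 0))
  expect_gt(abs(dr[length(dr)]), 0.5)

  expect_error(simulate_encounter_pair(CFG, "bypass", params = list(sep0 = 0)),
               "non-overlapping")
})

test_that("codiffusion dwell draws have the configured exponential mean", {
  dw <- vapply(1:2000, function(r)
    simulate_encounter_pair(CFG, "codiffuse", seed = 10000 + r)$truth$dwell_true,
    numeric(1))
  se <- 0.70 / sqrt(2000)
  expect_lt(abs(mean(dw) - 0.70), 3 * se)
})

test_that("dwell mixture sampler matches its moments", {
  d1 <- simulate_dwells(1e4, 2, seed = 1)
  expect_lt(abs(mean(d1) - 2), 3 * 2 / sqrt(1e4))
  d2 <- simulate_dwells(5000, c(5, 1), weights = c(1, 0), seed = 2)
  expect_lt(abs(mean(d2) - 5), 3 * 5 / sqrt(5000))
  d3 <- simulate_dwells(1e4, c(2, 20), weights = c(0.5, 0.5), seed = 3)
  # mixture mean 11, variance w1*2*tau1^2 + w2*2*tau2^2 - mean^2
  sdm <- sqrt(0.5 * 2 * 4 + 0.5 * 2 * 400 - 121)
  expect_lt(abs(mean(d3) - 11), 3 * sdm / sqrt(1e4))
  expect_error(simulate_dwells(10, numeric(0)), "non-empty")
  expect_error(simulate_dwells(10, c(1, 2), weights = c(0.7, 0.7)), "sum to 1")
})

test_that("translocation tracks follow the piecewise-linear closed form", {
  cfg0 <- sim_config(noise_sigma = 0)
  still <- simulate_translocation_track(0, 10, cfg0, seed = 1)
  expect_true(all(still$track$positions == still$track$positions[1]))

  sim <- simulate_translocation_track(29, 33, cfg0, seed = 1)
  expect_equal(sim$truth$net_displacement_bp, 29 * 33)  # 957 bp

  two <- simulate_translocation_track(c(20, 40), 10, cfg0, changepoints = 5,
                                      seed = 1)
  expect_equal(two$truth$net_displacement_bp, 300)
  # observed noiseless displacement matches the mean path on the frame grid
  got_bp <- um_to_bp(diff(range(two$track$positions)), cfg0)
  expect_lt(abs(got_bp - 300), 40 * cfg0$line_time * 2)

  expect_error(simulate_translocation_track(29, 10, cfg0, changepoints = 12),
               "inside")
  expect_error(simulate_translocation_track(29, 10, cfg0,
                                            changepoints = c(6, 4)),
               "increasing|inside")
})

test_that("co-moving nucleosome channel shares the mean path", {
  cfg <- sim_config(noise_sigma = 0.02)
  sim <- simulate_translocation_track(29, 20, cfg, emit_nucleosome = TRUE,
                                      seed = 9)
  expect_s3_class(sim$nucleosome, "kymo_track")
  expect_equal(sim$nucleosome$channel, "green")
  d <- sim$track$positions - sim$nucleosome$positions
  expect_lt(abs(mean(d)), 3 * sqrt(2) * 0.02 / sqrt(length(d)))
})

test_that("force-clamp traces step by the configured amount", {
  flat <- simulate_force_clamp_trace(0, noise_sigma = 0, seed = 1)
  expect_equal(diff(range(flat$trace$distance_nm)), 0)
  clean <- simulate_force_clamp_trace(10, noise_sigma = 0, seed = 2)
  expect_equal(clean$trace$distance_nm[length(clean$trace$distance_nm)] -
                 clean$trace$distance_nm[1], 250)
  expect_length(clean$truth$step_times, 10)
  expect_error(simulate_force_clamp_trace(5, step_size = -1), "non-negative")
})

test_that("observation model applies pulses and bleaching", {
  tr <- drift_track(0.01, 1000)
  same <- apply_observation_model(tr, sim_config(pulse_pattern = TRUE))
  expect_identical(same$observed, tr$observed)

  gone <- apply_observation_model(tr, sim_config(bleach_rate = Inf), seed = 1)
  expect_length(gone$times, 0)

  # 1 s on / 9 s off schedule: observed fraction ~ 0.1
  on <- round(1 / CFG$line_time); off <- round(9 / CFG$line_time)
  pat <- rep(c(TRUE, FALSE), c(on, off))
  pulsed <- apply_observation_model(tr, sim_config(pulse_pattern = pat))
  expect_lt(abs(mean(pulsed$observed) - 0.1), 0.02)
})
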