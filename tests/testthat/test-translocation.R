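test_that("a noiseless constant-speed trace yields one admitted segment", {
  cfg0 <- sim_config(noise_sigma = 0)
  sim <- simulate_translocation_track(29, 33, cfg0, seed = 1)
  seg <- segment_speeds(sim$track, cfg0)
  expect_equal(nrow(seg), 1L)
  expect_true(seg$admitted)
  expect_equal(seg$speed_bp_s, 29, tolerance = 1e-9)
  expect_equal(seg$distance_bp, seg$speed_bp_s * seg$duration_s,
               tolerance = 1e-9)
  expect_equal(seg$r_squared, 1)
})

test_that("admission filters reject short, slow and poorly fit segments", {
  cfg0 <- sim_config(noise_sigma = 0)
  # 20 bp/s for 10 s: only 200 bp, under the 300 bp filter
  s200 <- segment_speeds(simulate_translocation_track(20, 10, cfg0)$track, cfg0)
  expect_false(s200$admitted)
  expect_match(s200$reason, "distance<300bp")

  # a trace shorter than the minimum duration yields no segments at all
  s4 <- segment_speeds(simulate_translocation_track(100, 4.5, cfg0)$track, cfg0)
  expect_equal(nrow(s4), 0L)

  # a manually delimited sub-5 s segment is rejected on duration first
  long <- simulate_translocation_track(100, 20, cfg0)$track
  s5 <- segment_speeds(long, cfg0, manual_breaks = 4)
  expect_false(s5$admitted[1])
  expect_match(s5$reason[1], "duration<5s")

  # static trace with noise: R^2 filter
  cfg <- sim_config(noise_sigma = 0.05)
  st <- segment_speeds(simulate_translocation_track(0, 33, cfg, seed = 2)$track,
                       cfg)
  expect_false(any(st$admitted))
  expect_true(any(grepl("r2<0.5|distance", st$reason)))
})

test_that("speed recovery at the reported operating point (1-pixel noise)", {
  cfg <- sim_config(noise_sigma = sim_config()$pixel_to_um)
  sp <- vapply(1:25, function(r) {
    sim <- simulate_translocation_track(29, 33, cfg, seed = 300 + r)
    seg <- segment_speeds(sim$track, cfg)
    adm <- seg[seg$admitted, ]
    if (nrow(adm)) stats::weighted.mean(abs(adm$speed_bp_s), adm$duration_s)
    else NA_real_
  }, numeric(1))
  expect_gt(mean(!is.na(sp)), 0.9)
  expect_lt(abs(mean(sp, na.rm = TRUE) - 29) / 29, 0.05)
})

test_that("speed changes are segmented and both speeds recovered", {
  cfg <- sim_config(noise_sigma = sim_config()$pixel_to_um)
  res <- vapply(1:25, function(r) {
    sim <- simulate_translocation_track(c(20, 40), 20, cfg, changepoints = 10,
                                        seed = r)
    seg <- segment_speeds(sim$track, cfg)
    if (nrow(seg) == 2)
      c(seg$speed_bp_s[1], seg$speed_bp_s[2], seg$t_end[1]) else rep(NA_real_, 3)
  }, numeric(3))
  found <- !is.na(res[1, ])
  expect_gte(mean(found), 0.9)
  expect_lt(abs(mean(res[1, found]) - 20) / 20, 0.1)
  expect_lt(abs(mean(res[2, found]) - 40) / 40, 0.1)
  expect_lt(abs(mean(res[3, found]) - 10), 1)
})

test_that("manual segment boundaries bypass the automatic search", {
  cfg0 <- sim_config(noise_sigma = 0)
  sim <- simulate_translocation_track(c(20, 40), 20, cfg0, changepoints = 10)
  seg <- segment_speeds(sim$track, cfg0, manual_breaks = 10)
  expect_equal(nrow(seg), 2L)
  expect_equal(seg$speed_bp_s, c(20, 40), tolerance = 1e-6)
})

test_that("direction changes count sign flips of admitted speeds only", {
  seg <- data.frame(t_start = c(0, 10, 20), t_end = c(10, 20, 30),
                    duration_s = 10, speed_bp_s = c(29, -29, -29),
                    distance_bp = c(290, -290, -290), r_squared = 1,
                    admitted = TRUE, reason = "")
  expect_equal(detect_direction_changes(seg)$n_changes, 1L)
  expect_equal(detect_direction_changes(seg[1, ])$n_changes, 0L)
  seg$speed_bp_s <- c(20, 40, 40)
  expect_equal(detect_direction_changes(seg)$n_changes, 0L)
})

test_that("trace fragmentation labels with the stated precedence", {
  cfg <- sim_config(noise_sigma = 0.02)
  # pure diffusion: everything is 1D search
  m <- diffusion_state_model(D_values = c(s = 0.05), mean_lifetimes = c(s = 1e6))
  dif <- simulate_switching_track(m, cfg, duration = 20, seed = 3)
  fr <- fragment_trace(dif$track, NULL, NULL)
  expect_equal(unique(fr$labels), "search_1D")

  # parked on a nucleosome: all engaged
  park <- static_track(200, cfg)
  fr2 <- fragment_trace(park, data.frame(t_start = 0, t_end = 200 * cfg$line_time),
                        NULL)
  expect_equal(unique(fr2$labels), "engaged_static")

  # search -> engage -> translocate in order
  sim <- simulate_search_engage_translocate(cfg, same_direction = TRUE, seed = 4)
  seg <- segment_speeds(sim$track, cfg)
  fr3 <- suppressWarnings(fragment_trace(sim$track, sim$coloc_events, seg))
  labs <- rle(fr3$labels)$values
  expect_equal(labs[1], "search_1D")
  expect_true("translocating" %in% labs)
  expect_lt(which(labs == "search_1D")[1], which(labs == "translocating")[1])
})

test_that("push/pull calls follow the approach and translocation directions", {
  cfg <- sim_config(noise_sigma = 0.02)
  for (same in c(TRUE, FALSE)) {
    sim <- simulate_search_engage_translocate(cfg, same_direction = same,
                                              seed = if (same) 5 else 6)
    seg <- segment_speeds(sim$track, cfg)
    fr <- suppressWarnings(fragment_trace(sim$track, sim$coloc_events, seg))
    pp <- classify_push_pull(fr, seg, sim$track)
    expect_equal(pp$call, if (same) "push" else "pull")
    expect_equal(pp$approach_direction, sim$truth$approach_direction)
    expect_equal(pp$translocation_direction, sim$truth$translocation_direction)
  }

  # no 1D segment anywhere: undefined
  park <- static_track(400, cfg)
  seg0 <- data.frame(t_start = 0, t_end = 5, duration_s = 5, speed_bp_s = 29,
                     distance_bp = 300, r_squared = 1, admitted = TRUE,
                     reason = "")
  fr0 <- fragment_trace(park,
                        data.frame(t_start = 0, t_end = 400 * cfg$line_time),
                        NULL)
  expect_equal(classify_push_pull(fr0, seg0, park)$call, "undefined")
})

test_that("push/pull recovery holds across seeds", {
  cfg <- sim_config(noise_sigma = 0.02)
  ok <- 0L
  for (r in 1:30) {
    same <- r %% 2 == 0
    sim <- simulate_search_engage_translocate(cfg, same_direction = same,
                                              seed = 700 + r)
    seg <- segment_speeds(sim$track, cfg)
    fr <- suppressWarnings(fragment_trace(sim$track, sim$coloc_events, seg))
    ok <- ok + (classify_push_pull(fr, seg, sim$track)$call ==
                  (if (same) "push" else "pull"))
  }
  expect_gte(ok / 30, 0.95)
})
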