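test_that("MSD is zero for a stationary track and quadratic under drift", {
  msd <- compute_msd(static_track(100), max_lag = 10, cfg = CFG)
  expect_true(all(msd$msd == 0))

  # x = v t with v = 1 um/s: msd(lag) = (v lag)^2
  msd_d <- compute_msd(drift_track(1, 100), max_lag = 5, cfg = CFG)
  expect_equal(msd_d$msd, (msd_d$lag_s)^2, tolerance = 1e-12)
  expect_equal(msd_d$msd[1], 1.798e-3, tolerance = 1e-3)
})

test_that("MSD equals the brute-force pairwise oracle, with and without gaps", {
  withr::with_seed(21, {
    for (rep in 1:3) {
      x <- cumsum(rnorm(50, 0, 0.05))
      obs <- runif(50) > 0.2
      obs[1] <- TRUE
      tr <- new_track("r", "red", (0:49) * CFG$line_time,
                      ifelse(obs, x, NA), obs)
      got <- compute_msd(tr, max_lag = 8, cfg = CFG)
      want <- msd_oracle(tr, 8, CFG)
      expect_equal(got$msd, want, tolerance = 1e-10)
    }
  })
})

test_that("max_lag beyond the track is truncated with a warning", {
  expect_warning(msd <- compute_msd(static_track(10), max_lag = 50, cfg = CFG),
                 "truncating")
  expect_equal(nrow(msd), 9L)
})

test_that("rolling-window D matches its brute-force oracle", {
  withr::with_seed(33, {
    x <- cumsum(rnorm(50, 0, 0.05))
    tr <- new_track("r", "red", (0:49) * CFG$line_time, x)
    got <- rolling_window_D(tr, CFG)$D
    want <- rolling_D_oracle(tr, CFG)
    expect_equal(got, want, tolerance = 1e-10)
  })
})

test_that("stationary and slow-drift tracks are non-diffusive; D recovers truth", {
  D_still <- rolling_window_D(static_track(200), CFG)$D
  expect_true(all(D_still < 0.01))

  # 300 bp/s directed drift falls below the non-diffusive threshold:
  # the stated detection limit of the rolling-window method
  v <- 300 * CFG$um_per_bp
  D_drift <- rolling_window_D(drift_track(v, 500), CFG)$D
  expect_true(all(D_drift < 0.01))

  m <- diffusion_state_model(D_values = c(s = 0.05), mean_lifetimes = c(s = 1e6))
  sim <- simulate_switching_track(m, CFG, duration = 5000 * CFG$line_time,
                                  seed = 4)
  expect_lt(abs(mean(rolling_window_D(sim$track, CFG)$D) - 0.05), 0.005)
})

test_that("window shorter than the fit is rejected", {
  expect_error(rolling_window_D(static_track(50), CFG, window = 5,
                                fit_points = 5), "fit_points")
})

test_that("window classification applies the 0.01/0.04 thresholds", {
  lab <- classify_windows(c(0.005, 0.02, 0.04, 0.1, NA))
  expect_equal(as.character(lab), c("non", "low", "high", "high", NA))
})

test_that("moving-average smoothing shrinks at the ends and preserves masks", {
  tr <- new_track("s", "red", (0:4) * CFG$line_time, c(0, 0, 5, 0, 0))
  sm <- smooth_positions(tr, span = 5)
  expect_equal(sm$positions[3], 1.0)
  expect_equal(sm$positions[1], 0)          # shrunk end window
  expect_equal(sm$positions[2], 5 / 3)      # 3-point end window

  expect_identical(smooth_positions(tr, span = 1), tr)
  cst <- static_track(20)
  expect_equal(smooth_positions(cst, 5)$positions, cst$positions)
  expect_error(smooth_positions(tr, span = 4), "odd")
})

test_that("state segmentation dissolves sub-min runs and conserves time", {
  lab <- c(rep("non", 30), rep("high", 5), rep("non", 30))
  seg <- segment_states(lab, min_run = 10, line_time = CFG$line_time)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$state, "non")
  expect_equal(seg$n_windows, 65L)

  seg2 <- segment_states(c(rep("low", 15), rep("high", 15)), min_run = 10,
                         line_time = CFG$line_time)
  expect_equal(nrow(seg2), 2L)
  expect_equal(unname(attr(seg2, "fractions")[c("low", "high")]), c(0.5, 0.5))

  expect_warning(seg3 <- segment_states(rep(c("non", "low"), 20), min_run = 10),
                 "modal")
  expect_equal(nrow(seg3), 1L)

  # conservation: total segment windows equal the classified length
  withr::with_seed(5, {
    runs <- sample(c("non", "low", "high"), 20, replace = TRUE)
    lens <- sample(5:30, 20, replace = TRUE)
    lab4 <- rep(runs, lens)
    seg4 <- segment_states(lab4, min_run = 10, line_time = CFG$line_time)
    expect_equal(sum(seg4$n_windows), length(lab4))
    expect_equal(sum(attr(seg4, "fractions")), 1)
    expect_true(all(seg4$n_windows >= 10L))
  })
})

test_that("localization precision follows s/sqrt(N)", {
  expect_equal(localization_precision(0.2, 100)$sigma0, 0.02)
  expect_equal(localization_precision(0.5, 25)$sigma0, 0.1)
  expect_equal(localization_precision(0.3, 1)$sigma0, 0.3)
  expect_error(localization_precision(0.2, 0), ">= 1")
})

test_that("diffusion profile fractions sum to one and segments partition", {
  m <- diffusion_state_model()
  sim <- simulate_switching_track(m, CFG, duration = 60, seed = 12)
  pr <- diffusion_profile(sim$track, CFG)
  expect_equal(sum(pr$fractions), 1)
  expect_equal(sum(pr$segments$n_windows),
               sum(!is.na(pr$windows$state)))
})

test_that("mean window D is nondecreasing in the generative D", {
  means <- vapply(c(0.005, 0.02, 0.05, 0.1), function(D) {
    m <- diffusion_state_model(D_values = c(s = D), mean_lifetimes = c(s = 1e6))
    sim <- simulate_switching_track(m, CFG, duration = 2000 * CFG$line_time,
                                    seed = 99)
    mean(rolling_window_D(sim$track, CFG)$D)
  }, numeric(1))
  expect_false(is.unsorted(means))
})
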