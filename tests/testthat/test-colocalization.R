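test_that("threshold closed form and monotonicity", {
  expect_equal(colocalization_threshold(0, 0, 0.0424)$d_threshold, 0)
  thr <- colocalization_threshold(0.04, 0.04, 0.0424)
  expect_equal(thr$d_threshold, 2 * sqrt(2 * 0.04 * 0.0424), tolerance = 1e-12)
  expect_equal(thr$d_threshold, 0.1165, tolerance = 1e-3)
  expect_equal(thr$d_threshold, thr$x1 + thr$x2)

  withr::with_seed(14, {
    for (i in 1:20) {
      D1 <- runif(1, 0, 0.2); D2 <- runif(1, 0, 0.2); dt <- runif(1, 0.01, 0.1)
      t0 <- colocalization_threshold(D1, D2, dt)
      # independent numeric check: empirical RMS one-frame displacement
      x1_emp <- sqrt(mean(rnorm(2e5, 0, sqrt(2 * D1 * dt))^2))
      x2_emp <- sqrt(mean(rnorm(2e5, 0, sqrt(2 * D2 * dt))^2))
      expect_equal(t0$d_threshold, x1_emp + x2_emp, tolerance = 0.02)
      # monotone in each argument
      expect_gte(colocalization_threshold(D1 * 2, D2, dt)$d_threshold,
                 t0$d_threshold)
      expect_gte(colocalization_threshold(D1, D2 * 2, dt)$d_threshold,
                 t0$d_threshold)
    }
  })
  fixed <- colocalization_threshold(0.04, 0.04, 0.0424, fixed_d = 0.31)
  expect_equal(fixed$d_threshold, 0.31)
})

test_that("colocalized-frame detection handles separated, identical and crossing tracks", {
  dt <- CFG$line_time
  n <- 40
  thr <- colocalization_threshold(0.04, 0.04, dt)
  par1 <- new_track("a", "red", (0:(n - 1)) * dt, rep(0, n))
  par2 <- new_track("b", "green", (0:(n - 1)) * dt, rep(1, n))
  expect_equal(nrow(detect_colocalized_frames(par1, par2, 0.3, cfg = CFG)), 0L)

  same <- new_track("c", "green", (0:19) * dt, rep(0.5, 20))
  same2 <- new_track("d", "red", (0:19) * dt, rep(0.5, 20))
  iv <- detect_colocalized_frames(same, same2, thr, cfg = CFG)
  expect_equal(nrow(iv), 1L)
  expect_equal(iv$n_frames, 20L)

  cr1 <- new_track("e", "red", (0:(n - 1)) * dt, seq(0, 2, length.out = n))
  cr2 <- new_track("f", "green", (0:(n - 1)) * dt, seq(2, 0, length.out = n))
  ivc <- detect_colocalized_frames(cr1, cr2, thr, cfg = CFG)
  expect_equal(nrow(ivc), 1L)
  mid <- (ivc$start + ivc$end) / 2
  expect_lt(abs(mid - (n + 1) / 2), 1.01)
})

test_that("detection is symmetric in the two tracks", {
  for (seed in c(2, 4)) {
    sim <- simulate_encounter_pair(CFG, "codiffuse", seed = seed)
    thr <- colocalization_threshold(0.04, 0.04, CFG$line_time)
    ab <- detect_colocalized_frames(sim$track1, sim$track2, thr, cfg = CFG)
    ba <- detect_colocalized_frames(sim$track2, sim$track1, thr, cfg = CFG)
    expect_equal(ab$start, ba$start)
    expect_equal(ab$end, ba$end)
  }
})

test_that("encounter classification follows the duration and validation rules", {
  dt <- CFG$line_time
  thr <- colocalization_threshold(0.04, 0.04, dt)
  # 20 co-moving frames: automatic long colocalization
  same <- new_track("c", "green", (0:19) * dt, rep(0.5, 20))
  same2 <- new_track("d", "red", (0:19) * dt, rep(0.5, 20))
  iv <- detect_colocalized_frames(same, same2, thr, cfg = CFG)
  ev <- classify_encounter(iv[1, ], attr(iv, "aligned"), thr, cfg = CFG)
  expect_equal(ev$kind, "long_coloc")

  # brief graze with fast relative motion: short
  g <- simulate_encounter_pair(CFG, "recoil", seed = 201)
  evg <- classify_encounters(g$track1, g$track2, thr, cfg = CFG)
  expect_true("short_coloc" %in% evg$kind)

  # sub-5-frame interval with a static interior: rescued as long
  v <- 0.0824
  x1 <- c(seq(0.6, 0, by = -v), rep(0, 3), seq(v, 0.6, by = v))
  nn <- length(x1)
  tr1 <- new_track("g", "red", (0:(nn - 1)) * dt, x1)
  tr2 <- new_track("h", "green", (0:(nn - 1)) * dt, rep(0, nn))
  ivs <- detect_colocalized_frames(tr1, tr2, thr, cfg = CFG)
  main <- ivs[which.max(ivs$n_frames), ]
  if (main$n_frames >= 4 && main$n_frames <= 5) {
    evs <- classify_encounter(main, attr(ivs, "aligned"), thr, cfg = CFG)
    expect_equal(evs$kind, "long_coloc")
  }
})

test_that("bypass detection requires a sign flip with sufficient flanks", {
  dt <- CFG$line_time
  n <- 40
  thr <- colocalization_threshold(0.04, 0.04, dt)
  cr1 <- new_track("e", "red", (0:(n - 1)) * dt, seq(0, 2, length.out = n))
  cr2 <- new_track("f", "green", (0:(n - 1)) * dt, seq(2, 0, length.out = n))
  iv <- detect_colocalized_frames(cr1, cr2, thr, cfg = CFG)
  expect_true(any(detect_bypass(iv)))

  # recoil geometry: approach then separate on the same side
  v1 <- c(seq(0, 1, length.out = n / 2), seq(1, 0, length.out = n / 2))
  re1 <- new_track("g", "red", (0:(n - 1)) * dt, v1)
  re2 <- new_track("h", "green", (0:(n - 1)) * dt, rep(1.05, n))
  iv2 <- detect_colocalized_frames(re1, re2, thr, cfg = CFG)
  if (nrow(iv2) > 0) expect_false(any(detect_bypass(iv2)))

  # crossing but the partner track ends 2 frames after the interval
  short2 <- new_track("i", "green", (0:(n / 2 + 1)) * dt,
                      seq(2, 0, length.out = n)[1:(n / 2 + 2)])
  iv3 <- detect_colocalized_frames(cr1, short2, thr, cfg = CFG)
  if (nrow(iv3) > 0) expect_false(any(detect_bypass(iv3)))
})

test_that("classified event kinds partition the intervals", {
  thr <- colocalization_threshold(0.04, 0.04, CFG$line_time)
  for (seed in c(31, 32)) {
    sim <- simulate_encounter_pair(CFG, "bypass", seed = seed)
    ev <- classify_encounters(sim$track1, sim$track2, thr, cfg = CFG)
    expect_true(all(ev$kind %in% c("short_coloc", "long_coloc", "bypass")))
    expect_true("bypass" %in% ev$kind)
  }
})

test_that("short/long classification recovers scenario labels at the reported dwell scales", {
  thr <- colocalization_threshold(0.04, 0.04, CFG$line_time)
  hits <- 0L; total <- 0L
  for (r in 1:200) {
    scen <- if (r %% 2) "recoil" else "codiffuse"
    sim <- simulate_encounter_pair(CFG, scen, seed = 40000 + r)
    ev <- classify_encounters(sim$track1, sim$track2, thr, cfg = CFG)
    if (nrow(ev) == 0) next
    main <- ev[which.max(ev$n_frames), ]
    total <- total + 1L
    want <- if (scen == "recoil") "short_coloc" else "long_coloc"
    hits <- hits + (main$kind == want)
  }
  expect_gte(hits / total, 0.9)
})

test_that("nucleosome maps extend positions and enforce stability rules", {
  dt <- CFG$line_time
  n <- round(10 / dt)
  pat <- rep(c(TRUE, FALSE), c(round(1 / dt), round(9 / dt)))[1:n]
  nuc <- new_track("n1", "green", (0:(n - 1)) * dt,
                   ifelse(pat, 2.0, NA), pat)
  map <- build_nucleosome_map(list(nuc), CFG)
  expect_equal(ncol(map$positions), 1L)
  expect_true(all(is.finite(map$positions)))       # defined across dark gaps
  expect_true(all(map$positions == 2.0))

  withr::with_seed(6, {
    jitter <- new_track("n2", "green", (0:99) * dt, rnorm(100, 2, 3 * 0.144))
    map2 <- build_nucleosome_map(list(nuc, jitter), CFG)
    expect_equal(colnames(map2$positions), "n1")
    expect_true("n2" %in% map2$excluded)

    # stable signal linked to an excluded one is excluded too
    expect_warning(
      map3 <- build_nucleosome_map(list(nuc, jitter), CFG,
                                   links = list(c("n1", "n2"))),
      "zero stable")
    expect_equal(ncol(map3$positions), 0L)
  })
  expect_warning(empty <- build_nucleosome_map(list(), CFG), "no nucleosome")
  expect_equal(ncol(empty$positions), 0L)
})

test_that("remodeler-nucleosome colocalization keys on the 500 bp radius", {
  dt <- CFG$line_time
  n <- 100
  nuc <- new_track("n1", "green", (0:(n - 1)) * dt, rep(2, n))
  map <- build_nucleosome_map(list(nuc), CFG)

  parked <- new_track("r1", "red", (0:(n - 1)) * dt, rep(2.01, n))
  ev <- remodeler_nucleosome_coloc(parked, map, CFG)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$n_frames, n)
  expect_equal(ev$nucleosome, "n1")

  far <- new_track("r2", "red", (0:(n - 1)) * dt,
                   rep(2 + bp_to_um(2000, CFG), n))
  expect_equal(nrow(remodeler_nucleosome_coloc(far, map, CFG)), 0L)

  # one-frame pass through the radius (steps of 2 radii: only one frame in)
  radius <- bp_to_um(500, CFG)
  x <- 2 + seq(-10, 10) * 2 * radius
  crossing <- new_track("r3", "red", (0:20) * dt, x)
  ev3 <- remodeler_nucleosome_coloc(crossing, map, CFG)
  expect_equal(nrow(ev3), 1L)
  expect_equal(ev3$n_frames, 1L)
})
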