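#' Three-state diffusion model for the trajectory generator
#'
#' Describes state-switching 1D Brownian motion with the three diffusive
#' levels seen for DNA-bound remodelers: a non-diffusive state (immobile at
#' the localization limit), a low-diffusive and a high-diffusive state.
#' Hidden states switch as a continuous-time Markov chain.
#'
#' Defaults place the three generative diffusion coefficients inside the three
#' classification bands (< 0.01, 0.01-0.04, >= 0.04 um^2/s) and give the
#' non-diffusive state the ~3.8 s mean lifetime measured for remodelers
#' paused on naked DNA; the low/high lifetimes, which are not constrained by
#' a printed value, default to 2 s.
#'
#' @param D_values Named numeric, um^2/s per state, >= 0.
#' @param mean_lifetimes Mean state lifetimes, s, > 0.
#' @param transition_matrix Row-stochastic matrix of switch probabilities of
#'   the embedded jump chain (diagonal 0 for a proper jump chain).
#' @param state_names Character names of the states.
#' @return Object of class `diffusion_state_model`.
#' @export
diffusion_state_model <- function(D_values = c(non = 0.001, low = 0.02, high = 0.06),
                                  mean_lifetimes = c(non = 3.8, low = 2, high = 2),
                                  transition_matrix = NULL,
                                  state_names = names(D_values)) {
  k <- length(D_values)
  if (is.null(state_names)) state_names <- paste0("state", seq_len(k))
  stopifnot(length(mean_lifetimes) == k, all(D_values >= 0),
            all(mean_lifetimes > 0))
  if (is.null(transition_matrix)) {
    if (k == 1L) {
      transition_matrix <- matrix(1, 1, 1)
    } else {
      transition_matrix <- matrix(1 / (k - 1), k, k)
      diag(transition_matrix) <- 0
    }
  }
  transition_matrix <- as.matrix(transition_matrix)
  if (nrow(transition_matrix) != k || ncol(transition_matrix) != k)
    stop("transition_matrix must be ", k, "x", k)
  if (any(transition_matrix < 0) ||
      any(abs(rowSums(transition_matrix) - 1) > 1e-8))
    stop("transition_matrix rows must be non-negative and sum to 1")
  structure(list(
    state_names = state_names,
    D_values = stats::setNames(as.numeric(D_values), state_names),
    mean_lifetimes = stats::setNames(as.numeric(mean_lifetimes), state_names),
    transition_matrix = transition_matrix
  ), class = "diffusion_state_model")
}

#' Simulate a state-switching Brownian track
#'
#' Positions evolve as `x(t+dt) = x(t) + N(0, 2 D_state dt)` with reflecting
#' boundaries at the tether ends, plus `N(0, noise_sigma^2)` localization
#' noise on the observed positions. Hidden states switch as a continuous-time
#' Markov chain with the model's mean lifetimes.
#'
#' @param model A [diffusion_state_model()].
#' @param cfg A [sim_config()].
#' @param duration Trace duration, s (>= one frame).
#' @param start_um Starting position; default the tether midpoint.
#' @param seed Optional integer seed.
#' @return A list with elements `track` ([new_track()]) and `truth` (per-frame
#'   hidden state labels and the state path).
#' @export
simulate_switching_track <- function(model, cfg = sim_config(), duration,
                                     start_um = NULL, seed = cfg$seed) {
  stopifnot(inherits(model, "diffusion_state_model"))
  dt <- cfg$line_time
  if (duration < dt) stop("duration shorter than one frame")
  n <- floor(duration / dt)
  tether_um <- bp_to_um(cfg$tether_length_bp, cfg)
  if (is.null(start_um)) start_um <- tether_um / 2
  k <- length(model$D_values)
  with_seed(seed, {
    # hidden state path
    state <- integer(n)
    s <- sample.int(k, 1L)
    t_left <- stats::rexp(1L, rate = 1 / model$mean_lifetimes[s])
    for (i in seq_len(n)) {
      state[i] <- s
      t_left <- t_left - dt
      while (t_left <= 0) {
        s <- if (k == 1L) s else
          sample.int(k, 1L, prob = model$transition_matrix[s, ])
        t_left <- t_left + stats::rexp(1L, rate = 1 / model$mean_lifetimes[s])
      }
    }
    sig <- sqrt(2 * model$D_values[state] * dt)
    steps <- stats::rnorm(n, 0, 1) * sig
    steps[1L] <- 0
    x <- start_um + cumsum(steps)
    # reflecting boundaries: fold into [0, tether]
    x <- abs(x)
    per <- 2 * tether_um
    x <- x %% per
    x <- ifelse(x > tether_um, per - x, x)
    obs <- x + if (cfg$noise_sigma > 0) stats::rnorm(n, 0, cfg$noise_sigma) else 0
    track <- new_track("sim", "red", times = (seq_len(n) - 1L) * dt,
                       positions = obs,
                       source = list(generator = "switching_track"))
    truth <- list(state = model$state_names[state],
                  D_true = unname(model$D_values[state]),
                  positions_true = x)
    list(track = track, truth = truth)
  })
}

#' Simulate an exponential (mixture) dwell sample
#'
#' I.i.d. draws from a mixture of exponentials; the generative counterpart of
#' the dwell-time likelihood fitted by [fit_exponential()].
#'
#' @param n Number of draws.
#' @param taus Component means, s, > 0.
#' @param weights Mixture fractions summing to 1.
#' @param seed Optional integer seed.
#' @return Numeric vector of durations.
#' @export
simulate_dwells <- function(n, taus, weights = rep(1 / length(taus), length(taus)),
                            seed = NULL) {
  if (length(taus) == 0L) stop("taus must be non-empty")
  stopifnot(all(taus > 0), length(weights) == length(taus),
            all(weights >= 0))
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  with_seed(seed, {
    comp <- sample.int(length(taus), n, replace = TRUE, prob = weights)
    stats::rexp(n, rate = 1 / taus[comp])
  })
}

#' Simulate a labeled two-particle encounter
#'
#' Constructs a two-color encounter of one of the three observed classes:
#' `recoil` (contact with continued independent relative motion for a short
#' exponential dwell, then separation on the same side), `codiffuse` (a shared
#' Brownian displacement applied to both particles for a long exponential
#' dwell), or `bypass` (the particles cross and continue). The approach and
#' retreat are stylized linear ramps with per-frame Brownian-scale jitter so
#' that the event geometry, not random walk luck, defines the class.
#'
#' @param cfg A [sim_config()].
#' @param scenario `"recoil"`, `"codiffuse"` or `"bypass"`.
#' @param params List overriding: `D` (per-molecule diffusion coefficient,
#'   um^2/s, default 0.04), `sep0` initial separation (um, default 1),
#'   `dwell_mean` (s; defaults 0.033 recoil / 0.70 codiffuse),
#'   `approach_time`, `post_time` (s; by default the time to close `sep0` at
#'   the RMS relative Brownian displacement per frame, so the approach moves
#'   at a physically plausible rate), `center_um` (default 5).
#' @param seed Optional seed.
#' @return List with `track1` (red), `track2` (green) and `truth` (scenario,
#'   continuous dwell draw, event frame interval).
#' @export
simulate_encounter_pair <- function(cfg = sim_config(),
                                    scenario = c("recoil", "codiffuse", "bypass"),
                                    params = list(), seed = cfg$seed) {
  scenario <- match.arg(scenario)
  p <- utils::modifyList(list(
    D = 0.04, sep0 = 1.0,
    dwell_mean = switch(scenario, recoil = 0.033, codiffuse = 0.70, bypass = 0),
    approach_time = NULL, post_time = NULL, center_um = 5
  ), params)
  rel_step <- sqrt(2 * 2 * p$D * cfg$line_time)
  if (is.null(p$approach_time))
    p$approach_time <- if (rel_step > 0)
      p$sep0 / rel_step * cfg$line_time else 2
  if (is.null(p$post_time)) p$post_time <- p$approach_time
  if (scenario == "bypass" && p$sep0 <= 0)
    stop("bypass scenario requires non-overlapping initial positions")
  dt <- cfg$line_time
  with_seed(seed, {
    dwell_true <- if (p$dwell_mean > 0) stats::rexp(1L, 1 / p$dwell_mean) else 0
    L <- max(1L, as.integer(round(dwell_true / dt)))
    if (scenario == "bypass") L <- 1L
    n_pre <- max(2L, as.integer(round(p$approach_time / dt)))
    n_post <- max(2L, as.integer(round(p$post_time / dt)))
    s_rel <- sqrt(2 * 2 * p$D * dt)  # relative-motion scale of two diffusers

    sep_pre <- seq(p$sep0, 0, length.out = n_pre + 1L)[seq_len(n_pre)] +
      stats::rnorm(n_pre, 0, s_rel / 4)
    sep_pre <- pmax(sep_pre, 0)
    sep_evt <- switch(scenario,
      recoil = abs(stats::rnorm(L, 0, s_rel)),
      codiffuse = abs(stats::rnorm(L, 0, max(cfg$noise_sigma, 1e-4))),
      bypass = rep(0, L))
    sep_post <- seq(0, p$sep0, length.out = n_post + 1L)[-1L] +
      stats::rnorm(n_post, 0, s_rel / 4)
    sep_post <- pmax(sep_post, 0)

    sep <- c(sep_pre, sep_evt, sep_post)
    n <- length(sep)
    # sign of (x1 - x2): starts negative; flips after the event for bypass
    sgn <- rep(-1, n)
    if (scenario == "bypass") sgn[(n_pre + L + 1L):n] <- 1
    center <- rep(p$center_um, n)
    if (scenario == "codiffuse" && L > 1L) {
      idx <- (n_pre + 1L):(n_pre + L)
      shared <- cumsum(c(0, stats::rnorm(L - 1L, 0, sqrt(2 * p$D * dt))))
      center[idx] <- center[idx] + shared
      center[(n_pre + L + 1L):n] <- center[n_pre + L]
    }
    x1 <- center + sgn * sep / 2
    x2 <- center - sgn * sep / 2
    if (cfg$noise_sigma > 0) {
      x1 <- x1 + stats::rnorm(n, 0, cfg$noise_sigma)
      x2 <- x2 + stats::rnorm(n, 0, cfg$noise_sigma)
    }
    times <- (seq_len(n) - 1L) * dt
    list(
      track1 = new_track("mol1", "red", times, x1,
                         source = list(generator = "encounter", scenario = scenario)),
      track2 = new_track("mol2", "green", times, x2,
                         source = list(generator = "encounter", scenario = scenario)),
      truth = list(scenario = scenario, dwell_true = dwell_true,
                   event_frames = c(n_pre + 1L, n_pre + L),
                   event_times = c(times[n_pre + 1L], times[n_pre + L]))
    )
  })
}

#' Simulate a piecewise-linear translocation trace
#'
#' A directed, constant-speed (or piecewise constant-speed) mean path with
#' Gaussian localization noise, optionally with a co-moving second-channel
#' nucleosome track, emulating ATP-driven processive nucleosome translocation.
#'
#' @param speed Speed magnitude(s), bp/s; one value per segment
#'   (`length(changepoints) + 1` segments).
#' @param duration Total duration, s.
#' @param cfg A [sim_config()]; `noise_sigma` sets the localization noise.
#' @param direction +1 or -1 (applied to all segments); per-segment signs can
#'   be given directly via signed `speed`.
#' @param changepoints Optional strictly increasing times in (0, duration)
#'   where the speed changes.
#' @param start_bp Start position, bp; default mid-tether.
#' @param emit_nucleosome Emit a co-moving green-channel track.
#' @param seed Optional seed.
#' @return List with `track` (red, remodeler), `nucleosome` (green or NULL)
#'   and `truth` (per-segment times, signed speeds in bp/s, net displacement).
#' @export
simulate_translocation_track <- function(speed, duration, cfg = sim_config(),
                                         direction = 1, changepoints = NULL,
                                         start_bp = NULL,
                                         emit_nucleosome = FALSE,
                                         seed = cfg$seed) {
  stopifnot(duration > 0, direction %in% c(-1, 1))
  if (!is.null(changepoints)) {
    if (any(changepoints <= 0) || any(changepoints >= duration))
      stop("changepoints must lie strictly inside (0, duration)")
    if (any(diff(changepoints) <= 0))
      stop("changepoints must be strictly increasing")
  }
  n_seg <- length(changepoints) + 1L
  if (length(speed) == 1L) speed <- rep(speed, n_seg)
  stopifnot(length(speed) == n_seg)
  speeds <- speed * direction
  dt <- cfg$line_time
  n <- floor(duration / dt) + 1L
  times <- (seq_len(n) - 1L) * dt
  bounds <- c(0, changepoints, duration)
  if (is.null(start_bp)) start_bp <- cfg$tether_length_bp / 2
  # integrated piecewise-linear mean path in bp
  pos_bp <- numeric(n)
  seg_of <- findInterval(times, bounds, rightmost.closed = TRUE)
  seg_of[seg_of < 1L] <- 1L
  seg_start_bp <- cumsum(c(0, speeds * diff(bounds)))
  pos_bp <- start_bp + seg_start_bp[seg_of] +
    speeds[seg_of] * (times - bounds[seg_of])
  pos_um <- bp_to_um(pos_bp, cfg)
  with_seed(seed, {
    noise1 <- if (cfg$noise_sigma > 0) stats::rnorm(n, 0, cfg$noise_sigma) else 0
    track <- new_track("rem", "red", times, pos_um + noise1,
                       source = list(generator = "translocation"))
    nuc <- NULL
    if (emit_nucleosome) {
      noise2 <- if (cfg$noise_sigma > 0) stats::rnorm(n, 0, cfg$noise_sigma) else 0
      nuc <- new_track("nuc", "green", times, pos_um + noise2,
                       source = list(generator = "translocation"))
    }
    truth <- list(
      segments = data.frame(t_start = bounds[-length(bounds)],
                            t_end = bounds[-1L],
                            speed_bp_s = speeds),
      net_displacement_bp = sum(speeds * diff(bounds)),
      start_bp = start_bp
    )
    list(track = track, nucleosome = nuc, truth = truth)
  })
}

#' Simulate a force-clamp unwrapping trace
#'
#' A monotone nondecreasing mean extension with `n_nucleosomes` discrete jumps
#' of `step_size` nm at exponential waiting times, plus Gaussian noise;
#' emulates nucleosome unwrapping under a 15-20 pN force clamp.
#'
#' @param n_nucleosomes Number of steps (>= 0).
#' @param step_size Step size, nm (default 25).
#' @param noise_sigma Gaussian noise, nm.
#' @param rate Unwrapping rate, 1/s (exponential waiting times).
#' @param cfg A [sim_config()] (unused constants kept for provenance).
#' @param sample_dt Sampling interval of the distance channel, s.
#' @param tail_time Flat time appended after the last step, s.
#' @param clamp_force Clamp force, pN (metadata).
#' @param seed Optional seed.
#' @return List with `trace` (a `force_trace`) and `truth` (step times/sizes).
#' @export
simulate_force_clamp_trace <- function(n_nucleosomes, step_size = 25,
                                       noise_sigma = 2, rate = 0.5,
                                       cfg = sim_config(), sample_dt = 0.01,
                                       tail_time = 2, clamp_force = 15,
                                       seed = cfg$seed) {
  stopifnot(n_nucleosomes >= 0)
  if (step_size < 0) stop("step_size must be non-negative")
  with_seed(seed, {
    step_times <- if (n_nucleosomes > 0)
      cumsum(stats::rexp(n_nucleosomes, rate)) else numeric(0)
    duration <- (if (n_nucleosomes > 0) max(step_times) else 0) + tail_time
    times <- seq(0, duration, by = sample_dt)
    mean_nm <- step_size * findInterval(times, step_times)
    dist_nm <- mean_nm +
      if (noise_sigma > 0) stats::rnorm(length(times), 0, noise_sigma) else 0
    trace <- force_trace(times, distance_nm = dist_nm, force_pN = clamp_force,
                         clamp_window = c(0, duration))
    list(trace = trace,
         truth = list(step_times = step_times,
                      step_sizes = rep(step_size, n_nucleosomes)))
  })
}

#' Apply the observation model (pulsed excitation and photobleaching)
#'
#' Frames falling in dark excitation pulses are marked unobserved; an
#' exponential photobleaching time truncates the track (bleaching is modeled
#' as single-step; the track terminates).
#'
#' @param track A [new_track()].
#' @param cfg A [sim_config()]; uses `pulse_pattern` and `bleach_rate`.
#' @param seed Optional seed (for the bleach time).
#' @return A `kymo_track` with updated observed mask and possible truncation.
#' @export
apply_observation_model <- function(track, cfg = sim_config(), seed = cfg$seed) {
  n <- n_frames(track)
  times <- track$times
  positions <- track$positions
  observed <- track$observed
  if (!is.null(cfg$pulse_pattern)) {
    pat <- rep_len(cfg$pulse_pattern, n)
    observed <- observed & pat
  }
  if (cfg$bleach_rate > 0) {
    tb <- if (is.infinite(cfg$bleach_rate)) 0 else
      with_seed(seed, stats::rexp(1L, cfg$bleach_rate))
    keep <- (times - times[1L]) < tb
    times <- times[keep]; positions <- positions[keep]; observed <- observed[keep]
  }
  src <- track$source
  src$observation_model <- list(pulsed = !is.null(cfg$pulse_pattern),
                                bleach_rate = cfg$bleach_rate)
  out <- track
  out$times <- times; out$positions <- positions; out$observed <- observed
  out$source <- src
  out
}
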