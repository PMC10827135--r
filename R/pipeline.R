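#' Pipeline run configuration
#'
#' Collects the physical constants and every module's tunable parameters with
#' defaults equal to the analysis' standard operating point: diffusion-state
#' thresholds 0.01/0.04 um^2/s, 20-frame windows with 5 fit lags and 10-window
#' minimum runs, 5-frame smoothing, translocation admission filters of 300 bp
#' / 5 s / R^2 0.5, 25 nm unwrapping steps, and a 500 bp remodeler-nucleosome
#' radius.
#'
#' @param input Optional track CSV path.
#' @param dialect CSV dialect for `input`.
#' @param cfg A [sim_config()].
#' @param diffusion,dwell,coloc,transloc,force Named lists overriding module
#'   parameter blocks.
#' @param seed Integer seed.
#' @param out_dir Optional output directory.
#' @return Object of class `run_config`.
#' @export
run_config <- function(input = NULL, dialect = "native", cfg = sim_config(),
                       diffusion = list(), dwell = list(), coloc = list(),
                       transloc = list(), force = list(), seed = 1L,
                       out_dir = NULL) {
  defaults <- list(
    diffusion = list(window = 20L, fit_points = 5L, dims = 1L,
                     thresholds = c(0.01, 0.04), min_run = 10L,
                     smooth_span = 5L),
    dwell = list(censoring = "none", min_duration = 0),
    coloc = list(smooth_span = 5, long_min = 5, flank = 5L,
                 nuc_radius_bp = 500, fixed_d = NULL),
    transloc = list(min_bp = 300, min_s = 5, min_r2 = 0.5,
                    penalty = NULL, penalty_mult = 1.5, min_seg_s = 2.5),
    force = list(expected_step = 25, noise_window = 50L)
  )
  structure(list(
    input = input, dialect = dialect, cfg = cfg,
    diffusion = utils::modifyList(defaults$diffusion, diffusion),
    dwell = utils::modifyList(defaults$dwell, dwell),
    coloc = utils::modifyList(defaults$coloc, coloc),
    transloc = utils::modifyList(defaults$transloc, transloc),
    force = utils::modifyList(defaults$force, force),
    seed = as.integer(seed), out_dir = out_dir
  ), class = "run_config")
}

track_condition <- function(track) {
  cond <- track$source$condition
  if (is.null(cond)) "all" else as.character(cond)
}

#' Run the full analysis pipeline
#'
#' Tracks -> per-track diffusion profiles -> bound-lifetime fits by condition
#' -> two-color encounter classification -> translocation segmentation with
#' push/pull calls -> nucleosome counts from force traces -> report.
#' Deterministic given (inputs, config, seed).
#'
#' @param tracks List of `kymo_track` (read from `config$input` when NULL).
#' @param force_traces Optional list of [force_trace()].
#' @param config A [run_config()].
#' @return Object of class `run_report` (a list of result tables plus
#'   provenance); written to `config$out_dir` as JSON/CSV when set.
#' @export
run_pipeline <- function(tracks = NULL, force_traces = NULL,
                         config = run_config()) {
  cfg <- config$cfg
  if (is.null(tracks)) {
    tracks <- if (!is.null(config$input))
      read_tracks(config$input, config$dialect, cfg) else list()
  }
  dp <- config$diffusion
  warnings_log <- character(0)

  # --- diffusion profiles ------------------------------------------------
  profiles <- vector("list", length(tracks))
  diff_rows <- list()
  for (i in seq_along(tracks)) {
    tr <- tracks[[i]]
    if (n_frames(tr) >= dp$window + dp$fit_points) {
      pr <- diffusion_profile(tr, cfg, dp$window, dp$fit_points, dp$dims,
                              dp$thresholds, dp$min_run, dp$smooth_span)
      profiles[[i]] <- pr
      fr <- pr$fractions
      diff_rows[[length(diff_rows) + 1L]] <- data.frame(
        track_id = tr$track_id, channel = tr$channel,
        n_frames = n_frames(tr), mean_D = pr$mean_D,
        frac_non = if ("non" %in% names(fr)) fr[["non"]] else 0,
        frac_low = if ("low" %in% names(fr)) fr[["low"]] else 0,
        frac_high = if ("high" %in% names(fr)) fr[["high"]] else 0,
        stringsAsFactors = FALSE)
    }
  }
  diffusion_tbl <- if (length(diff_rows)) do.call(rbind, diff_rows) else NULL

  # --- bound lifetimes by condition --------------------------------------
  durs <- vapply(tracks, track_duration, numeric(1))
  conds <- vapply(tracks, track_condition, character(1))
  ok <- durs > 0
  dwell_tbl <- NULL
  if (sum(ok) >= 3L) {
    dwell_tbl <- tryCatch(
      bound_lifetime_by_condition(
        data.frame(duration = durs[ok], condition = conds[ok]),
        censoring = config$dwell$censoring),
      error = function(e) { warnings_log <<- c(warnings_log, conditionMessage(e)); NULL })
  }

  # --- two-color encounters ----------------------------------------------
  reds <- tracks[vapply(tracks, function(x) x$channel == "red", logical(1))]
  greens <- tracks[vapply(tracks, function(x) x$channel == "green", logical(1))]
  events <- list()
  for (a in reds) for (b in greens) {
    if (a$times[1L] > b$times[n_frames(b)] ||
        b$times[1L] > a$times[n_frames(a)]) next
    mD <- function(tr) {
      if (n_frames(tr) < dp$window + dp$fit_points) return(NA_real_)
      mean(rolling_window_D(tr, cfg, dp$window, dp$fit_points, dp$dims)$D,
           na.rm = TRUE)
    }
    d1 <- mD(a); d2 <- mD(b)
    if (is.na(d1) || is.na(d2)) next
    thr <- colocalization_threshold(d1, d2, cfg$line_time,
                                    fixed_d = config$coloc$fixed_d)
    ev <- classify_encounters(a, b, thr, config$coloc$smooth_span,
                              config$coloc$long_min, config$coloc$flank, cfg)
    if (nrow(ev) > 0L) {
      ev$track1 <- a$track_id; ev$track2 <- b$track_id
      events[[length(events) + 1L]] <- ev
    }
  }
  events_tbl <- if (length(events)) do.call(rbind, events) else NULL
  event_props <- if (!is.null(events_tbl))
    as.list(table(events_tbl$kind) / nrow(events_tbl)) else NULL

  # --- translocation ------------------------------------------------------
  tp <- config$transloc
  seg_rows <- list()
  pushpull <- list()
  for (i in seq_along(tracks)) {
    tr <- tracks[[i]]
    seg <- segment_speeds(tr, cfg, tp$penalty, tp$penalty_mult, tp$min_seg_s,
                          tp$min_bp, tp$min_s, tp$min_r2)
    if (nrow(seg) > 0L) {
      seg$track_id <- tr$track_id
      seg_rows[[length(seg_rows) + 1L]] <- seg
    }
    if (any(seg$admitted)) {
      frag <- fragment_trace(tr, coloc_events = NULL, segments = seg)
      pp <- classify_push_pull(frag, seg, tr)
      pushpull[[tr$track_id]] <- pp$call
    }
  }
  segments_tbl <- if (length(seg_rows)) do.call(rbind, seg_rows) else NULL
  push_pull_counts <- if (length(pushpull))
    as.list(table(unlist(pushpull))) else NULL

  # --- nucleosome counting -----------------------------------------------
  nuc_counts <- NULL
  if (!is.null(force_traces)) {
    nuc_counts <- vapply(force_traces, function(ft) {
      rec <- detect_unwrap_steps(ft, config$force$expected_step,
                                 noise_window = config$force$noise_window)
      as.integer(count_nucleosomes(rec, config$force$expected_step))
    }, integer(1))
  }

  report <- structure(list(
    n_tracks = length(tracks),
    diffusion = diffusion_tbl,
    dwell = dwell_tbl,
    encounters = events_tbl,
    encounter_proportions = event_props,
    translocation = segments_tbl,
    push_pull = push_pull_counts,
    nucleosome_counts = nuc_counts,
    warnings = warnings_log,
    provenance = list(seed = config$seed,
                      package_version = as.character(utils::packageVersion("kymoflux")),
                      line_time = cfg$line_time, um_per_bp = cfg$um_per_bp)
  ), class = "run_report")
  if (length(tracks) == 0L) warning("empty input; empty report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("run_report: %d tracks\n", x$n_tracks))
  if (!is.null(x$diffusion))
    cat(sprintf("  diffusion profiles: %d\n", nrow(x$diffusion)))
  if (!is.null(x$encounters))
    cat(sprintf("  encounter events: %d\n", nrow(x$encounters)))
  if (!is.null(x$translocation))
    cat(sprintf("  translocation segments: %d (%d admitted)\n",
                nrow(x$translocation), sum(x$translocation$admitted)))
  if (!is.null(x$nucleosome_counts))
    cat("  nucleosome counts:", paste(x$nucleosome_counts, collapse = ", "), "\n")
  invisible(x)
}

#' Write a run report to disk
#'
#' @param report A `run_report`.
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(report = file.path(out_dir, "report.json"))
  jsonlite::write_json(unclass(report), paths[["report"]],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns", na = "null")
  for (nm in c("diffusion", "encounters", "translocation")) {
    if (!is.null(report[[nm]])) {
      p <- file.path(out_dir, paste0(nm, ".csv"))
      utils::write.csv(report[[nm]], p, row.names = FALSE)
      paths[[nm]] <- p
    }
  }
  invisible(paths)
}

#' Hash a run report (reproducibility check)
#'
#' @param report A `run_report`.
#' @return MD5 hex string of the serialized report.
#' @export
report_hash <- function(report) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(report), tmp, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null")
  unname(tools::md5sum(tmp))
}

#' Synthetic parameter-recovery validation suite
#'
#' Executes the parameter-recovery studies that underpin every analysis stage
#' (diffusion-state classification, dwell-time MLE, encounter classification,
#' translocation speed and filters, push/pull calls, nucleosome counting) on
#' freshly generated synthetic data, and reports a pass/fail table.
#'
#' @param seed Integer seed.
#' @param n_scale Multiplier on the study sizes (1 = fast validation scale).
#' @return Data.frame with `check`, `value`, `threshold`, `comparison`,
#'   `pass`.
#' @export
run_validation_suite <- function(seed = 1L, n_scale = 1) {
  cfg <- sim_config()
  rows <- list()
  add <- function(check, value, threshold, comparison = ">=") {
    pass <- if (comparison == ">=") value >= threshold else value <= threshold
    rows[[length(rows) + 1L]] <<- data.frame(
      check = check, value = value, threshold = threshold,
      comparison = comparison, pass = pass, stringsAsFactors = FALSE)
  }

  # diffusion-state recovery and monotonicity
  Ds <- c(non = 0.005, low = 0.02, high = 0.05)
  n_tracks <- max(10L, as.integer(10 * n_scale))
  meanDs <- numeric(0)
  for (j in seq_along(Ds)) {
    hits <- 0L
    mD <- numeric(n_tracks)
    for (r in seq_len(n_tracks)) {
      sim <- simulate_switching_track(
        diffusion_state_model(D_values = Ds[j], mean_lifetimes = 10,
                              state_names = names(Ds)[j]),
        cfg, duration = 5000 * cfg$line_time,
        seed = derive_seed(seed, paste0("diff", j, "_", r)))
      D <- rolling_window_D(sim$track, cfg)$D
      mD[r] <- mean(D, na.rm = TRUE)
      lab <- classify_windows(D)
      modal <- names(which.max(table(lab)))
      hits <- hits + (modal == names(Ds)[j])
    }
    meanDs[j] <- mean(mD)
    add(paste0("diffusion_modal_accuracy_", names(Ds)[j]),
        hits / n_tracks, 0.9)
  }
  add("diffusion_meanD_monotone", as.numeric(!is.unsorted(meanDs)), 1)

  # dwell-time recovery bias (averaged over replicates)
  for (tau in c(0.03, 0.7, 3.8, 12, 18, 28)) {
    reps <- max(10L, as.integer(10 * n_scale))
    est <- vapply(seq_len(reps), function(r) {
      d <- simulate_dwells(1000, tau,
                           seed = derive_seed(seed, paste0("dw", tau, "_", r)))
      fit_exponential(d, 1L)$taus
    }, numeric(1))
    add(paste0("dwell_bias_tau_", tau), abs(mean(est) - tau) / tau, 0.05, "<=")
  }

  # encounter classification accuracy
  n_ev <- max(20L, as.integer(100 * n_scale))
  correct <- 0L
  for (r in seq_len(n_ev)) {
    scen <- if (r %% 2L == 0L) "recoil" else "codiffuse"
    sim <- simulate_encounter_pair(cfg, scen,
                                   seed = derive_seed(seed, paste0("enc", r)))
    thr <- colocalization_threshold(0.04, 0.04, cfg$line_time)
    ev <- classify_encounters(sim$track1, sim$track2, thr, cfg = cfg)
    if (nrow(ev) > 0L) {
      main <- ev[which.max(ev$n_frames), ]
      want <- if (scen == "recoil") "short_coloc" else "long_coloc"
      correct <- correct + (main$kind == want)
    }
  }
  add("encounter_accuracy", correct / n_ev, 0.9)

  # translocation speed recovery and filter soundness
  n_tr <- max(5L, as.integer(20 * n_scale))
  sp <- vapply(seq_len(n_tr), function(r) {
    cfg_n <- sim_config(noise_sigma = cfg$pixel_to_um)
    sim <- simulate_translocation_track(29, 33, cfg_n,
                                        seed = derive_seed(seed, paste0("tl", r)))
    seg <- segment_speeds(sim$track, cfg_n)
    adm <- seg[seg$admitted, ]
    if (nrow(adm)) stats::weighted.mean(abs(adm$speed_bp_s), adm$duration_s)
    else NA_real_
  }, numeric(1))
  add("translocation_speed_error", abs(mean(sp, na.rm = TRUE) - 29) / 29,
      0.05, "<=")
  n_adm <- vapply(seq_len(n_tr), function(r) {
    cfg_n <- sim_config(noise_sigma = cfg$pixel_to_um)
    sim <- simulate_translocation_track(0, 33, cfg_n,
                                        seed = derive_seed(seed, paste0("st", r)))
    sum(segment_speeds(sim$track, cfg_n)$admitted)
  }, integer(1))
  add("static_traces_admitted", sum(n_adm), 0, "<=")

  # push/pull recovery
  n_pp <- max(10L, as.integer(40 * n_scale))
  ok_pp <- 0L
  cfg_pp <- sim_config(noise_sigma = cfg$pixel_to_um)
  for (r in seq_len(n_pp)) {
    same <- r %% 2L == 0L
    sim <- simulate_search_engage_translocate(
      cfg_pp, same_direction = same,
      seed = derive_seed(seed, paste0("pp", r)))
    seg <- segment_speeds(sim$track, cfg_pp)
    frag <- suppressWarnings(fragment_trace(sim$track, sim$coloc_events, seg))
    pp <- classify_push_pull(frag, seg, sim$track)
    want <- if (same) "push" else "pull"
    ok_pp <- ok_pp + (pp$call == want)
  }
  add("push_pull_accuracy", ok_pp / n_pp, 0.95)

  # nucleosome counting recovery
  n_fc <- max(5L, as.integer(20 * n_scale))
  exact <- 0L
  for (r in seq_len(n_fc)) {
    nn <- if (r %% 2L == 0L) 10L else 30L
    sim <- simulate_force_clamp_trace(nn, seed = derive_seed(seed, paste0("fc", r)))
    rec <- detect_unwrap_steps(sim$trace)
    exact <- exact + (as.integer(count_nucleosomes(rec)) == nn)
  }
  add("nucleosome_count_exact", exact / n_fc, 0.95)

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a search -> engage -> translocate trace with known directionality
#'
#' Builds a labeled composite trace: a 1D diffusive search ending in a clear
#' approach to the nucleosome position, a static engaged period, and an
#' admitted-scale translocation whose direction is the approach direction
#' (`same_direction = TRUE`, push-like) or its opposite (pull-like).
#'
#' @param cfg A [sim_config()].
#' @param same_direction Translocation parallel to the approach?
#' @param approach_from +1 approaches from below, -1 from above; default
#'   random.
#' @param speed_bp_s,transloc_s,engage_s,search_s Stage parameters (defaults
#'   29 bp/s and a 33 s translocation — the average speed and median
#'   constant-speed segment duration of the translocation population — with
#'   5 s engaged and 10 s of search).
#' @param seed Optional seed.
#' @return List with `track`, `coloc_events` (the engaged+translocating
#'   window), and `truth` (approach/translocation directions and the expected
#'   call).
#' @export
simulate_search_engage_translocate <- function(cfg = sim_config(),
                                               same_direction = TRUE,
                                               approach_from = NULL,
                                               speed_bp_s = 29,
                                               transloc_s = 33, engage_s = 5,
                                               search_s = 10, seed = cfg$seed) {
  dt <- cfg$line_time
  with_seed(seed, {
    if (is.null(approach_from)) approach_from <- sample(c(-1, 1), 1L)
    nuc_um <- bp_to_um(cfg$tether_length_bp / 2, cfg)
    n_search <- round(search_s / dt)
    n_eng <- round(engage_s / dt)
    n_tr <- round(transloc_s / dt)
    # diffusive search that ends with a deterministic approach leg
    n_appr <- 20L
    D_search <- 0.03
    start <- nuc_um - approach_from * 0.8
    wander <- cumsum(c(0, stats::rnorm(n_search - n_appr - 1L, 0,
                                       sqrt(2 * D_search * dt))))
    wander <- start + wander - (wander[length(wander)])  # end back at start
    appr <- seq(start, nuc_um, length.out = n_appr + 1L)[-1L]
    search <- c(wander, appr)
    engaged <- rep(nuc_um, n_eng)
    tr_dir <- if (same_direction) approach_from else -approach_from
    transloc <- nuc_um + tr_dir * bp_to_um(speed_bp_s, cfg) * dt * seq_len(n_tr)
    x <- c(search, engaged, transloc)
    noise <- if (cfg$noise_sigma > 0)
      stats::rnorm(length(x), 0, cfg$noise_sigma) else 0
    times <- (seq_along(x) - 1L) * dt
    track <- new_track("pp", "red", times, x + noise,
                       source = list(generator = "search_engage_translocate"))
    coloc_events <- data.frame(t_start = times[n_search + 1L],
                               t_end = times[length(x)])
    list(track = track, coloc_events = coloc_events,
         truth = list(approach_direction = approach_from,
                      translocation_direction = tr_dir,
                      call = if (same_direction) "push" else "pull"))
  })
}
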