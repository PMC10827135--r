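#' Colocalization distance threshold from mean diffusion coefficients
#'
#' Per-molecule maximum displacement over one frame under independent Brownian
#' motion, `x_i = sqrt(2 mean_D_i dt)` (the 1D RMS displacement), summed into
#' the pair threshold `d = x1 + x2`. A multiplicative safety factor is
#' available, and an empirically determined constant threshold can be imposed
#' directly via `fixed_d`.
#'
#' @param mean_D_1,mean_D_2 Mean diffusion coefficients of the two molecules,
#'   um^2/s, >= 0.
#' @param dt Frame (exposure) time, s.
#' @param safety Multiplicative factor on `d` (default 1).
#' @param fixed_d Optional constant threshold in um overriding the model.
#' @return Object of class `coloc_threshold` with `x1`, `x2`, `d_threshold`.
#' @export
colocalization_threshold <- function(mean_D_1, mean_D_2, dt, safety = 1,
                                     fixed_d = NULL) {
  stopifnot(mean_D_1 >= 0, mean_D_2 >= 0, dt > 0)
  x1 <- sqrt(2 * mean_D_1 * dt)
  x2 <- sqrt(2 * mean_D_2 * dt)
  d <- if (is.null(fixed_d)) safety * (x1 + x2) else fixed_d
  structure(list(mean_D_1 = mean_D_1, mean_D_2 = mean_D_2, dt = dt,
                 x1 = x1, x2 = x2, d_threshold = d, safety = safety,
                 fixed = !is.null(fixed_d)),
            class = "coloc_threshold")
}

# Gaussian kernel smoothing of a numeric vector, NA-aware, kernel truncated at
# 4 sigma and renormalized at the edges.
gaussian_smooth <- function(x, sigma, truncate = 4) {
  if (is.na(sigma) || sigma <= 0) return(x)
  half <- max(1L, as.integer(ceiling(truncate * sigma)))
  kern <- stats::dnorm(-half:half, sd = sigma)
  n <- length(x)
  ok <- !is.na(x)
  xv <- ifelse(ok, x, 0)
  num <- stats::filter(c(rep(0, half), xv, rep(0, half)), kern, sides = 2)
  den <- stats::filter(c(rep(0, half), as.numeric(ok), rep(0, half)), kern,
                       sides = 2)
  y <- (num / den)[(half + 1L):(half + n)]
  y[!ok] <- NA_real_
  as.numeric(y)
}

# Align two tracks on a common frame grid. Returns times, x1, x2 (NA where
# unobserved), restricted to the overlapping span.
align_tracks <- function(track1, track2, line_time) {
  t0 <- min(track1$times[1L], track2$times[1L])
  g1 <- dense_positions(track1, line_time)
  g2 <- dense_positions(track2, line_time)
  off1 <- as.integer(round((g1$t0 - t0) / line_time))
  off2 <- as.integer(round((g2$t0 - t0) / line_time))
  n <- max(off1 + g1$n, off2 + g2$n)
  x1 <- rep(NA_real_, n); x2 <- rep(NA_real_, n)
  x1[off1 + seq_len(g1$n)] <- g1$x
  x2[off2 + seq_len(g2$n)] <- g2$x
  list(times = t0 + (seq_len(n) - 1L) * line_time, x1 = x1, x2 = x2)
}

#' Detect colocalized frame intervals between two tracks
#'
#' Each track is Gaussian-smoothed over a time window of `smooth_span`
#' exposure points (kernel sigma = `smooth_span / 4`, so the stated window is
#' the kernel support), the per-frame separation is compared to the threshold
#' on co-observed frames, and maximal sub-threshold runs are returned.
#' Symmetric in the two tracks.
#'
#' @param track1,track2 `kymo_track`s with overlapping time spans.
#' @param threshold A [colocalization_threshold()] or a numeric distance (um).
#' @param smooth_span Smoothing window in frames (default 5); 0 disables.
#' @param cfg A [sim_config()].
#' @return Data.frame with one row per interval: `start`, `end` (frame index
#'   on the common grid), `t_start`, `t_end`, `n_frames`. Attribute `aligned`
#'   carries the smoothed aligned positions for downstream classification.
#' @export
detect_colocalized_frames <- function(track1, track2, threshold,
                                      smooth_span = 5, cfg = sim_config()) {
  d <- if (inherits(threshold, "coloc_threshold")) threshold$d_threshold
       else as.numeric(threshold)
  al <- align_tracks(track1, track2, cfg$line_time)
  s1 <- gaussian_smooth(al$x1, smooth_span / 4)
  s2 <- gaussian_smooth(al$x2, smooth_span / 4)
  sep <- abs(s1 - s2)
  below <- !is.na(sep) & sep < d
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  out <- data.frame(start = starts[keep], end = ends[keep],
                    t_start = al$times[starts[keep]],
                    t_end = al$times[ends[keep]],
                    n_frames = r$lengths[keep])
  attr(out, "aligned") <- list(times = al$times, x1 = s1, x2 = s2,
                               raw1 = al$x1, raw2 = al$x2, d = d)
  out
}

#' Classify one colocalized interval as short or long
#'
#' Intervals longer than `long_min` frames are automatically long
#' colocalizations. Shorter intervals pass through two validation tests on the
#' raw (unsmoothed) separations, in order: (1) if the separation displacement
#' across the interval exceeds the threshold model's expected displacement the
#' event is long; (2) otherwise the interval interior is tested for
#' co-movement: when the interval has at least 4 frames and the median
#' interior separation increment is below `static_frac` of the per-frame
#' relative RMS displacement `sqrt(2 mean_D dt)`, the relative motion is far
#' slower than two independent diffusers could sustain and the event is a long
#' colocalization (brief co-diffusion); otherwise it is a short colocalization
#' (a graze with recoil). Sub-frame co-diffusion events are observationally
#' identical to grazes and are necessarily classified short; the local
#' relative diffusion coefficient is recorded in the metrics either way.
#'
#' @param interval One row of [detect_colocalized_frames()] output.
#' @param aligned The `aligned` attribute of that output.
#' @param threshold The [colocalization_threshold()] used.
#' @param long_min Duration threshold in frames (default 5).
#' @param static_frac Fraction of the relative RMS frame displacement below
#'   which the interval interior counts as co-moving (default 0.15).
#' @param cfg A [sim_config()].
#' @return Object of class `encounter_event` (a list): `kind`, `t_start`,
#'   `t_end`, `duration`, `mean_separation`, `metrics`.
#' @export
classify_encounter <- function(interval, aligned, threshold, long_min = 5,
                               static_frac = 0.15, cfg = sim_config()) {
  dt <- cfg$line_time
  i0 <- interval$start; i1 <- interval$end
  if (i1 < i0) stop("invalid interval")
  sep <- abs(aligned$raw1 - aligned$raw2)
  mean_D <- (threshold$mean_D_1 + threshold$mean_D_2) / 2
  dur_frames <- i1 - i0 + 1L
  metrics <- list()
  if (dur_frames > long_min) {
    kind <- "long_coloc"
  } else {
    disp <- abs(sep[i1] - sep[i0])
    metrics$separation_displacement <- disp
    # local relative D over the interval (entry/exit included when too short
    # for interior increments), recorded for reporting
    j0 <- if (dur_frames >= 3L) i0 else max(1L, i0 - 1L)
    j1 <- if (dur_frames >= 3L) i1 else min(length(sep), i1 + 1L)
    ds_all <- diff(sep[j0:j1]); ds_all <- ds_all[!is.na(ds_all)]
    metrics$local_D_rel <- if (length(ds_all))
      mean(ds_all^2) / (2 * dt) else NA_real_
    if (is.finite(disp) && disp > threshold$d_threshold) {
      kind <- "long_coloc"
    } else {
      kind <- "short_coloc"
      if (dur_frames >= 4L) {
        dsi <- abs(diff(sep[(i0 + 1L):(i1 - 1L)]))
        dsi <- dsi[!is.na(dsi)]
        c1 <- static_frac * sqrt(2 * max(mean_D, 1e-12) * dt)
        metrics$median_interior_step <- if (length(dsi))
          stats::median(dsi) else NA_real_
        if (length(dsi) && stats::median(dsi) < c1) kind <- "long_coloc"
      }
    }
  }
  structure(list(kind = kind,
                 t_start = interval$t_start, t_end = interval$t_end,
                 duration = dur_frames * dt,
                 mean_separation = mean(sep[i0:i1], na.rm = TRUE),
                 n_frames = dur_frames,
                 metrics = metrics),
            class = "encounter_event")
}

#' Detect bypass events among colocalized intervals
#'
#' An interval is a bypass when the sign of `x1 - x2`, averaged over `flank`
#' smoothed frames immediately before versus after the interval, flips, and
#' both tracks persist for at least `flank` frames on each side. Intervals
#' with insufficient flanking data are not classifiable as bypass.
#'
#' @param intervals Output of [detect_colocalized_frames()].
#' @param aligned Its `aligned` attribute (taken automatically when
#'   `intervals` is passed with the attribute present).
#' @param flank Flanking frames (default 5).
#' @return Logical vector, one per interval.
#' @export
detect_bypass <- function(intervals, aligned = attr(intervals, "aligned"),
                          flank = 5L) {
  if (is.null(aligned)) stop("aligned positions required")
  diffxy <- aligned$x1 - aligned$x2
  n <- length(diffxy)
  vapply(seq_len(nrow(intervals)), function(i) {
    i0 <- intervals$start[i]; i1 <- intervals$end[i]
    pre <- seq(max(1L, i0 - flank), i0 - 1L)
    post <- seq(i1 + 1L, min(n, i1 + flank))
    if (i0 - flank < 1L || i1 + flank > n) return(FALSE)
    pre_v <- diffxy[pre]; post_v <- diffxy[post]
    if (sum(!is.na(pre_v)) < flank || sum(!is.na(post_v)) < flank) return(FALSE)
    s_pre <- sign(mean(pre_v, na.rm = TRUE))
    s_post <- sign(mean(post_v, na.rm = TRUE))
    s_pre != 0 && s_post != 0 && s_pre != s_post
  }, logical(1))
}

#' Detect and classify all encounters between two tracks
#'
#' Runs [detect_colocalized_frames()], applies bypass precedence, and
#' classifies the remaining intervals as short or long colocalizations.
#'
#' @inheritParams detect_colocalized_frames
#' @param long_min Long-colocalization duration threshold, frames.
#' @param flank Bypass flanking frames.
#' @return Data.frame with one row per event: `kind`, `t_start`, `t_end`,
#'   `duration`, `n_frames`, `mean_separation`.
#' @export
classify_encounters <- function(track1, track2, threshold, smooth_span = 5,
                                long_min = 5, flank = 5L, cfg = sim_config()) {
  intervals <- detect_colocalized_frames(track1, track2, threshold,
                                         smooth_span, cfg)
  aligned <- attr(intervals, "aligned")
  if (nrow(intervals) == 0L)
    return(data.frame(kind = character(0), t_start = numeric(0),
                      t_end = numeric(0), duration = numeric(0),
                      n_frames = integer(0), mean_separation = numeric(0)))
  byp <- detect_bypass(intervals, aligned, flank)
  rows <- lapply(seq_len(nrow(intervals)), function(i) {
    if (byp[i]) {
      sep <- abs(aligned$x1 - aligned$x2)
      data.frame(kind = "bypass",
                 t_start = intervals$t_start[i], t_end = intervals$t_end[i],
                 duration = intervals$n_frames[i] * cfg$line_time,
                 n_frames = intervals$n_frames[i],
                 mean_separation = mean(sep[intervals$start[i]:intervals$end[i]],
                                        na.rm = TRUE),
                 stringsAsFactors = FALSE)
    } else {
      ev <- classify_encounter(intervals[i, ], aligned, threshold,
                               long_min = long_min, cfg = cfg)
      data.frame(kind = ev$kind, t_start = ev$t_start, t_end = ev$t_end,
                 duration = ev$duration, n_frames = intervals$n_frames[i],
                 mean_separation = ev$mean_separation, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Build a nucleosome position map from pulsed-excitation tracks
#'
#' Nucleosome positions are extended piecewise-constant across dark pulses and
#' after photobleaching using the last visible fluorescence signal (back-filled
#' before the first observation). Signals are excluded as unstable when their
#' positional SD while observed exceeds `sd_bound`, and stable signals linked
#' to an excluded signal are excluded too (exclusion propagates through
#' links).
#'
#' @param nuc_tracks List of green-channel `kymo_track`s with observed masks
#'   reflecting the pulsing.
#' @param cfg A [sim_config()].
#' @param sd_bound Stability bound on positional SD while observed, um;
#'   default twice the 0.072 um localization precision.
#' @param links Optional list of length-2 character vectors of linked track
#'   ids.
#' @param n_frames_total Length of the map grid, frames; default the span of
#'   the tracks.
#' @return Object of class `nucleosome_map`: list with `positions` (matrix,
#'   frames x nucleosomes, um), `times`, `stable`, `excluded`.
#' @export
build_nucleosome_map <- function(nuc_tracks, cfg = sim_config(),
                                 sd_bound = 2 * 0.072, links = list(),
                                 n_frames_total = NULL) {
  if (length(nuc_tracks) == 0L) {
    warning("no nucleosome tracks; empty map")
    return(structure(list(positions = matrix(numeric(0), 0, 0),
                          times = numeric(0), stable = logical(0),
                          excluded = character(0)),
                     class = "nucleosome_map"))
  }
  dt <- cfg$line_time
  t0 <- min(vapply(nuc_tracks, function(tr) tr$times[1L], numeric(1)))
  t1 <- max(vapply(nuc_tracks, function(tr) tr$times[n_frames(tr)], numeric(1)))
  n <- if (is.null(n_frames_total))
    as.integer(round((t1 - t0) / dt)) + 1L else as.integer(n_frames_total)
  ids <- vapply(nuc_tracks, function(tr) tr$track_id, character(1))
  sds <- vapply(nuc_tracks, function(tr)
    stats::sd(tr$positions[tr$observed]), numeric(1))
  stable <- is.na(sds) | sds <= sd_bound   # single-point signals count stable
  names(stable) <- ids
  # propagate exclusion through links
  repeat {
    changed <- FALSE
    for (lk in links) {
      lk <- intersect(lk, names(stable))
      if (length(lk) >= 2L && any(!stable[lk]) && any(stable[lk])) {
        stable[lk] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  keep <- which(stable)
  pos <- matrix(NA_real_, nrow = n, ncol = length(keep),
                dimnames = list(NULL, ids[keep]))
  for (j in seq_along(keep)) {
    tr <- nuc_tracks[[keep[j]]]
    idx <- as.integer(round((tr$times - t0) / dt)) + 1L
    obs <- tr$observed
    v <- rep(NA_real_, n)
    v[idx[obs]] <- tr$positions[obs]
    # last-observation carried forward, then back-fill the head
    filled <- v
    last <- NA_real_
    for (i in seq_len(n)) {
      if (!is.na(filled[i])) last <- filled[i] else filled[i] <- last
    }
    first_obs <- which(!is.na(v))[1L]
    if (!is.na(first_obs) && first_obs > 1L)
      filled[seq_len(first_obs - 1L)] <- v[first_obs]
    pos[, j] <- filled
  }
  if (length(keep) == 0L) warning("zero stable nucleosomes; empty map")
  structure(list(positions = pos, times = t0 + (seq_len(n) - 1L) * dt,
                 stable = stable, excluded = ids[!stable]),
            class = "nucleosome_map")
}

#' Remodeler-nucleosome colocalization events
#'
#' Maximal runs of frames in which the remodeler lies within `radius` of a
#' mapped nucleosome position, tagged with the nucleosome id (nearest
#' nucleosome wins when several are within the radius).
#'
#' @param rem_track Remodeler `kymo_track`.
#' @param map A [build_nucleosome_map()].
#' @param radius Colocalization radius, um; default 500 bp converted via
#'   `um_per_bp`.
#' @param cfg A [sim_config()].
#' @return Data.frame with `nucleosome`, `t_start`, `t_end`, `duration`,
#'   `n_frames`.
#' @export
remodeler_nucleosome_coloc <- function(rem_track, map, cfg = sim_config(),
                                       radius = bp_to_um(500, cfg)) {
  empty <- data.frame(nucleosome = character(0), t_start = numeric(0),
                      t_end = numeric(0), duration = numeric(0),
                      n_frames = integer(0))
  if (ncol(map$positions) == 0L) return(empty)
  dt <- cfg$line_time
  idx <- as.integer(round((rem_track$times - map$times[1L]) / dt)) + 1L
  inmap <- idx >= 1L & idx <= length(map$times) & rem_track$observed
  if (!any(inmap)) return(empty)
  x <- rem_track$positions
  nearest <- rep(NA_integer_, length(x))
  dist <- rep(NA_real_, length(x))
  for (i in which(inmap)) {
    dd <- abs(map$positions[idx[i], ] - x[i])
    if (all(is.na(dd))) next
    nearest[i] <- which.min(dd)
    dist[i] <- min(dd, na.rm = TRUE)
  }
  hit <- !is.na(dist) & dist <= radius
  key <- ifelse(hit, nearest, 0L)
  r <- rle(key)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0L & !is.na(r$values)
  if (!any(keep)) return(empty)
  data.frame(nucleosome = colnames(map$positions)[r$values[keep]],
             t_start = rem_track$times[starts[keep]],
             t_end = rem_track$times[ends[keep]],
             duration = r$lengths[keep] * dt,
             n_frames = r$lengths[keep],
             stringsAsFactors = FALSE)
}
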