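#' Mean squared displacement of a track
#'
#' `msd[k]` is the average, over all observed frame pairs separated by `k`
#' frames, of the squared displacement. Gap (unobserved) frames contribute no
#' pairs.
#'
#' @param track A [new_track()] with at least 2 observed frames.
#' @param max_lag Maximum lag in frames; truncated (with a warning) to the
#'   track length minus one.
#' @param cfg A [sim_config()] supplying `line_time`.
#' @return A data.frame of class `msd_curve` with columns `lag_frames`,
#'   `lag_s`, `msd` (um^2) and `n_pairs`.
#' @export
compute_msd <- function(track, max_lag, cfg = sim_config()) {
  if (sum(track$observed) < 2L) stop("need at least 2 observed frames")
  d <- dense_positions(track, cfg$line_time)
  x <- d$x
  n <- length(x)
  if (max_lag >= n) {
    warning("max_lag >= track length; truncating to ", n - 1L)
    max_lag <- n - 1L
  }
  lags <- seq_len(max_lag)
  msd <- numeric(max_lag)
  npairs <- integer(max_lag)
  for (k in lags) {
    dk <- (x[(1L + k):n] - x[1L:(n - k)])^2
    npairs[k] <- sum(!is.na(dk))
    msd[k] <- if (npairs[k] > 0) mean(dk, na.rm = TRUE) else NA_real_
  }
  structure(data.frame(lag_frames = lags, lag_s = lags * cfg$line_time,
                       msd = msd, n_pairs = npairs),
            class = c("msd_curve", "data.frame"))
}

#' Rolling-window diffusion coefficient series
#'
#' Sub-trajectories of `window` frames are taken from the beginning to the end
#' of the track (stride one frame). For each window the MSD over the first
#' `fit_points` lags is fit by ordinary least squares (with intercept), and
#' `D = slope / (2 d)`. Negative fitted slopes are floored at `D = 0` so every
#' window is classified. Windows in which any of the first `fit_points` lags
#' has no observed pair are returned as `NA` (unclassified).
#'
#' @param track A [new_track()] with length >= `window`.
#' @param cfg A [sim_config()].
#' @param window Window size, frames (default 20).
#' @param fit_points Number of MSD lags used in the fit (default 5).
#' @param dims Dimensionality `d` (default 1, motion along the tether).
#' @return Data.frame with `window` (start frame, 1-based), `center` (frame),
#'   `time_s` (window center time) and `D` (um^2/s).
#' @export
rolling_window_D <- function(track, cfg = sim_config(), window = 20L,
                             fit_points = 5L, dims = 1L) {
  if (window < fit_points + 1L)
    stop("window must be at least fit_points + 1")
  dt <- cfg$line_time
  d <- dense_positions(track, dt)
  x <- d$x
  n <- length(x)
  if (n < window) stop("track shorter than one window")
  nw <- n - window + 1L
  msd <- matrix(NA_real_, nrow = nw, ncol = fit_points)
  cnt <- matrix(0L, nrow = nw, ncol = fit_points)
  for (k in seq_len(fit_points)) {
    dk <- (x[(1L + k):n] - x[1L:(n - k)])^2
    ok <- !is.na(dk)
    v <- ifelse(ok, dk, 0)
    cs <- cumsum(c(0, v))
    cc <- cumsum(c(0L, ok))
    m <- window - k            # pairs of lag k inside a window
    j <- seq_len(nw)
    cnt[, k] <- cc[j + m] - cc[j]
    s <- cs[j + m] - cs[j]
    msd[, k] <- ifelse(cnt[, k] > 0, s / cnt[, k], NA_real_)
  }
  # OLS slope over (lag_s, msd) with intercept; fixed abscissae
  lag_s <- seq_len(fit_points) * dt
  w <- (lag_s - mean(lag_s)) / sum((lag_s - mean(lag_s))^2)
  slope <- as.numeric(msd %*% w)
  slope[apply(cnt == 0L, 1L, any)] <- NA_real_
  D <- pmax(slope, 0) / (2 * dims)
  start <- seq_len(nw)
  data.frame(window = start,
             center = start + (window - 1) / 2,
             time_s = d$t0 + (start - 1 + (window - 1) / 2) * dt,
             D = D)
}

#' Classify window diffusion coefficients into three states
#'
#' `D < thresholds[1]` is non-diffusive (the immobile-control band),
#' `thresholds[1] <= D < thresholds[2]` is low-diffusive, and
#' `D >= thresholds[2]` is high-diffusive (the boundary value is assigned
#' upward). Defaults 0.01 and 0.04 um^2/s.
#'
#' @param D Numeric vector of window diffusion coefficients (um^2/s).
#' @param thresholds Length-2 increasing numeric vector.
#' @return Factor with levels `non`, `low`, `high` (`NA` preserved).
#' @export
classify_windows <- function(D, thresholds = c(0.01, 0.04)) {
  if (length(D) == 0L) stop("empty D series")
  stopifnot(length(thresholds) == 2L, thresholds[1] < thresholds[2])
  lab <- ifelse(is.na(D), NA_character_,
                ifelse(D < thresholds[1], "non",
                       ifelse(D < thresholds[2], "low", "high")))
  factor(lab, levels = c("non", "low", "high"))
}

#' Moving-average smoothing of track positions
#'
#' Centered moving average with shrinking (odd-sized) windows at the ends,
#' applied to the observed positions in sequence; the observed mask is
#' preserved.
#'
#' @param track A `kymo_track`.
#' @param span Odd window size, frames (default 5); `span = 1` is the
#'   identity.
#' @return A smoothed `kymo_track`.
#' @export
smooth_positions <- function(track, span = 5L) {
  span <- as.integer(span)
  if (span < 1L || span %% 2L == 0L) stop("span must be odd and >= 1")
  if (span == 1L) return(track)
  x <- track$positions[track$observed]
  y <- moving_average(x, span)
  out <- track
  out$positions[track$observed] <- y
  out
}

moving_average <- function(x, span) {
  n <- length(x)
  if (n == 0L) return(x)
  half <- (span - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  y <- numeric(n)
  for (i in seq_len(n)) {
    h <- min(half, i - 1L, n - i)
    y[i] <- (cs[i + h + 1L] - cs[i - h]) / (2L * h + 1L)
  }
  y
}

#' Segment a state-label sequence into filtered runs
#'
#' Maximal runs of equal labels form segments; runs shorter than `min_run`
#' windows are treated as spurious detections and absorbed into the flanking
#' segment with the longer duration (tie: the earlier segment). If every run
#' is shorter than `min_run` the whole sequence collapses to a single segment
#' of the modal label, with a warning.
#'
#' @param labels Factor/character vector of per-window states (no `NA`).
#' @param min_run Minimum run length in windows (default 10).
#' @param line_time Seconds per window step, for durations.
#' @return Data.frame of class `state_segments` with columns `state`,
#'   `start`, `end`, `n_windows`, `duration_s`; attributes `fractions` (named,
#'   summing to 1) and `state_durations` (per-state total seconds).
#' @export
segment_states <- function(labels, min_run = 10L, line_time = 0.0424) {
  labels <- as.character(labels)
  if (length(labels) == 0L) stop("labels must be non-empty")
  if (anyNA(labels)) stop("labels must not contain NA (filter unclassified windows first)")
  r <- rle(labels)
  if (all(r$lengths < min_run) && length(r$lengths) > 1L) {
    warning("all runs shorter than min_run; collapsing to modal label")
    tab <- tapply(r$lengths, r$values, sum)
    modal <- names(tab)[which.max(tab)]
    r <- list(lengths = length(labels), values = modal)
  } else {
    repeat {
      short <- which(r$lengths < min_run)
      if (length(short) == 0L || length(r$lengths) == 1L) break
      i <- short[which.min(r$lengths[short])]
      if (i == 1L) {
        r$values[i] <- r$values[i + 1L]
      } else if (i == length(r$lengths)) {
        r$values[i] <- r$values[i - 1L]
      } else {
        left <- r$lengths[i - 1L]; right <- r$lengths[i + 1L]
        r$values[i] <- if (right > left) r$values[i + 1L] else r$values[i - 1L]
      }
      merged <- rle(inverse.rle(r))
      r <- list(lengths = merged$lengths, values = merged$values)
    }
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- data.frame(state = r$values, start = starts, end = ends,
                    n_windows = r$lengths,
                    duration_s = r$lengths * line_time,
                    stringsAsFactors = FALSE)
  tot <- sum(seg$n_windows)
  dur <- c(tapply(seg$duration_s, seg$state, sum))
  frac <- c(tapply(seg$n_windows, seg$state, sum)) / tot
  attr(seg, "fractions") <- frac
  attr(seg, "state_durations") <- dur
  class(seg) <- c("state_segments", "data.frame")
  seg
}

#' Localization precision from a Gaussian fit
#'
#' The standard Gaussian-fit relation `sigma0 = s / sqrt(N)` where `s` is the
#' standard deviation of the fitted point-spread Gaussian and `N` the photon
#' count.
#'
#' @param s Gaussian fit SD, um (> 0).
#' @param N Photon count (>= 1).
#' @return List with `s`, `N`, `sigma0` (um), class `precision_estimate`.
#' @export
localization_precision <- function(s, N) {
  stopifnot(is.numeric(s), s > 0)
  if (any(N < 1)) stop("N must be >= 1")
  structure(list(s = s, N = N, sigma0 = s / sqrt(N)),
            class = "precision_estimate")
}

#' Full per-track diffusion profile
#'
#' Runs the rolling-window pipeline: raw-position window `D` values for
#' reporting, then (following the two-pass classification procedure) a
#' moving-average smoothed copy of the track is windowed, classified by the
#' two thresholds, and runs shorter than `min_run` windows are filtered, giving
#' state segments, durations, and per-state time fractions.
#'
#' @param track A `kymo_track`.
#' @param cfg A [sim_config()].
#' @param window,fit_points,dims See [rolling_window_D()].
#' @param thresholds See [classify_windows()].
#' @param min_run See [segment_states()].
#' @param smooth_span Moving-average span used before classification
#'   (default 5); `1` disables smoothing.
#' @return Object of class `diffusion_profile`: list with `windows` (data.frame
#'   of window, time_s, D raw, D_smoothed, state), `segments`, `fractions`,
#'   `state_durations`, `mean_D` and the parameters used.
#' @export
diffusion_profile <- function(track, cfg = sim_config(), window = 20L,
                              fit_points = 5L, dims = 1L,
                              thresholds = c(0.01, 0.04), min_run = 10L,
                              smooth_span = 5L) {
  raw <- rolling_window_D(track, cfg, window, fit_points, dims)
  sm <- if (smooth_span > 1L) smooth_positions(track, smooth_span) else track
  smw <- rolling_window_D(sm, cfg, window, fit_points, dims)
  state <- classify_windows(smw$D, thresholds)
  ok <- !is.na(state)
  segments <- if (any(ok))
    segment_states(state[ok], min_run, cfg$line_time) else NULL
  structure(list(
    windows = data.frame(window = raw$window, time_s = raw$time_s,
                         D = raw$D, D_smoothed = smw$D, state = state),
    segments = segments,
    fractions = if (!is.null(segments)) attr(segments, "fractions") else NULL,
    state_durations = if (!is.null(segments))
      attr(segments, "state_durations") else NULL,
    mean_D = mean(raw$D, na.rm = TRUE),
    params = list(window = window, fit_points = fit_points, dims = dims,
                  thresholds = thresholds, min_run = min_run,
                  smooth_span = smooth_span)
  ), class = "diffusion_profile")
}

#' @export
print.diffusion_profile <- function(x, ...) {
  cat(sprintf("diffusion_profile: %d windows, mean D = %.4g um^2/s\n",
              nrow(x$windows), x$mean_D))
  if (!is.null(x$fractions)) {
    cat("  state fractions:",
        paste(sprintf("%s %.2f", names(x$fractions), x$fractions),
              collapse = ", "), "\n")
  }
  invisible(x)
}
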