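#' A single-particle track
#'
#' One particle's time-ordered positions along the DNA tether, as tracked from
#' a kymograph. Frames are assumed to lie on the regular line-time grid of the
#' instrument; unobserved frames (dark excitation pulses, linked gaps) are kept
#' in place with `observed = FALSE` so that lag arithmetic stays exact.
#'
#' @param track_id Identifier (coerced to character).
#' @param channel `"red"` or `"green"`.
#' @param times Numeric, seconds, strictly increasing.
#' @param positions Numeric, um along the tether; must be finite where
#'   observed (may be `NA` on unobserved frames).
#' @param observed Logical per-frame mask (recycled if length 1).
#' @param source Optional metadata list (file, kymograph id, condition...).
#'
#' @return Object of class `kymo_track`.
#' @export
new_track <- function(track_id, channel = c("red", "green"),
                      times, positions, observed = TRUE, source = list()) {
  channel <- match.arg(channel)
  times <- as.numeric(times)
  positions <- as.numeric(positions)
  if (length(observed) == 1L) observed <- rep(observed, length(times))
  observed <- as.logical(observed)
  if (length(times) != length(positions) || length(times) != length(observed))
    stop("times, positions and observed must have equal length")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  if (any(observed & !is.finite(positions)))
    stop("positions must be finite on observed frames")
  structure(list(
    track_id = as.character(track_id),
    channel = channel,
    times = times,
    positions = positions,
    observed = observed,
    source = source
  ), class = "kymo_track")
}

#' @export
print.kymo_track <- function(x, ...) {
  cat(sprintf("kymo_track %s [%s]: %d frames (%d observed), t = %.3f..%.3f s\n",
              x$track_id, x$channel, length(x$times), sum(x$observed),
              if (length(x$times)) min(x$times) else NA,
              if (length(x$times)) max(x$times) else NA))
  invisible(x)
}

#' @export
as.data.frame.kymo_track <- function(x, ...) {
  data.frame(track_id = rep(x$track_id, length(x$times)),
             channel = rep(x$channel, length(x$times)),
             time_s = x$times,
             position_um = x$positions,
             observed = x$observed,
             stringsAsFactors = FALSE)
}

n_frames <- function(track) length(track$times)

track_duration <- function(track) {
  if (n_frames(track) < 2L) return(0)
  diff(range(track$times))
}

# Frame index of each sample on the regular line-time grid, anchored at the
# first frame.
frame_index <- function(track, line_time) {
  as.integer(round((track$times - track$times[1L]) / line_time))
}

# Positions on a dense frame grid, NA where unobserved or absent.
dense_positions <- function(track, line_time) {
  idx <- frame_index(track, line_time)
  n <- idx[length(idx)] + 1L
  x <- rep(NA_real_, n)
  keep <- track$observed
  x[idx[keep] + 1L] <- track$positions[keep]
  list(x = x, t0 = track$times[1L], n = n)
}
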