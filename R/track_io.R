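#' Force-clamp distance trace
#'
#' @param times Seconds, strictly increasing.
#' @param distance_nm Extension/distance in nm (give either this or
#'   `distance_um`).
#' @param distance_um Distance in um.
#' @param force_pN Optional force channel or scalar, pN.
#' @param clamp_window Optional `c(t_start, t_end)` of the force clamp.
#' @return Object of class `force_trace`.
#' @export
force_trace <- function(times, distance_nm = NULL, distance_um = NULL,
                        force_pN = NULL, clamp_window = NULL) {
  times <- as.numeric(times)
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  if (is.null(distance_nm) && is.null(distance_um))
    stop("give distance_nm or distance_um")
  if (is.null(distance_nm)) distance_nm <- as.numeric(distance_um) * 1000
  stopifnot(length(distance_nm) == length(times))
  structure(list(times = times, distance_nm = as.numeric(distance_nm),
                 force_pN = force_pN, clamp_window = clamp_window),
            class = "force_trace")
}

#' @export
print.force_trace <- function(x, ...) {
  cat(sprintf("force_trace: %d samples, t = %.3f..%.3f s, dist %.1f..%.1f nm\n",
              length(x$times), min(x$times), max(x$times),
              min(x$distance_nm), max(x$distance_nm)))
  invisible(x)
}

# column-name maps per CSV dialect; the dryad map follows the deposited
# tracker-export naming and is overridable via col_map.
.dialect_maps <- list(
  native = c(track_id = "track_id", channel = "channel", time_s = "time_s",
             position_um = "position_um", observed = "observed"),
  dryad = c(track_id = "track index", channel = "channel",
            time_s = "time (seconds)", position_um = "position (um)",
            observed = NA)
)

#' Read single-particle tracks from CSV
#'
#' Reads a track table (the shape exported by kymograph trackers) and returns
#' one [new_track()] per `(track_id, channel)` pair. Times/positions are
#' normalized to s/um; frames missing from the file relative to the regular
#' `line_time` grid are re-inserted as unobserved gap frames.
#'
#' @param path CSV file.
#' @param dialect `"native"` (this package's schema) or `"dryad"` (deposited
#'   tracker-export column names).
#' @param cfg A [sim_config()] supplying `line_time` for gap inference.
#' @param col_map Optional named character vector overriding the dialect's
#'   column mapping (names: track_id, channel, time_s, position_um, observed).
#' @param channel Channel to assume when the file has no channel column.
#' @return List of `kymo_track`.
#' @export
read_tracks <- function(path, dialect = c("native", "dryad"),
                        cfg = sim_config(), col_map = NULL,
                        channel = "red") {
  dialect <- match.arg(dialect)
  map <- .dialect_maps[[dialect]]
  if (!is.null(col_map)) map[names(col_map)] <- col_map
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) return(list())
  need <- c("track_id", "time_s", "position_um")
  for (f in need) {
    if (is.na(map[[f]]) || !map[[f]] %in% names(df))
      stop("column for '", f, "' (", map[[f]], ") not found in ", path)
  }
  ch <- if (!is.na(map[["channel"]]) && map[["channel"]] %in% names(df))
    df[[map[["channel"]]]] else rep(channel, nrow(df))
  obs <- if (!is.na(map[["observed"]]) && map[["observed"]] %in% names(df))
    as.logical(df[[map[["observed"]]]]) else rep(TRUE, nrow(df))
  ids <- as.character(df[[map[["track_id"]]]])
  tt <- as.numeric(df[[map[["time_s"]]]])
  xx <- as.numeric(df[[map[["position_um"]]]])
  out <- list()
  for (key in unique(paste(ids, ch, sep = "\r"))) {
    sel <- paste(ids, ch, sep = "\r") == key
    t_i <- tt[sel]; x_i <- xx[sel]; o_i <- obs[sel]
    if (any(diff(t_i) <= 0)) {
      bad <- which(diff(t_i) <= 0)[1L] + 1L
      stop("non-monotone time in track ", ids[sel][1L], " at row ",
           which(sel)[bad])
    }
    tr <- new_track(ids[sel][1L], ch[sel][1L], t_i, x_i, o_i,
                    source = list(file = path, dialect = dialect))
    out[[length(out) + 1L]] <- regularize_track(tr, cfg$line_time)
  }
  out
}

# Re-insert unobserved frames where the file skipped grid frames.
regularize_track <- function(track, line_time) {
  n <- n_frames(track)
  if (n < 2L) return(track)
  idx <- frame_index(track, line_time)
  if (any(duplicated(idx))) stop("duplicate frames in track ", track$track_id)
  m <- idx[n] + 1L
  if (m == n) return(track)
  times <- track$times[1L] + (seq_len(m) - 1L) * line_time
  positions <- rep(NA_real_, m)
  observed <- rep(FALSE, m)
  positions[idx + 1L] <- track$positions
  observed[idx + 1L] <- track$observed
  new_track(track$track_id, track$channel, times, positions, observed,
            source = track$source)
}

#' Write tracks to CSV
#'
#' Writes the native schema: `track_id, channel, time_s, position_um,
#' observed`. Unobserved gap frames are written as rows with empty positions.
#'
#' @param tracks List of `kymo_track` (or a single track).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  if (inherits(tracks, "kymo_track")) tracks <- list(tracks)
  header <- c("track_id", "channel", "time_s", "position_um", "observed")
  if (length(tracks) == 0L) {
    df <- as.data.frame(stats::setNames(rep(list(character(0)), 5), header))
  } else {
    df <- do.call(rbind, lapply(tracks, as.data.frame))
  }
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Connect track fragments across short gaps
#'
#' Merges fragments of the same particle whose temporal gap is at most
#' `max_gap_frames` and whose positional jump is at most `max_jump`; the
#' spanned gap frames are inserted as unobserved. When two candidate fragments
#' fall within tolerance the one with the smallest positional discrepancy
#' wins (deterministic after a stable sort by start time).
#'
#' @param tracks List of `kymo_track` from one kymograph and one channel.
#' @param max_gap_frames Maximum gap, frames (default 8).
#' @param max_jump Maximum positional jump, um.
#' @param cfg A [sim_config()] supplying `line_time`.
#' @return List of merged `kymo_track`.
#' @export
connect_track_gaps <- function(tracks, max_gap_frames = 8, max_jump = 0.4,
                               cfg = sim_config()) {
  if (length(tracks) <= 1L) return(tracks)
  dt <- cfg$line_time
  ord <- order(vapply(tracks, function(tr) tr$times[1L], numeric(1)))
  tracks <- tracks[ord]
  merged <- list()
  open <- tracks[[1L]]
  rest <- tracks[-1L]
  while (TRUE) {
    if (length(rest) == 0L) { merged[[length(merged) + 1L]] <- open; break }
    t_end <- open$times[n_frames(open)]
    x_end <- open$positions[max(which(open$observed))]
    gaps <- vapply(rest, function(tr) (tr$times[1L] - t_end) / dt, numeric(1))
    jumps <- vapply(rest, function(tr)
      abs(tr$positions[which(tr$observed)[1L]] - x_end), numeric(1))
    cand <- which(gaps > 0 & gaps <= max_gap_frames + 0.5 & jumps <= max_jump)
    if (length(cand) == 0L) {
      merged[[length(merged) + 1L]] <- open
      open <- rest[[1L]]
      rest <- rest[-1L]
    } else {
      pick <- cand[which.min(jumps[cand])]
      if (length(cand) > 1L)
        message("ambiguous merge for track ", open$track_id,
                ": nearest-in-position fragment chosen")
      nxt <- rest[[pick]]
      rest <- rest[-pick]
      gap_n <- as.integer(round((nxt$times[1L] - t_end) / dt)) - 1L
      gap_times <- if (gap_n > 0) t_end + dt * seq_len(gap_n) else numeric(0)
      open <- new_track(open$track_id, open$channel,
                        c(open$times, gap_times, nxt$times),
                        c(open$positions, rep(NA_real_, gap_n), nxt$positions),
                        c(open$observed, rep(FALSE, gap_n), nxt$observed),
                        source = open$source)
    }
  }
  merged
}

#' Read a force trace from CSV
#'
#' Expects columns `time_s` and `distance_um` or `distance_nm`, with optional
#' `force_pN`.
#'
#' @param path CSV file.
#' @return A [force_trace()].
#' @export
read_force_trace <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"time_s" %in% names(df)) stop("missing time_s column")
  if ("distance_nm" %in% names(df)) {
    force_trace(df$time_s, distance_nm = df$distance_nm,
                force_pN = df$force_pN)
  } else if ("distance_um" %in% names(df)) {
    force_trace(df$time_s, distance_um = df$distance_um,
                force_pN = df$force_pN)
  } else stop("missing distance_um/distance_nm column")
}

#' Serialize ground truth to a JSON sidecar
#'
#' @param truth Ground-truth list from a generator.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}
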