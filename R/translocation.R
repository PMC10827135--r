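#' Piecewise-linear translocation segmentation
#'
#' Candidate directed-motion segments are found by penalized least-squares
#' changepoint fitting: since a translocation path is continuous in position,
#' changepoints are located by recursive continuous piecewise-linear (hinge)
#' splitting, each split accepted when it improves the residual sum of squares
#' by more than `penalty` noise variances (BIC-style, `penalty_mult * log(n)`
#' by default, with the noise variance estimated robustly from first
#' differences). Each resulting segment receives an ordinary least-squares
#' speed (slope converted to bp/s via `um_per_bp`), an R-squared and a spanned
#' distance, and the admission filters are applied: admitted segments last at
#' least `min_s` seconds, span at least `min_bp` base pairs, and have
#' R-squared of at least `min_r2`. Static (ATP-gamma-S-like or no-ATP) traces
#' processed identically yield no admitted segments.
#'
#' @param track A `kymo_track` with at least `min_s` seconds observed.
#' @param cfg A [sim_config()].
#' @param penalty Changepoint penalty on the scaled RSS improvement
#'   (`delta RSS / sigma^2`); `NULL` (auto) uses `penalty_mult * log(n)`.
#' @param penalty_mult Multiplier of the auto penalty (default 1.5, calibrated
#'   on synthetic speed-change recovery).
#' @param boundary_trim_s Seconds excluded on each side of an internal
#'   changepoint when fitting segment speeds (default 1), so that changepoint
#'   location error and the kink-selection effect do not contaminate the
#'   slopes; segment bounds and durations are reported untrimmed.
#' @param min_seg_s Minimum segment length considered by the changepoint
#'   search, s (default 2.5).
#' @param min_bp,min_s,min_r2 Admission filters (defaults 300 bp, 5 s, 0.5).
#' @param manual_breaks Optional numeric vector of segment boundary times
#'   (s), bypassing the automatic search (for manually segmented traces).
#' @return Data.frame of class `transloc_segments`: `t_start`, `t_end`,
#'   `duration_s`, `speed_bp_s` (signed), `distance_bp` (signed),
#'   `r_squared`, `admitted`, `reason` (empty when admitted).
#' @export
segment_speeds <- function(track, cfg = sim_config(), penalty = NULL,
                           penalty_mult = 1.5, min_seg_s = 2.5,
                           min_bp = 300, min_s = 5, min_r2 = 0.5,
                           boundary_trim_s = 1, manual_breaks = NULL) {
  obs <- track$observed
  t <- track$times[obs]
  y <- track$positions[obs]
  n <- length(t)
  empty <- structure(
    data.frame(t_start = numeric(0), t_end = numeric(0),
               duration_s = numeric(0), speed_bp_s = numeric(0),
               distance_bp = numeric(0), r_squared = numeric(0),
               admitted = logical(0), reason = character(0)),
    class = c("transloc_segments", "data.frame"))
  if (n < 2L || diff(range(t)) < min_s) return(empty)
  dt_med <- stats::median(diff(t))
  min_pts <- max(4L, as.integer(round(min_seg_s / dt_med)))
  if (!is.null(manual_breaks)) {
    bounds <- sort(unique(c(t[1L], manual_breaks, t[n])))
    cps <- findInterval(bounds[-c(1L, length(bounds))], t)
    starts <- c(1L, cps + 1L)
    ends <- c(cps, n)
  } else {
    sig2 <- (stats::mad(diff(y)) / sqrt(2))^2
    if (!is.finite(sig2) || sig2 <= 0) sig2 <- stats::var(diff(y)) / 2
    if (!is.finite(sig2) || sig2 <= 0) sig2 <- 1e-12
    if (is.null(penalty)) penalty <- penalty_mult * log(n)
    cps <- .hinge_split(t, y, min_pts, penalty * sig2)
    starts <- c(1L, cps + 1L)
    ends <- c(cps, n)
  }
  n_seg <- length(starts)
  rows <- lapply(seq_len(n_seg), function(i) {
    ii <- starts[i]:ends[i]
    ts <- t[ii]; ys <- y[ii]
    t_lo <- ts[1L]; t_hi <- ts[length(ts)]
    # trim around internal changepoints for the fit
    fit_lo <- if (i > 1L) t_lo + boundary_trim_s else t_lo
    fit_hi <- if (i < n_seg) t_hi - boundary_trim_s else t_hi
    use <- ts >= fit_lo & ts <= fit_hi
    if (sum(use) < 4L) use <- rep(TRUE, length(ts))
    fit <- stats::lm.fit(cbind(1, ts[use]), ys[use])
    slope <- fit$coefficients[2L]
    tss <- sum((ys[use] - mean(ys[use]))^2)
    rss <- sum(fit$residuals^2)
    r2 <- if (tss > .Machine$double.eps) 1 - rss / tss else 0
    dur <- t_hi - t_lo
    speed_bp <- slope / cfg$um_per_bp
    dist_bp <- speed_bp * dur
    reason <- ""
    if (dur < min_s) reason <- sprintf("duration<%gs", min_s)
    else if (abs(dist_bp) < min_bp) reason <- sprintf("distance<%gbp", min_bp)
    else if (r2 < min_r2) reason <- sprintf("r2<%g", min_r2)
    data.frame(t_start = ts[1L], t_end = ts[length(ts)], duration_s = dur,
               speed_bp_s = speed_bp, distance_bp = dist_bp, r_squared = r2,
               admitted = reason == "", reason = reason,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("transloc_segments", "data.frame")
  out
}

# Residual sum of squares of an OLS line on points i..j, from cumulative sums.
.make_rss <- function(t, y) {
  cx <- cumsum(c(0, t)); cy <- cumsum(c(0, y))
  cxx <- cumsum(c(0, t * t)); cxy <- cumsum(c(0, t * y))
  cyy <- cumsum(c(0, y * y))
  function(i, j) {
    m <- j - i + 1
    sx <- cx[j + 1] - cx[i]; sy <- cy[j + 1] - cy[i]
    vx <- (cxx[j + 1] - cxx[i]) - sx * sx / m
    vxy <- (cxy[j + 1] - cxy[i]) - sx * sy / m
    vy <- (cyy[j + 1] - cyy[i]) - sy * sy / m
    max(vy - if (vx > 1e-300) vxy * vxy / vx else 0, 0)
  }
}

# Recursive continuous piecewise-linear (hinge) changepoint search. A split
# of segment [lo, hi] at cp is accepted when the best continuous two-piece
# fit improves the segment's straight-line RSS by more than `penalty`
# (already scaled by the noise variance). Returns sorted changepoint indices.
.hinge_split <- function(t, y, min_pts, penalty) {
  n <- length(t)
  rss_line <- .make_rss(t, y)
  cps <- integer(0)
  recurse <- function(lo, hi) {
    m <- hi - lo + 1L
    if (m < 2L * min_pts) return()
    ts <- t[lo:hi]; ys <- y[lo:hi]
    base <- rss_line(lo, hi)
    cand <- (min_pts):(m - min_pts)
    best_rss <- Inf; best_k <- NA_integer_
    for (k in cand) {
      h <- pmax(ts - ts[k], 0)
      X <- cbind(1, ts, h)
      fit <- stats::lm.fit(X, ys)
      rss <- sum(fit$residuals^2)
      if (rss < best_rss) { best_rss <- rss; best_k <- k }
    }
    if (is.na(best_k) || base - best_rss <= penalty) return()
    k <- lo + best_k - 1L
    cps <<- c(cps, k)
    recurse(lo, k)
    recurse(k + 1L, hi)
  }
  recurse(1L, n)
  sort(cps)
}

#' Count direction changes between admitted segments
#'
#' @param segments A [segment_speeds()] result.
#' @return List with `n_changes` and `locations` (times of the boundaries at
#'   which the sign of the speed flips between consecutive admitted segments).
#' @export
detect_direction_changes <- function(segments) {
  adm <- segments[segments$admitted, , drop = FALSE]
  if (nrow(adm) < 2L) return(list(n_changes = 0L, locations = numeric(0)))
  s <- sign(adm$speed_bp_s)
  flips <- which(s[-1L] != s[-length(s)])
  list(n_changes = length(flips), locations = adm$t_start[flips + 1L])
}

#' Fragment a trace into search / engaged / translocating segments
#'
#' Labels every frame of the track as `search_1D` (diffusive, not
#' colocalized), `engaged_static` (colocalized with a nucleosome but not
#' translocating) or `translocating` (inside an admitted translocation
#' segment), with precedence translocating > engaged_static > search_1D, and
#' records the ordered transitions.
#'
#' @param track The remodeler `kymo_track`.
#' @param coloc_events Data.frame with `t_start`/`t_end` of
#'   remodeler-nucleosome colocalizations ([remodeler_nucleosome_coloc()]),
#'   or NULL.
#' @param segments [segment_speeds()] result, or NULL.
#' @return Object of class `trace_fragmentation`: data.frame `segments`
#'   (label, t_start, t_end, start, end frame), vector `labels` per frame,
#'   `transitions`.
#' @export
fragment_trace <- function(track, coloc_events = NULL, segments = NULL) {
  n <- n_frames(track)
  lab <- rep("search_1D", n)
  tt <- track$times
  if (!is.null(coloc_events) && nrow(coloc_events) > 0L) {
    for (i in seq_len(nrow(coloc_events)))
      lab[tt >= coloc_events$t_start[i] & tt <= coloc_events$t_end[i]] <-
        "engaged_static"
  }
  if (!is.null(segments) && nrow(segments) > 0L) {
    adm <- segments[segments$admitted, , drop = FALSE]
    for (i in seq_len(nrow(adm))) {
      sel <- tt >= adm$t_start[i] & tt <= adm$t_end[i]
      if (any(lab[sel] == "search_1D"))
        warning("translocation outside any colocalization; labeled translocating")
      lab[sel] <- "translocating"
    }
  }
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- data.frame(label = r$values, start = starts, end = ends,
                    t_start = tt[starts], t_end = tt[ends],
                    stringsAsFactors = FALSE)
  structure(list(segments = seg, labels = lab,
                 transitions = if (nrow(seg) > 1L)
                   paste(seg$label[-nrow(seg)], seg$label[-1L], sep = " -> ")
                 else character(0)),
            class = "trace_fragmentation")
}

#' Push/pull directionality of translocation relative to 1D approach
#'
#' The approach direction is the sign of the net smoothed displacement over
#' the final `window` observed frames of the 1D-search segment adjacent
#' (directly or across one engaged segment) to the translocating segment.
#' When only a search segment *after* the translocation exists (translocation
#' leading to 1D disengagement), the initial `window` frames of that segment
#' are used with the sign inverted. The call is `push` when translocation and
#' approach share a direction, `pull` when opposite, `undefined` when either
#' direction is unavailable.
#'
#' @param frag A [fragment_trace()] result.
#' @param segments A [segment_speeds()] result (admitted segments supply the
#'   translocation direction).
#' @param track The remodeler `kymo_track`.
#' @param window Frames used to measure the approach (default 5).
#' @param smooth_span Moving-average span applied before measuring (default 5).
#' @return Object of class `push_pull_call`: `approach_direction`,
#'   `translocation_direction`, `call`, `scenario`.
#' @export
classify_push_pull <- function(frag, segments, track, window = 5L,
                               smooth_span = 5L) {
  undef <- structure(list(approach_direction = NA_integer_,
                          translocation_direction = NA_integer_,
                          call = "undefined", scenario = NA_character_),
                     class = "push_pull_call")
  adm <- segments[segments$admitted, , drop = FALSE]
  seg <- frag$segments
  ti <- which(seg$label == "translocating")
  if (nrow(adm) == 0L || length(ti) == 0L) return(undef)
  # the dominant translocation event, and its admitted segment (max overlap)
  ti <- ti[which.max(seg$t_end[ti] - seg$t_start[ti])]
  ov <- pmin(adm$t_end, seg$t_end[ti]) - pmax(adm$t_start, seg$t_start[ti])
  tr_dir <- sign(adm$speed_bp_s[which.max(ov)])
  sm <- smooth_positions(track, smooth_span)
  x <- sm$positions
  obsw <- which(track$observed)
  net_dir <- function(frames) {
    frames <- intersect(frames, obsw)
    if (length(frames) < 2L) return(NA_integer_)
    as.integer(sign(x[frames[length(frames)]] - x[frames[1L]]))
  }
  # search before the translocation, directly or across one engaged segment
  before <- NULL
  if (ti > 1L && seg$label[ti - 1L] == "search_1D") before <- ti - 1L
  else if (ti > 2L && seg$label[ti - 1L] == "engaged_static" &&
           seg$label[ti - 2L] == "search_1D") before <- ti - 2L
  if (!is.null(before)) {
    fr <- seg$start[before]:seg$end[before]
    fr <- utils::tail(intersect(fr, obsw), window)
    ap <- net_dir(fr)
    if (!is.na(ap) && ap != 0L && tr_dir != 0) {
      scen <- if (before == ti - 1L) "search->translocation"
              else "search->engaged->translocation"
      return(structure(list(approach_direction = ap,
                            translocation_direction = as.integer(tr_dir),
                            call = if (ap == tr_dir) "push" else "pull",
                            scenario = scen),
                       class = "push_pull_call"))
    }
  }
  # search after the translocation (disengagement); sign inverted
  after <- NULL
  nseg <- nrow(seg)
  if (ti < nseg && seg$label[ti + 1L] == "search_1D") after <- ti + 1L
  else if (ti < nseg - 1L && seg$label[ti + 1L] == "engaged_static" &&
           seg$label[ti + 2L] == "search_1D") after <- ti + 2L
  if (!is.null(after)) {
    fr <- seg$start[after]:seg$end[after]
    fr <- utils::head(intersect(fr, obsw), window)
    dd <- net_dir(fr)
    if (!is.na(dd) && dd != 0L && tr_dir != 0) {
      ap <- -dd
      scen <- if (after == ti + 1L) "translocation->disengagement"
              else "translocation->engaged->disengagement"
      return(structure(list(approach_direction = as.integer(ap),
                            translocation_direction = as.integer(tr_dir),
                            call = if (ap == tr_dir) "push" else "pull",
                            scenario = scen),
                       class = "push_pull_call"))
    }
  }
  undef
}
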