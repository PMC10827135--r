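# shared fixtures, all built in code

CFG <- sim_config()

# a straight drift track: x = v * t (um/s), n frames on the line-time grid
drift_track <- function(v_um_s, n, cfg = CFG, x0 = 0) {
  tt <- (seq_len(n) - 1L) * cfg$line_time
  new_track("drift", "red", tt, x0 + v_um_s * tt)
}

static_track <- function(n, cfg = CFG, x0 = 1) {
  tt <- (seq_len(n) - 1L) * cfg$line_time
  new_track("static", "red", tt, rep(x0, n))
}

# brute-force MSD: O(n^2) pair enumeration over observed frames
msd_oracle <- function(track, max_lag, cfg = CFG) {
  idx <- round((track$times - track$times[1L]) / cfg$line_time)
  x <- track$positions
  keep <- track$observed
  idx <- idx[keep]; x <- x[keep]
  vapply(seq_len(max_lag), function(k) {
    sq <- c()
    for (i in seq_along(idx)) {
      j <- which(idx == idx[i] + k)
      if (length(j)) sq <- c(sq, (x[j] - x[i])^2)
    }
    if (length(sq)) mean(sq) else NA_real_
  }, numeric(1))
}

# brute-force rolling-window D: per-window MSD via msd_oracle + lm()
rolling_D_oracle <- function(track, cfg = CFG, window = 20L, fit_points = 5L,
                             dims = 1L) {
  idx <- round((track$times - track$times[1L]) / cfg$line_time)
  n <- max(idx) + 1L
  vapply(seq_len(n - window + 1L), function(s) {
    sel <- idx >= (s - 1L) & idx <= (s - 1L + window - 1L)
    sub <- new_track("w", track$channel, track$times[sel],
                     track$positions[sel], track$observed[sel])
    msd <- msd_oracle(sub, fit_points, cfg)
    if (anyNA(msd)) return(NA_real_)
    lag_s <- seq_len(fit_points) * cfg$line_time
    max(unname(stats::coef(stats::lm(msd ~ lag_s))[2L]), 0) / (2 * dims)
  }, numeric(1))
}
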