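#' Simulation and instrument configuration
#'
#' Physical constants of the imaging setup and the synthetic-data generator.
#' All positions are carried internally in micrometers; base pairs enter and
#' leave only through the single `um_per_bp` conversion.
#'
#' @param line_time Seconds per kymograph line (frame). Default 0.0424 s, the
#'   confocal line time of the instrument setup this package targets.
#' @param pixel_to_um Micrometers per kymograph pixel. Default 0.05 um, a
#'   standard confocal line-scan pixel setting.
#' @param um_per_bp Micrometers per base pair of DNA under ~5 pN tension.
#'   Default 0.072/225 (72 nm corresponds to 225 bp), approximately 3.2e-4.
#' @param tether_length_bp Length of the DNA tether in base pairs. Default is
#'   the length of bacteriophage lambda DNA (48502 bp).
#' @param noise_sigma Gaussian localization noise per frame, um. Default 0.
#' @param bleach_rate Photobleaching rate, 1/s. 0 disables bleaching.
#' @param pulse_pattern Logical vector giving the excitation schedule
#'   (TRUE = illuminated/observed frame); recycled over the trace. `NULL`
#'   means continuous excitation.
#' @param seed Optional integer seed recorded in the config and used by the
#'   generators when no explicit seed is passed.
#'
#' @return An object of class `sim_config` (a list).
#' @export
#' @examples
#' cfg <- sim_config()
#' bp_to_um(225, cfg)   # 0.072
sim_config <- function(line_time = 0.0424,
                       pixel_to_um = 0.05,
                       um_per_bp = 0.072 / 225,
                       tether_length_bp = 48502,
                       noise_sigma = 0,
                       bleach_rate = 0,
                       pulse_pattern = NULL,
                       seed = NULL) {
  stopifnot(is.numeric(line_time), length(line_time) == 1L, line_time > 0)
  stopifnot(is.numeric(um_per_bp), um_per_bp > 0)
  stopifnot(is.numeric(pixel_to_um), pixel_to_um > 0)
  stopifnot(is.numeric(tether_length_bp), tether_length_bp > 0)
  stopifnot(is.numeric(noise_sigma), noise_sigma >= 0)
  stopifnot(is.numeric(bleach_rate), bleach_rate >= 0)
  if (!is.null(pulse_pattern)) {
    stopifnot(is.logical(pulse_pattern), length(pulse_pattern) >= 1L,
              !anyNA(pulse_pattern))
  }
  structure(list(
    line_time = line_time,
    pixel_to_um = pixel_to_um,
    um_per_bp = um_per_bp,
    tether_length_bp = tether_length_bp,
    noise_sigma = noise_sigma,
    bleach_rate = bleach_rate,
    pulse_pattern = pulse_pattern,
    seed = seed
  ), class = "sim_config")
}

#' Convert base pairs to micrometers (and back)
#'
#' @param bp,um Numeric vectors.
#' @param cfg A [sim_config()] supplying `um_per_bp`.
#' @return Numeric vector.
#' @export
bp_to_um <- function(bp, cfg = sim_config()) bp * cfg$um_per_bp

#' @rdname bp_to_um
#' @export
um_to_bp <- function(um, cfg = sim_config()) um / cfg$um_per_bp

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:\n")
  cat(sprintf("  line_time     %.4g s\n", x$line_time))
  cat(sprintf("  pixel_to_um   %.4g um\n", x$pixel_to_um))
  cat(sprintf("  um_per_bp     %.4g um\n", x$um_per_bp))
  cat(sprintf("  tether        %d bp\n", as.integer(x$tether_length_bp)))
  cat(sprintf("  noise_sigma   %.4g um\n", x$noise_sigma))
  cat(sprintf("  bleach_rate   %.4g /s\n", x$bleach_rate))
  cat(sprintf("  pulses        %s\n",
              if (is.null(x$pulse_pattern)) "continuous" else
                paste0(sum(x$pulse_pattern), "/", length(x$pulse_pattern),
                       " frames on")))
  invisible(x)
}

# Deterministic per-stage seed fan-out so module order does not perturb
# randomness. Kept below 2^31 (R integers are 32-bit).
derive_seed <- function(seed, label) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
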