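#' Specification of true theta phase offsets for a synthetic LFP session
#'
#' @param offsets Per-channel true phase offset (radians) relative to the
#'   first channel. Values outside `(-pi, pi]` are wrapped with a warning.
#' @param freq Theta frequency in Hz (default 8, inside the 4-10 Hz pass
#'   band).
#' @param snr Signal-to-noise ratio, RMS(theta) / RMS(noise); `Inf` disables
#'   noise.
#' @param duration Session length in seconds.
#' @return An object of class `phase_offset_spec`.
#' @export
phase_offset_spec <- function(offsets, freq = 8, snr = 10, duration = 600) {
  stopifnot(length(offsets) >= 1, freq > 0, snr > 0, duration > 0)
  if (any(offsets <= -pi | offsets > pi)) {
    warning("offsets outside (-pi, pi]; wrapped")
    offsets <- wrap_angle(offsets)
  }
  structure(list(offsets = offsets, freq = freq, snr = snr,
                 duration = duration), class = "phase_offset_spec")
}

#' Alternating run/still schedule for a behavior session
#'
#' @param run_s,still_s Block durations in seconds (session starts with a
#'   run block).
#' @param run_speed,still_speed Body speed (cm/s) in each state; the default
#'   still speed sits below and the run speed above the 10 cm/s running
#'   criterion.
#' @return Data frame with columns `state` and `duration`, recycled over the
#'   session by [generate_lfp_session()].
#' @export
run_schedule <- function(run_s = 20, still_s = 10,
                         run_speed = 25, still_speed = 3) {
  data.frame(state = c("run", "still"), duration = c(run_s, still_s),
             speed = c(run_speed, still_speed))
}

#' Generate a multichannel LFP session with known theta phase offsets
#'
#' Each channel k is `sin(2 pi f t + offset_k)` plus white Gaussian noise
#' scaled to the requested SNR, emulating the ~8 Hz hippocampal theta rhythm
#' shared across tetrodes with systematic septo-temporal phase shifts. A
#' body-speed trace alternates between running and still blocks per the
#' schedule, so run-period gating can be exercised downstream.
#'
#' @param spec A [phase_offset_spec()].
#' @param fs LFP sampling rate in Hz; must be at least 4x the theta
#'   frequency.
#' @param schedule Block table from [run_schedule()].
#' @param speed_fs Sampling rate of the speed trace (Hz).
#' @param seed Integer seed for the noise.
#' @return A list with `lfp` (class `lfp_record`: `data` channels x samples,
#'   `fs`) and `speed` (class `speed_trace`: `values`, `fs`).
#' @export
generate_lfp_session <- function(spec, fs = 1500, schedule = run_schedule(),
                                 speed_fs = 25, seed = 1L) {
  stopifnot(inherits(spec, "phase_offset_spec"), fs >= 4 * spec$freq)
  n <- round(spec$duration * fs)
  tt <- (seq_len(n) - 1) / fs
  noise_sd <- if (is.finite(spec$snr)) (1 / sqrt(2)) / spec$snr else 0
  data <- with_seed(seed, {
    m <- matrix(0, nrow = length(spec$offsets), ncol = n)
    for (k in seq_along(spec$offsets)) {
      m[k, ] <- sin(2 * pi * spec$freq * tt + spec$offsets[k])
      if (noise_sd > 0) m[k, ] <- m[k, ] + rnorm(n, 0, noise_sd)
    }
    m
  })
  ns <- round(spec$duration * speed_fs)
  ts <- (seq_len(ns) - 1) / speed_fs
  cycle <- sum(schedule$duration)
  pos <- ts %% cycle
  edges <- cumsum(c(0, schedule$duration))
  state <- findInterval(pos, edges, rightmost.closed = FALSE)
  state[state > nrow(schedule)] <- nrow(schedule)
  speed <- schedule$speed[state]
  list(lfp = new_lfp_record(data, fs),
       speed = structure(list(values = speed, fs = speed_fs),
                         class = "speed_trace"))
}

new_lfp_record <- function(data, fs) {
  stopifnot(is.matrix(data), fs > 0)
  structure(list(data = data, fs = fs), class = "lfp_record")
}

#' @export
print.lfp_record <- function(x, ...) {
  cat("<lfp_record> ", nrow(x$data), " channels x ", ncol(x$data),
      " samples @ ", x$fs, " Hz\n", sep = "")
  invisible(x)
}

#' @export
print.speed_trace <- function(x, ...) {
  cat("<speed_trace> ", length(x$values), " samples @ ", x$fs, " Hz\n", sep = "")
  invisible(x)
}
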