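# Theta phase-offset chain: decimation to 1.5 kHz, equiripple band-pass
# (4-10 Hz pass, 3/11 Hz stops), zero-phase filtering, Hilbert phase,
# run-period gating, and two-stage circular averaging of pairwise offsets.

#' Decimate a raw multichannel recording to the LFP rate
#'
#' Anti-alias low-pass filters each channel (zero-phase FIR, 400 Hz cutoff)
#' and resamples to the target rate: integer stride when the ratio divides
#' evenly, otherwise linear interpolation at the output sample times.
#'
#' @param raw Channels x samples numeric matrix (a vector is treated as one
#'   channel).
#' @param fs_in Input sampling rate in Hz; must be >= `fs_out`.
#' @param fs_out Output rate (default 1500 Hz).
#' @param cutoff Anti-alias cutoff in Hz (default 400).
#' @return An `lfp_record` at `fs_out`.
#' @export
decimate_lfp <- function(raw, fs_in, fs_out = 1500, cutoff = 400) {
  if (is.vector(raw)) raw <- matrix(raw, nrow = 1L)
  if (fs_in < fs_out) stop("fs_in must be at least ", fs_out, " Hz")
  if (fs_in == fs_out) return(new_lfp_record(raw, fs_out))
  ntap <- 2L * ceiling(3 * fs_in / cutoff) + 1L
  h <- signal::fir1(ntap - 1L, cutoff / (fs_in / 2), type = "low")
  h <- h / sum(h)                     # exactly unit gain at DC
  n_out <- floor(ncol(raw) * fs_out / fs_in)
  t_out <- (seq_len(n_out) - 1) / fs_out
  q <- fs_in / fs_out
  out <- matrix(0, nrow(raw), n_out)
  for (k in seq_len(nrow(raw))) {
    y <- fir_zero_phase(raw[k, ], h, passes = 1L)
    if (q == round(q)) {
      out[k, ] <- y[1 + (seq_len(n_out) - 1) * q]
    } else {
      out[k, ] <- stats::approx(x = (seq_along(y) - 1) / fs_in, y = y,
                                xout = t_out, rule = 2)$y
    }
  }
  new_lfp_record(out, fs_out)
}

#' Design the theta band-pass filter
#'
#' Parks-McClellan optimal equiripple linear-phase FIR with pass band 4-10
#' Hz and stop bands below 3 and above 11 Hz at the LFP sampling rate. The
#' tap count starts at the standard (Kaiser) order estimate for the default
#' single-pass stopband target and is then increased along a small ladder
#' until the realized design verifies against the two-pass (forward +
#' reverse) magnitude requirements: at least 40 dB combined stopband
#' attenuation away from the transition bands, combined gain >= 0.99 at the
#' 8 Hz theta peak, and symmetric coefficients. The verified design is
#' cached per (fs, band) within a session.
#'
#' @param fs Sampling rate in Hz (default 1500).
#' @param pass_band,stop_edges Band edges in Hz.
#' @param stop_atten_db Target combined (two-pass) stopband attenuation.
#' @return An object of class `filter_spec`: coefficients `h`, `fs`, band
#'   edges, realized two-pass gains, and the tap count.
#' @export
design_theta_bandpass <- function(fs = 1500, pass_band = c(4, 10),
                                  stop_edges = c(3, 11),
                                  stop_atten_db = 40) {
  key <- paste(fs, paste(pass_band, collapse = ","),
               paste(stop_edges, collapse = ","), stop_atten_db, sep = "|")
  cached <- filter_cache[[key]]
  if (!is.null(cached)) return(cached)
  stopifnot(stop_edges[1] < pass_band[1], pass_band[1] < pass_band[2],
            pass_band[2] < stop_edges[2], stop_edges[2] < fs / 2)
  delta_s <- 10^(-stop_atten_db / 40)          # single-pass ripple target
  df <- min(pass_band[1] - stop_edges[1], stop_edges[2] - pass_band[2])
  a_db <- -20 * log10(delta_s)
  n0 <- ceiling((a_db - 7.95) / (2.285 * 2 * pi * df / fs))
  bands <- c(0, stop_edges[1], pass_band[1], pass_band[2], stop_edges[2], fs / 2)
  spec <- NULL
  for (mult in c(1, 1.15, 1.3, 1.5, 1.75, 2, 2.3)) {
    for (density in c(16, 20, 24)) {
      n <- 2L * ceiling(n0 * mult / 2)          # even order, odd length
      h <- tryCatch(signal::remez(n, bands / (fs / 2), c(0, 0, 1, 1, 0, 0),
                                  density = density),
                    error = function(e) NULL)
      if (is.null(h)) next
      # normalize to unit single-pass gain at the theta center frequency so
      # the equiripple passband ripple does not offset the 8 Hz response
      h <- h / fir_gain(h, 8, fs)
      v <- verify_bandpass(h, fs, pass_band, stop_edges, stop_atten_db)
      if (v$ok) {
        spec <- structure(list(h = h, fs = fs, pass_band = pass_band,
                               stop_edges = stop_edges, n_taps = length(h),
                               order = n, density = density,
                               gains = v$gains), class = "filter_spec")
        break
      }
    }
    if (!is.null(spec)) break
  }
  if (is.null(spec))
    stop("equiripple band-pass specification unattainable within the order ladder")
  filter_cache[[key]] <- spec
  spec
}

filter_cache <- new.env(parent = emptyenv())

# Two-pass magnitude checks for a candidate design.
verify_bandpass <- function(h, fs, pass_band, stop_edges, stop_atten_db) {
  mag2 <- function(f) fir_gain(h, f, fs)^2      # forward + reverse response
  f_stop <- c(seq(0.1, stop_edges[1] - 0.5, by = 0.2),
              seq(stop_edges[2] + 1, min(fs / 2 - 1, 5 * stop_edges[2]), by = 1))
  g_stop <- max(mag2(f_stop))
  g_theta <- mag2(8)
  g_pass_mid <- min(mag2(seq(mean(pass_band) - 1, mean(pass_band) + 1, by = 0.25)))
  ok <- g_stop <= 10^(-stop_atten_db / 20) && g_stop <= 0.01 &&
        g_theta >= 0.99 && g_pass_mid >= 0.85 &&
        max(abs(h - rev(h))) < 1e-12
  list(ok = ok, gains = c(stop_max = g_stop, theta = g_theta, pass_mid = g_pass_mid))
}

# Single-pass magnitude response of an FIR filter at frequencies f (Hz).
fir_gain <- function(h, f, fs) {
  vapply(f, function(ff)
    Mod(sum(h * exp(-2i * pi * ff / fs * (seq_along(h) - 1)))), numeric(1))
}

#' @export
print.filter_spec <- function(x, ...) {
  cat("<filter_spec> equiripple FIR, ", x$n_taps, " taps @ ", x$fs,
      " Hz; pass ", x$pass_band[1], "-", x$pass_band[2], " Hz, stops <",
      x$stop_edges[1], " / >", x$stop_edges[2], " Hz; two-pass gain at 8 Hz ",
      round(x$gains["theta"], 4), ", max stop ",
      signif(x$gains["stop_max"], 3), "\n", sep = "")
  invisible(x)
}

# FFT-based FIR convolution keeping the central (zero-delay-compensated)
# part; h must be odd-length symmetric for zero phase per pass pair.
fft_conv_centered <- function(x, h) {
  n <- length(x); L <- length(h)
  half <- (L - 1L) %/% 2L
  N <- stats::nextn(n + L - 1L, 2)
  y <- Re(stats::fft(stats::fft(c(x, numeric(N - n))) *
                     stats::fft(c(h, numeric(N - L))), inverse = TRUE)) / N
  y[(half + 1L):(half + n)]
}

# Zero-phase FIR filtering: odd-reflection padding at both ends, then
# `passes` forward+reverse pass pairs (a symmetric kernel makes each
# forward+reverse pair equal to one centered convolution with conv(h, rev(h));
# implemented that way for speed).
fir_zero_phase <- function(x, h, passes = 1L) {
  n <- length(x); L <- length(h)
  if (n <= 3L * L) stop("signal too short for the filter (need > 3 x taps)")
  pad <- min(3L * L, n - 1L)
  xp <- c(2 * x[1] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  g <- stats::convolve(h, rev(h), type = "open")   # zero-phase two-pass kernel
  for (p in seq_len(passes)) xp <- fft_conv_centered(xp, g)
  xp[(pad + 1L):(pad + n)]
}

#' Zero-phase theta-band filtering
#'
#' Applies the equiripple band-pass in the forward direction and then in
#' the reverse direction so that phase distortion cancels and the overall
#' magnitude response is the single-pass response squared; edge transients
#' are handled by odd-reflection padding of three filter lengths.
#'
#' @param x Numeric signal (one channel).
#' @param spec A [design_theta_bandpass()] result.
#' @return Filtered signal, same length.
#' @export
filtfilt_zero_phase <- function(x, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  fir_zero_phase(x, spec$h, passes = 1L)
}

#' Instantaneous phase via the Hilbert transform
#'
#' The analytic signal is formed in the frequency domain (positive
#' frequencies doubled, negative zeroed) and the phase is its complex
#' angle, wrapped to `(-pi, pi]`.
#'
#' @param x Band-limited numeric signal.
#' @return Phase series in radians, same length as `x`.
#' @export
instantaneous_phase <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  w <- numeric(n)
  if (n %% 2 == 0) {
    w[1] <- 1; w[n / 2 + 1] <- 1
    w[2:(n / 2)] <- 2
  } else {
    w[1] <- 1
    w[2:((n + 1) / 2)] <- 2
  }
  z <- stats::fft(X * w, inverse = TRUE) / n
  wrap_angle(atan2(Im(z), Re(z)))
}

#' Detect running periods from a speed trace
#'
#' Maximal intervals with body speed strictly above the threshold,
#' converted to half-open LFP sample intervals `[start, end)` by
#' nearest-sample resampling, and dropped when shorter than
#' `min_duration`.
#'
#' @param speed A `speed_trace` (from [generate_lfp_session()] or built as
#'   `list(values=, fs=)` with that class).
#' @param fs_lfp LFP sampling rate the intervals should index into.
#' @param threshold Running criterion in cm/s (default 10).
#' @param min_duration Minimum period length in seconds (default 1).
#' @return A `run_periods` object: integer matrix with columns `start`,
#'   `end` (1-based, half-open at `end`), possibly zero rows.
#' @export
detect_run_periods <- function(speed, fs_lfp, threshold = 10, min_duration = 1) {
  v <- speed$values
  r <- rle(v > threshold)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    t0 <- (starts[k] - 1) / speed$fs
    t1 <- ends[k] / speed$fs
    s <- round(t0 * fs_lfp) + 1L
    e <- round(t1 * fs_lfp) + 1L
    if ((e - s) / fs_lfp >= min_duration)
      out[[length(out) + 1L]] <- c(start = s, end = e)
  }
  m <- if (length(out)) do.call(rbind, out) else
    matrix(integer(0), 0, 2, dimnames = list(NULL, c("start", "end")))
  structure(m, class = c("run_periods", class(m)))
}

#' Circular mean of a set of angles
#'
#' The angle of the mean resultant vector. A near-zero resultant (antipodal
#' cancellation) has no meaningful mean direction and raises an error
#' reporting the resultant length.
#'
#' @param angles Nonempty numeric vector of radians.
#' @param tol Resultant length below which the mean is degenerate.
#' @return Angle in `(-pi, pi]`.
#' @export
circular_mean <- function(angles, tol = 1e-8) {
  stopifnot(length(angles) >= 1L)
  z <- mean(exp(1i * angles))
  if (Mod(z) < tol)
    stop("degenerate circular mean: resultant length ", format(Mod(z)))
  wrap_angle(atan2(Im(z), Re(z)))
}

#' Pairwise theta phase offsets over a behavior session
#'
#' The full estimation chain: (optional) decimation to 1.5 kHz, zero-phase
#' equiripple theta filtering, Hilbert phase, restriction to running
#' periods, then two-stage circular averaging — the instantaneous phase
#' difference `angle(e^{i phi_a} e^{-i phi_b})` is circularly averaged
#' within each running period, and the session offset is the (unweighted)
#' circular mean of the per-period means. Unit phasors are used, so every
#' time point contributes equally regardless of instantaneous amplitude.
#'
#' @param lfp An `lfp_record` (>= 2 channels).
#' @param speed A `speed_trace` aligned to the LFP start.
#' @param spec Optional [design_theta_bandpass()] result (designed at the
#'   record's rate when `NULL`).
#' @param threshold,min_duration Run-period gating parameters
#'   ([detect_run_periods()]).
#' @param weight_by_duration Weight per-period means by period duration in
#'   the session average (off by default: each period counts once).
#' @return A `phase_offset_matrix`: `offsets` (channels x channels,
#'   radians, antisymmetric mod 2 pi, zero diagonal), `resultant`
#'   (session-level mean resultant length per pair), `n_periods`,
#'   `filter_spec`.
#' @export
pairwise_theta_offsets <- function(lfp, speed, spec = NULL, threshold = 10,
                                   min_duration = 1,
                                   weight_by_duration = FALSE) {
  stopifnot(inherits(lfp, "lfp_record"))
  nch <- nrow(lfp$data)
  if (nch < 2L) stop("need at least 2 channels")
  if (lfp$fs > 1500) lfp <- decimate_lfp(lfp$data, lfp$fs)
  if (is.null(spec)) spec <- design_theta_bandpass(fs = lfp$fs)
  periods <- detect_run_periods(speed, lfp$fs, threshold, min_duration)
  if (nrow(periods) == 0L) stop("no running periods: nothing to average")
  phasor <- matrix(0i, nch, ncol(lfp$data))
  for (k in seq_len(nch)) {
    th <- filtfilt_zero_phase(lfp$data[k, ], spec)
    phasor[k, ] <- exp(1i * instantaneous_phase(th))
  }
  offsets <- matrix(0, nch, nch)
  resultant <- diag(1, nch)
  degenerate <- matrix(FALSE, nch, nch)
  w <- if (weight_by_duration) periods[, "end"] - periods[, "start"] else
    rep(1, nrow(periods))
  w <- w / sum(w)
  for (i in seq_len(nch - 1L)) for (j in (i + 1L):nch) {
    zm <- complex(real = numeric(nrow(periods)),
                  imaginary = numeric(nrow(periods)))
    for (p in seq_len(nrow(periods))) {
      idx <- periods[p, "start"]:(periods[p, "end"] - 1L)
      idx <- idx[idx <= ncol(phasor)]
      dz <- phasor[i, idx] * Conj(phasor[j, idx])
      zp <- mean(dz)
      if (Mod(zp) < 1e-12) {          # antipodal cancellation within a period
        degenerate[i, j] <- degenerate[j, i] <- TRUE
        zm[p] <- 0i
      } else zm[p] <- zp / Mod(zp)    # per-period mean direction, unit length
    }
    zs <- sum(w * zm)
    offsets[i, j] <- wrap_angle(atan2(Im(zs), Re(zs)))
    offsets[j, i] <- wrap_angle(-offsets[i, j])
    resultant[i, j] <- resultant[j, i] <- Mod(zs)
  }
  structure(list(offsets = offsets, resultant = resultant,
                 degenerate = degenerate,
                 n_periods = nrow(periods), filter_spec = spec),
            class = "phase_offset_matrix")
}

#' @export
print.phase_offset_matrix <- function(x, ...) {
  cat("<phase_offset_matrix> ", nrow(x$offsets), " channels, ",
      x$n_periods, " run periods; offsets (deg) vs channel 1: ",
      paste(round(x$offsets[1, ] * 180 / pi, 1), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}
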