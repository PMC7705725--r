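test_that("decimation preserves DC, amplitude, and lands at 1500 Hz", {
  dc <- matrix(0.7, 1, 60000)
  out <- decimate_lfp(dc, 30000)
  expect_equal(out$fs, 1500)
  mid <- out$data[1, 500:2500]
  expect_lt(max(abs(mid - 0.7)), 1e-6)
  # 8 Hz unit sinusoid keeps its amplitude within 1%
  t <- seq(0, 10, by = 1 / 30000)
  x <- sin(2 * pi * 8 * t)
  d <- decimate_lfp(x, 30000)
  tt <- (seq_len(ncol(d$data)) - 1) / 1500
  core <- tt > 1 & tt < 9
  fit <- stats::lm(d$data[1, core] ~ sin(2 * pi * 8 * tt[core]) +
                     cos(2 * pi * 8 * tt[core]))
  amp <- sqrt(sum(stats::coef(fit)[2:3]^2))
  expect_lt(abs(amp - 1), 0.01)
  expect_error(decimate_lfp(x, 1000), "fs_in")
})

test_that("the equiripple theta band-pass meets its two-pass response spec", {
  spec <- design_theta_bandpass()
  g2 <- lesionscope:::fir_gain(spec$h, c(1, 8, 20), 1500)^2
  expect_gte(g2[2], 0.99)
  expect_lte(g2[1], 0.01)
  expect_lte(g2[3], 0.01)
  # symmetric coefficients (exact linear phase)
  expect_equal(spec$h, rev(spec$h), tolerance = 1e-14)
  expect_equal(spec$fs, 1500)
})

test_that("zero-phase filtering neither shifts peaks nor breaks reversal symmetry", {
  spec <- design_theta_bandpass()
  fs <- 1500
  t <- seq(0, 20, by = 1 / fs)
  x <- sin(2 * pi * 8 * t)
  y <- filtfilt_zero_phase(x, spec)
  core <- seq(round(length(x) * 0.2), round(length(x) * 0.8))
  lags <- -5:5
  cc <- vapply(lags, function(l)
    stats::cor(x[core], y[core + l]), numeric(1))
  expect_lt(abs(lags[which.max(cc)]), 1)
  # commutes with time reversal
  set.seed(4)
  z <- stats::rnorm(3 * length(spec$h) + 1000)
  expect_equal(filtfilt_zero_phase(rev(z), spec),
               rev(filtfilt_zero_phase(z, spec)), tolerance = 1e-9)
  expect_error(filtfilt_zero_phase(stats::rnorm(100), spec), "too short")
})

test_that("instantaneous phase has the right slope, offset, and range", {
  fs <- 1000
  t <- seq(0, 10, by = 1 / fs)
  ph_cos <- instantaneous_phase(cos(2 * pi * 8 * t))
  core <- seq(round(length(t) * 0.1), round(length(t) * 0.9))
  unw <- cumsum(c(ph_cos[core[1]],
                  lesionscope:::wrap_angle(diff(ph_cos[core]))))
  slope <- stats::coef(stats::lm(unw ~ t[core]))[2]
  expect_lt(abs(slope - 2 * pi * 8) / (2 * pi * 8), 0.001)
  # sin lags cos by pi/2 at the same frequency
  ph_sin <- instantaneous_phase(sin(2 * pi * 8 * t))
  dd <- lesionscope:::wrap_angle(ph_sin[core] - ph_cos[core])
  expect_lt(max(abs(dd + pi / 2)), 0.01)
  expect_true(all(ph_cos > -pi & ph_cos <= pi))
})

test_that("run periods follow the strict speed threshold and duration gate", {
  sp <- function(v, fs = 10) structure(list(values = v, fs = fs),
                                       class = "speed_trace")
  # constant running: one interval spanning the session
  p <- detect_run_periods(sp(rep(20, 100)), fs_lfp = 100)
  expect_equal(nrow(p), 1L)
  expect_equal(unname(p[1, "start"]), 1L)
  expect_equal(unname(p[1, "end"]), 1001L)
  # constant stillness (and exactly-at-threshold speeds): empty
  expect_equal(nrow(detect_run_periods(sp(rep(5, 100)), 100)), 0L)
  expect_equal(nrow(detect_run_periods(sp(rep(10, 100)), 100)), 0L)
  # square wave alternating 20/0 every 10 s at 10 Hz speed sampling
  v <- rep(rep(c(20, 0), each = 100), 3)
  p2 <- detect_run_periods(sp(v), fs_lfp = 1000)
  expect_equal(nrow(p2), 3L)
  expect_equal(p2[, "start"], c(1L, 20001L, 40001L), ignore_attr = TRUE)
  expect_equal(p2[, "end"], c(10001L, 30001L, 50001L), ignore_attr = TRUE)
  # min_duration drops short bursts
  v3 <- c(rep(0, 50), rep(20, 4), rep(0, 50))
  expect_equal(nrow(detect_run_periods(sp(v3), 1000, min_duration = 1)), 0L)
})

test_that("circular means follow vector addition and flag degeneracy", {
  expect_equal(circular_mean(c(0, 0)), 0)
  expect_equal(circular_mean(c(0, pi / 2)), pi / 4, tolerance = 1e-12)
  expect_equal(circular_mean(c(-3, 3)), pi, tolerance = 1e-9)
  expect_error(circular_mean(c(-pi / 2, pi / 2)), "degenerate")
})

test_that("pairwise offsets are antisymmetric with zero diagonal", {
  po <- phase_offset_spec(c(0, pi / 5, -2), snr = 8, duration = 90)
  ses <- generate_lfp_session(po, seed = 2L)
  pom <- pairwise_theta_offsets(ses$lfp, ses$speed)
  expect_equal(diag(pom$offsets), rep(0, 3))
  for (i in 1:2) for (j in (i + 1):3)
    expect_lt(circ_dist(pom$offsets[i, j], -pom$offsets[j, i]), 1e-12)
  # short-session recovery already lands near truth
  est <- pom$offsets[, 1]
  expect_lt(max(circ_dist(est, po$offsets)), 2 * pi / 180)
})

test_that("two-stage averaging differs from pooled averaging when periods are unbalanced", {
  # one long period with offset ~ +60 deg and ten short ones at -20 deg:
  # pooled (sample-weighted) and two-stage (period-weighted) means disagree
  fs <- 1500
  spec <- design_theta_bandpass()
  mk <- function(offset, dur) {
    t <- seq(0, dur - 1 / fs, by = 1 / fs)
    rbind(sin(2 * pi * 8 * t), sin(2 * pi * 8 * t - offset))
  }
  long <- mk(60 * pi / 180, 100)
  shorts <- lapply(1:10, function(i) mk(-20 * pi / 180, 10))
  gap <- matrix(0, 2, 5 * fs)
  data <- long
  for (s in shorts) data <- cbind(data, gap, s)
  speed_fs <- 25
  speed <- c(rep(20, 100 * speed_fs),
             rep(c(rep(0, 5 * speed_fs), rep(20, 10 * speed_fs)), 10))
  ses_speed <- structure(list(values = speed, fs = speed_fs),
                         class = "speed_trace")
  lfp <- lesionscope:::new_lfp_record(data, fs)
  two_stage <- pairwise_theta_offsets(lfp, ses_speed, spec = spec)
  pooled <- pairwise_theta_offsets(lfp, ses_speed, spec = spec,
                                   weight_by_duration = TRUE)
  # two-stage: 1 period at +60 and 10 at -20 -> mean near -20 side;
  # pooled: half the samples at +60 -> pulled toward the long period
  expect_gt(circ_dist(two_stage$offsets[1, 2], pooled$offsets[1, 2]),
            5 * pi / 180)
  expect_lt(circ_dist(two_stage$offsets[1, 2],
                      circular_mean(c(rep(-20, 10), 60) * pi / 180)),
            3 * pi / 180)
})

test_that("estimation uses only running periods", {
  po <- phase_offset_spec(c(0, pi / 6), snr = 10, duration = 120)
  ses <- generate_lfp_session(po, seed = 5L)
  base <- pairwise_theta_offsets(ses$lfp, ses$speed)
  # slam large artifacts into still periods only
  run <- detect_run_periods(ses$speed, ses$lfp$fs, threshold = 10,
                            min_duration = 0)
  in_run <- rep(FALSE, ncol(ses$lfp$data))
  for (p in seq_len(nrow(run))) in_run[run[p, 1]:(run[p, 2] - 1)] <- TRUE
  dirty <- ses$lfp
  nstill <- sum(!in_run)
  dirty$data[, !in_run] <- dirty$data[, !in_run] +
    matrix(20 * sin(2 * pi * 50 * seq_len(nstill) / 1500), 2, nstill,
           byrow = TRUE) + 5
  est <- pairwise_theta_offsets(dirty, ses$speed)
  expect_lt(circ_dist(est$offsets[1, 2], base$offsets[1, 2]), 0.5 * pi / 180)
})
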