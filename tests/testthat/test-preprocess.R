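# Signal extraction: filtering, R peaks, beat series, PAT, resampling,
# band power, window selection, stationarity, standardization.

test_that("ECG band-pass removes DC, passes 10 Hz, rejects 50 Hz", {
  fs <- 250
  t <- seq(0, 30, by = 1 / fs)
  # constant input is annihilated (trim clears the 1 Hz pole transients)
  y <- filter_ecg(rep(5, length(t)), fs)
  trim <- seq(6 * fs, length(y) - 6 * fs)
  expect_lt(max(abs(y[trim])), 1e-3)
  gain_at <- function(f) {
    x <- sin(2 * pi * f * t)
    y <- filter_ecg(x, fs)
    max(abs(y[trim])) # amplitude after edge trim
  }
  expect_gt(gain_at(10), 10^(-1 / 20))        # within 1 dB
  expect_lt(gain_at(50), 1 / 10)              # > 10x attenuation
  expect_error(filter_ecg(rnorm(100), fs = 30), "too low")
})

test_that("template matching recovers R peaks against generator truth", {
  rec <- default_recording()
  peaks <- detect_r_peaks(filter_ecg(rec$ecg$x, rec$ecg$fs), rec$ecg$fs)
  expect_true(all(diff(peaks) > 0.25))
  rates <- match_rates(peaks, rec$truth$beat_times, tol = 0.004)
  expect_gte(rates["sensitivity"], 0.99)
  expect_gte(rates["precision"], 0.99)
  expect_equal(length(peaks), length(rec$truth$beat_times), tolerance = 2 / 500)
})

test_that("detection degrades gracefully and fails loudly on no signal", {
  recn <- synth_recording(duration = 400, ecg_noise_sd = 0.2, seed = 99)
  peaks <- detect_r_peaks(filter_ecg(recn$ecg$x, 250), 250)
  rates <- match_rates(peaks, recn$truth$beat_times, tol = 0.008)
  expect_gte(rates["sensitivity"], 0.95)
  expect_error(detect_r_peaks(rep(0, 250 * 20), 250), "no beats")
  expect_error(detect_r_peaks(rnorm(100), 250), "at least 10 s")
})

test_that("beat_rr computes intervals and corrects split beats", {
  bs <- beat_rr(c(0.0, 0.8, 1.6))
  expect_equal(bs$rr, c(0.8, 0.8))
  expect_equal(bs$times, c(0.8, 1.6))
  expect_error(beat_rr(1.0), "at least 2")

  # a false detection splitting one 0.8 s interval into 0.3 + 0.5 is
  # merged back
  peaks <- seq(0, 40, by = 0.8)
  k <- 21
  peaks_bad <- sort(c(peaks, peaks[k] + 0.3))
  bs <- beat_rr(peaks_bad)
  expect_equal(length(bs$rr), length(peaks) - 1)
  expect_equal(bs$rr, rep(0.8, length(peaks) - 1), tolerance = 1e-9)
  expect_gte(bs$n_corrected, 1)

  # recovered intervals track generator truth within 2 samples of 250 Hz
  rec <- default_recording()
  peaks <- detect_r_peaks(filter_ecg(rec$ecg$x, 250), 250)
  bs <- beat_rr(peaks)
  truth_rr <- rec$truth$rr[-length(rec$truth$rr)] # last interval unclosed
  expect_length(bs$rr, length(truth_rr))
  expect_lt(max(abs(bs$rr - truth_rr)), 2 / 250)
})

test_that("respiration is sampled at the beats", {
  fs <- 25
  t <- seq(0, 40, by = 1 / fs)
  resp <- sin(2 * pi * 0.25 * t)
  expect_equal(resp_at_beats(resp, fs, 1.0), sin(pi / 2), tolerance = 0.01)
  expect_equal(resp_at_beats(rep(3.2, 100), fs, c(0.5, 1, 2)), rep(3.2, 3))
  expect_error(resp_at_beats(resp, fs, 100), "span")
  rec <- default_recording()
  v <- resp_at_beats(rec$resp$x, rec$resp$fs, rec$truth$beat_times)
  expect_gt(stats::cor(v, sin(rec$truth$resp_phase)), 0.99)
})

test_that("PAT is recovered from the BVP steepest rise", {
  recc <- synth_recording(duration = 360, pat_var = 0, seed = 5)
  p <- compute_pat(recc$truth$beat_times, recc$bvp$x, recc$bvp$fs)
  expect_lt(max(abs(p$pat - 0.25)), 1 / 64)

  # ramp 0.20 -> 0.30 s over the record
  recr <- synth_recording(duration = 360,
                          pat_profile = function(t) 0.20 + 0.1 * t / 360,
                          seed = 6)
  p <- compute_pat(recr$truth$beat_times, recr$bvp$x, 64)
  expect_lt(max(abs(p$pat - recr$truth$pat)), 2 / 64)

  # flat BVP in all windows is a hard failure
  expect_error(compute_pat(seq(1, 50, by = 0.8), rep(0, 64 * 60), 64),
               "pulse")
})

test_that("spline resampling is exact on constants and linear ramps", {
  times <- cumsum(c(1, rep(0.8, 50)))
  grid <- 2:38
  expect_equal(resample_1hz(times, rep(0.8, 51), grid), rep(0.8, length(grid)))
  ramp <- 2 * times + 1
  expect_equal(resample_1hz(times, ramp, grid), 2 * grid + 1, tolerance = 1e-6)
  expect_error(resample_1hz(times, ramp, 0:50), "span")
  expect_error(resample_1hz(1:3, 1:3, 2), "at least 4")
  # sinusoidal truth RR modulation (period 10 s) is recovered on the grid
  truth <- function(t) 0.8 + 0.05 * sin(2 * pi * t / 10)
  vals <- truth(times)
  out <- resample_1hz(times, vals, grid)
  expect_lt(sqrt(mean((out - truth(grid))^2)), 0.02 * 0.05)
})

test_that("band power concentrates in the right band and counts epochs", {
  fs <- 256
  x <- sin(2 * pi * 10 * seq(0, 300, by = 1 / fs))
  bp <- eeg_band_power(x, fs)
  expect_equal(ncol(bp), 299)
  expect_equal(attr(bp, "times"), 1:299)
  frac <- bp["alpha", ] / colSums(bp)
  expect_true(all(frac >= 0.95))
  # power scales with amplitude^2
  bp2 <- eeg_band_power(3 * x, fs)
  expect_equal(unname(bp2), unname(3^2 * bp), tolerance = 1e-9)
  expect_error(eeg_band_power(rnorm(100), 256), "epoch")
  # doubling the delta envelope mid-record quadruples delta power
  const <- function(a) function(t) a
  rec <- synth_recording(duration = 400, seed = 8,
                         band_env = list(function(t) if (t < 200) 10 else 20,
                                         const(12), const(10), const(6)))
  bp <- eeg_band_power(rec$eeg$x, 256)
  tms <- attr(bp, "times")
  ratio <- mean(bp["delta", tms > 210]) / mean(bp["delta", tms < 190])
  expect_equal(ratio, 4, tolerance = 0.25)
})

test_that("window selection honours per-state offsets and lengths", {
  X <- matrix(rnorm(7 * 500), 7)
  attr(X, "times") <- 1:500
  w <- select_window(X, "REST")
  expect_equal(ncol(w$X), 300)
  expect_equal(w$t, 180:479)
  w2 <- select_window(X, "MA")
  expect_equal(w2$t, 60:359)
  w3 <- select_window(X, "SG", task_offset = 120)
  expect_equal(w3$t, 120:419)
  expect_error(select_window(X[, 1:200], "MA", times = 1:200), "insufficient")
})

test_that("stationarity screen is calibrated on Gaussian noise and catches breaks", {
  set.seed(101)
  pass <- mean(replicate(1000, check_stationarity(rnorm(300))$pass))
  expect_gte(pass, 0.90)
  # step of 3 SD at midpoint
  expect_false(check_stationarity(c(rnorm(150), rnorm(150) + 3), seed = 1)$pass)
  # linear trend spanning 4 SD
  set.seed(102)
  fail_rate <- mean(replicate(200,
    !check_stationarity(rnorm(300) + seq(0, 4, length.out = 300))$pass))
  expect_gte(fail_rate, 0.9)
  expect_error(check_stationarity(rep(1, 300)), "degenerate")
})

test_that("standardization is exact, idempotent, and rejects constants", {
  x <- matrix(c(1, 2, 3), 1)
  z <- standardize(x)
  expect_equal(mean(z), 0)
  expect_equal(mean(z^2), 1)
  expect_equal(standardize(z), z, tolerance = 1e-12)
  expect_error(standardize(matrix(2, 1, 10)), "constant")
})

test_that("full alignment yields a synchronous finite matrix tracking truth", {
  rec <- default_recording()
  X <- align_recording(rec)
  expect_true(all(is.finite(X)))
  expect_equal(rownames(X), c("RR", "RESP", "PAT", "delta", "theta", "alpha", "beta"))
  tms <- attr(X, "times")
  expect_equal(tms, tms[1]:tms[length(tms)])
  # rows correlate with generator truth
  tr <- rec$truth
  rr_truth <- resample_1hz(tr$beat_times[-1], tr$rr[-length(tr$rr)], tms)
  expect_gt(stats::cor(X["RR", ], rr_truth), 0.95)
  expect_gt(stats::cor(X["RESP", ],
                       sin(stats::approx(tr$beat_times, tr$resp_phase,
                                         xout = tms, rule = 2)$y)), 0.95)
  pat_truth <- resample_1hz(tr$beat_times, tr$pat, tms)
  expect_gt(stats::cor(X["PAT", ], pat_truth), 0.95)
})

test_that("detection chain recovers a 0.1 Hz cardiac modulation spectrally", {
  rec <- synth_recording(duration = 400, resp_rate = 0.1, rsa_gain = 0.1,
                         rr_sd = 0.005, seed = 13)
  peaks <- detect_r_peaks(filter_ecg(rec$ecg$x, 250), 250)
  bs <- beat_rr(peaks)
  grid <- ceiling(min(bs$times)):floor(max(bs$times))
  rr1 <- resample_1hz(bs$times, bs$rr, grid)
  sp <- stats::spec.pgram(stats::ts(rr1, frequency = 1), taper = 0,
                          plot = FALSE, detrend = TRUE)
  f_peak <- sp$freq[which.max(sp$spec)]
  expect_equal(f_peak, 0.1, tolerance = 0.25)
})
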