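# Synthetic multi-rate physiological recordings: R-peaked ECG with
# respiratory sinus arrhythmia, sinusoid-plus-noise respiration, delayed
# BVP pulses giving beat-varying pulse arrival times, and EEG as a sum of
# band-limited noise carriers with slowly varying amplitude envelopes.
# Every generated quantity is kept as ground truth so downstream
# extraction stages can be scored exactly.

#' Default EEG analysis bands (Hz, half-open [low, high))
#' @export
eeg_bands <- function() {
  list(delta = c(0.5, 3), theta = c(3, 8), alpha = c(8, 12), beta = c(12, 25))
}

# Raised-cosine QRS surrogate: 40 ms wide, amplitude 1, peak at center.
qrs_template_wave <- function(fs, width = 0.04) {
  half <- round(width / 2 * fs)
  tau <- (-half:half) / fs
  0.5 * (1 + cos(2 * pi * tau / width))
}

# Gamma-like pulse tau^2 exp(-tau/b), unit peak amplitude; its steepest
# rise (inflection) sits at tau = (2 - sqrt(2)) * b after onset. The
# default shape scale makes the derivative maximum sharp enough to be
# localized to within one sample at 64 Hz.
bvp_pulse_wave <- function(fs, b = 0.08, span = 1.0) {
  tau <- seq(0, span, by = 1 / fs)
  w <- tau^2 * exp(-tau / b)
  w / max(w)
}
bvp_inflection_offset <- function(b = 0.08) (2 - sqrt(2)) * b

# Slow AR(1) drawn on a 1 Hz grid (stationary start), for quasi-periodic
# frequency/phase drifts and band envelopes.
slow_ar1 <- function(n, phi, sd) {
  z <- numeric(n)
  z[1] <- stats::rnorm(1, 0, sd / sqrt(1 - phi^2))
  for (i in seq_len(n)[-1]) z[i] <- phi * z[i - 1] + stats::rnorm(1, 0, sd)
  z
}

#' Generate a synthetic raw physiological recording
#'
#' Emulates the four wearable-sensor channels at typical native rates (ECG 250 Hz,
#' respiration 25 Hz, BVP 64 Hz, EEG 256 Hz). Beat-to-beat cardiac
#' periods follow `rr = rr_mean * (1 + rsa_gain * sin(phase_resp)) +
#' noise`, the simplest respiratory phase coupling the transfer analysis
#' can detect. Each beat puts a 40 ms raised-cosine spike in the ECG and
#' one gamma-like pulse in the BVP whose steepest-rise point lags the R
#' peak by the stored per-beat pulse arrival time. EEG is the sum of four
#' band-limited noise carriers scaled by slowly varying positive
#' envelopes (first-order autoregressive on the log scale, one value per
#' second).
#'
#' @param duration record length in seconds (>= 360).
#' @param state one of `"REST"`, `"MA"`, `"SG"`.
#' @param subject_id subject identifier string.
#' @param rr_mean,rr_sd mean cardiac period (s) and beat-to-beat jitter SD.
#' @param resp_rate respiration frequency (Hz).
#' @param rsa_gain fractional RR modulation by respiratory phase.
#' @param pat_base,pat_var,pat_rate pulse arrival time (s): base value,
#'   sinusoidal variation amplitude and its frequency (Hz).
#' @param pat_profile optional function(t) -> PAT (s) overriding the
#'   sinusoidal law.
#' @param band_amp named amplitudes of the four EEG band carriers.
#' @param band_env_phi,band_env_sd AR(1) coefficient and innovation SD of
#'   the log-envelopes.
#' @param band_env optional list of functions(t) -> amplitude (one per
#'   band) overriding the autoregressive envelopes.
#' @param ecg_noise_sd,bvp_noise_sd,resp_noise_sd additive noise SDs.
#' @param seed optional integer for reproducibility.
#' @return object of class `raw_recording`: channels `ecg`, `resp`, `bvp`,
#'   `eeg` (each a list with `x` samples and `fs` Hz), `state`,
#'   `subject_id` and `truth` (beat times, per-beat RR / PAT / respiration
#'   phase, 1 Hz band envelopes, parameters).
#' @export
synth_recording <- function(duration = 420, state = c("REST", "MA", "SG"),
                            subject_id = "S01",
                            rr_mean = 0.8, rr_sd = 0.03,
                            resp_rate = 0.25, rsa_gain = 0.05,
                            pat_base = 0.25, pat_var = 0.02, pat_rate = 0.1,
                            pat_profile = NULL,
                            band_amp = c(delta = 20, theta = 12, alpha = 10, beta = 6),
                            band_env_phi = 0.7, band_env_sd = 0.1,
                            band_env = NULL,
                            ecg_noise_sd = 0.05, bvp_noise_sd = 0.002,
                            resp_noise_sd = 0.02,
                            seed = NULL) {
  state <- match.arg(state)
  if (duration < 360) stop("duration must be at least 360 s")
  if (rr_mean <= 0 || resp_rate <= 0) stop("rates must be positive")
  fs <- c(ecg = 250, resp = 25, bvp = 64, eeg = 256)
  with_seed(seed, function() {
    ## quasi-periodic respiratory phase: the instantaneous frequency
    ## drifts slowly (~5% SD), as real breathing does -- a pure sinusoid
    ## would put poles of the extracted series on the unit circle
    t1 <- 0:ceiling(duration)
    fmod <- slow_ar1(length(t1), 0.95, 0.016)
    phi_grid <- cumsum(c(0, 2 * pi * resp_rate * (1 + fmod[-1])))
    resp_phase <- stats::approxfun(t1, phi_grid, rule = 2)

    ## beat times with respiratory sinus arrhythmia
    n_guess <- ceiling(duration / rr_mean) + 20
    beat_t <- numeric(n_guess); rr <- numeric(n_guess)
    t <- rr_mean  # first beat away from the record edge
    k <- 0
    while (t < duration - 1.5) {
      k <- k + 1
      beat_t[k] <- t
      rr_k <- rr_mean * (1 + rsa_gain * sin(resp_phase(t))) +
        stats::rnorm(1, 0, rr_sd)
      rr_k <- max(rr_k, 0.3)
      rr[k] <- rr_k
      t <- t + rr_k
    }
    beat_t <- beat_t[seq_len(k)]
    rr <- rr[seq_len(k)]   # rr[k] = interval opened at beat k

    ## per-beat pulse arrival times: slow sinusoid with drifting phase
    ## plus per-beat jitter, all scaled by pat_var (pat_var = 0 gives a
    ## constant PAT exactly)
    pat <- if (is.null(pat_profile)) {
      theta <- stats::approx(t1, slow_ar1(length(t1), 0.95, 0.1),
                             xout = beat_t, rule = 2)$y
      pat_base + pat_var * (sin(2 * pi * pat_rate * beat_t + theta) +
                              0.15 * stats::rnorm(k))
    } else vapply(beat_t, pat_profile, numeric(1))
    if (any(pat <= 0) || any(pat >= c(rr)))
      stop("pulse arrival times must satisfy 0 < PAT < RR")

    ## ECG: baseline noise + raised-cosine spikes
    n_ecg <- round(duration * fs["ecg"])
    ecg <- stats::rnorm(n_ecg, 0, ecg_noise_sd)
    w <- qrs_template_wave(fs["ecg"])
    half <- (length(w) - 1) / 2
    for (tb in beat_t) {
      c0 <- round(tb * fs["ecg"]) + 1
      idx <- (c0 - half):(c0 + half)
      ok <- idx >= 1 & idx <= n_ecg
      ecg[idx[ok]] <- ecg[idx[ok]] + w[ok]
    }

    ## respiration: sinusoid + noise
    t_resp <- (seq_len(round(duration * fs["resp"])) - 1) / fs["resp"]
    resp <- sin(resp_phase(t_resp)) +
      stats::rnorm(length(t_resp), 0, resp_noise_sd)

    ## BVP: one pulse per beat, steepest rise at beat + PAT
    n_bvp <- round(duration * fs["bvp"])
    bvp <- stats::rnorm(n_bvp, 0, bvp_noise_sd)
    pw <- bvp_pulse_wave(fs["bvp"])
    infl <- bvp_inflection_offset()
    for (i in seq_along(beat_t)) {
      onset <- beat_t[i] + pat[i] - infl
      i0 <- round(onset * fs["bvp"]) + 1
      idx <- i0:(i0 + length(pw) - 1)
      ok <- idx >= 1 & idx <= n_bvp
      bvp[idx[ok]] <- bvp[idx[ok]] + pw[ok]
    }

    ## EEG: band-limited carriers with slow positive envelopes
    n_eeg <- round(duration * fs["eeg"])
    bands <- eeg_bands()
    t_env <- 0:(floor(duration) - 1)
    env <- matrix(NA_real_, length(bands), length(t_env),
                  dimnames = list(names(bands), NULL))
    eeg <- numeric(n_eeg)
    t_eeg <- (seq_len(n_eeg) - 1) / fs["eeg"]
    for (b in seq_along(bands)) {
      if (is.null(band_env)) {
        env[b, ] <- band_amp[b] * exp(slow_ar1(length(t_env), band_env_phi, band_env_sd))
      } else {
        env[b, ] <- vapply(t_env, band_env[[b]], numeric(1))
      }
      carrier <- bandlimited_noise(n_eeg, fs["eeg"], bands[[b]][1], bands[[b]][2])
      env_s <- stats::approx(t_env, env[b, ], xout = t_eeg, rule = 2)$y
      eeg <- eeg + carrier * env_s
    }

    structure(list(
      ecg = list(x = ecg, fs = unname(fs["ecg"])),
      resp = list(x = resp, fs = unname(fs["resp"])),
      bvp = list(x = bvp, fs = unname(fs["bvp"])),
      eeg = list(x = eeg, fs = unname(fs["eeg"])),
      state = state, subject_id = subject_id, duration = duration,
      truth = list(beat_times = beat_t, rr = rr, pat = pat,
                   resp_phase = resp_phase(beat_t),
                   band_env = env, env_times = t_env,
                   params = list(rr_mean = rr_mean, rr_sd = rr_sd,
                                 resp_rate = resp_rate, rsa_gain = rsa_gain,
                                 pat_base = pat_base, pat_var = pat_var))),
      class = "raw_recording")
  })
}

# White noise restricted to [lo, hi) Hz by FFT masking (exact band edges,
# stable at very low normalized frequencies where IIR designs are not).
bandlimited_noise <- function(n, fs, lo, hi) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)              # two-sided frequency axis
  X[f < lo | f >= hi] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  y / stats::sd(y)
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("raw_recording %s [%s], %.0f s: ECG %g Hz, RESP %g Hz, BVP %g Hz, EEG %g Hz, %d beats\n",
              x$subject_id, x$state, x$duration, x$ecg$fs, x$resp$fs,
              x$bvp$fs, x$eeg$fs, length(x$truth$beat_times)))
  invisible(x)
}

#' Write / read a raw recording as CSV channels plus a JSON manifest
#'
#' One `time_s,value` CSV per channel, a `manifest.json` mapping channels
#' to files and rates, and (when present) the generator ground truth as
#' `truth.json`.
#'
#' @param rec a `raw_recording`.
#' @param dir output directory (created if needed).
#' @return `write_recording`: the manifest path, invisibly.
#' @export
write_recording <- function(rec, dir) {
  stopifnot(inherits(rec, "raw_recording"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  channels <- list()
  for (ch in c("ecg", "resp", "bvp", "eeg")) {
    f <- paste0(ch, ".csv")
    x <- rec[[ch]]
    utils::write.csv(data.frame(time_s = (seq_along(x$x) - 1) / x$fs, value = x$x),
                     file.path(dir, f), row.names = FALSE)
    channels[[ch]] <- list(file = f, rate_hz = x$fs)
  }
  manifest <- list(subject_id = rec$subject_id, state = rec$state,
                   duration_s = rec$duration, channels = channels)
  if (!is.null(rec$truth)) {
    tr <- rec$truth
    tr$band_env <- unname(as.matrix(tr$band_env))
    jsonlite::write_json(tr, file.path(dir, "truth.json"),
                         digits = NA, auto_unbox = TRUE)
    manifest$truth <- "truth.json"
  }
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, digits = NA, auto_unbox = TRUE)
  invisible(mp)
}

#' @rdname write_recording
#' @param manifest path to a `manifest.json` (or its directory).
#' @return `read_recording`: a `raw_recording`.
#' @export
read_recording <- function(manifest) {
  if (dir.exists(manifest)) manifest <- file.path(manifest, "manifest.json")
  man <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  dir <- dirname(manifest)
  need <- c("ecg", "resp", "bvp", "eeg")
  missing <- setdiff(need, names(man$channels))
  if (length(missing))
    stop("manifest missing channel(s): ", paste(missing, collapse = ", "))
  rec <- list()
  for (ch in need) {
    info <- man$channels[[ch]]
    tab <- utils::read.csv(file.path(dir, info$file))
    rec[[ch]] <- list(x = tab$value, fs = info$rate_hz)
  }
  rec$state <- man$state
  rec$subject_id <- man$subject_id
  rec$duration <- if (!is.null(man$duration_s)) man$duration_s
                  else length(rec$ecg$x) / rec$ecg$fs
  if (!is.null(man$truth)) {
    tr <- jsonlite::read_json(file.path(dir, man$truth), simplifyVector = TRUE)
    if (!is.null(tr$band_env)) {
      tr$band_env <- as.matrix(tr$band_env)
      rownames(tr$band_env) <- names(eeg_bands())
    }
    rec$truth <- tr
  }
  structure(rec, class = "raw_recording")
}
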