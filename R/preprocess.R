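# From raw multi-rate recordings to the synchronous 7 x 300 network
# series: ECG band-pass filtering, template-matching R-peak detection,
# RR / respiration-at-beats / pulse-arrival-time beat series, 1 Hz spline
# resampling, EEG band-power series, window selection, stationarity
# screening and standardization.

#' Band-pass filter an ECG signal (1-20 Hz, zero phase)
#'
#' Removes baseline wander with a high-pass at 1 Hz and high-frequency
#' noise with a low-pass at 20 Hz (half-power corners of the 4th-order
#' designs), each applied forward-backward so R-peak timing is preserved.
#'
#' @param ecg raw samples.
#' @param fs sampling rate in Hz (> 40).
#' @return filtered samples, same length as the input.
#' @export
filter_ecg <- function(ecg, fs) {
  if (fs <= 40) stop("sampling rate too low for the 20 Hz corner")
  hp <- signal::butter(4, 1 / (fs / 2), type = "high")
  lp <- signal::butter(4, 20 / (fs / 2), type = "low")
  x <- signal::filtfilt(hp, ecg)
  as.numeric(signal::filtfilt(lp, x))
}

local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

# Greedy refractory enforcement: keep candidates in decreasing score
# order, dropping any within `refr` samples of an already kept one.
enforce_refractory <- function(idx, score, refr) {
  ord <- idx[order(score[idx], decreasing = TRUE)]
  kept <- integer(0)
  for (i in ord) if (!length(kept) || min(abs(kept - i)) > refr) kept <- c(kept, i)
  sort(kept)
}

#' Detect R peaks by template matching
#'
#' Two-pass detection: a provisional amplitude-threshold pass (threshold
#' 0.6 x the 95th percentile of the rectified signal, 250 ms refractory)
#' supplies the beats from which a QRS template (mean of +/- 60 ms around
#' the 20 largest provisional peaks) is built; the template is then slid
#' over the signal and beats are declared at local maxima of the
#' normalized cross-correlation above 0.6, again with the refractory
#' period. The R-peak time is refined to the signal maximum within
#' +/- 4 ms of the aligned template peak.
#'
#' @param ecg_filtered band-passed ECG samples.
#' @param fs sampling rate (Hz).
#' @param ncc_threshold normalized cross-correlation acceptance threshold.
#' @return strictly increasing R-peak times in seconds.
#' @export
detect_r_peaks <- function(ecg_filtered, fs, ncc_threshold = 0.6) {
  x <- as.numeric(ecg_filtered)
  if (length(x) < 10 * fs) stop("need at least 10 s of signal")
  refr <- round(0.25 * fs)
  thr <- 0.6 * stats::quantile(abs(x), 0.95, names = FALSE)
  cand <- local_maxima(x)
  cand <- cand[x[cand] > thr]
  if (thr <= 0 || !length(cand))
    stop("no beats: no candidate R peaks above the amplitude threshold")
  prov <- enforce_refractory(cand, x, refr)
  half <- round(0.06 * fs)
  prov <- prov[prov > half & prov <= length(x) - half]
  if (!length(prov))
    stop("no beats: all provisional peaks too close to the record edges")
  best <- prov[order(x[prov], decreasing = TRUE)][seq_len(min(20L, length(prov)))]
  tmpl <- rowMeans(vapply(best, function(c0) x[(c0 - half):(c0 + half)],
                          numeric(2 * half + 1)))
  L <- length(tmpl)
  t0 <- tmpl - mean(tmpl)
  sst <- sum(t0^2)
  if (sst <= 0) stop("no beats: degenerate template")
  # rolling sums over windows ending at i (length L)
  ends <- L:length(x)
  num <- stats::filter(x, rev(t0), method = "convolution", sides = 1)[ends]
  s1 <- stats::filter(x, rep(1, L), method = "convolution", sides = 1)[ends]
  s2 <- stats::filter(x^2, rep(1, L), method = "convolution", sides = 1)[ends]
  denom <- sqrt(pmax(s2 - s1^2 / L, 0) * sst)
  ncc <- rep(0, length(x))
  good <- denom > 0
  ncc[ends[good]] <- num[good] / denom[good]   # indexed by window END
  peaks_ncc <- local_maxima(ncc)
  peaks_ncc <- peaks_ncc[ncc[peaks_ncc] > ncc_threshold]
  if (!length(peaks_ncc))
    stop("no beats: cross-correlation never exceeded the matching threshold")
  peaks_ncc <- enforce_refractory(peaks_ncc, ncc, refr)
  # aligned template peak position, then refine on the signal
  tpk <- which.max(tmpl)
  ref_w <- as.integer(max(1, round(0.004 * fs)))
  peak_idx <- vapply(peaks_ncc, function(e) {
    c0 <- as.integer(e - L + tpk)        # template max within aligned window
    lo <- max(1L, c0 - ref_w); hi <- min(length(x), c0 + ref_w)
    lo + which.max(x[lo:hi]) - 1L
  }, integer(1))
  # amplitude gate: normalized correlation alone also accepts low-amplitude
  # bump-shaped noise, so require a peak height commensurate with the
  # beats the template was built from
  amp_gate <- 0.4 * stats::median(x[best])
  peak_idx <- peak_idx[x[peak_idx] > amp_gate]
  if (!length(peak_idx))
    stop("no beats: no matched peak above the amplitude gate")
  peak_idx <- sort(unique(peak_idx))
  (peak_idx - 1) / fs
}

#' Beat-to-beat RR intervals with automated ectopy correction
#'
#' `rr[k] = times[k+1] - times[k]`, attributed to the time of the second
#' peak of each pair (the interval is known only once it closes).
#' Implausible intervals -- outside 0.7-1.3 x the 11-beat running median
#' -- are corrected automatically: two consecutive short intervals whose
#' sum is plausible are merged back (false extra detection); any remaining
#' implausible values are replaced by spline interpolation over the
#' plausible neighbours (missed or ectopic beats).
#'
#' @param peaks strictly increasing R-peak times (s), at least 2.
#' @return list (class `beat_series`): `times` (s, time of each closing
#'   peak), `rr` (s), `n_corrected`.
#' @export
beat_rr <- function(peaks) {
  peaks <- as.numeric(peaks)
  if (length(peaks) < 2) stop("need at least 2 peaks")
  rr <- diff(peaks)
  times <- peaks[-1]
  plaus_band <- function(rr) {
    med <- stats::runmed(rr, k = min(11L, length(rr) - (1 - length(rr) %% 2)),
                         endrule = "median")
    cbind(0.7 * med, 1.3 * med)
  }
  n_corrected <- 0L
  # merge pass for split beats
  repeat {
    if (length(rr) < 3) break
    band <- plaus_band(rr)
    short <- rr < band[, 1]
    k <- which(short[-length(short)] & short[-1])
    if (!length(k)) break
    k <- k[1]
    merged <- rr[k] + rr[k + 1]
    if (merged >= band[k, 1] && merged <= band[k + 1, 2]) {
      rr <- c(rr[seq_len(k - 1)], merged, rr[-seq_len(k + 1)])
      times <- times[-k]
      n_corrected <- n_corrected + 1L
    } else break
  }
  # interpolation pass for remaining implausible intervals
  if (length(rr) >= 4) {
    band <- plaus_band(rr)
    bad <- rr < band[, 1] | rr > band[, 2]
    if (any(bad) && sum(!bad) >= 4) {
      rr[bad] <- stats::spline(times[!bad], rr[!bad], xout = times[bad],
                               method = "fmm")$y
      n_corrected <- n_corrected + sum(bad)
    }
  }
  structure(list(times = times, rr = rr, n_corrected = n_corrected),
            class = "beat_series")
}

#' Respiration sampled at the R peaks
#'
#' @param resp respiration samples.
#' @param fs respiration sampling rate (Hz).
#' @param peaks R-peak times (s), all within the respiration time span.
#' @return respiration value at the sample nearest each peak time.
#' @export
resp_at_beats <- function(resp, fs, peaks) {
  n <- length(resp)
  idx <- round(peaks * fs) + 1
  if (any(idx < 1 | idx > n)) stop("R peak outside the respiration time span")
  resp[idx]
}

#' Per-beat pulse arrival time from the BVP signal
#'
#' For each R peak the BVP is searched over (peak, peak + min(next RR,
#' `w_max`)); the pulse arrival time is the position of the maximum first
#' difference (steepest rise) minus the peak time. Beats whose steepest
#' in-window rise falls below 20% of the median across beats are marked
#' missing and bridged by spline interpolation; more than 20% missing is
#' a hard failure.
#'
#' @param peaks R-peak times (s).
#' @param bvp BVP samples covering the peak span.
#' @param fs BVP sampling rate (Hz).
#' @param w_max search-window cap (s); wrist arrival times are far below
#'   the 0.6 s default.
#' @return list: `pat` (s, one per peak), `missing` (logical),
#'   `n_missing`.
#' @export
compute_pat <- function(peaks, bvp, fs, w_max = 0.6) {
  n <- length(bvp)
  nb <- length(peaks)
  if (nb < 2) stop("need at least 2 peaks")
  next_rr <- c(diff(peaks), stats::median(diff(peaks)))
  d <- diff(bvp)
  pat <- rep(NA_real_, nb)
  slope <- rep(NA_real_, nb)
  for (k in seq_len(nb)) {
    w <- min(next_rr[k], w_max)
    i0 <- floor(peaks[k] * fs) + 2
    i1 <- min(ceiling((peaks[k] + w) * fs), n - 1)
    if (i0 >= i1) next
    dd <- d[i0:i1]
    # locate the steepest rise on a 3-point-smoothed derivative (robust to
    # sample noise on the near-flat derivative top), then refine by a
    # parabolic fit to the raw first differences around it
    ds <- stats::filter(dd, rep(1 / 3, 3), sides = 2)
    ds[is.na(ds)] <- -Inf
    j <- which.max(ds)
    slope[k] <- dd[which.max(dd)]
    jj <- max(3L, min(length(dd) - 2L, j))
    win <- (jj - 2L):(jj + 2L)
    cf <- stats::lm.fit(cbind(1, win, win^2), dd[win])$coefficients
    jstar <- if (is.finite(cf[3]) && cf[3] < 0) -cf[2] / (2 * cf[3]) else j
    if (!is.finite(jstar) || abs(jstar - j) > 2) jstar <- j
    # first difference d[i] spans samples i..i+1: midpoint (i - 0.5)/fs
    pat[k] <- ((i0 + jstar - 1.5) / fs) - peaks[k]
  }
  ok <- !is.na(slope)
  if (!any(ok)) stop("no acceptable pulse found for any beat")
  med_slope <- stats::median(slope[ok])
  missing <- !ok | slope < 0.2 * med_slope | med_slope <= 0
  missing[is.na(missing)] <- TRUE
  if (mean(missing) > 0.2)
    stop(sprintf("pulse missing for %.0f%% of beats (> 20%%)", 100 * mean(missing)))
  if (any(missing))
    pat[missing] <- stats::spline(peaks[!missing], pat[!missing],
                                  xout = peaks[missing], method = "fmm")$y
  list(pat = pat, missing = missing, n_missing = sum(missing))
}

#' Resample a beat series to a uniform 1 Hz grid by cubic splines
#'
#' @param times beat times (s, strictly increasing, >= 4).
#' @param values values attributed at `times`.
#' @param grid evaluation instants (s); must lie within the beat span.
#' @return values interpolated at `grid`.
#' @export
resample_1hz <- function(times, values, grid) {
  if (length(times) < 4) stop("need at least 4 beats for spline resampling")
  if (min(grid) < min(times) || max(grid) > max(times))
    stop("evaluation grid extends outside the beat-time span")
  if (mean(diff(times)) > 1)
    warning("mean beat interval exceeds 1 s; 1 Hz grid is denser than the data")
  stats::spline(times, values, xout = grid, method = "fmm")$y
}

#' EEG band-power time series (delta, theta, alpha, beta)
#'
#' Periodogram band powers over 2 s epochs with 50% overlap: each epoch is
#' mean-removed, a rectangular-window periodogram is computed, and the
#' ordinates whose bin center lies in each half-open band [low, high) are
#' summed. A duration-D record yields D - 1 values per band, timestamped
#' at the epoch centers t = 1, ..., D - 1 s.
#'
#' @param eeg EEG samples.
#' @param fs sampling rate (>= 64 Hz).
#' @param bands named list of c(low, high) band edges in Hz.
#' @param epoch,hop epoch length and hop in seconds.
#' @return matrix n_bands x n_epochs with a `"times"` attribute (s).
#' @export
eeg_band_power <- function(eeg, fs, bands = eeg_bands(), epoch = 2, hop = 1) {
  if (fs < 64) stop("sampling rate must be at least 64 Hz")
  nper <- round(epoch * fs)
  if (length(eeg) < nper) stop("signal shorter than one epoch")
  n_ep <- floor(length(eeg) / fs) - 1
  if (n_ep < 1) stop("signal shorter than one epoch")
  freqs <- (0:(nper %/% 2)) * fs / nper
  sel <- lapply(bands, function(b) which(freqs >= b[1] & freqs < b[2]))
  out <- matrix(NA_real_, length(bands), n_ep,
                dimnames = list(names(bands), NULL))
  for (e in seq_len(n_ep)) {
    i0 <- round((e - 1) * hop * fs) + 1
    seg <- eeg[i0:(i0 + nper - 1)]
    seg <- seg - mean(seg)
    pg <- (Mod(stats::fft(seg))^2 / (fs * nper))[seq_along(freqs)]
    for (b in seq_along(bands)) out[b, e] <- sum(pg[sel[[b]]])
  }
  attr(out, "times") <- seq_len(n_ep) * hop
  out
}

#' Select the 300-sample analysis window
#'
#' REST windows start 180 s after the beginning of the record (at least
#' three minutes into the rest period); task windows (MA, SG) start
#' `task_offset` seconds (default 60, configurable 60-120) after the
#' task transition.
#'
#' @param series matrix M x L of aligned 1 Hz samples with a `"times"`
#'   attribute (or a `times` argument).
#' @param state `"REST"`, `"MA"` or `"SG"`.
#' @param n_window window length in samples (default 300 = five minutes).
#' @param rest_offset,task_offset window start offsets in seconds.
#' @param times timestamps of the columns (s), if not attached.
#' @return object of class `network_series` (unstandardized): `X` (M x
#'   n_window), `labels`, `state`, `t`, `standardized = FALSE`.
#' @export
select_window <- function(series, state = c("REST", "MA", "SG"),
                          n_window = 300L, rest_offset = 180,
                          task_offset = 60, times = NULL) {
  state <- match.arg(state)
  X <- as.matrix(series)
  if (is.null(times)) times <- attr(series, "times")
  if (is.null(times)) times <- seq_len(ncol(X)) - 1
  offset <- if (state == "REST") rest_offset else task_offset
  start <- which(times >= offset)[1]
  if (is.na(start) || start + n_window - 1 > ncol(X))
    stop(sprintf("insufficient length: need %d samples from t = %g s, have %d",
                 n_window, offset, max(0L, ncol(X) - ifelse(is.na(start), ncol(X), start - 1L))))
  idx <- start:(start + n_window - 1)
  labels <- rownames(X)
  if (is.null(labels)) labels <- paste0("X", seq_len(nrow(X)))
  structure(list(X = X[, idx, drop = FALSE], labels = labels, state = state,
                 t = times[idx], standardized = FALSE),
            class = "network_series")
}

#' @export
print.network_series <- function(x, ...) {
  cat(sprintf("network_series [%s]: %d x %d at 1 Hz, t = %g..%g s%s\n",
              x$state, nrow(x$X), ncol(x$X), min(x$t), max(x$t),
              if (isTRUE(x$standardized)) ", standardized" else ""))
  invisible(x)
}

#' Restricted weak-sense stationarity check
#'
#' Draws `n_sub` random subwindows and compares each subwindow against
#' the pooled remainder of the series -- two tests per subwindow: a Welch
#' t-test for steadiness of the mean and a Brown-Forsythe-type test for
#' steadiness of the variance (Welch t-test on absolute deviations from
#' each group's median, robust to the heavy tails of band-power series).
#' The series fails when more than `max_reject` of the 2 x `n_sub` tests
#' reject at level `alpha`; the default bound is calibrated by Monte
#' Carlo so that i.i.d. Gaussian series pass in over 90% of cases (the
#' 20 tests share data and are positively dependent, so the bound is
#' looser than a binomial account would suggest).
#'
#' @param x numeric series (typically 300 samples).
#' @param n_sub number of random subwindows.
#' @param sub_len subwindow length in samples.
#' @param alpha per-test two-sided level.
#' @param max_reject largest tolerated number of rejections.
#' @param seed optional integer for reproducible subwindow draws.
#' @return list: `pass`, `n_reject`, `rejections` (per-subwindow logical
#'   matrix, rows mean/variance), `starts`.
#' @export
check_stationarity <- function(x, n_sub = 10L, sub_len = 50L, alpha = 0.05,
                               max_reject = 3L, seed = NULL) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2 * sub_len) stop("series shorter than twice the subwindow length")
  if (stats::var(x) == 0) stop("degenerate (zero-variance) series")
  with_seed(seed, function() {
    starts <- sample.int(n - sub_len + 1, n_sub, replace = TRUE)
    rej <- matrix(FALSE, 2, n_sub, dimnames = list(c("mean", "variance"), NULL))
    for (s in seq_len(n_sub)) {
      idx <- starts[s]:(starts[s] + sub_len - 1)
      a <- x[idx]; b <- x[-idx]
      rej["mean", s] <- stats::t.test(a, b)$p.value < alpha
      rej["variance", s] <- stats::t.test(abs(a - stats::median(a)),
                                          abs(b - stats::median(b)))$p.value < alpha
    }
    list(pass = sum(rej) <= max_reject, n_reject = sum(rej),
         rejections = rej, starts = starts)
  })
}

#' Standardize a network series to zero mean and unit variance
#'
#' Row-wise: subtract the sample mean and divide by the standard
#' deviation with the 1/N variance convention, so the Gaussian entropy of
#' each standardized row is exactly 0.5 log(2 pi e).
#'
#' @param net a `network_series` (or plain matrix).
#' @return the standardized object (idempotent within rounding).
#' @export
standardize <- function(net) {
  X <- if (inherits(net, "network_series")) net$X else as.matrix(net)
  mu <- rowMeans(X)
  Xc <- X - mu
  s2 <- rowMeans(Xc^2)
  if (any(s2 == 0)) {
    lab <- rownames(X)[s2 == 0]
    stop("constant row(s): ", paste(if (is.null(lab)) which(s2 == 0) else lab,
                                    collapse = ", "))
  }
  Xs <- Xc / sqrt(s2)
  if (inherits(net, "network_series")) {
    net$X <- Xs
    net$standardized <- TRUE
    net
  } else Xs
}

#' Preprocess a raw recording into aligned 1 Hz node series
#'
#' Runs the full extraction chain: ECG filtering, R-peak detection, RR /
#' respiration-at-beats / PAT beat series, 1 Hz spline resampling, EEG
#' band powers, and alignment of all seven node series on the common
#' integer-second grid (cropped to timestamps covered by every series).
#'
#' @param rec a `raw_recording` (or path to its manifest).
#' @param bands EEG bands (named list).
#' @return matrix 7 x L (rows RR, RESP, PAT, delta, theta, alpha, beta)
#'   with a `"times"` attribute, plus attributes `"peaks"` and
#'   `"n_corrected"`.
#' @export
align_recording <- function(rec, bands = eeg_bands()) {
  if (is.character(rec)) rec <- read_recording(rec)
  stopifnot(inherits(rec, "raw_recording"))
  fecg <- filter_ecg(rec$ecg$x, rec$ecg$fs)
  peaks <- detect_r_peaks(fecg, rec$ecg$fs)
  bs <- beat_rr(peaks)
  respb <- resp_at_beats(rec$resp$x, rec$resp$fs, peaks)
  patr <- compute_pat(peaks, rec$bvp$x, rec$bvp$fs)
  bp <- eeg_band_power(rec$eeg$x, rec$eeg$fs, bands = bands)
  bp_t <- attr(bp, "times")
  # common integer-second grid covered by every series
  lo <- max(ceiling(min(bs$times)), ceiling(min(peaks)), min(bp_t))
  hi <- min(floor(max(bs$times)), floor(max(peaks)), max(bp_t))
  if (hi - lo + 1 < 10) stop("aligned overlap too short")
  grid <- lo:hi
  X <- rbind(
    RR = resample_1hz(bs$times, bs$rr, grid),
    RESP = resample_1hz(peaks, respb, grid),
    PAT = resample_1hz(peaks, patr$pat, grid),
    bp[, match(grid, bp_t), drop = FALSE])
  attr(X, "times") <- grid
  attr(X, "peaks") <- peaks
  attr(X, "n_corrected") <- bs$n_corrected
  attr(X, "n_missing_pulse") <- patr$n_missing
  X
}

#' Write a network series as CSV plus JSON sidecar
#'
#' 300-row CSV with columns `t,RR,RESP,PAT,delta,theta,alpha,beta` and a
#' sidecar with state, window information and preprocessing flags.
#'
#' @param net a `network_series`.
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.json`.
#' @param extra named list merged into the sidecar.
#' @export
write_network_series <- function(net, path, extra = list()) {
  stopifnot(inherits(net, "network_series"))
  tab <- data.frame(t = net$t, t(net$X))
  names(tab) <- c("t", net$labels)
  utils::write.csv(tab, path, row.names = FALSE)
  side <- c(list(state = net$state, n = ncol(net$X),
                 t_start = min(net$t), t_end = max(net$t),
                 standardized = isTRUE(net$standardized),
                 stationarity = net$stationarity), extra)
  jsonlite::write_json(side, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE, null = "null")
  invisible(path)
}
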