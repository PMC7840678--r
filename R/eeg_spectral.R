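## Epoched EEG container, preprocessing (zero-phase Butterworth band-pass,
## resampling, amplitude-based trial rejection), time-mirror padding of the
## pre-stimulus window, Morlet time-frequency decomposition and simple
## spectra.

#' Epoched EEG container
#'
#' @param data numeric array `trial x channel x time` (microvolts).
#' @param times sample times in seconds relative to stimulus onset (onset at
#'   0, pre-stimulus negative); must be strictly increasing and uniform.
#' @param sample_rate_hz sampling rate.
#' @param ch_names channel names.
#' @param rejected_trials indices of trials removed by preprocessing.
#' @return object of class `epoched_eeg`.
#' @export
epoched_eeg <- function(data, times, sample_rate_hz, ch_names = NULL,
                        rejected_trials = integer(0)) {
  stopifnot(length(dim(data)) == 3, dim(data)[3] == length(times))
  dt <- diff(times)
  stop_if(any(dt <= 0) || diff(range(dt)) > 1e-6 / sample_rate_hz * 1e3,
          "times must be strictly increasing and uniform")
  stop_if(any(!is.finite(data)), "data contains non-finite values")
  ch_names <- ch_names %||% sprintf("ch%02d", seq_len(dim(data)[2]))
  structure(list(data = data, times = times,
                 sample_rate_hz = sample_rate_hz, ch_names = ch_names,
                 rejected_trials = rejected_trials),
            class = "epoched_eeg")
}

#' @export
print.epoched_eeg <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("epoched_eeg: %d trials x %d channels x %d samples (%g Hz), t = [%.3f, %.3f] s\n",
              d[1], d[2], d[3], x$sample_rate_hz,
              min(x$times), max(x$times)))
  if (length(x$rejected_trials))
    cat(sprintf("  %d trials rejected\n", length(x$rejected_trials)))
  invisible(x)
}

#' Preprocess epoched EEG
#'
#' Zero-phase (forward-backward) Butterworth band-pass, anti-aliased
#' resampling, and rejection of trials whose peak amplitude on the
#' designated central channels exceeds the threshold.
#'
#' Ocular/muscular artifact removal by ICA and bad-channel interpolation are
#' deliberately not implemented (the synthetic generator produces
#' artifact-free data): for real recordings, run those steps in a dedicated
#' EEG toolchain and enter the cleaned epochs through [epoched_eeg()] before
#' calling this function.
#'
#' @param eeg an [epoched_eeg()].
#' @param band band-pass edges in Hz (default 0.6-70).
#' @param order Butterworth order (default 3).
#' @param resample_to target rate in Hz (default 150); `NULL` keeps the rate.
#' @param reject_uv peak-amplitude rejection threshold in microvolts
#'   (default 175); `NULL` disables rejection.
#' @param central_channels channel names or indices used for rejection
#'   (default: all channels).
#' @return a preprocessed [epoched_eeg()] with `rejected_trials` recorded.
#' @export
preprocess_eeg <- function(eeg, band = c(0.6, 70), order = 3,
                           resample_to = 150, reject_uv = 175,
                           central_channels = NULL) {
  stopifnot(inherits(eeg, "epoched_eeg"))
  fs <- eeg$sample_rate_hz
  stop_if(fs < 2 * band[2], "sample rate below twice the band upper edge")
  d <- dim(eeg$data)
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  flt <- array(NA_real_, d)
  for (tr in seq_len(d[1]))
    for (ch in seq_len(d[2]))
      flt[tr, ch, ] <- signal::filtfilt(bf, eeg$data[tr, ch, ])

  times <- eeg$times
  if (!is.null(resample_to) && resample_to != fs) {
    # rational resampling; common cases (1024 -> 150) reduce exactly
    p <- resample_to; q <- fs
    g <- gcd(p, q)
    p <- p / g; q <- q / g
    n_new <- floor(d[3] * p / q)
    out <- array(NA_real_, c(d[1], d[2], n_new))
    for (tr in seq_len(d[1]))
      for (ch in seq_len(d[2])) {
        r <- signal::resample(flt[tr, ch, ], p, q)
        out[tr, ch, ] <- r[seq_len(n_new)]
      }
    flt <- out
    times <- times[1] + (seq_len(n_new) - 1) / resample_to
    fs <- resample_to
    d <- dim(flt)
  }

  rejected <- integer(0)
  if (!is.null(reject_uv)) {
    cc <- central_channels %||% seq_len(d[2])
    if (is.character(cc)) cc <- match(cc, eeg$ch_names)
    peak <- apply(abs(flt[, cc, , drop = FALSE]), 1, max)
    rejected <- which(peak > reject_uv)
    stop_if(length(rejected) == d[1], "all trials rejected")
    if (length(rejected)) flt <- flt[-rejected, , , drop = FALSE]
  }
  epoched_eeg(flt, times, fs, eeg$ch_names, rejected_trials = rejected)
}

gcd <- function(a, b) if (b == 0) a else gcd(b, a %% b)

#' Re-reference epoched EEG
#'
#' Subtracts the instantaneous mean of the reference channels from every
#' channel (average reference when `reference = NULL`). The synthetic
#' generator produces average-referenced data; this is the plumbing for
#' recordings referenced elsewhere.
#'
#' @param eeg an [epoched_eeg()].
#' @param reference channel names or indices of the new reference (default:
#'   all channels, i.e. common average).
#' @return a re-referenced [epoched_eeg()].
#' @export
rereference <- function(eeg, reference = NULL) {
  stopifnot(inherits(eeg, "epoched_eeg"))
  ref <- reference %||% seq_len(dim(eeg$data)[2])
  if (is.character(ref)) ref <- match(ref, eeg$ch_names)
  stop_if(anyNA(ref), "reference channels not found")
  m <- apply(eeg$data[, ref, , drop = FALSE], c(1, 3), mean)
  out <- eeg$data - aperm(array(m, c(dim(m), dim(eeg$data)[2])), c(1, 3, 2))
  epoched_eeg(out, eeg$times, eeg$sample_rate_hz, eeg$ch_names,
              eeg$rejected_trials)
}

#' Time-mirror padding of the pre-stimulus window
#'
#' Wavelet estimates near the edges of the pre-stimulus window would
#' otherwise be contaminated by the epoch edge and by post-stimulus
#' activity. The post-onset period is faded out (half-Hanning) and replaced
#' by the time-mirrored pre-stimulus data, and the pre-stimulus data are
#' also mirrored backwards in time, so the analysis window sits in the
#' middle of a symmetric segment.
#'
#' @param eeg an [epoched_eeg()] covering at least (-1, 0) s.
#' @param fade fade window type for the (discarded) post-onset period;
#'   `"hanning"` only.
#' @return an [epoched_eeg()] whose time axis spans three copies of the
#'   pre-stimulus window (mirror, original, mirror); attribute
#'   `orig_pre_idx` marks the samples of the original pre-stimulus data.
#' @export
time_mirror_pad <- function(eeg, fade = "hanning") {
  stopifnot(inherits(eeg, "epoched_eeg"))
  pre_idx <- which(eeg$times < 0)
  stop_if(length(pre_idx) < 2, "no pre-stimulus samples")
  n <- length(pre_idx)
  d <- dim(eeg$data)
  pre <- eeg$data[, , pre_idx, drop = FALSE]
  out <- array(NA_real_, c(d[1], d[2], 3 * n))
  out[, , seq_len(n)] <- pre[, , rev(seq_len(n))]
  out[, , n + seq_len(n)] <- pre
  out[, , 2 * n + seq_len(n)] <- pre[, , rev(seq_len(n))]
  dt <- 1 / eeg$sample_rate_hz
  t0 <- eeg$times[pre_idx[1]]
  times <- t0 - n * dt + (seq_len(3 * n) - 1) * dt
  res <- epoched_eeg(out, times, eeg$sample_rate_hz, eeg$ch_names,
                     eeg$rejected_trials)
  attr(res, "orig_pre_idx") <- n + seq_len(n)
  res
}

# complex Morlet wavelet in the frequency domain, energy-normalized
morlet_kernel_fft <- function(n_fft, fs, freq, n_cycles) {
  sigma_t <- n_cycles / (2 * pi * freq)
  half <- floor(n_fft / 2)
  tt <- c(0:half, -(n_fft - half - 1):-1) / fs
  w <- exp(2i * pi * freq * tt) * exp(-tt^2 / (2 * sigma_t^2))
  w <- w / sqrt(sum(Mod(w)^2))
  stats::fft(w)
}

#' Morlet time-frequency decomposition
#'
#' Convolves each trial and channel with complex Morlet wavelets (default 4
#' cycles, 2-13 Hz in 1 Hz steps) and returns single-trial power and phase.
#'
#' @param eeg an [epoched_eeg()] (typically after [time_mirror_pad()]).
#' @param freqs analysis frequencies in Hz.
#' @param n_cycles wavelet width in cycles (default 4).
#' @param keep_times optional vector of output times (nearest samples are
#'   used); default: all samples.
#' @return object of class `tf_decomposition`: arrays `power` and `phase`
#'   of shape `trial x channel x freq x time`, plus `freqs`, `times`,
#'   `ch_names`.
#' @export
morlet_tf <- function(eeg, freqs = 2:13, n_cycles = 4, keep_times = NULL) {
  stopifnot(inherits(eeg, "epoched_eeg"))
  d <- dim(eeg$data)
  fs <- eeg$sample_rate_hz
  span <- diff(range(eeg$times))
  need <- n_cycles / min(freqs)
  stop_if(span < need,
          sprintf("epoch too short for %g cycles at %g Hz (need %.2f s)",
                  n_cycles, min(freqs), need))
  if (is.null(keep_times)) {
    keep_idx <- seq_len(d[3])
  } else {
    keep_idx <- vapply(keep_times, function(t)
      which.min(abs(eeg$times - t)), integer(1))
  }
  n_fft <- d[3]
  # time x (trial*channel) matrix, FFT once
  M <- matrix(aperm(eeg$data, c(3, 1, 2)), n_fft, d[1] * d[2])
  Mf <- stats::mvfft(M)
  nf <- length(freqs); nt <- length(keep_idx)
  power <- array(NA_real_, c(d[1], d[2], nf, nt))
  phase <- array(NA_real_, c(d[1], d[2], nf, nt))
  for (k in seq_len(nf)) {
    wf <- morlet_kernel_fft(n_fft, fs, freqs[k], n_cycles)
    conv <- stats::mvfft(Mf * wf, inverse = TRUE) / n_fft
    conv <- conv[keep_idx, , drop = FALSE]
    pw <- array(Mod(conv)^2, c(nt, d[1], d[2]))
    ph <- array(Arg(conv), c(nt, d[1], d[2]))
    power[, , k, ] <- aperm(pw, c(2, 3, 1))
    phase[, , k, ] <- aperm(ph, c(2, 3, 1))
  }
  structure(list(power = power, phase = phase, freqs = freqs,
                 times = eeg$times[keep_idx], ch_names = eeg$ch_names),
            class = "tf_decomposition")
}

#' Extract per-trial power or phase from a decomposition
#'
#' @param tf a `tf_decomposition`.
#' @param channel channel name or index.
#' @param freq frequency in Hz (nearest grid frequency is used).
#' @param time_s single time (phase) in seconds.
#' @param window time window `(lo, hi)` over which power is averaged.
#' @param what `"phase"` or `"power"`.
#' @return numeric vector, one value per trial.
#' @export
extract_tf <- function(tf, channel, freq, time_s = NULL, window = NULL,
                       what = c("phase", "power")) {
  what <- match.arg(what)
  if (is.character(channel)) channel <- match(channel, tf$ch_names)
  k <- which.min(abs(tf$freqs - freq))
  if (what == "phase") {
    stop_if(is.null(time_s), "time_s required for phase extraction")
    i <- which.min(abs(tf$times - time_s))
    tf$phase[, channel, k, i]
  } else {
    stop_if(is.null(window), "window required for power extraction")
    sel <- tf$times >= window[1] & tf$times <= window[2]
    stop_if(!any(sel), "window contains no samples")
    rowMeans(tf$power[, channel, k, sel, drop = FALSE], dims = 1)
  }
}

#' Select the pre-stimulus time point with the most significant channels
#'
#' Given first-pass p-values per channel, frequency and time, returns the
#' time maximizing the number of channels with `p < alpha`, summed over
#' frequencies. Ties resolve to the earliest (most negative) time.
#'
#' @param pvals array `channel x freq x time`.
#' @param times time axis matching the third dimension.
#' @param alpha significance level (default 0.05).
#' @return list with `time_s`, `index` and the per-time significant-channel
#'   `counts`.
#' @export
select_timepoint <- function(pvals, times, alpha = 0.05) {
  stopifnot(length(dim(pvals)) == 3, dim(pvals)[3] == length(times))
  counts <- apply(pvals < alpha, 3, sum)
  ord <- order(-counts, times)
  i <- ord[1]
  list(time_s = times[i], index = i, counts = counts)
}

#' Trial- and channel-averaged amplitude spectrum
#'
#' Welch-style average of per-trial, per-channel FFT amplitude spectra over
#' a time window.
#'
#' @param eeg an [epoched_eeg()].
#' @param window time range `(lo, hi)` in seconds; default the full epoch.
#' @param channels channel names or indices (default all).
#' @param detrend remove the per-segment mean before the FFT.
#' @return list with `freqs` (Hz) and `amplitude`.
#' @export
eeg_spectrum <- function(eeg, window = NULL, channels = NULL,
                         detrend = TRUE) {
  stopifnot(inherits(eeg, "epoched_eeg"))
  sel <- if (is.null(window)) seq_along(eeg$times)
         else which(eeg$times >= window[1] & eeg$times <= window[2])
  stop_if(length(sel) < 8, "window too short")
  ch <- channels %||% seq_len(dim(eeg$data)[2])
  if (is.character(ch)) ch <- match(ch, eeg$ch_names)
  seg <- eeg$data[, ch, sel, drop = FALSE]
  n <- length(sel)
  M <- matrix(aperm(seg, c(3, 1, 2)), n)
  if (detrend) M <- sweep(M, 2, colMeans(M))
  taper <- 0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1)))
  amp <- rowMeans(Mod(stats::mvfft(M * taper))) / n
  half <- floor(n / 2)
  freqs <- (seq_len(half) - 1) * eeg$sample_rate_hz / n
  list(freqs = freqs[-1], amplitude = amp[2:half])
}
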