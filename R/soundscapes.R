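## Tone-cloud soundscape generation.
##
## A soundscape is 1.2 s of 30 simultaneous four-tone sequences. Each tone
## lasts 30 ms; within a sequence the tones step up or down by 20 cents. The
## stimulus is divided into ten 120 ms epochs and the per-epoch "coherence"
## (the excess fraction of sequences sweeping in the trial's nominal
## direction, 0 = half/half, 1 = all congruent) is controlled epoch by epoch.
## Sequences run in 30 slots; a finished sequence is immediately replaced, so
## every slot starts one sequence per epoch and the per-epoch coherence is
## realized exactly up to counting quantization out of the sequences starting
## in that epoch.

STIM_DURATION_S <- 1.2
N_EPOCHS <- 10L
EPOCH_DUR_S <- 0.12
TONE_DUR_S <- 0.03
CENTS_STEP <- 20

#' Quantize a coherence value to a sequence count
#'
#' With `n` sequences available in an epoch, coherence is realized by making
#' `k = round(n * (1 + c) / 2)` of them congruent with the trial direction
#' (rounding half up, i.e. ties resolve toward the requested value from
#' below), giving realized coherence `(2 k - n) / n`. With 30 sequences the
#' grid has steps of 1/15.
#'
#' @param coherence requested coherence values in `[0, 1]`.
#' @param n_sequences number of sequences the epoch draws from.
#' @return list with integer counts `n_congruent` and `realized` coherences.
#' @export
quantize_coherence <- function(coherence, n_sequences = 30L) {
  stop_if(any(coherence < 0 | coherence > 1),
          "coherence must lie in [0, 1]")
  n <- as.integer(n_sequences)
  k <- round_half_up(n * (1 + coherence) / 2)
  k <- pmin(pmax(k, 0L), n)
  list(n_congruent = as.integer(k), realized = (2 * k - n) / n)
}

#' Generate one tone-cloud soundscape
#'
#' Builds the full parametric description of a trial's stimulus: 30 slots of
#' four-tone sequences with random start frequencies (log-uniform between 128
#' and 16384 Hz by default), random initial starting positions (tone 1-4),
#' per-tone onset jitter up to 30 ms, and per-epoch sequence directions chosen
#' so each epoch realizes its requested coherence after quantization.
#'
#' @param direction overall sweep direction, `+1` (up) or `-1` (down).
#' @param coherences 10 per-epoch coherence values in `[0, 1]`.
#' @param seed integer seed; fixed seed gives a bit-identical spec.
#' @param n_sequences number of simultaneous sequence slots (default 30).
#' @param freq_dist `"log"` (perceptually uniform, default) or `"linear"`
#'   start-frequency distribution over `freq_range`.
#' @param freq_range start-frequency range in Hz.
#' @param jitter_s maximal per-tone onset jitter in seconds.
#' @return an object of class `soundscape_spec`: the direction, requested and
#'   realized coherences, a sequence table (slot, nominal onset, direction,
#'   start frequency, epoch) and a tone table (frequency, jittered onset,
#'   duration).
#' @export
generate_soundscape <- function(direction, coherences, seed = NULL,
                                n_sequences = 30L,
                                freq_dist = c("log", "linear"),
                                freq_range = c(128, 16384),
                                jitter_s = 0.03) {
  freq_dist <- match.arg(freq_dist)
  stop_if(!direction %in% c(-1, 1), "direction must be +1 or -1")
  stop_if(length(coherences) != N_EPOCHS,
          sprintf("coherences must have length %d", N_EPOCHS))
  stop_if(any(coherences < 0 | coherences > 1),
          "coherence must lie in [0, 1]")
  stop_if(n_sequences < 2, "need at least 2 sequence slots")
  n_seq <- as.integer(n_sequences)

  with_seed(seed, {
    ## sequence onsets per slot: the initial sequence is entered at a random
    ## tone position p in 1..4 (so 5 - p tones remain), after which each slot
    ## starts a fresh 4-tone sequence every 120 ms until the stimulus ends.
    start_pos <- sample.int(4L, n_seq, replace = TRUE)
    seq_rows <- vector("list", n_seq)
    for (j in seq_len(n_seq)) {
      offset <- (5L - start_pos[j]) * TONE_DUR_S
      onsets <- c(0, seq(offset, STIM_DURATION_S - 1e-9, by = EPOCH_DUR_S))
      onsets <- onsets[onsets < STIM_DURATION_S]
      if (length(onsets) > 1 && onsets[2] <= onsets[1]) onsets <- onsets[-1]
      first_tone <- c(start_pos[j], rep(1L, length(onsets) - 1L))
      seq_rows[[j]] <- data.frame(slot = j, onset = onsets,
                                  first_tone = first_tone)
    }
    sequences <- do.call(rbind, seq_rows)
    sequences$epoch <- pmin(floor(sequences$onset / EPOCH_DUR_S) + 1L,
                            N_EPOCHS)

    ## per-epoch direction assignment realizing the requested coherence
    sequences$direction <- NA_real_
    realized <- numeric(N_EPOCHS)
    for (e in seq_len(N_EPOCHS)) {
      idx <- which(sequences$epoch == e)
      n_e <- length(idx)
      q <- quantize_coherence(coherences[e], n_e)
      congruent <- rep(FALSE, n_e)
      congruent[sample.int(n_e, q$n_congruent)] <- TRUE
      sequences$direction[idx] <- ifelse(congruent, direction, -direction)
      realized[e] <- q$realized
    }

    ## start frequencies and tones
    lo <- freq_range[1]; hi <- freq_range[2]
    u <- stats::runif(nrow(sequences))
    sequences$freq_start <- if (freq_dist == "log") {
      exp(log(lo) + u * (log(hi) - log(lo)))
    } else lo + u * (hi - lo)

    tone_rows <- vector("list", nrow(sequences))
    for (i in seq_len(nrow(sequences))) {
      s <- sequences[i, ]
      n_tones_left <- 5L - s$first_tone
      nominal <- s$onset + (seq_len(n_tones_left) - 1L) * TONE_DUR_S
      keep <- nominal < STIM_DURATION_S
      nominal <- nominal[keep]
      step_idx <- seq(0L, n_tones_left - 1L)[keep]
      freqs <- s$freq_start *
        2 ^ (s$direction * CENTS_STEP * step_idx / 1200)
      jit <- stats::runif(length(nominal), 0, jitter_s)
      tone_rows[[i]] <- data.frame(
        seq_id = i, slot = s$slot,
        freq_hz = freqs,
        onset_s = nominal + jit,
        duration_s = TONE_DUR_S,
        epoch = pmin(floor(nominal / EPOCH_DUR_S) + 1L, N_EPOCHS)
      )
    }
    tones <- do.call(rbind, tone_rows)
    rownames(tones) <- NULL

    structure(list(direction = direction,
                   coherences = coherences,
                   realized_coherences = realized,
                   sequences = sequences,
                   tones = tones,
                   seed = seed),
              class = "soundscape_spec")
  })
}

#' Evidence trace of a soundscape
#'
#' Maps the realized (quantized) per-epoch coherence to the evidence scale:
#' `e = 0.5 + direction * coherence / 2`, so 0.5 is ambiguous, 1 a fully
#' coherent increasing epoch and 0 a fully coherent decreasing epoch.
#'
#' @param spec a `soundscape_spec`.
#' @return numeric vector of 10 evidence values in `[0, 1]`.
#' @export
evidence_trace <- function(spec) {
  stopifnot(inherits(spec, "soundscape_spec"))
  0.5 + spec$direction * spec$realized_coherences / 2
}

# evidence from direction + realized coherence without building a spec;
# the fast path used by the synthetic cohort.
evidence_from_coherence <- function(direction, coherence, n_sequences = 30L) {
  q <- quantize_coherence(coherence, n_sequences)
  0.5 + direction * q$realized / 2
}

#' Render a soundscape to a waveform
#'
#' Sums equal-amplitude pure tones with raised-cosine on/off ramps. Tone
#' level scaling is arbitrary (presentation calibration is out of scope); the
#' waveform is normalized to a peak of 0.9.
#'
#' @param spec a `soundscape_spec` (or any list with a `tones` data frame).
#' @param sample_rate_hz output rate; must be at least twice the highest tone
#'   frequency.
#' @param ramp_s raised-cosine ramp duration (default 5 ms).
#' @return numeric waveform with attributes `sample_rate_hz`.
#' @export
synthesize_waveform <- function(spec, sample_rate_hz = 48000, ramp_s = 0.005) {
  tones <- spec$tones
  n <- ceiling((STIM_DURATION_S + 2 * TONE_DUR_S) * sample_rate_hz)
  wave <- numeric(n)
  if (!is.null(tones) && nrow(tones) > 0) {
    stop_if(max(tones$freq_hz) > sample_rate_hz / 2,
            "tone frequency exceeds Nyquist; raise sample_rate_hz")
    n_tone <- round(TONE_DUR_S * sample_rate_hz)
    tt <- (seq_len(n_tone) - 1) / sample_rate_hz
    n_ramp <- round(ramp_s * sample_rate_hz)
    env <- rep(1, n_tone)
    if (n_ramp > 0) {
      r <- 0.5 * (1 - cos(pi * seq_len(n_ramp) / n_ramp))
      env[seq_len(n_ramp)] <- r
      env[n_tone + 1 - seq_len(n_ramp)] <- r
    }
    for (i in seq_len(nrow(tones))) {
      i0 <- round(tones$onset_s[i] * sample_rate_hz)
      idx <- i0 + seq_len(n_tone)
      idx <- idx[idx <= n]
      wave[idx] <- wave[idx] +
        sin(2 * pi * tones$freq_hz[i] * tt[seq_along(idx)]) * env[seq_along(idx)]
    }
    pk <- max(abs(wave))
    if (pk > 0) wave <- 0.9 * wave / pk
  }
  attr(wave, "sample_rate_hz") <- sample_rate_hz
  wave
}

#' Acoustic temporal modulation spectrum
#'
#' Band-limits each waveform in logarithmically spaced carrier bands, takes
#' the Hilbert envelope magnitude per band, and averages the Fourier
#' amplitude spectra of the envelopes across waveforms.
#'
#' @param waveforms a list of waveforms (as from [synthesize_waveform()]) or
#'   a single waveform.
#' @param sample_rate_hz sampling rate; taken from the waveform attribute if
#'   missing.
#' @param n_bands number of carrier bands (default 10).
#' @param band_lo,band_hi carrier band range in Hz (default 100-12000).
#' @param env_rate_hz rate to which envelopes are decimated before the FFT.
#' @param max_mod_hz highest modulation frequency returned.
#' @return list with `freqs` (modulation frequencies, Hz), `amplitude`
#'   (band x frequency matrix averaged over waveforms) and `band_edges`.
#' @export
modulation_spectrum <- function(waveforms, sample_rate_hz = NULL,
                                n_bands = 10, band_lo = 100, band_hi = 12000,
                                env_rate_hz = 300, max_mod_hz = 30) {
  if (!is.list(waveforms)) waveforms <- list(waveforms)
  stop_if(length(waveforms) < 1, "need at least one waveform")
  fs <- sample_rate_hz %||% attr(waveforms[[1]], "sample_rate_hz")
  stop_if(is.null(fs), "sample_rate_hz not given and not found on waveform")
  edges <- exp(seq(log(band_lo), log(band_hi), length.out = n_bands + 1))
  ds <- max(1L, round(fs / env_rate_hz))
  n_env <- length(seq(1L, length(waveforms[[1]]), by = ds))
  fs_env <- fs / ds
  fgrid <- (seq_len(n_env) - 1) * fs_env / n_env
  keep <- fgrid <= max_mod_hz
  amp <- matrix(0, n_bands, sum(keep))
  for (w in waveforms) {
    n <- length(w)
    stop_if(n < 64, "waveform shorter than filter length")
    ## band-limited analytic signal per carrier band: one-sided spectrum
    ## restricted to the band, so Mod() is the band's Hilbert envelope
    X <- stats::fft(as.numeric(w))
    f_axis <- (seq_len(n) - 1) * fs / n
    for (b in seq_len(n_bands)) {
      mask <- numeric(n)
      sel <- f_axis >= edges[b] & f_axis <= edges[b + 1]  # positive side only
      mask[sel & f_axis <= fs / 2] <- 2
      env <- Mod(stats::fft(X * mask, inverse = TRUE) / n)
      # block-averaged decimation (boxcar anti-aliasing of the envelope)
      if (ds > 1L) {
        m <- floor(length(env) / ds)
        env <- colMeans(matrix(env[seq_len(m * ds)], ds, m))
      }
      env <- env[seq_len(min(length(env), n_env))]
      length(env) <- n_env
      env[is.na(env)] <- 0
      sp <- Mod(stats::fft(env)) / length(env)
      amp[b, ] <- amp[b, ] + sp[keep]
    }
  }
  amp <- amp / length(waveforms)
  list(freqs = fgrid[keep], amplitude = amp, band_edges = edges)
}

#' Serialize / restore a soundscape specification as JSON
#'
#' @param spec a `soundscape_spec`.
#' @param path JSON file path.
#' @return `path` / the restored `soundscape_spec`.
#' @export
write_soundscape_json <- function(spec, path) {
  stopifnot(inherits(spec, "soundscape_spec"))
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_soundscape_json
#' @export
read_soundscape_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$sequences <- as.data.frame(x$sequences)
  x$tones <- as.data.frame(x$tones)
  structure(x, class = "soundscape_spec")
}

# analytic signal x + i H(x) via the one-sided FFT construction
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Peak-to-trend ratio of a modulation spectrum
#'
#' Measures whether a modulation band contains a local spectral peak between
#' `flo` and `fhi` Hz, as the maximal ratio of the spectrum to its running-
#' median trend. Values near 1 indicate a smooth (peak-free) spectrum.
#'
#' @param ms result of [modulation_spectrum()].
#' @param flo,fhi frequency range to screen (default 1-4 Hz).
#' @param k running-median window (odd, default 9).
#' @return maximal ratio over bands and frequencies in range.
#' @export
modspec_peak_ratio <- function(ms, flo = 1, fhi = 4, k = 9) {
  sel <- ms$freqs >= flo & ms$freqs <= fhi
  stopifnot(any(sel))
  ratios <- apply(ms$amplitude, 1, function(a) {
    trend <- stats::runmed(a, k)
    max(a[sel] / pmax(trend[sel], .Machine$double.eps))
  })
  max(ratios)
}

#' Write a waveform as 16-bit PCM WAV
#'
#' Minimal mono PCM writer for exporting generated soundscapes.
#'
#' @param wave numeric waveform in `[-1, 1]`.
#' @param path output file.
#' @param sample_rate_hz sampling rate; taken from the waveform attribute if
#'   missing.
#' @return `path`, invisibly.
#' @export
write_wav <- function(wave, path, sample_rate_hz = NULL) {
  fs <- sample_rate_hz %||% attr(wave, "sample_rate_hz")
  stop_if(is.null(fs), "sample_rate_hz required")
  pcm <- as.integer(round(pmax(-1, pmin(1, as.numeric(wave))) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * length(pcm)), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")  # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * length(pcm)), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
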