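# Tone-cloud generation: coherence realization, evidence mapping, waveform
# synthesis and modulation spectra.

test_that("requested coherence is realized up to counting quantization", {
  set.seed(1)
  for (r in 1:100) {
    d <- sample(c(-1, 1), 1)
    coh <- runif(10)
    sp <- generate_soundscape(d, coh, seed = r)
    expect_true(all(abs(sp$realized_coherences - coh) <= 1 / 30 + 1e-12))
    ev <- evidence_trace(sp)
    expect_true(all(ev >= 0 & ev <= 1))
    # evidence is an involution under direction flip on the same coherences
    sp2 <- generate_soundscape(-d, coh, seed = r)
    expect_equal(evidence_trace(sp) + evidence_trace(sp2), rep(1, 10),
                 tolerance = 1 / 15)
  }
})

test_that("fully coherent and ambiguous soundscapes hit the evidence anchors", {
  up <- generate_soundscape(1, rep(1, 10), seed = 2)
  expect_equal(evidence_trace(up), rep(1, 10))
  expect_true(all(up$sequences$direction == 1))
  dn <- generate_soundscape(-1, rep(1, 10), seed = 2)
  expect_equal(evidence_trace(dn), rep(0, 10))
  amb <- generate_soundscape(1, rep(0, 10), seed = 3)
  expect_equal(evidence_trace(amb), rep(0.5, 10))
  # half the sequences sweep each way in every epoch (up to rounding)
  for (e in 1:10) {
    sel <- amb$sequences$epoch == e
    expect_lte(abs(sum(amb$sequences$direction[sel] == 1) -
                     sum(amb$sequences$direction[sel] == -1)), 1)
  }
})

test_that("soundscape generation is deterministic under a fixed seed", {
  a <- generate_soundscape(1, runif(10), seed = 99)
  b <- generate_soundscape(1, a$coherences, seed = 99)
  expect_identical(a, b)
})

test_that("soundscape geometry respects the tone grammar", {
  sp <- generate_soundscape(1, rep(0.5, 10), seed = 4)
  # frequency range: start in [128, 16384], at most 3 steps of 20 cents out
  lim <- c(128 * 2^(-60 / 1200), 16384 * 2^(60 / 1200))
  expect_true(all(sp$tones$freq_hz >= lim[1] & sp$tones$freq_hz <= lim[2]))
  # tones end within the jitter allowance
  expect_true(all(sp$tones$onset_s + sp$tones$duration_s <= 1.23 + 1e-9))
  # each sequence steps monotonically in its direction
  for (i in sample(unique(sp$tones$seq_id), 20)) {
    f <- sp$tones$freq_hz[sp$tones$seq_id == i]
    if (length(f) > 1) {
      s <- sp$sequences$direction[i]
      expect_true(all(diff(f) * s > 0))
      expect_equal(f[-1] / f[-length(f)], rep(2^(s * 20 / 1200),
                                              length(f) - 1))
    }
  }
})

test_that("invalid soundscape requests are rejected", {
  expect_error(generate_soundscape(1, rep(1.2, 10)), "\\[0, 1\\]")
  expect_error(generate_soundscape(0, rep(0.5, 10)), "direction")
  expect_error(generate_soundscape(1, rep(0.5, 10), n_sequences = 1),
               "at least 2")
  expect_error(quantize_coherence(-0.1), "\\[0, 1\\]")
})

test_that("waveform synthesis produces the expected spectra", {
  # single 1 kHz tone: spectral peak at 1 kHz
  spec <- list(tones = data.frame(seq_id = 1, slot = 1, freq_hz = 1000,
                                  onset_s = 0.2, duration_s = 0.03,
                                  epoch = 2))
  w <- synthesize_waveform(spec, sample_rate_hz = 48000)
  n <- length(w)
  amp <- Mod(stats::fft(as.numeric(w)))[1:(n / 2)]
  fgrid <- (0:(n / 2 - 1)) * 48000 / n
  expect_lt(abs(fgrid[which.max(amp)] - 1000), 50)
  # empty tone list: all-zero waveform
  w0 <- synthesize_waveform(list(tones = NULL), sample_rate_hz = 48000)
  expect_true(all(w0 == 0))
  # full soundscape: finite, non-degenerate
  sp <- generate_soundscape(1, rep(0.5, 10), seed = 5)
  wf <- synthesize_waveform(sp, sample_rate_hz = 44100)
  expect_true(all(is.finite(wf)))
  expect_gt(sqrt(mean(wf^2)), 0)
  # aliasing guarded
  expect_error(synthesize_waveform(sp, sample_rate_hz = 8000), "Nyquist")
})

test_that("modulation spectrum localizes envelope rhythms", {
  fs <- 24000
  tt <- seq(0, 1.5, by = 1 / fs)
  # constant-envelope pure tone: energy concentrated at 0 Hz
  tone <- sin(2 * pi * 1000 * tt)
  ms <- modulation_spectrum(tone, sample_rate_hz = fs, band_lo = 200,
                            band_hi = 4000, n_bands = 4)
  band <- which.max(rowSums(ms$amplitude))
  expect_equal(which.max(ms$amplitude[band, ]), 1L)  # DC bin
  # 4 Hz AM noise: peak at 4 Hz in the containing band
  set.seed(8)
  noise <- rnorm(length(tt))
  am <- noise * (1 + 0.9 * sin(2 * pi * 4 * tt))
  ms2 <- modulation_spectrum(am, sample_rate_hz = fs, band_lo = 200,
                             band_hi = 4000, n_bands = 4)
  nz <- ms2$freqs > 1   # exclude DC
  peak_f <- ms2$freqs[nz][which.max(colSums(ms2$amplitude)[nz])]
  expect_lt(abs(peak_f - 4), 1)
  expect_error(modulation_spectrum(rnorm(5), sample_rate_hz = fs),
               "shorter")
})

test_that("soundscape specs round-trip through JSON", {
  sp <- generate_soundscape(-1, runif(10), seed = 31)
  path <- tempfile(fileext = ".json")
  write_soundscape_json(sp, path)
  back <- read_soundscape_json(path)
  expect_equal(back$realized_coherences, sp$realized_coherences)
  expect_equal(back$tones$freq_hz, sp$tones$freq_hz, tolerance = 1e-12)
  expect_equal(evidence_trace(back), evidence_trace(sp))
})
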