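---
title: "Rhythmic perceptual sampling and pre-stimulus brain state: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rhythmic perceptual sampling and pre-stimulus brain state: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the science it implements:
the generative model behind the synthetic cohort, the estimators and
statistics, the parameters that matter and why their defaults are what they
are, and what the passing test suite does and does not establish about real
data.

## The task and the stimulus

An observer hears a 1.2 s "tone cloud": 30 simultaneous sequences of four
30 ms tones, each sequence sweeping up or down in 20-cent steps from a
random (log-uniform, 128–16384 Hz) start frequency, and judges the overall
sweep direction. The stimulus is divided into ten 120 ms epochs. The
epoch's *coherence* — the excess proportion of direction-congruent
sequences — is set independently per epoch, so the momentary evidence

$$e_t = \tfrac12 + d\,\tfrac{c_t}{2}, \qquad t = 1,\dots,10$$

fluctuates within a trial around the observer's threshold. Sequences live
in 30 slots; the initial sequences are entered at a random tone position
(1–4) and a finished sequence is immediately replaced, so each slot starts
one sequence per epoch and each epoch's coherence is realized exactly out
of 30 sequences. This quantizes coherence to steps of 1/15; all simulation
fast paths apply the same quantization so that generated evidence equals
what rendered audio would convey. The modulation spectra of rendered
soundscapes are flat at 1–4 Hz (tested: no local peak exceeds 1.2× the
running-median trend), so any rhythmicity found in behavior is not
inherited from the stimulus.

## The generative observer

The observer weighs evidence linearly and decides by sign:

$$D = \sum_t w_t\,(e_t - \tfrac12) + \varepsilon,\qquad
\varepsilon \sim \mathcal N(0, \sigma^2),\qquad
\text{choice} = \mathrm{sign}(D),$$

with epoch weights

$$w_t = w_0 + w_\ell\,\ell(t) + w_{uv}\cos(2\pi t/T)
      + a\,\cos(2\pi f t - \varphi),$$

where $\ell(t)$ is the zero-mean unit-SD ramp, $T = 1.2$ s, and the
rhythmic phase is coupled to the trial's pre-stimulus oscillatory state:

$$\varphi = \varphi_0 + g_\theta\,\theta + g_P\,L,$$

with $\theta$ the oscillation phase at $-0.32$ s and $L$ the trial's
log-power. The decision noise itself may depend on the state,
$\sigma_{\text{trial}} = \sigma\,e^{-g_{acc}L - h_{acc}\cos\theta}$, which
is what makes pre-stimulus power and phase predictive of accuracy (the
substrate of the first-pass time-point selection).

The probit form was chosen because it makes the reverse-correlation
estimator unbiased for the weight *shape*: the response-conditioned
evidence difference is proportional to $w_t$ under this model.

### Calibration of the defaults

The defaults were fixed once, from the study's design conditions, before
the acceptance assertions were frozen:

- `decision_noise_sd = 2.9` places the constant-coherence 70.7%-correct
  point of the default observer at ≈0.32 coherence, so the 2-down-1-up
  staircases (starts 0.15/0.4/0.8, step 0.1, mean of six reversals after
  discarding four, averaged over three staircases) return cohort-mean
  thresholds of ≈0.32 and the threshold-centered test trials land at
  ≈0.72 fraction correct (the truncation of N(threshold, 0.2) to [0, 1]
  by resampling adds ≈+0.023 mean coherence, hence the excess over
  70.7%). Median d′ then falls near 1.17 and the criterion near 0 for
  these bias-free observers.
- The staircase step stays constant at 0.1 (`n_halvings = 0`). With the
  stimulus's own 1/15 coherence quantization, steps far below the grid
  cannot equilibrate — the track freezes wherever the initial transient
  left it and the threshold estimate is biased upward by ≈0.05. A step
  comparable to the grid converges to the 70.7% point without bias; the
  halving schedule remains configurable.
- `rhythm_amp = 3` (in units of the mean weight) makes the implanted
  rhythm "strong relative to the decision noise": its z-scored amplitude
  in recovered weight profiles is ≈2, and in a pre-freeze calibration
  sweep this was the smallest amplitude at which the 0.1 Hz evidence-scan
  argmax was stable across replicate cohorts (15/15 at amplitude 3 vs
  12/15 at amplitude 2).
- `phase_coupling_gain = 0.5` rad/rad implants a 90° shift of the
  weighting phase between opposing EEG-phase bins (uniform phases in the
  two half-planes average at ±π/2, so the between-bin shift is the gain
  times π). Much larger gains wrap the trial-wise phase around the circle,
  which destroys both the global rhythm (resultant attenuation) and the
  detectability of the shift itself — the implant would erase the very
  signature it is meant to produce.
- `power_coupling_gain = 1.65` rad per log-power unit puts the power
  median-split shift at ≈75° (the expected split difference of the
  log-power state is 2·0.4 with `trial_log_power_sd = 0.5`).
- The EEG oscillation (4 Hz, amplitude 2× the unit 1/f background on the
  strongest channels, Gaussian temporal envelope centered at −0.32 s with
  SD 0.2 s) concentrates its expression — and therefore the
  power/phase–behavior association — around the reference time point, so
  the first-pass selection has something to find. Without the envelope the
  oscillation is coherent across the whole window and the selected time
  would be arbitrary (every time point carries the same phase information,
  rotated deterministically).

Two cohort regimes are used deliberately. The *global* analyses (weight
profiles, frequency scan, exceedance) assume a trial-stable weighting
phase — exactly the assumption the reverse-correlation estimator makes —
so their cohorts set the state couplings to zero. The *linkage* analyses
use the coupled defaults. Amplitudes and noise are identical in both.

## Estimators

**Reverse correlation.** Per epoch, the mean-evidence difference between
"up" and "down" responses is computed within each true sweep direction and
averaged (removing the direction-induced evidence offset; the pooled
variant is available via `contrast = "pooled"`). The difference is
z-scored against 4000 permutations of the response labels within direction
subsets. Permutations are derived from per-trial uniform keys drawn before
the direction split, which makes the z-profile exactly invariant to
relabeling up↔down together with reflecting the evidence — a property the
tests assert bit-exactly. Binned re-estimation drops bins under 50 trials
with a warning rather than filling them silently.

**Bayesian weight models.** With the design $X$ (offset; zero-mean unit-SD
ramp; $\cos 2\pi t/T$; optionally $\sin 2\pi f t$, $\cos 2\pi f t$), the
model is $y \sim \mathcal N(X\beta, s^2 I)$ with ridge prior
$\beta \mid s^2 \sim \mathcal N(0, s^2/\lambda\, I)$, $\lambda = 1$ on
these near-unit-scale regressors (a unit-information prior), and Jeffreys
$p(s^2) \propto 1/s^2$. The marginal likelihood is closed-form,

$$\log p(y) = \log\Gamma(\tfrac n2) - \tfrac n2\log\pi
 - \tfrac12\log\frac{|X^\top X + \lambda I|}{\lambda^p}
 - \tfrac n2 \log\!\big(y^\top y - y^\top X (X^\top X + \lambda I)^{-1} X^\top y\big),$$

verified against two-dimensional adaptive quadrature to 1e-6 on a toy
problem. The improper noise prior is shared by both models, so model
comparison is well defined. No source names a prior for this regression;
robustness is therefore tested, not assumed: the frequency-scan argmax is
unchanged under λ×{0.1, 10}. Group evidence sums over participants;
exceedance probability bootstraps participants (10 000 draws); WAIC comes
from a two-chain Gibbs sampler over the same conjugate model (split-Rhat
guarded), with the variance-based penalty. Note one consequence of the
Occam penalty: on pure-noise profiles the *fixed-frequency* rhythmic model
loses evidence on average, while at the *scanned best* frequency the
maximization over the 1.1–4 Hz grid offsets the penalty and the bootstrap
exceedance hovers near indifference — the null behavior the tests pin.

**Time–frequency analysis.** Zero-phase Butterworth filtering was chosen
so pre-stimulus phase is not lag-shifted (filter direction is an analysis
choice, not a datum). The pre-stimulus window is replaced by a
mirror–original–mirror triple so 4-cycle Morlet estimates (2–13 Hz,
energy-normalized; normalization is scale-free for every downstream
median-split and phase statistic, asserted by a scale-invariance test) are
uncontaminated by post-onset activity: with mirroring, a large post-onset
step changes pre-stimulus power estimates by exactly nothing, and the
phase at −0.32 s by < 0.05 rad.

**Selection and binning.** The first pass median-splits power per channel
× frequency × time against the fraction correct (group t-test), and
contrasts correct/incorrect phase distributions with the phase opposition
sum (POS = ITC₁ + ITC₂ − 2·ITC_all), per-participant permutation p-values
combined by Stouffer. The time with the most significant channels (p <
0.05, summed over frequencies; ties to the earliest time) defines the
power window (±100 ms) and the phase time point. Because the wavelet
integrates ≈1 s at 4 Hz, the selected time recovers the implanted −0.32 s
only up to that smoothing; the tests require it to fall within the
oscillation's envelope (±0.15 s), not within one sample.

**Group statistics.** Signed contrasts (power bins) use one-sample t maps
thresholded two-sided at p < 0.05, clustered over channel adjacency and
neighboring frequencies (both modes available), max-sum mass, minimum
cluster size 2, sign-flip null (2000 permutations by default), p = (1 +
#null ≥ obs)/(1 + n_perm). Absolute contrasts with max-over-four-divisions
selection use a null that re-runs the entire selection pipeline on
permuted trial–behavior pairings, cells above the per-cell 95th null
percentile are clustered, and cluster exceedance mass is compared to the
null maximum. The selection inflates the naive null (the expected absolute
circular difference of unrelated phases is already 90°, and the max over
divisions pushes it higher); re-running the selection inside the null
absorbs this, which the type-I calibration tests verify. BH-FDR at q =
0.01 is applied within each contrast family — behavior-by-power {d′, c},
weights-by-power, behavior-by-phase, weights-by-phase — with each contrast
entering at the p-value of its strongest cluster (cluster inference is
already max-corrected within a contrast; pooling all clusters of all
contrasts would make a single true discovery unable to clear q = 0.01 at
permutation resolution).

## Numerical choices and degenerate inputs

- Coherence quantization rounds half away from zero toward the requested
  count; realized coherence is always within 1/30 of the request.
- SDT rates are clamped to [1/(2N), 1 − 1/(2N)] (log-linear correction
  available) so d′ and c stay finite.
- Power splits break ties by trial order; constant power is an error, not
  a silent 0/100 split.
- Phases are wrapped to (−π, π]; the rhythm phase is undefined (error)
  below an amplitude floor of 1e-10.
- Permutation p-values use the add-one rule, so their resolution is
  1/(n_perm + 1); Stouffer inputs are clamped accordingly.
- Every stochastic function takes a seed; cohort simulation derives
  per-participant, per-stage sub-seeds from the master seed (`derive_seed`),
  so the ground-truth ledger regenerates any sub-stream bit-identically.

## Problem sizes used by the test suite

The cohort-scale tests run the design at 20 participants × 1000 trials.
The EEG-linked pipeline demo uses a 16-channel (4×4 grid) montage sampled
at 150 Hz with the Morlet grid at 2–8 Hz, 500-shuffle weight z-scores,
200 POS permutations, 500 recompute permutations for the selection nulls
and 500–1000 sign-flip permutations — problem sizes chosen so the whole
suite exercises every stage at full trial counts while remaining
comfortable on a single CPU; function defaults keep the full 64-channel,
2–13 Hz, 4000-shuffle settings. Type-I calibrations use 150–200 null
replicates at reduced permutation counts (the validity bound
P(p ≤ α) ≤ α + 1/(n_perm+1) is what is asserted, with a binomial margin).

## What the synthetic cohort does and does not establish

The generator emulates the study's design dimensions (trial counts,
staircase rule, threshold-centered evidence sampling), a rhythmic
weighting process with realistic effect scale, and an oscillatory EEG
state with 1/f background whose phase/power lawfully shift the weighting
phase and modulate accuracy. It does not emulate volume conduction from
realistic sources, artifacts (blinks, muscle; the ±175 µV screen and the
documented ICA/bad-channel hooks are exercised on synthetic artifacts
only), non-stationary oscillation frequency, or between-participant
heterogeneity beyond parameter jitter. Passing tests therefore establish
that the estimators and statistics are correct and calibrated under the
stated generative model — not that real EEG satisfies that model. The
(implemented) across-participant rank correlation of power- and
phase-linked effect strengths, for instance, is only meaningful on real
cohorts with genuine individual differences.

## Known limitations

- The evidence-scan grid (0.1 Hz) and the 10-epoch profile limit frequency
  resolution; neighboring-bin confusions (2.1/2.3 Hz) are the dominant
  replicate-to-replicate variability of the argmax.
- The max-over-division phase-shift estimate is selection-biased upward by
  construction; the package therefore also reports the fixed-division
  estimate, which is the one to compare against ground truth.
- Bins halve (or quarter) trial counts; below 50 trials a bin is dropped.
- The recompute-style nulls are the computational bottleneck; their
  permutation counts trade resolution (1/(n_perm+1)) against runtime.
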