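## Synthetic cohort: probit observers with a rhythmic temporal weighting
## profile whose phase is coupled to a simulated pre-stimulus EEG
## oscillation, adaptive staircase thresholding, and multi-channel EEG
## epochs with 1/f background noise.

#' Epoch centers of the weighting profile
#'
#' @param n_epochs number of epochs (default 10).
#' @param duration stimulus duration in seconds (default 1.2).
#' @return epoch-center times in seconds.
#' @export
epoch_centers <- function(n_epochs = 10L, duration = 1.2) {
  dt <- duration / n_epochs
  (seq_len(n_epochs) - 0.5) * dt
}

#' Parametric temporal-weighting observer
#'
#' The observer weighs the evidence of epoch `t` by
#' `w(t) = w_offset + w_linear * l(t) + w_uv * cos(2 pi t / duration) +
#' rhythm_amp * cos(2 pi rhythm_freq_hz t - phi)`, where `l(t)` is the
#' zero-mean unit-SD linear ramp and the rhythmic phase
#' `phi = rhythm_phase0 + phase_coupling_gain * eeg_phase +
#' power_coupling_gain * eeg_log_power` shifts trial by trial with the
#' pre-stimulus oscillatory state. The decision variable is the weighted sum
#' of evidence (relative to the 0.5 ambiguity point) plus Gaussian noise;
#' `power_accuracy_gain`/`phase_accuracy_gain` let the noise SD itself
#' depend on the oscillatory state (excitability), which is what makes
#' pre-stimulus power and phase predictive of accuracy.
#'
#' @param w_offset,w_linear,w_uv trivial weight components (weight units).
#' @param rhythm_amp rhythmic component amplitude (weight units, >= 0).
#' @param rhythm_freq_hz rhythm frequency; must lie in (0, 4.17] Hz, the
#'   Nyquist range of the 120 ms epoch grid.
#' @param rhythm_phase0 baseline rhythm phase (radians).
#' @param decision_noise_sd decision noise SD (> 0).
#' @param phase_coupling_gain radians of weighting-phase shift per radian of
#'   pre-stimulus oscillation phase.
#' @param power_coupling_gain radians of weighting-phase shift per unit of
#'   trial log-power.
#' @param power_accuracy_gain,phase_accuracy_gain log-scale modulation of the
#'   decision noise by trial log-power / oscillation phase.
#' @param phase_accuracy_pref phase at which the noise is lowest.
#' @return an `observer_params` object.
#' @export
observer_params <- function(w_offset = 1, w_linear = -0.23, w_uv = 0.006,
                            rhythm_amp = 3, rhythm_freq_hz = 2.2,
                            rhythm_phase0 = 0.5,
                            decision_noise_sd = 2.9,
                            phase_coupling_gain = 0,
                            power_coupling_gain = 0,
                            power_accuracy_gain = 0,
                            phase_accuracy_gain = 0,
                            phase_accuracy_pref = 0) {
  vals <- c(w_offset, w_linear, w_uv, rhythm_amp, rhythm_freq_hz,
            rhythm_phase0, decision_noise_sd, phase_coupling_gain,
            power_coupling_gain)
  stop_if(!all(is.finite(vals)), "observer parameters must be finite")
  stop_if(rhythm_amp < 0, "rhythm_amp must be >= 0")
  stop_if(decision_noise_sd <= 0, "decision_noise_sd must be > 0")
  stop_if(rhythm_freq_hz <= 0 || rhythm_freq_hz > 1 / (2 * 0.12),
          "rhythm_freq_hz outside (0, 4.17] Hz (epoch Nyquist)")
  structure(list(w_offset = w_offset, w_linear = w_linear, w_uv = w_uv,
                 rhythm_amp = rhythm_amp, rhythm_freq_hz = rhythm_freq_hz,
                 rhythm_phase0 = rhythm_phase0,
                 decision_noise_sd = decision_noise_sd,
                 phase_coupling_gain = phase_coupling_gain,
                 power_coupling_gain = power_coupling_gain,
                 power_accuracy_gain = power_accuracy_gain,
                 phase_accuracy_gain = phase_accuracy_gain,
                 phase_accuracy_pref = phase_accuracy_pref),
            class = "observer_params")
}

#' Trial weights of an observer
#'
#' @param obs an [observer_params()] object.
#' @param eeg_phase,eeg_log_power pre-stimulus oscillatory state of the trial.
#' @param n_epochs,duration weighting grid (defaults 10 epochs over 1.2 s).
#' @return numeric vector of epoch weights.
#' @export
observer_weights <- function(obs, eeg_phase = 0, eeg_log_power = 0,
                             n_epochs = 10L, duration = 1.2) {
  t <- epoch_centers(n_epochs, duration)
  lin <- (t - mean(t)) / stats::sd(t)
  phi <- obs$rhythm_phase0 + obs$phase_coupling_gain * eeg_phase +
    obs$power_coupling_gain * eeg_log_power
  obs$w_offset + obs$w_linear * lin + obs$w_uv * cos(2 * pi * t / duration) +
    obs$rhythm_amp * cos(2 * pi * obs$rhythm_freq_hz * t - phi)
}

# per-trial decision noise SD given the oscillatory state
observer_noise_sd <- function(obs, eeg_phase = 0, eeg_log_power = 0) {
  obs$decision_noise_sd * exp(
    -obs$power_accuracy_gain * eeg_log_power -
      obs$phase_accuracy_gain * cos(eeg_phase - obs$phase_accuracy_pref))
}

#' Simulate the observer's response to one or many trials
#'
#' Forms the decision variable `D = sum_t w_t (e_t - 0.5) + noise` and
#' responds "up" (+1) when `D > 0`.
#'
#' @param evidence numeric vector of 10 evidence values, or an
#'   `n_trials x n_epochs` matrix.
#' @param obs an [observer_params()] object.
#' @param eeg_phase,eeg_log_power per-trial oscillatory state (recycled).
#' @param seed optional seed for the decision noise.
#' @param duration stimulus duration in seconds.
#' @return list with `choice` (+1 up / -1 down) and `decision_variable`.
#' @export
simulate_response <- function(evidence, obs, eeg_phase = 0,
                              eeg_log_power = 0, seed = NULL,
                              duration = 1.2) {
  E <- if (is.matrix(evidence)) evidence else matrix(evidence, nrow = 1)
  stop_if(!all(is.finite(E)), "evidence must be finite")
  n <- nrow(E)
  t <- epoch_centers(ncol(E), duration)
  lin <- (t - mean(t)) / stats::sd(t)
  base <- obs$w_offset + obs$w_linear * lin +
    obs$w_uv * cos(2 * pi * t / duration)
  phi <- obs$rhythm_phase0 + obs$phase_coupling_gain * rep_len(eeg_phase, n) +
    obs$power_coupling_gain * rep_len(eeg_log_power, n)
  Ec <- E - 0.5
  d_base <- as.numeric(Ec %*% base)
  cvec <- cos(2 * pi * obs$rhythm_freq_hz * t)
  svec <- sin(2 * pi * obs$rhythm_freq_hz * t)
  d_rhythm <- obs$rhythm_amp *
    (as.numeric(Ec %*% cvec) * cos(phi) + as.numeric(Ec %*% svec) * sin(phi))
  sds <- observer_noise_sd(obs, rep_len(eeg_phase, n),
                           rep_len(eeg_log_power, n))
  D <- with_seed(seed, d_base + d_rhythm + stats::rnorm(n, 0, sds))
  list(choice = ifelse(D > 0, 1, -1), decision_variable = D)
}

#' Staircase configuration
#'
#' Three interleaved 2-down-1-up staircases varying the coherence; the
#' threshold is the mean of six reversals per staircase after discarding the
#' first four, averaged over staircases. The step halves at each of the first
#' `n_halvings` reversals and is constant thereafter.
#'
#' @param starts initial coherences of the staircases.
#' @param initial_step initial coherence step.
#' @param n_reversals_used,n_reversals_discarded reversal bookkeeping.
#' @param n_halvings number of initial reversals at which the step halves.
#' @param max_trials per-staircase trial budget.
#' @return a `staircase_config` object.
#' @export
staircase_config <- function(starts = c(0.15, 0.4, 0.8), initial_step = 0.1,
                             n_reversals_used = 6L,
                             n_reversals_discarded = 4L,
                             n_halvings = 0L, max_trials = 1000L) {
  structure(list(rule = "2-down-1-up", starts = starts,
                 initial_step = initial_step,
                 n_reversals_used = as.integer(n_reversals_used),
                 n_reversals_discarded = as.integer(n_reversals_discarded),
                 n_halvings = as.integer(n_halvings),
                 max_trials = as.integer(max_trials)),
            class = "staircase_config")
}

# default distribution of oscillatory trial states (uniform phase,
# Gaussian log-power); also used by the cohort simulator.
draw_trial_states <- function(n, log_power_sd = 0.5) {
  list(phase = stats::runif(n, -pi, pi),
       log_power = stats::rnorm(n, 0, log_power_sd))
}

#' Estimate an observer's coherence threshold by adaptive staircases
#'
#' Runs interleaved 2-down-1-up staircases presenting constant-coherence
#' soundscapes (quantized to the 30-sequence grid) and returns the mean of
#' the used reversals, averaged over staircases. Converges near the 70.7
#' percent correct point of the observer's psychometric function.
#'
#' @param obs an [observer_params()] object, or a function
#'   `(coherence) -> logical` returning whether a trial at that coherence is
#'   answered correctly (useful for testing arbitrary psychometric rules).
#' @param config a [staircase_config()].
#' @param seed integer seed.
#' @param n_sequences sequence count defining coherence quantization.
#' @param log_power_sd SD of the trial log-power states during the staircase.
#' @return list with `threshold`, per-staircase `thresholds`, and the
#'   reversal coherences per staircase.
#' @export
run_staircases <- function(obs, config = staircase_config(), seed = NULL,
                           n_sequences = 30L, log_power_sd = 0.5) {
  n_rev_needed <- config$n_reversals_used + config$n_reversals_discarded
  with_seed(seed, {
    res <- lapply(seq_along(config$starts), function(k) {
      level <- config$starts[k]
      step <- config$initial_step
      n_correct_run <- 0L
      last_move <- 0  # -1 down, +1 up
      reversals <- numeric(0)
      for (trial in seq_len(config$max_trials)) {
        if (is.function(obs)) {
          correct <- isTRUE(obs(level))
        } else {
          d <- sample(c(-1, 1), 1)
          ev <- evidence_from_coherence(d, rep(level, N_EPOCHS), n_sequences)
          st <- draw_trial_states(1, log_power_sd)
          resp <- simulate_response(matrix(ev, 1), obs,
                                    eeg_phase = st$phase,
                                    eeg_log_power = st$log_power)
          correct <- resp$choice == d
        }
        move <- 0
        if (correct) {
          n_correct_run <- n_correct_run + 1L
          if (n_correct_run >= 2L) {
            move <- -1
            n_correct_run <- 0L
          }
        } else {
          move <- +1
          n_correct_run <- 0L
        }
        if (move != 0) {
          if (last_move != 0 && move != last_move) {
            reversals <- c(reversals, level)
            if (length(reversals) <= config$n_halvings) step <- step / 2
            if (length(reversals) >= n_rev_needed) break
          }
          last_move <- move
          level <- min(1, max(0, level + move * step))
        }
      }
      stop_if(length(reversals) < n_rev_needed,
              sprintf("staircase %d: only %d reversals in %d trials",
                      k, length(reversals), config$max_trials))
      used <- reversals[(config$n_reversals_discarded + 1):n_rev_needed]
      list(threshold = mean(used), reversals = reversals)
    })
    ths <- vapply(res, `[[`, numeric(1), "threshold")
    list(threshold = mean(ths), thresholds = ths,
         reversals = lapply(res, `[[`, "reversals"))
  })
}

#' Parameters of the synthetic EEG generator
#'
#' Pre-stimulus epochs contain a narrow-band oscillation (default 4 Hz) whose
#' trial-wise phase (referenced at `phase_ref_s`) and log-power are the
#' ground-truth states coupled into the observer, on top of 1/f Gaussian
#' background noise. The oscillation has a Gaussian temporal envelope
#' centered pre-stimulus so its expression is localized in time.
#'
#' @param n_channels number of channels; must be a perfect square (channels
#'   live on a square grid montage).
#' @param sample_rate_hz sampling rate of the generated epochs.
#' @param osc_freq_hz oscillation frequency in `[2, 13]` Hz.
#' @param osc_amp oscillation amplitude (times the per-channel topography
#'   gain) in the same units as the noise SD.
#' @param osc_topography per-channel gains; default a Gaussian bump on the
#'   grid via [grid_topography()].
#' @param noise_exponent spectral slope of the background (power ~ 1/f^exp).
#' @param noise_sd per-channel background RMS.
#' @param envelope `"gaussian"` (default) or `"constant"` temporal envelope.
#' @param env_center_s,env_sd_s Gaussian envelope center and width.
#' @param phase_ref_s time at which the trial phase is referenced.
#' @param trial_log_power_sd SD of the trial-wise log-power state.
#' @param evoked_amp amplitude of an optional post-onset evoked bump.
#' @return an `eeg_sim_params` object.
#' @export
eeg_sim_params <- function(n_channels = 64L, sample_rate_hz = 150,
                           osc_freq_hz = 4, osc_amp = 2,
                           osc_topography = NULL,
                           noise_exponent = 1.5, noise_sd = 1,
                           envelope = c("gaussian", "constant"),
                           env_center_s = -0.32, env_sd_s = 0.2,
                           phase_ref_s = -0.32,
                           trial_log_power_sd = 0.5,
                           evoked_amp = 0) {
  envelope <- match.arg(envelope)
  stop_if(osc_freq_hz < 2 || osc_freq_hz > 13,
          "osc_freq_hz must lie in [2, 13]")
  side <- sqrt(n_channels)
  stop_if(side != round(side),
          "n_channels must be a perfect square (grid montage)")
  topo <- osc_topography %||% grid_topography(n_channels)
  stop_if(!all(is.finite(topo)) || length(topo) != n_channels,
          "osc_topography must give one finite gain per channel")
  structure(list(n_channels = as.integer(n_channels),
                 sample_rate_hz = sample_rate_hz,
                 osc_freq_hz = osc_freq_hz, osc_amp = osc_amp,
                 osc_topography = topo,
                 noise_exponent = noise_exponent, noise_sd = noise_sd,
                 envelope = envelope, env_center_s = env_center_s,
                 env_sd_s = env_sd_s, phase_ref_s = phase_ref_s,
                 trial_log_power_sd = trial_log_power_sd,
                 evoked_amp = evoked_amp),
            class = "eeg_sim_params")
}

#' Gaussian topography on a square grid montage
#'
#' @param n_channels perfect-square channel count.
#' @param center bump center in relative grid coordinates (0-1).
#' @param width bump SD in relative coordinates.
#' @return per-channel gains in `[0, 1]`.
#' @export
grid_topography <- function(n_channels = 64L, center = c(0.35, 0.35),
                            width = 0.22) {
  side <- as.integer(round(sqrt(n_channels)))
  stopifnot(side * side == n_channels)
  gx <- (rep(seq_len(side), side) - 1) / (side - 1)
  gy <- (rep(seq_len(side), each = side) - 1) / (side - 1)
  exp(-((gx - center[1])^2 + (gy - center[2])^2) / (2 * width^2))
}

# 1/f^exponent Gaussian noise, one column per signal; returns n x m matrix
# with unit RMS columns scaled to `sd`.
pink_noise <- function(n, m, exponent, sd = 1) {
  f <- c(1, seq_len(n - 1))  # avoid 0 division; DC handled below
  f <- pmin(f, n - f + 1)    # symmetric frequency index
  shape <- f ^ (-exponent / 2)
  shape[1] <- 0              # no DC
  spec <- matrix(stats::rnorm(n * m), n, m) +
    1i * matrix(stats::rnorm(n * m), n, m)
  spec <- spec * shape
  x <- Re(stats::mvfft(spec, inverse = TRUE)) / n
  rms <- sqrt(colMeans(x^2))
  sweep(x, 2, rms / sd, "/")
}

#' Simulate pre-stimulus EEG epochs
#'
#' Generates `n_trials` epochs of `n_channels x time` covering
#' `t_range` around stimulus onset: oscillation (amplitude scaled by
#' `exp(log_power/2)` per trial and the channel topography) plus independent
#' 1/f noise per channel, plus an optional evoked bump after onset.
#'
#' @param params an [eeg_sim_params()] object.
#' @param trial_phase per-trial oscillation phase at `params$phase_ref_s`.
#' @param trial_log_power per-trial log-power state.
#' @param seed integer seed for the background noise.
#' @param t_range epoch time range in seconds relative to onset.
#' @return an [epoched_eeg()] object with the trial states attached as
#'   attributes `trial_phase` and `trial_log_power`.
#' @export
simulate_eeg_epochs <- function(params, trial_phase, trial_log_power = NULL,
                                seed = NULL, t_range = c(-1.1, 1.3)) {
  n_trials <- length(trial_phase)
  trial_log_power <- trial_log_power %||% rep(0, n_trials)
  fs <- params$sample_rate_hz
  times <- seq(t_range[1], t_range[2], by = 1 / fs)
  nt <- length(times)
  nc <- params$n_channels
  env <- switch(params$envelope,
                gaussian = exp(-(times - params$env_center_s)^2 /
                                 (2 * params$env_sd_s^2)),
                constant = rep(1, nt))
  osc <- vapply(seq_len(n_trials), function(i) {
    params$osc_amp * exp(trial_log_power[i] / 2) * env *
      cos(2 * pi * params$osc_freq_hz * (times - params$phase_ref_s) +
            trial_phase[i])
  }, numeric(nt))                       # time x trial
  data <- with_seed(seed, {
    noise <- if (params$noise_sd > 0) {
      pink_noise(nt, n_trials * nc, params$noise_exponent, params$noise_sd)
    } else matrix(0, nt, n_trials * nc)
    arr <- array(noise, dim = c(nt, n_trials, nc))
    for (ch in seq_len(nc)) {
      arr[, , ch] <- arr[, , ch] + osc * params$osc_topography[ch]
    }
    if (params$evoked_amp > 0) {
      evoked <- params$evoked_amp * exp(-(times - 0.2)^2 / (2 * 0.05^2)) *
        (times > 0)
      arr <- arr + outer(evoked, rep(1, n_trials)) %o% params$osc_topography
    }
    aperm(arr, c(2, 3, 1))              # trial x channel x time
  })
  ee <- epoched_eeg(data, times, fs,
                    ch_names = sprintf("ch%02d", seq_len(nc)))
  attr(ee, "trial_phase") <- trial_phase
  attr(ee, "trial_log_power") <- trial_log_power
  ee
}

# truncated Gaussian by resampling (preserves shape away from the bounds)
rtrunc_gauss <- function(n, mean, sd, lo = 0, hi = 1) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad) > 0) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  x
}

#' Default observer distribution for a simulated cohort
#'
#' Draws per-participant observers sharing a strong rhythmic weighting
#' component at `rhythm_freq_hz` with small between-participant variation, a
#' common baseline rhythm phase, and oscillatory-state couplings of the
#' weighting phase (by EEG phase and log-power) and of the decision noise.
#'
#' @param i participant index.
#' @param seed master seed.
#' @param rhythm_freq_hz implanted rhythm frequency (default 2.2 Hz).
#' @param rhythm_amp mean implanted rhythm amplitude in weight units.
#' @param phase_coupling_gain,power_coupling_gain weighting-phase couplings.
#' @param power_accuracy_gain,phase_accuracy_gain decision-noise couplings.
#' @return an [observer_params()] object.
#' @export
default_observer_sampler <- function(i, seed,
                                     rhythm_freq_hz = 2.2,
                                     rhythm_amp = 3,
                                     phase_coupling_gain = 0.5,
                                     power_coupling_gain = 1.65,
                                     power_accuracy_gain = 0.3,
                                     phase_accuracy_gain = 0.25) {
  with_seed(derive_seed(seed, 11L, i), {
    observer_params(
      w_offset = stats::rnorm(1, 1, 0.05),
      w_linear = stats::rnorm(1, -0.23, 0.05),
      w_uv = stats::rnorm(1, 0.006, 0.02),
      rhythm_amp = max(0.3, stats::rnorm(1, rhythm_amp, 0.3)),
      rhythm_freq_hz = rhythm_freq_hz,
      rhythm_phase0 = wrap_angle(stats::rnorm(1, 0.5, 0.3)),
      decision_noise_sd = 2.9,
      phase_coupling_gain = phase_coupling_gain,
      power_coupling_gain = power_coupling_gain,
      power_accuracy_gain = power_accuracy_gain,
      phase_accuracy_gain = phase_accuracy_gain,
      phase_accuracy_pref = 0)
  })
}

#' Simulate a synthetic cohort with ground truth
#'
#' For each participant: estimate the staircase threshold, draw per-epoch
#' trial coherences from a Gaussian centered on that threshold (SD 0.2,
#' truncated to `[0, 1]` by resampling), quantize them to the 30-sequence
#' grid, draw oscillatory trial states, and simulate the observer's binary
#' responses. Optionally generates the matching EEG epochs. All implanted
#' parameters and derived seeds are returned in a ground-truth ledger so any
#' sub-stream can be regenerated bit-identically.
#'
#' @param n_participants,n_trials cohort dimensions (defaults 20 x 1000).
#' @param obs_sampler function `(i, seed) -> observer_params`; default
#'   [default_observer_sampler()].
#' @param eeg_params an [eeg_sim_params()] object.
#' @param staircase a [staircase_config()].
#' @param seed master seed.
#' @param coherence_sd SD of the per-epoch coherence distribution.
#' @param make_eeg generate EEG epoch arrays (memory-heavy) or only the
#'   ground-truth trial states.
#' @param n_sequences sequence count defining coherence quantization.
#' @return list with `trials` (data frame: participant, trial, direction,
#'   realized coherences c1..c10, evidence e1..e10, response, correct),
#'   `ledger` (per-participant parameters, thresholds, trial states, seeds)
#'   and, if requested, `eeg` (list of [epoched_eeg()] per participant).
#' @export
simulate_cohort <- function(n_participants = 20L, n_trials = 1000L,
                            obs_sampler = NULL,
                            eeg_params = eeg_sim_params(),
                            staircase = staircase_config(),
                            seed = 1L, coherence_sd = 0.2,
                            make_eeg = FALSE, n_sequences = 30L) {
  obs_sampler <- obs_sampler %||% default_observer_sampler
  trials_list <- vector("list", n_participants)
  ledger <- vector("list", n_participants)
  eeg_list <- if (make_eeg) vector("list", n_participants) else NULL
  for (p in seq_len(n_participants)) {
    obs <- obs_sampler(p, seed)
    sc_seed <- derive_seed(seed, 21L, p)
    th <- run_staircases(obs, staircase, seed = sc_seed,
                         n_sequences = n_sequences,
                         log_power_sd = eeg_params$trial_log_power_sd)
    trial_seed <- derive_seed(seed, 31L, p)
    resp_seed <- derive_seed(seed, 41L, p)
    eeg_seed <- derive_seed(seed, 51L, p)
    dat <- with_seed(trial_seed, {
      direction <- sample(rep(c(-1, 1), length.out = n_trials))
      coh <- matrix(rtrunc_gauss(n_trials * N_EPOCHS, th$threshold,
                                 coherence_sd), n_trials, N_EPOCHS)
      q <- quantize_coherence(coh, n_sequences)
      coh_real <- matrix(q$realized, n_trials, N_EPOCHS)
      st <- draw_trial_states(n_trials, eeg_params$trial_log_power_sd)
      list(direction = direction, coh = coh_real, states = st)
    })
    E <- 0.5 + dat$direction * dat$coh / 2
    resp <- simulate_response(E, obs, eeg_phase = dat$states$phase,
                              eeg_log_power = dat$states$log_power,
                              seed = resp_seed)
    df <- data.frame(participant = p, trial = seq_len(n_trials),
                     direction = dat$direction)
    colnames_c <- sprintf("c%d", seq_len(N_EPOCHS))
    colnames_e <- sprintf("e%d", seq_len(N_EPOCHS))
    df[colnames_c] <- as.data.frame(dat$coh)
    df[colnames_e] <- as.data.frame(E)
    df$response <- resp$choice
    df$correct <- as.integer(resp$choice == dat$direction)
    trials_list[[p]] <- df
    ledger[[p]] <- list(participant = p, observer = unclass(obs),
                        threshold = th$threshold,
                        staircase_thresholds = th$thresholds,
                        trial_phase = dat$states$phase,
                        trial_log_power = dat$states$log_power,
                        seeds = list(staircase = sc_seed, trials = trial_seed,
                                     responses = resp_seed, eeg = eeg_seed))
    if (make_eeg) {
      eeg_list[[p]] <- simulate_eeg_epochs(eeg_params, dat$states$phase,
                                           dat$states$log_power,
                                           seed = eeg_seed)
    }
  }
  out <- list(trials = do.call(rbind, trials_list), ledger = ledger,
              eeg_params = eeg_params, seed = seed)
  if (make_eeg) out$eeg <- eeg_list
  out
}

#' Write / read a trial table as TSV
#'
#' Columns: participant, trial, direction, c1..c10 (realized coherences),
#' response (+1/-1). Evidence is reconstructed as `0.5 + direction * c / 2`.
#'
#' @param trials trial data frame from [simulate_cohort()].
#' @param path TSV path.
#' @return `path` / the trial data frame (with evidence columns restored).
#' @export
write_trial_table <- function(trials, path) {
  keep <- c("participant", "trial", "direction",
            sprintf("c%d", seq_len(N_EPOCHS)), "response")
  utils::write.table(trials[keep], path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t")
  cc <- sprintf("c%d", seq_len(N_EPOCHS))
  stop_if(!all(c("participant", "direction", cc, "response") %in% names(df)),
          "trial table missing required columns")
  E <- 0.5 + df$direction * as.matrix(df[cc]) / 2
  df[sprintf("e%d", seq_len(N_EPOCHS))] <- as.data.frame(E)
  if (!"correct" %in% names(df))
    df$correct <- as.integer(df$response == df$direction)
  df
}

# evidence matrix from a trial table
evidence_matrix <- function(trials) {
  as.matrix(trials[sprintf("e%d", seq_len(N_EPOCHS))])
}
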