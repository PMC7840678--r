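# Shared fixture builders: everything is generated in code at test time.

# small uncoupled cohort (consistent weighting phase, no EEG-state coupling)
make_uncoupled_cohort <- function(n_participants = 4, n_trials = 600,
                                  seed = 7, rhythm_amp = 3) {
  sampler <- function(i, s)
    default_observer_sampler(i, s, rhythm_amp = rhythm_amp,
                             phase_coupling_gain = 0,
                             power_coupling_gain = 0,
                             power_accuracy_gain = 0,
                             phase_accuracy_gain = 0)
  simulate_cohort(n_participants, n_trials, obs_sampler = sampler,
                  eeg_params = eeg_sim_params(n_channels = 4),
                  seed = seed)
}

# evidence/response set from a single observer, fast path
make_observer_trials <- function(obs, n, seed, threshold = 0.32,
                                 coherence_sd = 0.2) {
  set.seed(seed)
  d <- sample(c(-1, 1), n, replace = TRUE)
  coh <- matrix(stats::rnorm(n * 10, threshold, coherence_sd), n, 10)
  coh <- pmin(pmax(coh, 0), 1)
  cr <- quantize_coherence(coh)$realized
  dim(cr) <- c(n, 10)
  E <- 0.5 + d * cr / 2
  r <- simulate_response(E, obs, seed = seed + 1)
  list(E = E, direction = d, response = r$choice,
       correct = as.integer(r$choice == d))
}

# trial data frame wrapper around make_observer_trials
make_trials_df <- function(obs, n, seed, ...) {
  x <- make_observer_trials(obs, n, seed, ...)
  df <- data.frame(participant = 1, trial = seq_len(n),
                   direction = x$direction)
  df[sprintf("e%d", 1:10)] <- as.data.frame(x$E)
  df$response <- x$response
  df$correct <- x$correct
  df
}
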