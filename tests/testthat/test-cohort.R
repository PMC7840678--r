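# Synthetic observers, staircases and the cohort simulator.

test_that("decision variable follows the closed form", {
  # unit weights, no rhythm, vanishing noise, e = 0.6 -> D = 1 -> "up"
  obs <- observer_params(w_offset = 1, w_linear = 0, w_uv = 0,
                         rhythm_amp = 0, decision_noise_sd = 1e-9)
  r <- simulate_response(rep(0.6, 10), obs, seed = 1)
  expect_equal(r$decision_variable, 1, tolerance = 1e-6)
  expect_equal(r$choice, 1)
  # ambiguous evidence: fair coin over many trials
  E <- matrix(0.5, 10000, 10)
  obs2 <- observer_params(rhythm_amp = 0, decision_noise_sd = 1)
  r2 <- simulate_response(E, obs2, seed = 2)
  p_up <- mean(r2$choice == 1)
  expect_lt(abs(p_up - 0.5), 3 * sqrt(0.25 / 10000) + 0.001)
  expect_error(simulate_response(c(rep(0.5, 9), NA), obs), "finite")
})

test_that("EEG phase shifts the effective weighting phase as constructed", {
  obs <- observer_params(rhythm_amp = 1, phase_coupling_gain = 1,
                         rhythm_phase0 = 0)
  w0 <- observer_weights(obs, eeg_phase = 0)
  wpi <- observer_weights(obs, eeg_phase = pi)
  t <- epoch_centers()
  rhythm0 <- w0 - observer_params(rhythm_amp = 0)$w_offset -
    obs$w_linear * scale(t)[, 1] - obs$w_uv * cos(2 * pi * t / 1.2)
  # phase-pi trial has the rhythmic part sign-flipped
  rhythmpi <- wpi - (w0 - rhythm0)
  expect_equal(rhythmpi, -rhythm0, tolerance = 1e-10)
})

test_that("observer parameter validation enforces the documented ranges", {
  expect_error(observer_params(rhythm_amp = -1), ">= 0")
  expect_error(observer_params(decision_noise_sd = 0), "> 0")
  expect_error(observer_params(rhythm_freq_hz = 5), "Nyquist")
  expect_error(observer_params(w_offset = Inf), "finite")
})

test_that("staircase converges to a deterministic observer's step threshold", {
  # correct iff coherence >= 0.3; bisection oracle says the track must
  # settle at the step location up to one step of resolution
  det <- function(level) level >= 0.3
  th <- run_staircases(det, staircase_config(), seed = 3)$threshold
  expect_lt(abs(th - 0.3), 0.1 + 1e-9)
})

test_that("staircase tracks the 70.7 percent point of a stochastic rule", {
  # Bernoulli observer with a known smooth psychometric function
  pfun <- function(c) pnorm((c - 0.3) / 0.15)
  # oracle: long-run 2-down-1-up Markov chain at constant step
  set.seed(11)
  level <- 0.5; step <- 0.1; nc <- 0; lvls <- numeric(20000)
  for (i in seq_along(lvls)) {
    ok <- runif(1) < pfun(level)
    if (ok) { nc <- nc + 1; if (nc >= 2) { level <- level - step; nc <- 0 } }
    else { level <- level + step; nc <- 0 }
    level <- min(1, max(0, level))
    lvls[i] <- level
  }
  longrun <- mean(lvls[-(1:2000)])
  target <- uniroot(function(c) pfun(c) - sqrt(0.5), c(0, 1))$root
  expect_lt(abs(longrun - target), 0.05)
  set.seed(12)
  ths <- replicate(8, run_staircases(function(l) runif(1) < pfun(l),
                                     seed = sample.int(1e6, 1))$threshold)
  expect_lt(abs(mean(ths) - target), 0.06)
})

test_that("staircase errors when the reversal budget cannot be met", {
  always_right <- function(level) TRUE
  expect_error(run_staircases(always_right,
                              staircase_config(max_trials = 50), seed = 1),
               "reversals")
})

test_that("cohort responses regenerate bit-identically from the ledger", {
  co <- make_uncoupled_cohort(n_participants = 2, n_trials = 120, seed = 21)
  led <- co$ledger[[2]]
  obs <- do.call(observer_params, led$observer)
  sub <- co$trials[co$trials$participant == 2, ]
  E <- as.matrix(sub[sprintf("e%d", 1:10)])
  r <- simulate_response(E, obs, eeg_phase = led$trial_phase,
                         eeg_log_power = led$trial_log_power,
                         seed = led$seeds$responses)
  expect_identical(r$choice, sub$response)
  # and the whole cohort is reproducible from the master seed
  co2 <- make_uncoupled_cohort(n_participants = 2, n_trials = 120, seed = 21)
  expect_identical(co$trials, co2$trials)
})

test_that("threshold-centered coherence sampling has the analytic truncation bias", {
  set.seed(31)
  for (th in c(0.25, 0.32, 0.4)) {
    x <- rhythmsamp:::rtrunc_gauss(40000, th, 0.2)
    a <- (0 - th) / 0.2; b <- (1 - th) / 0.2
    expected <- th + 0.2 * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
    expect_lt(abs(mean(x) - expected), 0.005)
    expect_true(all(x >= 0 & x <= 1))
  }
})

test_that("synthetic EEG carries the implanted phase and spectrum", {
  pars <- eeg_sim_params(n_channels = 4, noise_sd = 0, osc_amp = 1)
  phases <- c(0.5, 0.5 + pi)
  ee <- simulate_eeg_epochs(pars, phases, seed = 1)
  tf <- morlet_tf(time_mirror_pad(ee), freqs = 2:13, keep_times = -0.32)
  est <- tf$phase[, 1, which(2:13 == 4), 1]
  # phases recovered at the reference time, difference of pi preserved
  expect_lt(max(abs(wrap_angle(est - phases))), 0.1)
  expect_lt(abs(abs(wrap_angle(est[1] - est[2])) - pi), 0.05)
  # pure 1/f background: log-log spectral slope near the exponent
  pars2 <- eeg_sim_params(n_channels = 4, osc_amp = 0, noise_exponent = 1.5)
  ee2 <- simulate_eeg_epochs(pars2, rep(0, 40), seed = 2)
  sp <- eeg_spectrum(ee2)
  sel <- sp$freqs > 1 & sp$freqs < 50
  slope <- coef(lm(log(sp$amplitude[sel]^2) ~ log(sp$freqs[sel])))[2]
  expect_lt(abs(slope + 1.5), 0.2)
  expect_error(eeg_sim_params(n_channels = 5), "square")
  expect_error(eeg_sim_params(osc_freq_hz = 20), "\\[2, 13\\]")
})

test_that("cohort trial tables round-trip through TSV", {
  co <- make_uncoupled_cohort(n_participants = 2, n_trials = 80, seed = 5)
  path <- tempfile(fileext = ".tsv")
  write_trial_table(co$trials, path)
  back <- read_trial_table(path)
  expect_equal(back$response, co$trials$response)
  expect_equal(as.matrix(back[sprintf("e%d", 1:10)]),
               as.matrix(co$trials[sprintf("e%d", 1:10)]),
               ignore_attr = TRUE, tolerance = 1e-12)
})
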