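# Bayesian weight-profile models: closed-form evidence, frequency scan,
# exceedance/model frequency, WAIC sampler, rhythm phase conventions.

test_that("posterior means show the analytic ridge shrinkage", {
  d <- weight_design(10)
  y <- 3 * d$X[, "offset"]
  fit <- fit_weight_model(y, d, lambda = 1)
  # analytic posterior mean for this design, computed independently
  A <- t(d$X) %*% d$X + diag(1, 3)
  beta_expected <- drop(solve(A, t(d$X) %*% y))
  expect_equal(unname(fit$betas), unname(beta_expected), tolerance = 1e-12)
  expect_lt(abs(fit$betas["offset"] - 3 * 10 / 11), 0.02
  )
  expect_lt(max(abs(fit$betas[c("linear", "uv")])), 0.05)
})

test_that("closed-form log evidence matches numerical integration", {
  # 5-epoch toy, single regressor: integrate the marginal likelihood over
  # (beta, sigma2) by adaptive quadrature and compare in log space
  set.seed(61)
  x <- c(0.5, -1, 2, 1, -0.3)
  y <- c(0.2, -0.7, 1.9, 1.2, 0.1)
  lambda <- 1
  n <- 5
  lik <- function(beta, s2) {
    prod(dnorm(y, x * beta, sqrt(s2))) * dnorm(beta, 0, sqrt(s2 / lambda)) / s2
  }
  inner <- function(s2) {
    vapply(s2, function(s) {
      integrate(function(b) vapply(b, lik, numeric(1), s2 = s),
                -20, 20, rel.tol = 1e-10)$value
    }, numeric(1))
  }
  quad <- integrate(inner, 1e-4, 200, rel.tol = 1e-10)$value
  cf <- rhythmsamp:::evidence_closed_form(y, matrix(x, ncol = 1), lambda)
  expect_equal(cf$log_evidence, log(quad), tolerance = 1e-6)
})

test_that("rhythm amplitude and phase follow the stated conventions", {
  d <- weight_design(10, rhythm_freq = 2.2)
  t <- d$t
  amp <- 1.4
  # the ridge prior shrinks the fitted amplitude; the analytically shrunk
  # coefficients (computed independently) are the exact expectation
  shrunk <- function(y) drop(solve(t(d$X) %*% d$X + diag(1, 5), t(d$X) %*% y))
  y_cos <- amp * cos(2 * pi * 2.2 * t)
  b <- shrunk(y_cos)
  fit_cos <- fit_weight_model(y_cos, d)
  expect_equal(unname(fit_cos$betas), unname(b), tolerance = 1e-12)
  expect_equal(unname(fit_cos$rhythm_rms),
               unname(sqrt((b[4]^2 + b[5]^2) / 2)), tolerance = 1e-12)
  # conventions: shrinkage leaves the phase axis intact up to the small
  # non-orthogonality of the 10-point design
  expect_lt(abs(fit_cos$rhythm_phase), 0.05)
  expect_lt(abs(fit_cos$rhythm_rms - amp / sqrt(2)) / (amp / sqrt(2)), 0.2)
  fit_sin <- fit_weight_model(amp * sin(2 * pi * 2.2 * t), d)
  expect_equal(unname(rhythm_phase_of(fit_sin)), pi / 2, tolerance = 0.05)
  fit_msin <- fit_weight_model(-amp * sin(2 * pi * 2.2 * t), d)
  expect_equal(unname(rhythm_phase_of(fit_msin)), -pi / 2, tolerance = 0.05)
  # degenerate amplitude: phase undefined
  fit0 <- fit_weight_model(rep(0, 10), d)
  expect_error(rhythm_phase_of(fit0), "undefined")
})

test_that("white-noise profiles prefer the trivial model (Occam penalty)", {
  set.seed(62)
  d0 <- weight_design(10)
  d1 <- weight_design(10, rhythm_freq = 2.2)
  deltas <- replicate(200, {
    y <- rnorm(10)
    rhythmsamp:::evidence_closed_form(y, d1$X, 1)$log_evidence -
      rhythmsamp:::evidence_closed_form(y, d0$X, 1)$log_evidence
  })
  expect_lt(mean(deltas), 0)          # rhythmic regressors penalized on noise
})

test_that("the evidence scan recovers an implanted grid frequency", {
  set.seed(63)
  hits <- replicate(20, {
    f0 <- 2.6
    t <- epoch_centers()
    W <- t(replicate(20, 3 * cos(2 * pi * f0 * t - 0.7) + rnorm(10, sd = 1)))
    scan_frequencies(W)$best_freq == f0
  })
  expect_gte(mean(hits), 0.9)
  # argmax invariant to common scaling of all profiles
  set.seed(64)
  W <- t(replicate(8, 2 * cos(2 * pi * 1.8 * epoch_centers()) + rnorm(10)))
  expect_equal(scan_frequencies(W)$best_freq,
               scan_frequencies(5 * W)$best_freq)
})

test_that("evidence ranking is robust to the ridge scale", {
  set.seed(65)
  W <- t(replicate(20, 3 * cos(2 * pi * 2.2 * epoch_centers() - 0.5) +
                     rnorm(10, sd = 1)))
  b1 <- scan_frequencies(W, lambda = 0.1)$best_freq
  b2 <- scan_frequencies(W, lambda = 1)$best_freq
  b3 <- scan_frequencies(W, lambda = 10)$best_freq
  expect_equal(b1, b2)
  expect_equal(b2, b3)
})

test_that("exceedance probability and model frequency behave at the anchors", {
  # unanimous advantage of >= 5 nats: exceedance 1
  ex <- exceedance_and_frequency(rep(0, 10), rep(5, 10) + runif(10),
                                 n_boot = 2000, seed = 1)
  expect_equal(ex$exceedance_prob, 1)
  expect_equal(unname(ex$model_frequency["rhythmic"]), 1)
  # symmetric differences: exceedance near a coin flip
  set.seed(66)
  d <- rep(c(-2, 2), 10)
  ex2 <- exceedance_and_frequency(rep(0, 20), d, n_boot = 4000, seed = 2)
  expect_lt(abs(ex2$exceedance_prob - 0.5), 0.1)
  # 19 of 20 favoring the rhythmic model: model frequency 0.95
  d3 <- c(rep(1, 19), -1)
  ex3 <- exceedance_and_frequency(rep(0, 20), d3, n_boot = 100, seed = 3)
  expect_equal(unname(ex3$model_frequency["rhythmic"]), 0.95)
  expect_error(exceedance_and_frequency(1:2, 2:3), "3 participants")
})

test_that("Gibbs posterior matches the conjugate closed form", {
  set.seed(67)
  d <- weight_design(10, rhythm_freq = 2.2)
  y <- 2 * cos(2 * pi * 2.2 * d$t - 0.4) + rnorm(10, sd = 0.8)
  w <- waic_fit(y, d, n_samples = 4000, n_burnin = 500, thinning = 2,
                seed = 68)
  cf <- rhythmsamp:::evidence_closed_form(y, d$X, 1)
  # posterior mean betas agree within Monte-Carlo error (3 SE, SE ~ sd/sqrt(n))
  expect_lt(max(abs(w$betas - cf$betas)), 0.15)
  expect_true(all(w$rhat < 1.1))
  expect_true(is.finite(w$waic))
})

test_that("WAIC and log-evidence rankings agree on structured profiles", {
  set.seed(69)
  agree <- replicate(15, {
    t <- epoch_centers()
    y <- 2.5 * cos(2 * pi * 2.2 * t - 0.5) + rnorm(10, sd = 1)
    d0 <- weight_design(10)
    d1 <- weight_design(10, rhythm_freq = 2.2)
    ev_pref <- rhythmsamp:::evidence_closed_form(y, d1$X, 1)$log_evidence >
      rhythmsamp:::evidence_closed_form(y, d0$X, 1)$log_evidence
    s <- sample.int(1e6, 1)
    waic_pref <- waic_fit(y, d1, 800, 200, 1, seed = s)$waic <
      waic_fit(y, d0, 800, 200, 1, seed = s + 1)$waic
    ev_pref == waic_pref
  })
  expect_gte(mean(agree), 0.8)
})
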