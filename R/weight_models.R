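## Regression description of weight profiles: trivial components (offset,
## linear ramp, u/v-shaped cosine over the stimulus) optionally augmented by
## a rhythmic sine/cosine pair at a scanned frequency. Models are compared by
## the closed-form Bayesian marginal likelihood (Gaussian ridge prior on the
## coefficients, Jeffreys prior on the noise variance), by bootstrap
## exceedance probability and model frequency, and by WAIC from a Gibbs
## sampler over the same conjugate model.

#' Design matrix for weight-profile regression
#'
#' Columns: offset (ones), zero-mean unit-SD linear ramp, u/v component
#' `cos(2 pi t fexp)` with `fexp = 1/duration`, and -- when `rhythm_freq` is
#' given -- `sin(2 pi f t)` and `cos(2 pi f t)`, all evaluated at the epoch
#' centers.
#'
#' @param n_epochs number of epochs (default 10).
#' @param duration stimulus duration in seconds (default 1.2).
#' @param rhythm_freq optional rhythm frequency in Hz.
#' @return object of class `weight_design`: matrix `X`, `t`, `rhythm_freq`.
#' @export
weight_design <- function(n_epochs = 10L, duration = 1.2,
                          rhythm_freq = NULL) {
  t <- epoch_centers(n_epochs, duration)
  X <- cbind(offset = rep(1, n_epochs),
             linear = (t - mean(t)) / stats::sd(t),
             uv = cos(2 * pi * t / duration))
  if (!is.null(rhythm_freq)) {
    stop_if(rhythm_freq <= 0, "rhythm_freq must be positive")
    X <- cbind(X,
               sin = sin(2 * pi * rhythm_freq * t),
               cos = cos(2 * pi * rhythm_freq * t))
  }
  stop_if(qr(X)$rank < ncol(X),
          "design matrix rank deficient at this rhythm frequency")
  structure(list(X = X, t = t, duration = duration,
                 rhythm_freq = rhythm_freq),
            class = "weight_design")
}

# closed-form log marginal likelihood and posterior for
# y | beta, s2 ~ N(X beta, s2 I), beta | s2 ~ N(0, s2/lambda I), p(s2) ~ 1/s2
evidence_closed_form <- function(y, X, lambda) {
  n <- length(y); p <- ncol(X)
  A <- crossprod(X) + diag(lambda, p)
  Xty <- crossprod(X, y)
  beta <- solve(A, Xty)
  Q <- sum(y^2) - sum(Xty * beta)
  logdet <- determinant(A, logarithm = TRUE)$modulus
  log_ev <- lgamma(n / 2) - (n / 2) * log(pi) -
    0.5 * (as.numeric(logdet) - p * log(lambda)) - (n / 2) * log(Q)
  list(betas = drop(beta), log_evidence = log_ev, A = A, Q = Q)
}

#' Fit a Bayesian weight-profile model
#'
#' Posterior-mean coefficients and the closed-form log marginal likelihood
#' of the conjugate Gaussian linear model with ridge prior
#' `beta | sigma2 ~ N(0, sigma2 / lambda I)` (default `lambda = 1`,
#' unit-information on the near-unit-scale regressors) and a Jeffreys prior
#' on the noise variance.
#'
#' @param profile a `weight_profile` (its z-weights are used), or a numeric
#'   vector of weights.
#' @param design a [weight_design()].
#' @param lambda ridge prior precision.
#' @return object of class `weight_model_fit`: `betas`, `log_evidence`, and,
#'   for rhythmic designs, `rhythm_rms` (`sqrt((b_sin^2 + b_cos^2)/2)`),
#'   `rhythm_norm` (`sqrt(b_sin^2 + b_cos^2)`) and `rhythm_phase` (radians,
#'   so the component is proportional to `cos(2 pi f t - phase)`).
#' @export
fit_weight_model <- function(profile, design, lambda = 1) {
  y <- if (inherits(profile, "weight_profile")) profile$z_weights
       else as.numeric(profile)
  stop_if(!all(is.finite(y)), "weights must be finite")
  stop_if(length(y) != nrow(design$X), "profile length does not match design")
  fit <- evidence_closed_form(y, design$X, lambda)
  out <- list(betas = fit$betas, log_evidence = fit$log_evidence,
              lambda = lambda, design = design, waic = NA_real_)
  if (!is.null(design$rhythm_freq)) {
    bs <- unname(fit$betas["sin"]); bc <- unname(fit$betas["cos"])
    out$rhythm_rms <- sqrt((bs^2 + bc^2) / 2)
    out$rhythm_norm <- sqrt(bs^2 + bc^2)
    out$rhythm_phase <- atan2(bs, bc)
  }
  structure(out, class = "weight_model_fit")
}

#' Phase of the fitted rhythmic component
#'
#' `atan2(beta_sin, beta_cos)`, mapping the component to
#' `amplitude * cos(2 pi f t - phase)` with phase in `(-pi, pi]`.
#'
#' @param fit a `weight_model_fit` from a rhythmic design.
#' @return phase in radians.
#' @export
rhythm_phase_of <- function(fit) {
  stop_if(is.null(fit$rhythm_norm), "fit has no rhythmic component")
  stop_if(fit$rhythm_norm < 1e-10, "phase undefined (amplitude at floor)")
  wrap_angle(fit$rhythm_phase)
}

#' Scan rhythm frequencies by group-level model evidence
#'
#' Fits the trivial model and, over a frequency grid, the trivial-plus-
#' rhythmic model to every participant's weight profile; participants
#' contribute independently, so the group log-evidence is the sum. Returns
#' the evidence curve, the group-best frequency (argmax of the summed
#' evidence), per-participant best frequencies and the group comparison at
#' the best frequency.
#'
#' @param profiles `participants x epochs` weight matrix (as from
#'   [cohort_weights()]).
#' @param grid frequency grid in Hz (default 1.1-4 in 0.1 steps).
#' @param duration stimulus duration in seconds.
#' @param lambda ridge prior precision.
#' @return list with `grid`, `group_log_ev` (per frequency),
#'   `group_neg_log_ev`, `trivial_log_ev` (per participant),
#'   `per_participant_log_ev` (participants x frequencies), `best_freq`,
#'   `participant_best_freqs`, `delta_neg_log_ev` (trivial minus rhythmic at
#'   the best frequency; positive favors the rhythmic model) and
#'   `model_frequency` at the best frequency.
#' @export
scan_frequencies <- function(profiles, grid = seq(1.1, 4, by = 0.1),
                             duration = 1.2, lambda = 1) {
  W <- as.matrix(profiles)
  P <- nrow(W)
  stop_if(P < 2, "need at least 2 participants")
  n_epochs <- ncol(W)
  d0 <- weight_design(n_epochs, duration)
  triv <- apply(W, 1, function(y)
    evidence_closed_form(y, d0$X, lambda)$log_evidence)
  per <- vapply(grid, function(f) {
    d1 <- weight_design(n_epochs, duration, rhythm_freq = f)
    apply(W, 1, function(y)
      evidence_closed_form(y, d1$X, lambda)$log_evidence)
  }, numeric(P))                          # participants x frequencies
  group <- colSums(per)
  best_i <- which.max(group)
  pbest <- grid[apply(per, 1, which.max)]
  rhyth_best <- per[, best_i]
  list(grid = grid, group_log_ev = group, group_neg_log_ev = -group,
       trivial_log_ev = triv, per_participant_log_ev = per,
       best_freq = grid[best_i],
       participant_best_freqs = pbest,
       delta_neg_log_ev = sum(rhyth_best) - sum(triv),
       model_frequency = mean(rhyth_best > triv),
       rhythmic_log_ev_best = rhyth_best)
}

#' Bootstrap exceedance probability and model frequency
#'
#' Resamples participants with replacement and reports the fraction of
#' bootstrap draws in which the summed log-evidence favors the rhythmic
#' model, plus the fraction of participants individually favoring each
#' model.
#'
#' @param logev_trivial,logev_rhythmic per-participant log-evidences.
#' @param n_boot bootstrap draws (default 10000).
#' @param seed integer seed.
#' @return list with `exceedance_prob` and `model_frequency` (named vector
#'   for the trivial and rhythmic models).
#' @export
exceedance_and_frequency <- function(logev_trivial, logev_rhythmic,
                                     n_boot = 10000L, seed = NULL) {
  P <- length(logev_trivial)
  stopifnot(length(logev_rhythmic) == P)
  stop_if(P < 3, "need at least 3 participants")
  d <- logev_rhythmic - logev_trivial
  with_seed(seed, {
    idx <- matrix(sample.int(P, P * n_boot, replace = TRUE), P, n_boot)
    sums <- colSums(matrix(d[idx], P, n_boot))
    mf_rhythmic <- mean(d > 0)
    list(exceedance_prob = mean(sums > 0),
         model_frequency = c(trivial = 1 - mf_rhythmic,
                             rhythmic = mf_rhythmic))
  })
}

#' WAIC of a weight-profile model by Gibbs sampling
#'
#' Samples the conjugate posterior (`beta | sigma2` Gaussian,
#' `sigma2 | beta` inverse gamma) and computes the Watanabe-Akaike
#' information criterion `-2 (lppd - p_waic)` with the variance-based
#' penalty. Two chains are run and split-Rhat convergence is checked.
#'
#' @param profile weights (vector or `weight_profile`).
#' @param design a [weight_design()].
#' @param n_samples retained posterior draws in total (default 10000).
#' @param n_burnin burn-in iterations per chain (default 10000).
#' @param thinning keep every `thinning`-th draw (default 5).
#' @param seed integer seed.
#' @param lambda ridge prior precision.
#' @param rhat_limit convergence threshold (error above it).
#' @return list with `waic`, `lppd`, `p_waic`, posterior mean `betas`, and
#'   `rhat` per coefficient.
#' @export
waic_fit <- function(profile, design, n_samples = 10000L, n_burnin = 10000L,
                     thinning = 5L, seed = NULL, lambda = 1,
                     rhat_limit = 1.1) {
  y <- if (inherits(profile, "weight_profile")) profile$z_weights
       else as.numeric(profile)
  X <- design$X
  n <- length(y); p <- ncol(X)
  A <- crossprod(X) + diag(lambda, p)
  A_inv <- solve(A)
  R <- chol(A_inv)                         # beta = mean + sigma * t(R) z
  mean_beta <- drop(A_inv %*% crossprod(X, y))
  n_chains <- 2L
  keep_per_chain <- ceiling(n_samples / n_chains)
  draws <- with_seed(seed, {
    lapply(seq_len(n_chains), function(ch) {
      # overdispersed initialization across chains
      s2 <- (stats::var(y) + 1e-6) * c(0.1, 10)[ch]
      B <- matrix(NA_real_, keep_per_chain, p)
      S2 <- numeric(keep_per_chain)
      kept <- 0L
      total <- n_burnin + keep_per_chain * thinning
      for (it in seq_len(total)) {
        beta <- mean_beta + sqrt(s2) * drop(crossprod(R, stats::rnorm(p)))
        rss <- sum((y - X %*% beta)^2) + lambda * sum(beta^2)
        s2 <- 1 / stats::rgamma(1, shape = (n + p) / 2, rate = rss / 2)
        if (it > n_burnin && (it - n_burnin) %% thinning == 0L) {
          kept <- kept + 1L
          B[kept, ] <- beta
          S2[kept] <- s2
        }
      }
      list(B = B, S2 = S2)
    })
  })
  B <- do.call(rbind, lapply(draws, `[[`, "B"))
  S2 <- unlist(lapply(draws, `[[`, "S2"))
  rhat <- vapply(seq_len(p), function(j) {
    split_rhat(lapply(draws, function(d) d$B[, j]))
  }, numeric(1))
  stop_if(any(rhat > rhat_limit),
          sprintf("Gibbs chains not converged (max Rhat = %.3f)", max(rhat)))
  mu <- tcrossprod(X, B)                   # n x draws
  ll <- stats::dnorm(y, mu, rep(sqrt(S2), each = n), log = TRUE)
  ll <- matrix(ll, n)
  lppd <- sum(log(rowMeans(exp(ll))))
  p_waic <- sum(apply(ll, 1, stats::var))
  list(waic = -2 * (lppd - p_waic), lppd = lppd, p_waic = p_waic,
       betas = colMeans(B), rhat = rhat)
}

# split-Rhat over a list of chains (vectors)
split_rhat <- function(chains) {
  halves <- unlist(lapply(chains, function(x) {
    h <- floor(length(x) / 2)
    list(x[seq_len(h)], x[h + seq_len(h)])
  }), recursive = FALSE)
  m <- length(halves); n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  Bv <- n * stats::var(means)
  if (W < .Machine$double.eps) return(1)
  sqrt(((n - 1) / n * W + Bv / n) / W)
}

#' Group WAIC comparison of trivial vs rhythmic models
#'
#' @param profiles `participants x epochs` weight matrix.
#' @param rhythm_freq rhythm frequency for the rhythmic model.
#' @param duration stimulus duration.
#' @param ... passed to [waic_fit()] (sampler settings, seed, lambda).
#' @return list with summed `waic_trivial`, `waic_rhythmic`, their
#'   difference `delta_waic` (positive favors the rhythmic model) and the
#'   per-participant WAICs.
#' @export
waic_group_comparison <- function(profiles, rhythm_freq = 2.2,
                                  duration = 1.2, ...) {
  W <- as.matrix(profiles)
  d0 <- weight_design(ncol(W), duration)
  d1 <- weight_design(ncol(W), duration, rhythm_freq = rhythm_freq)
  args <- list(...)
  seed <- args$seed
  args$seed <- NULL
  w0 <- vapply(seq_len(nrow(W)), function(i) {
    do.call(waic_fit, c(list(W[i, ], d0,
                             seed = if (is.null(seed)) NULL
                                    else derive_seed(seed, 71L, i)), args))$waic
  }, numeric(1))
  w1 <- vapply(seq_len(nrow(W)), function(i) {
    do.call(waic_fit, c(list(W[i, ], d1,
                             seed = if (is.null(seed)) NULL
                                    else derive_seed(seed, 72L, i)), args))$waic
  }, numeric(1))
  list(waic_trivial = sum(w0), waic_rhythmic = sum(w1),
       delta_waic = sum(w0) - sum(w1),
       per_participant = cbind(trivial = w0, rhythmic = w1))
}
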