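## End-to-end orchestration: simulate a synthetic cohort -> perceptual
## weights -> model comparison -> EEG time-frequency linkage -> group
## statistics -> report. All randomness derives from the single config seed;
## two runs with the same config are numerically identical.

#' Pipeline configuration
#'
#' Returns the default run configuration, optionally overridden by named
#' arguments (nested lists are merged; unknown keys are rejected).
#'
#' The defaults define the synthetic study: 20 participants x 1000 trials,
#' a strong 2.2 Hz rhythmic weighting component, a 4 Hz pre-stimulus
#' oscillation on a 16-channel grid montage whose phase and log-power shift
#' the weighting phase (gains 0.5 and 1.65, i.e. an implanted 90 degree
#' shift between opposing phase bins) and modulate accuracy, Morlet
#' analysis at 2-13 Hz, and reduced permutation counts for the
#' recompute-style nulls (see the methods vignette for the rationale).
#'
#' @param ... overrides, e.g. `run_config(n_participants = 8, eeg =
#'   list(n_channels = 16))`.
#' @return a `run_config` object (nested list).
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    n_participants = 20L,
    n_trials = 1000L,
    coherence_sd = 0.2,
    observer = list(rhythm_freq_hz = 2.2, rhythm_amp = 3,
                    phase_coupling_gain = 0.5,
                    power_coupling_gain = 1.65,
                    power_accuracy_gain = 0.3,
                    phase_accuracy_gain = 0.25),
    eeg = list(n_channels = 16L, sample_rate_hz = 150, osc_freq_hz = 4,
               osc_amp = 2, noise_exponent = 1.5, noise_sd = 1,
               trial_log_power_sd = 0.5),
    weights = list(n_perm_z = 4000L),
    scan = list(grid = seq(1.1, 4, by = 0.1), lambda = 1,
                n_boot = 10000L),
    tf = list(freqs = 2:13, n_cycles = 4, time_decim = 5L),
    link = list(rhythm_freq = 2.2, power_halfwidth = 0.1,
                n_perm_pos = 200L, n_perm_null = 500L, min_trials = 50L),
    stats = list(n_perm_cluster = 1000L, t_thresh_p = 0.05, min_size = 2L,
                 percentile = 0.95, fdr_q = 0.01)
  )
  cfg <- merge_config(cfg, list(...))
  class(cfg) <- "run_config"
  cfg
}

merge_config <- function(base, over, path = "") {
  for (nm in names(over)) {
    stop_if(!nm %in% names(base),
            sprintf("unknown config key '%s%s'", path, nm))
    if (is.list(base[[nm]]) && is.list(over[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], over[[nm]],
                                 paste0(path, nm, "$"))
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

cfg_eeg_params <- function(cfg) {
  eeg_sim_params(n_channels = cfg$eeg$n_channels,
                 sample_rate_hz = cfg$eeg$sample_rate_hz,
                 osc_freq_hz = cfg$eeg$osc_freq_hz,
                 osc_amp = cfg$eeg$osc_amp,
                 noise_exponent = cfg$eeg$noise_exponent,
                 noise_sd = cfg$eeg$noise_sd,
                 trial_log_power_sd = cfg$eeg$trial_log_power_sd)
}

cfg_obs_sampler <- function(cfg) {
  ob <- cfg$observer
  function(i, seed) {
    default_observer_sampler(i, seed,
                             rhythm_freq_hz = ob$rhythm_freq_hz,
                             rhythm_amp = ob$rhythm_amp,
                             phase_coupling_gain = ob$phase_coupling_gain,
                             power_coupling_gain = ob$power_coupling_gain,
                             power_accuracy_gain = ob$power_accuracy_gain,
                             phase_accuracy_gain = ob$phase_accuracy_gain)
  }
}

#' Simulate the cohort stage
#'
#' @param cfg a [run_config()].
#' @return output of [simulate_cohort()] (behavior and ground truth only;
#'   EEG epochs are regenerated deterministically from the ledger seeds
#'   when needed).
#' @export
stage_simulate <- function(cfg) {
  simulate_cohort(n_participants = cfg$n_participants,
                  n_trials = cfg$n_trials,
                  obs_sampler = cfg_obs_sampler(cfg),
                  eeg_params = cfg_eeg_params(cfg),
                  seed = cfg$seed,
                  coherence_sd = cfg$coherence_sd)
}

#' Behavioral summary and perceptual weights stage
#'
#' @param cohort output of [stage_simulate()].
#' @param cfg a [run_config()].
#' @return list with per-participant SDT measures and the
#'   `participants x epochs` z-weight matrix.
#' @export
stage_weights <- function(cohort, cfg) {
  ids <- sort(unique(cohort$trials$participant))
  sdt <- do.call(rbind, lapply(ids, function(p) {
    s <- sdt_measures(cohort$trials[cohort$trials$participant == p, ])
    data.frame(participant = p, hit_rate = s$hit_rate, fa_rate = s$fa_rate,
               dprime = s$dprime, criterion = s$criterion,
               fraction_correct = s$fraction_correct)
  }))
  W <- cohort_weights(cohort$trials, n_perm = cfg$weights$n_perm_z,
                      seed = derive_seed(cfg$seed, 101L))
  list(sdt = sdt, weights = W)
}

#' Model comparison stage
#'
#' @param W weight matrix from [stage_weights()].
#' @param cfg a [run_config()].
#' @return frequency-scan results plus bootstrap exceedance probability and
#'   model frequency at the group-best frequency.
#' @export
stage_modelcompare <- function(W, cfg) {
  scan <- scan_frequencies(W, grid = cfg$scan$grid,
                           lambda = cfg$scan$lambda)
  ex <- exceedance_and_frequency(scan$trivial_log_ev,
                                 scan$rhythmic_log_ev_best,
                                 n_boot = cfg$scan$n_boot,
                                 seed = derive_seed(cfg$seed, 102L))
  c(scan, ex)
}

## ---- EEG linkage internals -------------------------------------------

# decimated pre-stimulus analysis times within (-1, 0) s
link_times <- function(fs, decim) {
  tt <- seq(-1 + 1 / fs, -1 / fs, by = 1 / fs)
  tt[seq(1, length(tt), by = decim)]
}

# regenerate one participant's EEG and return its mirrored-padded TF at the
# requested times
participant_tf <- function(cohort, p, cfg, keep_times) {
  led <- cohort$ledger[[p]]
  eeg <- simulate_eeg_epochs(cohort$eeg_params, led$trial_phase,
                             led$trial_log_power, seed = led$seeds$eeg)
  padded <- time_mirror_pad(eeg)
  morlet_tf(padded, freqs = cfg$tf$freqs, n_cycles = cfg$tf$n_cycles,
            keep_times = keep_times)
}

# first pass: per-participant accuracy-by-power differences and POS
# p-values per channel x freq x time cell
first_pass_maps <- function(cohort, cfg) {
  fs <- cfg$eeg$sample_rate_hz
  times <- link_times(fs, cfg$tf$time_decim)
  ids <- sort(unique(cohort$trials$participant))
  n_ch <- cfg$eeg$n_channels
  n_f <- length(cfg$tf$freqs)
  n_cells <- n_ch * n_f * length(times)
  pc_diff <- matrix(NA_real_, length(ids), n_cells)
  pos_p <- matrix(NA_real_, length(ids), n_cells)
  for (k in seq_along(ids)) {
    p <- ids[k]
    tf <- participant_tf(cohort, p, cfg, keep_times = times)
    correct <- cohort$trials$correct[cohort$trials$participant == p]
    n <- length(correct)
    PW <- matrix(tf$power, n)
    med <- apply(PW, 2, stats::median)
    HI <- PW > rep(med, each = n)
    nhi <- colSums(HI)
    s_hi <- drop(crossprod(correct, HI))
    pc_diff[k, ] <- s_hi / nhi - (sum(correct) - s_hi) / (n - nhi)

    U <- exp(1i * matrix(tf$phase, n))
    np <- cfg$link$n_perm_pos
    L <- with_seed(derive_seed(cfg$seed, 111L, k), {
      idx <- vapply(seq_len(np), function(i) sample.int(n), integer(n))
      cbind(correct, matrix(correct[idx], n, np))
    })
    SC <- crossprod(U, L)                    # cells x (1 + np)
    ncorr <- sum(correct)
    SA <- drop(crossprod(U, rep(1, n)))
    itc_all <- Mod(SA) / n
    POS <- Mod(SC) / ncorr + Mod(SA - SC) / (n - ncorr) - 2 * itc_all
    pos_p[k, ] <- (1 + rowSums(POS[, -1, drop = FALSE] >= POS[, 1])) /
      (1 + np)
  }
  list(times = times, pc_diff = pc_diff, pos_p = pos_p,
       dims = c(n_ch, n_f, length(times)))
}

# one-sample t p-values per column of a participants x cells matrix
col_t_pvals <- function(M) {
  P <- nrow(M)
  m <- colMeans(M)
  v <- (colSums(M^2) - P * m^2) / (P - 1)
  tv <- m / sqrt(pmax(v, .Machine$double.eps) / P)
  2 * stats::pt(-abs(tv), df = P - 1)
}

# vectorized SDT contrast between the two bins of each column of HI
# (TRUE = bin "high"/1); returns dprime and criterion differences per column
sdt_bin_diffs <- function(HI, response, direction) {
  up <- direction > 0
  ru <- response > 0
  n <- length(response)
  cnt <- function(v) drop(crossprod(v, HI))   # counts in bin1 per column
  n_up1 <- cnt(as.numeric(up));  n_dn1 <- cnt(as.numeric(!up))
  h1 <- cnt(as.numeric(up & ru)); f1 <- cnt(as.numeric(!up & ru))
  n_up2 <- sum(up) - n_up1; n_dn2 <- sum(!up) - n_dn1
  h2 <- sum(up & ru) - h1; f2 <- sum(!up & ru) - f1
  rate <- function(x, m) pmin(pmax(x / m, 1 / (2 * m)), 1 - 1 / (2 * m))
  z <- stats::qnorm
  zH1 <- z(rate(h1, n_up1)); zF1 <- z(rate(f1, n_dn1))
  zH2 <- z(rate(h2, n_up2)); zF2 <- z(rate(f2, n_dn2))
  list(dprime = (zH1 - zF1) - (zH2 - zF2),
       criterion = (-(zH1 + zF1) / 2) - (-(zH2 + zF2) / 2))
}

# vectorized within-direction response contrast of evidence for both bins of
# each column of HI; returns raw weight profiles (epochs x columns) per bin
binned_raw_profiles <- function(E, HI, response, direction) {
  n <- nrow(E)
  classes <- list(uu = direction > 0 & response > 0,
                  ud = direction > 0 & response <= 0,
                  du = direction <= 0 & response > 0,
                  dd = direction <= 0 & response <= 0)
  Emask <- do.call(cbind, lapply(classes, function(cl) E * cl))
  S1 <- crossprod(Emask, HI)                  # (10*4) x cols, bin1 sums
  tot <- colSums(Emask)                       # (10*4) totals
  S2 <- tot - S1
  n1 <- vapply(classes, function(cl) drop(crossprod(as.numeric(cl), HI)),
               numeric(ncol(HI)))             # cols x 4
  n2 <- sweep(-n1, 2, vapply(classes, sum, numeric(1)), `+`)
  ne <- ncol(E)
  prof <- function(S, cnts) {
    g <- function(j) S[(j - 1) * ne + seq_len(ne), , drop = FALSE] /
      rep(cnts[, j], each = ne)
    (g(1) - g(2) + g(3) - g(4)) / 2
  }
  list(bin1 = prof(S1, n1), bin2 = prof(S2, n2),
       counts1 = n1, counts2 = n2)
}

# betas / rhythm amplitude / phase for each column of an epochs x columns
# raw-profile matrix, under the fixed-frequency rhythmic design
profile_fits <- function(raw, design, lambda = 1) {
  X <- design$X
  A <- crossprod(X) + diag(lambda, ncol(X))
  B <- solve(A, crossprod(X, raw))            # 5 x columns
  bs <- B["sin", ]; bc <- B["cos", ]
  list(betas = B, rms = sqrt((bs^2 + bc^2) / 2), phase = atan2(bs, bc))
}

# per-participant link-stage data: evidence, behavior, power bins (one
# column per channel x freq) and phase bins per division
participant_link_data <- function(cohort, p, cfg, power_time, phase_time) {
  fs <- cfg$eeg$sample_rate_hz
  hw <- cfg$link$power_halfwidth
  wlo <- max(power_time - hw, -1 + 1 / fs)
  whi <- min(power_time + hw, -1 / fs)
  wt <- seq(wlo, whi, by = cfg$tf$time_decim / fs)
  keep <- sort(unique(c(wt, phase_time)))
  tf <- participant_tf(cohort, p, cfg, keep_times = keep)
  sub <- cohort$trials[cohort$trials$participant == p, ]
  n <- nrow(sub)
  wsel <- which(tf$times >= wlo - 1e-9 & tf$times <= whi + 1e-9)
  PW <- matrix(0, n, dim(tf$power)[2] * dim(tf$power)[3])
  for (i in wsel) PW <- PW + matrix(tf$power[, , , i], n)
  PW <- PW / length(wsel)
  med <- apply(PW, 2, stats::median)
  HIpow <- (PW > rep(med, each = n)) * 1      # numeric for BLAS
  it <- which.min(abs(tf$times - phase_time))
  PH <- matrix(tf$phase[, , , it], n)
  HIphase <- lapply(0:3, function(k) {
    (matrix(split_by_phase(PH, k), n) == 1L) * 1
  })
  list(E = evidence_matrix(sub), response = sub$response,
       direction = sub$direction, correct = sub$correct,
       HIpow = HIpow, HIphase = HIphase, phases = PH,
       n_ch = cfg$eeg$n_channels, n_f = length(cfg$tf$freqs))
}

# all link-stage effect maps for one participant under an optional trial
# permutation of the behavioral data
link_effects_one <- function(pd, design, perm = NULL) {
  idx <- perm %||% seq_len(nrow(pd$E))
  E <- pd$E[idx, , drop = FALSE]
  resp <- pd$response[idx]; dir <- pd$direction[idx]
  ncf <- ncol(pd$HIpow)
  eff <- list()
  ## power bins: signed component differences, |delta phase|, d', c
  pr <- binned_raw_profiles(E, pd$HIpow, resp, dir)
  f1 <- profile_fits(pr$bin1, design); f2 <- profile_fits(pr$bin2, design)
  comp <- rbind(f1$betas[c("offset", "linear", "uv"), , drop = FALSE] -
                  f2$betas[c("offset", "linear", "uv"), , drop = FALSE],
                rhythm_rms = f1$rms - f2$rms)
  sd_ <- sdt_bin_diffs(pd$HIpow, resp, dir)
  eff$power_comp <- comp                       # 4 x ncf, signed (high-low)
  eff$power_absphase <- abs(wrap_angle(f1$phase - f2$phase))
  eff$power_dprime <- sd_$dprime
  eff$power_crit <- sd_$criterion
  ## phase divisions: absolute differences per division
  pc <- array(NA_real_, c(4, ncf, 4))          # comp x cell x division
  pp <- matrix(NA_real_, ncf, 4)
  pdp <- matrix(NA_real_, ncf, 4)
  pcr <- matrix(NA_real_, ncf, 4)
  for (k in 1:4) {
    prk <- binned_raw_profiles(E, pd$HIphase[[k]], resp, dir)
    g1 <- profile_fits(prk$bin1, design); g2 <- profile_fits(prk$bin2, design)
    pc[, , k] <- abs(rbind(g1$betas[c("offset", "linear", "uv"), ,
                                    drop = FALSE] -
                             g2$betas[c("offset", "linear", "uv"), ,
                                      drop = FALSE],
                           g1$rms - g2$rms))
    pp[, k] <- abs(wrap_angle(g1$phase - g2$phase))
    sdk <- sdt_bin_diffs(pd$HIphase[[k]], resp, dir)
    pdp[, k] <- abs(sdk$dprime)
    pcr[, k] <- abs(sdk$criterion)
  }
  eff$phase_comp <- pc
  eff$phase_absphase <- pp
  eff$phase_dprime <- pdp
  eff$phase_crit <- pcr
  eff
}

# statistics that use the recompute (percentile) null, as
# name -> function(eff) returning a per-cell vector (max over divisions
# where applicable)
percentile_stats <- function() {
  comp_idx <- c(offset = 1L, linear = 2L, uv = 3L, rhythm_rms = 4L)
  base <- list(
    power_absphase = function(e) e$power_absphase,
    phase_absphase = function(e) apply(e$phase_absphase, 1, max),
    phase_dprime = function(e) apply(e$phase_dprime, 1, max),
    phase_crit = function(e) apply(e$phase_crit, 1, max)
  )
  comps <- lapply(comp_idx, function(j)
    function(e) apply(e$phase_comp[j, , ], 1, max))
  names(comps) <- paste0("phase_", names(comp_idx))
  c(base, comps)
}

# threshold/cluster core shared by max_division_perm_test and the pipeline:
# group map vs per-cell percentile of null group maps
percentile_cluster_core <- function(group_obs, null_maps, graph, n_f,
                                    percentile = 0.95, min_size = 2L,
                                    freq_adjacency = TRUE) {
  n_ch <- nrow(graph)
  thresh <- apply(null_maps, 2, stats::quantile, probs = percentile,
                  names = FALSE)
  nb <- lattice_neighbors(graph, n_f, freq_adjacency)
  masses_of <- function(v) {
    comps <- cluster_components(v > thresh, nb, min_size)
    vapply(comps, function(ix) sum(v[ix] - thresh[ix]), numeric(1))
  }
  n_perm <- nrow(null_maps)
  null_max <- vapply(seq_len(n_perm), function(i) {
    mm <- masses_of(null_maps[i, ])
    if (length(mm)) max(mm) else 0
  }, numeric(1))
  comps <- cluster_components(group_obs > thresh, nb, min_size)
  rows <- lapply(comps, function(ix) {
    ch <- ((ix - 1L) %% n_ch) + 1L
    fr <- ((ix - 1L) %/% n_ch) + 1L
    mass <- sum(group_obs[ix] - thresh[ix])
    data.frame(channels = I(list(sort(unique(ch)))),
               freq_idx = I(list(sort(unique(fr)))),
               size = length(ix), mass = mass,
               p = (1 + sum(null_max >= mass)) / (1 + n_perm))
  })
  clusters <- if (length(rows)) do.call(rbind, rows) else
    data.frame(channels = I(list()), freq_idx = I(list()),
               size = integer(0), mass = numeric(0), p = numeric(0))
  if (nrow(clusters)) clusters <- clusters[order(-clusters$mass), ]
  structure(list(clusters = clusters,
                 group_map = matrix(group_obs, n_ch, n_f),
                 thresholds = matrix(thresh, n_ch, n_f),
                 supra_rate = mean(group_obs > thresh),
                 null_max = null_max, n_perm = n_perm,
                 min_size = min_size),
            class = "cluster_result")
}

#' EEG-behavior-weights linkage stage
#'
#' First pass: accuracy-by-power median splits and phase-opposition-sum
#' p-values per channel, frequency and pre-stimulus time; the time points
#' with the most significant channels define the power window and the phase
#' time point. Second pass: per channel and frequency, trials are binned by
#' median power / by phase (four division boundaries), weights and their
#' model components are re-fit per bin, and the per-participant contrast
#' maps plus their recompute-style permutation null maps are returned.
#'
#' @param cohort output of [stage_simulate()].
#' @param cfg a [run_config()].
#' @return list with the selected time points, observed per-participant
#'   effect arrays, group maps and null group maps for the max-selection
#'   statistics, and per-participant selection details at the ground-truth
#'   best channel.
#' @export
stage_eeglink <- function(cohort, cfg) {
  fp <- first_pass_maps(cohort, cfg)
  dims <- fp$dims
  pw_p <- array(col_t_pvals(fp$pc_diff), dims)
  power_sel <- select_timepoint(pw_p, fp$times)
  pos_group_p <- array(apply(fp$pos_p, 2, function(pv)
    stouffer(pv, n_perm = cfg$link$n_perm_pos)$p), dims)
  phase_sel <- select_timepoint(pos_group_p, fp$times)

  ids <- sort(unique(cohort$trials$participant))
  P <- length(ids)
  design <- weight_design(N_EPOCHS, rhythm_freq = cfg$link$rhythm_freq)
  pdata <- lapply(seq_along(ids), function(k)
    participant_link_data(cohort, ids[k], cfg,
                          power_sel$time_s, phase_sel$time_s))
  obs <- lapply(pdata, link_effects_one, design = design)

  ncf <- cfg$eeg$n_channels * length(cfg$tf$freqs)
  stat_funs <- percentile_stats()
  ## observed per-participant stat maps (P x cells per statistic)
  obs_stats <- lapply(stat_funs, function(f)
    t(vapply(obs, f, numeric(ncf))))
  ## signed sign-flip effects (P x ch x freq arrays)
  signed <- list(
    power_dprime = t(vapply(obs, `[[`, numeric(ncf), "power_dprime")),
    power_crit = t(vapply(obs, `[[`, numeric(ncf), "power_crit")))
  for (j in 1:4) {
    nmj <- c("offset", "linear", "uv", "rhythm_rms")[j]
    signed[[paste0("power_", nmj)]] <-
      t(vapply(obs, function(e) e$power_comp[j, ], numeric(ncf)))
  }
  ## recompute null group maps
  n_null <- cfg$link$n_perm_null
  null_maps <- lapply(stat_funs, function(f)
    matrix(NA_real_, n_null, ncf))
  n <- cfg$n_trials
  for (i in seq_len(n_null)) {
    acc <- lapply(stat_funs, function(f) numeric(ncf))
    for (k in seq_len(P)) {
      perm <- with_seed(derive_seed(cfg$seed, 121L, i, k), sample.int(n))
      eff <- link_effects_one(pdata[[k]], design, perm = perm)
      for (nm in names(stat_funs))
        acc[[nm]] <- acc[[nm]] + stat_funs[[nm]](eff)
    }
    for (nm in names(stat_funs))
      null_maps[[nm]][i, ] <- acc[[nm]] / P
  }

  ## participant-level selections at the ground-truth best channel / 4 Hz
  best_ch <- which.max(cohort$eeg_params$osc_topography)
  f4 <- which.min(abs(cfg$tf$freqs - cohort$eeg_params$osc_freq_hz))
  cell <- best_ch + (f4 - 1L) * cfg$eeg$n_channels
  per_part <- data.frame(
    participant = ids,
    power_absphase = vapply(obs, function(e)
      e$power_absphase[cell], numeric(1)),
    phase_absphase = vapply(obs, function(e)
      max(e$phase_absphase[cell, ]), numeric(1)),
    # fixed first division: unbiased recovery estimate (no max-selection)
    phase_absphase_fixed = vapply(obs, function(e)
      e$phase_absphase[cell, 1], numeric(1)),
    best_division = vapply(obs, function(e)
      which.max(e$phase_absphase[cell, ]) - 1L, integer(1)))
  # trial bin memberships at that cell (for ground-truth comparisons)
  best_cell_bins <- lapply(pdata, function(pd) list(
    power_high = pd$HIpow[, cell] > 0,
    phase_bin1 = pd$HIphase[[1]][, cell] > 0))

  list(times = fp$times, power_time = power_sel$time_s,
       phase_time = phase_sel$time_s,
       power_counts = power_sel$counts, phase_counts = phase_sel$counts,
       obs_stats = obs_stats, null_maps = null_maps, signed = signed,
       best_channel = best_ch, best_freq_idx = f4, per_participant = per_part,
       best_cell_bins = best_cell_bins,
       dims = c(cfg$eeg$n_channels, length(cfg$tf$freqs)))
}

#' Group statistics stage
#'
#' Sign-flip cluster permutation tests for the signed power contrasts,
#' percentile-null cluster tests for the max-over-division absolute
#' contrasts, and BH-FDR flags within each contrast family.
#'
#' @param link output of [stage_eeglink()].
#' @param cfg a [run_config()].
#' @return list of `cluster_result`s per contrast plus FDR flags per family.
#' @export
stage_stats <- function(link, cfg) {
  graph <- grid_graph(cfg$eeg$n_channels)
  n_f <- length(cfg$tf$freqs)
  P <- nrow(link$obs_stats[[1]])
  res <- list()
  for (nm in names(link$signed)) {
    arr <- array(link$signed[[nm]], c(P, cfg$eeg$n_channels, n_f))
    res[[nm]] <- cluster_perm_test(arr, graph,
                                   n_perm = cfg$stats$n_perm_cluster,
                                   t_thresh_p = cfg$stats$t_thresh_p,
                                   min_size = cfg$stats$min_size,
                                   seed = derive_seed(cfg$seed, 131L,
                                                      match(nm, names(link$signed))))
  }
  for (nm in names(link$obs_stats)) {
    group_obs <- colMeans(link$obs_stats[[nm]])
    res[[nm]] <- percentile_cluster_core(group_obs, link$null_maps[[nm]],
                                         graph, n_f,
                                         percentile = cfg$stats$percentile,
                                         min_size = cfg$stats$min_size)
  }
  families <- list(
    behavior_power = c("power_dprime", "power_crit"),
    weights_power = c("power_offset", "power_linear", "power_uv",
                      "power_rhythm_rms", "power_absphase"),
    behavior_phase = c("phase_dprime", "phase_crit"),
    weights_phase = c("phase_offset", "phase_linear", "phase_uv",
                      "phase_rhythm_rms", "phase_absphase"))
  ## FDR across the contrasts of each family: each contrast enters with the
  ## p-value of its strongest cluster (1 when no cluster formed)
  fdr <- lapply(families, function(members) {
    ps <- vapply(members, function(nm) {
      p <- res[[nm]]$clusters$p
      if (length(p)) min(p) else 1
    }, numeric(1))
    list(p = ps, significant = fdr_bh(ps, q = cfg$stats$fdr_q))
  })
  list(tests = res, fdr = fdr, families = families)
}

#' Run the full analysis pipeline
#'
#' Simulate -> weights -> model comparison -> EEG linkage -> statistics ->
#' report. All stages derive their randomness from `cfg$seed`; rerunning
#' with the same config reproduces every number exactly.
#'
#' @param cfg a [run_config()].
#' @param out_dir optional directory; when given, trial tables, weights,
#'   the model comparison, cluster reports and a manifest are written there.
#' @param verbose print stage progress.
#' @return list with `cohort`, `behavior` (SDT), `weights`, `models`,
#'   `link`, `stats`, and `summary` (headline numbers: best frequency,
#'   exceedance probability, selected time points, group phase shifts).
#' @export
run_full <- function(cfg = run_config(), out_dir = NULL, verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  say("stage 1/5: simulating cohort (%d participants x %d trials)",
      cfg$n_participants, cfg$n_trials)
  cohort <- stage_simulate(cfg)
  say("stage 2/5: reverse-correlation weights")
  bw <- stage_weights(cohort, cfg)
  say("stage 3/5: model comparison")
  models <- stage_modelcompare(bw$weights, cfg)
  say("stage 4/5: EEG linkage")
  link <- stage_eeglink(cohort, cfg)
  say("stage 5/5: group statistics")
  stats_res <- stage_stats(link, cfg)

  shift_power <- group_phase_shift(link$per_participant$power_absphase *
                                     180 / pi)
  shift_phase <- group_phase_shift(link$per_participant$phase_absphase *
                                     180 / pi)
  shift_phase_fixed <- group_phase_shift(
    link$per_participant$phase_absphase_fixed * 180 / pi)
  summary <- list(
    best_freq = models$best_freq,
    delta_neg_log_ev = models$delta_neg_log_ev,
    exceedance_prob = models$exceedance_prob,
    model_frequency = models$model_frequency,
    median_fraction_correct = stats::median(bw$sdt$fraction_correct),
    median_dprime = stats::median(bw$sdt$dprime),
    median_criterion = stats::median(bw$sdt$criterion),
    power_time = link$power_time, phase_time = link$phase_time,
    phase_shift_power_deg = shift_power,
    phase_shift_phase_deg = shift_phase,
    phase_shift_phase_fixed_deg = shift_phase_fixed)
  out <- list(config = cfg, cohort = cohort, behavior = bw$sdt,
              weights = bw$weights, models = models, link = link,
              stats = stats_res, summary = summary)
  if (!is.null(out_dir)) write_run(out, out_dir)
  out
}

# serialize the text artifacts of a run
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_trial_table(run$cohort$trials, file.path(out_dir, "trials.tsv"))
  write_weights(run$weights, file.path(out_dir, "weights.tsv"))
  utils::write.table(run$behavior, file.path(out_dir, "behavior.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  models <- run$models
  jsonlite::write_json(
    list(grid = models$grid, group_neg_log_ev = models$group_neg_log_ev,
         best_freq = models$best_freq,
         delta_neg_log_ev = models$delta_neg_log_ev,
         exceedance_prob = models$exceedance_prob,
         model_frequency = as.list(models$model_frequency)),
    file.path(out_dir, "model_comparison.json"),
    auto_unbox = TRUE, digits = NA)
  cl <- lapply(run$stats$tests, function(x) {
    df <- x$clusters
    lapply(seq_len(nrow(df)), function(i)
      list(channels = df$channels[[i]], freq_idx = df$freq_idx[[i]],
           size = df$size[i], mass = df$mass[i], p = df$p[i]))
  })
  jsonlite::write_json(cl, file.path(out_dir, "clusters.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(seed = run$config$seed,
         n_participants = run$config$n_participants,
         n_trials = run$config$n_trials,
         summary = run$summary[c("best_freq", "exceedance_prob",
                                 "median_fraction_correct", "median_dprime",
                                 "median_criterion", "power_time",
                                 "phase_time")]),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
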