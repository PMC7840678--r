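## Linking single-trial pre-stimulus power/phase to behavior (signal
## detection measures, phase opposition sum) and to binned re-estimates of
## the perceptual weights (component amplitude and rhythm-phase contrasts).

#' Signal detection measures of sweep-direction judgments
#'
#' Hit rate `H = P(up | up)`, false-alarm rate `FA = P(up | down)`,
#' sensitivity `d' = z(H) - z(FA)` and criterion `c = -(z(H) + z(FA)) / 2`.
#' Rates are clamped away from 0 and 1 (default: to `1/(2N)`), or corrected
#' log-linearly, to keep the inverse normal finite.
#'
#' @param direction per-trial true direction (+1/-1), or a trial data frame.
#' @param response per-trial response (+1/-1).
#' @param clamp `"halfn"` (default) or `"loglinear"` rate correction.
#' @return list with `hit_rate`, `fa_rate`, `dprime`, `criterion`,
#'   `fraction_correct`.
#' @export
sdt_measures <- function(direction, response = NULL,
                         clamp = c("halfn", "loglinear")) {
  clamp <- match.arg(clamp)
  if (is.data.frame(direction)) {
    response <- direction$response
    direction <- direction$direction
  }
  up <- direction > 0
  stop_if(!any(up) || all(up), "both directions required")
  n_up <- sum(up); n_dn <- sum(!up)
  if (clamp == "halfn") {
    H <- min(max(mean(response[up] > 0), 1 / (2 * n_up)), 1 - 1 / (2 * n_up))
    FA <- min(max(mean(response[!up] > 0), 1 / (2 * n_dn)),
              1 - 1 / (2 * n_dn))
  } else {
    H <- (sum(response[up] > 0) + 0.5) / (n_up + 1)
    FA <- (sum(response[!up] > 0) + 0.5) / (n_dn + 1)
  }
  zH <- stats::qnorm(H); zFA <- stats::qnorm(FA)
  list(hit_rate = H, fa_rate = FA, dprime = zH - zFA,
       criterion = -(zH + zFA) / 2,
       fraction_correct = mean((response > 0) == (direction > 0)))
}

#' Bin trials by pre-stimulus power
#'
#' Median split (2 bins) or equi-populated quartiles (4 bins) of a per-trial
#' power value; ties are broken deterministically by trial order.
#'
#' @param power per-trial power values (e.g. from [extract_tf()]).
#' @param n_bins 2 (median split) or 4 (quartiles).
#' @return integer bin labels (1 = lowest power).
#' @export
split_by_power <- function(power, n_bins = 2L) {
  stop_if(!n_bins %in% c(2L, 4L), "n_bins must be 2 or 4")
  stop_if(diff(range(power)) == 0, "degenerate split: constant power")
  r <- rank(power, ties.method = "first")
  as.integer(cut(r, breaks = stats::quantile(r, seq(0, 1, length.out = n_bins + 1)),
                 include.lowest = TRUE))
}

#' Bin trials by pre-stimulus phase
#'
#' Splits the circle by a diameter with boundaries at
#' `{k pi/4, k pi/4 + pi}` for division index `k` in 0..3; bin 1 is the
#' half-plane `[k pi/4, k pi/4 + pi)`.
#'
#' @param phase per-trial phases in radians.
#' @param division_index 0, 1, 2 or 3.
#' @return integer bin labels (1 or 2).
#' @export
split_by_phase <- function(phase, division_index = 0L) {
  stop_if(!division_index %in% 0:3, "division_index must be in 0..3")
  shifted <- (phase - division_index * pi / 4) %% (2 * pi)
  ifelse(shifted < pi, 1L, 2L)
}

#' Phase opposition sum
#'
#' `POS = ITC_A + ITC_B - 2 ITC_all`, where ITC is the resultant length of
#' the unit phase vectors; elevated when the two trial classes cluster at
#' opposing phases.
#'
#' @param phases_a,phases_b phases (radians) of the two trial classes.
#' @return the POS statistic.
#' @export
pos_stat <- function(phases_a, phases_b) {
  itc(phases_a) + itc(phases_b) - 2 * itc(c(phases_a, phases_b))
}

#' Permutation test of the phase opposition sum
#'
#' Permutes the class labels over trials and returns the POS with its
#' permutation p-value.
#'
#' @param phases per-trial phases.
#' @param labels logical/binary class labels (e.g. correct vs incorrect).
#' @param n_perm permutations (default 1000).
#' @param seed integer seed.
#' @param min_per_class minimal class size (default 10); smaller classes
#'   raise an error (callers exclude such participants).
#' @return list with `pos`, `p`, and the permutation null draws.
#' @export
pos_test <- function(phases, labels, n_perm = 1000L, seed = NULL,
                     min_per_class = 10L) {
  labels <- as.logical(labels)
  stop_if(min(sum(labels), sum(!labels)) < min_per_class,
          "class too small for phase opposition test")
  obs <- pos_stat(phases[labels], phases[!labels])
  with_seed(seed, {
    null <- vapply(seq_len(n_perm), function(i) {
      l <- sample(labels)
      pos_stat(phases[l], phases[!l])
    }, numeric(1))
    list(pos = obs, p = (1 + sum(null >= obs)) / (1 + n_perm), null = null)
  })
}

#' Combine per-participant p-values by the Stouffer method
#'
#' @param pvals vector of p-values (each clamped into the open unit
#'   interval resolvable by its permutation count, if `n_perm` is given).
#' @param n_perm optional permutation count used to clamp p = 1.
#' @return list with the combined `z` and `p`.
#' @export
stouffer <- function(pvals, n_perm = NULL) {
  if (!is.null(n_perm)) {
    eps <- 1 / (2 * (n_perm + 1))
    pvals <- pmin(pmax(pvals, eps), 1 - eps)
  }
  z <- sum(stats::qnorm(1 - pvals)) / sqrt(length(pvals))
  list(z = z, p = 1 - stats::pnorm(z))
}

#' Group-level phase opposition from per-participant p-values
#'
#' Combines per-participant POS permutation p-values (scalars, vectors or
#' arrays over channels/frequencies/times) cell-wise with the Stouffer
#' method.
#'
#' @param pvals_list list with one p-value array per participant, all of the
#'   same shape.
#' @param n_perm permutation count used for the per-participant tests
#'   (clamps p away from 0/1).
#' @return array of group p-values with the shape of the inputs.
#' @export
pos_group <- function(pvals_list, n_perm = NULL) {
  stopifnot(length(pvals_list) >= 2)
  M <- vapply(pvals_list, as.numeric,
              numeric(length(pvals_list[[1]])))
  out <- apply(M, 1, function(p) stouffer(p, n_perm = n_perm)$p)
  dims <- dim(pvals_list[[1]])
  if (!is.null(dims)) dim(out) <- dims
  out
}

#' Re-estimate weights and their model components within bins
#'
#' Runs the reverse-correlation and model-fit pipeline separately for the
#' trials of each bin (e.g. low/high pre-stimulus power, or two phase
#' bins), at a fixed rhythm frequency.
#'
#' @param trials trial data frame for one participant.
#' @param bins integer bin labels, one per trial.
#' @param rhythm_freq rhythm frequency of the rhythmic component (default
#'   2.2 Hz).
#' @param n_perm shuffles for the z-score (0 = fit raw differences, the
#'   fast scale-free default for contrast maps).
#' @param seed integer seed.
#' @param min_trials minimal trials per bin; smaller bins are dropped with
#'   a warning and returned as `NULL`.
#' @param lambda ridge prior precision.
#' @return list, one element per bin label, each with the `weight_profile`
#'   and `weight_model_fit`.
#' @export
binned_weights <- function(trials, bins, rhythm_freq = 2.2, n_perm = 0L,
                           seed = NULL, min_trials = 50L, lambda = 1) {
  design <- weight_design(N_EPOCHS, rhythm_freq = rhythm_freq)
  labs <- sort(unique(bins))
  out <- vector("list", length(labs))
  names(out) <- paste0("bin", labs)
  for (i in seq_along(labs)) {
    mask <- bins == labs[i]
    if (sum(mask) < min_trials) {
      warning(sprintf("bin %s dropped: only %d trials", labs[i], sum(mask)))
      next
    }
    prof <- perceptual_weights(trials, n_perm = n_perm,
                               seed = if (is.null(seed)) NULL
                                      else derive_seed(seed, 81L, i),
                               bin_mask = mask, min_trials = min_trials,
                               bin_label = as.character(labs[i]))
    y <- if (n_perm > 0) prof$z_weights else prof$raw_diff
    fit <- fit_weight_model(y, design, lambda = lambda)
    out[[i]] <- list(profile = prof, fit = fit)
  }
  out
}

#' Contrast two binned weight-model fits
#'
#' @param fit1,fit2 `weight_model_fit` objects of the two bins.
#' @return list with `abs_phase_diff_deg` (absolute circular difference of
#'   the rhythm phases, 0-180 degrees), `phase_diff_rad` (signed, wrapped),
#'   and `component_diffs` (bin1 - bin2 for each beta, with the rhythm
#'   amplitude compared as `rhythm_rms`).
#' @export
phase_contrast <- function(fit1, fit2) {
  stop_if(is.null(fit1$rhythm_norm) || is.null(fit2$rhythm_norm),
          "both fits need a rhythmic component")
  comp <- c(fit1$betas[c("offset", "linear", "uv")] -
              fit2$betas[c("offset", "linear", "uv")],
            rhythm_rms = unname(fit1$rhythm_rms - fit2$rhythm_rms))
  list(abs_phase_diff_deg = circ_diff_deg(fit1$rhythm_phase,
                                          fit2$rhythm_phase),
       phase_diff_rad = wrap_angle(fit1$rhythm_phase - fit2$rhythm_phase),
       component_diffs = comp)
}

#' Select the phase division with the largest effect
#'
#' @param contrasts list of [phase_contrast()] results, one per division.
#' @param by field used for the selection (default the absolute rhythm
#'   phase difference).
#' @return the winning contrast, with `selected_division` (0-based index).
#' @export
best_division <- function(contrasts, by = "abs_phase_diff_deg") {
  vals <- vapply(contrasts, function(ct)
    if (is.null(ct)) -Inf else ct[[by]], numeric(1))
  stop_if(all(!is.finite(vals)), "no defined contrast in any division")
  i <- which.max(vals)
  out <- contrasts[[i]]
  out$selected_division <- i - 1L
  out
}

#' Group-level absolute phase shift
#'
#' Arithmetic mean of per-participant absolute rhythm-phase differences
#' (degrees) with a 95 percent t confidence interval, or a bootstrap CI.
#' Under a null (uniform) phase relation the expected absolute circular
#' difference is 90 degrees, which is the baseline any permutation test has
#' to beat.
#'
#' @param diffs_deg per-participant absolute phase differences in degrees.
#' @param method `"t"` (default) or `"bootstrap"`.
#' @param n_boot bootstrap draws.
#' @param seed seed for the bootstrap.
#' @return list with `mean_deg` and `ci95`.
#' @export
group_phase_shift <- function(diffs_deg, method = c("t", "bootstrap"),
                              n_boot = 10000L, seed = NULL) {
  method <- match.arg(method)
  n <- length(diffs_deg)
  stop_if(n < 3, "need at least 3 participants")
  m <- mean(diffs_deg)
  if (method == "t") {
    se <- stats::sd(diffs_deg) / sqrt(n)
    ci <- m + c(-1, 1) * stats::qt(0.975, n - 1) * se
  } else {
    ci <- with_seed(seed, {
      bm <- vapply(seq_len(n_boot), function(i)
        mean(diffs_deg[sample.int(n, n, replace = TRUE)]), numeric(1))
      stats::quantile(bm, c(0.025, 0.975), names = FALSE)
    })
  }
  list(mean_deg = m, ci95 = ci)
}

#' Rank correlation of effect strengths across participants
#'
#' Spearman correlation between two per-participant effect measures with a
#' bootstrap confidence interval (the across-participant side analysis
#' relating power- and phase-linked effects).
#'
#' @param x,y per-participant effect strengths.
#' @param n_boot bootstrap draws (default 2000).
#' @param seed integer seed.
#' @return list with `r`, `p` (two-sided), and `ci95`.
#' @export
rank_effect_correlation <- function(x, y, n_boot = 2000L, seed = NULL) {
  ct <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
  ci <- with_seed(seed, {
    n <- length(x)
    bs <- vapply(seq_len(n_boot), function(i) {
      j <- sample.int(n, n, replace = TRUE)
      suppressWarnings(stats::cor(x[j], y[j], method = "spearman"))
    }, numeric(1))
    stats::quantile(bs, c(0.025, 0.975), names = FALSE, na.rm = TRUE)
  })
  list(r = unname(ct$estimate), p = ct$p.value, ci95 = ci)
}
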