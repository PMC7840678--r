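## Psychophysical reverse correlation: per-epoch perceptual weights as the
## response-conditioned difference of mean evidence, z-scored against a
## permutation distribution obtained by shuffling the alignment of stimuli
## and responses.

# response contrast of mean evidence per epoch within one direction subset:
# observed raw difference and the permutation draws (epochs x n_perm).
# Shuffled label assignments are derived from per-trial uniform keys (`U`,
# drawn once for the full trial set) so that the null is invariant to how
# the trials are partitioned into subsets.
contrast_with_null <- function(E, is_up, U = NULL) {
  n_up <- sum(is_up)
  n_dn <- sum(!is_up)
  tot <- colSums(E)
  raw <- colSums(E[is_up, , drop = FALSE]) / n_up -
    (tot - colSums(E[is_up, , drop = FALSE])) / n_dn
  null <- NULL
  if (!is.null(U) && ncol(U) > 0) {
    n <- nrow(U); np <- ncol(U)
    # within-column orderings in a single radix pass over (column, key)
    o <- order(rep(seq_len(np), each = n), as.vector(U))
    idx <- matrix(((o - 1L) %% n) + 1L, n, np)
    P <- matrix(is_up[idx], n, np)
    s_up <- crossprod(E, P)                 # epochs x n_perm
    null <- s_up / n_up - (tot - s_up) / n_dn
  }
  list(raw = raw, null = null)
}

#' Perceptual weights by reverse correlation
#'
#' For each 120 ms epoch, computes the difference in mean evidence between
#' trials answered "up" and trials answered "down", within each true sweep
#' direction separately (removing the direction-induced evidence offset) and
#' averaged across the two direction subsets. The difference is converted to
#' a z-score against a null distribution of `n_perm` weights obtained by
#' shuffling the response labels against the stimuli within each direction
#' subset.
#'
#' @param evidence `n_trials x n_epochs` evidence matrix, or a trial data
#'   frame (as from [simulate_cohort()] / [read_trial_table()]) from which
#'   evidence, response and direction are taken.
#' @param response per-trial response (+1 up / -1 down).
#' @param direction per-trial true sweep direction (+1 / -1).
#' @param n_perm number of shuffles for the z-score (default 4000; 0 skips
#'   z-scoring and returns only raw differences).
#' @param seed seed for the shuffles.
#' @param bin_mask optional logical/index vector restricting the trials
#'   (e.g. one EEG-defined bin).
#' @param min_trials minimal number of trials required (default 50).
#' @param contrast `"within_direction"` (default) or `"pooled"` (response
#'   contrast over all trials, retaining the direction offset).
#' @param zscore `"averaged"` (z-score the direction-averaged contrast,
#'   default) or `"per_direction"` (z-score per direction then average).
#' @param bin_label optional label stored on the result.
#' @param participant_id optional id stored on the result.
#' @return object of class `weight_profile`: `z_weights`, `raw_diff`,
#'   `n_trials_used`, `null_mean`, `null_sd`, `bin_label`, `participant_id`.
#' @export
perceptual_weights <- function(evidence, response = NULL, direction = NULL,
                               n_perm = 4000L, seed = NULL, bin_mask = NULL,
                               min_trials = 50L,
                               contrast = c("within_direction", "pooled"),
                               zscore = c("averaged", "per_direction"),
                               bin_label = NULL, participant_id = NULL) {
  contrast <- match.arg(contrast)
  zscore <- match.arg(zscore)
  if (is.data.frame(evidence)) {
    response <- evidence$response
    direction <- evidence$direction
    evidence <- evidence_matrix(evidence)
  }
  E <- as.matrix(evidence)
  if (!is.null(bin_mask)) {
    E <- E[bin_mask, , drop = FALSE]
    response <- response[bin_mask]
    direction <- direction[bin_mask]
  }
  n <- nrow(E)
  stop_if(n < min_trials,
          sprintf("only %d trials (< min_trials = %d)", n, min_trials))
  is_up <- response > 0
  stop_if(length(unique(is_up)) < 2, "degenerate responses")

  with_seed(seed, {
    U <- if (n_perm > 0) matrix(stats::runif(n * n_perm), n, n_perm)
         else NULL
    if (contrast == "pooled") {
      parts <- list(contrast_with_null(E, is_up, U))
    } else {
      parts <- lapply(c(1, -1), function(d) {
        sel <- direction == d
        sub_up <- is_up[sel]
        stop_if(length(unique(sub_up)) < 2,
                "degenerate responses within a direction subset")
        contrast_with_null(E[sel, , drop = FALSE], sub_up,
                           U[sel, , drop = FALSE])
      })
    }
    raw <- rowMeans(vapply(parts, `[[`, numeric(ncol(E)), "raw"))
    z <- null_mean <- null_sd <- rep(NA_real_, ncol(E))
    if (n_perm > 0) {
      if (zscore == "averaged" || length(parts) == 1L) {
        null <- Reduce(`+`, lapply(parts, `[[`, "null")) / length(parts)
        null_mean <- rowMeans(null)
        null_sd <- apply(null, 1, stats::sd)
        z <- (raw - null_mean) / null_sd
      } else {
        zs <- lapply(parts, function(p) {
          (p$raw - rowMeans(p$null)) / apply(p$null, 1, stats::sd)
        })
        z <- rowMeans(do.call(cbind, zs))
      }
    }
    structure(list(z_weights = z, raw_diff = raw, n_trials_used = n,
                   null_mean = null_mean, null_sd = null_sd,
                   bin_label = bin_label, participant_id = participant_id),
              class = "weight_profile")
  })
}

#' Weight profiles for every participant of a trial table
#'
#' @param trials trial data frame with a `participant` column.
#' @param n_perm,seed,... passed to [perceptual_weights()].
#' @return matrix `participants x epochs` of z-weights (or raw differences
#'   when `n_perm = 0`), with a `profiles` attribute holding the full
#'   per-participant objects.
#' @export
cohort_weights <- function(trials, n_perm = 4000L, seed = NULL, ...) {
  ids <- sort(unique(trials$participant))
  profs <- lapply(seq_along(ids), function(k) {
    sub <- trials[trials$participant == ids[k], ]
    perceptual_weights(sub, n_perm = n_perm,
                       seed = if (is.null(seed)) NULL
                              else derive_seed(seed, 61L, k),
                       participant_id = ids[k], ...)
  })
  W <- t(vapply(profs, function(p) {
    if (all(is.na(p$z_weights))) p$raw_diff else p$z_weights
  }, numeric(N_EPOCHS)))
  rownames(W) <- ids
  attr(W, "profiles") <- profs
  W
}

#' Write weight profiles as TSV
#'
#' One row per participant, bin and epoch with raw and z-scored weights.
#'
#' @param profiles list of `weight_profile` objects (or the attribute of
#'   [cohort_weights()] output).
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_weights <- function(profiles, path) {
  if (is.matrix(profiles)) profiles <- attr(profiles, "profiles")
  rows <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(participant = p$participant_id %||% NA,
               bin = p$bin_label %||% "all",
               epoch = seq_along(p$raw_diff),
               raw = p$raw_diff, z = p$z_weights)
  }))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
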