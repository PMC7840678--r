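## Group-level statistics over channel x frequency maps: sign-flip
## cluster-based permutation tests (max-sum cluster statistic, minimal
## cluster size 2), permutation nulls for max-over-division selection
## statistics, and BH false-discovery-rate control across contrast families
## (fdr_bh lives in utils.R).

#' Square-grid channel neighbor graph
#'
#' Rook adjacency on a `side x side` montage (the synthetic default); used
#' for cluster formation.
#'
#' @param n_channels perfect-square channel count.
#' @param ch_names optional channel names.
#' @return symmetric, irreflexive logical adjacency matrix.
#' @export
grid_graph <- function(n_channels = 64L, ch_names = NULL) {
  side <- as.integer(round(sqrt(n_channels)))
  stopifnot(side * side == n_channels)
  adj <- matrix(FALSE, n_channels, n_channels)
  idx <- function(r, c) (c - 1L) * side + r
  for (r in seq_len(side)) for (c in seq_len(side)) {
    if (r < side) adj[idx(r, c), idx(r + 1L, c)] <- TRUE
    if (c < side) adj[idx(r, c), idx(r, c + 1L)] <- TRUE
  }
  adj <- adj | t(adj)
  ch_names <- ch_names %||% sprintf("ch%02d", seq_len(n_channels))
  dimnames(adj) <- list(ch_names, ch_names)
  adj
}

#' Read a channel neighbor graph from an edge-list file
#'
#' Plain-text file with one `channelA channelB` pair per line.
#'
#' @param path edge-list file.
#' @param ch_names channel set (defaults to the channels seen in the file).
#' @return symmetric logical adjacency matrix.
#' @export
read_neighbors <- function(path, ch_names = NULL) {
  ed <- utils::read.table(path, col.names = c("a", "b"),
                          colClasses = "character")
  ch_names <- ch_names %||% sort(unique(c(ed$a, ed$b)))
  n <- length(ch_names)
  adj <- matrix(FALSE, n, n, dimnames = list(ch_names, ch_names))
  ia <- match(ed$a, ch_names); ib <- match(ed$b, ch_names)
  stop_if(anyNA(ia) || anyNA(ib), "edge list names not in ch_names")
  adj[cbind(ia, ib)] <- TRUE
  adj | t(adj)
}

# neighbor lists over the flattened channel x freq lattice
lattice_neighbors <- function(graph, n_freq, freq_adjacency = TRUE) {
  n_ch <- nrow(graph)
  ch_nb <- apply(graph, 1, which, simplify = FALSE)
  nb <- vector("list", n_ch * n_freq)
  for (f in seq_len(n_freq)) {
    off <- (f - 1L) * n_ch
    for (ch in seq_len(n_ch)) {
      v <- ch_nb[[ch]] + off
      if (freq_adjacency) {
        if (f > 1L) v <- c(v, ch + off - n_ch)
        if (f < n_freq) v <- c(v, ch + off + n_ch)
      }
      nb[[ch + off]] <- v
    }
  }
  nb
}

# connected components among `active` lattice cells; returns list of cell
# index vectors with at least min_size members
cluster_components <- function(active, neighbors, min_size = 2L) {
  todo <- which(active)
  if (!length(todo)) return(list())
  in_set <- logical(length(neighbors))
  in_set[todo] <- TRUE
  seen <- logical(length(neighbors))
  comps <- list()
  for (s in todo) {
    if (seen[s]) next
    comp <- integer(0)
    queue <- s
    seen[s] <- TRUE
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      comp <- c(comp, v)
      nbv <- neighbors[[v]]
      new <- nbv[in_set[nbv] & !seen[nbv]]
      seen[new] <- TRUE
      queue <- c(queue, new)
    }
    if (length(comp) >= min_size) comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

#' Sign-flip cluster-based permutation test
#'
#' Paired (one-sample) t statistics per channel and frequency are
#' thresholded at a two-sided level, supra-threshold cells are clustered
#' over channel adjacency (and, by default, neighboring frequencies), and
#' each observed cluster's t-sum is compared to the permutation null of the
#' maximal cluster mass under sign flips of the per-participant effects.
#'
#' @param effects array `participant x channel x freq` of effect values
#'   (differences against zero).
#' @param graph channel adjacency matrix covering all channels.
#' @param n_perm permutations (default 2000).
#' @param t_thresh_p two-sided cell threshold (default 0.05).
#' @param min_size minimal cluster size in cells (default 2).
#' @param seed integer seed.
#' @param freq_adjacency cluster across neighboring frequencies (default
#'   TRUE).
#' @return object of class `cluster_result`: data frame `clusters`
#'   (channels, freqs, size, mass, p) sorted by decreasing `|mass|`, the
#'   observed `t_map`, and the null max-mass distribution.
#' @export
cluster_perm_test <- function(effects, graph, n_perm = 2000L,
                              t_thresh_p = 0.05, min_size = 2L,
                              seed = NULL, freq_adjacency = TRUE) {
  d <- dim(effects)
  stopifnot(length(d) == 3)
  P <- d[1]; n_ch <- d[2]; n_f <- d[3]
  stop_if(P < 5, "need at least 5 participants")
  stop_if(nrow(graph) != n_ch,
          "neighbor graph does not cover the data channels")
  comp_sizes <- graph_components(graph)
  stop_if(length(comp_sizes) > 1, "neighbor graph is disconnected")
  X <- matrix(effects, P)                      # P x (ch*freq)
  ss <- colSums(X^2)
  tcrit <- stats::qt(1 - t_thresh_p / 2, df = P - 1)
  nb <- lattice_neighbors(graph, n_f, freq_adjacency)

  t_of <- function(m) {
    v <- (ss - P * m^2) / (P - 1)
    m / sqrt(pmax(v, .Machine$double.eps) / P)
  }
  masses_of <- function(tv) {
    out <- numeric(0)
    for (s in c(1, -1)) {
      comps <- cluster_components(s * tv > tcrit, nb, min_size)
      out <- c(out, vapply(comps, function(ix) sum(tv[ix]), numeric(1)))
    }
    out
  }

  t_obs <- t_of(colMeans(X))
  null_max <- with_seed(seed, {
    flips <- matrix(sample(c(-1, 1), n_perm * P, replace = TRUE), n_perm, P)
    vapply(seq_len(n_perm), function(i) {
      tv <- t_of(drop(flips[i, ] %*% X) / P)
      mm <- masses_of(tv)
      if (length(mm)) max(abs(mm)) else 0
    }, numeric(1))
  })

  rows <- list()
  for (s in c(1, -1)) {
    comps <- cluster_components(s * t_obs > tcrit, nb, min_size)
    for (ix in comps) {
      ch <- ((ix - 1L) %% n_ch) + 1L
      fr <- ((ix - 1L) %/% n_ch) + 1L
      mass <- sum(t_obs[ix])
      rows[[length(rows) + 1L]] <- data.frame(
        channels = I(list(sort(unique(ch)))),
        freq_idx = I(list(sort(unique(fr)))),
        size = length(ix), mass = mass,
        p = (1 + sum(null_max >= abs(mass))) / (1 + n_perm))
    }
  }
  clusters <- if (length(rows)) do.call(rbind, rows) else
    data.frame(channels = I(list()), freq_idx = I(list()),
               size = integer(0), mass = numeric(0), p = numeric(0))
  if (nrow(clusters)) clusters <- clusters[order(-abs(clusters$mass)), ]
  structure(list(clusters = clusters,
                 t_map = matrix(t_obs, n_ch, n_f),
                 null_max = null_max, n_perm = n_perm,
                 t_thresh = tcrit, min_size = min_size),
            class = "cluster_result")
}

graph_components <- function(graph) {
  n <- nrow(graph)
  nb <- apply(graph, 1, which, simplify = FALSE)
  seen <- logical(n)
  sizes <- integer(0)
  for (s in seq_len(n)) {
    if (seen[s]) next
    queue <- s; seen[s] <- TRUE; size <- 0L
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]; size <- size + 1L
      new <- nb[[v]][!seen[nb[[v]]]]
      seen[new] <- TRUE
      queue <- c(queue, new)
    }
    sizes <- c(sizes, size)
  }
  sizes
}

#' Permutation test for max-over-division selection statistics
#'
#' For non-negative effects where, per participant, channel and frequency,
#' the largest of several (e.g. four phase-division) effects was selected,
#' the selection bias must be present in the null as well. The null is
#' therefore built by re-running the entire selection pipeline on permuted
#' trial-behavior pairings (`null_fun`), the group-average map is
#' thresholded at the per-cell 95th percentile of the null maps, and
#' supra-threshold cells are clustered; each cluster's exceedance mass is
#' compared to the null distribution of the maximal cluster mass.
#'
#' @param observed array `participant x channel x freq x n_divisions` (or
#'   already division-maximized `participant x channel x freq`).
#' @param null_fun function of the permutation index returning an array of
#'   the same form, computed on permuted trial-behavior pairings.
#' @param n_perm permutations (default 2000).
#' @param graph channel adjacency matrix.
#' @param percentile per-cell null quantile for thresholding (default 0.95).
#' @param min_size minimal cluster size (default 2).
#' @param freq_adjacency cluster across neighboring frequencies.
#' @return object of class `cluster_result` with `clusters` (channels,
#'   freqs, size, mass, p), the group map, the per-cell thresholds, and the
#'   per-cell exceedance rate of the null (its mean is `1 - percentile` by
#'   construction).
#' @export
max_division_perm_test <- function(observed, null_fun, n_perm = 2000L,
                                   graph, percentile = 0.95, min_size = 2L,
                                   freq_adjacency = TRUE) {
  maxdiv <- function(a) {
    if (length(dim(a)) == 4L) apply(a, c(1, 2, 3), max) else a
  }
  obs <- maxdiv(observed)
  d <- dim(obs)
  P <- d[1]; n_ch <- d[2]; n_f <- d[3]
  stop_if(nrow(graph) != n_ch,
          "neighbor graph does not cover the data channels")
  group_obs <- colMeans(matrix(obs, P))        # ch*freq
  null_maps <- matrix(NA_real_, n_perm, n_ch * n_f)
  for (i in seq_len(n_perm)) {
    null_maps[i, ] <- colMeans(matrix(maxdiv(null_fun(i)), P))
  }
  percentile_cluster_core(group_obs, null_maps, graph, n_f,
                          percentile = percentile, min_size = min_size,
                          freq_adjacency = freq_adjacency)
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: %d cluster(s), %d permutations\n",
              nrow(x$clusters), x$n_perm))
  if (nrow(x$clusters)) {
    df <- x$clusters
    for (i in seq_len(nrow(df))) {
      cat(sprintf("  size %d, mass %.3f, p = %.4f, freq idx %s\n",
                  df$size[i], df$mass[i], df$p[i],
                  paste(df$freq_idx[[i]], collapse = ",")))
    }
  }
  invisible(x)
}
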