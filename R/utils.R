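#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules: seed streams, circular arithmetic,
## small numerics. Nothing here is exported except the seed derivation, which
## users need to reproduce sub-streams of a cohort simulation.

#' Derive a reproducible sub-stream seed
#'
#' Deterministically mixes a master seed with one or more integer keys
#' (participant index, trial index, stage id, ...) into a new seed below
#' 2^31. Used throughout the package so that every random component of a
#' simulation can be regenerated in isolation.
#'
#' @param seed master seed (integer).
#' @param ... integer keys identifying the sub-stream.
#' @return a single integer seed.
#' @export
#' @examples
#' derive_seed(1, 3, 7)
derive_seed <- function(seed, ...) {
  keys <- c(...)
  x <- as.double(seed) %% 2147483647
  for (k in c(keys, 0x9e37)) {
    # 64-bit-safe LCG mix in doubles: 69069 * 2^31 < 2^53
    x <- (x * 69069 + as.double(k) * 2654435 + 12345) %% 2147483647
  }
  as.integer(x)
}

# Evaluate expr with a local RNG state seeded at `seed`; caller's stream is
# untouched. seed = NULL leaves the global stream in use.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Wrap angles to (-pi, pi]
#'
#' @param x angles in radians.
#' @return wrapped angles in (-pi, pi].
#' @export
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  # map -pi to +pi so the interval is half-open on the left
  y[y <= -pi] <- pi
  y
}

#' Absolute circular difference in degrees
#'
#' Shortest arc between two angles, in `[0, 180]` degrees.
#'
#' @param a,b angles in radians.
#' @return absolute difference in degrees.
#' @export
circ_diff_deg <- function(a, b) {
  abs(wrap_angle(a - b)) * 180 / pi
}

# Resultant vector length of a set of phases (inter-trial coherence).
itc <- function(phases) Mod(mean(exp(1i * phases)))

# round-half-up (base round() is banker's)
round_half_up <- function(x) floor(x + 0.5)

stop_if <- function(cond, msg) if (isTRUE(cond)) stop(msg, call. = FALSE)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Benjamini-Hochberg significance flags
#'
#' Step-up false-discovery-rate control: flags the hypotheses rejected at
#' level `q`.
#'
#' @param p vector of p-values.
#' @param q FDR level (default 0.01).
#' @return logical vector, `TRUE` where the hypothesis is rejected.
#' @export
fdr_bh <- function(p, q = 0.01) {
  stopifnot(is.numeric(p), all(p >= 0 & p <= 1, na.rm = TRUE))
  m <- length(p)
  if (m == 0L) return(logical(0))
  adj <- stats::p.adjust(p, method = "BH")
  flags <- !is.na(adj) & adj <= q
  flags
}
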