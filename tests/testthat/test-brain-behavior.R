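# Signal detection measures, EEG-defined trial bins, phase opposition and
# phase contrasts.

test_that("d-prime and criterion identities hold against independent inversion", {
  # independent oracle: invert the normal CDF by root finding, not qnorm
  zroot <- function(p) uniroot(function(z) pnorm(z) - p, c(-8, 8),
                               tol = 1e-12)$root
  grid <- expand.grid(H = c(0.05, 0.284, 0.5, 0.716, 0.9, 0.975),
                      FA = c(0.05, 0.284, 0.5, 0.716, 0.9))
  for (i in seq_len(nrow(grid))) {
    H <- grid$H[i]; FA <- grid$FA[i]
    n <- 10000  # large class counts so clamping is inactive
    d <- c(rep(1, n), rep(-1, n))
    r <- c(rep(1, round(H * n)), rep(-1, n - round(H * n)),
           rep(1, round(FA * n)), rep(-1, n - round(FA * n)))
    s <- sdt_measures(d, r)
    expect_equal(s$dprime, zroot(H) - zroot(FA), tolerance = 1e-10)
    expect_equal(s$criterion, -(zroot(H) + zroot(FA)) / 2, tolerance = 1e-10)
  }
  # anchor cases frozen from the oracle
  n <- 1000
  d <- c(rep(1, n), rep(-1, n))
  r1 <- c(rep(1, 716), rep(-1, 284), rep(1, 284), rep(-1, 716))
  expect_equal(sdt_measures(d, r1)$dprime, 1.14193, tolerance = 1e-4)
  expect_equal(sdt_measures(d, r1)$criterion, 0, tolerance = 1e-10)
  r2 <- c(rep(1, 975), rep(-1, 25), rep(1, 500), rep(-1, 500))
  expect_equal(sdt_measures(d, r2)$criterion, -0.97998, tolerance = 1e-4)
  # H = FA: no sensitivity
  r3 <- c(rep(1, 300), rep(-1, 700), rep(1, 300), rep(-1, 700))
  expect_equal(sdt_measures(d, r3)$dprime, 0, tolerance = 1e-12)
  expect_error(sdt_measures(rep(1, 10), rep(1, 10)), "both directions")
})

test_that("power bins are equi-populated with deterministic ties", {
  expect_equal(table(split_by_power(rnorm(100)))[[1]], 50)
  q <- split_by_power(rnorm(1000), n_bins = 4)
  expect_equal(as.integer(table(q)), rep(250L, 4))
  # ties broken by trial order, reproducibly
  p <- rep(c(1, 2), each = 10)
  expect_identical(split_by_power(p), split_by_power(p))
  expect_error(split_by_power(rep(1, 50)), "degenerate")
})

test_that("phase divisions split the circle along rotated diameters", {
  # boundaries at {0, pi}: the upper half-plane is one bin
  expect_equal(split_by_phase(0.1, 0), split_by_phase(3.0, 0))
  expect_false(split_by_phase(0.1, 0) == split_by_phase(-0.1, 0))
  ph <- runif(500, -pi, pi)
  for (k in 0:3) {
    b <- split_by_phase(ph, k)
    # rotating all phases by pi swaps every label
    b2 <- split_by_phase(wrap_angle(ph + pi), k)
    expect_true(all(b != b2))
    expect_lt(abs(mean(b == 1) - 0.5), 0.1)
  }
  expect_error(split_by_phase(ph, 4), "division_index")
})

test_that("phase opposition sum detects opposing clusters and stays bounded", {
  set.seed(81)
  # same uniform distribution in both classes: POS near zero
  null_pos <- replicate(50, pos_stat(runif(100, -pi, pi),
                                     runif(100, -pi, pi)))
  expect_lt(abs(mean(null_pos)), 0.05)
  # oracle: concentrated opposing von Mises classes. ITCs computed directly
  # from the constructed samples must reproduce the statistic
  rvm <- function(n, mu, k) {
    # simple rejection sampler
    out <- numeric(0)
    while (length(out) < n) {
      x <- runif(2 * n, -pi, pi)
      acc <- runif(2 * n) < exp(k * (cos(x - mu) - 1))
      out <- c(out, x[acc])
    }
    out[1:n]
  }
  a <- rvm(200, 0, 8); b <- rvm(200, pi, 8)
  itc <- function(x) Mod(mean(exp(1i * x)))
  expect_equal(pos_stat(a, b), itc(a) + itc(b) - 2 * itc(c(a, b)),
               tolerance = 1e-12)
  pt <- pos_test(c(a, b), rep(c(TRUE, FALSE), each = 200), n_perm = 500,
                 seed = 1)
  expect_gt(pt$pos, 1.5)
  expect_lt(pt$p, 0.005)
  # identical phases give ITC 1, so POS is bounded by 2
  expect_lte(pos_stat(rep(1, 50), rep(1, 50) + pi), 2)
  # global rotation invariance
  expect_equal(pos_stat(a + 1.3, b + 1.3), pos_stat(a, b), tolerance = 1e-12)
  expect_error(pos_test(runif(30), c(rep(TRUE, 25), rep(FALSE, 5)),
                        n_perm = 10), "class too small")
})

test_that("Stouffer combination aggregates permutation p-values", {
  st <- stouffer(c(0.01, 0.02, 0.05), n_perm = 200)
  expect_lt(st$p, 0.001)
  st_null <- stouffer(c(0.5, 0.5, 0.5))
  expect_equal(st_null$p, 0.5, tolerance = 1e-12)
  # p = 1 from a permutation test stays finite after clamping
  expect_true(is.finite(stouffer(c(1, 0.2), n_perm = 100)$z))
})

test_that("phase contrasts wrap on the circle and select the best division", {
  d <- weight_design(10, rhythm_freq = 2.2)
  t <- d$t
  mk <- function(phi) fit_weight_model(2 * cos(2 * pi * 2.2 * t - phi), d)
  expect_equal(phase_contrast(mk(0.4), mk(0.4))$abs_phase_diff_deg, 0,
               tolerance = 1e-6)
  expect_equal(phase_contrast(mk(0), mk(pi))$abs_phase_diff_deg, 180,
               tolerance = 0.5)
  expect_equal(phase_contrast(mk(0), mk(3 * pi / 2))$abs_phase_diff_deg, 90,
               tolerance = 0.5)
  cons <- list(phase_contrast(mk(0), mk(0.3)),
               phase_contrast(mk(0), mk(1.2)),
               phase_contrast(mk(0), mk(0.7)),
               phase_contrast(mk(0), mk(0.1)))
  best <- best_division(cons)
  expect_equal(best$selected_division, 1L)   # 0-based index of 1.2 rad
})

test_that("group phase shift summarises with the right null baseline", {
  gs <- group_phase_shift(rep(90, 8))
  expect_equal(gs$mean_deg, 90)
  expect_equal(diff(gs$ci95), 0)
  # |difference of independent uniform phases| has expectation 90 degrees
  set.seed(82)
  diffs <- abs(wrap_angle(runif(20000, -pi, pi) -
                            runif(20000, -pi, pi))) * 180 / pi
  expect_lt(abs(mean(diffs) - 90), 2)
  gb <- group_phase_shift(diffs[1:12], method = "bootstrap", seed = 3,
                          n_boot = 500)
  expect_true(gb$ci95[1] < gb$mean_deg & gb$mean_deg < gb$ci95[2])
  expect_error(group_phase_shift(c(10, 20)), "3 participants")
})

test_that("rank correlation of effect strengths matches cor.test", {
  set.seed(83)
  x <- rnorm(20); y <- x + rnorm(20)
  rc <- rank_effect_correlation(x, y, n_boot = 200, seed = 1)
  expect_equal(rc$r, unname(cor.test(x, y, method = "spearman",
                                     exact = FALSE)$estimate))
  expect_true(rc$ci95[1] <= rc$r & rc$r <= rc$ci95[2])
})

test_that("group POS combination respects shape and aggregates evidence", {
  set.seed(84)
  shape <- c(2, 3)
  strong <- lapply(1:6, function(p) array(0.01, shape))
  g <- pos_group(strong, n_perm = 200)
  expect_equal(dim(g), shape)
  expect_true(all(g < 1e-6))
  nulls <- lapply(1:6, function(p) array(runif(6), shape))
  expect_true(all(pos_group(nulls) >= 0 & pos_group(nulls) <= 1))
})
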