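kT <- 0.596

test_that("the one-window unbiased limit reduces WHAM to -kT log p", {
  set.seed(41)
  w <- umbrella_window(0, rnorm(1e5, 0, 1), spring_k = 0)
  p <- wham(list(w), bin_width = 0.1, kT = kT)
  sel <- abs(p$profile$z) < 2
  # F(z) should equal kT z^2 / 2 up to a constant for a unit Gaussian
  resid <- p$profile$F[sel] - kT * p$profile$z[sel]^2 / 2
  expect_lt(max(abs(resid - mean(resid))), 0.05)
})

test_that("exact Gaussian windows of a flat potential give a flat PMF", {
  set.seed(42)
  anchors <- seq(-2, 2, by = 0.4)
  wins <- lapply(anchors, function(a)
    umbrella_window(a, rnorm(2e4, a, sqrt(kT / 25)), 25))
  p <- wham(wins)
  sel <- p$profile$z >= -2 & p$profile$z <= 2
  expect_lt(max(p$profile$F[sel]) - min(p$profile$F[sel]), 0.1)
  expect_equal(min(p$profile$F), 0)
})

test_that("WHAM is invariant to window order and global coordinate shifts", {
  set.seed(43)
  pot <- analytic_potential("harmonic", a = 2)
  anchors <- seq(-1.2, 1.2, by = 0.4)
  wins <- lapply(seq_along(anchors), function(i)
    umbrella_window(anchors[i],
                    simulate_langevin_1d(pot, anchors[i], 25,
                                         n_steps = 2e4, dt = 0.005,
                                         seed = 50 + i, sample_stride = 4),
                    25))
  p1 <- wham(wins)
  p2 <- wham(rev(wins))
  expect_equal(p2$profile$F, p1$profile$F, tolerance = 1e-9)
  shifted <- lapply(wins, function(w)
    umbrella_window(w$anchor + 7.3, w$samples + 7.3, w$spring_k))
  p3 <- wham(shifted)
  expect_equal(p3$profile$F, p1$profile$F, tolerance = 1e-6)
  expect_equal(p3$profile$z, p1$profile$z + 7.3, tolerance = 1e-9)
  # duplicating a window adds no information beyond statistical noise
  p4 <- wham(c(wins, wins[3]))
  common <- intersect(p4$profile$z, p1$profile$z)
  expect_lt(max(abs(p4$profile$F[p4$profile$z %in% common] -
                      p1$profile$F[p1$profile$z %in% common])), 0.1)
})

test_that("non-overlapping windows raise a coverage-gap error", {
  set.seed(44)
  wins <- list(umbrella_window(-3, rnorm(1000, -3, 0.1), 25),
               umbrella_window(3, rnorm(1000, 3, 0.1), 25))
  expect_error(wham(wins), "coverage gap")
})

test_that("autocorrelation time follows the e^-2 decay rule", {
  set.seed(45)
  expect_equal(autocorrelation_time(rnorm(1e4)), 1L)
  ar <- as.numeric(stats::filter(rnorm(1e5), 0.8, "recursive"))
  t_ar <- autocorrelation_time(ar)
  expect_true(abs(t_ar - 9) <= 1)          # ceil(-2 / log 0.8) = 9
  # duplicating each value in place doubles the decay lag
  dup <- rep(ar[1:5e4], each = 2)
  expect_true(abs(autocorrelation_time(dup) - 2 * t_ar) <= 2)
  expect_error(autocorrelation_time(rep(1, 100)), "constant")
  expect_error(autocorrelation_time(rnorm(5)), "short")
})

test_that("bootstrap error bars subsample N/t and grow with t", {
  set.seed(46)
  anchors <- seq(-1, 1, by = 0.4)
  mk <- function(n) lapply(anchors, function(a)
    umbrella_window(a, rnorm(n, a, sqrt(kT / 25)), 25))
  expect_error(bootstrap_pmf(mk(500), n_boot = 5), "n_boot")
  b_small <- bootstrap_pmf(mk(500), n_boot = 30, seed = 1)
  b_large <- bootstrap_pmf(mk(5000), n_boot = 30, seed = 1)
  expect_lt(mean(b_large$profile$sd, na.rm = TRUE),
            mean(b_small$profile$sd, na.rm = TRUE))
  expect_true(all(b_small$autocorr_times == 1L))
  # correlated windows: the same data analysed at t = 1 (duplicated
  # samples break the correlation estimate) gives smaller bars than
  # the honest autocorrelation-aware resampling
  ar_wins <- lapply(anchors, function(a) {
    x <- a + sqrt(kT / 25) *
      as.numeric(stats::filter(rnorm(4000, 0, sqrt(1 - 0.8^2)), 0.8,
                               "recursive"))
    umbrella_window(a, x, 25)
  })
  b_corr <- bootstrap_pmf(ar_wins, n_boot = 30, seed = 2)
  expect_true(all(b_corr$autocorr_times > 1L))
  iid_wins <- lapply(ar_wins, function(w)
    umbrella_window(w$anchor, sample(w$samples), w$spring_k))
  b_iid <- bootstrap_pmf(iid_wins, n_boot = 30, seed = 2)
  expect_gt(mean(b_corr$profile$sd, na.rm = TRUE),
            mean(b_iid$profile$sd, na.rm = TRUE))
})

test_that("split-half convergence is zero on identical halves", {
  set.seed(47)
  anchors <- seq(-1, 1, by = 0.4)
  half <- lapply(anchors, function(a) rnorm(500, a, sqrt(kT / 25)))
  wins <- lapply(seq_along(anchors), function(i)
    umbrella_window(anchors[i], rep(half[[i]], 2), 25))
  cc <- convergence_check(wins)
  expect_equal(cc$max_diff, 0, tolerance = 1e-9)
  expect_error(convergence_check(list(umbrella_window(0, rnorm(100), 25))),
               ">= 200")
})

test_that("split-half difference localises a planted potential change", {
  # first half sampled from a stiff harmonic well, second half from a
  # soft one: the half-PMFs must differ most away from the well bottom
  set.seed(48)
  anchors <- seq(-1.2, 1.2, by = 0.4)
  wins <- lapply(anchors, function(a) {
    sd1 <- sqrt(kT / (25 + 4))   # biased width under U = 2 z^2
    sd2 <- sqrt(kT / (25 + 0.5)) # biased width under U = 0.25 z^2
    m1 <- a * 25 / (25 + 4)      # biased mean shifts toward 0 under U
    m2 <- a * 25 / (25 + 0.5)
    umbrella_window(a, c(rnorm(3000, m1, sd1), rnorm(3000, m2, sd2)), 25)
  })
  cc <- convergence_check(wins)
  # analytic PMF difference at |z| = 1: (2 - 0.25) z^2 = 1.75 kcal/mol
  idx <- which.min(abs(cc$z - 1))
  expect_equal(cc$pmf_first[idx] - cc$pmf_second[idx], 1.75,
               tolerance = 0.4)
  expect_gt(cc$max_diff, 1)
})
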