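test_that("the two-plane hysteresis counter scores hand-replayed traces", {
  # single monotone passage
  expect_equal(count_crossings(c(0, -7, -17))$n_down, 1L)
  # aborted excursion between the planes does not double-count
  lg <- count_crossings(c(0, -7, -3, -7, -17))
  expect_equal(lg$n_down, 1L)
  expect_equal(lg$n_up, 0L)
  # never crosses the entry plane
  expect_equal(count_crossings(c(0, -5.9, 0))$n_down, 0L)
  # return passage after completion scores an upward event
  lg2 <- count_crossings(c(0, -17, 0, -17))
  expect_equal(lg2$n_down, 2L)
  expect_equal(lg2$n_up, 1L)
  expect_error(count_crossings(c(0, -17), entry_z = -16, exit_z = -6),
               "entry_z")
})

test_that("counted events equal planted events on generator output", {
  for (s in c(1, 17, 3141)) {
    tr <- gen_particle_traces(1000, 2, 0.8, 20, stride = 20, seed = s)
    lg <- count_crossings(tr)
    expect_identical(lg$n_down, tr$planted_downward)
    expect_identical(lg$n_up, tr$planted_upward)
  }
})

test_that("time reversal swaps downward and upward counts", {
  tr <- gen_particle_traces(300, 1.5, 0.5, 30, stride = 10, seed = 5)
  fwd <- count_crossings(tr)
  rev_ <- count_crossings(tr$z[, ncol(tr$z):1], time_ps = tr$time_ps)
  expect_identical(rev_$n_down, fwd$n_up)
  expect_identical(rev_$n_up, fwd$n_down)
})

test_that("counting is robust to stride decimation of monotone passages", {
  z <- c(2, 1.5, -20, -21)                      # jumps both planes in one step
  expect_equal(count_crossings(z)$n_down, 1L)
  tr <- gen_particle_traces(200, 1, 0, 20, stride = 10, seed = 8)
  dec <- tr$z[, seq(1, ncol(tr$z), by = 5)]
  lg <- count_crossings(dec, time_ps = tr$time_ps[seq(1, ncol(tr$z), by = 5)])
  expect_identical(lg$n_down, tr$planted_downward)
})

test_that("permeation rates divide counts by time, whole and per block", {
  tr <- gen_particle_traces(500, 0.5, 0, 60, stride = 20, seed = 2)
  lg <- count_crossings(tr)
  r <- permeation_rate(lg)
  expect_equal(r$rate, lg$n_down / 60, tolerance = 1e-12)
  empty <- count_crossings(matrix(0, 2, 10))
  expect_equal(permeation_rate(empty)$rate, 0)
  # Poisson block statistics: mean of block rates near the true rate
  tr2 <- gen_particle_traces(2000, 0.8, 0, 440, stride = 100, seed = 3)
  lg2 <- count_crossings(tr2)
  br <- permeation_rate(lg2, blocks = c(40, 40))
  se <- sqrt(0.8 / (40 * length(br$block_rates)))
  expect_lt(abs(mean(br$block_rates) - 0.8), 3 * se + 0.05)
})

test_that("interval recalibration reports OLS slope, intercept and R2", {
  f <- c(4, 8, 12, 16, 20)
  # exact fixtures: summary.lm warns about perfect fits, which is the point
  fit_ff <- suppressWarnings(interval_recalibration(f, f))
  expect_equal(fit_ff$slope, 1, tolerance = 1e-12)
  expect_equal(fit_ff$r_squared, 1, tolerance = 1e-12)
  half <- suppressWarnings(interval_recalibration(f, f / 2))
  expect_equal(half$slope, 2, tolerance = 1e-12)
  expect_equal(half$r_squared, 1, tolerance = 1e-12)
  # noisy linear fixture vs closed-form normal equations
  set.seed(4)
  x <- rpois(24, 20); y <- 1.7 * x + rnorm(24)
  fit <- interval_recalibration(y, x)
  beta <- cov(x, y) / var(x)
  expect_equal(fit$slope, beta, tolerance = 1e-9)
  expect_equal(fit$intercept, mean(y) - beta * mean(x), tolerance = 1e-9)
  expect_equal(fit$slope_origin, sum(x * y) / sum(x^2), tolerance = 1e-9)
  expect_error(interval_recalibration(1:2, 1:2), "segments")
  expect_error(interval_recalibration(1:5, rep(3, 5)), "variance")
})

test_that("occupancy maps conserve in-cylinder totals", {
  # one stationary particle: a single occupied z-row
  z <- matrix(-10, 1, 50)
  m <- occupancy_map(z, time_ps = seq(0, 4900, by = 100), z_bin = 5,
                     time_bin = 1)
  occ_rows <- which(rowSums(m$counts) > 0)
  expect_length(occ_rows, 1L)
  expect_equal(sum(m$counts), 50)
  # totals equal a brute-force in-range recount
  set.seed(6)
  z2 <- matrix(runif(200 * 40, -50, 15), 200, 40)
  m2 <- occupancy_map(z2, time_ps = seq(0, 3900, by = 100), z_bin = 5,
                      time_bin = 1)
  expect_equal(sum(m2$counts), sum(z2 >= -45 & z2 <= 10))
  expect_error(occupancy_map(matrix(0, 1, 0), numeric(0)), "empty")
})

test_that("uniform occupancy stays within Poisson expectation", {
  set.seed(7)
  z <- matrix(runif(400 * 100, -45, 10), 400, 100)
  m <- occupancy_map(z, time_ps = seq(0, 99) * 1000, z_bin = 5, time_bin = 100)
  expected <- 400 * 100 / nrow(m$counts)
  expect_true(all(abs(m$counts - expected) < 4 * sqrt(expected)))
})

test_that("open intervals are the maximal runs of full gate occupancy", {
  mk_map <- function(open_bins) {
    counts <- matrix(1L, 4, length(open_bins))
    counts[2, !open_bins] <- 0L
    structure(list(counts = counts, z_edges = seq(-16, -6, length.out = 5),
                   t_edges_ps = seq(0, length(open_bins)) * 1000),
              class = "occupancy_map")
  }
  full <- open_intervals(mk_map(rep(TRUE, 10)), c(-16, -6))
  expect_equal(nrow(full$intervals), 1L)
  expect_equal(full$total_open_ns, 10)
  gap <- open_intervals(mk_map(c(rep(TRUE, 4), FALSE, rep(TRUE, 5))),
                        c(-16, -6))
  expect_equal(nrow(gap$intervals), 2L)
  # random 0/1 occupancy equals a run-length-encoding oracle
  set.seed(8)
  pat <- runif(60) > 0.4
  got <- open_intervals(mk_map(pat), c(-16, -6))
  rl <- rle(pat)
  expect_equal(nrow(got$intervals), sum(rl$values))
  expect_equal(got$total_open_ns, sum(rl$lengths[rl$values]))
  expect_error(open_intervals(mk_map(pat), c(100, 110)), "outside")
})

test_that("conductance arithmetic matches hand calculation and is linear", {
  g <- conductance_from_counts(15, 360, 600)
  expect_equal(g, 15 * 1.602176634e-19 / (360e-9 * 0.6) * 1e12,
               tolerance = 1e-12)
  expect_equal(round(g, 1), 11.1)
  expect_equal(conductance_from_counts(0, 360, 600), 0)
  expect_equal(conductance_from_counts(30, 360, 600), 2 * g)
  expect_error(conductance_from_counts(5, 0, 600), "duration")
  expect_error(conductance_from_counts(5, 360, 0), "voltage")
})
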