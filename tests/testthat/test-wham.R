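# analytic sampling targets used throughout: a single harmonic well,
# a quartic double well, and a flat potential

sample_harmonic_window <- function(kappa = 10, seed = 3) {
  sys <- rc_system(force = function(d) -kappa * d)
  run_window(sys, umbrella_window(0, 0), seed = seed, equil_steps = 2000,
             prod_steps = 500000, dt = 0.004, sample_every = 10)
}

sample_double_well <- function(a = 5, b = 1, seed = 11, spacing = 0.1) {
  sys <- rc_system(force = function(z) -4 * a * z * (z^2 - b^2))
  run_umbrella_ladder(sys, generate_windows(-2, 2, spacing), k = 300,
                      seed = seed, equil_steps = 2000, prod_steps = 200000,
                      dt = 3e-5, sample_every = 80)
}

aligned_rmse <- function(profile, analytic_fn, z_window) {
  ok <- is.finite(profile$pmf) & abs(profile$z) <= z_window &
    profile$counts >= 10
  res <- profile$pmf[ok] - analytic_fn(profile$z[ok])
  res <- res - mean(res)  # free energies are defined up to a constant
  sqrt(mean(res^2))
}

test_that("WHAM recovers a harmonic PMF from one unbiased window", {
  kappa <- 10
  w <- sample_harmonic_window(kappa)
  prof <- wham(list(w), n_bins = 100, n_boot = 0, reference = "min")
  expect_true(prof$converged)
  expect_lt(aligned_rmse(prof, function(z) 0.5 * kappa * z^2, 1.0), 0.2)
})

test_that("WHAM recovers an analytic double well under an umbrella ladder", {
  a <- 5; b <- 1
  wins <- sample_double_well(a, b)
  prof <- wham(wins, n_bins = 60, n_boot = 0, reference = "min")
  expect_true(prof$converged)
  expect_lt(aligned_rmse(prof, function(z) a * (z^2 - b^2)^2, 1.6), 0.5)
  m <- pmf_minimum(prof)
  bin_w <- diff(prof$z[1:2])
  expect_lt(abs(abs(m$z_min) - b), bin_w)
})

test_that("a flat potential yields a flat PMF within bootstrap noise", {
  sys <- rc_system(force = function(z) 0)
  wins <- run_umbrella_ladder(sys, generate_windows(0, 1, 0.1), k = 500,
                              seed = 5, equil_steps = 500,
                              prod_steps = 30000, dt = 4e-5,
                              sample_every = 40)
  prof <- wham(wins, n_bins = 60, n_boot = 40, reference = "min")
  ok <- is.finite(prof$pmf) & prof$counts >= 10
  centred <- prof$pmf[ok] - weighted.mean(prof$pmf[ok], prof$counts[ok])
  expect_true(all(abs(centred) < 3 * prof$se[ok] + 1e-6))
  expect_lt(max(abs(centred)), 1.5)
  expect_true(pmf_minimum(prof)$degenerate)
})

test_that("WHAM is robust to bin-count doubling and grid translation", {
  wins <- sample_double_well(seed = 21)
  p100 <- wham(wins, n_bins = 60, n_boot = 0, reference = "min")
  p200 <- wham(wins, n_bins = 120, n_boot = 0, reference = "min")
  ok <- is.finite(p200$pmf) & p200$counts >= 20 & abs(p200$z) < 1.5
  interp <- approx(p100$z[is.finite(p100$pmf)],
                   p100$pmf[is.finite(p100$pmf)], xout = p200$z[ok])$y
  expect_lt(max(abs(p200$pmf[ok] - interp), na.rm = TRUE), 0.5)
  # translating every window and sample leaves the PMF shape unchanged
  shift <- 3.7
  wins_s <- lapply(wins, function(w) {
    w$d0 <- w$d0 + shift; w$samples <- w$samples + shift; w
  })
  ps <- wham(wins_s, n_bins = 60, n_boot = 0, reference = "min")
  expect_equal(ps$z, p100$z + shift, tolerance = 1e-9)
  expect_equal(ps$pmf, p100$pmf, tolerance = 1e-9)
})

test_that("recovered shifts reproduce the window histograms", {
  wins <- sample_double_well(seed = 31, spacing = 0.2)
  n_bins <- 60
  prof <- wham(wins, n_bins = n_bins, n_boot = 0, reference = "min")
  kT <- KB * 300
  edges <- seq(min(unlist(lapply(wins, `[[`, "samples"))),
               max(unlist(lapply(wins, `[[`, "samples"))),
               length.out = n_bins + 1)
  p_unb <- exp(-prof$pmf / kT)
  p_unb[!is.finite(p_unb)] <- 0
  for (w in wins[seq(1, length(wins), by = 5)]) {
    n_i <- length(w$samples)
    bias <- exp(-bias_energy(prof$z, w$d0, w$k) / kT)
    pred <- p_unb * bias
    pred <- pred / sum(pred) * n_i
    obs <- tabulate(findInterval(w$samples, edges, rightmost.closed = TRUE,
                                 all.inside = TRUE), nbins = n_bins)
    keep <- pred > 5
    z_res <- (obs[keep] - pred[keep]) / sqrt(pred[keep])
    expect_lt(mean(abs(z_res)), 3)  # within multinomial noise
  }
})

test_that("WHAM input validation and convergence flags", {
  wins <- sample_double_well(seed = 41, spacing = 0.4)
  expect_warning(prof <- wham(wins, n_bins = 50, n_boot = 0, max_iter = 2),
                 "did not converge")
  expect_false(prof$converged)
  expect_true(is.finite(prof$residual) && prof$residual > 0)
  # disjoint windows: no overlap error names the gap
  sys <- rc_system(force = function(z) 0)
  far <- run_umbrella_ladder(sys, c(0, 5), k = 5000, seed = 1,
                             equil_steps = 100, prod_steps = 5000,
                             dt = 1e-5, sample_every = 10)
  expect_error(wham(far, n_bins = 400), "overlap")
})

test_that("PMF minima and differences behave analytically", {
  wins <- sample_double_well(a = 5, b = 1, seed = 51)
  prof <- wham(wins, n_bins = 100, n_boot = 10, reference = "bulk")
  m <- pmf_minimum(prof)
  expect_false(m$degenerate)
  expect_lt(abs(abs(m$z_min) - 1), 2 * diff(prof$z[1:2]))
  # profile against itself: difference exactly zero
  d0 <- pmf_difference(prof, prof)
  expect_identical(d0$difference, 0)
  # antisymmetry against a distinct profile
  wins2 <- sample_double_well(a = 3, b = 1, seed = 52)
  prof2 <- wham(wins2, n_bins = 100, n_boot = 10, reference = "bulk")
  d12 <- pmf_difference(prof, prof2)
  d21 <- pmf_difference(prof2, prof)
  expect_equal(d12$difference, -d21$difference, tolerance = 1e-9)
  # synthetic profiles with known depths difference
  mk <- function(depth) {
    z <- seq(0, 3, length.out = 100)
    pmf <- -depth * exp(-(z - 0.8)^2 / 0.18)
    structure(list(z = z, pmf = pmf, counts = rep(1000, 100),
                   se = rep(0.01, 100), converged = TRUE,
                   reference = "bulk", temperature = 300),
              class = "pmf_profile")
  }
  dd <- pmf_difference(mk(12), mk(7))
  expect_equal(dd$difference, 5, tolerance = 0.05)
  expect_error(pmf_difference(mk(5), {
    p <- mk(5); p$z <- p$z + 100; p
  }), "disjoint")
})
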