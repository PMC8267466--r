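test_that("langevin step is identity at zero force and temperature", {
  st <- list(x = c(1, 2, 3), time = 0)
  out <- langevin_step(st, function(x) rep(0, 3), dt = 0.01, temperature = 0)
  expect_identical(out$x, st$x)
  expect_equal(out$time, 0.01)
  expect_error(
    langevin_step(st, function(x) rep(NaN, 3), dt = 0.01),
    "non-finite")
})

test_that("seeded integration is reproducible bit for bit", {
  force <- function(x) -5 * x
  run <- function(seed) {
    set.seed(seed)
    st <- list(x = 0.5, time = 0)
    for (i in 1:50) st <- langevin_step(st, force, dt = 0.01)
    st$x
  }
  expect_identical(run(42), run(42))
  expect_false(run(42) == run(43))
})

test_that("harmonic sampling reproduces the Boltzmann variance", {
  kappa <- 10
  set.seed(99)
  res <- sheetmem:::run_langevin_1d(0, function(x) -kappa * x,
                                    n_steps = 150000, dt = 0.002,
                                    temperature = 300, equil_steps = 5000,
                                    sample_every = 60)
  v <- var(res$x)
  target <- KB * 300 / kappa
  se <- v * sqrt(2 / (length(res$x) - 1))
  expect_lt(abs(v - target), 3 * se + 0.02 * target)
})

test_that("long-run 1-D density matches the Boltzmann weight (chi-square)", {
  kappa <- 12
  set.seed(4)
  res <- sheetmem:::run_langevin_1d(0, function(x) -kappa * x,
                                    n_steps = 250000, dt = 0.001,
                                    temperature = 300, equil_steps = 5000,
                                    sample_every = 120)
  sdv <- sqrt(KB * 300 / kappa)
  edges <- seq(-3 * sdv, 3 * sdv, length.out = 13)
  obs <- table(cut(res$x[abs(res$x) < 3 * sdv], edges))
  p <- diff(pnorm(edges, sd = sdv)) / diff(pnorm(c(-3, 3) * sdv, sd = sdv))
  expect_gt(chisq.test(as.integer(obs), p = p)$p.value, 0.01)
})

test_that("insertion simulation bookkeeping and determinism", {
  sheet <- assign_aging_state(build_triangular_nanosheet(1.5), "fresh")
  pot <- implicit_membrane(tail_well_depth = -10)
  sys <- insertion_system(sheet, pot)
  tr <- simulate(sys, n_steps = 1000, report_interval = 100, seed = 8)
  expect_s3_class(tr, "md_trajectory")
  expect_length(tr$times, 11)  # 10 frames plus the initial one
  expect_true(all(vapply(tr$frames, nrow, integer(1)) == nrow(sheet$atoms)))
  expect_identical(tr$metadata$seed, 8)
  tr2 <- simulate(sys, n_steps = 1000, report_interval = 100, seed = 8)
  expect_identical(tr$frames, tr2$frames)
  expect_false(identical(
    tr$frames,
    simulate(sys, n_steps = 1000, report_interval = 100, seed = 9)$frames))
})

test_that("attractive system inserts from 4.2 nm; repulsive never enters", {
  sheet <- assign_aging_state(build_triangular_nanosheet(1.5), "fresh")
  att <- implicit_membrane(tail_well_depth = -6 * 1.6744)
  tr <- simulate(insertion_system(sheet, att, start_distance = 4.2),
                 n_steps = 20000, report_interval = 100, seed = 5)
  z <- tr$metadata$com[, 3]
  expect_equal(z[1], 4.2)
  expect_lt(mean(abs(tail(z, 100))), 4.2)
  rep_pot <- implicit_membrane(tail_well_depth = 30, head_barrier = 10)
  trR <- simulate(insertion_system(sheet, rep_pot, start_distance = 4.2),
                  n_steps = 20000, report_interval = 50, seed = 6)
  expect_true(all(abs(trR$metadata$com[, 3]) >= rep_pot$half_thickness))
})

test_that("deeper tail wells do not increase the equilibrium CoM height", {
  sheet <- assign_aging_state(build_triangular_nanosheet(1.5), "fresh")
  eq_h <- function(depth, seed) {
    pot <- implicit_membrane(tail_well_depth = depth)
    tr <- simulate(insertion_system(sheet, pot), n_steps = 15000,
                   report_interval = 50, seed = seed)
    mean(abs(tail(tr$metadata$com[, 3], 150)))
  }
  seeds <- 1:6
  deep <- vapply(seeds, function(s) eq_h(-6 * 1.6744, s), numeric(1))
  shallow <- vapply(seeds, function(s) eq_h(-6 * 1.0450, s), numeric(1))
  expect_lt(mean(deep), mean(shallow))
})

test_that("membrane relaxation rejects overlapping particles and lifts heads", {
  mem <- build_coarse_membrane(16, spacing = 0.7, beads_per_chain = 3)
  bad <- matrix(mem$pos[1, ] + 0.001, 1, 3)
  expect_error(relax_membrane(mem, bad, n_steps = 10), "overlap")
  # zero-temperature mechanics: a flat midplane sheet pushes the bilayer
  # apart locally
  sheet <- assign_aging_state(build_triangular_nanosheet(1.5), "fresh")
  sp <- sheet_pose(sheet, mem, 0, tilt = 0)
  fr <- relax_membrane(mem, sp, n_steps = 800, temperature = 0, seed = 1)
  fr0 <- relax_membrane(mem, NULL, n_steps = 800, temperature = 0, seed = 1)
  expect_gt(membrane_thickness(fr), membrane_thickness(fr0))
})
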