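#' Overdamped Langevin step
#'
#' One Euler-Maruyama update of the overdamped (Brownian) Langevin
#' equation: `x <- x + dt * F(x) / (friction * mass) + xi`, with `xi`
#' Gaussian noise of variance `2 kB T dt / (friction * mass)` per
#' coordinate. At zero temperature and zero force the state is unchanged.
#' Randomness is drawn from R's global RNG stream, so runs are fully
#' reproducible after `set.seed()`.
#'
#' @param state List with numeric vector `x` (any number of degrees of
#'   freedom) and scalar `time` (ps).
#' @param force_fn Function of `x` returning the force vector (kJ/mol/nm
#'   for translational coordinates).
#' @param dt Time step (ps, > 0).
#' @param temperature Temperature (K, >= 0).
#' @param friction Friction coefficient gamma (1/ps, > 0).
#' @param mass Particle mass (g/mol, > 0).
#' @return Updated state.
#' @export
langevin_step <- function(state, force_fn, dt, temperature = 300,
                          friction = 1, mass = 1) {
  stopifnot(dt > 0, temperature >= 0, friction > 0, mass > 0)
  f <- force_fn(state$x)
  if (any(!is.finite(f))) {
    stop("non-finite forces at x = ", paste(signif(state$x, 6), collapse = ", "),
         " (t = ", state$time, " ps)")
  }
  mob <- 1 / (friction * mass)
  sd <- sqrt(2 * KB * temperature * dt * mob)
  state$x <- state$x + dt * mob * f +
    if (sd > 0) stats::rnorm(length(state$x), sd = sd) else 0
  state$time <- state$time + dt
  state
}

# tight-loop driver for a scalar coordinate; records every `sample_every`
# steps after `equil_steps`. Returns list(x = samples, t = times, x_final).
run_langevin_1d <- function(x0, force_fn, n_steps, dt, temperature,
                            mobility = 1, equil_steps = 0, sample_every = 1) {
  sd <- sqrt(2 * KB * temperature * dt * mobility)
  n_rec <- (n_steps - equil_steps) %/% sample_every
  xs <- numeric(n_rec)
  ts <- numeric(n_rec)
  x <- x0
  k <- 0L
  noise <- stats::rnorm(n_steps, sd = sd)
  for (i in seq_len(n_steps)) {
    f <- force_fn(x)
    if (!is.finite(f)) {
      stop("non-finite force at x = ", signif(x, 6), ", step ", i)
    }
    x <- x + dt * mobility * f + noise[i]
    if (i > equil_steps && (i - equil_steps) %% sample_every == 0L) {
      k <- k + 1L
      xs[k] <- x
      ts[k] <- i * dt
    }
  }
  list(x = xs, t = ts, x_final = x)
}

# vectorized replica driver: integrates a whole vector of independent
# scalar coordinates (e.g. one per umbrella window) in one time loop.
# Returns samples as an (n_recorded x n_replica) matrix.
run_langevin_vec <- function(x0, force_fn, n_steps, dt, temperature,
                             mobility = 1, equil_steps = 0, sample_every = 1) {
  m <- length(x0)
  sd <- sqrt(2 * KB * temperature * dt * mobility)
  n_rec <- (n_steps - equil_steps) %/% sample_every
  xs <- matrix(NA_real_, n_rec, m)
  ts <- numeric(n_rec)
  x <- x0
  k <- 0L
  for (i in seq_len(n_steps)) {
    f <- force_fn(x)
    if (any(!is.finite(f))) {
      stop("non-finite force in replica ", which(!is.finite(f))[1],
           " at step ", i)
    }
    x <- x + dt * mobility * f + stats::rnorm(m, sd = sd)
    if (i > equil_steps && (i - equil_steps) %% sample_every == 0L) {
      k <- k + 1L
      xs[k, ] <- x
      ts[k] <- i * dt
    }
  }
  list(x = xs, t = ts)
}

#' Assemble a sheet + implicit-membrane simulation system
#'
#' The sheet is treated as a rigid body with four stochastic degrees of
#' freedom: centre-of-mass x, y (free lateral diffusion under periodic
#' boundaries), z (governed by the implicit-membrane potential, with
#' reflecting walls far from the membrane) and the tilt angle between the
#' sheet normal and the membrane normal.
#'
#' @param sheet A parameterized [build_triangular_nanosheet()] sheet.
#' @param potential An [implicit_membrane()] object.
#' @param box Simulation box (nm), periodic in x,y.
#' @param start_distance Initial sheet CoM distance from the midplane (nm);
#'   the reference systems start at about 4.2 nm.
#' @param start_tilt Initial tilt (radians).
#' @param friction,mass Langevin friction (1/ps) and effective mass.
#' @param wall Reflecting-wall distance from the midplane (nm).
#' @return A `sim_system` list.
#' @export
insertion_system <- function(sheet, potential, box = c(6, 6, 12),
                             start_distance = 4.2, start_tilt = 0,
                             friction = 1, mass = 1, wall = 4.5) {
  stopifnot(inherits(sheet, "nanosheet"), inherits(potential, "implicit_membrane"))
  structure(list(sheet = sheet, potential = potential, box = box,
                 start_distance = start_distance, start_tilt = start_tilt,
                 friction = friction, mass = mass, wall = wall),
            class = "sim_system")
}

# analytic z-force and tilt-torque of the implicit membrane potential
# (vectorized over z)
membrane_force_z <- function(z, tilt, params) {
  s0 <- z - params$midplane
  s <- abs(s0)
  w <- params$width; h <- params$half_thickness
  t <- (s - (h - w)) / (2 * w)
  dS <- ifelse(t > 0 & t < 1, 30 * t^2 * (t - 1)^2 / (2 * w), 0)
  u <- (s - h) / w
  db <- numeric(length(u))
  in_supp <- abs(u) < 1
  us <- u[in_supp]
  db[in_supp] <- exp(1 - 1 / (1 - us^2)) * (-2 * us / (1 - us^2)^2) / w
  dUds <- -(params$tail_well_depth + params$orient_coupling * cos(tilt)^2) * dS +
    params$head_barrier * db
  -dUds * sign(s0)
}

membrane_torque_tilt <- function(z, tilt, params) {
  s <- abs(z - params$midplane)
  w <- params$width; h <- params$half_thickness
  t <- (s - (h - w)) / (2 * w)
  f_well <- 1 - smoothstep(t)
  params$orient_coupling * f_well * sin(2 * tilt)
}

#' Run the coarse insertion simulation
#'
#' Overdamped Langevin dynamics of the rigid sheet in the implicit
#' membrane. Returns a trajectory of sheet-atom positions: the initial
#' frame plus one frame every `report_interval` steps. Identical
#' `(system, n_steps, report_interval, seed)` inputs give bit-identical
#' trajectories.
#'
#' @param system An [insertion_system()].
#' @param n_steps Number of integration steps (>= 1).
#' @param report_interval Steps between recorded frames.
#' @param seed Integer RNG seed.
#' @param dt Time step (ps).
#' @param temperature Temperature (K).
#' @return An [md_trajectory()] whose metadata records every parameter
#'   used; `metadata$com` and `metadata$tilt` carry the per-frame rigid
#'   body coordinates.
#' @export
simulate <- function(system, n_steps, report_interval = 100, seed = 1,
                     dt = 1e-3, temperature = 300) {
  stopifnot(inherits(system, "sim_system"), n_steps >= 1)
  set.seed(seed)
  p <- system$potential
  mob <- 1 / (system$friction * system$mass)
  sd_t <- sqrt(2 * KB * temperature * dt * mob)
  # rotational mobility of the same scale; tilt is an angle, mobility 1/(g I)
  mob_r <- mob
  sd_r <- sqrt(2 * KB * temperature * dt * mob_r)

  com <- c(system$box[1] / 2, system$box[2] / 2,
           p$midplane + system$start_distance)
  tilt <- system$start_tilt
  z_hi <- p$midplane + system$wall
  z_lo <- p$midplane - system$wall

  n_frames <- n_steps %/% report_interval + 1L
  com_rec <- matrix(NA_real_, n_frames, 3)
  tilt_rec <- numeric(n_frames)
  times <- numeric(n_frames)
  com_rec[1, ] <- com; tilt_rec[1] <- tilt; times[1] <- 0
  k <- 1L

  nz <- stats::rnorm(n_steps, sd = sd_t)
  nx <- stats::rnorm(n_steps, sd = sd_t)
  ny <- stats::rnorm(n_steps, sd = sd_t)
  nr <- stats::rnorm(n_steps, sd = sd_r)

  for (i in seq_len(n_steps)) {
    fz <- membrane_force_z(com[3], tilt, p)
    ft <- membrane_torque_tilt(com[3], tilt, p)
    if (!is.finite(fz) || !is.finite(ft)) {
      stop("non-finite forces at step ", i, " (z = ", signif(com[3], 6), ")")
    }
    com[1] <- (com[1] + nx[i]) %% system$box[1]
    com[2] <- (com[2] + ny[i]) %% system$box[2]
    com[3] <- com[3] + dt * mob * fz + nz[i]
    if (com[3] > z_hi) com[3] <- 2 * z_hi - com[3]
    if (com[3] < z_lo) com[3] <- 2 * z_lo - com[3]
    tilt <- tilt + dt * mob_r * ft + nr[i]
    if (i %% report_interval == 0L) {
      k <- k + 1L
      com_rec[k, ] <- com
      tilt_rec[k] <- tilt
      times[k] <- i * dt
    }
  }

  ref <- sheet_positions(system$sheet)
  frames <- lapply(seq_len(n_frames), function(j) {
    place_sheet(ref, com_rec[j, ], tilt_rec[j])
  })
  top <- sheet_topology(system$sheet)
  md_trajectory(top, times, frames, system$box,
                metadata = list(seed = seed, temperature = temperature,
                                dt = dt, friction = system$friction,
                                mass = system$mass,
                                report_interval = report_interval,
                                potential = unclass(p),
                                com = com_rec, tilt = tilt_rec))
}

# rigid placement: rotate reference coords about the x axis by `tilt`,
# then translate to `com`
place_sheet <- function(ref, com, tilt) {
  ct <- cos(tilt); st <- sin(tilt)
  rot <- rbind(c(1, 0, 0), c(0, ct, -st), c(0, st, ct))
  out <- ref %*% t(rot)
  out[, 1] <- out[, 1] + com[1]
  out[, 2] <- out[, 2] + com[2]
  out[, 3] <- out[, 3] + com[3]
  colnames(out) <- c("x", "y", "z")
  out
}

# md_frame-style topology for a sheet
sheet_topology <- function(sheet) {
  at <- sheet$atoms
  data.frame(name = at$element, element = at$element, group = "sheet",
             region = NA_character_, leaflet = NA_character_,
             lipid_id = NA_integer_, chain_index = NA_integer_,
             mass = unname(ATOMIC_MASS[at$element]),
             sigma = at$sigma %||% NA_real_,
             epsilon = at$epsilon %||% NA_real_,
             charge = at$charge %||% NA_real_,
             stringsAsFactors = FALSE)
}

#' Relax the bead membrane around a (fixed) nanosheet
#'
#' Overdamped Langevin relaxation of the bead bilayer: beads are bonded
#' along each lipid (head-C1-...-Cn harmonic springs at the built rest
#' lengths), weakly tethered to their lattice sites (anisotropic, soft in
#' z so the bilayer can swell), and repelled by the sheet atoms through a
#' soft exponential wall `A exp(-r / lambda)`. The sheet itself is held
#' fixed; this stage exists to give the thickness and chain-order analyses
#' a membrane that responds to an inserted particle.
#'
#' Structural observables are read from the time-averaged (mean)
#' structure over the final `avg_fraction` of the run, the standard way
#' to separate a mechanical deformation from bead-level thermal noise;
#' the final instantaneous positions are kept in attribute `final_pos`.
#'
#' @param membrane A [build_coarse_membrane()] object.
#' @param sheet_pos Optional n x 3 matrix of sheet atom positions (nm).
#' @param n_steps,dt,temperature,friction Integration controls.
#' @param seed RNG seed.
#' @param k_bond Intra-lipid bond spring (kJ/mol/nm^2).
#' @param k_tether_xy,k_tether_z Lattice tether springs (kJ/mol/nm^2).
#' @param repulsion_a,repulsion_lambda Soft-wall amplitude (kJ/mol) and
#'   decay length (nm) of the sheet-bead repulsion.
#' @param attraction_b,attraction_range Amplitude (kJ/mol) and decay
#'   length (nm) of an optional attraction of tail beads to the sheet
#'   surface; scaling the amplitude with the sulfur well depth eps_S
#'   transfers the fresh/aged contrast to the bead membrane.
#' @param avg_fraction Final fraction of the run averaged into the
#'   returned mean structure.
#' @param nlist_every,nlist_range Refresh interval (steps) and capture
#'   range (nm) of the bead-sheet neighbour list.
#' @return `md_frame` of the relaxed membrane (beads only), positions
#'   time-averaged.
#' @export
relax_membrane <- function(membrane, sheet_pos = NULL, n_steps = 4000,
                           dt = 5e-5, temperature = 300, friction = 1,
                           seed = 1, k_bond = 1200, k_tether_xy = 40,
                           k_tether_z = 40, repulsion_a = 500,
                           repulsion_lambda = 0.12, attraction_b = 0,
                           attraction_range = 0.3, avg_fraction = 0.5,
                           nlist_every = 100, nlist_range = 1.4) {
  stopifnot(inherits(membrane, "coarse_membrane"))
  set.seed(seed)
  pos <- membrane$pos
  ref <- membrane$pos
  box <- membrane$box
  if (!is.null(sheet_pos)) {
    d0 <- pair_dists(sheet_pos, pos, box, c(TRUE, TRUE, FALSE))
    if (min(d0) < 0.05) {
      stop("overlapping initial particles: sheet-bead distance ",
           signif(min(d0), 3), " nm")
    }
  }
  # bond list along each lipid: head -> C1 -> ... -> Cn
  top <- membrane$topology
  bi <- integer(0); bj <- integer(0)
  for (lid in unique(top$lipid_id)) {
    idx <- which(top$lipid_id == lid)
    idx <- idx[order(ifelse(is.na(top$chain_index[idx]), 0L, top$chain_index[idx]))]
    bi <- c(bi, idx[-length(idx)])
    bj <- c(bj, idx[-1])
  }
  r0 <- sqrt(rowSums((pos[bi, , drop = FALSE] - pos[bj, , drop = FALSE])^2))
  bond_grp <- c(bi, bj)
  is_tail <- !is.na(top$region) & top$region == "tail"

  mob <- 1 / (friction * 1)
  sd <- sqrt(2 * KB * temperature * dt * mob)
  n <- nrow(pos)
  kt <- matrix(rep(c(k_tether_xy, k_tether_xy, k_tether_z), each = n), n, 3)
  if (!is.null(sheet_pos)) {
    ns <- nrow(sheet_pos)
    ia_all <- rep(seq_len(n), times = ns)  # bead index of each bead-sheet pair
    ib_all <- rep(seq_len(ns), each = n)
    ia <- ia_all; ib <- ib_all
  }

  avg_from <- n_steps - floor(avg_fraction * n_steps) + 1L
  pos_sum <- matrix(0, n, 3)
  n_avg <- 0L
  for (step in seq_len(n_steps)) {
    if (!is.null(sheet_pos) && (step - 1L) %% nlist_every == 0L) {
      # refresh bead-sheet neighbour list; the soft wall is negligible
      # beyond a few decay lengths
      dall <- pair_dists(sheet_pos, pos, box, c(TRUE, TRUE, FALSE))
      close_beads <- which(apply(dall, 2, min) < nlist_range)
      keep <- ia_all %in% close_beads
      ia <- ia_all[keep]; ib <- ib_all[keep]
    }
    f <- -kt * (pos - ref)
    db <- pos[bi, , drop = FALSE] - pos[bj, , drop = FALSE]
    dl <- sqrt(rowSums(db^2))
    fb <- -k_bond * (dl - r0) / pmax(dl, 1e-12) * db
    acc <- rowsum(rbind(fb, -fb), bond_grp)
    rows <- as.integer(rownames(acc))
    f[rows, ] <- f[rows, ] + acc
    if (!is.null(sheet_pos) && length(ia) > 0) {
      # soft-wall repulsion (all beads) plus a longer-ranged attraction
      # of tail beads to the sheet surface, minimum image in x,y
      dx <- pos[ia, , drop = FALSE] - sheet_pos[ib, , drop = FALSE]
      dx <- min_image(dx, box, c(TRUE, TRUE, FALSE))
      d <- sqrt(rowSums(dx^2))
      mag <- repulsion_a / repulsion_lambda * exp(-d / repulsion_lambda)
      if (attraction_b > 0) {
        mag <- mag - ifelse(is_tail[ia],
                            attraction_b / attraction_range *
                              exp(-d / attraction_range), 0)
      }
      acc2 <- rowsum(mag / pmax(d, 1e-12) * dx, ia)
      rows2 <- as.integer(rownames(acc2))
      f[rows2, ] <- f[rows2, ] + acc2
    }
    pos <- pos + dt * mob * f + matrix(stats::rnorm(3 * n, sd = sd), n, 3)
    if (step >= avg_from) {
      pos_sum <- pos_sum + pos
      n_avg <- n_avg + 1L
    }
  }
  out <- membrane_frame(membrane)
  out$pos <- pos_sum / n_avg
  attr(out, "final_pos") <- pos
  out
}
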