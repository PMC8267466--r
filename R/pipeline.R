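#' Run the full insertion pipeline
#'
#' Chains the stages of the study design: build the parameterized sheet,
#' build the bead membrane, run the coarse insertion simulation, run the
#' umbrella ladder and WHAM to a PMF, and compute the trajectory
#' statistics. Outputs land in a deterministic directory layout
#' (`structures/`, `trajectories/`, `windows/`, `pmf/`, `analysis/`) with
#' a JSON manifest recording the seed, package version, every parameter
#' used and an md5 hash of every output file, so identical config + seed
#' give hash-identical reruns. Completed stages whose outputs already
#' exist are reused unless `overwrite = TRUE`.
#'
#' The umbrella stage samples the implicit-membrane reaction coordinate;
#' its ladder is truncated to the reflecting-wall span actually reachable
#' by the coarse simulator. Stage failures halt the run with the stage
#' name.
#'
#' @param config Config list from [load_config()] / [default_config()].
#' @param out_dir Output root directory.
#' @param overwrite Recompute stages whose outputs exist.
#' @return Invisibly, the manifest list.
#' @export
pipeline_run <- function(config = default_config(), out_dir,
                         overwrite = FALSE) {
  dirs <- file.path(out_dir, c("structures", "trajectories", "windows",
                               "pmf", "analysis"))
  for (d in dirs) dir.create(d, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  manifest <- list(seed = seed,
                   package_version = as.character(utils::packageVersion("sheetmem")),
                   config = config, stages = list(), files = list())
  stage <- function(name, outputs, fn) {
    if (!overwrite && all(file.exists(outputs))) {
      manifest$stages[[name]] <<- "reused"
      return(invisible())
    }
    ok <- tryCatch({ fn(); TRUE }, error = function(e) e)
    if (inherits(ok, "error")) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(ok))
    }
    manifest$stages[[name]] <<- "completed"
  }

  # --- structures ------------------------------------------------------
  sheet_gro <- file.path(out_dir, "structures", "sheet.gro")
  sheet_pdb <- file.path(out_dir, "structures", "sheet.pdb")
  mem_gro <- file.path(out_dir, "structures", "membrane.gro")
  sheet <- assign_aging_state(
    build_triangular_nanosheet(config$sheet$side_length, config$lattice),
    config$sheet$aging)
  mem <- build_coarse_membrane(config$membrane$n_lipids_per_leaflet,
                               config$membrane$spacing,
                               config$membrane$beads_per_chain,
                               config$membrane$head_z)
  stage("structures", c(sheet_gro, sheet_pdb, mem_gro), function() {
    write_gro(sheet, sheet_gro)
    write_pdb(sheet, sheet_pdb)
    write_gro(membrane_frame(mem), mem_gro)
  })

  # --- simulate --------------------------------------------------------
  sim <- config$simulator
  eps_s <- sheet$aging$species$S$epsilon
  pot <- implicit_membrane(
    midplane = 0, half_thickness = sim$half_thickness,
    tail_well_depth = -sim$tail_depth_per_eps * eps_s,
    head_barrier = sim$head_barrier, width = sim$interface_width,
    orient_coupling = sim$orient_coupling)
  traj_bin <- file.path(out_dir, "trajectories", "insertion.trj")
  com_tsv <- file.path(out_dir, "analysis", "com_z.tsv")
  traj <- NULL
  stage("simulate", traj_bin, function() {
    traj <<- simulate(
      insertion_system(sheet, pot, start_distance = sim$start_distance,
                       friction = sim$friction, mass = sim$mass),
      n_steps = sim$n_steps, report_interval = sim$report_interval,
      seed = seed, dt = sim$dt, temperature = config$temperature)
    write_trajectory(traj, traj_bin, "bin")
    utils::write.table(
      data.frame(time = traj$times, com_z = traj$metadata$com[, 3]),
      com_tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  })

  # --- umbrella + wham -------------------------------------------------
  umb <- config$umbrella
  pmf_tsv <- file.path(out_dir, "pmf", "pmf.tsv")
  stage("umbrella_wham", pmf_tsv, function() {
    d0s <- generate_windows(umb$d_min, umb$d_max, umb$spacing)
    rc <- rc_system_implicit(pot)
    windows <- run_umbrella_ladder(rc, d0s, k = umb$k,
                                   seed = seed + 1000L,
                                   equil_steps = umb$equil_steps,
                                   prod_steps = umb$prod_steps,
                                   dt = umb$dt,
                                   sample_every = umb$sample_every,
                                   temperature = config$temperature)
    for (i in seq_along(windows)) {
      write_window(windows[[i]],
                   file.path(out_dir, "windows", sprintf("window_%03d.txt", i)))
    }
    profile <- wham(windows, temperature = config$temperature,
                    n_bins = config$wham$n_bins, tol = config$wham$tol,
                    max_iter = config$wham$max_iter,
                    n_boot = config$wham$n_boot,
                    bulk_fraction = config$wham$bulk_fraction)
    write_pmf(profile, pmf_tsv)
  })

  # --- analysis --------------------------------------------------------
  ana <- config$analysis
  ana_csv <- file.path(out_dir, "analysis", "summary.csv")
  stage("analysis", ana_csv, function() {
    if (is.null(traj)) {
      traj <- read_trajectory_bin(traj_bin, sheet_topology(sheet))
    }
    # pose the sheet at its equilibrium depth in the bead membrane
    tail_z <- traj$metadata$com[, 3]
    depth <- mean(abs(utils::tail(tail_z, length(tail_z) %/% 2)))
    frame <- posed_frame(sheet, mem, depth)
    si <- select_atoms(frame, group = "sheet")
    li <- select_atoms(frame, group = "lipid")
    splits <- split_head_tail_contacts(frame, si, li, ana$contact_cutoff)
    loc <- local_lipid_selection(frame, si, ana$local_radius)
    sc <- tryCatch(chain_order(frame, if (length(loc)) loc else NULL)$s_chain,
                   error = function(e) NA_real_)
    utils::write.csv(data.frame(
      statistic = c("contacts_total", "contacts_head", "contacts_tail",
                    "local_lipids", "s_chain_local", "thickness",
                    "mean_com_depth"),
      value = c(splits$head + splits$tail, splits$head, splits$tail,
                length(loc), sc, membrane_thickness(frame), depth)),
      ana_csv, row.names = FALSE)
  })

  # --- manifest --------------------------------------------------------
  outputs <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  outputs <- outputs[basename(outputs) != "manifest.json"]
  hashes <- tools::md5sum(outputs)
  manifest$files <- as.list(stats::setNames(unname(hashes),
                                            sub(paste0("^", out_dir, "/?"), "",
                                                outputs)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Pose a sheet in a bead membrane as a single frame
#'
#' Places the (rigid) sheet at height `depth` above the membrane
#' midplane, tilted by `tilt` (pi/2 = inserted edge-on, the pose sheets
#' adopt inside membranes; 0 = flat), and combines it with the membrane
#' beads into one analysable [md_frame()]. Custom bead positions (e.g.
#' the mean structure from [relax_membrane()]) may be supplied.
#'
#' @param sheet A parameterized nanosheet.
#' @param membrane A [build_coarse_membrane()] object.
#' @param depth Sheet CoM height above the midplane (nm).
#' @param tilt Sheet tilt (radians).
#' @param bead_pos Optional replacement bead positions.
#' @return An `md_frame` with sheet atoms first, then membrane beads.
#' @export
posed_frame <- function(sheet, membrane, depth, tilt = pi / 2,
                        bead_pos = NULL) {
  ref <- sheet_positions(sheet)
  com <- c(membrane$box[1] / 2, membrane$box[2] / 2, membrane$midplane + depth)
  sp <- place_sheet(ref, com, tilt)
  top <- rbind(sheet_topology(sheet),
               cbind(membrane$topology, sigma = NA_real_,
                     epsilon = NA_real_, charge = NA_real_))
  rownames(top) <- NULL
  pos <- rbind(sp, bead_pos %||% membrane$pos)
  colnames(pos) <- c("x", "y", "z")
  md_frame(top, pos, c(membrane$box[1], membrane$box[2],
                       membrane$box[3]))
}

#' Sheet atom positions for a given pose
#'
#' @inheritParams posed_frame
#' @return n x 3 matrix of sheet atom positions (nm).
#' @export
sheet_pose <- function(sheet, membrane, depth, tilt = pi / 2) {
  place_sheet(sheet_positions(sheet),
              c(membrane$box[1] / 2, membrane$box[2] / 2,
                membrane$midplane + depth), tilt)
}
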