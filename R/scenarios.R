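#' Scripted insertion scenarios with embedded ground truth
#'
#' Deterministic trajectories of a small fresh nanosheet over a bead
#' bilayer in a static water bath, following the qualitative stages the
#' insertion simulations show: free approach through water, optional
#' face-to-face preorganization on the membrane surface, vertex-first
#' insertion, and dehydration of the sheet surface as it leaves the water
#' slab. Each trajectory carries machine-readable ground truth computed by
#' an independent brute-force pass inside the generator, so the analysis
#' functions can be tested against it exactly.
#'
#' Scenarios: `"approach"` (descends to just above the head groups),
#' `"preorganize_insert"` (flat adhesion plateau, reorientation, then
#' insertion), `"direct_insert"` (inserts without preorganization),
#' `"no_insert"` (hovers above the membrane for the whole run).
#'
#' @param name Scenario name.
#' @param seed Seed for water placement and the lateral offset; the sheet
#'   path itself is deterministic.
#' @param n_waters Number of water oxygens in the bath.
#' @param contact_cutoff,water_cutoff Cutoffs (nm) used for the embedded
#'   ground-truth contact and bound-water series (defaults 0.5 and 0.35,
#'   matching the analysis conventions).
#' @return An [md_trajectory()] whose `truth` element holds per-frame
#'   `contacts`, `head_contacts`, `tail_contacts`, `bound_waters`, the
#'   `insertion_time` (ps, or NA) and the head-plane height used.
#' @export
scripted_scenario <- function(name = c("approach", "preorganize_insert",
                                       "direct_insert", "no_insert"),
                              seed = 1, n_waters = 250,
                              contact_cutoff = 0.5, water_cutoff = 0.35) {
  if (!is.character(name) || length(name) != 1 ||
      !name %in% c("approach", "preorganize_insert", "direct_insert", "no_insert")) {
    stop("unknown scenario name: ", paste(name, collapse = ", "))
  }
  set.seed(seed)
  mem <- build_coarse_membrane(n_lipids_per_leaflet = 36, spacing = 0.6,
                               beads_per_chain = 3, head_z = 1.9)
  sheet <- assign_aging_state(build_triangular_nanosheet(1.5), "fresh")
  box <- c(mem$box[1], mem$box[2], 12)
  head_plane <- mem$head_z  # upper head-bead plane (midplane at 0)

  # static water bath above the membrane
  wpos <- cbind(stats::runif(n_waters, 0, box[1]),
                stats::runif(n_waters, 0, box[2]),
                stats::runif(n_waters, head_plane + 0.25, 6.5))

  n_frames <- 61L
  dt_rep <- 10  # ps between frames
  center <- c(box[1] / 2, box[2] / 2)

  path <- scenario_path(name, n_frames, head_plane)
  ref <- sheet_positions(sheet)
  sheet_frames <- lapply(seq_len(n_frames), function(j) {
    place_sheet(ref, c(center, path$z[j]), path$tilt[j])
  })

  wtop <- data.frame(name = "OW", element = "O", group = "water",
                     region = NA_character_, leaflet = NA_character_,
                     lipid_id = NA_integer_, chain_index = NA_integer_,
                     mass = 18.015, sigma = NA_real_, epsilon = NA_real_,
                     charge = NA_real_, stringsAsFactors = FALSE)
  wtop <- wtop[rep(1, n_waters), ]
  mtop <- mem$topology
  mtop$sigma <- NA_real_; mtop$epsilon <- NA_real_; mtop$charge <- NA_real_
  topology <- rbind(sheet_topology(sheet), mtop, wtop)
  rownames(topology) <- NULL
  ns <- nrow(ref); nb <- nrow(mem$pos)

  frames <- lapply(sheet_frames, function(sp) {
    out <- rbind(sp, mem$pos, wpos)
    colnames(out) <- c("x", "y", "z")
    out
  })

  # --- embedded ground truth: independent brute-force pass -------------
  pbc <- c(TRUE, TRUE, FALSE)
  head_idx <- which(mtop$region == "head")
  tail_idx <- which(mtop$region == "tail")
  truth_contacts <- integer(n_frames)
  truth_head <- integer(n_frames)
  truth_tail <- integer(n_frames)
  truth_waters <- integer(n_frames)
  com_z <- numeric(n_frames)
  masses <- sheet_masses(sheet)
  for (j in seq_len(n_frames)) {
    sp <- sheet_frames[[j]]
    dmat <- pair_dists(sp, mem$pos, box, pbc)
    mind <- apply(dmat, 2, min)
    truth_contacts[j] <- sum(mind < contact_cutoff)
    truth_head[j] <- sum(mind[head_idx] < contact_cutoff)
    truth_tail[j] <- sum(mind[tail_idx] < contact_cutoff)
    dw <- pair_dists(sp, wpos, box, pbc)
    truth_waters[j] <- sum(apply(dw, 2, min) <= water_cutoff)
    com_z[j] <- sum(masses * sp[, 3]) / sum(masses)
  }
  below <- com_z < head_plane
  ins_frame <- if (any(below)) which(below)[1] else NA_integer_
  insertion_time <- if (is.na(ins_frame)) NA_real_ else (ins_frame - 1) * dt_rep

  md_trajectory(topology, times = (seq_len(n_frames) - 1) * dt_rep,
                frames = frames, box = box,
                metadata = list(scenario = name, seed = seed,
                                report_dt = dt_rep, head_plane = head_plane,
                                com_z = com_z,
                                sheet_idx = seq_len(ns),
                                membrane_idx = ns + seq_len(nb),
                                water_idx = ns + nb + seq_len(n_waters)),
                truth = list(contacts = truth_contacts,
                             head_contacts = truth_head,
                             tail_contacts = truth_tail,
                             bound_waters = truth_waters,
                             insertion_time = insertion_time,
                             insertion_frame = ins_frame,
                             head_plane = head_plane,
                             plateau_frames = path$plateau,
                             contact_cutoff = contact_cutoff,
                             water_cutoff = water_cutoff))
}

# deterministic per-frame sheet CoM height and tilt for each scenario
scenario_path <- function(name, n_frames, head_plane) {
  z <- numeric(n_frames); tilt <- numeric(n_frames); plateau <- NULL
  ramp <- function(i0, i1, z0, z1) seq(z0, z1, length.out = i1 - i0 + 1)
  switch(name,
    approach = {
      z[1:41] <- ramp(1, 41, 4.2, head_plane + 0.5)
      z[42:n_frames] <- head_plane + 0.5
      tilt[] <- 0
    },
    no_insert = {
      z[1:41] <- ramp(1, 41, 4.2, head_plane + 0.5)
      z[42:n_frames] <- head_plane + 0.5 +
        0.1 * sin(seq_len(n_frames - 41))
      tilt[] <- 0
    },
    direct_insert = {
      z[1:21] <- ramp(1, 21, 4.2, head_plane + 0.3)
      z[22:41] <- ramp(22, 41, head_plane + 0.2, 0.3)
      z[42:n_frames] <- 0.3
      tilt[] <- pi / 2
    },
    preorganize_insert = {
      z[1:16] <- ramp(1, 16, 4.2, head_plane + 0.25)
      z[17:31] <- head_plane + 0.25            # face-to-face plateau
      z[32:36] <- head_plane + 0.25
      z[37:51] <- ramp(37, 51, head_plane + 0.1, 0.3)
      z[52:n_frames] <- 0.3
      tilt[1:31] <- 0
      tilt[32:36] <- seq(0, pi / 2, length.out = 5)  # reorientation
      tilt[37:n_frames] <- pi / 2
      plateau <- 17:31
    })
  list(z = z, tilt = tilt, plateau = plateau)
}
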