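#' Count atom contacts between two groups
#'
#' Number of atoms of `group_b` having at least one atom of `group_a`
#' within `cutoff` (strictly less than, following the 5 Angstrom contact
#' criterion), with minimum-image distances under the frame's periodic
#' box. Distances are atom-centre to atom-centre. With
#' `heavy_only = TRUE` hydrogen atoms are excluded from both groups (the
#' coarse model carries no hydrogens, so the flag matters only for
#' imported atomistic structures).
#'
#' The default method bins atoms of `group_a` on a periodic cell grid and
#' searches only neighbouring cells; `method = "brute"` computes the full
#' O(N^2) distance matrix and exists as the independent cross-check.
#'
#' @param frame An [md_frame()].
#' @param group_a,group_b Disjoint, non-empty integer index vectors into
#'   the frame topology.
#' @param cutoff Contact cutoff (nm), default 0.5.
#' @param heavy_only Drop hydrogens first (default TRUE).
#' @param method `"cell"` or `"brute"`.
#' @return Integer contact count.
#' @export
count_contacts <- function(frame, group_a, group_b, cutoff = 0.5,
                           heavy_only = TRUE, method = c("cell", "brute")) {
  method <- match.arg(method)
  stopifnot(inherits(frame, "md_frame"), cutoff > 0)
  if (length(group_a) == 0 || length(group_b) == 0) stop("empty group")
  if (length(intersect(group_a, group_b)) > 0) stop("groups must be disjoint")
  if (heavy_only) {
    el <- frame$topology$element
    group_a <- group_a[el[group_a] != "H"]
    group_b <- group_b[el[group_b] != "H"]
    if (length(group_a) == 0 || length(group_b) == 0) stop("empty group after hydrogen filter")
  }
  mind <- min_dists(frame$pos[group_a, , drop = FALSE],
                    frame$pos[group_b, , drop = FALSE],
                    frame$box, frame$pbc, cutoff, method)
  sum(mind < cutoff)
}

# minimum distance from each row of pb to any row of pa
min_dists <- function(pa, pb, box, pbc, cutoff, method = "cell") {
  if (method == "brute" || nrow(pa) * nrow(pb) < 2000) {
    return(apply(pair_dists(pa, pb, box, pbc), 2, min))
  }
  cell_min_dists(pa, pb, box, pbc, cutoff)
}

# periodic cell-grid search: exact for distances < cutoff, reports Inf
# (or any value >= cutoff) beyond it
cell_min_dists <- function(pa, pb, box, pbc, cutoff) {
  ncell <- pmax(1L, floor(box / cutoff))
  csize <- box / ncell
  idx3 <- function(p) {
    ci <- sapply(1:3, function(k) {
      x <- p[, k]
      if (pbc[k]) x <- x %% box[k]
      i <- floor(x / csize[k])
      if (pbc[k]) i %% ncell[k] else pmin(pmax(i, 0), ncell[k] - 1)
    })
    matrix(as.integer(idx3_guard(ci)), ncol = 3)
  }
  key <- function(ci) ci[, 1] + ncell[1] * (ci[, 2] + ncell[2] * ci[, 3])
  ca <- idx3(pa); cb <- idx3(pb)
  amap <- split(seq_len(nrow(pa)), key(ca))
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  out <- numeric(nrow(pb))
  for (j in seq_len(nrow(pb))) {
    cand <- integer(0)
    for (o in seq_len(nrow(offs))) {
      ci <- cb[j, ] + offs[o, ]
      for (k in 1:3) {
        if (pbc[k]) ci[k] <- ci[k] %% ncell[k]
        else if (ci[k] < 0 || ci[k] >= ncell[k]) { ci <- NULL; break }
      }
      if (is.null(ci)) next
      hit <- amap[[as.character(ci[1] + ncell[1] * (ci[2] + ncell[2] * ci[3]))]]
      if (!is.null(hit)) cand <- c(cand, hit)
    }
    if (length(cand) == 0) { out[j] <- Inf; next }
    cand <- unique(cand)
    dx <- pa[cand, , drop = FALSE] -
      matrix(pb[j, ], length(cand), 3, byrow = TRUE)
    dx <- min_image(dx, box, pbc)
    out[j] <- sqrt(min(rowSums(dx^2)))
  }
  out
}

idx3_guard <- function(ci) { ci[!is.finite(ci)] <- 0; ci }

#' Split contacts by lipid head and tail regions
#'
#' Contacts of the sheet partitioned by the membrane beads' region label.
#' Because head and tail labels partition the lipid beads, the two counts
#' always sum to the contact count over the union.
#'
#' @param frame An [md_frame()].
#' @param sheet_idx Sheet atom indices.
#' @param membrane_idx Lipid bead/atom indices; all must carry a
#'   head/tail region label.
#' @inheritParams count_contacts
#' @return List with `head` and `tail` counts.
#' @export
split_head_tail_contacts <- function(frame, sheet_idx, membrane_idx,
                                     cutoff = 0.5, heavy_only = TRUE) {
  reg <- frame$topology$region[membrane_idx]
  if (any(is.na(reg))) stop("membrane atoms without head/tail region label")
  head_idx <- membrane_idx[reg == "head"]
  tail_idx <- membrane_idx[reg == "tail"]
  list(
    head = if (length(head_idx)) {
      count_contacts(frame, sheet_idx, head_idx, cutoff, heavy_only)
    } else 0L,
    tail = if (length(tail_idx)) {
      count_contacts(frame, sheet_idx, tail_idx, cutoff, heavy_only)
    } else 0L)
}

#' Count waters bound to the sheet surface
#'
#' Number of water oxygens whose minimum distance to any sheet atom is
#' within `cutoff` (inclusive; the 3.5 Angstrom first-shell criterion,
#' with the surface taken as the nearest sheet atom centre).
#'
#' @param frame An [md_frame()].
#' @param sheet_idx Sheet atom indices.
#' @param water_idx Water oxygen indices.
#' @param cutoff Binding cutoff (nm), default 0.35.
#' @return Integer count (0 when `water_idx` is empty).
#' @export
count_bound_waters <- function(frame, sheet_idx, water_idx, cutoff = 0.35) {
  stopifnot(length(sheet_idx) > 0)
  if (length(water_idx) == 0) return(0L)
  mind <- min_dists(frame$pos[sheet_idx, , drop = FALSE],
                    frame$pos[water_idx, , drop = FALSE],
                    frame$box, frame$pbc, cutoff * 1.0001, "brute")
  sum(mind <= cutoff)
}

#' Sheet-membrane centre-of-mass separation along the normal
#'
#' Mass-weighted |z_CoM(sheet) - z_CoM(membrane)|, the reaction
#' coordinate of the insertion study (initial placements sit at about
#' 4.2 nm). Invariant under rigid translations of the whole frame.
#'
#' @param frame An [md_frame()].
#' @param sheet_idx,membrane_idx Non-empty index vectors.
#' @return Distance (nm).
#' @export
com_distance_z <- function(frame, sheet_idx, membrane_idx) {
  stopifnot(length(sheet_idx) > 0, length(membrane_idx) > 0)
  m <- frame$topology$mass
  comz <- function(idx) {
    sum(m[idx] * frame$pos[idx, 3]) / sum(m[idx])
  }
  abs(comz(sheet_idx) - comz(membrane_idx))
}

#' Sheet-lipid interaction energy decomposition
#'
#' Pairwise van der Waals and Coulomb sums over all sheet-lipid pairs
#' within the cutoff, using [pair_energy()] (cutoff-shifted
#' Lennard-Jones, truncated Coulomb; the same scheme as the simulator,
#' not particle-mesh electrostatics). Both groups must carry `sigma`,
#' `epsilon` and `charge` in the topology.
#'
#' @param frame An [md_frame()].
#' @param sheet_idx,lipid_idx Index vectors.
#' @param cutoff Truncation (nm), default 1.2.
#' @return List with total `vdw` and `coul` (kJ/mol).
#' @export
interaction_energy <- function(frame, sheet_idx, lipid_idx, cutoff = 1.2) {
  top <- frame$topology
  need <- c("sigma", "epsilon", "charge")
  for (idx in list(sheet_idx, lipid_idx)) {
    bad <- idx[!stats::complete.cases(top[idx, need])]
    if (length(bad)) {
      stop("missing force-field parameters for atom(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  pa <- frame$pos[sheet_idx, , drop = FALSE]
  pb <- frame$pos[lipid_idx, , drop = FALSE]
  na <- length(sheet_idx); nb <- length(lipid_idx)
  ai <- rep(seq_len(na), times = nb)
  bi <- rep(seq_len(nb), each = na)
  dx <- min_image(pa[ai, , drop = FALSE] - pb[bi, , drop = FALSE],
                  frame$box, frame$pbc)
  r <- sqrt(rowSums(dx^2))
  keep <- r < cutoff
  if (!any(keep)) return(list(vdw = 0, coul = 0))
  r <- r[keep]; ai <- ai[keep]; bi <- bi[keep]
  sa <- top$sigma[sheet_idx][ai]; sb <- top$sigma[lipid_idx][bi]
  ea <- top$epsilon[sheet_idx][ai]; eb <- top$epsilon[lipid_idx][bi]
  qa <- top$charge[sheet_idx][ai]; qb <- top$charge[lipid_idx][bi]
  sig <- (sa + sb) / 2
  eps <- sqrt(ea * eb)
  sr6 <- (sig / r)^6
  src6 <- (sig / cutoff)^6
  vdw <- 4 * eps * ((sr6^2 - sr6) - (src6^2 - src6))
  coul <- COULOMB_CONST * qa * qb / r
  list(vdw = sum(vdw), coul = sum(coul))
}

#' Acyl-chain orientational order parameter
#'
#' S_chain = < (3 cos^2 theta - 1) / 2 > over the selected chains (and
#' frames, for a trajectory), where theta is the angle between the
#' membrane normal and the chain vector from the first to the last chain
#' bead. S_chain = 1 for chains aligned with the normal, -1/2 for chains
#' perpendicular to it, and 0 for isotropically random orientations;
#' values always lie in \[-0.5, 1\]. Chains with a zero-length vector are
#' skipped with a warning.
#'
#' @param x An [md_frame()] or [md_trajectory()].
#' @param lipid_ids Optional lipid ids to restrict to (e.g. from
#'   [local_lipid_selection()]); default all lipids.
#' @return Object of class `order_parameter_result`: list with `s_chain`,
#'   `angles` (per-chain theta, radians, last frame analysed), and
#'   `selection` descriptor.
#' @export
chain_order <- function(x, lipid_ids = NULL) {
  if (inherits(x, "md_trajectory")) {
    per_frame <- vapply(seq_along(x$times), function(i) {
      chain_order(traj_frame(x, i), lipid_ids)$s_chain
    }, numeric(1))
    res <- chain_order(traj_frame(x, length(x$times)), lipid_ids)
    res$s_chain <- mean(per_frame)
    res$per_frame <- per_frame
    return(res)
  }
  stopifnot(inherits(x, "md_frame"))
  top <- x$topology
  rows <- which(!is.na(top$chain_index))
  if (!is.null(lipid_ids)) rows <- rows[top$lipid_id[rows] %in% lipid_ids]
  # first and last chain bead of every lipid, vectorized
  rows <- rows[order(top$lipid_id[rows], top$chain_index[rows])]
  lid <- top$lipid_id[rows]
  first <- rows[!duplicated(lid)]
  last <- rows[rev(!duplicated(rev(lid)))]
  multi <- first != last   # lipids with a defined chain vector
  v <- x$pos[last[multi], , drop = FALSE] - x$pos[first[multi], , drop = FALSE]
  len <- sqrt(rowSums(v^2))
  skipped <- sum(len < 1e-12)
  if (skipped > 0) warning(skipped, " zero-length chain vector(s) skipped")
  keep <- len >= 1e-12
  cos2 <- as.vector((v[keep, , drop = FALSE] %*% x$normal) / len[keep])^2
  angles <- acos(pmin(1, sqrt(cos2)))
  ids <- lipid_ids
  if (length(cos2) == 0) stop("no usable chains in selection")
  structure(list(s_chain = mean(0.5 * (3 * cos2 - 1)), angles = angles,
                 selection = if (is.null(lipid_ids)) "all lipids" else
                   paste(length(ids), "selected lipids")),
            class = "order_parameter_result")
}

#' Select whole lipids near the sheet
#'
#' Lipids with at least one atom within `radius` of any sheet atom
#' (minimum image). Whole lipids are returned, never fragments; the
#' 10 Angstrom default mirrors the local-perturbation analyses.
#'
#' @param frame An [md_frame()].
#' @param sheet_idx Sheet atom indices.
#' @param radius Selection radius (nm), > 0.
#' @return Vector of lipid ids (possibly empty).
#' @export
local_lipid_selection <- function(frame, sheet_idx, radius = 1.0) {
  stopifnot(radius > 0, length(sheet_idx) > 0)
  top <- frame$topology
  lip <- which(top$group == "lipid")
  if (length(lip) == 0) return(integer(0))
  mind <- min_dists(frame$pos[sheet_idx, , drop = FALSE],
                    frame$pos[lip, , drop = FALSE],
                    frame$box, frame$pbc, radius, "brute")
  sort(unique(top$lipid_id[lip[mind <= radius]]))
}

#' Membrane thickness from head-bead planes
#'
#' Mean z of upper-leaflet head beads minus mean z of lower-leaflet head
#' beads, optionally restricted to a lipid subset (local thickness around
#' an inserted sheet). The inter-head-plane definition is used because it
#' is the standard phosphate-plane convention.
#'
#' @param frame An [md_frame()].
#' @param lipid_ids Optional lipid subset.
#' @return Thickness (nm).
#' @export
membrane_thickness <- function(frame, lipid_ids = NULL) {
  top <- frame$topology
  keep <- top$group == "lipid" & !is.na(top$region) & top$region == "head"
  if (!is.null(lipid_ids)) keep <- keep & top$lipid_id %in% lipid_ids
  up <- keep & top$leaflet == "upper"
  lo <- keep & top$leaflet == "lower"
  if (!any(up) || !any(lo)) stop("missing leaflet in thickness selection")
  mean(frame$pos[up, 3]) - mean(frame$pos[lo, 3])
}

#' Detect the insertion time of a trajectory
#'
#' First time the sheet centre of mass crosses below the proximal
#' head-bead plane and stays below it for at least `sustain_window`
#' (default: 5 percent of the trajectory length, which makes the
#' estimator deterministic where visual inspection would be ambiguous).
#' Transient dips shorter than the sustain window are not counted.
#'
#' @param traj An [md_trajectory()] containing sheet and lipid groups.
#' @param sustain_window Sustain requirement (ps).
#' @return Insertion time (ps) or `NA` if the sheet never inserts.
#' @export
insertion_time <- function(traj, sustain_window = NULL) {
  stopifnot(inherits(traj, "md_trajectory"))
  times <- traj$times
  span <- times[length(times)] - times[1]
  sustain_window <- sustain_window %||% (0.05 * span)
  if (span <= sustain_window) stop("trajectory shorter than sustain window")
  top <- traj$topology
  sheet_idx <- which(top$group == "sheet")
  head_up <- which(top$group == "lipid" & top$region == "head" &
                     top$leaflet == "upper")
  head_lo <- which(top$group == "lipid" & top$region == "head" &
                     top$leaflet == "lower")
  stopifnot(length(sheet_idx) > 0, length(head_up) > 0, length(head_lo) > 0)
  m <- top$mass[sheet_idx]
  com_z <- vapply(traj$frames, function(p) {
    sum(m * p[sheet_idx, 3]) / sum(m)
  }, numeric(1))
  # proximal leaflet: the side the sheet starts on
  first_up <- mean(traj$frames[[1]][head_up, 3])
  proximal <- if (com_z[1] >= first_up) head_up else head_lo
  below <- vapply(seq_along(traj$frames), function(i) {
    plane <- mean(traj$frames[[i]][proximal, 3])
    if (com_z[1] >= first_up) com_z[i] < plane else com_z[i] > plane
  }, logical(1))
  for (i in which(below)) {
    t_end <- times[i] + sustain_window
    horizon <- which(times >= times[i] & times <= t_end)
    if (all(below[horizon]) &&
        (times[length(times)] >= t_end)) {
      return(times[i])
    }
  }
  NA_real_
}

#' Time series of a per-frame statistic
#'
#' Applies one of the named statistics to every frame of a trajectory and
#' returns an `analysis_series` (times, values, label, parameters).
#' Statistics: `"contacts"`, `"head_contacts"`, `"tail_contacts"`,
#' `"bound_waters"`, `"com_z"`, `"vdw"`, `"coul"`, `"schain"`,
#' `"thickness"`.
#'
#' @param traj An [md_trajectory()].
#' @param stat Statistic name.
#' @param ... Passed to the underlying per-frame function.
#' @return `analysis_series` object.
#' @export
traj_series <- function(traj, stat = c("contacts", "head_contacts",
                                       "tail_contacts", "bound_waters",
                                       "com_z", "vdw", "coul", "schain",
                                       "thickness"), ...) {
  stat <- match.arg(stat)
  top <- traj$topology
  sheet_idx <- which(top$group == "sheet")
  lipid_idx <- which(top$group == "lipid")
  water_idx <- which(top$group == "water")
  fn <- switch(stat,
    contacts = function(fr) count_contacts(fr, sheet_idx, lipid_idx, ...),
    head_contacts = function(fr)
      split_head_tail_contacts(fr, sheet_idx, lipid_idx, ...)$head,
    tail_contacts = function(fr)
      split_head_tail_contacts(fr, sheet_idx, lipid_idx, ...)$tail,
    bound_waters = function(fr)
      count_bound_waters(fr, sheet_idx, water_idx, ...),
    com_z = function(fr) com_distance_z(fr, sheet_idx, lipid_idx),
    vdw = function(fr) interaction_energy(fr, sheet_idx, lipid_idx, ...)$vdw,
    coul = function(fr) interaction_energy(fr, sheet_idx, lipid_idx, ...)$coul,
    schain = function(fr) chain_order(fr, ...)$s_chain,
    thickness = function(fr) membrane_thickness(fr, ...))
  vals <- vapply(seq_along(traj$times),
                 function(i) as.numeric(fn(traj_frame(traj, i))), numeric(1))
  structure(list(times = traj$times, values = vals, statistic = stat,
                 params = list(...)),
            class = "analysis_series")
}

#' Write an analysis series as TSV
#' @param series An `analysis_series`.
#' @param path Output file.
#' @export
write_series <- function(series, path) {
  utils::write.table(data.frame(time = series$times, value = series$values),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Tail-window summary across replicate trajectories
#'
#' For each requested statistic: the mean over the final
#' `averaging_window` of each trajectory, then the across-trajectory mean
#' and standard error (the "average of the last stretch over independent
#' runs" convention of the insertion analyses).
#'
#' @param trajectories List of [md_trajectory()] objects.
#' @param stats Character vector of [traj_series()] statistic names.
#' @param averaging_window Tail window length (ps); must not exceed any
#'   trajectory span.
#' @return data.frame with columns statistic, mean, se, n.
#' @export
batch_summary <- function(trajectories, stats, averaging_window) {
  stopifnot(length(trajectories) >= 1)
  spans <- vapply(trajectories, function(tr) {
    tr$times[length(tr$times)] - tr$times[1]
  }, numeric(1))
  if (any(averaging_window > spans)) {
    stop("averaging window (", averaging_window,
         " ps) longer than trajectory span (", min(spans), " ps)")
  }
  rows <- lapply(stats, function(s) {
    tail_means <- vapply(trajectories, function(tr) {
      ser <- traj_series(tr, s)
      t_end <- ser$times[length(ser$times)]
      keep <- ser$times >= t_end - averaging_window
      mean(ser$values[keep])
    }, numeric(1))
    n <- length(tail_means)
    data.frame(statistic = s, mean = mean(tail_means),
               se = if (n > 1) stats::sd(tail_means) / sqrt(n) else 0,
               n = n)
  })
  do.call(rbind, rows)
}
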