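#' Molecular frame and trajectory containers
#'
#' The package represents a single configuration as an `md_frame`: a
#' topology data.frame (one row per particle) plus an n x 3 position
#' matrix, a periodic box and a membrane normal. A trajectory
#' (`md_trajectory`) shares one topology across an ordered list of
#' position matrices with strictly increasing times.
#'
#' Topology columns: `name`, `element`, `group` (one of `"sheet"`,
#' `"lipid"`, `"water"`), `region` (`"head"`/`"tail"`/`NA`), `leaflet`
#' (`"upper"`/`"lower"`/`NA`), `lipid_id`, `chain_index` (position along
#' the acyl chain, NA for head beads), `mass`, and optionally `sigma`,
#' `epsilon`, `charge`.
#'
#' @param topology Topology data.frame as described above.
#' @param pos n x 3 numeric matrix of positions (nm).
#' @param box Length-3 box vector (nm).
#' @param pbc Logical length-3; which axes are periodic. The package
#'   default is slab geometry: periodic in x,y only.
#' @param normal Membrane normal (unit 3-vector).
#' @param time Frame time (ps).
#' @return An `md_frame` object.
#' @export
md_frame <- function(topology, pos, box, pbc = c(TRUE, TRUE, FALSE),
                     normal = c(0, 0, 1), time = 0) {
  stopifnot(is.data.frame(topology), is.matrix(pos), ncol(pos) == 3,
            nrow(pos) == nrow(topology), length(box) == 3)
  structure(list(topology = topology, pos = pos, box = as.numeric(box),
                 pbc = pbc, normal = normal / sqrt(sum(normal^2)),
                 time = time),
            class = "md_frame")
}

#' @param times Strictly increasing frame times (ps).
#' @param frames List of n x 3 position matrices, one per time.
#' @param metadata Free-form provenance list (seed, temperature, dt, ...).
#' @param truth Optional machine-readable ground truth embedded by the
#'   scripted scenario generator.
#' @rdname md_frame
#' @export
md_trajectory <- function(topology, times, frames, box,
                          pbc = c(TRUE, TRUE, FALSE), normal = c(0, 0, 1),
                          metadata = list(), truth = NULL) {
  stopifnot(length(times) == length(frames), !is.unsorted(times, strictly = TRUE))
  shapes <- vapply(frames, function(p) nrow(p), integer(1))
  stopifnot(all(shapes == nrow(topology)))
  structure(list(topology = topology, times = as.numeric(times),
                 frames = frames, box = as.numeric(box), pbc = pbc,
                 normal = normal / sqrt(sum(normal^2)),
                 metadata = metadata, truth = truth),
            class = "md_trajectory")
}

#' Extract one frame of a trajectory
#' @param traj An `md_trajectory`.
#' @param i Frame index.
#' @rdname md_frame
#' @export
traj_frame <- function(traj, i) {
  stopifnot(inherits(traj, "md_trajectory"), i >= 1, i <= length(traj$times))
  md_frame(traj$topology, traj$frames[[i]], traj$box, traj$pbc,
           traj$normal, traj$times[i])
}

#' @export
print.md_frame <- function(x, ...) {
  cat(sprintf("md_frame: %d particles (%s), box %.2f x %.2f x %.2f nm, t = %g ps\n",
              nrow(x$topology),
              paste(names(table(x$topology$group)), table(x$topology$group),
                    sep = ":", collapse = ", "),
              x$box[1], x$box[2], x$box[3], x$time))
  invisible(x)
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("md_trajectory: %d frames, %d particles, t = %g..%g ps\n",
              length(x$times), nrow(x$topology),
              x$times[1], x$times[length(x$times)]))
  invisible(x)
}

#' Select particle indices by topology fields
#'
#' @param x An `md_frame` or `md_trajectory`.
#' @param group,region,leaflet Optional filters on topology columns.
#' @return Integer indices into the topology.
#' @export
select_atoms <- function(x, group = NULL, region = NULL, leaflet = NULL) {
  top <- x$topology
  keep <- rep(TRUE, nrow(top))
  if (!is.null(group)) keep <- keep & top$group %in% group
  if (!is.null(region)) keep <- keep & !is.na(top$region) & top$region %in% region
  if (!is.null(leaflet)) keep <- keep & !is.na(top$leaflet) & top$leaflet %in% leaflet
  which(keep)
}

# minimum-image displacement components for one periodic box
min_image <- function(dx, box, pbc) {
  for (k in which(pbc)) {
    dx[, k] <- dx[, k] - box[k] * round(dx[, k] / box[k])
  }
  dx
}

# all pair distances between rows of two position matrices, minimum image
pair_dists <- function(pa, pb, box, pbc) {
  na <- nrow(pa); nb <- nrow(pb)
  dx <- pa[rep(seq_len(na), times = nb), , drop = FALSE] -
    pb[rep(seq_len(nb), each = na), , drop = FALSE]
  dx <- min_image(dx, box, pbc)
  matrix(sqrt(rowSums(dx^2)), nrow = na, ncol = nb)
}
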