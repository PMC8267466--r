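#' Build a coarse bead bilayer membrane
#'
#' Constructs two planar leaflets of coarse-grained lipids on a square
#' grid, mirrored about the midplane (z = 0 by default). Each lipid is one
#' head bead (outermost) plus `beads_per_chain` chain beads running toward
#' the midplane, so every chain starts perfectly aligned with the membrane
#' normal (chain order parameter S_chain = 1 by construction). This bead
#' membrane is the explicit-particle stand-in the contact, thickness and
#' chain-order analyses operate on; free-energy sampling uses the implicit
#' membrane instead.
#'
#' @param n_lipids_per_leaflet Lipids per leaflet (>= 1).
#' @param spacing In-plane grid spacing between lipids (nm, > 0).
#' @param beads_per_chain Chain beads per lipid (>= 2 so a chain vector is
#'   defined; the head bead is extra).
#' @param head_z Height of the head-bead plane above the midplane (nm).
#' @param midplane z of the bilayer midplane (nm).
#' @return A `coarse_membrane`: list with `topology` (md_frame-style
#'   topology of the beads), `pos` reference positions, `box`, `normal`,
#'   `midplane`.
#' @export
build_coarse_membrane <- function(n_lipids_per_leaflet, spacing = 0.8,
                                  beads_per_chain = 3, head_z = 1.9,
                                  midplane = 0) {
  stopifnot(n_lipids_per_leaflet >= 1, beads_per_chain >= 2, head_z > 0)
  if (spacing <= 0) stop("spacing must be positive")
  nx <- ceiling(sqrt(n_lipids_per_leaflet))
  grid <- expand.grid(ix = seq_len(nx) - 1L, iy = seq_len(nx) - 1L)
  grid <- grid[seq_len(n_lipids_per_leaflet), , drop = FALSE]
  box_xy <- nx * spacing
  # chain beads from just under the head down toward the midplane
  chain_z <- seq(head_z - 0.4, 0.25, length.out = beads_per_chain)

  rows <- list(); pos <- list(); lipid_id <- 0L
  for (leaf in c("upper", "lower")) {
    sgn <- if (leaf == "upper") 1 else -1
    for (i in seq_len(n_lipids_per_leaflet)) {
      lipid_id <- lipid_id + 1L
      x <- (grid$ix[i] + 0.5) * spacing
      y <- (grid$iy[i] + 0.5) * spacing
      zs <- c(head_z, chain_z) * sgn + midplane
      nb <- length(zs)
      rows[[lipid_id]] <- data.frame(
        name = c("HD", paste0("C", seq_len(beads_per_chain))),
        element = "B", group = "lipid",
        region = c("head", rep("tail", beads_per_chain)),
        leaflet = leaf, lipid_id = lipid_id,
        chain_index = c(NA, seq_len(beads_per_chain)),
        mass = 60, stringsAsFactors = FALSE)
      pos[[lipid_id]] <- cbind(rep(x, nb), rep(y, nb), zs)
    }
  }
  topology <- do.call(rbind, rows)
  rownames(topology) <- NULL
  pos <- do.call(rbind, pos)
  colnames(pos) <- c("x", "y", "z")
  structure(list(topology = topology, pos = pos,
                 box = c(box_xy, box_xy, 4 * head_z + 4),
                 normal = c(0, 0, 1), midplane = midplane,
                 head_z = head_z, spacing = spacing,
                 beads_per_chain = beads_per_chain),
            class = "coarse_membrane")
}

#' @export
print.coarse_membrane <- function(x, ...) {
  cat(sprintf("coarse membrane: %d lipids (%d beads), head planes at %+.2f/%+.2f nm\n",
              max(x$topology$lipid_id), nrow(x$topology),
              x$midplane + x$head_z, x$midplane - x$head_z))
  invisible(x)
}

#' View a bead membrane as an analysable frame
#'
#' @param membrane A [build_coarse_membrane()] object.
#' @param time Frame time (ps).
#' @return An [md_frame()] of the membrane beads.
#' @export
membrane_frame <- function(membrane, time = 0) {
  md_frame(membrane$topology, membrane$pos, membrane$box,
           normal = membrane$normal, time = time)
}
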