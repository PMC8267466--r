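#' Force-field parameter set for fresh and aged MoS2
#'
#' Lennard-Jones parameters (CHARMM-like 12-6 form) and partial charges for
#' molybdenum and sulfur sites of a MoS2 nanosheet. Surface aging by
#' airborne hydrocarbon adsorption is represented entirely by a reduction of
#' the sulfur well depth `epsilon_S`: the fresh surface (water contact angle
#' ~69 deg) carries eps_S = 1.6744 kJ/mol, the aged surface (~90 deg)
#' eps_S = 1.0450 kJ/mol. All other parameters are identical between the
#' two states.
#'
#' @param label `"fresh"` or `"aged"`.
#' @return An object of class `aging_state`: a list with elements `label`,
#'   `wca` (the water contact angle associated with the state, degrees) and
#'   `species`, a named list mapping element (`Mo`, `S`) to a list with
#'   `sigma` (nm), `epsilon` (kJ/mol) and `charge` (e).
#' @examples
#' aging_state("fresh")$species$S$epsilon  # 1.6744
#' aging_state("aged")$species$S$epsilon   # 1.0450
#' @export
aging_state <- function(label = c("fresh", "aged")) {
  label <- match.arg(label)
  eps_s <- switch(label, fresh = 1.6744, aged = 1.0450)
  wca <- switch(label, fresh = 69, aged = 90)
  structure(list(
    label = label,
    wca = wca,
    species = list(
      Mo = list(sigma = 0.2551, epsilon = 0.5441, charge = +0.76),
      S  = list(sigma = 0.3550, epsilon = eps_s,  charge = -0.38)
    )
  ), class = "aging_state")
}

#' Sulfur well depth from water contact angle
#'
#' Linear calibration of the sulfur Lennard-Jones well depth against the
#' experimentally measured water contact angle (WCA) of the MoS2 surface.
#' The line passes exactly through the two tabulated anchor states:
#' (69 deg, 1.6744 kJ/mol) for the fresh surface and (90 deg, 1.0450
#' kJ/mol) for the aged surface, and is strictly decreasing in the WCA
#' (more hydrophobic surfaces bind the sulfur site more weakly).
#'
#' @param wca Water contact angle in degrees. Values outside the
#'   calibration bracket \[69, 90\] are extrapolated with a warning and the
#'   result carries attribute `extrapolated = TRUE`.
#' @return epsilon_S in kJ/mol.
#' @examples
#' eps_from_wca(69)    # 1.6744
#' eps_from_wca(90)    # 1.0450
#' eps_from_wca(79.5)  # midpoint, 1.3597
#' @export
eps_from_wca <- function(wca) {
  if (!is.numeric(wca) || any(!is.finite(wca))) {
    stop("wca must be finite numeric")
  }
  x1 <- 69; y1 <- 1.6744
  x2 <- 90; y2 <- 1.0450
  slope <- (y2 - y1) / (x2 - x1)
  out <- y1 + slope * (wca - x1)
  extra <- wca < x1 | wca > x2
  if (any(extra)) {
    warning("wca outside calibration bracket [69, 90] degrees; extrapolating")
    attr(out, "extrapolated") <- TRUE
  }
  out
}

# lattice-site generator for a 2H-MoS2 monolayer.
# Honeycomb registry: S columns on the triangular lattice
# i*a1 + j*a2 (a1 = (a, 0), a2 = (a/2, a*sqrt(3)/2)) with one column at
# the triangle centroid; Mo sites offset by -(a/2, a/(2*sqrt(3))). Each S
# column is duplicated at z = +/- mo_s_offset.
mos2_sites <- function(side_length, a, within_fn) {
  rmax <- side_length / sqrt(3) + 2 * a
  nmax <- ceiling(rmax / (a * sqrt(3) / 2)) + 2
  ij <- expand.grid(i = -nmax:nmax, j = -nmax:nmax)
  sx <- ij$i * a + ij$j * a / 2
  sy <- ij$j * a * sqrt(3) / 2
  keep_s <- within_fn(sx, sy)
  mx <- sx - a / 2
  my <- sy - a / (2 * sqrt(3))
  keep_mo <- within_fn(mx, my)
  list(mo = cbind(x = mx[keep_mo], y = my[keep_mo]),
       s = cbind(x = sx[keep_s], y = sy[keep_s]))
}

# point-in-equilateral-triangle test; vertex on +y axis, centroid at
# origin. `pad` expands the cut outward by a true distance margin: the
# default half in-plane Mo-S bond projection keeps edge unit cells whole
# instead of splitting them at the nominal boundary.
triangle_within_fn <- function(side_length, pad = 0) {
  rc <- side_length / sqrt(3)
  v <- rbind(c(0, rc),
             c(-side_length / 2, -rc / 2),
             c(side_length / 2, -rc / 2))
  function(x, y) {
    inside <- rep(TRUE, length(x))
    for (k in 1:3) {
      p1 <- v[k, ]; p2 <- v[k %% 3 + 1, ]
      elen <- sqrt(sum((p2 - p1)^2))
      # signed distance to each ccw edge; interior is on the left
      sd <- ((p2[1] - p1[1]) * (y - p1[2]) -
               (p2[2] - p1[2]) * (x - p1[1])) / elen
      inside <- inside & (sd >= -pad - 1e-9)
    }
    inside
  }
}

#' Build an equilateral triangular MoS2 nanosheet
#'
#' Cuts a three-layer S-Mo-S sheet from the 2H-MoS2 lattice as an
#' equilateral triangle of the requested side length. The triangle lies in
#' the xy-plane (sheet normal along +z) with one vertex on the +y axis, and
#' the returned sheet is centred so that the mean atom position is the
#' origin. Non-stoichiometric cuts are neutralized by trimming excess edge
#' atoms of the over-represented species (farthest from the centroid first,
#' ties broken by lexicographic position) until the Mo:S ratio is exactly
#' 1:2, which keeps the tabulated partial charges exact and the net charge
#' identically zero.
#'
#' If a cut smaller than a couple of unit cells lacks one species entirely,
#' the builder augments the cut with that species' lattice sites nearest
#' the centroid before trimming, so the smallest valid sheet is a single Mo
#' with two of its coordinating S atoms.
#'
#' @param side_length Triangle side in nm (the tabulated reference sheet
#'   uses 2.89 nm).
#' @param lattice List with `a` (in-plane lattice constant, nm, default
#'   0.316) and `mo_s_offset` (Mo to S-plane vertical offset, nm, default
#'   0.156).
#' @return Object of class `nanosheet`: list with `atoms` (data.frame with
#'   columns `element`, `x`, `y`, `z` in nm, plus `sigma`, `epsilon`,
#'   `charge` once an aging state is assigned), `side_length`, `lattice`,
#'   and `aging` (NULL until [assign_aging_state()] is called).
#' @seealso [assign_aging_state()], [net_charge()], [write_gro()]
#' @export
build_triangular_nanosheet <- function(side_length,
                                       lattice = list(a = MOS2_LATTICE_A,
                                                      mo_s_offset = MOS2_MO_S_OFFSET)) {
  a <- lattice$a %||% MOS2_LATTICE_A
  zoff <- lattice$mo_s_offset %||% MOS2_MO_S_OFFSET
  if (!is.finite(side_length) || side_length < a) {
    stop("degenerate geometry: side_length must be at least one lattice spacing (",
         a, " nm)")
  }
  within <- triangle_within_fn(side_length, pad = a / (2 * sqrt(3)))
  sites <- mos2_sites(side_length, a, within)

  # augment with nearest missing-species sites so tiny cuts stay chemical
  if (nrow(sites$mo) == 0L || nrow(sites$s) == 0L) {
    all_sites <- mos2_sites(side_length + 4 * a, a, function(x, y) rep(TRUE, length(x)))
    fill <- function(m, want) {
      if (nrow(m) >= want) return(m)
      pool <- if (identical(want, 1L)) all_sites$mo else all_sites$s
      d <- pool[, "x"]^2 + pool[, "y"]^2
      ord <- order(d, pool[, "x"], pool[, "y"])
      pool[ord[seq_len(want)], , drop = FALSE]
    }
    if (nrow(sites$mo) == 0L) sites$mo <- fill(sites$mo, 1L)
    if (nrow(sites$s) == 0L) sites$s <- fill(sites$s, 3L)
  }

  atoms <- rbind(
    data.frame(element = "Mo", x = sites$mo[, "x"], y = sites$mo[, "y"], z = 0),
    data.frame(element = "S", x = sites$s[, "x"], y = sites$s[, "y"], z = +zoff),
    data.frame(element = "S", x = sites$s[, "x"], y = sites$s[, "y"], z = -zoff)
  )
  atoms <- trim_to_stoichiometry(atoms)
  # recentre: centroid of atoms at the origin
  atoms$x <- atoms$x - mean(atoms$x)
  atoms$y <- atoms$y - mean(atoms$y)
  atoms$z <- atoms$z - mean(atoms$z)
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, side_length = side_length,
                 lattice = list(a = a, mo_s_offset = zoff), aging = NULL),
            class = "nanosheet")
}

# deterministic trimming of excess atoms until n_S == 2 * n_Mo:
# remove the over-represented species' atom farthest from the cut centroid,
# ties broken lexicographically on (x, y, z)
trim_to_stoichiometry <- function(atoms) {
  repeat {
    n_mo <- sum(atoms$element == "Mo")
    n_s <- sum(atoms$element == "S")
    if (n_s == 2L * n_mo) break
    drop_el <- if (n_s > 2L * n_mo) "S" else "Mo"
    idx <- which(atoms$element == drop_el)
    d2 <- atoms$x[idx]^2 + atoms$y[idx]^2
    ord <- order(-d2, atoms$x[idx], atoms$y[idx], atoms$z[idx])
    atoms <- atoms[-idx[ord[1L]], , drop = FALSE]
    if (nrow(atoms) == 0L) stop("trimming removed all atoms; invalid cut")
  }
  atoms
}

#' Assign the fresh or aged parameter set to a nanosheet
#'
#' Attaches per-atom Lennard-Jones parameters and partial charges from the
#' tabulated fresh/aged set. Re-assignment fully overwrites any previous
#' state, so assignments are idempotent. The two states differ in exactly
#' one scalar: the sulfur well depth epsilon_S.
#'
#' @param sheet A `nanosheet` from [build_triangular_nanosheet()].
#' @param label `"fresh"` or `"aged"`.
#' @return The sheet with `aging` set and per-atom `sigma`, `epsilon`,
#'   `charge` columns filled.
#' @export
assign_aging_state <- function(sheet, label = c("fresh", "aged")) {
  stopifnot(inherits(sheet, "nanosheet"))
  state <- aging_state(label)
  sp <- state$species
  el <- sheet$atoms$element
  if (!all(el %in% names(sp))) {
    stop("unknown element in sheet: ", paste(setdiff(el, names(sp)), collapse = ", "))
  }
  sheet$atoms$sigma <- vapply(sp[el], `[[`, numeric(1), "sigma")
  sheet$atoms$epsilon <- vapply(sp[el], `[[`, numeric(1), "epsilon")
  sheet$atoms$charge <- vapply(sp[el], `[[`, numeric(1), "charge")
  sheet$aging <- state
  sheet
}

#' Net charge of a parameterized nanosheet
#'
#' Sum of atomic partial charges in elementary charge units. Because the
#' builder trims cuts to exact 1:2 Mo:S stoichiometry and the tabulated
#' charges satisfy q_Mo + 2 q_S = 0, any built and parameterized sheet is
#' neutral to well below 1e-9 e.
#'
#' @param sheet A parameterized `nanosheet`.
#' @return Net charge (e).
#' @export
net_charge <- function(sheet) {
  stopifnot(inherits(sheet, "nanosheet"))
  if (is.null(sheet$atoms$charge)) {
    stop("parameters not assigned; call assign_aging_state() first")
  }
  sum(sheet$atoms$charge)
}

#' @export
print.nanosheet <- function(x, ...) {
  n_mo <- sum(x$atoms$element == "Mo")
  n_s <- sum(x$atoms$element == "S")
  cat(sprintf("MoS2 nanosheet: side %.3f nm, %d Mo + %d S atoms",
              x$side_length, n_mo, n_s))
  if (!is.null(x$aging)) {
    cat(sprintf(", %s (WCA ~%g deg, eps_S = %.4f kJ/mol)",
                x$aging$label, x$aging$wca, x$aging$species$S$epsilon))
  }
  cat("\n")
  invisible(x)
}

# sheet atom positions as an n x 3 matrix
sheet_positions <- function(sheet) {
  as.matrix(sheet$atoms[, c("x", "y", "z")])
}

# masses of sheet atoms
sheet_masses <- function(sheet) {
  unname(ATOMIC_MASS[sheet$atoms$element])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
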