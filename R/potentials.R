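#' Implicit-membrane potential for the coarse insertion model
#'
#' A smooth one-dimensional surrogate for the free-energy landscape a rigid
#' nanosheet experiences along the bilayer normal: zero in bulk water, a
#' small head-group barrier of height `head_barrier` centred at the
#' interface (|z - midplane| = half_thickness), and an attractive well of
#' depth `tail_well_depth` across the hydrophobic core. An orientational
#' term penalizes sheet normals parallel to the membrane normal inside the
#' core, so the in-membrane optimum has the sheet plane perpendicular to
#' the bilayer surface, the pose inserted sheets adopt.
#'
#' The tail well scales linearly with the sulfur well depth eps_S of the
#' aging state (`tail_well_depth = -depth_per_eps * eps_S`), since eps_S is
#' the single parameter that distinguishes fresh from aged surfaces.
#'
#' @param midplane Bilayer midplane z0 (nm).
#' @param half_thickness Half the hydrophobic slab thickness h (nm).
#' @param tail_well_depth Well depth U_t (kJ/mol, negative = attractive).
#' @param head_barrier Interfacial barrier height U_h (kJ/mol, >= 0).
#' @param width Interface smoothing width w (nm); must be < half_thickness
#'   so that the midplane energy equals `tail_well_depth` exactly.
#' @param orient_coupling Orientational coupling strength (kJ/mol, >= 0).
#' @return Object of class `implicit_membrane`.
#' @export
implicit_membrane <- function(midplane = 0, half_thickness = 2.0,
                              tail_well_depth = -10, head_barrier = 1.5,
                              width = 0.5, orient_coupling = 5) {
  stopifnot(half_thickness > 0, width > 0, width < half_thickness,
            head_barrier >= 0, orient_coupling >= 0)
  structure(list(midplane = midplane, half_thickness = half_thickness,
                 tail_well_depth = tail_well_depth,
                 head_barrier = head_barrier, width = width,
                 orient_coupling = orient_coupling),
            class = "implicit_membrane")
}

# quintic smoothstep, C2, 0 -> 1 over t in [0, 1]
smoothstep <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  t * t * t * (t * (6 * t - 15) + 10)
}

# C-infinity bump with compact support |u| < 1, bump(0) = 1
bump <- function(u) {
  out <- numeric(length(u))
  in_supp <- abs(u) < 1
  out[in_supp] <- exp(1 - 1 / (1 - u[in_supp]^2))
  out
}

#' Evaluate the implicit-membrane potential
#'
#' @param z Position(s) along the membrane normal (nm).
#' @param tilt Angle between the sheet normal and the membrane normal
#'   (radians). `tilt = pi/2` (sheet plane perpendicular to the bilayer
#'   surface) is the in-membrane optimum.
#' @param params An [implicit_membrane()] object.
#' @return Potential energy in kJ/mol; exactly `tail_well_depth` at the
#'   midplane with optimal tilt, exactly 0 in bulk beyond
#'   `half_thickness + width`.
#' @export
membrane_potential <- function(z, tilt = pi / 2, params) {
  stopifnot(inherits(params, "implicit_membrane"))
  s <- abs(z - params$midplane)
  # well envelope: 1 across the core, C2 descent to 0 over [h - w, h + w]
  f_well <- 1 - smoothstep((s - (params$half_thickness - params$width)) /
                             (2 * params$width))
  # barrier: compactly supported bump centred on the interface
  b <- bump((s - params$half_thickness) / params$width)
  params$tail_well_depth * f_well + params$head_barrier * b +
    params$orient_coupling * f_well * cos(tilt)^2
}

#' Pairwise Lennard-Jones and Coulomb energy
#'
#' CHARMM-like 12-6 Lennard-Jones interaction with Lorentz-Berthelot
#' combining (arithmetic-mean sigma, geometric-mean epsilon), shifted so
#' the dispersion term is exactly zero at the cutoff, plus a truncated
#' Coulomb term f q_a q_b / r with f = 138.935458 kJ mol^-1 nm e^-2.
#' Both components are identically zero for r >= cutoff. With an infinite
#' cutoff no shift is applied, so the well depth at r = 2^(1/6) sigma is
#' exactly -epsilon.
#'
#' @param r Pair distance(s), nm; must be > 0.
#' @param a,b Species parameter lists with `sigma` (nm), `epsilon`
#'   (kJ/mol) and `charge` (e), e.g. entries of `aging_state()$species`.
#' @param cutoff Truncation distance (nm), default 1.2; may be `Inf`.
#' @return List with numeric vectors `vdw` and `coul` (kJ/mol).
#' @export
pair_energy <- function(r, a, b, cutoff = 1.2) {
  if (any(r <= 0)) stop("singularity: pair distance must be positive")
  sigma <- (a$sigma + b$sigma) / 2
  eps <- sqrt(a$epsilon * b$epsilon)
  qq <- (a$charge %||% 0) * (b$charge %||% 0)
  lj <- function(x) {
    sr6 <- (sigma / x)^6
    4 * eps * (sr6 * sr6 - sr6)
  }
  inside <- r < cutoff
  vdw <- numeric(length(r))
  coul <- numeric(length(r))
  shift <- if (is.finite(cutoff)) lj(cutoff) else 0
  vdw[inside] <- lj(r[inside]) - shift
  coul[inside] <- COULOMB_CONST * qq / r[inside]
  list(vdw = vdw, coul = coul)
}
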