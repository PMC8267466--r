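#' Physical constants and package-wide unit conventions
#'
#' All quantities in the package use a fixed unit system: lengths in
#' nanometres, times in picoseconds, energies in kJ/mol, temperatures in
#' kelvin and charges in elementary charge units.
#'
#' @format `KB` is the Boltzmann constant in kJ mol^-1 K^-1;
#'   `COULOMB_CONST` is the electric conversion factor
#'   f = 1/(4 pi eps0) in kJ mol^-1 nm e^-2, the value used by common
#'   molecular dynamics engines.
#' @name constants
NULL

#' @rdname constants
#' @export
KB <- 0.0083144621

#' @rdname constants
#' @export
COULOMB_CONST <- 138.935458

# default 2H-MoS2 lattice: in-plane constant and Mo-S vertical offset (nm)
MOS2_LATTICE_A <- 0.316
MOS2_MO_S_OFFSET <- 0.156

# atomic masses (g/mol) for centre-of-mass weighting
ATOMIC_MASS <- c(Mo = 95.95, S = 32.06, O = 15.999, H = 1.008,
                 C = 12.011, N = 14.007, P = 30.974, B = 60.0)
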