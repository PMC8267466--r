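#' Default run configuration
#'
#' Nested key tree holding every tunable parameter of the pipeline, with
#' defaults equal to the reference protocol wherever it states a value:
#' umbrella force constant k = 2000 kJ mol^-1 nm^-2, window spacing
#' 0.1 nm, temperature 300 K, van der Waals cutoff 1.2 nm, contact cutoff
#' 0.5 nm, bound-water cutoff 0.35 nm, local-selection radius 1.0 nm,
#' sheet side length 2.89 nm, initial CoM distance 4.2 nm. Lattice
#' constants and coarse-model parameters are package defaults (see the
#' methods vignette).
#'
#' @return Nested list of parameters.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    temperature = 300,
    lattice = list(a = 0.316, mo_s_offset = 0.156),
    sheet = list(side_length = 2.89, aging = "fresh"),
    membrane = list(n_lipids_per_leaflet = 25L, spacing = 0.8,
                    beads_per_chain = 3L, head_z = 1.9),
    simulator = list(friction = 1, mass = 1, dt = 1e-3,
                     start_distance = 4.2, n_steps = 20000L,
                     report_interval = 100L,
                     half_thickness = 2.0, head_barrier = 1.5,
                     interface_width = 0.5, orient_coupling = 5,
                     tail_depth_per_eps = 6.0),
    umbrella = list(d_min = 0.0, d_max = 4.9, spacing = 0.1, k = 2000,
                    equil_steps = 2000L, prod_steps = 40000L,
                    dt = 1e-5, sample_every = 50L),
    wham = list(n_bins = 200L, tol = 1e-7, max_iter = 100000L,
                n_boot = 50L, bulk_fraction = 0.1),
    analysis = list(contact_cutoff = 0.5, water_cutoff = 0.35,
                    local_radius = 1.0, energy_cutoff = 1.2,
                    sustain_fraction = 0.05)
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML key tree, fills omissions from [default_config()],
#' rejects unknown keys, and validates value constraints. An empty file
#' yields the full default configuration. The effective configuration is
#' echoed to the log (via `message`) when `echo = TRUE`, so every
#' parameter actually used is auditable.
#'
#' @param path YAML file.
#' @param echo Log the effective configuration.
#' @return Validated config list.
#' @export
load_config <- function(path, echo = FALSE) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- merge_config(default_config(), user, "")
  validate_config(cfg)
  if (echo) {
    message("effective configuration:\n", yaml::as.yaml(cfg))
  }
  cfg
}

#' @rdname load_config
#' @param config Config list to write.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

merge_config <- function(defaults, user, prefix) {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ",
         paste0(prefix, unknown, collapse = ", "))
  }
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      if (!is.list(user[[k]])) stop("config key ", prefix, k, " must be a map")
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]],
                                    paste0(prefix, k, "."))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

validate_config <- function(cfg) {
  chk <- function(ok, key, what) {
    if (!ok) stop("config violation: ", key, " ", what)
  }
  chk(cfg$temperature > 0, "temperature", "must be > 0 K")
  chk(cfg$lattice$a > 0, "lattice.a", "must be > 0 nm")
  chk(cfg$lattice$mo_s_offset > 0, "lattice.mo_s_offset", "must be > 0 nm")
  chk(cfg$sheet$side_length >= cfg$lattice$a, "sheet.side_length",
      "must be at least one lattice spacing")
  chk(cfg$sheet$aging %in% c("fresh", "aged"), "sheet.aging",
      "must be 'fresh' or 'aged'")
  chk(cfg$membrane$n_lipids_per_leaflet >= 1, "membrane.n_lipids_per_leaflet",
      "must be >= 1")
  chk(cfg$membrane$spacing > 0, "membrane.spacing", "must be > 0 nm")
  chk(cfg$membrane$beads_per_chain >= 2, "membrane.beads_per_chain",
      "must be >= 2")
  chk(cfg$umbrella$k >= 0, "umbrella.k", "must be >= 0")
  chk(cfg$umbrella$spacing > 0, "umbrella.spacing", "must be > 0 nm")
  chk(cfg$umbrella$d_max > cfg$umbrella$d_min, "umbrella.d_max",
      "must exceed umbrella.d_min")
  chk(cfg$simulator$dt > 0, "simulator.dt", "must be > 0 ps")
  chk(cfg$simulator$friction > 0, "simulator.friction", "must be > 0")
  for (key in c("contact_cutoff", "water_cutoff", "local_radius",
                "energy_cutoff")) {
    chk(cfg$analysis[[key]] > 0, paste0("analysis.", key), "must be > 0 nm")
  }
  invisible(cfg)
}
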