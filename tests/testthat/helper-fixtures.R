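# shared fixtures and independent oracle implementations for the tests.
# Oracles deliberately avoid the package's distance/neighbour machinery:
# they are direct double loops over atom pairs.

# minimum-image distance between two points, plain arithmetic
oracle_dist <- function(p, q, box, pbc) {
  d <- p - q
  for (k in 1:3) {
    if (pbc[k]) d[k] <- d[k] - box[k] * round(d[k] / box[k])
  }
  sqrt(sum(d^2))
}

# O(Na*Nb) contact count: atoms of b with any a-atom strictly closer
# than cutoff
oracle_contacts <- function(pos_a, pos_b, box, pbc, cutoff) {
  n <- 0L
  for (j in seq_len(nrow(pos_b))) {
    for (i in seq_len(nrow(pos_a))) {
      if (oracle_dist(pos_a[i, ], pos_b[j, ], box, pbc) < cutoff) {
        n <- n + 1L
        break
      }
    }
  }
  n
}

# O(Na*Nb) shifted-LJ + truncated-Coulomb double loop
oracle_energy <- function(pos_a, pos_b, par_a, par_b, box, pbc, cutoff) {
  vdw <- 0; coul <- 0
  fel <- 138.935458
  for (i in seq_len(nrow(pos_a))) {
    for (j in seq_len(nrow(pos_b))) {
      r <- oracle_dist(pos_a[i, ], pos_b[j, ], box, pbc)
      if (r >= cutoff) next
      sig <- (par_a$sigma[i] + par_b$sigma[j]) / 2
      eps <- sqrt(par_a$epsilon[i] * par_b$epsilon[j])
      lj <- function(x) 4 * eps * ((sig / x)^12 - (sig / x)^6)
      vdw <- vdw + lj(r) - lj(cutoff)
      coul <- coul + fel * par_a$charge[i] * par_b$charge[j] / r
    }
  }
  list(vdw = vdw, coul = coul)
}

# random two-group frame with force-field parameters, for oracle tests
random_frame <- function(n_a = 15, n_b = 30, box = c(3, 3, 3),
                         pbc = c(TRUE, TRUE, FALSE)) {
  n <- n_a + n_b
  top <- data.frame(
    name = "X", element = "X",
    group = rep(c("sheet", "lipid"), c(n_a, n_b)),
    region = c(rep(NA_character_, n_a),
               sample(c("head", "tail"), n_b, replace = TRUE)),
    leaflet = NA_character_,
    lipid_id = c(rep(NA_integer_, n_a), seq_len(n_b)),
    chain_index = NA_integer_, mass = 1,
    sigma = runif(n, 0.2, 0.5), epsilon = runif(n, 0.2, 2),
    charge = runif(n, -0.5, 0.5), stringsAsFactors = FALSE)
  pos <- cbind(runif(n, 0, box[1]), runif(n, 0, box[2]),
               runif(n, -1, box[3] - 1))
  colnames(pos) <- c("x", "y", "z")
  md_frame(top, pos, box, pbc)
}

# frame of n two-bead chains with prescribed unit direction vectors
chain_frame <- function(dirs, length = 1) {
  n <- nrow(dirs)
  top <- data.frame(
    name = rep(c("C1", "C2"), n), element = "B", group = "lipid",
    region = "tail", leaflet = "upper",
    lipid_id = rep(seq_len(n), each = 2),
    chain_index = rep(c(1L, 2L), n), mass = 1, stringsAsFactors = FALSE)
  base <- cbind(runif(n, 0, 10), runif(n, 0, 10), runif(n, 0, 10))
  pos <- matrix(NA_real_, 2 * n, 3)
  pos[seq(1, 2 * n, 2), ] <- base
  pos[seq(2, 2 * n, 2), ] <- base + length * dirs
  colnames(pos) <- c("x", "y", "z")
  md_frame(top, pos, c(20, 20, 20), pbc = c(FALSE, FALSE, FALSE))
}

# uniformly random unit vectors
random_unit_vectors <- function(n) {
  v <- matrix(rnorm(3 * n), n, 3)
  v / sqrt(rowSums(v^2))
}

# quick small config for pipeline tests
tiny_config <- function() {
  cfg <- default_config()
  cfg$simulator$n_steps <- 2000L
  cfg$umbrella$d_max <- 1.0
  cfg$umbrella$prod_steps <- 4000L
  cfg$umbrella$equil_steps <- 500L
  cfg$wham$n_boot <- 0L
  cfg
}
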