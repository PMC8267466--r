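two_atom_frame <- function(r, group_b = "lipid") {
  top <- data.frame(name = c("A", "B"), element = c("S", "B"),
                    group = c("sheet", group_b),
                    region = c(NA, "tail"), leaflet = c(NA, "upper"),
                    lipid_id = c(NA, 1L), chain_index = NA_integer_,
                    mass = 1, stringsAsFactors = FALSE)
  pos <- rbind(c(1, 1, 1), c(1 + r, 1, 1))
  colnames(pos) <- c("x", "y", "z")
  md_frame(top, pos, c(10, 10, 10))
}

test_that("contact criterion is strict at the 5 Angstrom boundary", {
  expect_identical(count_contacts(two_atom_frame(0.49), 1, 2), 1L)
  expect_identical(count_contacts(two_atom_frame(0.51), 1, 2), 0L)
  expect_identical(count_contacts(two_atom_frame(0.5), 1, 2), 0L)
  fr <- two_atom_frame(0.3)
  expect_error(count_contacts(fr, integer(0), 2), "empty group")
  expect_error(count_contacts(fr, c(1, 2), 2), "disjoint")
})

test_that("cell-list contacts equal the brute-force oracle on random frames", {
  set.seed(101)
  for (rep in 1:100) {
    fr <- random_frame(n_a = 12, n_b = 25)
    a <- which(fr$topology$group == "sheet")
    b <- which(fr$topology$group == "lipid")
    want <- oracle_contacts(fr$pos[a, ], fr$pos[b, ], fr$box, fr$pbc, 0.5)
    expect_identical(count_contacts(fr, a, b, method = "cell"), want)
    expect_identical(count_contacts(fr, a, b, method = "brute"), want)
  }
})

test_that("head/tail split partitions the total contact count", {
  set.seed(55)
  for (rep in 1:25) {
    fr <- random_frame(n_a = 10, n_b = 30)
    a <- which(fr$topology$group == "sheet")
    b <- which(fr$topology$group == "lipid")
    sp <- split_head_tail_contacts(fr, a, b)
    expect_identical(sp$head + sp$tail, count_contacts(fr, a, b))
    # brute-force recomputation per region
    reg <- fr$topology$region[b]
    for (r in c("head", "tail")) {
      idx <- b[reg == r]
      want <- if (length(idx)) {
        oracle_contacts(fr$pos[a, ], fr$pos[idx, , drop = FALSE],
                        fr$box, fr$pbc, 0.5)
      } else 0L
      expect_identical(if (r == "head") sp$head else sp$tail, want)
    }
  }
  fr <- random_frame()
  fr$topology$region[fr$topology$group == "lipid"][1] <- NA
  expect_error(split_head_tail_contacts(
    fr, which(fr$topology$group == "sheet"),
    which(fr$topology$group == "lipid")), "label")
})

test_that("bound-water count is inclusive at the 3.5 Angstrom boundary", {
  expect_identical(count_bound_waters(two_atom_frame(0.34), 1, 2), 1L)
  expect_identical(count_bound_waters(two_atom_frame(0.36), 1, 2), 0L)
  # inclusive boundary, at an exactly representable distance
  expect_identical(count_bound_waters(two_atom_frame(0.25), 1, 2,
                                      cutoff = 0.25), 1L)
  expect_identical(count_bound_waters(two_atom_frame(1), 1, integer(0)), 0L)
})

test_that("CoM separation is mass-weighted and translation invariant", {
  tr <- scripted_scenario("approach", seed = 1)
  fr <- traj_frame(tr, 1)
  si <- tr$metadata$sheet_idx; mi <- tr$metadata$membrane_idx
  # initial placement of the reference system: about 4.2 nm
  expect_equal(com_distance_z(fr, si, mi), 4.2, tolerance = 0.05)
  shifted <- fr
  shifted$pos <- fr$pos + matrix(rep(c(1.3, -0.7, 2.2), each = nrow(fr$pos)),
                                 ncol = 3)
  expect_equal(com_distance_z(shifted, si, mi),
               com_distance_z(fr, si, mi), tolerance = 1e-12)
  # sheet at the membrane midplane gives zero
  at0 <- fr
  at0$pos[si, 3] <- at0$pos[si, 3] -
    (sum(fr$pos[si, 3] * fr$topology$mass[si]) / sum(fr$topology$mass[si]))
  expect_equal(com_distance_z(at0, si, mi), 0, tolerance = 1e-9)
})

test_that("interaction energy decomposition matches a double-loop oracle", {
  set.seed(77)
  for (rep in 1:20) {
    fr <- random_frame(n_a = 10, n_b = 40)
    a <- which(fr$topology$group == "sheet")
    b <- which(fr$topology$group == "lipid")
    got <- interaction_energy(fr, a, b, cutoff = 1.2)
    want <- oracle_energy(fr$pos[a, ], fr$pos[b, ],
                          fr$topology[a, ], fr$topology[b, ],
                          fr$box, fr$pbc, 1.2)
    expect_equal(got$vdw, want$vdw, tolerance = 1e-10)
    expect_equal(got$coul, want$coul, tolerance = 1e-10)
  }
})

test_that("interaction energy landmarks and error handling", {
  s <- aging_state("fresh")$species$S
  top <- data.frame(name = "S", element = "S",
                    group = c("sheet", "lipid"), region = NA,
                    leaflet = NA, lipid_id = c(NA, 1L),
                    chain_index = NA_integer_, mass = 32,
                    sigma = s$sigma, epsilon = s$epsilon, charge = 0,
                    stringsAsFactors = FALSE)
  rmin <- 2^(1 / 6) * s$sigma
  pos <- rbind(c(2, 2, 2), c(2 + rmin, 2, 2)); colnames(pos) <- c("x", "y", "z")
  fr <- md_frame(top, pos, c(8, 8, 8))
  sig6 <- (s$sigma / 1.2)^6
  shift <- 4 * s$epsilon * (sig6^2 - sig6)
  expect_equal(interaction_energy(fr, 1, 2)$vdw, -1.6744 - shift,
               tolerance = 1e-12)
  far <- fr; far$pos[2, 1] <- 7.9  # beyond cutoff in any image? keep simple
  far$pbc <- c(FALSE, FALSE, FALSE)
  expect_identical(interaction_energy(far, 1, 2), list(vdw = 0, coul = 0))
  bad <- fr; bad$topology$sigma[2] <- NA
  expect_error(interaction_energy(bad, 1, 2), "atom")
})

test_that("chain order hits its analytic limits and stays in range", {
  n <- 40
  aligned <- chain_frame(matrix(rep(c(0, 0, 1), n), n, 3, byrow = TRUE))
  expect_identical(chain_order(aligned)$s_chain, 1)
  perp <- chain_frame(matrix(rep(c(1, 0, 0), n), n, 3, byrow = TRUE))
  expect_equal(chain_order(perp)$s_chain, -0.5, tolerance = 1e-12)
  set.seed(8)
  for (rep in 1:20) {
    fr <- chain_frame(random_unit_vectors(30))
    s <- chain_order(fr)$s_chain
    expect_gte(s, -0.5); expect_lte(s, 1)
  }
  # zero-length chain vector: skipped with a warning, not silently
  degen <- chain_frame(matrix(c(0, 0, 1, 0, 0, 1), 2, 3, byrow = TRUE))
  degen$pos[4, ] <- degen$pos[3, ]
  expect_warning(res <- chain_order(degen), "zero-length")
  expect_identical(res$s_chain, 1)
})

test_that("uniformly random chains give S_chain near zero", {
  set.seed(12)
  n <- 1e5
  fr <- chain_frame(random_unit_vectors(n))
  s <- chain_order(fr)$s_chain
  # var of P2(cos theta) under uniform orientation is 1/5
  se <- sqrt(1 / 5 / n)
  expect_lt(abs(s), 3 * se)
})

test_that("local lipid selection picks whole lipids by minimum distance", {
  tr <- scripted_scenario("direct_insert", seed = 3)
  fr <- traj_frame(tr, length(tr$times))
  si <- tr$metadata$sheet_idx
  # far-away sheet selects nothing
  far <- traj_frame(tr, 1)
  expect_length(local_lipid_selection(far, si, 1.0), 0)
  # huge radius selects every lipid
  all_ids <- unique(fr$topology$lipid_id[fr$topology$group == "lipid"])
  expect_identical(local_lipid_selection(fr, si, 50), sort(all_ids))
  # brute-force oracle: per-lipid minimum distance
  sel <- local_lipid_selection(fr, si, 1.0)
  want <- integer(0)
  for (lid in all_ids) {
    idx <- which(fr$topology$lipid_id == lid &
                   fr$topology$group == "lipid")
    mind <- Inf
    for (i in idx) {
      for (j in si) {
        mind <- min(mind, oracle_dist(fr$pos[i, ], fr$pos[j, ],
                                      fr$box, fr$pbc))
      }
    }
    if (mind <= 1.0) want <- c(want, lid)
  }
  expect_identical(sel, sort(want))
})

test_that("membrane thickness reads the head-bead planes", {
  mem <- build_coarse_membrane(16, head_z = 2.0)
  fr <- sheetmem:::membrane_frame(mem)
  expect_equal(membrane_thickness(fr), 4, tolerance = 1e-12)
  shifted <- fr; shifted$pos[, 3] <- fr$pos[, 3] + 3.7
  expect_equal(membrane_thickness(shifted), 4, tolerance = 1e-12)
  up_only <- unique(fr$topology$lipid_id[fr$topology$leaflet == "upper"])
  expect_error(membrane_thickness(fr, up_only), "leaflet")
})

test_that("distance statistics are invariant under symmetry operations", {
  tr <- scripted_scenario("direct_insert", seed = 13)
  fr <- traj_frame(tr, 45)
  si <- tr$metadata$sheet_idx; mi <- tr$metadata$membrane_idx
  base <- count_contacts(fr, si, mi)
  # translation in x,y with periodic re-wrap
  shifted <- fr
  shifted$pos[, 1] <- (fr$pos[, 1] + 1.234) %% fr$box[1]
  shifted$pos[, 2] <- (fr$pos[, 2] - 0.777) %% fr$box[2]
  expect_identical(count_contacts(shifted, si, mi), base)
  # quarter-turn about the membrane normal through the box centre
  # (an exact symmetry of the periodic square box)
  rot <- fr
  cx <- fr$box[1] / 2; cy <- fr$box[2] / 2
  rot$pos[, 1] <- (cx - (fr$pos[, 2] - cy)) %% fr$box[1]
  rot$pos[, 2] <- (cy + (fr$pos[, 1] - cx)) %% fr$box[2]
  expect_identical(count_contacts(rot, si, mi), base)
  expect_equal(com_distance_z(rot, si, mi), com_distance_z(fr, si, mi),
               tolerance = 1e-12)
})

test_that("batch summaries average tail windows across replicas", {
  trajs <- lapply(1:5, function(s) scripted_scenario("no_insert", seed = s))
  out <- batch_summary(trajs, c("contacts", "com_z"), averaging_window = 100)
  expect_identical(nrow(out), 2L)
  expect_identical(out$n, c(5L, 5L))
  expect_error(batch_summary(trajs, "contacts", averaging_window = 1e6),
               "longer")
  # a single constant series: mean equals the constant, SE = 0
  one <- batch_summary(trajs[1], "com_z",
                       averaging_window = diff(range(trajs[[1]]$times)))
  ser <- traj_series(trajs[[1]], "com_z")
  expect_equal(one$mean, mean(ser$values), tolerance = 1e-12)
  expect_identical(one$se, 0)
})

test_that("traj_series computes labelled per-frame statistics", {
  tr <- scripted_scenario("direct_insert", seed = 5)
  ser <- traj_series(tr, "contacts")
  expect_s3_class(ser, "analysis_series")
  expect_identical(as.integer(ser$values), tr$truth$contacts)
  expect_identical(ser$statistic, "contacts")
  sw <- traj_series(tr, "bound_waters")
  expect_identical(as.integer(sw$values), tr$truth$bound_waters)
})
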