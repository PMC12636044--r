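two_atom_system <- function(dist_nm, box = c(5, 5, 5)) {
  atoms <- atom_table(c("CA", "P"), residue_index = c(1, 2),
                      residue_name = c("ALA", "DOPC"),
                      group = c("protein", "membrane"))
  coords <- rbind(c(2.5, 2.5, 1 + dist_nm), c(2.5, 2.5, 1))
  list(atoms = atoms, coords = coords, box = box)
}

test_that("the 0.4 nm cutoff is closed: at it counts, just above does not", {
  s <- two_atom_system(0.35)
  r <- count_contacts(s$coords, s$atoms, 1, 2, box = s$box)
  expect_equal(r$pair_count, 1L)
  expect_true(r$residue_contact[["1"]])
  expect_equal(r$min_distance, 0.35)

  r2 <- count_contacts(two_atom_system(0.45)$coords, s$atoms, 1, 2, box = s$box)
  expect_equal(r2$pair_count, 0L)
  expect_false(r2$residue_contact[["1"]])
  expect_equal(r2$min_distance, 0.45)

  r3 <- count_contacts(two_atom_system(0.4)$coords, s$atoms, 1, 2, box = s$box)
  expect_equal(r3$pair_count, 1L)
})

test_that("minimum image in x,y finds contacts across the boundary", {
  atoms <- atom_table(c("CA", "P"), residue_index = c(1, 2),
                      residue_name = c("ALA", "DOPC"),
                      group = c("protein", "membrane"))
  coords <- rbind(c(0.1, 2.5, 1), c(4.9, 2.5, 1))  # 0.2 nm across x
  r <- count_contacts(coords, atoms, 1, 2, box = c(5, 5, 5))
  expect_equal(r$pair_count, 1L)
  r_nopbc <- count_contacts(coords, atoms, 1, 2, pbc_xy = FALSE)
  expect_equal(r_nopbc$pair_count, 0L)
})

test_that("input validation: empty/overlapping selections, missing box", {
  s <- two_atom_system(0.3)
  expect_error(count_contacts(s$coords, s$atoms, integer(0), 2,
                              box = s$box), "empty")
  expect_error(count_contacts(s$coords, s$atoms, 1:2, 2, box = s$box),
               "overlap")
  expect_error(count_contacts(s$coords, s$atoms, 1, 2, box = NULL,
                              pbc_xy = TRUE), "box")
})

test_that("cell-list counts equal the all-pairs oracle on random configs", {
  for (seed in 1:25) {
    cfg <- random_contact_config(seed)
    got <- count_contacts(cfg$coords, cfg$atoms, cfg$protein_idx,
                          cfg$membrane_idx, box = cfg$box)
    want <- brute_force_contacts(cfg$coords, cfg$protein_idx,
                                 cfg$membrane_idx, box = cfg$box)
    expect_identical(got$pair_count, as.integer(want$pair_count))
    expect_equal(got$min_distance, want$min_distance, tolerance = 1e-12)
  }
})

test_that("contact series tracks a constructed approach frame by frame", {
  mem <- build_membrane_slab(5, 5, 0.5, seed = 1, z_jitter = 0,
                             box_height = 6)
  pep <- build_ideal_helix(6)
  pc <- pep$coords
  pc[, 1] <- pc[, 1] + 1; pc[, 2] <- pc[, 2] + 1
  atoms <- dplyr::bind_rows(pep$atoms, mem$atoms)
  lift <- c(3, 3, 0.1, 0.1, 0.1)  # frames 3-5 touch the slab
  frames <- lapply(lift, function(z) {
    p <- pc; p[, 3] <- p[, 3] - min(p[, 3]) + z
    rbind(p, mem$coords)
  })
  tr <- mh_trajectory(atoms, frames, times = 0:4, box = mem$box)
  cs <- contact_series(tr)
  expect_equal(cs$frames$pair_count[1:2], c(0L, 0L))
  expect_true(all(cs$frames$pair_count[3:5] > 0))
  expect_equal(cs$frames$min_distance[1], cs$frames$min_distance[2],
               tolerance = 1e-12)

  # frame-by-frame brute-force agreement on a simulated trajectory
  mem2 <- build_membrane_slab(6, 6, 1, seed = 3, box_height = 3.5)
  tr2 <- simulate_binding_trajectory(build_hairpin(6, 3, 6), mem2,
                                     well_depth = 5, pg_fraction = 1,
                                     n_frames = 20, seed = 9)
  cs2 <- contact_series(tr2)
  pidx <- which(tr2$atoms$group == "protein" & tr2$atoms$is_heavy)
  midx <- which(tr2$atoms$group == "membrane" & tr2$atoms$is_heavy)
  for (i in seq_len(20)) {
    bf <- brute_force_contacts(tr2$coords[, , i], pidx, midx, box = tr2$box)
    expect_identical(cs2$frames$pair_count[i], as.integer(bf$pair_count))
  }
})

test_that("residue flags imply a nonzero pair count", {
  cfg <- random_contact_config(99)
  got <- count_contacts(cfg$coords, cfg$atoms, cfg$protein_idx,
                        cfg$membrane_idx, box = cfg$box)
  if (any(got$residue_contact)) expect_gte(got$pair_count, 1L)
})
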