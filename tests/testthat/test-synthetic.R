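test_that("ideal-helix dihedrals are reproduced from the coordinates", {
  h <- build_ideal_helix(20, phi = -57, psi = -47)
  d <- backbone_dihedrals(h)
  expect_lt(max(abs(d$phi[-1] + 57)), 1e-4)
  expect_lt(max(abs(d$psi[-20] + 47)), 1e-4)

  g <- build_ideal_helix(15, phi = -120.5, psi = 130.25)
  dg <- backbone_dihedrals(g)
  expect_lt(max(abs(dg$phi[-1] + 120.5)), 1e-4)
  expect_lt(max(abs(dg$psi[-15] - 130.25)), 1e-4)
})

test_that("two-residue chain has exactly one phi/psi pair", {
  h <- build_ideal_helix(2)
  d <- backbone_dihedrals(h)
  expect_equal(sum(!is.na(d$phi)), 1L)
  expect_equal(sum(!is.na(d$psi)), 1L)
  expect_error(build_ideal_helix(1), "2 residues")
})

test_that("extended chains are longer end-to-end than helices", {
  n <- 20
  hel <- build_ideal_helix(n)
  ext <- build_ideal_helix(n, phi = -179.9, psi = 179.9)
  e2e <- function(s) {
    ca <- s$coords[s$atoms$name == "CA", ]
    sqrt(sum((ca[n, ] - ca[1, ])^2))
  }
  expect_gt(e2e(ext), e2e(hel))
})

test_that("hairpin numbering, atom order and antiparallel axes", {
  hp <- build_hairpin(50, 5, 50, first_residue = 26)
  expect_equal(range(hp$atoms$residue_index), c(26, 130))
  expect_false(is.unsorted(hp$atoms$residue_index))
  expect_false(is.unsorted(hp$atoms$index))

  ca <- hp$coords[hp$atoms$name == "CA", ]
  res <- hp$atoms$residue_index[hp$atoms$name == "CA"]
  ax1 <- memhairpin:::principal_axis(ca[res %in% 26:75, ])
  ax2 <- memhairpin:::principal_axis(ca[res %in% 81:130, ])
  angle <- acos(pmin(1, abs(sum(ax1 * -ax2)))) * 180 / pi
  expect_gt(180 - angle, 150)
  expect_error(build_hairpin(3, 2, 10), "at least 4")
})

test_that("membrane slab species counts, area and determinism", {
  m <- build_membrane_slab(10, 10, pg_fraction = 0.5, seed = 7)
  heads <- m$atoms$name == "P"
  expect_equal(sum(m$atoms$residue_name[heads] == "DOPG"), 50L)
  expect_equal(prod(m$box[1:2]), 100 * 0.75, tolerance = 1e-12)
  m2 <- build_membrane_slab(10, 10, pg_fraction = 0.5, seed = 7)
  expect_identical(m$coords, m2$coords)
  expect_identical(m$atoms$residue_name, m2$atoms$residue_name)
  m3 <- build_membrane_slab(10, 10, pg_fraction = 0.5, seed = 8)
  expect_false(identical(m$atoms$residue_name, m3$atoms$residue_name))
  expect_true(all(m$atoms$group == "membrane"))
})

test_that("binding simulator is deterministic and rigid up to wobble", {
  pep <- build_hairpin(8, 3, 8)
  mem <- build_membrane_slab(6, 6, 1, seed = 2, box_height = 3.5)
  t1 <- simulate_binding_trajectory(pep, mem, well_depth = 3, pg_fraction = 1,
                                    n_frames = 30, seed = 11)
  t2 <- simulate_binding_trajectory(pep, mem, well_depth = 3, pg_fraction = 1,
                                    n_frames = 30, seed = 11)
  expect_identical(t1$coords, t2$coords)

  # intra-peptide distances conserved up to the wobble amplitude
  npep <- nrow(pep$coords)
  pick <- cbind(c(1, 5, 20), c(10, 30, npep))
  d_ref <- sqrt(rowSums((pep$coords[pick[, 1], ] - pep$coords[pick[, 2], ])^2))
  for (f in c(1, 15, 30)) {
    d <- sqrt(rowSums((t1$coords[pick[, 1], , f] -
                       t1$coords[pick[, 2], , f])^2))
    expect_lt(max(abs(d - d_ref)), 6 * 0.02)
  }
})

test_that("with no attraction the peptide stays out of contact", {
  pep <- build_hairpin(8, 3, 8)
  mem <- build_membrane_slab(6, 6, 0, seed = 2, box_height = 3.5)
  tr <- simulate_binding_trajectory(pep, mem, well_depth = 0, pg_fraction = 0,
                                    n_frames = 200, seed = 4)
  cs <- contact_series(tr, min_distance = FALSE)
  expect_equal(median(cs$frames$pair_count), 0)
})

test_that("two-state contact series has the right stationary behaviour", {
  s0 <- generate_contact_series(k_on = 0.05, k_off = 0.05, mu_bound = 10,
                                mu_unbound = 0, n_frames = 400, seed = 1)
  expect_true(all(s0$count[s0$latent_state == "unbound"] == 0))

  s <- generate_contact_series(k_on = 0.02, k_off = 0.08, mu_bound = 20,
                               mu_unbound = 1, n_frames = 20000, seed = 42)
  frac <- mean(s$latent_state == "bound")
  # stationary bound fraction k_on/(k_on+k_off) = 0.2; SE from the
  # effective number of independent dwells
  n_eff <- 20000 / (1 / (0.02 + 0.08))  # frames per relaxation time
  se <- sqrt(0.2 * 0.8 / n_eff)
  expect_lt(abs(frac - 0.2), 3 * se)

  s2 <- generate_contact_series(k_on = 0.02, k_off = 0.08, mu_bound = 20,
                                mu_unbound = 1, n_frames = 20000, seed = 42)
  expect_identical(s$count, s2$count)
})

test_that("binding-curve generator satisfies Hill identities", {
  exact <- generate_binding_curve(0.05, 0.3, kd = 2, n_hill = 1.5,
                                  concentrations = c(2, 1e6))
  expect_equal(exact$gp[1], 0.05 + 0.15)         # half-saturation at KD
  expect_equal(exact$gp[2], 0.35, tolerance = 1e-6)  # saturation asymptote
  n1 <- generate_binding_curve(0, 1, 2, 1, noise_sd = 0.01, seed = 5)
  n2 <- generate_binding_curve(0, 1, 2, 1, noise_sd = 0.01, seed = 5)
  expect_identical(n1$gp, n2$gp)
})
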