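test_that("Kabsch recovers exact rigid motions and rejects reflections", {
  h <- build_ideal_helix(10)
  x <- h$coords
  rot <- rot_about(c(0, 0, 1), 37 * pi / 180)
  y <- sweep(x %*% t(rot), 2, c(1, -2, 0.5), `+`)
  fit <- kabsch_superpose(x, y)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  expect_lt(max(abs(fit$transform(x) - y)), 1e-9)

  mirrored <- x
  mirrored[, 1] <- -mirrored[, 1]
  fit_m <- kabsch_superpose(mirrored, x)
  expect_equal(det(fit_m$rotation), 1, tolerance = 1e-9)
  expect_gt(fit_m$rmsd, 0.01)

  expect_error(kabsch_superpose(x[1:2, ], x[1:2, ]), "3 points")
  degenerate <- matrix(rep(c(0, 0, 0), 5), 5, 3, byrow = TRUE)
  expect_error(kabsch_superpose(degenerate, degenerate), "degenerate")
})

test_that("Kabsch RMSD agrees with the quaternion oracle on random pairs", {
  set.seed(31)
  for (i in 1:50) {
    a <- matrix(rnorm(30), 10, 3)
    b <- matrix(rnorm(30), 10, 3)
    expect_equal(kabsch_superpose(a, b)$rmsd, quaternion_rmsd(a, b),
                 tolerance = 1e-9)
  }
})

test_that("Kabsch RMSD is symmetric and obeys the triangle inequality", {
  set.seed(8)
  for (i in 1:10) {
    a <- matrix(rnorm(24), 8, 3)
    b <- matrix(rnorm(24), 8, 3)
    cc <- matrix(rnorm(24), 8, 3)
    dab <- kabsch_superpose(a, b)$rmsd
    dba <- kabsch_superpose(b, a)$rmsd
    expect_equal(dab, dba, tolerance = 1e-9)
    dac <- kabsch_superpose(a, cc)$rmsd
    dcb <- kabsch_superpose(cc, b)$rmsd
    expect_lte(dab, dac + dcb + 1e-12)
  }
})

synthetic_breathing_traj <- function(n_frames = 30, n_res = 8, seed = 1) {
  h <- build_ideal_helix(n_res)
  with_seed_frames <- function() {
    set.seed(seed)
    lapply(seq_len(n_frames), function(i) {
      # one dominant collective mode plus small isotropic noise
      s <- sin(2 * pi * i / n_frames)
      x <- h$coords
      x[, 1] <- x[, 1] * (1 + 0.1 * s)
      x + matrix(rnorm(length(x), sd = 0.005), nrow(x), 3)
    })
  }
  mh_trajectory(h$atoms, with_seed_frames(), times = seq_len(n_frames) - 1)
}

test_that("zero-variance and rank-one inputs give the expected spectra", {
  h <- build_ideal_helix(6)
  same <- mh_trajectory(h$atoms, list(h$coords, h$coords, h$coords),
                        times = 0:2)
  m0 <- fit_pca(same)
  expect_true(m0$degenerate)
  expect_lt(max(m0$values), 1e-20)
  expect_error(project_pca(same, m0), "zero variance")

  # two frames differing along one direction: all variance on PC1
  x2 <- h$coords
  x2[2, 1] <- x2[2, 1] + 0.2
  two <- mh_trajectory(h$atoms, list(h$coords, x2), times = 0:1)
  m2 <- fit_pca(two)
  expect_equal(m2$var_fraction[1], 1, tolerance = 1e-9)
})

test_that("eigenpairs match a dense covariance decomposition", {
  tr <- synthetic_breathing_traj()
  model <- fit_pca(tr)

  # rebuild the fitted, centred coordinate matrix exactly as the model
  # defines it, then take the dense eigendecomposition
  att <- memhairpin:::pca_atoms(tr, NULL)
  flat <- t(vapply(seq_len(n_frames(tr)), function(i) {
    k <- kabsch_superpose(tr$coords[att$idx, , i], model$mean)
    as.vector(t(k$transform(tr$coords[att$idx, , i])))
  }, numeric(3 * length(att$idx))))
  cc <- stats::cov(flat)
  ev <- eigen(cc, symmetric = TRUE)
  keep <- seq_len(min(10, ncol(model$vectors)))
  expect_equal(model$values[keep], ev$values[keep], tolerance = 1e-8)
  for (k in keep) {
    dotp <- abs(sum(model$vectors[, k] * ev$vectors[, k]))
    expect_equal(dotp, 1, tolerance = 1e-6)
  }
  # trace identity and orthonormality
  expect_equal(sum(model$values), sum(diag(cc)), tolerance = 1e-8)
  gram <- t(model$vectors) %*% model$vectors
  expect_lt(max(abs(gram - diag(ncol(gram)))), 1e-8)
  expect_equal(sum(model$var_fraction), 1, tolerance = 1e-9)
})

test_that("training projections have mean zero and variance lambda", {
  tr <- synthetic_breathing_traj(seed = 4)
  model <- fit_pca(tr)
  p1 <- project_pca(tr, model, k = 1)
  expect_lt(abs(mean(p1$projection)), 1e-8)
  expect_equal(var(p1$projection), model$values[1], tolerance = 1e-8)
  p2 <- project_pca(tr, model, k = 2)
  expect_lt(abs(stats::cor(p1$projection, p2$projection)), 1e-6)

  # the mean structure itself projects to zero
  mean_traj <- mh_trajectory(
    tr$atoms[memhairpin:::pca_atoms(tr, NULL)$idx, ],
    list(model$mean, model$mean), times = 0:1)
  pm <- project_pca(mean_traj, model)
  expect_lt(max(abs(pm$projection)), 1e-8)
})

test_that("the fragment spec excludes the mobile C-terminal residues", {
  hp <- build_hairpin(60, 11, 60, first_residue = 26)
  tr <- mh_trajectory(hp$atoms, list(hp$coords, hp$coords + 0.01,
                                     hp$coords * 1.001),
                      times = 0:2)
  model <- fit_pca(tr, fragment = fragment_spec())
  expect_true(all(model$atom_residues <= 151))
  expect_true(all(model$atom_residues >= 26))
  expect_error(project_pca(tr, model, fragment = NULL), "does not match")

  td <- tidy(model)
  expect_equal(td$var_fraction, model$var_fraction)
  expect_equal(glance(model)$pc1_fraction, model$var_fraction[1])
})
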