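test_that("GP arithmetic: symmetry, bounds and antisymmetry", {
  expect_equal(compute_gp(2, 2), 0)
  expect_equal(compute_gp(3, 1), 0.5)
  expect_equal(compute_gp(5, 0), 1)
  expect_equal(compute_gp(1, 3), -compute_gp(3, 1))
  expect_error(compute_gp(0, 0), "nonzero")
  expect_equal(compute_gp(c(3, 1), c(1, 3)), c(0.5, -0.5))
})

test_that("spectrum GP picks nearest-or-interpolated intensities", {
  sp <- tibble::tibble(wavelength = seq(400, 550, by = 1),
                       intensity = seq(400, 550, by = 1) / 100)
  g <- spectrum_gp(sp)
  expect_equal(g$i440, 4.40)
  expect_equal(g$i490, 4.90)
  sp2 <- tibble::tibble(wavelength = c(400, 437, 443, 488, 492, 550),
                        intensity = c(1, 2, 4, 6, 8, 3))
  g2 <- spectrum_gp(sp2)
  expect_equal(g2$i440, 3)  # linear midpoint of 437/443
  expect_equal(g2$i490, 7)
  expect_error(spectrum_gp(tibble::tibble(wavelength = 450:500,
                                          intensity = 1)), "cover")
})

test_that("emission normalization divides by the apo window mean", {
  wl <- 300:450
  apo <- tibble::tibble(wavelength = wl, intensity = rep(2, length(wl)))
  sam <- tibble::tibble(wavelength = wl, intensity = rep(6, length(wl)))
  out <- normalize_emission(list(a = apo, b = sam), apo)
  expect_equal(unique(out$a$intensity), 1)
  expect_equal(unique(out$b$intensity), 3)
  # the window is inclusive: exactly the 333..337 samples on a 1-nm grid
  apo2 <- tibble::tibble(wavelength = wl,
                         intensity = ifelse(wl %in% 333:337, 10, 0))
  out2 <- normalize_emission(apo2, apo2)
  sel <- out2$wavelength %in% 333:337
  expect_equal(mean(out2$intensity[sel]), 1)
  expect_error(normalize_emission(apo, tibble::tibble(wavelength = 400:450,
                                                      intensity = 1)),
               "window")
})

test_that("noise-free Hill curves are recovered to 1e-6 relative", {
  truth <- c(gp0 = 0.05, delta_gp = 0.30, kd = 2.0, n = 1.5)
  curve <- generate_binding_curve(0.05, 0.30, 2.0, 1.5)
  fit <- fit_hill(curve)
  expect_true(fit$converged)
  expect_false(fit$low_confidence)
  for (p in names(truth)) {
    expect_lt(abs(fit$estimates[[p]] - truth[[p]]) / truth[[p]], 1e-6)
  }
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "kd"], fit$estimates[["kd"]])
  expect_true(is.finite(glance(fit)$rss))
})

test_that("fixing the cooperativity reproduces a fixed-n curve", {
  curve <- generate_binding_curve(0.1, 0.2, 1.2, 1)
  fit <- fit_hill(curve, fix_n = 1)
  expect_equal(unname(fit$estimates["n"]), 1)
  expect_lt(abs(fit$estimates[["kd"]] - 1.2) / 1.2, 1e-6)
})

test_that("degenerate curves are flagged, not thrown", {
  flat <- tibble::tibble(concentration_uM = 0.125 * 2^(0:7), gp = 0.2)
  fit <- fit_hill(flat)
  expect_true(fit$low_confidence)
  expect_true(is.na(fit$estimates[["delta_gp"]]) ||
                abs(fit$estimates[["delta_gp"]]) < 1e-3)
  few <- generate_binding_curve(0, 0.3, 2, 1,
                                concentrations = c(0.5, 2, 8))
  expect_true(fit_hill(few)$low_confidence)
})

test_that("the fit is equivariant under concentration rescaling", {
  curve <- generate_binding_curve(0.02, 0.25, 3.0, 2.0)
  f1 <- fit_hill(curve)
  scaled <- curve
  scaled$concentration_uM <- scaled$concentration_uM * 1000  # to nM
  f2 <- fit_hill(scaled)
  expect_equal(f2$estimates[["kd"]] / 1000, f1$estimates[["kd"]],
               tolerance = 1e-6)
  expect_equal(f2$estimates[["n"]], f1$estimates[["n"]], tolerance = 1e-6)
  expect_equal(f2$estimates[["gp0"]], f1$estimates[["gp0"]], tolerance = 1e-6)
  expect_equal(f2$estimates[["delta_gp"]], f1$estimates[["delta_gp"]],
               tolerance = 1e-6)
})

test_that("recovery error stays below 10% at realistic noise", {
  errs <- vapply(1:200, function(seed) {
    curve <- generate_binding_curve(0.05, 0.30, 2.0, 1.5,
                                    noise_sd = 0.01, seed = seed)
    fit <- fit_hill(curve)
    abs(fit$estimates[["kd"]] - 2.0) / 2.0
  }, 0.0)
  expect_lt(median(errs), 0.10)
})

test_that("melt normalization is the affine [-1, 0] map", {
  tt <- seq(20, 96, by = 2)
  ell <- -30 + 25 * (tt - 20) / 76
  curve <- tibble::tibble(temperature = tt, ellipticity = ell)
  norm <- normalize_melt(curve)
  expect_equal(norm$normalized[1], -1)
  expect_equal(norm$normalized[length(tt)], 0)
  expect_equal(norm$normalized[which.min(abs(ell + 17.5))], -0.5,
               tolerance = 1e-9)

  # idempotence on an already-normalized curve
  again <- normalize_melt(tibble::tibble(temperature = tt,
                                         ellipticity = norm$normalized))
  expect_equal(again$normalized, norm$normalized, tolerance = 1e-12)

  # an affine map preserves monotonicity of a sigmoid melt
  sig <- -1 / (1 + exp((tt - 60) / 5))
  ns <- normalize_melt(tibble::tibble(temperature = tt, ellipticity = sig))
  expect_true(all(diff(ns$normalized) >= 0))

  expect_error(normalize_melt(tibble::tibble(temperature = tt,
                                             ellipticity = rep(1, length(tt)))),
               "equal anchor")
  expect_error(normalize_melt(curve, t_low = 10), "outside")
})
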