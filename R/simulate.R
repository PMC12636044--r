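#' Simulate a peptide-membrane binding trajectory
#'
#' A deliberately simple dynamics emulator: the peptide moves as a rigid
#' body whose gap above the membrane head-group plane follows overdamped
#' one-dimensional Brownian motion in a short-ranged attractive potential,
#' plus seeded per-atom Gaussian wobble. The attraction well has depth
#' `well_depth * pg_fraction` (kT), so the PG dependence of binding enters
#' only through a monotone well-depth scaling. The membrane is static.
#' The emulator is not molecular dynamics; it produces trajectories with
#' controllable binding statistics that exercise the geometric pipeline.
#'
#' The peptide is first rotated so its long axis lies in the membrane
#' plane (binding-competent orientation, optionally tilted), then released
#' with its lowest atom `start_height` above the head groups.
#'
#' @param peptide An [mh_structure] (group `"protein"`).
#' @param membrane An [mh_structure] from [build_membrane_slab()] with a
#'   periodic x,y box.
#' @param well_depth Attraction at contact, in kT, before PG scaling.
#' @param pg_fraction PG mole fraction scaling the well depth.
#' @param diffusion_z Vertical diffusion coefficient, nm^2/ns.
#' @param wobble_amplitude Per-atom Gaussian jitter sd, nm.
#' @param start_height Initial gap above the head groups, nm (default 2).
#' @param tilt Initial tilt of the long axis out of the plane, degrees.
#' @param dt Frame spacing, ns.
#' @param n_frames Number of frames.
#' @param well_range Decay length of the attraction, nm.
#' @param replica_id,condition Metadata stored on the trajectory.
#' @param seed Integer seed; identical seeds give identical trajectories.
#' @return An [mh_trajectory] containing the peptide followed by the
#'   membrane atoms.
#' @export
simulate_binding_trajectory <- function(peptide, membrane,
                                        well_depth, pg_fraction,
                                        diffusion_z = 0.1,
                                        wobble_amplitude = 0.02,
                                        start_height = 2.0,
                                        tilt = 0,
                                        dt = 0.5, n_frames = 400,
                                        well_range = 0.3,
                                        replica_id = 1L,
                                        condition = pg_fraction,
                                        seed = 1L) {
  stopifnot(well_depth >= 0, diffusion_z > 0, wobble_amplitude >= 0,
            start_height > 0, dt > 0, n_frames >= 1, well_range > 0)
  if (is.null(membrane$box)) abort("membrane must carry a periodic box")
  # gap reference: the mean head-group plane (individual heads jitter
  # around it, so small gaps still produce contacts)
  z_head <- mean(tapply(membrane$coords[, 3],
                        membrane$atoms$residue_index, max))

  # orient: long axis into the xy-plane (plus optional tilt about y)
  pc <- peptide$coords
  ax <- principal_axis(pc[peptide$atoms$name == "CA", , drop = FALSE])
  r1 <- rotation_between(ax, c(1, 0, 0))
  if (tilt != 0) {
    th <- tilt * pi / 180
    r1 <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)),
                 3, 3, byrow = TRUE) %*% r1
  }
  pc <- pc %*% t(r1)
  # centre in x,y; lowest atom defines the gap
  pc[, 1] <- pc[, 1] - mean(range(pc[, 1])) + membrane$box[1] / 2
  pc[, 2] <- pc[, 2] - mean(range(pc[, 2])) + membrane$box[2] / 2
  pc[, 3] <- pc[, 3] - min(pc[, 3])  # lowest atom at gap 0
  if (start_height <= 0) abort("peptide would initially overlap the membrane")

  depth <- well_depth * pg_fraction
  gap_min <- 0.02
  pep_height <- max(pc[, 3])
  gap_max <- membrane$box[3] - z_head - pep_height - 0.2
  if (gap_max <= start_height)
    abort("box too short for the requested start height")

  n_pep <- nrow(pc)
  with_seed(seed, {
    gaps <- numeric(n_frames)
    g <- start_height
    # substep the overdamped Euler integration: the well is stiff on the
    # frame-saving timescale, so the gap advances at <= 0.01 ns per step
    n_sub <- max(1L, ceiling(dt / 0.01))
    h <- dt / n_sub
    sq <- sqrt(2 * diffusion_z * h)
    noise <- rnorm(n_frames * n_sub)
    k <- 0L
    for (i in seq_len(n_frames)) {
      for (s in seq_len(n_sub)) {
        k <- k + 1L
        # U(g) = -depth * exp(-g / range)  [kT]
        force <- -(depth / well_range) * exp(-g / well_range)
        g <- g + diffusion_z * force * h + sq * noise[k]
        if (g < gap_min) g <- 2 * gap_min - g
        if (g > gap_max) g <- 2 * gap_max - g
      }
      gaps[i] <- g
    }
    n_mem <- nrow(membrane$coords)
    coords <- array(NA_real_, c(n_pep + n_mem, 3, n_frames))
    for (i in seq_len(n_frames)) {
      fp <- pc
      fp[, 3] <- fp[, 3] + z_head + gaps[i]
      if (wobble_amplitude > 0)
        fp <- fp + matrix(rnorm(n_pep * 3, sd = wobble_amplitude), n_pep, 3)
      coords[, , i] <- rbind(fp, membrane$coords)
    }
    atoms <- bind_rows(peptide$atoms, membrane$atoms)
    atoms$index <- seq_len(nrow(atoms)) - 1L
    mh_trajectory(atoms, coords, times = (seq_len(n_frames) - 1) * dt,
                  box = membrane$box, replica_id = replica_id,
                  condition = condition)
  })
}

#' Generate a two-state contact-count series with known latent states
#'
#' A latent bound/unbound Markov chain with switching rates `k_on`,
#' `k_off` (per ns) is sampled at spacing `dt`; per-frame contact counts
#' are Poisson with state-dependent means. The latent labels are returned
#' so that state-classification can be scored against ground truth.
#'
#' @param k_on,k_off Switching rates, 1/ns.
#' @param mu_bound,mu_unbound Mean contact counts in each state.
#' @param dt Frame spacing, ns.
#' @param n_frames Number of frames.
#' @param start_state `"unbound"` (default) or `"bound"`.
#' @param seed Integer seed.
#' @return Tibble with `time`, `count`, `latent_state`; `dt` is attached
#'   as an attribute.
#' @export
generate_contact_series <- function(k_on, k_off, mu_bound, mu_unbound,
                                    dt = 1, n_frames = 1000,
                                    start_state = "unbound", seed = 1L) {
  stopifnot(k_on >= 0, k_off >= 0, mu_bound >= 0, mu_unbound >= 0,
            dt > 0, n_frames >= 1)
  p_on <- 1 - exp(-k_on * dt)
  p_off <- 1 - exp(-k_off * dt)
  with_seed(seed, {
    state <- integer(n_frames)  # 0 unbound, 1 bound
    s <- if (identical(start_state, "bound")) 1L else 0L
    u <- runif(n_frames)
    for (i in seq_len(n_frames)) {
      s <- if (s == 0L) (if (u[i] < p_on) 1L else 0L) else
        (if (u[i] < p_off) 0L else 1L)
      state[i] <- s
    }
    count <- rpois(n_frames, ifelse(state == 1L, mu_bound, mu_unbound))
    out <- tibble(time = (seq_len(n_frames) - 1) * dt,
                  count = count,
                  latent_state = ifelse(state == 1L, "bound", "unbound"))
    attr(out, "dt") <- dt
    out
  })
}

#' Generate a noisy Hill-shaped binding curve
#'
#' GP values over a protein-concentration series follow the Hill
#' expression `gp0 + delta_gp * P^n / (kd^n + P^n)` plus additive Gaussian
#' noise.
#'
#' @param gp0 GP in the absence of protein.
#' @param delta_gp GP change at saturation.
#' @param kd Apparent dissociation constant, uM.
#' @param n_hill Apparent cooperativity index.
#' @param concentrations Protein concentrations in uM; default the
#'   doubling series 0.125-16 uM used in titration experiments.
#' @param noise_sd Gaussian noise sd on GP (0 gives the exact curve).
#' @param seed Integer seed.
#' @return Tibble with `concentration_uM` and `gp`.
#' @export
generate_binding_curve <- function(gp0, delta_gp, kd, n_hill,
                                   concentrations = 0.125 * 2^(0:7),
                                   noise_sd = 0, seed = 1L) {
  stopifnot(kd > 0, n_hill > 0, all(concentrations > 0), noise_sd >= 0)
  gp <- gp0 + delta_gp * concentrations^n_hill /
    (kd^n_hill + concentrations^n_hill)
  if (noise_sd > 0)
    gp <- with_seed(seed, gp + rnorm(length(gp), sd = noise_sd))
  tibble(concentration_uM = as.numeric(concentrations), gp = gp)
}
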