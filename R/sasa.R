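#' Shrake-Rupley solvent-accessible surface area
#'
#' Each atom's van der Waals sphere is expanded by the probe radius
#' (default 0.14 nm) and sampled with a quasi-uniform Fibonacci lattice
#' of test points; the accessible fraction is the share of points not
#' buried inside any neighbour's expanded sphere, times the expanded
#' sphere's area. Per-residue SASA is the sum over the residue's atoms.
#'
#' @param structure An [mh_structure]; solvent atoms are ignored.
#' @param probe_radius Probe radius, nm (default 0.14).
#' @param n_points Sphere points per atom (default 960, >= 32).
#' @param radii Named van der Waals radii by element, nm (Bondi defaults:
#'   C 0.170, N 0.155, O 0.152, S 0.180, H 0.120, P 0.180).
#' @param per_residue Also return the per-residue table.
#' @param include_h Include hydrogens in the calculation (default FALSE:
#'   heavy atoms only, the usual convention for united surfaces).
#' @return List with `total` (nm^2), `per_atom` (numeric vector) and,
#'   when `per_residue`, a tibble `residue` with `residue_index` and
#'   `sasa`.
#' @export
shrake_rupley_sasa <- function(structure, probe_radius = 0.14,
                               n_points = 960L,
                               radii = c(C = 0.170, N = 0.155, O = 0.152,
                                         S = 0.180, H = 0.120, P = 0.180),
                               per_residue = FALSE, include_h = FALSE) {
  stopifnot(probe_radius > 0, n_points >= 32)
  a <- structure$atoms
  keep <- a$group != "solvent"
  if (!include_h) keep <- keep & a$is_heavy
  idx <- which(keep)
  if (length(idx) == 0) abort("no atoms to analyse")
  el <- a$element[idx]
  unknown <- setdiff(unique(el), names(radii))
  if (length(unknown) > 0)
    abort(sprintf("no van der Waals radius for element(s): %s",
                  paste(unknown, collapse = ", ")))
  xyz <- structure$coords[idx, , drop = FALSE]
  r <- unname(radii[el]) + probe_radius
  n <- length(idx)

  sphere <- fibonacci_sphere(n_points)
  area <- numeric(n)
  # neighbour prefilter: pairs closer than the sum of expanded radii
  rmax <- max(r)
  for (i in seq_len(n)) {
    d <- sqrt(rowSums(sweep(xyz, 2, xyz[i, ])^2))
    nb <- which(d < r[i] + r & seq_len(n) != i)
    pts <- sweep(sphere * r[i], 2, xyz[i, ], `+`)
    if (length(nb) > 0) {
      acc <- rep(TRUE, n_points)
      for (j in nb) {
        d2 <- rowSums(sweep(pts, 2, xyz[j, ])^2)
        acc <- acc & d2 > r[j]^2
        if (!any(acc)) break
      }
      frac <- mean(acc)
    } else frac <- 1
    area[i] <- frac * 4 * pi * r[i]^2
  }
  out <- list(total = sum(area),
              per_atom = setNames(area, a$index[idx]))
  if (per_residue) {
    out$residue <- tibble(residue_index = a$residue_index[idx],
                          sasa = area) |>
      group_by(residue_index) |>
      summarise(sasa = sum(sasa), .groups = "drop")
  }
  out
}

# quasi-uniform points on the unit sphere (Fibonacci lattice)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Per-frame SASA series (total and one tracked residue)
#'
#' @param trajectory An [mh_trajectory].
#' @param residue Residue to track separately (default 71, the
#'   fluorescence-reporter tryptophan position of the hairpin fragment);
#'   `NULL` to skip.
#' @inheritParams shrake_rupley_sasa
#' @return Tibble with `time`, `sasa_total` and (when tracked)
#'   `sasa_residue` (nm^2).
#' @export
sasa_series <- function(trajectory, residue = 71L, probe_radius = 0.14,
                        n_points = 960L) {
  nf <- n_frames(trajectory)
  tot <- resv <- numeric(nf)
  prot <- which(trajectory$atoms$group == "protein")
  for (i in seq_len(nf)) {
    st <- mh_structure(trajectory$atoms[prot, ],
                       trajectory$coords[prot, , i])
    s <- shrake_rupley_sasa(st, probe_radius = probe_radius,
                            n_points = n_points,
                            per_residue = !is.null(residue))
    tot[i] <- s$total
    if (!is.null(residue)) {
      hit <- s$residue$sasa[s$residue$residue_index == residue]
      resv[i] <- if (length(hit) == 1) hit else NA_real_
    }
  }
  out <- tibble(time = trajectory$times, sasa_total = tot)
  if (!is.null(residue)) out$sasa_residue <- resv
  out
}
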