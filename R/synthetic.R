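#' Synthetic structure generators
#'
#' Deterministic builders for ideal helices, helical hairpins and planar
#' lipid slabs. They exist so that every analysis stage can be exercised
#' against known ground truth; they are geometric emulations, not
#' chemically parameterised models.
#'
#' @name synthetic-structures
NULL

# standard backbone geometry (nm / degrees)
BB <- list(
  n_ca = 0.1458, ca_c = 0.1525, c_n = 0.1329, c_o = 0.1231, n_h = 0.100,
  ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7, ang_ca_c_o = 120.8
)

# evaluate `code` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Build an ideal polyalanine helix (backbone only)
#'
#' Places N, CA, C, O per residue by sequential internal-coordinate
#' construction at the given backbone dihedrals, using standard bond
#' lengths (N-CA 0.1458, CA-C 0.1525, C-N 0.1329, C=O 0.1231 nm) and
#' angles. The amide hydrogen of residues 2..n is reconstructed 0.1 nm
#' from N along the preceding residue's O->C direction (the convention
#' used by DSSP-style hydrogen-bond energies).
#'
#' @param n_residues Number of residues (>= 2).
#' @param phi,psi,omega Backbone dihedrals in degrees, in (-180, 180].
#'   Defaults are the canonical alpha-helix (-57, -47, 180). Scalars or
#'   per-residue vectors.
#' @param first_residue First residue number (author numbering).
#' @param residue_name Residue name for all residues.
#' @return An [mh_structure] with atoms ordered N, (H,) CA, C, O per
#'   residue.
#' @export
#' @examples
#' h <- build_ideal_helix(12)
#' backbone_dihedrals(h)
build_ideal_helix <- function(n_residues, phi = -57, psi = -47, omega = 180,
                              first_residue = 1L, residue_name = "ALA") {
  n <- as.integer(n_residues)
  if (n < 2) abort("need at least 2 residues")
  bad <- function(x) any(x <= -180 | x > 180)
  if (bad(phi) || bad(psi) || bad(omega))
    abort("dihedrals must lie in (-180, 180] degrees")
  phi <- rep_len(phi, n); psi <- rep_len(psi, n); omega <- rep_len(omega, n)

  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(BB$n_ca, 0, 0)
  th <- BB$ang_n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + BB$ca_c * c(-cos(th), sin(th), 0)
  for (i in seq_len(n - 1)) {
    N[i + 1, ] <- place_atom(N[i, ], CA[i, ], C[i, ], BB$c_n,
                             BB$ang_ca_c_n, psi[i])
    CA[i + 1, ] <- place_atom(CA[i, ], C[i, ], N[i + 1, ], BB$n_ca,
                              BB$ang_c_n_ca, omega[i])
    C[i + 1, ] <- place_atom(C[i, ], N[i + 1, ], CA[i + 1, ], BB$ca_c,
                             BB$ang_n_ca_c, phi[i + 1])
  }
  for (i in seq_len(n)) {
    tor <- psi[i] + 180
    if (tor > 180) tor <- tor - 360
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], BB$c_o, BB$ang_ca_c_o, tor)
  }

  name <- character(0); resno <- integer(0); coords <- NULL
  for (i in seq_len(n)) {
    rows <- N[i, , drop = FALSE]
    nm <- "N"
    if (i > 1) {
      h <- N[i, ] + BB$n_h * unitv(C[i - 1, ] - O[i - 1, ])
      rows <- rbind(rows, h); nm <- c(nm, "H")
    }
    rows <- rbind(rows, CA[i, ], C[i, ], O[i, ])
    nm <- c(nm, "CA", "C", "O")
    coords <- rbind(coords, rows)
    name <- c(name, nm)
    resno <- c(resno, rep(first_residue + i - 1L, length(nm)))
  }
  atoms <- atom_table(name, resno, residue_name, group = "protein")
  mh_structure(atoms, coords)
}

#' Recompute backbone dihedrals from coordinates
#'
#' @param structure An [mh_structure] with N, CA, C backbone atoms.
#' @return Tibble with `residue_index`, `phi`, `psi` (degrees; NA where
#'   undefined at the chain ends).
#' @export
backbone_dihedrals <- function(structure) {
  a <- structure$atoms
  res <- unique(a$residue_index)
  pick <- function(i, nm) {
    j <- which(a$residue_index == res[i] & a$name == nm)
    if (length(j) != 1) return(NULL)
    structure$coords[j, ]
  }
  n <- length(res)
  phi <- psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    Ni <- pick(i, "N"); CAi <- pick(i, "CA"); Ci <- pick(i, "C")
    if (i > 1) {
      Cp <- pick(i - 1, "C")
      if (!is.null(Cp)) phi[i] <- dihedral_angle(Cp, Ni, CAi, Ci)
    }
    if (i < n) {
      Nn <- pick(i + 1, "N")
      if (!is.null(Nn)) psi[i] <- dihedral_angle(Ni, CAi, Ci, Nn)
    }
  }
  tibble(residue_index = res, phi = phi, psi = psi)
}

#' Build a helical-hairpin peptide
#'
#' Two antiparallel ideal helices joined by a short stretch of extended
#' residues, mimicking the alpha-helical hairpin topology of ESCRT-III
#' family membrane binders. The construction is geometric: helix 2 is
#' helix 1 rotated by 180 degrees about an in-plane axis and laid back
#' alongside it.
#'
#' @param n1,n2 Residues in the two helices (>= 4 each).
#' @param loop Residues in the connecting extended stretch.
#' @param first_residue First residue number; residues are numbered
#'   consecutively across helix 1, loop, helix 2 (default start 26, the
#'   hairpin fragment convention).
#' @param separation Axis-to-axis distance between the helices (nm).
#' @return An [mh_structure].
#' @export
build_hairpin <- function(n1, loop, n2, first_residue = 26L,
                          separation = 1.0) {
  if (n1 < 4 || n2 < 4) abort("helices need at least 4 residues each")
  h1 <- build_ideal_helix(n1)
  ca1 <- h1$coords[h1$atoms$name == "CA", , drop = FALSE]
  a1 <- principal_axis(ca1)
  p <- unitv(pracma_cross(a1, if (abs(a1[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)))

  h2 <- build_ideal_helix(n2)
  rot <- 2 * tcrossprod(p) - diag(3)  # 180-degree rotation about p
  c2 <- h2$coords %*% t(rot)
  ca2_first <- c2[which(h2$atoms$name == "CA")[1], ]
  target <- ca1[nrow(ca1), ] + separation * p
  c2 <- sweep(c2, 2, target - ca2_first, `+`)

  lp <- build_ideal_helix(max(loop, 2), phi = -179.9, psi = 179.9)
  keep_res <- unique(lp$atoms$residue_index)[seq_len(max(loop, 2))]
  cal <- lp$coords[lp$atoms$name == "CA", , drop = FALSE]
  ve <- cal[nrow(cal), ] - cal[1, ]
  vt <- target - ca1[nrow(ca1), ]
  rl <- rotation_between(unitv(ve), unitv(vt))
  cl <- lp$coords %*% t(rl)
  cl <- sweep(cl, 2, ca1[nrow(ca1), ] + 0.3 * unitv(vt) -
                cl[which(lp$atoms$name == "CA")[1], ], `+`)

  pieces <- list(list(h1$atoms, h1$coords), list(lp$atoms, cl),
                 list(h2$atoms, c2))
  name <- unlist(lapply(pieces, function(x) x[[1]]$name))
  coords <- do.call(rbind, lapply(pieces, function(x) x[[2]]))
  # consecutive renumbering across the three pieces
  resno <- integer(0); offset <- as.integer(first_residue)
  for (x in pieces) {
    r <- x[[1]]$residue_index
    resno <- c(resno, offset + match(r, unique(r)) - 1L)
    offset <- offset + length(unique(r))
  }
  atoms <- atom_table(name, resno, "ALA", group = "protein")
  mh_structure(atoms, coords)
}

# minimal rotation taking unit vector u onto unit vector v (Rodrigues)
rotation_between <- function(u, v) {
  w <- pracma_cross(u, v)
  s <- vnorm(w); cc <- sum(u * v)
  if (s < 1e-12) return(if (cc > 0) diag(3) else 2 * tcrossprod(unitv(
    pracma_cross(u, if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)))) - diag(3))
  k <- w / s
  kx <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + s * kx + (1 - cc) * kx %*% kx
}

#' Build a planar PC/PG lipid slab
#'
#' Lipids are placed on a jittered square lattice with the given area per
#' head group; each lipid is a vertical stack of heavy pseudo-atoms with
#' the head bead at `z_head`. A seeded shuffle assigns
#' `round(pg_fraction * n)` lipids the anionic species DOPG and the rest
#' DOPC.
#'
#' @param nx,ny Lattice counts.
#' @param pg_fraction PG mole fraction in `[0, 1]`.
#' @param area_per_lipid Area per head group, nm^2 (default 0.75).
#' @param beads_per_lipid Heavy pseudo-atoms per lipid (head + tail).
#' @param z_head Mean head-group height (nm).
#' @param z_jitter Half-width of the uniform head-height jitter (nm),
#'   emulating membrane roughness; tails follow their head bead.
#' @param box_height Box z-length (nm).
#' @param seed Integer seed controlling jitter and species assignment.
#' @return An [mh_structure] with `group = "membrane"` and a periodic
#'   x,y box of area `nx * ny * area_per_lipid`.
#' @export
build_membrane_slab <- function(nx, ny, pg_fraction, area_per_lipid = 0.75,
                                beads_per_lipid = 4L, z_head = 0,
                                z_jitter = 0.18,
                                box_height = 12, seed = 1L) {
  stopifnot(nx >= 1, ny >= 1, pg_fraction >= 0, pg_fraction <= 1,
            beads_per_lipid >= 1)
  a <- sqrt(area_per_lipid)
  nlip <- nx * ny
  with_seed(seed, {
    g <- expand.grid(ix = seq_len(nx) - 1L, iy = seq_len(ny) - 1L)
    # strong in-plane disorder: fluid membranes are not lattices
    x <- (g$ix + 0.5) * a + runif(nlip, -0.3 * a, 0.3 * a)
    y <- (g$iy + 0.5) * a + runif(nlip, -0.3 * a, 0.3 * a)
    n_pg <- round(pg_fraction * nlip)
    species <- rep("DOPC", nlip)
    species[sample.int(nlip, n_pg)] <- "DOPG"
    zoff <- runif(nlip, -z_jitter, z_jitter)
    # two head-region beads ("O") laterally offset on opposite sides of
    # the phosphate: head groups spread ~0.2-0.3 nm in the membrane plane
    oang <- runif(nlip, 0, 2 * pi)
    orad <- runif(nlip, 0.15, 0.28)
    coords <- matrix(NA_real_, nlip * beads_per_lipid, 3)
    name <- character(nlip * beads_per_lipid)
    resno <- integer(nlip * beads_per_lipid)
    resnm <- character(nlip * beads_per_lipid)
    k <- 1L
    for (i in seq_len(nlip)) {
      zh <- z_head + zoff[i]
      for (b in seq_len(beads_per_lipid)) {
        sgn <- if (b == 2) 1 else -1
        coords[k, ] <- if (b == 1) c(x[i], y[i], zh)
          else if (b <= 3) c(x[i] + sgn * orad[i] * cos(oang[i]),
                             y[i] + sgn * orad[i] * sin(oang[i]), zh - 0.08)
          else c(x[i], y[i], zh - 0.3 * (b - 3))
        name[k] <- if (b == 1) "P" else if (b <= 3) paste0("O", b - 1) else
          paste0("C", b - 3)
        resno[k] <- i
        resnm[k] <- species[i]
        k <- k + 1L
      }
    }
    atoms <- atom_table(name, resno, resnm, group = "membrane")
    mh_structure(atoms, coords, box = c(nx * a, ny * a, box_height))
  })
}
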