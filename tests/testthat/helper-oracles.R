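# independent oracles used across tests

# all-pairs contact count (reference for the cell-list implementation)
brute_force_contacts <- function(coords, protein_idx, membrane_idx,
                                 cutoff = 0.4, box = NULL, pbc_xy = TRUE) {
  p <- coords[protein_idx, , drop = FALSE]
  m <- coords[membrane_idx, , drop = FALSE]
  dx <- outer(p[, 1], m[, 1], `-`)
  dy <- outer(p[, 2], m[, 2], `-`)
  if (pbc_xy) {
    dx <- dx - box[1] * round(dx / box[1])
    dy <- dy - box[2] * round(dy / box[2])
  }
  dz <- outer(p[, 3], m[, 3], `-`)
  d2 <- dx^2 + dy^2 + dz^2
  list(pair_count = sum(d2 <= cutoff^2), min_distance = sqrt(min(d2)))
}

# Horn's quaternion method for optimal superposition RMSD
quaternion_rmsd <- function(mobile, reference) {
  mc <- sweep(mobile, 2, colMeans(mobile))
  rc <- sweep(reference, 2, colMeans(reference))
  s <- t(mc) %*% rc
  key <- matrix(0, 4, 4)
  key[1, 1] <- s[1, 1] + s[2, 2] + s[3, 3]
  key[1, 2] <- key[2, 1] <- s[2, 3] - s[3, 2]
  key[1, 3] <- key[3, 1] <- s[3, 1] - s[1, 3]
  key[1, 4] <- key[4, 1] <- s[1, 2] - s[2, 1]
  key[2, 2] <- s[1, 1] - s[2, 2] - s[3, 3]
  key[2, 3] <- key[3, 2] <- s[1, 2] + s[2, 1]
  key[2, 4] <- key[4, 2] <- s[1, 3] + s[3, 1]
  key[3, 3] <- -s[1, 1] + s[2, 2] - s[3, 3]
  key[3, 4] <- key[4, 3] <- s[2, 3] + s[3, 2]
  key[4, 4] <- -s[1, 1] - s[2, 2] + s[3, 3]
  lmax <- max(eigen(key, symmetric = TRUE)$values)
  msd <- (sum(mc^2) + sum(rc^2) - 2 * lmax) / nrow(mobile)
  sqrt(max(msd, 0))
}

# rotation matrix about an axis
rot_about <- function(axis, theta) {
  k <- axis / sqrt(sum(axis^2))
  kx <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0),
               3, 3, byrow = TRUE)
  diag(3) + sin(theta) * kx + (1 - cos(theta)) * kx %*% kx
}

# accessible area of sphere 1 (radius r1) partly buried by sphere 2
# (radius r2) at centre distance d: closed-form spherical cap
two_sphere_accessible <- function(r1, r2, d) {
  if (d >= r1 + r2) return(4 * pi * r1^2)
  if (d + r1 <= r2) return(0)
  h <- r1 - (d^2 + r1^2 - r2^2) / (2 * d)
  4 * pi * r1^2 - 2 * pi * r1 * h
}

# random peptide-above-slab configuration for contact oracle checks
random_contact_config <- function(seed, n_p = 60, n_m = 120, box = c(5, 5, 5)) {
  set.seed(seed)
  coords <- rbind(
    cbind(runif(n_p, 0, box[1]), runif(n_p, 0, box[2]), runif(n_p, 0.5, 2.5)),
    cbind(runif(n_m, 0, box[1]), runif(n_m, 0, box[2]), runif(n_m, 0, 1.2))
  )
  atoms <- atom_table(name = rep("C", n_p + n_m),
                      residue_index = c(rep(1:10, length.out = n_p),
                                        10 + seq_len(n_m)),
                      residue_name = c(rep("ALA", n_p), rep("DOPC", n_m)),
                      group = c(rep("protein", n_p), rep("membrane", n_m)))
  list(coords = coords, atoms = atoms, box = box,
       protein_idx = seq_len(n_p), membrane_idx = n_p + seq_len(n_m))
}
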