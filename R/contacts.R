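#' Heavy-atom contact counting between protein and membrane
#'
#' A contact is a (protein heavy atom, membrane heavy atom) pair within
#' the cutoff distance, 0.4 nm by default, under the minimum-image
#' convention in the periodic x,y directions (z is not wrapped; membranes
#' are z-oriented slabs). Distances exactly at the cutoff count as
#' contacts. Pairs are found by spatial binning with a cell size of at
#' least one cutoff, so the result equals an all-pairs scan exactly.
#'
#' @param coords n_atoms x 3 coordinate matrix (nm).
#' @param atoms Atom tibble matching `coords`.
#' @param protein_idx,membrane_idx Row positions of the heavy protein and
#'   membrane selections (see [select_atoms()]); must be disjoint.
#' @param cutoff Contact cutoff, nm (default 0.4).
#' @param box Orthorhombic box lengths; required when `pbc_xy` is TRUE.
#' @param pbc_xy Apply the x,y minimum image.
#' @param min_distance Also report the exact minimum protein-membrane
#'   distance when it exceeds the cutoff (requires a full rescan of
#'   distant pairs; `FALSE` returns `NA` in that case).
#' @return A list with `pair_count`, `min_distance` (nm) and
#'   `residue_contact`, a named logical vector over the protein residues
#'   present in the selection (TRUE when any atom of that residue is in
#'   at least one contact pair).
#' @export
count_contacts <- function(coords, atoms, protein_idx, membrane_idx,
                           cutoff = 0.4, box = NULL, pbc_xy = TRUE,
                           min_distance = TRUE) {
  if (length(protein_idx) == 0 || length(membrane_idx) == 0)
    abort("empty selection")
  if (length(intersect(protein_idx, membrane_idx)) > 0)
    abort("protein and membrane selections overlap")
  if (pbc_xy && is.null(box))
    abort("`box` is required when `pbc_xy` is TRUE")
  stopifnot(cutoff > 0)
  p <- coords[protein_idx, , drop = FALSE]
  m <- coords[membrane_idx, , drop = FALSE]
  res_ids <- atoms$residue_index[protein_idx]
  residues <- sort(unique(res_ids))

  hits <- cell_list_pairs(p, m, cutoff, box, pbc_xy, min_distance)
  touched <- unique(res_ids[hits$i])
  residue_contact <- setNames(residues %in% touched, residues)
  list(pair_count = hits$n_pairs,
       min_distance = hits$min_distance,
       residue_contact = residue_contact)
}

# All (i in p, j in m) pairs with distance <= cutoff, via spatial binning.
# Returns protein-row indices of the contact pairs, the pair count and the
# global minimum distance.
cell_list_pairs <- function(p, m, cutoff, box, pbc_xy, full_min = TRUE) {
  if (pbc_xy) {
    lx <- box[1]; ly <- box[2]
    nxc <- max(1L, floor(lx / cutoff))
    nyc <- max(1L, floor(ly / cutoff))
    cwx <- lx / nxc; cwy <- ly / nyc   # cell widths >= cutoff
    wrap <- function(v, l) v - l * floor(v / l)
    px <- wrap(p[, 1], lx); py <- wrap(p[, 2], ly)
    mx <- wrap(m[, 1], lx); my <- wrap(m[, 2], ly)
  } else {
    x0 <- min(p[, 1], m[, 1]); y0 <- min(p[, 2], m[, 2])
    px <- p[, 1] - x0; py <- p[, 2] - y0
    mx <- m[, 1] - x0; my <- m[, 2] - y0
    cwx <- cwy <- cutoff
    nxc <- max(1L, ceiling((max(px, mx) + 1e-9) / cwx))
    nyc <- max(1L, ceiling((max(py, my) + 1e-9) / cwy))
  }
  z0 <- min(p[, 3], m[, 3])
  pz <- p[, 3] - z0; mz <- m[, 3] - z0
  nzc <- max(1L, ceiling((max(pz, mz) + 1e-9) / cutoff))

  cix <- function(x, w, nmax) pmin(nmax - 1L, pmax(0L, as.integer(floor(x / w))))
  keyof <- function(cx, cy, cz) (cz * nyc + cy) * nxc + cx
  pkey <- keyof(cix(px, cwx, nxc), cix(py, cwy, nyc), cix(pz, cutoff, nzc))
  mkey <- keyof(cix(mx, cwx, nxc), cix(my, cwy, nyc), cix(mz, cutoff, nzc))
  mcells <- split(seq_len(nrow(m)), mkey)

  # membrane candidates for each occupied protein cell: the 27 neighbours
  # (x,y wrapped when periodic, z clamped)
  pcells <- split(seq_len(nrow(p)), pkey)
  n_pairs <- 0L
  min_d2 <- Inf
  hit_i <- integer(0)
  cut2 <- cutoff^2
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  for (keystr in names(pcells)) {
    key <- as.numeric(keystr)
    cz <- key %/% (nxc * nyc); rem <- key %% (nxc * nyc)
    cy <- rem %/% nxc; cx <- rem %% nxc
    ncx <- cx + off[, 1]; ncy <- cy + off[, 2]; ncz <- cz + off[, 3]
    if (pbc_xy) {
      ncx <- (ncx + nxc) %% nxc
      ncy <- (ncy + nyc) %% nyc
    }
    ok <- ncx >= 0 & ncx < nxc & ncy >= 0 & ncy < nyc & ncz >= 0 & ncz < nzc
    nkeys <- unique(keyof(ncx[ok], ncy[ok], ncz[ok]))
    cand <- unlist(mcells[as.character(nkeys)], use.names = FALSE)
    if (is.null(cand) || length(cand) == 0) next
    pi <- pcells[[keystr]]
    dx <- outer(px[pi], mx[cand], `-`)
    dy <- outer(py[pi], my[cand], `-`)
    if (pbc_xy) {
      dx <- dx - lx * round(dx / lx)
      dy <- dy - ly * round(dy / ly)
    }
    dz <- outer(pz[pi], mz[cand], `-`)
    d2 <- dx^2 + dy^2 + dz^2
    within <- d2 <= cut2
    n_pairs <- n_pairs + sum(within)
    if (any(within)) hit_i <- c(hit_i, pi[which(rowSums(within) > 0)])
    min_d2 <- min(min_d2, min(d2))
  }
  # the cell list is complete only within the cutoff: a binned minimum
  # above the cutoff may miss a closer pair in a distant cell, so rescan
  if (!is.finite(min_d2) || min_d2 > cut2) {
    min_d2 <- if (full_min)
      min_dist2_all(px, py, pz, mx, my, mz,
                    if (pbc_xy) c(lx, ly) else NULL)
    else NA_real_
  }
  list(i = unique(hit_i), n_pairs = as.integer(n_pairs),
       min_distance = if (is.na(min_d2)) NA_real_ else sqrt(min_d2))
}

min_dist2_all <- function(px, py, pz, mx, my, mz, lxy) {
  best <- Inf
  chunk <- 2000L
  for (s in seq(1, length(px), by = chunk)) {
    e <- min(s + chunk - 1L, length(px))
    dx <- outer(px[s:e], mx, `-`)
    dy <- outer(py[s:e], my, `-`)
    if (!is.null(lxy)) {
      dx <- dx - lxy[1] * round(dx / lxy[1])
      dy <- dy - lxy[2] * round(dy / lxy[2])
    }
    dz <- outer(pz[s:e], mz, `-`)
    best <- min(best, min(dx^2 + dy^2 + dz^2))
  }
  best
}

#' Per-frame contact series of a trajectory
#'
#' Applies [count_contacts()] to every frame, returning the frame-wise
#' heavy-atom pair count, the minimum protein-membrane distance and the
#' per-residue contact flags.
#'
#' @param trajectory An [mh_trajectory].
#' @param cutoff Contact cutoff, nm.
#' @param pbc_xy Apply the x,y minimum image (requires a box).
#' @param min_distance Report exact minimum distances beyond the cutoff
#'   (slower; `FALSE` leaves them `NA` for kinetics-only workflows).
#' @return An object of class `"mh_contacts"`: list with `frames`
#'   (tibble: `time`, `pair_count`, `min_distance`), `residue_contact`
#'   (logical frame x residue matrix), `dt`, `replica_id`, `condition`.
#' @export
contact_series <- function(trajectory, cutoff = 0.4, pbc_xy = TRUE,
                           min_distance = TRUE) {
  a <- trajectory$atoms
  pidx <- which(a$group == "protein" & a$is_heavy)
  midx <- which(a$group == "membrane" & a$is_heavy)
  nf <- n_frames(trajectory)
  residues <- sort(unique(a$residue_index[pidx]))
  rc <- matrix(FALSE, nf, length(residues),
               dimnames = list(NULL, as.character(residues)))
  pair_count <- integer(nf)
  mind <- numeric(nf)
  for (i in seq_len(nf)) {
    res <- count_contacts(trajectory$coords[, , i], a, pidx, midx,
                          cutoff = cutoff, box = trajectory$box,
                          pbc_xy = pbc_xy, min_distance = min_distance)
    pair_count[i] <- res$pair_count
    mind[i] <- res$min_distance
    rc[i, ] <- res$residue_contact
  }
  structure(list(
    frames = tibble(time = trajectory$times, pair_count = pair_count,
                    min_distance = mind),
    residue_contact = rc,
    dt = trajectory$dt,
    replica_id = trajectory$replica_id,
    condition = trajectory$condition
  ), class = "mh_contacts")
}

#' @export
print.mh_contacts <- function(x, ...) {
  cat(sprintf("<mh_contacts> %d frames, dt = %s ns, median pairs %g\n",
              nrow(x$frames), format(x$dt), median(x$frames$pair_count)))
  invisible(x)
}
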