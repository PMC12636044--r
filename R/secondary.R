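#' Kabsch-Sander alpha-helix assignment
#'
#' Backbone hydrogen bonds are scored with the Kabsch-Sander
#' electrostatic energy
#' `E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)` kcal/mol
#' (distances in angstrom) between the C=O of the acceptor residue and
#' the N-H of the donor; a bond exists when `E < -0.5` kcal/mol. A
#' residue is labelled alpha-helical (`"H"`) when it lies inside a
#' stretch supported by two consecutive i -> i+4 bonds (4-turns at i-1
#' and i mark residues i..i+3). Prolines never donate. Missing amide
#' hydrogens are reconstructed 0.1 nm from N along the preceding
#' residue's O -> C direction; residues whose backbone cannot be
#' completed are excluded with a warning.
#'
#' Only the alpha class is counted as helical by default, matching
#' helicity panels that report "residues in alpha-helical conformation";
#' gmx dssp-style counts that also include 3-10/pi helices will differ
#' slightly.
#'
#' @param structure An [mh_structure] with backbone N, CA, C, O atoms.
#' @param energy_cutoff Hydrogen-bond energy cutoff, kcal/mol (< 0).
#' @return List with `labels` (tibble: `residue_index`, `ss` in
#'   `{"H", "-"}`) and `helical_count` (number of H residues).
#' @export
assign_secondary_structure <- function(structure, energy_cutoff = -0.5) {
  stopifnot(energy_cutoff < 0)
  a <- structure$atoms
  res <- sort(unique(a$residue_index[a$group == "protein"]))
  n <- length(res)
  get <- function(i, nm) {
    j <- which(a$residue_index == res[i] & a$name == nm)
    if (length(j) == 0) return(NULL)
    structure$coords[j[1], ]
  }
  N <- CA <- C <- O <- H <- matrix(NA_real_, n, 3)
  ok <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (nm in c("N", "CA", "C", "O")) {
      v <- get(i, nm)
      if (is.null(v)) { ok[i] <- FALSE; next }
      if (nm == "N") N[i, ] <- v else if (nm == "CA") CA[i, ] <- v
      else if (nm == "C") C[i, ] <- v else O[i, ] <- v
    }
    h <- get(i, "H")
    if (!is.null(h)) H[i, ] <- h
  }
  if (any(!ok))
    warn(sprintf("%d residue(s) with incomplete backbone excluded", sum(!ok)))
  # reconstruct missing amide hydrogens (not for the N-terminus)
  for (i in 2:n) {
    if (any(is.na(H[i, ])) && ok[i] && ok[i - 1]) {
      H[i, ] <- N[i, ] + 0.1 * unitv(C[i - 1, ] - O[i - 1, ])
    }
  }
  resname <- vapply(res, function(r)
    a$residue_name[which(a$residue_index == r)[1]], "")

  # hbond[i, j]: C=O of residue i accepts from N-H of residue j
  q <- 0.084 * 332  # kcal * angstrom / mol
  hbond <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    if (!ok[i]) next
    for (j in seq_len(n)) {
      if (abs(i - j) < 2 || !ok[j]) next
      if (resname[j] == "PRO" || any(is.na(H[j, ]))) next
      r_on <- vnorm(O[i, ] - N[j, ]) * 10
      r_ch <- vnorm(C[i, ] - H[j, ]) * 10
      r_oh <- vnorm(O[i, ] - H[j, ]) * 10
      r_cn <- vnorm(C[i, ] - N[j, ]) * 10
      e <- q * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
      hbond[i, j] <- e < energy_cutoff
    }
  }
  turn4 <- vapply(seq_len(n), function(i)
    i + 4 <= n && hbond[i, i + 4], TRUE)
  helix <- rep(FALSE, n)
  for (i in 2:n) {
    if (i + 3 <= n && turn4[i - 1] && turn4[i]) helix[i:(i + 3)] <- TRUE
  }
  labels <- tibble(residue_index = res, ss = ifelse(helix, "H", "-"))
  list(labels = labels, helical_count = sum(helix))
}

#' Helical residue count per trajectory frame
#'
#' @param trajectory An [mh_trajectory] whose protein atoms include the
#'   backbone.
#' @inheritParams assign_secondary_structure
#' @return Tibble with `time` and `helical_count`.
#' @export
helicity_series <- function(trajectory, energy_cutoff = -0.5) {
  nf <- n_frames(trajectory)
  counts <- integer(nf)
  for (i in seq_len(nf)) {
    counts[i] <- assign_secondary_structure(get_frame(trajectory, i),
                                            energy_cutoff)$helical_count
  }
  tibble(time = trajectory$times, helical_count = counts)
}
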