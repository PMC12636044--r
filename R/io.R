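#' Read a structure file (PDB or GRO)
#'
#' Coordinates are converted to nanometres on read: PDB files store
#' angstroms (divided by 10), GRO files store nm natively. Elements are
#' taken from the PDB element column when present and inferred from the
#' atom name otherwise.
#'
#' @param path Path to the file.
#' @param format `"pdb"` or `"gro"`; guessed from the extension by default.
#' @param lookup Residue-name group lookup (see [assign_groups()]).
#' @return An [mh_structure].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "gro"),
                           lookup = default_group_lookup()) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("pdb", "gro"))
      abort(sprintf("cannot guess format from extension '%s'; pass `format`", ext))
    format <- ext
  }
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  switch(format, pdb = read_structure_pdb(path, lookup),
         gro = read_structure_gro(path, lookup))
}

read_structure_pdb <- function(path, lookup) {
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  atom_lines <- which(rec %in% c("ATOM  ", "HETATM"))
  if (length(atom_lines) == 0) abort(sprintf("no ATOM/HETATM records in %s", path))
  short <- atom_lines[nchar(lines[atom_lines]) < 54]
  if (length(short) > 0)
    abort(sprintf("truncated ATOM record at line %d of %s", short[1], path))
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e)
                    abort(sprintf("failed to parse %s: %s", path, conditionMessage(e))))
  a <- pdb$atom
  elem <- trimws(a$elesy %||% "")
  elem <- ifelse(is.na(elem) | elem == "", NA_character_, toupper(elem))
  name <- trimws(a$elety)
  elem[is.na(elem)] <- infer_element(name[is.na(elem)])
  atoms <- atom_table(name, a$resno, trimws(a$resid), element = elem,
                      lookup = lookup)
  coords <- cbind(a$x, a$y, a$z) / 10  # angstrom -> nm
  mh_structure(atoms, coords)
}

read_structure_gro <- function(path, lookup) {
  lines <- readLines(path)
  if (length(lines) < 3) abort(sprintf("%s is not a valid GRO file (too short)", path))
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n)) abort(sprintf("%s line 2: expected the atom count", path))
  if (length(lines) < 3 + n)
    abort(sprintf("%s: header declares %d atoms but the file is shorter", path, n))
  body <- lines[3:(2 + n)]
  bad <- which(nchar(body) < 44)
  if (length(bad) > 0)
    abort(sprintf("truncated atom line at line %d of %s", bad[1] + 2L, path))
  resno <- as.integer(substr(body, 1, 5))
  resnm <- trimws(substr(body, 6, 10))
  name <- trimws(substr(body, 11, 15))
  x <- as.numeric(substr(body, 21, 28))
  y <- as.numeric(substr(body, 29, 36))
  z <- as.numeric(substr(body, 37, 44))
  if (anyNA(c(resno, x, y, z)))
    abort(sprintf("unparseable numeric field in the atom block of %s", path))
  box <- suppressWarnings(as.numeric(strsplit(trimws(lines[3 + n]), "\\s+")[[1]]))
  box <- if (length(box) >= 3 && !anyNA(box[1:3]) && all(box[1:3] > 0)) box[1:3] else NULL
  atoms <- atom_table(name, resno, resnm, lookup = lookup)
  mh_structure(atoms, cbind(x, y, z), box = box)
}

#' Write / read the package's plain-text trajectory format
#'
#' A simple line-oriented format used for fixtures and result exchange:
#' a header with the atom table, then one row per frame holding the time
#' (ns) followed by the flattened xyz coordinates (nm).
#'
#' @param trajectory An [mh_trajectory].
#' @param path Output path.
#' @return `write_trajectory()` returns `path` invisibly;
#'   `read_internal_trajectory()` returns an [mh_trajectory].
#' @export
write_trajectory <- function(trajectory, path) {
  a <- trajectory$atoms
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# memhairpin trajectory v1", con)
  writeLines(sprintf("# natoms %d", nrow(a)), con)
  writeLines(if (is.null(trajectory$box)) "# box none" else
    sprintf("# box %.9g %.9g %.9g", trajectory$box[1], trajectory$box[2],
            trajectory$box[3]), con)
  writeLines(sprintf("# replica %d condition %s", trajectory$replica_id,
                     format(trajectory$condition)), con)
  writeLines("# atoms name element residue_index residue_name group", con)
  writeLines(sprintf("%s %s %d %s %s", a$name, a$element, a$residue_index,
                     a$residue_name, a$group), con)
  writeLines("# frames", con)
  nf <- n_frames(trajectory)
  for (i in seq_len(nf)) {
    xyz <- t(trajectory$coords[, , i])
    writeLines(paste(format(c(trajectory$times[i], as.vector(xyz)),
                            digits = 12, scientific = FALSE, trim = TRUE),
                     collapse = " "), con)
  }
  invisible(path)
}

#' @param replica_id,condition Metadata overrides; defaults come from the
#'   file header.
#' @rdname write_trajectory
#' @export
read_internal_trajectory <- function(path, replica_id = NULL, condition = NULL) {
  lines <- readLines(path)
  if (length(lines) < 1 || !startsWith(lines[1], "# memhairpin trajectory"))
    abort(sprintf("%s is not a memhairpin trajectory file", path))
  natoms <- as.integer(sub("# natoms ", "", lines[2]))
  boxline <- sub("# box ", "", lines[3])
  box <- if (identical(boxline, "none")) NULL else
    as.numeric(strsplit(boxline, " ")[[1]])
  meta <- strsplit(sub("# replica ", "", lines[4]), " condition ")[[1]]
  atom_rows <- lines[6:(5 + natoms)]
  parts <- strsplit(atom_rows, " ")
  atoms <- atom_table(
    name = vapply(parts, `[`, "", 1),
    residue_index = as.integer(vapply(parts, `[`, "", 3)),
    residue_name = vapply(parts, `[`, "", 4),
    element = vapply(parts, `[`, "", 2),
    group = vapply(parts, `[`, "", 5)
  )
  frame_rows <- lines[(7 + natoms):length(lines)]
  vals <- lapply(strsplit(frame_rows, " "), as.numeric)
  times <- vapply(vals, `[`, 0, 1)
  frames <- lapply(vals, function(v) matrix(v[-1], ncol = 3, byrow = TRUE))
  mh_trajectory(atoms, frames, times, box = box,
                replica_id = replica_id %||% as.integer(meta[1]),
                condition = condition %||% meta[2])
}

#' Read a trajectory from a topology plus one or more frame files
#'
#' @param topology Path to a PDB/GRO file defining the atoms.
#' @param traj Path (or character vector of paths, concatenated in order)
#'   to files in the internal trajectory format.
#' @inheritParams read_internal_trajectory
#' @return An [mh_trajectory]; frame spacing `dt` is estimated from the
#'   stored times, with a warning (and the median spacing) when the times
#'   are not uniform.
#' @export
read_trajectory <- function(topology, traj, replica_id = NULL, condition = NULL) {
  top <- read_structure(topology)
  parts <- lapply(traj, read_internal_trajectory)
  for (p in parts) {
    if (dim(p$coords)[1] != nrow(top$atoms))
      abort(sprintf("trajectory has %d atoms but topology has %d",
                    dim(p$coords)[1], nrow(top$atoms)))
  }
  coords <- do.call(abind3, lapply(parts, function(p) p$coords))
  times <- do.call(c, lapply(parts, function(p) p$times))
  if (any(diff(times) <= 0))
    abort("concatenated frame times are not strictly increasing")
  mh_trajectory(top$atoms, coords, times, box = parts[[1]]$box,
                replica_id = replica_id %||% parts[[1]]$replica_id,
                condition = condition %||% parts[[1]]$condition)
}

abind3 <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])
  array(do.call(c, lapply(xs, as.vector)),
        dim = c(d[1], d[2], sum(vapply(xs, function(x) dim(x)[3], 0L))))
}

#' Atom selection
#'
#' Selectors mirror the analysis needs: heavy protein atoms, heavy membrane
#' atoms, backbone atoms, and residue ranges. Selections compose by
#' intersection when several are given.
#'
#' @param atoms Atom tibble (see [structures]).
#' @param ... Selectors: the strings `"protein_heavy"`, `"membrane_heavy"`,
#'   `"protein"`, `"membrane"`, `"backbone"`, or [residue_range()] /
#'   [residue()] objects.
#' @param include_h Include backbone amide hydrogens in `"backbone"`.
#' @return Integer vector of 1-based row positions into `atoms` (sorted).
#'   An empty selection raises a warning, not an error.
#' @export
#' @examples
#' helix <- build_ideal_helix(10)
#' select_atoms(helix$atoms, "protein_heavy")
select_atoms <- function(atoms, ..., include_h = FALSE) {
  sels <- list(...)
  if (length(sels) == 0) abort("no selector given")
  keep <- seq_len(nrow(atoms))
  for (s in sels) keep <- intersect(keep, eval_selector(atoms, s, include_h))
  keep <- sort(keep)
  if (length(keep) == 0) warn("selection is empty")
  keep
}

eval_selector <- function(atoms, s, include_h) {
  if (inherits(s, "mh_residue_range")) {
    rng <- range(atoms$residue_index)
    if (s$last < rng[1] || s$first > rng[2])
      abort(sprintf("residue range %d-%d is outside the structure (%d-%d)",
                    s$first, s$last, rng[1], rng[2]))
    return(which(atoms$residue_index >= s$first & atoms$residue_index <= s$last))
  }
  if (!is.character(s) || length(s) != 1)
    abort("unknown selector")
  switch(s,
    protein = which(atoms$group == "protein"),
    membrane = which(atoms$group == "membrane"),
    protein_heavy = which(atoms$group == "protein" & atoms$is_heavy),
    membrane_heavy = which(atoms$group == "membrane" & atoms$is_heavy),
    backbone = {
      nm <- c("N", "CA", "C", "O", if (include_h) "H")
      which(atoms$group == "protein" & atoms$name %in% nm)
    },
    abort(sprintf("unknown selector '%s'", s))
  )
}

#' @rdname select_atoms
#' @param first,last,i Residue numbers (author numbering, inclusive).
#' @export
residue_range <- function(first, last) {
  stopifnot(first <= last)
  structure(list(first = as.integer(first), last = as.integer(last)),
            class = "mh_residue_range")
}

#' @rdname select_atoms
#' @export
residue <- function(i) residue_range(i, i)
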