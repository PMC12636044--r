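#' Atom tables, structures and trajectories
#'
#' A *structure* couples an atom table with one set of coordinates; a
#' *trajectory* couples the same atom table with a time-ordered stack of
#' coordinate frames. Coordinates are always stored in nanometres and times
#' in nanoseconds; unit conversion happens only at I/O boundaries.
#'
#' The atom table is a tibble with one row per atom and columns
#' `index` (0-based), `name`, `element`, `residue_index` (author numbering,
#' e.g. 26-156 for the hairpin fragment), `residue_name`, `group`
#' (`"protein"`, `"membrane"`, `"solvent"` or `"other"`) and `is_heavy`
#' (`element != "H"`).
#'
#' @param atoms Atom tibble as described above.
#' @param coords Numeric matrix, one row per atom, columns x, y, z in nm.
#' @param box Optional orthorhombic box lengths `c(lx, ly, lz)` in nm.
#' @return `mh_structure()` returns an object of class `"mh_structure"`;
#'   `mh_trajectory()` an object of class `"mh_trajectory"`.
#' @name structures
NULL

# residue_name -> group lookup; extendable by the caller
default_group_lookup <- function() {
  list(
    membrane = c("POPC", "POPG", "DOPC", "DOPG", "POPE", "DPPC", "CHL1"),
    solvent  = c("SOL", "HOH", "TIP3", "WAT", "K", "CL", "NA", "POT", "CLA",
                 "SOD", "ION")
  )
}

#' Infer the chemical element from an atom name
#'
#' First alphabetic character of the name after stripping digits, with an
#' override table for two-letter elements (useful for PDB files without an
#' element column).
#'
#' @param name Character vector of atom names.
#' @param overrides Named character vector mapping atom names to elements.
#' @return Character vector of element symbols.
#' @export
infer_element <- function(name, overrides = NULL) {
  out <- character(length(name))
  if (!is.null(overrides)) {
    hit <- name %in% names(overrides)
    out[hit] <- unname(overrides[name[hit]])
  }
  todo <- out == ""
  stripped <- gsub("[0-9]", "", name[todo])
  out[todo] <- toupper(substr(stripped, 1, 1))
  out
}

#' Assign protein/membrane/solvent groups from residue names
#'
#' @param residue_name Character vector of residue names.
#' @param lookup List with character vectors `membrane` and `solvent`;
#'   residues in neither are labelled `"protein"`.
#' @return Character vector of group labels.
#' @export
assign_groups <- function(residue_name, lookup = default_group_lookup()) {
  out <- rep("protein", length(residue_name))
  out[toupper(residue_name) %in% toupper(lookup$membrane)] <- "membrane"
  out[toupper(residue_name) %in% toupper(lookup$solvent)] <- "solvent"
  out
}

#' Build an atom tibble
#'
#' @param name,residue_index,residue_name Per-atom vectors.
#' @param element Optional; inferred from `name` when missing.
#' @param group Optional; assigned from `residue_name` when missing.
#' @param lookup Group lookup passed to [assign_groups()].
#' @return Atom tibble (see [structures]).
#' @export
atom_table <- function(name, residue_index, residue_name,
                       element = NULL, group = NULL,
                       lookup = default_group_lookup()) {
  n <- length(name)
  if (length(residue_index) == 1) residue_index <- rep_len(residue_index, n)
  if (length(residue_name) == 1) residue_name <- rep_len(residue_name, n)
  stopifnot(length(residue_index) == n, length(residue_name) == n)
  element <- element %||% infer_element(name)
  group <- group %||% assign_groups(residue_name, lookup)
  tibble(
    index = seq_len(n) - 1L,
    name = as.character(name),
    element = as.character(element),
    residue_index = as.integer(residue_index),
    residue_name = as.character(residue_name),
    group = group,
    is_heavy = element != "H"
  )
}

#' @rdname structures
#' @export
mh_structure <- function(atoms, coords, box = NULL) {
  coords <- as.matrix(coords)
  if (nrow(coords) != nrow(atoms) || ncol(coords) != 3)
    abort("`coords` must be an n_atoms x 3 matrix matching `atoms`.")
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 3 || any(box <= 0))
      abort("`box` must be three positive lengths (nm).")
  }
  structure(list(atoms = as_tibble(atoms), coords = unname(coords), box = box),
            class = "mh_structure")
}

#' @export
print.mh_structure <- function(x, ...) {
  cat(sprintf("<mh_structure> %d atoms, %d residues%s\n",
              nrow(x$atoms), length(unique(x$atoms$residue_index)),
              if (is.null(x$box)) "" else
                sprintf(", box %.2f x %.2f x %.2f nm", x$box[1], x$box[2], x$box[3])))
  invisible(x)
}

#' @param times Frame times in ns, strictly increasing and uniformly spaced.
#' @param frames List of coordinate matrices (one per frame) or a 3-d array
#'   `n_atoms x 3 x n_frames`.
#' @param replica_id Integer replica identifier.
#' @param condition Condition label; conventionally the PG mole fraction
#'   (0, 0.5 or 1) or any string.
#' @param dt_tol Tolerance for uniform spacing (ns).
#' @rdname structures
#' @export
mh_trajectory <- function(atoms, frames, times, box = NULL,
                          replica_id = 1L, condition = NA,
                          dt_tol = 1e-9) {
  if (is.list(frames)) {
    frames <- array(unlist(frames), dim = c(nrow(frames[[1]]), 3, length(frames)))
  }
  stopifnot(length(dim(frames)) == 3)
  if (dim(frames)[1] != nrow(atoms))
    abort("frame atom count does not match the atom table")
  if (dim(frames)[3] != length(times))
    abort("number of frames does not match `times`")
  if (length(times) > 1) {
    d <- diff(times)
    if (any(d <= 0)) abort("frame times must be strictly increasing")
    dt <- d[1]
    if (any(abs(d - dt) > dt_tol)) {
      dt <- median(d)
      warn(sprintf(
        "frame spacing is not uniform within %g ns; dt set to median spacing %g ns",
        dt_tol, dt))
    }
  } else {
    dt <- NA_real_
  }
  structure(list(atoms = as_tibble(atoms), coords = unname(frames),
                 times = as.numeric(times), dt = dt, box = box,
                 replica_id = as.integer(replica_id), condition = condition),
            class = "mh_trajectory")
}

#' @export
print.mh_trajectory <- function(x, ...) {
  cat(sprintf(
    "<mh_trajectory> %d atoms, %d frames, dt = %s ns, replica %d, condition %s\n",
    dim(x$coords)[1], dim(x$coords)[3], format(x$dt), x$replica_id,
    format(x$condition)))
  invisible(x)
}

#' Number of frames / extract one frame as a structure
#' @param trajectory An `mh_trajectory`.
#' @param i Frame number (1-based).
#' @return `n_frames()`: integer; `get_frame()`: an `mh_structure`.
#' @export
n_frames <- function(trajectory) dim(trajectory$coords)[3]

#' @rdname n_frames
#' @export
get_frame <- function(trajectory, i) {
  stopifnot(i >= 1, i <= n_frames(trajectory))
  mh_structure(trajectory$atoms, trajectory$coords[, , i], trajectory$box)
}

#' Residue-span bookkeeping for the hairpin fragment
#'
#' `fragment_spec()` records the residue numbering of the analysed fragment:
#' its first and last residues (defaults 26 and 156), the last residue kept
#' for PCA (default 151, excluding the mobile C-terminal stretch 152-156)
#' and the tryptophan residue monitored by fluorescence (default 71).
#' `residue_span_length()` is the inclusive residue count of a span.
#'
#' @param first_residue,last_residue,pca_last_residue,trp_residue Integers.
#' @return A list of class `"fragment_spec"` with an `n_residues` field.
#' @export
#' @examples
#' fragment_spec()$n_residues   # 131
#' residue_span_length(77, 133) # 57
fragment_spec <- function(first_residue = 26L, last_residue = 156L,
                          pca_last_residue = 151L, trp_residue = 71L) {
  stopifnot(first_residue <= pca_last_residue,
            pca_last_residue <= last_residue)
  structure(list(
    first_residue = as.integer(first_residue),
    last_residue = as.integer(last_residue),
    pca_last_residue = as.integer(pca_last_residue),
    trp_residue = as.integer(trp_residue),
    n_residues = residue_span_length(first_residue, last_residue)
  ), class = "fragment_spec")
}

#' @rdname fragment_spec
#' @param first,last Span endpoints (inclusive).
#' @export
residue_span_length <- function(first, last) {
  stopifnot(last >= first)
  as.integer(last - first + 1L)
}

#' Cumulative simulation time of a replica campaign
#'
#' @param n_replicas Number of independent replicas.
#' @param replica_length_ns Production length of each replica in ns.
#' @return Tibble with the total in ns and in microseconds.
#' @export
#' @examples
#' campaign_time(20, 200) # 4 us per lipid composition
campaign_time <- function(n_replicas, replica_length_ns) {
  stopifnot(n_replicas > 0, replica_length_ns > 0)
  total_ns <- n_replicas * replica_length_ns
  tibble(n_replicas = as.integer(n_replicas),
         replica_length_ns = replica_length_ns,
         total_ns = total_ns,
         total_us = total_ns / 1000)
}
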