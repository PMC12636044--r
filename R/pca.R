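#' Essential-dynamics PCA of fitted backbone coordinates
#'
#' Frames from one condition (by convention the 1:1 PC:PG replicas) are
#' concatenated, least-squares fitted to an iteratively refined mean
#' structure, and the covariance matrix of the fitted backbone
#' coordinates is diagonalised. The mobile C-terminal residues are
#' excluded via the `pca_last_residue` field of the fragment spec
#' (default: residues 26-151 of the 26-156 fragment are used).
#'
#' @param trajectories A single [mh_trajectory] or a list of them (the
#'   training condition's replicas, concatenated).
#' @param fragment A [fragment_spec()]; `NULL` uses all protein residues.
#' @param fit `"iterative"` (fit to the running mean until the mean
#'   structure moves < `tol`) or `"first_frame"` (single pass).
#' @param tol Convergence tolerance on the mean structure RMSD, nm.
#' @param max_iter Iteration cap for the mean refinement.
#' @return An object of class `"mh_pca"`: `mean` (n_atoms x 3), `vectors`
#'   (3N x k, orthonormal columns, sign fixed so the largest-magnitude
#'   component is positive), `values` (eigenvalues, nm^2, descending),
#'   `var_fraction`, `atom_names`, `atom_residues`, `n_frames`,
#'   `degenerate` (TRUE when all frames are identical).
#' @export
fit_pca <- function(trajectories, fragment = NULL, fit = c("iterative",
                    "first_frame"), tol = 1e-6, max_iter = 50L) {
  fit <- match.arg(fit)
  if (inherits(trajectories, "mh_trajectory")) trajectories <- list(trajectories)
  x <- pca_frames(trajectories, fragment)
  nf <- dim(x)[3]
  if (nf < 2) abort("need at least 2 frames")
  natom <- dim(x)[1]
  if (natom < 3) abort("need at least 3 backbone atoms")

  ref <- x[, , 1]
  repeat {
    fitted <- array(NA_real_, dim(x))
    for (i in seq_len(nf)) {
      k <- kabsch_superpose(x[, , i], ref)
      fitted[, , i] <- k$transform(x[, , i])
    }
    newmean <- apply(fitted, c(1, 2), mean)
    if (fit == "first_frame") { ref <- newmean; break }
    shift <- sqrt(mean(rowSums((newmean - ref)^2)))
    ref <- newmean
    max_iter <- max_iter - 1L
    if (shift < tol || max_iter <= 0L) break
  }
  # final pass against the converged mean
  flat <- matrix(NA_real_, nf, 3 * natom)
  for (i in seq_len(nf)) {
    k <- kabsch_superpose(x[, , i], ref)
    flat[i, ] <- as.vector(t(k$transform(x[, , i])))
  }
  mu <- colMeans(flat)
  xc <- sweep(flat, 2, mu)
  degenerate <- max(abs(xc)) < 1e-12
  sv <- svd(xc, nu = 0)
  values <- sv$d^2 / (nf - 1)
  vectors <- sv$v
  # sign convention: largest-magnitude component positive
  for (k in seq_len(ncol(vectors))) {
    j <- which.max(abs(vectors[, k]))
    if (vectors[j, k] < 0) vectors[, k] <- -vectors[, k]
  }
  tot <- sum(values)
  att <- pca_atoms(trajectories[[1]], fragment)
  structure(list(
    mean = matrix(mu, natom, 3, byrow = TRUE),
    vectors = vectors, values = values,
    var_fraction = if (tot > 0) values / tot else rep(NA_real_, length(values)),
    atom_names = att$name, atom_residues = att$residue_index,
    n_frames = nf, degenerate = degenerate
  ), class = "mh_pca")
}

pca_atoms <- function(trajectory, fragment) {
  a <- trajectory$atoms
  idx <- which(a$group == "protein" & a$name %in% c("N", "CA", "C", "O"))
  if (!is.null(fragment)) {
    idx <- idx[a$residue_index[idx] >= fragment$first_residue &
               a$residue_index[idx] <= fragment$pca_last_residue]
  }
  if (length(idx) == 0) abort("no backbone atoms in the requested range")
  list(idx = idx, name = a$name[idx], residue_index = a$residue_index[idx])
}

pca_frames <- function(trajectories, fragment) {
  att <- pca_atoms(trajectories[[1]], fragment)
  parts <- lapply(trajectories, function(tr) {
    a2 <- pca_atoms(tr, fragment)
    if (!identical(a2$name, att$name) ||
        !identical(a2$residue_index, att$residue_index))
      abort("trajectories have incompatible backbone atom subsets")
    tr$coords[a2$idx, , , drop = FALSE]
  })
  do.call(abind3, parts)
}

#' @export
print.mh_pca <- function(x, ...) {
  cat(sprintf("<mh_pca> %d atoms, %d frames; PC1 %.2f%% of variance\n",
              nrow(x$mean), x$n_frames,
              100 * (x$var_fraction[1] %||% NA)))
  invisible(x)
}

#' Project a trajectory onto a principal component
#'
#' Each frame is fitted to the model's mean structure, centred, and
#' dotted with the requested eigenvector. Projections of the training
#' data itself have mean zero and variance equal to the component's
#' eigenvalue.
#'
#' @param trajectory An [mh_trajectory] (or list, concatenated).
#' @param model An `"mh_pca"` from [fit_pca()].
#' @param k Component number (default 1).
#' @param fragment The same [fragment_spec()] used in fitting.
#' @return Tibble with `time` and `projection` (nm).
#' @export
project_pca <- function(trajectory, model, k = 1L, fragment = NULL) {
  if (isTRUE(model$degenerate))
    abort("the model has zero variance; projections are undefined")
  if (inherits(trajectory, "mh_trajectory")) trajectory <- list(trajectory)
  att <- pca_atoms(trajectory[[1]], fragment)
  if (!identical(att$name, model$atom_names) ||
      !identical(att$residue_index, model$atom_residues))
    abort("trajectory atom subset does not match the PCA model")
  x <- pca_frames(trajectory, fragment)
  nf <- dim(x)[3]
  v <- model$vectors[, k]
  mu <- as.vector(t(model$mean))
  proj <- numeric(nf)
  for (i in seq_len(nf)) {
    fit <- kabsch_superpose(x[, , i], model$mean)
    proj[i] <- sum((as.vector(t(fit$transform(x[, , i]))) - mu) * v)
  }
  times <- do.call(c, lapply(trajectory, function(tr) tr$times))
  tibble(time = times, projection = proj)
}

#' @export
tidy.mh_pca <- function(x, ...) {
  tibble(component = seq_along(x$values),
         eigenvalue = x$values,
         var_fraction = x$var_fraction,
         cumulative = cumsum(x$var_fraction))
}

#' @export
glance.mh_pca <- function(x, ...) {
  tibble(n_frames = x$n_frames, n_atoms = nrow(x$mean),
         total_variance = sum(x$values),
         pc1_fraction = x$var_fraction[1])
}
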