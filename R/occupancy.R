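#' Per-residue fractional occupancy with BCa bootstrap intervals
#'
#' The fractional occupancy of a residue is the fraction of analysed
#' frames in which it has at least one heavy-atom contact with the
#' membrane. Each replica contributes one occupancy value per residue;
#' the profile reports the mean over replicas with a bias-corrected
#' accelerated (BCa) bootstrap confidence interval over the replica-level
#' values (1000 resamples, level 0.95 by default). Replicas, not frames,
#' are the resampling unit because frames are autocorrelated.
#'
#' @param contact_list List of `"mh_contacts"` objects, one per replica,
#'   sharing residue indexing.
#' @param n_resamples Bootstrap resamples (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed for the bootstrap.
#' @param pooled Also report the pooled variant (all frames of all
#'   replicas pooled before dividing) in a `p_contact_pooled` column.
#' @return A tibble of class `"mh_occupancy"` with columns `residue`,
#'   `p_contact`, `ci_low`, `ci_high` (all in `[0, 1]`), plus attributes
#'   `n_replicas`, `n_resamples`, `level`.
#' @export
residue_occupancy <- function(contact_list, n_resamples = 1000L,
                              level = 0.95, seed = 1L, pooled = FALSE) {
  stopifnot(length(contact_list) >= 1)
  rc <- lapply(contact_list, function(x) x$residue_contact)
  cols <- colnames(rc[[1]])
  for (m in rc) {
    if (nrow(m) == 0) abort("a replica has zero frames")
    if (!identical(colnames(m), cols))
      abort("replicas do not share residue indexing")
  }
  # replica x residue occupancy matrix
  occ <- do.call(rbind, lapply(rc, colMeans))
  p <- unname(colMeans(occ))
  nrep <- nrow(occ)
  ci <- matrix(NA_real_, length(cols), 2)
  if (nrep >= 2) {
    seeds <- with_seed(seed, sample.int(.Machine$integer.max, length(cols)))
    for (j in seq_along(cols)) {
      ci[j, ] <- bca_bootstrap(occ[, j], n_resamples = n_resamples,
                               level = level, seed = seeds[j])
    }
  } else {
    ci[, 1] <- ci[, 2] <- p
  }
  out <- tibble(residue = as.integer(cols), p_contact = p,
                ci_low = ci[, 1], ci_high = ci[, 2])
  if (pooled) {
    tot <- sum(vapply(rc, nrow, 0L))
    out$p_contact_pooled <-
      unname(colSums(do.call(rbind, lapply(rc, colSums)))) / tot
  }
  structure(out, class = c("mh_occupancy", class(out)),
            n_replicas = nrep, n_resamples = n_resamples, level = level)
}

#' Bias-corrected accelerated (BCa) bootstrap interval for a mean
#'
#' The bias correction `z0` comes from the fraction of bootstrap means
#' below the point estimate; the acceleration `a` from the jackknife
#' skewness. When the acceleration is undefined (all jackknife values
#' equal) the plain percentile interval is returned with a notice.
#' Identical input values give a zero-width interval at that value.
#'
#' @param values Numeric vector (>= 2 values), one per replica.
#' @param n_resamples Number of bootstrap resamples (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed.
#' @return Length-2 numeric vector `c(ci_low, ci_high)`.
#' @export
bca_bootstrap <- function(values, n_resamples = 1000L, level = 0.95,
                          seed = 1L) {
  n <- length(values)
  if (n < 2) abort("need at least 2 values")
  theta <- mean(values)
  if (max(values) - min(values) == 0) return(c(theta, theta))
  boot_means <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_resamples, replace = TRUE),
                  n_resamples, n)
    rowMeans(matrix(values[idx], n_resamples, n))
  })
  alpha <- (1 - level) / 2
  # jackknife acceleration
  jack <- (sum(values) - values) / (n - 1)
  jm <- mean(jack)
  denom <- sum((jm - jack)^2)^1.5
  if (denom == 0) {
    inform("acceleration undefined (all jackknife values equal); using the percentile interval")
    return(unname(quantile(boot_means, c(alpha, 1 - alpha), type = 6)))
  }
  a <- sum((jm - jack)^3) / (6 * denom)
  frac <- mean(boot_means < theta)
  # guard the probit against exact 0/1 fractions
  frac <- min(max(frac, 1 / (n_resamples + 1)), n_resamples / (n_resamples + 1))
  z0 <- qnorm(frac)
  zl <- qnorm(alpha); zu <- qnorm(1 - alpha)
  a1 <- pnorm(z0 + (z0 + zl) / (1 - a * (z0 + zl)))
  a2 <- pnorm(z0 + (z0 + zu) / (1 - a * (z0 + zu)))
  unname(quantile(boot_means, c(a1, a2), type = 6))
}
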