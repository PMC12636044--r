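#' Laurdan generalized polarization
#'
#' `GP = (I440 - I490) / (I440 + I490)` from the emission intensities at
#' 440 and 490 nm. For positive intensities GP lies in `[-1, 1]`;
#' swapping the two intensities flips the sign.
#'
#' @param i440,i490 Fluorescence intensities (vectorised).
#' @return Numeric GP values.
#' @export
#' @examples
#' compute_gp(3, 1)  # 0.5
compute_gp <- function(i440, i490) {
  denom <- i440 + i490
  if (any(denom == 0)) abort("I440 + I490 must be nonzero")
  (i440 - i490) / denom
}

#' GP from an emission spectrum
#'
#' Intensities at 440 and 490 nm are taken from the nearest sampled
#' wavelength within 1 nm, or linearly interpolated otherwise.
#'
#' @param spectrum Tibble with `wavelength` (nm, ascending) and
#'   `intensity`.
#' @return A one-row tibble with `i440`, `i490` and `gp`.
#' @export
spectrum_gp <- function(spectrum) {
  i440 <- intensity_at(spectrum, 440)
  i490 <- intensity_at(spectrum, 490)
  tibble(i440 = i440, i490 = i490, gp = compute_gp(i440, i490))
}

intensity_at <- function(spectrum, wl) {
  w <- spectrum$wavelength
  if (wl < min(w) || wl > max(w))
    abort(sprintf("spectrum does not cover %g nm", wl))
  d <- abs(w - wl)
  j <- which.min(d)
  if (d[j] <= 1) return(spectrum$intensity[j])
  stats::approx(w, spectrum$intensity, xout = wl)$y
}

#' Normalize emission spectra to the apo reference window
#'
#' Every spectrum is divided by the mean intensity of the lipid-free
#' (apo) spectrum over the inclusive window 333-337 nm, so the apo
#' spectrum's own normalized value near 335 nm is close to 1.
#'
#' @param spectra A list of spectra (tibbles with `wavelength`,
#'   `intensity`) or a single spectrum.
#' @param apo The apo spectrum; must cover 333-337 nm.
#' @param window Normalization window in nm (inclusive).
#' @return The spectra with `intensity` rescaled (same shape as input).
#' @export
normalize_emission <- function(spectra, apo, window = c(333, 337)) {
  sel <- apo$wavelength >= window[1] & apo$wavelength <= window[2]
  if (!any(sel)) abort("apo spectrum has no samples in the normalization window")
  ref <- mean(apo$intensity[sel])
  if (ref == 0) abort("apo reference intensity is zero")
  rescale <- function(s) { s$intensity <- s$intensity / ref; s }
  if (is.data.frame(spectra)) rescale(spectra) else lapply(spectra, rescale)
}

#' Fit the Hill binding model to a GP titration curve
#'
#' Fits `GP = GP0 + dGP * P^n / (KD^n + P^n)` by bounded nonlinear least
#' squares (Levenberg-Marquardt), with starting values GP0 = GP at the
#' lowest concentration, dGP = GP range, KD = geometric-median
#' concentration and n = 1, and bounds KD > 0, n in `[0.25, 8]`. The
#' cooperativity n can be fixed instead of floated. Non-convergence or a
#' degenerate curve yields a flagged result, not an error.
#'
#' @param curve Tibble with `concentration_uM` (positive, ascending) and
#'   `gp`; optional `weight` column for replicate-weighted fitting.
#' @param fix_n Fix the cooperativity at this value instead of fitting
#'   it; `NULL` (default) floats n.
#' @param n_bounds Bounds for the cooperativity index.
#' @return An object of class `"mh_hillfit"` with `estimates` (gp0,
#'   delta_gp, kd, n), `std_errors`, `rss`, `converged`,
#'   `low_confidence`, `data` and `fitted(conc)`.
#' @export
fit_hill <- function(curve, fix_n = NULL, n_bounds = c(0.25, 8)) {
  conc <- curve$concentration_uM
  gp <- curve$gp
  if (any(conc <= 0)) abort("concentrations must be strictly positive")
  low_conf <- FALSE
  notes <- character(0)
  if (length(conc) < 5) {
    low_conf <- TRUE
    notes <- c(notes, "fewer than 5 points")
  }
  start <- list(gp0 = gp[which.min(conc)],
                delta_gp = max(gp) - min(gp),
                kd = exp(median(log(conc))),
                n = 1)
  if (start$delta_gp == 0) start$delta_gp <- 1e-3
  lower <- c(gp0 = -Inf, delta_gp = -Inf, kd = 1e-9, n = n_bounds[1])
  upper <- c(gp0 = Inf, delta_gp = Inf, kd = Inf, n = n_bounds[2])
  w <- curve[["weight"]] %||% rep(1, length(conc))

  if (is.null(fix_n)) {
    form <- gp ~ gp0 + delta_gp * conc^n / (kd^n + conc^n)
    st <- start
  } else {
    form <- gp ~ gp0 + delta_gp * conc^fixn / (kd^fixn + conc^fixn)
    st <- start[c("gp0", "delta_gp", "kd")]
    lower <- lower[1:3]; upper <- upper[1:3]
  }
  dat <- data.frame(conc = conc, gp = gp, fixn = fix_n %||% NA_real_)
  # optimizer warnings (e.g. under-determined inputs) become notes on the
  # flagged result rather than console noise
  fit <- withCallingHandlers(
    tryCatch(
      minpack.lm::nlsLM(form, data = dat, start = st, weights = w,
                        lower = unname(lower), upper = unname(upper),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) e),
    warning = function(w) {
      notes <<- c(notes, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (inherits(fit, "error")) {
    est <- c(gp0 = start$gp0, delta_gp = NA, kd = NA,
             n = fix_n %||% NA_real_)
    return(new_hillfit(est, rep(NA_real_, 4), NA_real_, FALSE, TRUE,
                       c(notes, conditionMessage(fit)), curve))
  }
  cf <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) setNames(rep(NA_real_, length(cf)),
                                              names(cf)))
  est <- c(gp0 = unname(cf["gp0"]), delta_gp = unname(cf["delta_gp"]),
           kd = unname(cf["kd"]), n = unname(fix_n %||% cf["n"]))
  ses <- c(gp0 = unname(se["gp0"]), delta_gp = unname(se["delta_gp"]),
           kd = unname(se["kd"]),
           n = if (is.null(fix_n)) unname(se["n"]) else NA_real_)
  rss <- sum(stats::residuals(fit)^2)
  # identifiability checks: a flat curve or a KD the data cannot pin down
  if (is.finite(ses["kd"]) && abs(est["kd"]) > 0 &&
      ses["kd"] / abs(est["kd"]) > 1) {
    low_conf <- TRUE; notes <- c(notes, "KD poorly determined")
  }
  if (abs(est["delta_gp"]) < 1e-8 ||
      (is.finite(ses["delta_gp"]) &&
       abs(est["delta_gp"]) < 2 * ses["delta_gp"])) {
    low_conf <- TRUE; notes <- c(notes, "GP change indistinguishable from zero")
  }
  if (est["kd"] < min(conc) || est["kd"] > max(conc)) {
    low_conf <- TRUE
    notes <- c(notes, "half-saturation outside the measured range")
  }
  new_hillfit(est, ses, rss, TRUE, low_conf, notes, curve)
}

new_hillfit <- function(est, se, rss, converged, low_conf, notes, data) {
  structure(list(
    estimates = est, std_errors = se, rss = rss,
    converged = converged, low_confidence = low_conf, notes = notes,
    data = data,
    fitted = function(conc)
      est["gp0"] + est["delta_gp"] * conc^est["n"] /
        (est["kd"]^est["n"] + conc^est["n"])
  ), class = "mh_hillfit")
}

#' @export
print.mh_hillfit <- function(x, ...) {
  e <- x$estimates; s <- x$std_errors
  cat(sprintf("<mh_hillfit> KD = %.4g +/- %.2g uM, n = %.3g, GP0 = %.3g, dGP = %.3g\n",
              e["kd"], s["kd"], e["n"], e["gp0"], e["delta_gp"]))
  if (!x$converged) cat("  fit did not converge\n")
  if (x$low_confidence)
    cat("  low confidence:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' @export
tidy.mh_hillfit <- function(x, ...) {
  tibble(term = names(x$estimates),
         estimate = unname(x$estimates),
         std.error = unname(x$std_errors))
}

#' @export
glance.mh_hillfit <- function(x, ...) {
  tibble(kd = unname(x$estimates["kd"]),
         n = unname(x$estimates["n"]),
         rss = x$rss, converged = x$converged,
         low_confidence = x$low_confidence,
         nobs = nrow(x$data))
}

#' Normalize a thermal-melt curve to the [-1, 0] convention
#'
#' The ellipticity trace (typically at 222 nm) is mapped affinely so that
#' its value at the low-temperature anchor becomes -1 and at the
#' high-temperature anchor becomes 0 (anchors 20 and 96 degrees C by
#' default). Values at the anchors are interpolated when not sampled
#' exactly.
#'
#' @param curve Tibble with `temperature` (degrees C, ascending) and
#'   `ellipticity`.
#' @param t_low,t_high Anchor temperatures.
#' @return The curve with an added `normalized` column.
#' @export
normalize_melt <- function(curve, t_low = 20, t_high = 96) {
  tt <- curve$temperature
  if (t_low < min(tt) || t_high > max(tt))
    abort("anchor temperatures outside the measured range")
  y_low <- stats::approx(tt, curve$ellipticity, xout = t_low)$y
  y_high <- stats::approx(tt, curve$ellipticity, xout = t_high)$y
  if (y_low == y_high) abort("equal anchor values; normalization undefined")
  curve$normalized <- (curve$ellipticity - y_high) / (y_high - y_low)
  curve
}
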