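#' State-conditioned distributions of a structural observable
#'
#' Frames are split by the bound/unbound labels of a state series and
#' each partition is summarised by a Gaussian KDE with the Scott
#' bandwidth `sd * n^(-1/5)` (optionally multiplied, e.g. by 2 for
#' helicity counts), normalised to unit area. An empty partition yields
#' no KDE and is flagged.
#'
#' @param series Tibble with `time` and one value column (the observable,
#'   e.g. helicity or SASA per frame), or a numeric vector aligned with
#'   the states.
#' @param states An `"mh_states"` object sharing the time axis.
#' @param value Name of the value column when `series` is a tibble.
#' @param bw_multiplier Bandwidth multiplier (default 1; use 2 for
#'   helicity-count violins).
#' @param n_grid KDE grid size.
#' @return An object of class `"mh_conditional"`: list with `data`
#'   (tibble: `time`, `value`, `state`), `kde` (tibble: `state`, `value`,
#'   `density`; absent states missing), `empty` (character vector of
#'   states with no frames) and per-state summary `stats`.
#' @export
conditional_distributions <- function(series, states, value = NULL,
                                      bw_multiplier = 1, n_grid = 512L) {
  stopifnot(bw_multiplier > 0)
  if (is.numeric(series)) {
    vals <- series
    times <- states$frames$time
    if (length(vals) != nrow(states$frames))
      abort("series length does not match the state series")
  } else {
    vc <- value %||% setdiff(names(series), "time")[1]
    vals <- series[[vc]]
    times <- series$time
    if (!isTRUE(all.equal(times, states$frames$time)))
      abort("series and states do not share a time axis")
  }
  lab <- states$frames$state
  data <- tibble(time = times, value = vals, state = lab)
  kdes <- list(); empty <- character(0); stats <- list()
  for (s in c("bound", "unbound")) {
    x <- vals[lab == s]
    if (length(x) == 0) { empty <- c(empty, s); next }
    stats[[s]] <- tibble(state = s, n = length(x), mean = mean(x),
                         sd = if (length(x) > 1) sd(x) else NA_real_)
    if (length(x) < 2 || sd(x) == 0) next
    bw <- scott_bandwidth(x) * bw_multiplier
    d <- density(x, bw = bw, n = n_grid,
                 from = min(x) - 3 * bw, to = max(x) + 3 * bw)
    kdes[[s]] <- tibble(state = s, value = d$x, density = d$y)
  }
  structure(list(data = data,
                 kde = if (length(kdes)) bind_rows(kdes) else NULL,
                 empty = empty,
                 stats = if (length(stats)) bind_rows(stats) else NULL),
            class = "mh_conditional")
}

#' Scott's bandwidth rule
#'
#' `sd(x) * n^(-1/5)`, the rule used by scipy/seaborn KDEs (base R's
#' `bw.nrd` includes an extra 1.06 factor).
#'
#' @param x Numeric vector.
#' @return Bandwidth on the scale of `x`.
#' @export
scott_bandwidth <- function(x) sd(x) * length(x)^(-1 / 5)

#' @export
print.mh_conditional <- function(x, ...) {
  cat("<mh_conditional>\n")
  if (!is.null(x$stats)) print(x$stats)
  if (length(x$empty)) cat("empty partitions:", paste(x$empty, collapse = ", "), "\n")
  invisible(x)
}
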