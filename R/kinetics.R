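#' Sustained-contact binding/unbinding state machine
#'
#' Binding is declared when the frame-wise heavy-atom contact count stays
#' at or above `min_contacts` for at least `bind_dwell` ns (default: >= 5
#' contacts maintained for >= 5 ns); the bound state starts at the first
#' frame of the qualifying run. After a binding event, a run of frames
#' below `min_contacts` lasting at least `unbind_dwell` ns (default 0.5)
#' switches the state back to unbound at that run's first frame.
#' Unbinding is only considered after a binding event. A run of k frames
#' represents `k * dt` ns of dwell time.
#'
#' @param series An `"mh_contacts"` object from [contact_series()], or a
#'   tibble with columns `time` and `count` (or `pair_count`) carrying a
#'   `dt` attribute.
#' @param min_contacts Contact threshold (default 5).
#' @param bind_dwell Minimum sustained-contact duration, ns (default 5).
#' @param unbind_dwell Minimum low-contact duration, ns (default 0.5).
#' @return An object of class `"mh_states"`: list with `frames` (tibble:
#'   `time`, `count`, `state`), `first_binding_time` (ns, `NA` when no
#'   event), `events` (tibble: `state`, `start`, `end`) and `dt`.
#' @export
classify_states <- function(series, min_contacts = 5L, bind_dwell = 5,
                            unbind_dwell = 0.5) {
  stopifnot(min_contacts > 0, bind_dwell > 0, unbind_dwell > 0)
  if (inherits(series, "mh_contacts")) {
    times <- series$frames$time
    counts <- series$frames$pair_count
    dt <- series$dt
  } else {
    times <- series$time
    counts <- series[["count"]] %||% series[["pair_count"]]
    dt <- attr(series, "dt") %||% (if (length(times) > 1) diff(times)[1] else NA)
  }
  if (is.na(dt) || is.null(dt)) abort("frame spacing dt is unknown")
  n <- length(counts)
  high <- counts >= min_contacts
  r <- rle(high)
  run_len <- r$lengths
  run_start <- cumsum(c(1L, run_len))[seq_along(run_len)]

  state <- rep("unbound", n)
  bound <- FALSE
  first_bind <- NA_real_
  cur <- 1L
  for (k in seq_along(run_len)) {
    s <- run_start[k]; e <- s + run_len[k] - 1L
    dur <- run_len[k] * dt
    if (!bound) {
      if (r$values[k] && dur >= bind_dwell) {
        bound <- TRUE
        if (is.na(first_bind)) first_bind <- times[s]
        state[s:n] <- "bound"
      }
    } else {
      if (!r$values[k] && dur >= unbind_dwell) {
        bound <- FALSE
        state[s:n] <- "unbound"
      }
    }
  }
  ev <- rle(state)
  ends <- cumsum(ev$lengths)
  starts <- c(1L, head(ends, -1) + 1L)
  events <- tibble(state = ev$values,
                   start = times[starts],
                   end = times[ends] + dt)
  structure(list(
    frames = tibble(time = times, count = counts, state = state),
    first_binding_time = first_bind,
    events = events,
    dt = dt
  ), class = "mh_states")
}

#' @export
print.mh_states <- function(x, ...) {
  fb <- if (is.na(x$first_binding_time)) "none" else
    sprintf("%.3g ns", x$first_binding_time)
  cat(sprintf("<mh_states> %d frames, first binding: %s, %d events\n",
              nrow(x$frames), fb, nrow(x$events)))
  invisible(x)
}

#' Cumulative distribution of first-binding times across replicas
#'
#' @param state_list List of `"mh_states"` objects (or a numeric vector of
#'   first-binding times with `NA` for replicas that never bind).
#' @param n_replicas Total number of replicas (the plateau ceiling).
#' @return An object of class `"mh_binding_cdf"`: tibble with `time` (ns)
#'   and `cumulative` (number of replicas bound by that time), plus
#'   attributes `n_replicas` and `n_bound`. The step function is
#'   non-decreasing and plateaus at the number of replicas that ever bind.
#' @export
first_binding_cdf <- function(state_list, n_replicas = length(state_list)) {
  times <- if (is.numeric(state_list)) state_list else
    vapply(state_list, function(s) s$first_binding_time, 0.0)
  times <- times[!is.na(times)]
  if (length(times) > n_replicas)
    abort("more binding events than replicas")
  st <- sort(times)
  out <- tibble(time = c(0, st),
                cumulative = c(sum(st <= 0), seq_along(st)))
  if (length(st) > 0 && st[1] <= 0) out <- out[-1, ]
  out <- out[!duplicated(out$time, fromLast = TRUE), ]
  structure(out, class = c("mh_binding_cdf", class(out)),
            n_replicas = as.integer(n_replicas),
            n_bound = length(st))
}
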