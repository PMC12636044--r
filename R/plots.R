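#' Plot methods
#'
#' `autoplot()` methods give quick ggplot2 views of the main result
#' types: the first-binding CDF, the per-residue occupancy profile with
#' its bootstrap band, state-conditioned KDEs, and Hill-fit curves.
#'
#' @param object A result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name plots
NULL

#' @rdname plots
#' @export
autoplot.mh_binding_cdf <- function(object, ...) {
  ggplot(object, aes(x = .data$time, y = .data$cumulative)) +
    geom_step() +
    labs(x = "first binding time (ns)",
         y = sprintf("replicas bound (of %d)", attr(object, "n_replicas"))) +
    theme_minimal()
}

#' @rdname plots
#' @export
autoplot.mh_occupancy <- function(object, ...) {
  ggplot(object, aes(x = .data$residue, y = .data$p_contact)) +
    geom_ribbon(aes(ymin = .data$ci_low, ymax = .data$ci_high),
                fill = "grey70", alpha = 0.6) +
    geom_line() +
    labs(x = "residue", y = expression(P[contact])) +
    theme_minimal()
}

#' @rdname plots
#' @export
autoplot.mh_conditional <- function(object, ...) {
  if (is.null(object$kde)) abort("no KDE available to plot")
  ggplot(object$kde, aes(x = .data$value, y = .data$density,
                         linetype = .data$state)) +
    geom_line() +
    labs(x = "value", y = "density", linetype = "state") +
    theme_minimal()
}

#' @rdname plots
#' @export
autoplot.mh_hillfit <- function(object, ...) {
  conc <- object$data$concentration_uM
  grid <- exp(seq(log(min(conc)), log(max(conc)), length.out = 200))
  fitted <- tibble(concentration_uM = grid, gp = object$fitted(grid))
  ggplot(object$data, aes(x = .data$concentration_uM, y = .data$gp)) +
    geom_point() +
    geom_line(data = fitted) +
    ggplot2::scale_x_log10() +
    labs(x = "[P] (uM)", y = "GP") +
    theme_minimal()
}
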