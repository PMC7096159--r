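# ggplot2 displays for the main result types

#' Plot a force-extension trace
#'
#' @param object An [fe_trace()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fe_trace <- function(object, ...) {
  ggplot(object, aes(x = .data$extension_nm, y = .data$force_pN)) +
    geom_line(linewidth = 0.3, colour = "grey30") +
    labs(x = "extension (nm)", y = "force (pN)") +
    theme_minimal()
}

#' Plot a Bell-Evans mixture fit over the force histogram
#'
#' @param object A `pg_mixture_fit`.
#' @param forces The rupture forces the fit was computed from (pN).
#' @param binwidth Histogram bin width, pN.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pg_mixture_fit <- function(object, forces, binwidth = 20, ...) {
  grid <- tibble(force = seq(0, max(forces) * 1.1, length.out = 400))
  grid$density <- mixture_density(object, grid$force)
  ggplot(tibble(force = forces), aes(x = .data$force)) +
    geom_histogram(aes(y = after_stat(density)), binwidth = binwidth,
                   fill = "grey80", colour = "grey50") +
    geom_line(data = grid, aes(y = .data$density), colour = "firebrick") +
    geom_vline(xintercept = object$components$modal_force,
               linetype = "dashed", colour = "firebrick") +
    labs(x = "rupture force (pN)", y = "density") +
    theme_minimal()
}

#' Plot a dynamic force spectrum
#'
#' Most probable rupture force versus log loading rate with the fitted
#' Bell-Evans line.
#'
#' @param object A `pg_force_spectrum`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pg_force_spectrum <- function(object, ...) {
  p <- ggplot(object$points,
              aes(x = log(.data$loading_rate), y = .data$modal_force)) +
    geom_point() +
    labs(x = "ln loading rate (pN/s)", y = "most probable force (pN)") +
    theme_minimal()
  if (!object$flagged) {
    p <- p + ggplot2::geom_abline(slope = object$slope,
                                  intercept = object$intercept,
                                  colour = "firebrick")
  }
  p
}

#' Plot a per-frame trajectory metric
#'
#' @param object A `pg_metric_series`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pg_metric_series <- function(object, ...) {
  ggplot(object, aes(x = .data$time_ns, y = .data$value)) +
    geom_line(colour = "grey30") +
    labs(x = "time (ns)",
         y = sprintf("%s (%s)", attr(object, "metric_kind"),
                     attr(object, "units"))) +
    theme_minimal()
}

#' Plot unloaded/loaded window histograms
#'
#' @param object A `pg_window_hist`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pg_window_hist <- function(object, ...) {
  df <- bind_rows(mutate(object$unloaded, condition = "unloaded"),
                  mutate(object$loaded, condition = "loaded"))
  ggplot(df, aes(x = .data$mid, y = .data$count,
                 fill = .data$condition)) +
    ggplot2::geom_col(position = "identity", alpha = 0.6) +
    ggplot2::scale_fill_manual(values = c(unloaded = "grey60",
                                          loaded = "firebrick")) +
    labs(x = sprintf("metric (%s)", object$units %||% ""), y = "count") +
    theme_minimal()
}
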