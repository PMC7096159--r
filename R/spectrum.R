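# --- dynamic force spectrum -------------------------------------------------

#' Fit a dynamic force spectrum to rupture events
#'
#' Bins rupture events by the logarithm of their loading rate, fits a
#' single-component Bell-Evans distribution per bin to obtain the most
#' probable rupture force, and fits a straight line F* versus ln(r), the
#' standard Bell-Evans dynamic force spectrum. The barrier parameters
#' follow from the line: x_dagger = kBT / slope and
#' k0 = (x_dagger r0 / kBT) exp(-intercept x_dagger / kBT) at the
#' reference rate r0 = 1 pN/s.
#'
#' @param events Data frame with columns `rupture_force` (pN) and
#'   `loading_rate` (pN/s); e.g. the rupture table of [pipeline_smfs()].
#' @param n_rate_bins Number of log-spaced loading-rate bins. Default 5.
#' @param min_per_bin Bins with fewer events are dropped. Default 50.
#' @param kBT Thermal energy, pN nm.
#' @param seed Passed to the per-bin fits.
#' @return Object of class `pg_force_spectrum`: `points` (tibble of
#'   loading_rate, modal_force, n per bin), `slope` (pN per ln(pN/s)),
#'   `intercept` (pN), `x_dagger` (nm), `k0` (1/s), `flagged`
#'   (insufficient rate span).
#' @export
dynamic_force_spectrum <- function(events, n_rate_bins = 5,
                                   min_per_bin = 50, kBT = KBT_300K,
                                   seed = 1) {
  events <- as_tibble(events)
  pg_assert(all(c("rupture_force", "loading_rate") %in% names(events)),
            "events needs rupture_force and loading_rate columns")
  events <- filter(events, is.finite(.data$rupture_force),
                   is.finite(.data$loading_rate), .data$loading_rate > 0)
  lr <- log(events$loading_rate)
  edges <- seq(min(lr), max(lr), length.out = n_rate_bins + 1)
  bin <- findInterval(lr, edges, rightmost.closed = TRUE)
  pts <- list()
  for (b in sort(unique(bin))) {
    idx <- bin == b
    if (sum(idx) < min_per_bin) next
    r_bin <- median(events$loading_rate[idx])
    fit <- fit_mixture(events$rupture_force[idx], r_bin, n_components = 1,
                       seed = seed, kBT = kBT)
    pts[[length(pts) + 1L]] <- tibble(loading_rate = r_bin,
                                      modal_force = fit$components$modal_force,
                                      n = sum(idx))
  }
  pts <- if (length(pts)) bind_rows(pts) else
    tibble(loading_rate = numeric(), modal_force = numeric(), n = integer())
  if (nrow(pts) < 3) {
    return(structure(list(points = pts, slope = NA_real_,
                          intercept = NA_real_, x_dagger = NA_real_,
                          k0 = NA_real_, kBT = kBT, flagged = TRUE),
                     class = "pg_force_spectrum"))
  }
  line <- lm(modal_force ~ log(loading_rate), data = pts)
  slope <- unname(coef(line)[2])
  intercept <- unname(coef(line)[1])
  x_dagger <- if (slope > 0) kBT / slope else NA_real_
  k0 <- if (is.finite(x_dagger))
    (x_dagger / kBT) * exp(-intercept * x_dagger / kBT) else NA_real_
  structure(list(points = pts, slope = slope, intercept = intercept,
                 x_dagger = x_dagger, k0 = k0, kBT = kBT, flagged = FALSE),
            class = "pg_force_spectrum")
}

#' @export
print.pg_force_spectrum <- function(x, ...) {
  cat(sprintf("<pg_force_spectrum> %d rate bins%s\n", nrow(x$points),
              if (x$flagged) " [flagged: insufficient rate span]" else ""))
  if (!x$flagged) {
    cat(sprintf("  slope %.3g pN per ln(pN/s), intercept %.3g pN\n",
                x$slope, x$intercept))
    cat(sprintf("  x_dagger = %.4g nm, k0 = %.4g 1/s\n", x$x_dagger, x$k0))
  }
  invisible(x)
}

#' @export
#' @rdname dynamic_force_spectrum
#' @param x A `pg_force_spectrum`.
#' @param ... Unused.
tidy.pg_force_spectrum <- function(x, ...) x$points

#' @export
#' @rdname dynamic_force_spectrum
glance.pg_force_spectrum <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, x_dagger = x$x_dagger,
         k0 = x$k0, n_bins = nrow(x$points), flagged = x$flagged)
}
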