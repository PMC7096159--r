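#' Bell-Evans bond kinetics parameters
#'
#' Parameters of thermally activated bond rupture under force: the bond
#' escapes over a single barrier at force-dependent rate
#' \eqn{k(F) = k_0 \exp(F x^\ddagger / k_BT)}. Under a constant force
#' loading rate this yields the classic Bell-Evans rupture-force
#' distribution.
#'
#' @param k0 Intrinsic (zero-force) off-rate, 1/s; > 0.
#' @param x_dagger Distance to the transition state, nm; > 0.
#' @param kBT Thermal energy, pN nm; default 4.14 (300 K).
#' @return An object of class `bell_evans_params`.
#' @examples
#' bell_evans_params(k0 = 1e-3, x_dagger = 0.4)
#' @export
bell_evans_params <- function(k0, x_dagger, kBT = KBT_300K) {
  pg_assert(is.numeric(k0) && length(k0) == 1 && k0 > 0, "k0 must be a single positive number")
  pg_assert(is.numeric(x_dagger) && length(x_dagger) == 1 && x_dagger > 0,
            "x_dagger must be a single positive number")
  pg_assert(is.numeric(kBT) && length(kBT) == 1 && kBT > 0, "kBT must be a single positive number")
  structure(list(k0 = k0, x_dagger = x_dagger, kBT = kBT),
            class = "bell_evans_params")
}

#' @export
print.bell_evans_params <- function(x, ...) {
  cat(sprintf("<bell_evans_params> k0 = %.4g 1/s, x_dagger = %.4g nm, kBT = %.3g pN nm\n",
              x$k0, x$x_dagger, x$kBT))
  invisible(x)
}

as_bell_evans <- function(x) {
  if (inherits(x, "bell_evans_params")) return(x)
  pg_assert(is.list(x) && all(c("k0", "x_dagger") %in% names(x)),
            "expected a bell_evans_params object or a list with k0 and x_dagger")
  bell_evans_params(x$k0, x$x_dagger, x$kBT %||% KBT_300K)
}

#' Bell-Evans rupture-force density under a constant loading rate
#'
#' Probability density of the rupture force for a bond loaded at a constant
#' rate `loading_rate` (pN/s):
#' \deqn{p(F) = \frac{k_0}{r} e^{F x^\ddagger / k_BT}
#'   \exp\!\left[\frac{k_0 k_BT}{x^\ddagger r}\left(1 - e^{F x^\ddagger / k_BT}\right)\right].}
#'
#' @param force Force values (pN), nonnegative; vectorised.
#' @param params A [bell_evans_params()] object.
#' @param loading_rate Constant force loading rate (pN/s), > 0.
#' @param log Return the log density?
#' @return Density in 1/pN (or its log).
#' @export
bell_evans_pdf <- function(force, params, loading_rate, log = FALSE) {
  params <- as_bell_evans(params)
  pg_assert(length(loading_rate) == 1 && loading_rate > 0,
            "loading_rate must be a single positive number")
  pg_assert(all(force >= 0), "force must be nonnegative")
  b <- params$x_dagger / params$kBT
  lk <- log(params$k0) - log(loading_rate) + b * force
  ll <- lk + (params$k0 / (b * loading_rate)) * (1 - exp(b * force))
  if (log) ll else exp(ll)
}

#' Bell-Evans rupture-force cumulative distribution
#'
#' @inheritParams bell_evans_pdf
#' @return P(rupture force <= `force`).
#' @export
bell_evans_cdf <- function(force, params, loading_rate) {
  params <- as_bell_evans(params)
  pg_assert(length(loading_rate) == 1 && loading_rate > 0,
            "loading_rate must be a single positive number")
  b <- params$x_dagger / params$kBT
  1 - exp((params$k0 / (b * loading_rate)) * (1 - exp(b * force)))
}

#' Most probable rupture force at a given loading rate
#'
#' The mode of the Bell-Evans rupture-force distribution,
#' \eqn{F^* = (k_BT/x^\ddagger)\,\ln(x^\ddagger r / k_0 k_BT)}. When the
#' loading rate is too low (\eqn{x^\ddagger r \le k_0 k_BT}) the
#' distribution is monotonically decreasing and the mode sits at zero
#' force; the returned value then is 0 and carries attribute
#' `at_boundary = TRUE`.
#'
#' @inheritParams bell_evans_pdf
#' @return Modal force in pN.
#' @export
modal_force <- function(params, loading_rate) {
  params <- as_bell_evans(params)
  pg_assert(all(loading_rate > 0), "loading_rate must be positive")
  arg <- params$x_dagger * loading_rate / (params$k0 * params$kBT)
  f <- (params$kBT / params$x_dagger) * log(pmax(arg, 1))
  attr(f, "at_boundary") <- arg <= 1
  f
}

#' Sample rupture forces under a constant loading rate
#'
#' Draws i.i.d. rupture forces from the Bell-Evans distribution by inverse
#' transform sampling,
#' \eqn{F = (k_BT/x^\ddagger)\ln[1 - (x^\ddagger r / k_0 k_BT)\ln u]},
#' with u uniform on (0,1).
#'
#' @inheritParams bell_evans_pdf
#' @param n Number of draws.
#' @param seed Optional integer seed for reproducibility.
#' @return Numeric vector of n forces (pN).
#' @examples
#' f <- sample_rupture_forces(bell_evans_params(1e-3, 0.4), 1e4, n = 5, seed = 1)
#' @export
sample_rupture_forces <- function(params, loading_rate, n, seed = NULL) {
  params <- as_bell_evans(params)
  pg_assert(length(loading_rate) == 1 && loading_rate > 0,
            "loading_rate must be a single positive number")
  pg_assert(n >= 1, "n must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  u <- runif(n)
  b <- params$x_dagger / params$kBT
  (1 / b) * log(1 - (b * loading_rate / params$k0) * log(u))
}
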