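#' Worm-like chain force at a given extension
#'
#' Marko-Siggia interpolated worm-like chain (WLC): the restoring force of a
#' semiflexible polymer of contour length `Lc` and persistence length `Lp`
#' held at end-to-end extension `x`,
#' \deqn{F(x) = \frac{k_BT}{L_p}\left[\frac{1}{4(1-s)^2} - \frac14 + s\right],
#'   \quad s = x/L_c.}
#' The force is zero at zero extension, strictly increasing in `x`, and
#' diverges as `x` approaches `Lc`.
#'
#' @param extension Extension (nm); vectorised. Must satisfy
#'   `0 <= extension < Lc`.
#' @param Lc Contour length (nm), > 0.
#' @param Lp Persistence length (nm), > 0.
#' @param kBT Thermal energy (pN nm); default 4.14 (300 K).
#' @return Force in pN, same length as `extension`.
#' @examples
#' wlc_force(20, Lc = 40, Lp = 0.4)
#' @export
wlc_force <- function(extension, Lc, Lp, kBT = KBT_300K) {
  pg_assert(all(Lc > 0) && all(Lp > 0) && kBT > 0,
            "Lc, Lp and kBT must be strictly positive")
  pg_assert(all(extension >= 0), "extension must be nonnegative")
  if (any(extension >= Lc)) {
    abort("extension must be strictly below the contour length Lc",
          class = "pullgeom_domain_error")
  }
  s <- extension / Lc
  (kBT / Lp) * (1 / (4 * (1 - s)^2) - 0.25 + s)
}

# Inverse of the Marko-Siggia form in fractional extension: given the
# dimensionless force a = F * Lp / kBT, return s in [0, 1) with
# f(s) = 1/(4(1-s)^2) - 1/4 + s = a. f is increasing and convex on (0, 1),
# so Newton started where f(s0) >= a (the high-force asymptote
# s ~ 1 - 1/(2 sqrt(a)), shifted to cover small a) converges monotonically
# from above; ~8 iterations reach machine precision.
wlc_fractional_extension <- function(a) {
  pg_assert(all(a >= 0), "dimensionless force must be nonnegative")
  s <- 1 - 1 / (2 * sqrt(a + 0.8))
  for (i in seq_len(40)) {
    u <- 1 - s
    f <- 1 / (4 * u^2) - 0.25 + s
    fp <- 1 / (2 * u^3) + 1
    step <- (f - a) / fp
    s <- s - step
    if (max(abs(step)) < 1e-15) break
  }
  pmin(pmax(s, 0), 1 - 1e-16)
}

#' Worm-like chain extension at a given force
#'
#' Inverse of [wlc_force()]: the extension of a WLC of contour length `Lc`
#' under tension `force`. Solved by bisection in fractional extension;
#' exact to machine precision.
#'
#' @param force Force (pN); vectorised, nonnegative.
#' @inheritParams wlc_force
#' @return Extension in nm.
#' @export
wlc_extension <- function(force, Lc, Lp, kBT = KBT_300K) {
  pg_assert(all(Lc > 0) && all(Lp > 0) && kBT > 0,
            "Lc, Lp and kBT must be strictly positive")
  pg_assert(all(force >= 0), "force must be nonnegative")
  Lc * wlc_fractional_extension(force * Lp / kBT)
}

# Derivative dF/dx of the Marko-Siggia force at fractional extension s;
# used by the Newton force-balance solver in simulate_trace().
wlc_force_deriv_s <- function(s, Lc, Lp, kBT) {
  (kBT / Lp) * (1 / (2 * (1 - s)^3) + 1) / Lc
}
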