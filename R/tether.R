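#' Tether model for simulated force-extension cycles
#'
#' Describes the mechanical tether between cantilever tip and surface: the
#' cantilever spring, one or more serial worm-like-chain segments (PEG
#' linkers plus folded protein), and an ordered list of fingerprint-domain
#' unfolding substeps, each of which adds contour length when it fires.
#'
#' Defaults emulate a maleimide-PEG(5000) linker in series with a ddFLN4
#' fingerprint domain: a 40 nm / 0.38 nm WLC segment and two unfolding
#' substeps releasing 15 and 16 nm of contour length. The PEG contour and
#' persistence lengths are configuration, not constants: adjust them to the
#' construct at hand.
#'
#' @param cantilever_stiffness Cantilever spring constant, N/m. Default 0.15.
#' @param segments Data frame with columns `Lc` (nm) and `Lp` (nm), one row
#'   per serial WLC segment.
#' @param unfolding_steps Data frame with columns `delta_Lc` (nm), `k0`
#'   (1/s), `x_dagger` (nm) and optionally `Lp` (nm): ordered fingerprint
#'   unfolding substeps.
#' @param kBT Thermal energy, pN nm.
#' @return Object of class `tether_model`.
#' @export
tether_model <- function(cantilever_stiffness = 0.15,
                         segments = data.frame(Lc = 40, Lp = 0.38),
                         unfolding_steps = data.frame(
                           delta_Lc = c(15, 16),
                           k0 = c(0.05, 0.05),
                           x_dagger = c(0.45, 0.45)
                         ),
                         kBT = KBT_300K) {
  pg_assert(cantilever_stiffness > 0, "cantilever_stiffness must be positive")
  pg_assert(kBT > 0, "kBT must be positive")
  segments <- as.data.frame(segments)
  pg_assert(all(c("Lc", "Lp") %in% names(segments)) &&
              all(segments$Lc > 0) && all(segments$Lp > 0),
            "segments needs positive Lc and Lp columns")
  unfolding_steps <- as.data.frame(unfolding_steps)
  if (nrow(unfolding_steps)) {
    pg_assert(all(c("delta_Lc", "k0", "x_dagger") %in% names(unfolding_steps)),
              "unfolding_steps needs delta_Lc, k0, x_dagger columns")
    pg_assert(all(unfolding_steps$delta_Lc > 0) &&
                all(unfolding_steps$k0 > 0) &&
                all(unfolding_steps$x_dagger > 0),
              "unfolding step parameters must be strictly positive")
    if (is.null(unfolding_steps$Lp)) unfolding_steps$Lp <- segments$Lp[1]
  }
  structure(list(cantilever_stiffness = cantilever_stiffness,
                 segments = segments,
                 unfolding_steps = unfolding_steps,
                 kBT = kBT),
            class = "tether_model")
}

#' Acquisition protocol for simulated retraction cycles
#'
#' Sampling and retraction settings of the emulated AFM measurement. The
#' defaults follow a constant-velocity retraction at 800 nm/s sampled at
#' 12,000 Hz over 350 nm.
#'
#' @param retract_velocity Retraction velocity, nm/s.
#' @param sampling_rate Channel sampling rate, Hz.
#' @param retract_distance Total retraction distance, nm.
#' @param force_noise_sd Gaussian force noise standard deviation, pN.
#'   Default 3 pN, typical of a small (0.15 N/m) cantilever at this
#'   bandwidth.
#' @param seed Optional integer seed.
#' @return Object of class `acquisition_protocol`.
#' @export
acquisition_protocol <- function(retract_velocity = 800,
                                 sampling_rate = 12000,
                                 retract_distance = 350,
                                 force_noise_sd = 3,
                                 seed = NULL) {
  pg_assert(retract_velocity > 0 && sampling_rate > 0 && retract_distance > 0,
            "velocity, sampling rate and retract distance must be positive")
  pg_assert(force_noise_sd >= 0, "force_noise_sd must be nonnegative")
  structure(list(retract_velocity = retract_velocity,
                 sampling_rate = sampling_rate,
                 retract_distance = retract_distance,
                 force_noise_sd = force_noise_sd,
                 seed = seed),
            class = "acquisition_protocol")
}

#' Default subunit kinetics for the streptavidin variants
#'
#' (k0, x_dagger) pairs for the four streptavidin subunits, chosen so that
#' the most probable rupture forces at the loading rates the emulated
#' experiment produces sit near 100 pN (subunits A and C), 210 pN
#' (subunit B) and 440 pN (subunit D). These are documented configuration
#' values, not measured constants.
#'
#' @param kBT Thermal energy, pN nm.
#' @return Named list of [bell_evans_params()], one per subunit A-D.
#' @export
default_subunit_params <- function(kBT = KBT_300K) {
  list(
    A = bell_evans_params(k0 = 0.12,    x_dagger = 0.40, kBT = kBT),
    B = bell_evans_params(k0 = 4.9e-5,  x_dagger = 0.35, kBT = kBT),
    C = bell_evans_params(k0 = 0.12,    x_dagger = 0.40, kBT = kBT),
    D = bell_evans_params(k0 = 8.2e-11, x_dagger = 0.30, kBT = kBT)
  )
}

subunits_for_variant <- function(variant_label) {
  switch(variant_label,
         "0SA" = character(0),
         "1SA" = "D",
         "3SA" = c("A", "B", "C"),
         "4SA" = c("A", "B", "C", "D"),
         abort("variant_label must be one of 0SA, 1SA, 3SA, 4SA"))
}

#' Configuration of a streptavidin variant measurement spot
#'
#' Describes which subunits of the tetramer are biotin-competent and with
#' what probabilities a retraction cycle yields a specific tether, a
#' nonspecific adhesion, or a spurious fingerprint-like background event.
#' The accessible subunits are fixed by the variant: 0SA exposes none, 1SA
#' only D (the anchored subunit), 3SA exposes A, B and C, and 4SA all four.
#'
#' @param variant_label One of "0SA", "1SA", "3SA", "4SA".
#' @param subunit_params Named list of [bell_evans_params()] for subunits
#'   A-D; defaults to [default_subunit_params()].
#' @param subunit_weights Named numeric of attachment probabilities over
#'   the accessible subunits; must sum to 1. Default: uniform.
#' @param nonspecific_rate Probability that a background cycle nevertheless
#'   shows a full fingerprint-like pattern. Default 1e-4 (two events in
#'   20,000 attempts).
#' @param fingerprint_attach_rate Probability that a cycle forms a full
#'   specific tether. Default 0.025.
#' @param background_adhesion_rate Probability that a background cycle
#'   shows a short-range nonspecific adhesion above the detection range.
#'   Default 0.10.
#' @return Object of class `variant_config`.
#' @export
variant_config <- function(variant_label,
                           subunit_params = default_subunit_params(),
                           subunit_weights = NULL,
                           nonspecific_rate = 1e-4,
                           fingerprint_attach_rate = 0.025,
                           background_adhesion_rate = 0.10) {
  accessible <- subunits_for_variant(variant_label)
  pg_assert(all(accessible %in% names(subunit_params)),
            "subunit_params must cover all accessible subunits")
  if (is.null(subunit_weights)) {
    subunit_weights <- setNames(rep(1 / max(length(accessible), 1),
                                    length(accessible)), accessible)
  }
  if (length(accessible)) {
    pg_assert(setequal(names(subunit_weights), accessible),
              "subunit_weights must be named by the accessible subunits")
    pg_assert(abs(sum(subunit_weights) - 1) < 1e-8,
              "subunit_weights must sum to 1")
    subunit_weights <- subunit_weights[accessible]
  } else {
    subunit_weights <- numeric(0)
  }
  pg_assert(nonspecific_rate >= 0 && nonspecific_rate <= 1 &&
              fingerprint_attach_rate >= 0 && fingerprint_attach_rate <= 1 &&
              background_adhesion_rate >= 0 && background_adhesion_rate <= 1,
            "rates must be probabilities in [0, 1]")
  structure(list(variant_label = variant_label,
                 accessible = accessible,
                 subunit_params = lapply(subunit_params, as_bell_evans),
                 subunit_weights = subunit_weights,
                 nonspecific_rate = nonspecific_rate,
                 fingerprint_attach_rate = fingerprint_attach_rate,
                 background_adhesion_rate = background_adhesion_rate),
            class = "variant_config")
}
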