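# --- raw-channel conversion -------------------------------------------------

#' Convert raw AFM channels to a force-extension trace
#'
#' Translates deflection and z-piezo voltages into force and tip-sample
#' distance using the cantilever spring constant, the optical lever
#' (inverse optical lever sensitivity, InvOLS) and the z-piezo
#' sensitivity, and applies the cantilever-bending correction:
#' force = k_c * InvOLS * deflection (pN), extension = piezo displacement
#' minus cantilever deflection (nm).
#'
#' @param deflection_V,piezo_V Raw channels, volts; equal length.
#' @param invols Inverse optical lever sensitivity, nm/V.
#' @param piezo_sensitivity z-piezo sensitivity, nm/V.
#' @param k_c Cantilever spring constant, N/m.
#' @param sampling_rate Sampling rate (Hz) used to build the time channel.
#' @return An [fe_trace()].
#' @export
convert_raw <- function(deflection_V, piezo_V, invols, piezo_sensitivity,
                        k_c, sampling_rate = 12000) {
  pg_assert(length(deflection_V) == length(piezo_V),
            "deflection and piezo channels must have equal length")
  pg_assert(invols > 0 && piezo_sensitivity > 0 && k_c > 0,
            "calibration constants must be positive")
  deflection_nm <- invols * deflection_V
  force_pN <- k_c * deflection_nm * 1000           # N/m * nm = nN -> pN
  extension_nm <- piezo_sensitivity * piezo_V - deflection_nm
  tt <- (seq_along(deflection_V) - 1) / sampling_rate
  fe_trace(tt, extension_nm, force_pN,
           metadata = list(invols = invols,
                           piezo_sensitivity = piezo_sensitivity,
                           cantilever_stiffness = k_c,
                           sampling_rate = sampling_rate))
}

# --- zero points ------------------------------------------------------------

#' Determine force and distance zero points of a trace
#'
#' The force offset is the median of the terminal detached-baseline window.
#' The distance offset is taken from the initial contact (indentation)
#' segment when the trace starts in contact: a line fitted to the smoothed
#' contact slope is extrapolated to its zero-force crossing. Traces that
#' never detach (no baseline) are flagged for exclusion.
#'
#' @param trace An [fe_trace()].
#' @param baseline_fraction Fraction of samples at the trace end used as
#'   the detached baseline window.
#' @param contact_threshold Force (pN) above which the initial samples are
#'   treated as a contact segment.
#' @param smooth_window Boxcar window (samples) for slope estimation.
#' @return List with `trace` (corrected), `force_offset` (pN),
#'   `distance_offset` (nm) and `excluded` (no detectable baseline).
#' @export
determine_zero_points <- function(trace, baseline_fraction = 0.1,
                                  contact_threshold = 25,
                                  smooth_window = 11) {
  n <- nrow(trace)
  nb <- max(5L, floor(n * baseline_fraction))
  tail_idx <- (n - nb + 1L):n
  force_offset <- median(trace$force_pN[tail_idx])
  f <- boxcar(trace$force_pN - force_offset, smooth_window)
  # the deflection offset is arbitrary, so "no baseline" cannot be read
  # off the force level: a detached baseline is *flat*, a trace still in
  # contact (or still loaded) at the end is not
  if (diff(range(f[tail_idx])) > contact_threshold) {
    return(list(trace = trace, force_offset = NA_real_,
                distance_offset = NA_real_, excluded = TRUE))
  }
  distance_offset <- 0
  if (f[1] > contact_threshold) {
    contact <- seq_len(max(2L, which(f <= 0)[1] - 1L))
    fit <- lm(f[contact] ~ trace$extension_nm[contact])
    slope <- coef(fit)[2]
    if (is.finite(slope) && slope != 0) {
      distance_offset <- -coef(fit)[1] / slope
    }
  }
  corrected <- fe_trace(trace$time_s,
                        trace$extension_nm - distance_offset,
                        trace$force_pN - force_offset,
                        metadata = trace_metadata(trace),
                        events = trace_events(trace))
  list(trace = corrected, force_offset = unname(force_offset),
       distance_offset = unname(distance_offset), excluded = FALSE)
}

# --- denoising --------------------------------------------------------------

# length-preserving boxcar with shrinking windows at the edges
boxcar <- function(x, window) {
  if (window == 1L) return(x)
  n <- length(x)
  h <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Denoise the force channel of a trace
#'
#' Moving-average (boxcar) smoothing of the force channel; length is
#' preserved and `window = 1` is the identity.
#'
#' @param trace An [fe_trace()].
#' @param window Odd window length in samples, >= 1.
#' @return The trace with the force channel smoothed.
#' @export
denoise <- function(trace, window = 11) {
  pg_assert(window >= 1 && window %% 2 == 1, "window must be odd and >= 1")
  pg_assert(window <= nrow(trace), "window larger than the trace")
  fe_trace(trace$time_s, trace$extension_nm, boxcar(trace$force_pN, window),
           metadata = trace_metadata(trace), events = trace_events(trace))
}

# --- contour-length transform ----------------------------------------------

#' Transform a force-extension trace into contour-length space
#'
#' For every sample with force above `min_force`, inverts the interpolated
#' WLC model: the instantaneous contour length is the unique Lc > extension
#' with `wlc_force(extension, Lc, Lp, kBT) = force`. Unfolding steps then
#' appear as discrete jumps of the transformed series. Points below
#' `min_force` (ill-conditioned inversion) or with nonpositive extension
#' are masked as `NA`.
#'
#' @param trace An [fe_trace()] (zeroed and, typically, denoised).
#' @param Lp Persistence length, nm.
#' @param kBT Thermal energy, pN nm.
#' @param min_force Mask threshold, pN (> 0). Default 10.
#' @return The trace tibble with an added `Lc_nm` column.
#' @export
contour_length_transform <- function(trace, Lp = 0.38, kBT = KBT_300K,
                                     min_force = 10) {
  pg_assert(min_force > 0, "min_force must be positive")
  ok <- trace$force_pN >= min_force & trace$extension_nm > 0
  Lc <- rep(NA_real_, nrow(trace))
  if (any(ok)) {
    s <- wlc_fractional_extension(trace$force_pN[ok] * Lp / kBT)
    Lc[ok] <- trace$extension_nm[ok] / s
  }
  out <- trace
  out$Lc_nm <- Lc
  out
}

# --- event detection --------------------------------------------------------

# mode of a contour-length segment: kernel-density argmax, median fallback
lc_mode <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 5 || sd(x) < 1e-9) return(median(x))
  d <- density(x, n = 512)
  d$x[which.max(d$y)]
}

#' Detect unfolding and detachment events in a transformed trace
#'
#' Finds local force maxima followed by a relative force drop of at least
#' `drop_fraction`, on the smoothed force channel. Contour lengths before
#' and after each event are the modes of the transformed (`Lc_nm`) series
#' on the flanking stretches. The last event whose following stretch has
#' no measurable contour length (force back at baseline) is marked as the
#' terminal detachment.
#'
#' @param trace Output of [contour_length_transform()] (has `Lc_nm`).
#' @param min_peak_force Minimum peak force for an event, pN.
#' @param min_delta_Lc Minimum contour-length increment (nm) for a
#'   non-terminal event to be kept.
#' @param drop_fraction Minimum force drop relative to the peak.
#' @param smooth_window Boxcar window used for peak finding.
#' @return Tibble of events ordered by time: `index`, `time_s`,
#'   `peak_force`, `Lc_before`, `Lc_after`, `delta_Lc`, `is_terminal`.
#' @export
detect_unfolding_events <- function(trace, min_peak_force = 20,
                                    min_delta_Lc = 4, drop_fraction = 0.25,
                                    smooth_window = 11) {
  pg_assert(!is.null(trace$Lc_nm), "run contour_length_transform() first")
  f <- boxcar(trace$force_pN, smooth_window)
  n <- length(f)

  # running-max drop trigger: an event fires when the force has fallen by
  # drop_fraction below the running maximum of the current stretch (and
  # that maximum is a real peak); the boundary then descends to the local
  # minimum with hysteresis, which keeps cascaded unfolding steps (the
  # next substep firing before the force recovers) as separate events
  events <- list()
  i <- 1L
  while (i < n) {
    pmax <- i
    j <- i
    fired <- FALSE
    while (j < n) {
      j <- j + 1L
      if (f[j] > f[pmax]) pmax <- j
      if (f[pmax] >= min_peak_force &&
          f[j] <= (1 - drop_fraction) * f[pmax]) {
        fired <- TRUE
        break
      }
    }
    if (!fired) break
    # descend: follow the drop to its local minimum, tolerating noise
    hyst <- max(2, 0.1 * (f[pmax] - f[j]))
    k <- j
    kmin <- j
    while (k < n) {
      k <- k + 1L
      if (f[k] < f[kmin]) kmin <- k
      if (f[k] > f[kmin] + hyst) break
    }
    events[[length(events) + 1L]] <- list(index = pmax, trough = kmin)
    i <- kmin
  }
  if (!length(events)) {
    return(tibble(index = integer(), time_s = numeric(),
                  peak_force = numeric(), Lc_before = numeric(),
                  Lc_after = numeric(), delta_Lc = numeric(),
                  is_terminal = logical()))
  }

  idx <- vapply(events, function(e) e$index, integer(1))
  bounds <- c(0L, vapply(events, function(e) e$trough, integer(1)), n)
  seg_mode <- function(a, b) {
    if (b <= a) return(NA_real_)
    lc_mode(trace$Lc_nm[(a + 1L):b])
  }
  out <- map(seq_along(events), function(k) {
    before <- seg_mode(bounds[k], idx[k])
    after <- seg_mode(bounds[k + 1L], if (k < length(events))
      idx[k + 1L] else n)
    tibble(index = idx[k], time_s = trace$time_s[idx[k]],
           peak_force = max(trace$force_pN[max(1L, idx[k] - 2L):
                                             min(n, idx[k] + 2L)]),
           Lc_before = before, Lc_after = after,
           delta_Lc = after - before,
           is_terminal = !is.finite(after))
  })
  out <- bind_rows(out)
  # only the last baseline-terminated event is the detachment;
  # earlier NA-after events are unclassifiable and dropped
  if (any(out$is_terminal)) {
    term <- max(which(out$is_terminal))
    out <- out[c(which(!out$is_terminal & seq_len(nrow(out)) < term), term), ]
  }
  keep <- out$is_terminal |
    (is.finite(out$delta_Lc) & out$delta_Lc >= min_delta_Lc)
  out[keep, ]
}

# --- fingerprint classification --------------------------------------------

#' Classify the ddFLN4 unfolding fingerprint
#'
#' TRUE iff the event table contains, in temporal order, one
#' contour-length increment matching each expected increment within
#' `tolerance`, all occurring before the terminal detachment. Used to
#' certify that a rupture event reports a single specific tether.
#'
#' @param events Event tibble from [detect_unfolding_events()].
#' @param expected_delta_Lcs Expected increments (nm), in order.
#'   Default c(15, 16), the two-step ddFLN4 signature.
#' @param tolerance Matching tolerance, nm (> 0). Default 2.
#' @return Logical flag.
#' @export
classify_fingerprint <- function(events, expected_delta_Lcs = c(15, 16),
                                 tolerance = 2) {
  pg_assert(tolerance > 0, "tolerance must be positive")
  if (!nrow(events) || !any(events$is_terminal)) return(FALSE)
  term <- which(events$is_terminal)[1]
  inc <- events$delta_Lc[seq_len(nrow(events)) < term & !events$is_terminal]
  inc <- inc[is.finite(inc)]
  j <- 1L
  for (target in expected_delta_Lcs) {
    hit <- which(abs(inc[seq.int(j, length.out = max(0, length(inc) - j + 1))]
                     - target) <= tolerance)
    if (!length(hit)) return(FALSE)
    j <- j + hit[1]
  }
  TRUE
}

# --- rupture extraction -----------------------------------------------------

#' Extract the terminal rupture event from a trace
#'
#' The rupture force is the force at the last peak before the final
#' detachment (the terminal event of [detect_unfolding_events()]); the
#' loading rate is the slope of a least-squares line fitted to force
#' versus time on the final rising flank immediately before that peak
#' (samples with smoothed force above `flank_threshold` times the peak
#' force).
#'
#' @param trace An [fe_trace()] (zeroed).
#' @param events Event tibble from [detect_unfolding_events()].
#' @param flank_threshold Fraction of the peak force delimiting the fit
#'   window. Default 0.75.
#' @param smooth_window Boxcar window for flank delimitation.
#' @return One-row tibble: `rupture_force` (pN), `loading_rate` (pN/s),
#'   `rupture_index`, `valid` (FALSE when no detachment was found).
#' @export
extract_rupture <- function(trace, events, flank_threshold = 0.75,
                            smooth_window = 11) {
  if (!nrow(events) || !any(events$is_terminal)) {
    return(tibble(rupture_force = NA_real_, loading_rate = NA_real_,
                  rupture_index = NA_integer_, valid = FALSE))
  }
  term <- events[max(which(events$is_terminal)), ]
  p <- term$index
  f <- boxcar(trace$force_pN, min(smooth_window, nrow(trace)))
  # peak amplitude from a short boxcar: long windows smear the drop and
  # bias the rupture force low, raw samples carry the full noise upward
  fp <- boxcar(trace$force_pN, min(5L, smooth_window, nrow(trace)))
  rupture_force <- max(fp[max(1L, p - smooth_window):min(length(fp), p +
                                                           smooth_window)])
  # final rising flank: contiguous run below the peak above the threshold
  thr <- flank_threshold * rupture_force
  i <- p
  while (i > 1L && f[i - 1L] >= thr && f[i - 1L] <= f[i] + 3 *
         stats::mad(diff(f)) + 1e-9) {
    i <- i - 1L
  }
  win <- i:p
  loading_rate <- NA_real_
  if (length(win) >= 3) {
    fit <- lm(trace$force_pN[win] ~ trace$time_s[win])
    loading_rate <- unname(coef(fit)[2])
  }
  tibble(rupture_force = rupture_force, loading_rate = loading_rate,
         rupture_index = p, valid = TRUE)
}

# --- trace-set filtering ----------------------------------------------------

#' Filter a trace set by maximum interaction force
#'
#' Keeps traces whose maximum (smoothed) force exceeds `force_threshold`,
#' the bookkeeping step separating interaction curves from empty
#' retractions. Kept/discarded counts are recorded as the `counts`
#' attribute.
#'
#' @param trace_set Tibble with a `trace` list-column (see
#'   [generate_variant_dataset()]).
#' @param force_threshold Threshold in pN (>= 0). Default 50.
#' @param smooth_window Boxcar window applied before taking the maximum.
#' @return The filtered trace-set tibble.
#' @export
filter_traces <- function(trace_set, force_threshold = 50,
                          smooth_window = 11) {
  pg_assert(force_threshold >= 0, "force_threshold must be nonnegative")
  mx <- map_dbl(trace_set$trace, function(tr)
    max(boxcar(tr$force_pN, min(smooth_window, nrow(tr)))))
  keep <- mx > force_threshold
  out <- trace_set[keep, , drop = FALSE]
  attr(out, "counts") <- list(input = nrow(trace_set), kept = sum(keep),
                              discarded = sum(!keep))
  out
}

#' Analyze one trace end to end
#'
#' Convenience chain: zero points, denoising, contour-length transform,
#' event detection, fingerprint classification and rupture extraction,
#' with the module defaults (overridable through `...`-style arguments).
#'
#' @param trace An [fe_trace()].
#' @param Lp,kBT,min_force Transform parameters, see
#'   [contour_length_transform()].
#' @param denoise_window Boxcar window for [denoise()].
#' @param expected_delta_Lcs,tolerance Fingerprint template, see
#'   [classify_fingerprint()].
#' @param min_peak_force,min_delta_Lc,drop_fraction Detector settings.
#' @param flank_threshold Rupture loading-rate window, see
#'   [extract_rupture()].
#' @return One-row tibble: rupture force/loading rate/validity plus
#'   `fingerprint_valid` and `n_events`; the event table is attached as
#'   the `events` attribute.
#' @export
analyze_trace <- function(trace, Lp = 0.38, kBT = KBT_300K, min_force = 10,
                          denoise_window = 11,
                          expected_delta_Lcs = c(15, 16), tolerance = 2,
                          min_peak_force = 20, min_delta_Lc = 4,
                          drop_fraction = 0.25, flank_threshold = 0.75) {
  zp <- determine_zero_points(trace)
  if (zp$excluded) {
    out <- tibble(rupture_force = NA_real_, loading_rate = NA_real_,
                  rupture_index = NA_integer_, valid = FALSE,
                  fingerprint_valid = FALSE, n_events = 0L)
    attr(out, "events") <- NULL
    return(out)
  }
  sm <- denoise(zp$trace, denoise_window)
  tl <- contour_length_transform(sm, Lp = Lp, kBT = kBT,
                                 min_force = min_force)
  ev <- detect_unfolding_events(tl, min_peak_force = min_peak_force,
                                min_delta_Lc = min_delta_Lc,
                                drop_fraction = drop_fraction,
                                smooth_window = 1)  # already denoised
  fp <- classify_fingerprint(ev, expected_delta_Lcs, tolerance)
  ru <- extract_rupture(zp$trace, ev, flank_threshold = flank_threshold,
                        smooth_window = denoise_window)
  out <- mutate(ru, fingerprint_valid = fp, n_events = nrow(ev))
  attr(out, "events") <- ev
  out
}
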