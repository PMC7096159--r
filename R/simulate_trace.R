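# --- force-extension trace container ---------------------------------------

#' Construct a force-extension trace
#'
#' A single retraction cycle: time, tip-sample extension and force channels
#' in a tibble, with acquisition metadata and (for synthetic traces) a
#' ground-truth event log carried as attributes.
#'
#' @param time_s,extension_nm,force_pN Equal-length numeric channels; time
#'   strictly increasing.
#' @param metadata Named list of acquisition/provenance metadata.
#' @param events Ground-truth or detected event log (tibble), optional.
#' @return A tibble of class `fe_trace`.
#' @export
fe_trace <- function(time_s, extension_nm, force_pN, metadata = list(),
                     events = NULL) {
  n <- length(time_s)
  pg_assert(length(extension_nm) == n && length(force_pN) == n,
            "time, extension and force channels must have equal length")
  pg_assert(n < 2 || all(diff(time_s) > 0), "time must be strictly increasing")
  out <- tibble(time_s = as.numeric(time_s),
                extension_nm = as.numeric(extension_nm),
                force_pN = as.numeric(force_pN))
  attr(out, "metadata") <- metadata
  attr(out, "events") <- events
  class(out) <- c("fe_trace", class(out))
  out
}

#' @export
#' @rdname fe_trace
#' @param x Object to query.
trace_metadata <- function(x) attr(x, "metadata")

#' @export
#' @rdname fe_trace
trace_events <- function(x) attr(x, "events")

# --- serial-WLC force balance -----------------------------------------------

# Solve the cantilever/tether force balance for a vector of tip-surface
# separations z (nm): find F with sum_i Lc_i * s_i(F) + F/kc = z, where
# s_i is the WLC fractional extension of segment i. The map z(F) is
# monotone; a coarse grid gives the initial guess and damped Newton
# iterations polish to ~1e-10 nm.
solve_force_balance <- function(z, segments, kc_pn_nm, kBT) {
  # collapse segments sharing a persistence length
  grp <- stats::aggregate(Lc ~ Lp, data = segments, FUN = sum)
  Lcs <- grp$Lc
  Lps <- grp$Lp

  z_of_F <- function(F) {
    tot <- F / kc_pn_nm
    for (g in seq_along(Lcs)) {
      tot <- tot + Lcs[g] * wlc_fractional_extension(F * Lps[g] / kBT)
    }
    tot
  }

  Fmax <- kc_pn_nm * max(max(z), 1e-6) + 1
  Fgrid <- c(seq(0, min(Fmax, 50), length.out = 60),
             seq(min(Fmax, 50), Fmax, length.out = 200)[-1])
  zgrid <- z_of_F(Fgrid)
  F <- stats::approx(zgrid, Fgrid, xout = z, rule = 2)$y

  for (it in seq_len(12)) {
    ztot <- F / kc_pn_nm
    dz <- rep(1 / kc_pn_nm, length(F))
    for (g in seq_along(Lcs)) {
      s <- wlc_fractional_extension(F * Lps[g] / kBT)
      ztot <- ztot + Lcs[g] * s
      dFds <- (kBT / Lps[g]) * (1 / (2 * (1 - s)^3) + 1)
      dz <- dz + Lcs[g] / dFds
    }
    resid <- ztot - z
    if (max(abs(resid)) < 1e-11 * max(1, max(z))) break
    F <- pmax(F - resid / dz, 0)
  }
  F
}

# instantaneous loading rate dF/dt at force F for a serial tether pulled at
# constant velocity v (nm/s): v / (dx/dF + 1/kc)
instantaneous_loading_rate <- function(F, segments, kc_pn_nm, kBT, velocity) {
  dxdF <- 1 / kc_pn_nm
  for (g in seq_len(nrow(segments))) {
    s <- wlc_fractional_extension(F * segments$Lp[g] / kBT)
    dFds <- (kBT / segments$Lp[g]) * (1 / (2 * (1 - s)^3) + 1)
    dxdF <- dxdF + segments$Lc[g] / dFds
  }
  velocity / dxdF
}

# --- trace simulation -------------------------------------------------------

#' Simulate one force-extension retraction cycle
#'
#' Integrates the retraction of a cantilever at constant velocity against a
#' serial WLC tether. At every sampling step the force balance between the
#' cantilever spring and the tether is solved; the next fingerprint
#' unfolding substep and the terminal bond each carry a Bell force-dependent
#' hazard \eqn{k(F) = k_0 e^{F x^\ddagger / k_BT}}, integrated on the
#' sampling grid as per-step rupture probabilities. An unfolding event adds
#' its contour-length increment; terminal bond rupture drops the force to
#' the detached baseline. Gaussian noise is added to the force channel
#' only; the ground-truth event log (times, noise-free forces, event kinds,
#' instantaneous loading rates) is attached as an attribute.
#'
#' @param tether A [tether_model()].
#' @param bond Terminal-bond [bell_evans_params()], or `NULL` for a
#'   permanently attached tether.
#' @param protocol An [acquisition_protocol()].
#' @param seed Optional integer seed (overrides `protocol$seed`).
#' @return An [fe_trace()] with `trace_events()` carrying the event log.
#' @examples
#' tr <- simulate_trace(tether_model(), default_subunit_params()$B,
#'                      acquisition_protocol(force_noise_sd = 0), seed = 1)
#' @export
simulate_trace <- function(tether, bond, protocol, seed = NULL) {
  pg_assert(inherits(tether, "tether_model"), "tether must be a tether_model")
  pg_assert(inherits(protocol, "acquisition_protocol"),
            "protocol must be an acquisition_protocol")
  if (!is.null(bond)) bond <- as_bell_evans(bond)
  seed <- seed %||% protocol$seed
  if (!is.null(seed)) set.seed(seed)

  dt <- 1 / protocol$sampling_rate
  n <- max(2L, ceiling(protocol$retract_distance /
                         (protocol$retract_velocity * dt)))
  tt <- (seq_len(n) - 1) * dt
  z <- protocol$retract_velocity * tt
  kc <- tether$cantilever_stiffness * 1000  # N/m -> pN/nm
  kBT <- tether$kBT

  force <- numeric(n)
  segments <- tether$segments
  steps <- tether$unfolding_steps
  step_idx <- if (nrow(steps)) 1L else NA_integer_
  events <- list()
  i0 <- 1L
  repeat {
    idx <- i0:n
    Fv <- solve_force_balance(z[idx], segments, kc, kBT)
    # competing exponential clocks on the cumulative hazard grid
    iu <- Inf
    if (!is.na(step_idx) && step_idx <= nrow(steps)) {
      ku <- steps$k0[step_idx] * exp(Fv * steps$x_dagger[step_idx] / kBT)
      Hu <- cumsum(ku * dt)
      hit <- which(Hu >= rexp(1))
      if (length(hit)) iu <- hit[1]
    }
    ir <- Inf
    if (!is.null(bond)) {
      kr <- bond$k0 * exp(Fv * bond$x_dagger / kBT)
      Hr <- cumsum(kr * dt)
      hit <- which(Hr >= rexp(1))
      if (length(hit)) ir <- hit[1]
    }
    if (is.infinite(iu) && is.infinite(ir)) {           # no event before end
      force[idx] <- Fv
      break
    }
    if (ir <= iu) {                                     # terminal rupture
      e <- idx[ir]
      force[idx[seq_len(ir)]] <- Fv[seq_len(ir)]
      if (e < n) force[(e + 1L):n] <- 0
      # window-averaged rate over the final rising flank (>= 75% of the
      # rupture force): the quantity a linear fit "immediately before
      # rupture" measures; the pointwise rate at the peak sits above it
      # when the tether stiffens nonlinearly
      flank <- which(Fv[seq_len(ir)] >= 0.75 * Fv[ir])
      rate_local <- if (length(flank) >= 2 && flank[1] < ir) {
        (Fv[ir] - Fv[flank[1]]) / ((ir - flank[1]) * dt)
      } else NA_real_
      events[[length(events) + 1L]] <- tibble(
        event = "rupture", index = e, time_s = tt[e], force_pN = Fv[ir],
        delta_Lc = NA_real_,
        loading_rate = instantaneous_loading_rate(
          Fv[ir], segments, kc, kBT, protocol$retract_velocity),
        loading_rate_local = rate_local)
      break
    }
    # unfolding: contour-length increment, continue after the event sample
    e <- idx[iu]
    force[idx[seq_len(iu)]] <- Fv[seq_len(iu)]
    events[[length(events) + 1L]] <- tibble(
      event = sprintf("unfold%d", step_idx), index = e, time_s = tt[e],
      force_pN = Fv[iu], delta_Lc = steps$delta_Lc[step_idx],
      loading_rate = instantaneous_loading_rate(
        Fv[iu], segments, kc, kBT, protocol$retract_velocity))
    segments <- rbind(segments[, c("Lc", "Lp")],
                      data.frame(Lc = steps$delta_Lc[step_idx],
                                 Lp = steps$Lp[step_idx]))
    step_idx <- step_idx + 1L
    if (e >= n) break
    i0 <- e + 1L
  }

  event_log <- if (length(events)) bind_rows(events) else
    tibble(event = character(), index = integer(), time_s = numeric(),
           force_pN = numeric(), delta_Lc = numeric(),
           loading_rate = numeric(), loading_rate_local = numeric())

  extension <- z - force / kc
  noisy <- force
  if (protocol$force_noise_sd > 0) {
    noisy <- force + rnorm(n, sd = protocol$force_noise_sd)
  }
  fe_trace(tt, extension, noisy,
           metadata = list(protocol = unclass(protocol),
                           kBT = kBT,
                           cantilever_stiffness = tether$cantilever_stiffness,
                           segment_Lc_total = sum(tether$segments$Lc),
                           seed = seed),
           events = event_log)
}

# Background cycle: pure baseline noise, or a short nonspecific adhesion
# tether (random short contour length, weak bond) with no fingerprint.
simulate_background_trace <- function(protocol, kBT = KBT_300K,
                                      adhesion = FALSE,
                                      cantilever_stiffness = 0.15) {
  if (!adhesion) {
    dt <- 1 / protocol$sampling_rate
    n <- max(2L, ceiling(protocol$retract_distance /
                           (protocol$retract_velocity * dt)))
    tt <- (seq_len(n) - 1) * dt
    f <- rnorm(n, sd = max(protocol$force_noise_sd, 1e-12))
    return(fe_trace(tt, protocol$retract_velocity * tt, f,
                    metadata = list(protocol = unclass(protocol), kBT = kBT),
                    events = tibble(event = character(), index = integer(),
                                    time_s = numeric(), force_pN = numeric(),
                                    delta_Lc = numeric(),
                                    loading_rate = numeric())))
  }
  teth <- tether_model(
    cantilever_stiffness = cantilever_stiffness,
    segments = data.frame(Lc = runif(1, 8, 30), Lp = 0.38),
    unfolding_steps = data.frame(delta_Lc = numeric(), k0 = numeric(),
                                 x_dagger = numeric()),
    kBT = kBT)
  # weak, broad adhesion bond: ruptures anywhere between ~30 and ~300 pN
  adh <- bell_evans_params(k0 = 10^runif(1, -2, 1), x_dagger = 0.3, kBT = kBT)
  simulate_trace(teth, adh, protocol)
}

#' Generate a labelled synthetic trace set for one variant spot
#'
#' Draws `n_traces` retraction cycles for a streptavidin-variant spot: with
#' probability `fingerprint_attach_rate` a cycle forms a full specific
#' tether whose terminal bond is drawn from the variant's accessible
#' subunits according to `subunit_weights`; otherwise the cycle is
#' background (baseline noise or a short nonspecific adhesion), and with
#' probability `nonspecific_rate` a background cycle nevertheless shows a
#' spurious full fingerprint. Every trace carries its ground-truth label.
#'
#' @param config A [variant_config()].
#' @param n_traces Number of retraction cycles.
#' @param protocol An [acquisition_protocol()].
#' @param tether A [tether_model()]; default [tether_model()].
#' @param seed Integer seed for the whole set.
#' @return A tibble (one row per trace) with columns `trace_id`,
#'   `spot_label`, `subunit` ("A".."D" or "background"), `category`
#'   ("specific", "adhesion", "baseline", "spurious_fingerprint"),
#'   `fingerprint_true` (did the full fingerprint unfold before rupture?),
#'   `rupture_force_true`, `loading_rate_true`, and a `trace` list-column
#'   of [fe_trace()] objects.
#' @export
generate_variant_dataset <- function(config, n_traces, protocol,
                                     tether = tether_model(), seed = 1) {
  pg_assert(inherits(config, "variant_config"),
            "config must be a variant_config")
  pg_assert(n_traces >= 1, "n_traces must be at least 1")
  set.seed(seed)
  no_fingerprint <- tether
  no_fingerprint$unfolding_steps <-
    tether$unfolding_steps[integer(0), , drop = FALSE]

  rows <- vector("list", n_traces)
  for (i in seq_len(n_traces)) {
    specific <- length(config$accessible) > 0 &&
      runif(1) < config$fingerprint_attach_rate
    if (specific) {
      subunit <- sample(config$accessible, 1, prob = config$subunit_weights)
      tr <- simulate_trace(tether, config$subunit_params[[subunit]], protocol)
      category <- "specific"
    } else if (runif(1) < config$nonspecific_rate) {
      # spurious fingerprint-like background event: full tether, random bond
      spurious <- bell_evans_params(k0 = 10^runif(1, -5, -2), x_dagger = 0.35,
                                    kBT = tether$kBT)
      tr <- simulate_trace(tether, spurious, protocol)
      subunit <- "background"
      category <- "spurious_fingerprint"
    } else if (runif(1) < config$background_adhesion_rate) {
      tr <- simulate_background_trace(protocol, tether$kBT, adhesion = TRUE,
                                      tether$cantilever_stiffness)
      subunit <- "background"
      category <- "adhesion"
    } else {
      tr <- simulate_background_trace(protocol, tether$kBT, adhesion = FALSE,
                                      tether$cantilever_stiffness)
      subunit <- "background"
      category <- "baseline"
    }
    ev <- trace_events(tr)
    n_unf <- sum(grepl("^unfold", ev$event))
    ruptured <- any(ev$event == "rupture")
    rows[[i]] <- tibble(
      trace_id = sprintf("%s_%05d", config$variant_label, i),
      spot_label = config$variant_label,
      subunit = subunit,
      category = category,
      fingerprint_true = n_unf == nrow(tether$unfolding_steps) &&
        nrow(tether$unfolding_steps) > 0 && ruptured,
      rupture_force_true = if (ruptured)
        ev$force_pN[ev$event == "rupture"] else NA_real_,
      loading_rate_true = if (ruptured)
        ev$loading_rate[ev$event == "rupture"] else NA_real_,
      loading_rate_local_true = if (ruptured)
        ev$loading_rate_local[ev$event == "rupture"] else NA_real_,
      trace = list(tr))
  }
  bind_rows(rows)
}
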