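# --- atom selection ---------------------------------------------------------

#' Select a single atom from a trajectory
#'
#' Selection by residue number (1-based, as in PDB records), atom name and
#' optionally chain and residue name. The selection must resolve to
#' exactly one atom; otherwise the error lists all matches.
#'
#' @param traj A [pg_trajectory()].
#' @param resid Residue number.
#' @param name Atom name (e.g. "CA").
#' @param chain Optional chain identifier.
#' @param resname Optional residue name.
#' @return The atom index (integer).
#' @export
select_atom <- function(traj, resid = NULL, name = NULL, chain = NULL,
                        resname = NULL) {
  at <- traj$atoms
  keep <- rep(TRUE, nrow(at))
  if (!is.null(resid)) keep <- keep & at$resid == resid
  if (!is.null(name)) keep <- keep & at$name == name
  if (!is.null(chain)) keep <- keep & at$chain == chain
  if (!is.null(resname)) keep <- keep & at$resname == resname
  idx <- which(keep)
  if (length(idx) != 1) {
    hits <- if (length(idx)) paste(
      sprintf("%d: %s %s%d/%s %s", idx, at$chain[idx], at$resname[idx],
              at$resid[idx], at$name[idx], at$element[idx]),
      collapse = "; ") else "none"
    abort(sprintf(
      "selection must resolve to exactly one atom; matched %d (%s)",
      length(idx), hits), class = "pullgeom_selection_error")
  }
  idx
}

new_metric_series <- function(values, traj, kind, atoms_used,
                              flagged = NULL) {
  out <- tibble(frame = seq_len(n_frames(traj)),
                time_ns = (seq_len(n_frames(traj)) - 1) *
                  traj$frame_interval_ns,
                value = values)
  attr(out, "metric_kind") <- kind
  attr(out, "units") <- if (kind == "distance") "nm" else "degrees"
  attr(out, "atoms_used") <- atoms_used
  attr(out, "frame_interval_ns") <- traj$frame_interval_ns
  attr(out, "flagged_frames") <- flagged
  class(out) <- c("pg_metric_series", class(out))
  out
}

# --- observables ------------------------------------------------------------

#' Rupture force, frame and loading rate of a pulling force series
#'
#' The rupture force is the global maximum of the applied-force series
#' (first occurrence on ties); the loading rate is the least-squares slope
#' of force versus time over the window immediately preceding the maximum.
#'
#' @param force_pN Applied force per frame (pN), or a [pg_trajectory()]
#'   carrying one.
#' @param frame_interval_ns Frame spacing, ns (ignored when a trajectory
#'   is given).
#' @param fit_window_ns Length of the loading-rate fit window, ns.
#'   Default 10. When fewer than 3 frames precede the maximum the rate is
#'   flagged undefined (`NA`).
#' @return One-row tibble: `rupture_force` (pN), `rupture_frame`,
#'   `loading_rate` (pN/s).
#' @export
smd_rupture <- function(force_pN, frame_interval_ns = 0.4,
                        fit_window_ns = 10) {
  if (inherits(force_pN, "pg_trajectory")) {
    frame_interval_ns <- force_pN$frame_interval_ns
    force_pN <- force_pN$force_pN
  }
  pg_assert(length(force_pN) >= 1, "force series must be nonempty")
  imax <- which.max(force_pN)
  wf <- max(1L, round(fit_window_ns / frame_interval_ns))
  win <- max(1L, imax - wf):imax
  rate <- NA_real_
  if (length(win) >= 3) {
    t_s <- (win - 1) * frame_interval_ns * 1e-9
    rate <- unname(coef(lm(force_pN[win] ~ t_s))[2])
  }
  tibble(rupture_force = force_pN[imax], rupture_frame = imax,
         loading_rate = rate)
}

#' Per-frame distance between two atoms
#'
#' Euclidean distance between two single-atom selections, per frame,
#' reported in nm. The canonical lid-opening metric is the distance
#' between the alpha carbons of the L3/4-loop tip (Gly48) and the middle
#' of beta-strand 8 (Leu124).
#'
#' @param traj A [pg_trajectory()].
#' @param sel_i,sel_j Named lists of [select_atom()] arguments (e.g.
#'   `list(resid = 48, name = "CA")`), or atom indices.
#' @return A `pg_metric_series` tibble: `frame`, `time_ns`, `value` (nm).
#' @export
pair_distance_series <- function(traj, sel_i, sel_j) {
  i <- if (is.numeric(sel_i)) as.integer(sel_i) else
    do.call(select_atom, c(list(traj), sel_i))
  j <- if (is.numeric(sel_j)) as.integer(sel_j) else
    do.call(select_atom, c(list(traj), sel_j))
  dv <- traj$coords[, i, , drop = FALSE] - traj$coords[, j, , drop = FALSE]
  d_A <- sqrt(rowSums(matrix(dv, nrow = n_frames(traj))^2))
  new_metric_series(d_A / 10, traj, "distance", c(i, j))
}

#' Per-frame three-atom angle
#'
#' Angle at vertex `sel_b` spanned by `sel_a` and `sel_c`, in degrees
#' within [0, 180]. Frames with a zero-length arm are flagged and return
#' `NA`.
#'
#' @param traj A [pg_trajectory()].
#' @param sel_a,sel_b,sel_c Single-atom selections as in
#'   [pair_distance_series()]; all three must be distinct atoms.
#' @return A `pg_metric_series` tibble (`value` in degrees).
#' @export
angle_series <- function(traj, sel_a, sel_b, sel_c) {
  ids <- map(list(sel_a, sel_b, sel_c), function(s)
    if (is.numeric(s)) as.integer(s) else
      do.call(select_atom, c(list(traj), s)))
  pg_assert(length(unique(unlist(ids))) == 3,
            "the three selections must be distinct atoms")
  nf <- n_frames(traj)
  u <- matrix(traj$coords[, ids[[1]], ] - traj$coords[, ids[[2]], ],
              nrow = nf)
  v <- matrix(traj$coords[, ids[[3]], ] - traj$coords[, ids[[2]], ],
              nrow = nf)
  nu <- sqrt(rowSums(u^2)); nv <- sqrt(rowSums(v^2))
  bad <- nu < 1e-12 | nv < 1e-12
  cosang <- rowSums(u * v) / pmax(nu * nv, 1e-300)
  ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  ang[bad] <- NA_real_
  new_metric_series(ang, traj, "angle", unlist(ids),
                    flagged = which(bad))
}

# --- windowed histograms ----------------------------------------------------

#' Unloaded/loaded window histograms of a lid metric
#'
#' Histograms of a per-frame metric over the first `window_ns` of the run
#' (unloaded condition) and the `window_ns` immediately before the rupture
#' frame (loaded condition), with shared bin edges, plus the shift of the
#' window means. The comparison reveals whether the metric (e.g. the lid
#' pair distance) has moved before the complex ruptures.
#'
#' @param series A `pg_metric_series` (or numeric vector).
#' @param rupture_frame Frame index of the rupture.
#' @param window_ns Window length, ns. Default 10.
#' @param bins Number of shared bins. Default 30.
#' @param frame_interval_ns Frame spacing when `series` is a bare vector.
#' @return Object of class `pg_window_hist`: tibbles `unloaded` and
#'   `loaded` (`mid`, `count`), shared `breaks`, `shift` (loaded minus
#'   unloaded mean, same units as the series), and the raw window values.
#' @export
window_histograms <- function(series, rupture_frame, window_ns = 10,
                              bins = 30, frame_interval_ns = NULL) {
  if (inherits(series, "pg_metric_series")) {
    frame_interval_ns <- attr(series, "frame_interval_ns")
    values <- series$value
  } else {
    values <- as.numeric(series)
    pg_assert(!is.null(frame_interval_ns),
              "frame_interval_ns needed for a bare vector")
  }
  wf <- max(1L, round(window_ns / frame_interval_ns))
  pg_assert(length(values) >= 2 * wf,
            "trajectory must span at least two windows")
  pg_assert(rupture_frame > wf,
            "rupture_frame must lie beyond the first window")
  unl_idx <- seq_len(wf)
  load_idx <- (rupture_frame - wf):(rupture_frame - 1L)
  pg_assert(min(load_idx) > max(unl_idx),
            "unloaded and loaded windows overlap")
  unl <- values[unl_idx]; loa <- values[load_idx]
  rng <- range(c(unl, loa), finite = TRUE)
  breaks <- seq(rng[1] - 1e-9, rng[2] + 1e-9, length.out = bins + 1)
  h1 <- graphics::hist(unl, breaks = breaks, plot = FALSE)
  h2 <- graphics::hist(loa, breaks = breaks, plot = FALSE)
  structure(list(
    unloaded = tibble(mid = h1$mids, count = h1$counts),
    loaded = tibble(mid = h2$mids, count = h2$counts),
    breaks = breaks,
    shift = mean(loa) - mean(unl),
    unloaded_values = unl, loaded_values = loa,
    window_frames = wf,
    units = if (inherits(series, "pg_metric_series"))
      attr(series, "units") else NULL),
    class = "pg_window_hist")
}

#' @export
print.pg_window_hist <- function(x, ...) {
  cat(sprintf(
    "<pg_window_hist> %d frames per window, shift = %.4g %s\n",
    x$window_frames, x$shift, x$units %||% ""))
  invisible(x)
}

# --- replica ensembles ------------------------------------------------------

#' Summarise an ensemble of pulling replicas
#'
#' Per-replica rupture force, rupture frame, loading rate and lid-metric
#' shift, grouped by pulling-geometry label, with pooled unloaded/loaded
#' metric values across replicas for ensemble histograms.
#'
#' @param replicas List of [pg_trajectory()] objects (each carrying its
#'   force series), or a tibble with columns `trajectory` (list) and
#'   optionally `label`.
#' @param pair List of two single-atom selections for the lid metric; when
#'   `NULL`, the generator's `lid_pair` metadata is used.
#' @param window_ns Window length for [window_histograms()].
#' @param fit_window_ns Loading-rate window for [smd_rupture()].
#' @param bins Histogram bins.
#' @return Tibble with one row per replica (`replica`, `label`,
#'   `rupture_force`, `rupture_frame`, `loading_rate`, `shift`); pooled
#'   window values are attached as the `pooled` attribute (a list of
#'   `unloaded`/`loaded` numeric vectors per label).
#' @export
replica_ensemble_summary <- function(replicas, pair = NULL, window_ns = 10,
                                     fit_window_ns = 10, bins = 30) {
  if (is_tibble(replicas) || is.data.frame(replicas)) {
    trajs <- replicas$trajectory
    labels <- replicas$label %||% rep("all", length(trajs))
  } else {
    trajs <- replicas
    labels <- rep("all", length(trajs))
  }
  pg_assert(length(trajs) >= 1, "need at least one replica")
  rows <- list()
  pooled <- list()
  for (k in seq_along(trajs)) {
    traj <- trajs[[k]]
    if (is.null(traj$force_pN)) {
      warn(sprintf("replica %d has no force series; skipped", k))
      next
    }
    ru <- smd_rupture(traj, fit_window_ns = fit_window_ns)
    pr <- pair %||% as.list(traj$metadata$lid_pair)
    series <- pair_distance_series(traj, pr[[1]], pr[[2]])
    shift <- NA_real_
    wf <- max(1L, round(window_ns / traj$frame_interval_ns))
    if (is.finite(ru$rupture_frame) && ru$rupture_frame > 2 * wf) {
      wh <- window_histograms(series, ru$rupture_frame, window_ns, bins)
      shift <- wh$shift
      lb <- labels[k]
      if (is.null(pooled[[lb]])) {
        pooled[[lb]] <- list(unloaded = numeric(), loaded = numeric())
      }
      pooled[[lb]]$unloaded <- c(pooled[[lb]]$unloaded, wh$unloaded_values)
      pooled[[lb]]$loaded <- c(pooled[[lb]]$loaded, wh$loaded_values)
    }
    rows[[length(rows) + 1L]] <- mutate(ru, replica = k, label = labels[k],
                                        shift = shift, .before = 1)
  }
  out <- bind_rows(rows)
  attr(out, "pooled") <- pooled
  out
}
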