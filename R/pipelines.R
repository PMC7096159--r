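# --- unit helpers -----------------------------------------------------------

#' Convert an MD spring constant to SI units
#'
#' 1 kcal/(mol Angstrom^2) = 4184 J / (N_A * 1e-20 m^2) = 0.69 N/m, the
#' conversion between the steered-MD pulling spring stiffness and the
#' AFM-style spring constant.
#'
#' @param k_kcal_mol_A2 Spring constant in kcal/(mol Angstrom^2).
#' @return Spring constant in N/m.
#' @examples
#' spring_constant_si(1.0)  # 0.69 N/m
#' @export
spring_constant_si <- function(k_kcal_mol_A2) {
  k_kcal_mol_A2 * 4184 / (6.02214076e23 * 1e-20)
}

#' Plan summary of a wide-sampling pulling campaign
#'
#' Bookkeeping of a replica-based steered-MD campaign: per-geometry and
#' total simulation time. The canonical wide-sampling design probes 4
#' pulling geometries with 100 replicas of 80 ns each, i.e. 32 us of
#' production pulling in total.
#'
#' @param n_geometries Number of pulling geometries. Default 4.
#' @param replicas_per_geometry Replicas per geometry. Default 100.
#' @param ns_per_replica Simulated time per replica, ns. Default 80.
#' @return Tibble with one row per geometry and the totals as attributes
#'   `total_ns` and `total_us`.
#' @examples
#' attr(smd_plan(), "total_us")  # 32
#' @export
smd_plan <- function(n_geometries = 4, replicas_per_geometry = 100,
                     ns_per_replica = 80) {
  pg_assert(n_geometries >= 1 && replicas_per_geometry >= 1 &&
              ns_per_replica > 0, "plan quantities must be positive")
  plan <- tibble(geometry = paste0("geometry_", seq_len(n_geometries)),
                 replicas = replicas_per_geometry,
                 ns_per_replica = ns_per_replica,
                 ns_total = replicas_per_geometry * ns_per_replica)
  attr(plan, "total_ns") <- sum(plan$ns_total)
  attr(plan, "total_us") <- sum(plan$ns_total) / 1000
  plan
}

# --- SMFS pipeline ----------------------------------------------------------

#' End-to-end analysis of an SMFS trace set
#'
#' The full retraction-curve chain: interaction filter (default 50 pN),
#' zero points, denoising, contour-length transform, unfolding-event
#' detection, fingerprint classification, rupture extraction, and
#' per-spot Bell-Evans mixture fits (BIC-selected order unless forced).
#' Record counts are logged at every stage.
#'
#' @param trace_set Trace-set tibble (from [generate_variant_dataset()],
#'   [read_trace_set()], or equivalent: columns `trace_id`, `spot_label`,
#'   `trace`).
#' @param config A [default_config()]-style configuration.
#' @param fit Fit mixtures per spot? Set `FALSE` to stop at the rupture
#'   table.
#' @return List of class `pg_smfs_result`: `rupture_events` (tibble, one
#'   row per analysed trace), `fits` (named list of `pg_mixture_fit` per
#'   spot, fingerprint-valid events only), `counts` (stage log),
#'   `config_hash`.
#' @export
pipeline_smfs <- function(trace_set, config = default_config(),
                          fit = TRUE) {
  config <- validate_config(config)
  pg_assert(is.data.frame(trace_set) && nrow(trace_set) > 0 &&
              "trace" %in% names(trace_set),
            "trace_set must be a nonempty tibble with a trace column")
  ta <- config$trace_analysis
  counts <- list(tibble(stage = "input", n_in = nrow(trace_set),
                        n_out = nrow(trace_set)))
  kept <- filter_traces(trace_set, ta$force_threshold,
                        smooth_window = ta$denoise_window)
  counts[[2]] <- tibble(stage = "force_filter", n_in = nrow(trace_set),
                        n_out = nrow(kept))
  rows <- map(seq_len(nrow(kept)), function(i) {
    res <- analyze_trace(kept$trace[[i]], Lp = ta$Lp, kBT = ta$kBT,
                         min_force = ta$min_force,
                         denoise_window = ta$denoise_window,
                         expected_delta_Lcs = ta$expected_delta_Lcs,
                         tolerance = ta$tolerance,
                         min_peak_force = ta$min_peak_force,
                         min_delta_Lc = ta$min_delta_Lc,
                         drop_fraction = ta$drop_fraction,
                         flank_threshold = ta$flank_threshold)
    mutate(res,
           trace_id = kept$trace_id[i] %||% as.character(i),
           spot_label = kept$spot_label[i] %||% "all", .before = 1)
  })
  events <- bind_rows(rows)
  valid <- filter(events, .data$valid)
  counts[[3]] <- tibble(stage = "rupture_extraction", n_in = nrow(kept),
                        n_out = nrow(valid))
  specific <- filter(valid, .data$fingerprint_valid)
  counts[[4]] <- tibble(stage = "fingerprint_filter", n_in = nrow(valid),
                        n_out = nrow(specific))
  fits <- list()
  if (fit && nrow(specific) >= 50) {
    rs <- config$rupture_stats
    for (spot in unique(specific$spot_label)) {
      f <- filter(specific, .data$spot_label == spot)
      if (nrow(f) < 50) next
      fits[[spot]] <- fit_mixture(f$rupture_force,
                                  median(f$loading_rate, na.rm = TRUE),
                                  n_components = rs$n_components,
                                  n_starts = rs$n_starts, seed = rs$seed,
                                  kBT = ta$kBT)
    }
  }
  structure(list(rupture_events = events,
                 fits = fits,
                 counts = bind_rows(counts),
                 config_hash = config_hash(config)),
            class = "pg_smfs_result")
}

#' @export
print.pg_smfs_result <- function(x, ...) {
  cat("<pg_smfs_result>\n")
  print(as.data.frame(x$counts))
  if (length(x$fits)) {
    cat(sprintf("fits: %s\n", paste(names(x$fits), collapse = ", ")))
  }
  invisible(x)
}

# --- SMD pipeline -----------------------------------------------------------

#' End-to-end analysis of a steered-pulling replica ensemble
#'
#' Per-replica rupture statistics and lid-metric window histograms
#' (pooled per pulling-geometry label), plus pooled force-propagation
#' edge usage from windowed dynamical network analysis of each replica.
#' Replicas without a force series are skipped with a warning.
#'
#' @param replicas Tibble with columns `trajectory` (list of
#'   [pg_trajectory()]) and optionally `label`, or a plain list of
#'   trajectories.
#' @param config A [default_config()]-style configuration.
#' @param pair Lid-metric atom pair (see [replica_ensemble_summary()]).
#' @param network Run the network stage? Needs `source`/`sink`.
#' @param source,sink Node selections for [windowed_network_analysis()].
#' @return List of class `pg_smd_result`: `replica_table`, `pooled`
#'   (per-label unloaded/loaded metric values), `edge_usage` (pooled over
#'   replicas and windows; `NULL` when the network stage is off),
#'   `config_hash`.
#' @export
pipeline_smd <- function(replicas, config = default_config(), pair = NULL,
                         network = FALSE, source = NULL, sink = NULL) {
  config <- validate_config(config)
  tj <- config$trajectory
  summary <- replica_ensemble_summary(replicas, pair = pair,
                                      window_ns = tj$window_ns,
                                      fit_window_ns = tj$fit_window_ns,
                                      bins = tj$bins)
  edge_usage <- NULL
  if (network) {
    pg_assert(!is.null(source) && !is.null(sink),
              "network stage needs source and sink nodes")
    nw <- config$network
    trajs <- if (is.data.frame(replicas)) replicas$trajectory else replicas
    pooled <- tibble(from = integer(), to = integer(), count = integer())
    for (traj in trajs) {
      if (is.null(traj$force_pN)) next
      res <- windowed_network_analysis(traj, source, sink,
                                       window_ns = tj$window_ns,
                                       stride_ns = tj$stride_ns,
                                       tolerance = nw$tolerance,
                                       max_paths = nw$max_paths,
                                       cutoff = nw$cutoff,
                                       min_fraction = nw$min_fraction)
      pooled <- bind_rows(pooled, res$pooled_edge_usage)
    }
    edge_usage <- arrange(
      summarise(group_by(pooled, .data$from, .data$to),
                count = sum(.data$count), .groups = "drop"),
      dplyr::desc(.data$count))
  }
  structure(list(replica_table = summary,
                 pooled = attr(summary, "pooled"),
                 edge_usage = edge_usage,
                 config_hash = config_hash(config)),
            class = "pg_smd_result")
}

#' @export
print.pg_smd_result <- function(x, ...) {
  cat(sprintf("<pg_smd_result> %d replica(s)\n", nrow(x$replica_table)))
  print(as.data.frame(x$replica_table), digits = 4)
  invisible(x)
}

#' Write an SMFS results bundle to disk
#'
#' The rupture table goes to tab-delimited text, the mixture fits and
#' stage counts to JSON, all stamped with the configuration hash.
#'
#' @param result A `pg_smfs_result`.
#' @param dir Output directory.
#' @return Named file paths, invisibly.
#' @export
write_smfs_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rupture_path <- file.path(dir, "rupture_events.tsv")
  utils::write.table(as.data.frame(result$rupture_events), rupture_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  fits <- map(result$fits, function(f)
    list(components = as.data.frame(f$components),
         n_components = f$n_components, loading_rate = f$loading_rate,
         log_likelihood = f$log_likelihood, bic = f$bic,
         converged = f$converged))
  json_path <- file.path(dir, "fits.json")
  jsonlite::write_json(list(config_hash = result$config_hash,
                            counts = as.data.frame(result$counts),
                            fits = fits),
                       json_path, auto_unbox = TRUE, digits = NA)
  invisible(list(rupture_events = rupture_path, fits = json_path))
}
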