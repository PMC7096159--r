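# --- trace IO ---------------------------------------------------------------

#' Write / read a force-extension trace
#'
#' A trace is stored as tab-delimited text with columns `time_s`,
#' `extension_nm`, `force_pN` plus a JSON sidecar (`<path>.json`) holding
#' the acquisition metadata and the event log; the round trip is lossless
#' to full double precision.
#'
#' @param trace An [fe_trace()].
#' @param path File path for the delimited text (sidecar written next to
#'   it).
#' @return `write_trace()`: the path, invisibly. `read_trace()`: an
#'   [fe_trace()].
#' @export
write_trace <- function(trace, path) {
  df <- as.data.frame(trace[, c("time_s", "extension_nm", "force_pN")])
  utils::write.table(format(df, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- list(metadata = trace_metadata(trace),
               events = trace_events(trace))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  need <- c("time_s", "extension_nm", "force_pN")
  if (!all(need %in% names(df))) {
    abort(sprintf("trace file %s is missing column(s): %s", path,
                  paste(setdiff(need, names(df)), collapse = ", ")),
          class = "pullgeom_parse_error")
  }
  bad <- which(diff(df$time_s) <= 0)
  if (length(bad)) {
    abort(sprintf("non-monotone time in %s at line %d", path, bad[1] + 2L),
          class = "pullgeom_parse_error")
  }
  meta <- list(); events <- NULL
  side_path <- paste0(path, ".json")
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    meta <- side$metadata
    if (!is.null(side$events) && length(side$events)) {
      events <- as_tibble(side$events)
    }
  }
  fe_trace(df$time_s, df$extension_nm, df$force_pN, metadata = meta,
           events = events)
}

#' Write / read a trace set directory
#'
#' A trace set is a directory of per-trace files plus a `manifest.json`
#' listing trace ids, file names and labels. `trace_set_manifest()` reads
#' only the manifest, so large sets can be iterated lazily, loading one
#' trace at a time with [read_trace()].
#'
#' @param trace_set Trace-set tibble (see [generate_variant_dataset()]).
#' @param dir Directory (created if needed).
#' @return `write_trace_set()`: `dir`, invisibly. `trace_set_manifest()`:
#'   a tibble with `trace_id`, `file`, `spot_label`, `subunit`,
#'   `fingerprint_true`. `read_trace_set()`: the full trace-set tibble.
#' @export
write_trace_set <- function(trace_set, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("trace_%05d.tsv", seq_len(nrow(trace_set)))
  for (i in seq_len(nrow(trace_set))) {
    write_trace(trace_set$trace[[i]], file.path(dir, files[i]))
  }
  manifest <- as.data.frame(
    trace_set[, setdiff(names(trace_set), "trace")])
  manifest$file <- files
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_trace_set
#' @export
trace_set_manifest <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  pg_assert(file.exists(mf), sprintf("no manifest.json in %s", dir))
  as_tibble(jsonlite::read_json(mf, simplifyVector = TRUE))
}

#' @rdname write_trace_set
#' @export
read_trace_set <- function(dir) {
  manifest <- trace_set_manifest(dir)
  manifest$trace <- map(manifest$file, function(f)
    read_trace(file.path(dir, f)))
  manifest
}

# --- trajectory IO ----------------------------------------------------------

#' Write / read a trajectory as PDB topology plus multi-frame XYZ
#'
#' The topology (atom names, residues, chains; first-frame coordinates)
#' is written as PDB via bio3d; all frames go into a plain multi-frame
#' XYZ file (per frame: atom count, comment, then `element x y z` lines,
#' 6 decimals); the applied-force series, when present, into a
#' tab-delimited text file; ground-truth metadata into JSON. DCD frames
#' can be read instead of XYZ via the `dcd` argument.
#'
#' @param traj A [pg_trajectory()].
#' @param dir Output directory.
#' @param name Basename for the files. Default "traj".
#' @return `write_trajectory()`: named file paths, invisibly.
#' @export
write_trajectory <- function(traj, dir, name = "traj") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pdb_path <- file.path(dir, paste0(name, ".pdb"))
  xyz_path <- file.path(dir, paste0(name, ".xyz"))
  at <- traj$atoms
  x1 <- traj$coords[1, , , drop = TRUE]
  bio3d::write.pdb(file = pdb_path,
                   xyz = as.numeric(t(x1)),
                   type = rep("ATOM", nrow(at)),
                   resno = at$resid, resid = at$resname,
                   chain = at$chain, elety = at$name,
                   elesy = at$element)
  con <- file(xyz_path, "w")
  on.exit(close(con), add = TRUE)
  nf <- n_frames(traj)
  for (f in seq_len(nf)) {
    writeLines(c(as.character(nrow(at)), sprintf("frame %d", f)), con)
    writeLines(sprintf("%s %.6f %.6f %.6f", at$element,
                       traj$coords[f, , 1], traj$coords[f, , 2],
                       traj$coords[f, , 3]), con)
  }
  paths <- list(pdb = pdb_path, xyz = xyz_path)
  if (!is.null(traj$force_pN)) {
    force_path <- file.path(dir, paste0(name, "_force.tsv"))
    utils::write.table(
      format(data.frame(frame = seq_len(nf),
                        time_ns = (seq_len(nf) - 1) * traj$frame_interval_ns,
                        force_pN = traj$force_pN),
             digits = 17, scientific = TRUE, trim = TRUE),
      force_path, sep = "\t", quote = FALSE, row.names = FALSE)
    paths$force <- force_path
  }
  meta_path <- file.path(dir, paste0(name, ".json"))
  jsonlite::write_json(
    c(traj$metadata, list(frame_interval_ns = traj$frame_interval_ns)),
    meta_path, auto_unbox = TRUE, digits = NA, null = "null")
  paths$metadata <- meta_path
  invisible(paths)
}

read_xyz_frames <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    na <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(na)) abort(sprintf("malformed XYZ atom count at line %d", i),
                         class = "pullgeom_parse_error")
    block <- lines[(i + 2L):(i + 1L + na)]
    parts <- strsplit(trimws(block), "\\s+")
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    frames[[length(frames) + 1L]] <- xyz
    i <- i + 2L + na
  }
  frames
}

#' @rdname write_trajectory
#' @param pdb_path Path to the PDB topology.
#' @param xyz_path Path to the multi-frame XYZ file (or `NULL` with
#'   `dcd`).
#' @param force_path Optional path to the force-series TSV.
#' @param metadata_path Optional path to the metadata JSON.
#' @param dcd Optional path to a DCD trajectory (read via bio3d) used in
#'   place of XYZ.
#' @param frame_interval_ns Frame spacing; overridden by the metadata
#'   JSON when present.
#' @export
read_trajectory <- function(pdb_path, xyz_path = NULL, force_path = NULL,
                            metadata_path = NULL, dcd = NULL,
                            frame_interval_ns = 0.4) {
  pdb <- bio3d::read.pdb(pdb_path)
  at <- pdb$atom
  atoms <- tibble(name = trimws(at$elety),
                  element = trimws(ifelse(is.na(at$elesy) |
                                            at$elesy == "",
                                          substr(trimws(at$elety), 1, 1),
                                          at$elesy)),
                  resname = trimws(at$resid), resid = at$resno,
                  chain = ifelse(is.na(at$chain), "A", at$chain))
  if (!is.null(dcd)) {
    m <- bio3d::read.dcd(dcd, verbose = FALSE)
    nf <- nrow(m)
    coords <- array(NA_real_, dim = c(nf, nrow(atoms), 3))
    for (f in seq_len(nf)) {
      coords[f, , ] <- matrix(m[f, ], ncol = 3, byrow = TRUE)
    }
  } else {
    pg_assert(!is.null(xyz_path), "either xyz_path or dcd is required")
    frames <- read_xyz_frames(xyz_path)
    nf <- length(frames)
    nat <- vapply(frames, nrow, integer(1))
    if (any(nat != nrow(atoms))) {
      abort(sprintf(
        "atom count mismatch: PDB has %d atoms, XYZ frames have %d",
        nrow(atoms), nat[which(nat != nrow(atoms))[1]]),
        class = "pullgeom_parse_error")
    }
    coords <- array(NA_real_, dim = c(nf, nrow(atoms), 3))
    for (f in seq_len(nf)) coords[f, , ] <- frames[[f]]
  }
  force <- NULL
  if (!is.null(force_path)) {
    force <- utils::read.table(force_path, header = TRUE, sep = "\t")$force_pN
  }
  metadata <- list()
  if (!is.null(metadata_path) && file.exists(metadata_path)) {
    metadata <- jsonlite::read_json(metadata_path, simplifyVector = TRUE)
    if (!is.null(metadata$frame_interval_ns)) {
      frame_interval_ns <- metadata$frame_interval_ns
    }
  }
  pg_trajectory(coords, atoms, frame_interval_ns, force_pN = force,
                metadata = metadata)
}

# --- run configuration ------------------------------------------------------

#' Default run configuration
#'
#' All stage parameters of the two pipelines in one schema-versioned
#' nested list. Defaults are the canonical analysis settings: 50 pN
#' interaction filter, 4.5 Angstrom / 75% contact criterion, path
#' tolerance -log(0.5), 10-ns windows sampled every 400 ps, 800 nm/s
#' retraction sampled at 12,000 Hz over 350 nm, 0.15 N/m cantilever.
#'
#' @return Nested named list of class `pg_config`.
#' @export
default_config <- function() {
  structure(list(
    schema_version = 1L,
    acquisition = list(retract_velocity = 800, sampling_rate = 12000,
                       retract_distance = 350, force_noise_sd = 3,
                       cantilever_stiffness = 0.15),
    trace_analysis = list(force_threshold = 50, denoise_window = 11,
                          Lp = 0.38, kBT = KBT_300K, min_force = 10,
                          min_peak_force = 20, min_delta_Lc = 4,
                          drop_fraction = 0.25,
                          expected_delta_Lcs = c(15, 16), tolerance = 2,
                          flank_threshold = 0.75),
    rupture_stats = list(n_components = NULL, n_starts = 10, seed = 1),
    trajectory = list(window_ns = 10, stride_ns = 0.4,
                      fit_window_ns = 10, bins = 30),
    network = list(cutoff = 4.5, min_fraction = 0.75,
                   tolerance = 0.6931471805599453, max_paths = 10000)
  ), class = "pg_config")
}

#' Validate, read and write run configurations
#'
#' `validate_config()` checks a configuration against the
#' [default_config()] schema: unknown keys are rejected, missing keys are
#' filled with defaults.
#'
#' @param config Nested list (e.g. from `read_config()`).
#' @param path JSON file path.
#' @return `validate_config()`/`read_config()`: a complete `pg_config`.
#' @export
validate_config <- function(config) {
  ref <- default_config()
  pg_assert(is.list(config), "config must be a list")
  unknown <- setdiff(names(config), names(ref))
  pg_assert(!length(unknown),
            paste("unknown config key(s):", paste(unknown, collapse = ", ")))
  out <- ref
  for (sec in names(config)) {
    if (sec == "schema_version") {
      out$schema_version <- config$schema_version
      next
    }
    unknown <- setdiff(names(config[[sec]]), names(ref[[sec]]))
    pg_assert(!length(unknown),
              sprintf("unknown config key(s) in %s: %s", sec,
                      paste(unknown, collapse = ", ")))
    for (k in names(config[[sec]])) out[[sec]][[k]] <- config[[sec]][[k]]
  }
  out
}

#' @rdname validate_config
#' @export
read_config <- function(path) {
  validate_config(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname validate_config
#' @param config A `pg_config`.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Hash of a run configuration
#'
#' Stable digest carried into every results bundle so outputs can be tied
#' to the exact configuration that produced them.
#'
#' @param config A `pg_config`.
#' @return Character md5 digest.
#' @export
config_hash <- function(config) {
  # hash the canonical JSON text so integer/double storage of the same
  # value (e.g. after a JSON round trip) hashes identically
  digest::digest(as.character(jsonlite::toJSON(unclass(config),
                                               auto_unbox = TRUE,
                                               digits = NA,
                                               null = "null")),
                 algo = "md5", serialize = FALSE)
}
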