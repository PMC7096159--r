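# shared fixtures: everything is generated in code, scaled small

# fast acquisition settings for tests that only need trace structure,
# not the full 350 nm retraction
fast_protocol <- function(noise = 3, distance = 90) {
  acquisition_protocol(retract_velocity = 800, sampling_rate = 12000,
                       retract_distance = distance, force_noise_sd = noise)
}

# tether without fingerprint substeps (single WLC segment)
plain_tether <- function(Lc = 40, Lp = 0.38) {
  tether_model(segments = data.frame(Lc = Lc, Lp = Lp),
               unfolding_steps = data.frame(delta_Lc = numeric(),
                                            k0 = numeric(),
                                            x_dagger = numeric()))
}

# positive-semidefinite correlation matrix from factor loadings: nodes
# with loading a share a common latent mode, C = aa' + diag(1 - a^2)
factor_correlation <- function(loadings) {
  C <- outer(loadings, loadings)
  diag(C) <- 1
  C
}

# trajectory with explicitly placed coordinates: coords is a list of
# per-frame n x 3 matrices
manual_trajectory <- function(frames, frame_interval_ns = 0.4,
                              names = NULL, force_pN = NULL) {
  nf <- length(frames)
  na <- nrow(frames[[1]])
  coords <- array(NA_real_, dim = c(nf, na, 3))
  for (f in seq_len(nf)) coords[f, , ] <- frames[[f]]
  atoms <- tibble::tibble(name = names %||% rep("CA", na),
                          element = "C", resname = "GLY",
                          resid = seq_len(na), chain = "A")
  pg_trajectory(coords, atoms, frame_interval_ns, force_pN = force_pN)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force simple-path enumeration oracle for suboptimal_paths():
# recursive depth-first walk with no pruning, then filter by weight
brute_force_paths <- function(W, s, t, tolerance) {
  n <- nrow(W)
  paths <- list()
  weights <- numeric()
  rec <- function(v, seen, w, cur) {
    if (v == t) {
      paths[[length(paths) + 1L]] <<- cur
      weights[length(weights) + 1L] <<- w
      return(invisible())
    }
    for (u in seq_len(n)) {
      if (u == v || seen[u] || !is.finite(W[v, u])) next
      seen[u] <- TRUE
      rec(u, seen, w + W[v, u], c(cur, u))
      seen[u] <- FALSE
    }
  }
  seen <- rep(FALSE, n)
  seen[s] <- TRUE
  rec(s, seen, 0, s)
  if (!length(paths)) {
    return(list(paths = list(), weights = numeric()))
  }
  keep <- weights <= min(weights) + tolerance + 1e-9
  ord <- order(weights[keep])
  list(paths = paths[keep][ord], weights = weights[keep][ord])
}

path_key <- function(p) paste(p, collapse = "-")

edge_usage_from_paths <- function(paths) {
  u <- list()
  for (p in paths) {
    for (e in seq_len(length(p) - 1L)) {
      a <- min(p[e], p[e + 1L]); b <- max(p[e], p[e + 1L])
      key <- paste(a, b)
      u[[key]] <- (u[[key]] %||% 0L) + 1L
    }
  }
  u
}
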