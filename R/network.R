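# --- nodes and contacts -----------------------------------------------------

#' Default network nodes of a trajectory
#'
#' One node per alpha carbon; ligand atoms can be added by name through
#' `extra_atoms` (e.g. the three biotin/linker atoms of the
#' streptavidin-biotin analysis; the atom choice is configuration).
#'
#' @param traj A [pg_trajectory()].
#' @param extra_atoms Optional tibble/data.frame with [select_atom()]
#'   argument columns, one row per extra node.
#' @return Tibble of nodes: `atom` (index), `label`, `resid`, `chain`.
#' @export
default_nodes <- function(traj, extra_atoms = NULL) {
  at <- traj$atoms
  idx <- which(at$name == "CA")
  nodes <- tibble(atom = idx,
                  label = sprintf("%s%d", at$chain[idx], at$resid[idx]),
                  resid = at$resid[idx], chain = at$chain[idx])
  if (!is.null(extra_atoms)) {
    extra_atoms <- as.data.frame(extra_atoms)
    for (r in seq_len(nrow(extra_atoms))) {
      i <- do.call(select_atom, c(list(traj), as.list(extra_atoms[r, ])))
      nodes <- bind_rows(nodes, tibble(
        atom = i, label = sprintf("%s%d.%s", at$chain[i], at$resid[i],
                                  at$name[i]),
        resid = at$resid[i], chain = at$chain[i]))
    }
  }
  nodes
}

# atom groups backing each node for the contact criterion: all heavy atoms
# of the node's residue when the residue hosts a single node, else the
# node atom alone
node_contact_groups <- function(traj, nodes, heavy_only = TRUE) {
  at <- traj$atoms
  res_key <- paste(at$chain, at$resid)
  node_key <- paste(nodes$chain, nodes$resid)
  per_res <- table(node_key)
  map(seq_len(nrow(nodes)), function(k) {
    if (per_res[[node_key[k]]] == 1L) {
      g <- which(res_key == node_key[k])
      if (heavy_only) g <- g[toupper(at$element[g]) != "H"]
      if (!length(g)) g <- nodes$atom[k]
      g
    } else {
      nodes$atom[k]
    }
  })
}

#' Contact map between network nodes
#'
#' Two nodes are in contact when the minimum distance between any heavy
#' (non-hydrogen) atoms of their residues is within `cutoff` in at least
#' `min_fraction` of the frames analysed. Defaults: 4.5 Angstrom and 75%.
#'
#' @param traj A [pg_trajectory()].
#' @param nodes Node table from [default_nodes()] (default).
#' @param cutoff Distance criterion, Angstrom (> 0).
#' @param min_fraction Minimum fraction of frames (0 < f <= 1).
#' @param frames Optional frame indices to analyse.
#' @param heavy_only Restrict the criterion to non-hydrogen atoms.
#' @param exclude_bonded Drop sequence-adjacent residue pairs (same chain,
#'   |resid difference| == 1). Default FALSE: they are kept.
#' @return Symmetric logical adjacency matrix (nodes x nodes), with the
#'   per-pair contact fractions as attribute `fraction`.
#' @export
contact_map <- function(traj, nodes = default_nodes(traj), cutoff = 4.5,
                        min_fraction = 0.75, frames = NULL,
                        heavy_only = TRUE, exclude_bonded = FALSE) {
  pg_assert(cutoff > 0, "cutoff must be positive")
  pg_assert(min_fraction > 0 && min_fraction <= 1,
            "min_fraction must be in (0, 1]")
  pg_assert(nrow(nodes) >= 2, "need at least two nodes")
  frames <- frames %||% seq_len(n_frames(traj))
  groups <- node_contact_groups(traj, nodes, heavy_only)
  nn <- nrow(nodes)
  within <- matrix(0L, nn, nn)
  for (f in frames) {
    xyz <- traj$coords[f, , , drop = TRUE]
    d <- as.matrix(stats::dist(xyz))
    for (i in seq_len(nn - 1)) {
      gi <- groups[[i]]
      for (j in (i + 1):nn) {
        mind <- min(d[gi, groups[[j]]])
        if (mind <= cutoff) {
          within[i, j] <- within[i, j] + 1L
        }
      }
    }
  }
  frac <- (within + t(within)) / length(frames)
  adj <- frac >= min_fraction
  diag(adj) <- FALSE
  if (exclude_bonded) {
    same_chain <- outer(nodes$chain, nodes$chain, "==")
    neighbor <- abs(outer(nodes$resid, nodes$resid, "-")) == 1
    adj[same_chain & neighbor] <- FALSE
  }
  dimnames(adj) <- list(nodes$label, nodes$label)
  attr(adj, "fraction") <- frac
  adj
}

# --- correlation ------------------------------------------------------------

#' Motional correlation matrix of network nodes
#'
#' Pearson-type correlation of node displacements about their window mean:
#' \deqn{C_{ij} = \langle \Delta r_i \cdot \Delta r_j \rangle /
#'   \sqrt{\langle |\Delta r_i|^2 \rangle \langle |\Delta r_j|^2 \rangle}}
#' with the 3-D dot-product convention (one scalar per pair). A strict
#' per-axis Pearson variant (averaged over axes) is available via
#' `method = "per_axis"`.
#'
#' @param traj A [pg_trajectory()].
#' @param nodes Node table ([default_nodes()] by default).
#' @param frames Optional frame indices (>= 3 required).
#' @param method `"dot3d"` (default) or `"per_axis"`.
#' @return Symmetric correlation matrix with unit diagonal; pairs
#'   involving a zero-variance node are `NA` (with a warning).
#' @export
correlation_matrix <- function(traj, nodes = default_nodes(traj),
                               frames = NULL, method = c("dot3d",
                                                         "per_axis")) {
  method <- match.arg(method)
  frames <- frames %||% seq_len(n_frames(traj))
  pg_assert(length(frames) >= 3, "need at least 3 frames for a correlation")
  nn <- nrow(nodes)
  X <- map(1:3, function(ax) {
    m <- traj$coords[frames, nodes$atom, ax, drop = TRUE]
    m <- matrix(m, nrow = length(frames))
    sweep(m, 2, colMeans(m))
  })
  if (method == "dot3d") {
    num <- crossprod(X[[1]]) + crossprod(X[[2]]) + crossprod(X[[3]])
    v <- diag(num)
    zero <- v < 1e-20
    C <- num / sqrt(outer(v, v))
  } else {
    C <- matrix(0, nn, nn)
    for (ax in 1:3) {
      num <- crossprod(X[[ax]])
      v <- diag(num)
      C <- C + num / sqrt(outer(pmax(v, 1e-300), pmax(v, 1e-300)))
    }
    C <- C / 3
    zero <- map_lgl(seq_len(nn), function(i)
      sum(vapply(X, function(m) stats::var(m[, i]), numeric(1))) < 1e-20)
  }
  if (any(zero)) {
    warn("zero-variance node(s): correlations flagged NA")
    C[zero, ] <- NA_real_
    C[, zero] <- NA_real_
  }
  diag(C) <- 1
  C <- pmin(pmax(C, -1), 1)
  dimnames(C) <- list(nodes$label, nodes$label)
  C
}

# --- network ----------------------------------------------------------------

#' Edge weight of the information-transfer network
#'
#' The probability of information (force) transfer across an edge is
#' encoded as \eqn{w_{ij} = -\log(|C_{ij}|)}: perfectly correlated nodes
#' communicate at zero cost, uncorrelated nodes at infinite cost. Natural
#' logarithm; `edge_weight(0.5)` is 0.69, the canonical suboptimal-path
#' tolerance.
#'
#' @param correlation Correlation value(s) in `[-1, 1]`.
#' @return Nonnegative weight(s).
#' @export
edge_weight <- function(correlation) {
  pg_assert(all(abs(correlation) <= 1 + 1e-12),
            "correlations must lie in [-1, 1]")
  -log(pmin(abs(correlation), 1))
}

#' Build a correlation-weighted contact network
#'
#' Combines a contact adjacency with a correlation matrix: edges exist
#' where the adjacency is true and `|C| > 0`, weighted by
#' [edge_weight()]. Contact edges with zero correlation (infinite weight)
#' are dropped with a warning. All weights are nonnegative, so shortest
#' paths are well defined (no negative cycles).
#'
#' @param adjacency Logical adjacency matrix from [contact_map()].
#' @param C Correlation matrix from [correlation_matrix()].
#' @param nodes Optional node table carried along.
#' @return Object of class `pg_network`: `nodes`, `adjacency`,
#'   `correlation`, `weights` (matrix, `Inf` off-edge), `edges` tibble
#'   (`from`, `to`, `correlation`, `weight`).
#' @export
build_network <- function(adjacency, C, nodes = NULL) {
  pg_assert(all(dim(adjacency) == dim(C)),
            "adjacency and correlation shapes must match")
  nn <- nrow(C)
  dropped <- which(adjacency & !is.na(C) & abs(C) == 0, arr.ind = TRUE)
  if (nrow(dropped)) {
    warn(sprintf(
      "%d contact edge(s) with zero correlation dropped (infinite weight)",
      nrow(dropped) / 2))
  }
  W <- matrix(Inf, nn, nn, dimnames = dimnames(C))
  on_edge <- adjacency & !is.na(C) & abs(C) > 0
  W[on_edge] <- edge_weight(C[on_edge])
  diag(W) <- 0
  pg_assert(all(W[is.finite(W)] >= 0), "edge weights must be nonnegative")
  ut <- which(upper.tri(W) & is.finite(W) & on_edge, arr.ind = TRUE)
  edges <- tibble(from = ut[, 1], to = ut[, 2],
                  correlation = C[ut], weight = W[ut])
  structure(list(nodes = nodes, adjacency = on_edge, correlation = C,
                 weights = W, edges = edges, n = nn),
            class = "pg_network")
}

#' @export
print.pg_network <- function(x, ...) {
  cat(sprintf("<pg_network> %d nodes, %d edges\n", x$n, nrow(x$edges)))
  invisible(x)
}

# Floyd-Warshall all-pairs shortest path distances (dense, vectorised)
floyd_warshall <- function(W) {
  D <- W
  diag(D) <- 0
  for (k in seq_len(nrow(D))) {
    Dk <- outer(D[, k], D[k, ], "+")
    D <- pmin(D, Dk)
  }
  D
}

#' Optimal and suboptimal force-propagation paths
#'
#' Finds the minimum-weight simple path from `source` to `sink` and every
#' simple path whose total weight lies within `tolerance` of it. All-pairs
#' distances from the Floyd-Warshall algorithm prune a depth-first
#' enumeration: a partial path is abandoned as soon as its weight plus the
#' shortest remaining distance exceeds the optimum plus the tolerance.
#' Per-edge usage counts over the returned ensemble measure how likely
#' force transfer across each edge is. The canonical tolerance is
#' `-log(0.5)` = 0.69.
#'
#' @param net A [build_network()] object.
#' @param source,sink Node indices or labels.
#' @param tolerance Weight tolerance (>= 0). Default `edge_weight(0.5)`.
#' @param max_paths Enumeration cap; exceeding it truncates the ensemble
#'   with a warning. Default 10000.
#' @return Object of class `pg_path_ensemble`: `paths` (tibble of
#'   node-vector list-column and weights, optimal first), `optimal_path`,
#'   `optimal_weight`, `edge_usage` (tibble `from`, `to`, `count`),
#'   `flagged` (disconnected), `truncated`.
#' @export
suboptimal_paths <- function(net, source, sink,
                             tolerance = edge_weight(0.5),
                             max_paths = 10000) {
  pg_assert(inherits(net, "pg_network"), "net must be a pg_network")
  pg_assert(tolerance >= 0, "tolerance must be nonnegative")
  lab <- rownames(net$weights)
  to_idx <- function(v) {
    if (is.character(v)) match(v, lab) else as.integer(v)
  }
  s <- to_idx(source); t <- to_idx(sink)
  pg_assert(!is.na(s) && !is.na(t) && s >= 1 && t >= 1 && s <= net$n &&
              t <= net$n, "source and sink must be nodes of the network")
  W <- net$weights
  D <- floyd_warshall(W)
  if (!is.finite(D[s, t])) {
    return(structure(list(source = s, sink = t, paths = tibble(
      path = list(), weight = numeric()), optimal_path = integer(),
      optimal_weight = NA_real_,
      edge_usage = tibble(from = integer(), to = integer(),
                          count = integer()),
      tolerance = tolerance, flagged = TRUE, truncated = FALSE),
      class = "pg_path_ensemble"))
  }
  budget <- D[s, t] + tolerance + 1e-9
  nbrs <- map(seq_len(net$n), function(i)
    which(is.finite(W[i, ]) & seq_len(net$n) != i))
  paths <- list()
  weights <- numeric()
  truncated <- FALSE
  visited <- rep(FALSE, net$n)
  walk <- function(v, cur, w) {
    if (truncated) return(invisible())
    if (v == t) {
      paths[[length(paths) + 1L]] <<- cur
      weights[length(weights) + 1L] <<- w
      if (length(paths) >= max_paths) truncated <<- TRUE
      return(invisible())
    }
    for (u in nbrs[[v]]) {
      if (visited[u]) next
      w2 <- w + W[v, u]
      if (w2 + D[u, t] > budget) next
      visited[u] <<- TRUE
      walk(u, c(cur, u), w2)
      visited[u] <<- FALSE
      if (truncated) return(invisible())
    }
    invisible()
  }
  visited[s] <- TRUE
  walk(s, s, 0)
  if (truncated) {
    warn(sprintf("suboptimal path enumeration truncated at %d paths",
                 max_paths))
  }
  ord <- order(weights)
  paths <- paths[ord]
  weights <- weights[ord]
  usage <- list()
  for (p in paths) {
    for (e in seq_len(length(p) - 1L)) {
      a <- min(p[e], p[e + 1L]); b <- max(p[e], p[e + 1L])
      key <- paste(a, b)
      usage[[key]] <- (usage[[key]] %||% 0L) + 1L
    }
  }
  eu <- if (length(usage)) {
    ab <- do.call(rbind, lapply(strsplit(names(usage), " "), as.integer))
    tibble(from = ab[, 1], to = ab[, 2],
           count = unlist(usage, use.names = FALSE))
  } else tibble(from = integer(), to = integer(), count = integer())
  structure(list(source = s, sink = t,
                 paths = tibble(path = paths, weight = weights),
                 optimal_path = if (length(paths)) paths[[1]] else integer(),
                 optimal_weight = if (length(weights)) weights[1] else
                   NA_real_,
                 edge_usage = arrange(eu, dplyr::desc(.data$count)),
                 tolerance = tolerance, flagged = FALSE,
                 truncated = truncated),
            class = "pg_path_ensemble")
}

#' @export
print.pg_path_ensemble <- function(x, ...) {
  if (x$flagged) {
    cat("<pg_path_ensemble> source and sink disconnected\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<pg_path_ensemble> %d path(s) within %.3g of optimum %.4g%s\n",
    nrow(x$paths), x$tolerance, x$optimal_weight,
    if (x$truncated) " [truncated]" else ""))
  invisible(x)
}

#' Windowed dynamical network analysis of a trajectory
#'
#' Splits a trajectory into consecutive windows (default 10 ns), resamples
#' frames within each window at a fixed stride (default 0.4 ns, i.e. 25
#' frames per window), and runs the contact map, correlation matrix and
#' suboptimal-path stages per window. Edge usage is pooled over windows.
#'
#' @param traj A [pg_trajectory()].
#' @param source,sink Node indices or labels.
#' @param nodes Node table; [default_nodes()] by default.
#' @param window_ns,stride_ns Window length and intra-window sampling
#'   stride, ns; `stride_ns` must not exceed `window_ns`.
#' @param tolerance,max_paths Passed to [suboptimal_paths()].
#' @param cutoff,min_fraction Passed to [contact_map()].
#' @return List: `windows` (list of per-window `pg_path_ensemble`),
#'   `pooled_edge_usage` (tibble `from`, `to`, `count` summed over
#'   windows), `n_windows`, `frames_per_window`.
#' @export
windowed_network_analysis <- function(traj, source, sink,
                                      nodes = default_nodes(traj),
                                      window_ns = 10, stride_ns = 0.4,
                                      tolerance = edge_weight(0.5),
                                      max_paths = 10000, cutoff = 4.5,
                                      min_fraction = 0.75) {
  pg_assert(stride_ns <= window_ns, "stride must not exceed the window")
  dt <- traj$frame_interval_ns
  wf <- max(1L, round(window_ns / dt))
  stride_f <- max(1L, round(stride_ns / dt))
  nf <- n_frames(traj)
  pg_assert(nf >= wf, "trajectory must span at least one window")
  starts <- seq(1L, nf - wf + 1L, by = wf)
  ensembles <- list()
  pooled <- tibble(from = integer(), to = integer(), count = integer())
  for (w in seq_along(starts)) {
    frames <- seq(starts[w], starts[w] + wf - 1L, by = stride_f)
    adj <- contact_map(traj, nodes, cutoff = cutoff,
                       min_fraction = min_fraction, frames = frames)
    C <- correlation_matrix(traj, nodes, frames = frames)
    net <- build_network(adj, C, nodes)
    pe <- suboptimal_paths(net, source, sink, tolerance = tolerance,
                           max_paths = max_paths)
    ensembles[[w]] <- pe
    if (nrow(pe$edge_usage)) {
      pooled <- bind_rows(pooled, pe$edge_usage)
    }
  }
  pooled <- summarise(group_by(pooled, .data$from, .data$to),
                      count = sum(.data$count), .groups = "drop")
  list(windows = ensembles,
       pooled_edge_usage = arrange(pooled, dplyr::desc(.data$count)),
       n_windows = length(starts),
       frames_per_window = length(seq(1L, wf, by = stride_f)))
}
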