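test_that("contact criterion applies the distance cutoff and frame fraction strictly", {
  # two nodes fixed 4.0 apart in every frame: contact at 4.5 / 0.75
  frames <- replicate(20, rbind(c(0, 0, 0), c(4, 0, 0)), simplify = FALSE)
  traj <- manual_trajectory(frames)
  adj <- contact_map(traj, cutoff = 4.5, min_fraction = 0.75)
  expect_true(adj[1, 2])
  # within cutoff in 74 of 100 frames: no contact
  frames2 <- c(replicate(74, rbind(c(0, 0, 0), c(4, 0, 0)),
                         simplify = FALSE),
               replicate(26, rbind(c(0, 0, 0), c(6, 0, 0)),
                         simplify = FALSE))
  traj2 <- manual_trajectory(frames2)
  adj2 <- contact_map(traj2, cutoff = 4.5, min_fraction = 0.75)
  expect_false(adj2[1, 2])
  expect_equal(attr(adj2, "fraction")[1, 2], 0.74)
  # 75 of 100 frames: contact (criterion is "at least")
  frames3 <- c(frames2[1:74], list(rbind(c(0, 0, 0), c(4, 0, 0))),
               frames2[76:100])
  adj3 <- contact_map(manual_trajectory(frames3), cutoff = 4.5,
                      min_fraction = 0.75)
  expect_true(adj3[1, 2])
})

test_that("contact map equals a direct per-frame enumeration oracle", {
  set.seed(101)
  nf <- 15; na <- 6
  frames <- lapply(seq_len(nf), function(f)
    matrix(rnorm(na * 3, sd = 3), na, 3))
  traj <- manual_trajectory(frames)
  adj <- contact_map(traj, cutoff = 4.0, min_fraction = 0.6)
  for (i in 1:(na - 1)) {
    for (j in (i + 1):na) {
      hits <- sum(vapply(frames, function(x)
        sqrt(sum((x[i, ] - x[j, ])^2)) <= 4.0, logical(1)))
      expect_identical(unname(adj[i, j]), hits / nf >= 0.6)
    }
  }
})

test_that("correlations hit the mirror and anti-mirror limits", {
  set.seed(102)
  # node 2 mirrors node 1 exactly; node 3 moves exactly opposite
  frames <- lapply(seq_len(20), function(f) {
    d <- rnorm(3)
    rbind(d, d + 5, -d + 10)
  })
  traj <- manual_trajectory(frames)
  C <- correlation_matrix(traj)
  expect_equal(unname(C[1, 2]), 1)
  expect_equal(unname(C[1, 3]), -1)
  expect_equal(unname(diag(C)), rep(1, 3))
  # zero-variance node flagged
  frames0 <- lapply(frames, function(x) rbind(x, c(0, 0, 0)))
  expect_warning(C0 <- correlation_matrix(manual_trajectory(frames0)))
  expect_true(is.na(C0[1, 4]))
})

test_that("edge weights follow -log|C| with the canonical anchor value", {
  expect_equal(round(edge_weight(0.5), 2), 0.69)
  expect_equal(edge_weight(1), 0)
  expect_equal(edge_weight(-1), 0)
  adj <- matrix(c(FALSE, TRUE, TRUE, FALSE), 2, 2)
  C <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  net <- build_network(adj, C)
  expect_equal(net$edges$weight, -log(0.5))
  # zero-correlation contact edge is dropped with a warning
  C0 <- matrix(c(1, 0, 0, 1), 2, 2)
  expect_warning(net0 <- build_network(adj, C0))
  expect_equal(nrow(net0$edges), 0)
})

test_that("triangle suboptimal enumeration matches the worked example", {
  # s-t 1.5 direct, s-m-t 1.0 + 1.0: both within tolerance 0.69
  W <- exp(-matrix(c(0, 1.5, 1.0,
                     1.5, 0, 1.0,
                     1.0, 1.0, 0), 3, 3))
  adj <- matrix(TRUE, 3, 3); diag(adj) <- FALSE
  net <- build_network(adj, W)
  pe <- suboptimal_paths(net, 1, 2, tolerance = 0.69)
  expect_equal(pe$optimal_weight, 1.5)
  expect_equal(nrow(pe$paths), 2)
  expect_equal(sort(vapply(pe$paths$path, path_key, character(1))),
               c("1-2", "1-3-2"))
  expect_equal(sort(pe$edge_usage$count), c(1L, 1L, 1L))
  # zero tolerance keeps only the optimum
  pe0 <- suboptimal_paths(net, 1, 2, tolerance = 0)
  expect_equal(nrow(pe0$paths), 1)
  # single-edge network
  adj1 <- matrix(c(FALSE, TRUE, TRUE, FALSE), 2, 2)
  C1 <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  pe1 <- suboptimal_paths(build_network(adj1, C1), 1, 2)
  expect_equal(nrow(pe1$paths), 1)
  expect_equal(pe1$edge_usage$count, 1L)
})

test_that("path enumeration equals brute force on random small graphs", {
  set.seed(103)
  for (g in 1:200) {
    n <- sample(2:7, 1)
    adj <- matrix(FALSE, n, n)
    adj[upper.tri(adj)] <- runif(n * (n - 1) / 2) < 0.55
    adj <- adj | t(adj)
    C <- diag(n)
    C[upper.tri(C)] <- runif(n * (n - 1) / 2, 0.05, 1)
    C[lower.tri(C)] <- t(C)[lower.tri(C)]
    net <- build_network(adj, C)
    st <- sample(n, 2)
    tol <- runif(1, 0, 1.5)
    pe <- suboptimal_paths(net, st[1], st[2], tolerance = tol)
    bf <- brute_force_paths(net$weights, st[1], st[2], tol)
    if (!length(bf$paths)) {
      expect_true(pe$flagged)
      next
    }
    expect_equal(sort(vapply(pe$paths$path, path_key, character(1))),
                 sort(vapply(bf$paths, path_key, character(1))))
    expect_equal(pe$optimal_weight, min(bf$weights))
    bf_usage <- edge_usage_from_paths(bf$paths)
    for (r in seq_len(nrow(pe$edge_usage))) {
      key <- paste(pe$edge_usage$from[r], pe$edge_usage$to[r])
      expect_identical(pe$edge_usage$count[r], bf_usage[[key]])
    }
  }
})

test_that("path ensembles are symmetric under source-sink reversal and -log additive", {
  set.seed(104)
  n <- 6
  adj <- matrix(FALSE, n, n)
  adj[upper.tri(adj)] <- runif(15) < 0.7
  adj <- adj | t(adj)
  C <- diag(n)
  C[upper.tri(C)] <- runif(15, 0.2, 1)
  C[lower.tri(C)] <- t(C)[lower.tri(C)]
  net <- build_network(adj, C)
  pe <- suboptimal_paths(net, 1, n, tolerance = 0.8)
  rev_pe <- suboptimal_paths(net, n, 1, tolerance = 0.8)
  expect_equal(sort(pe$paths$weight), sort(rev_pe$paths$weight))
  expect_setequal(vapply(pe$paths$path, path_key, character(1)),
                  vapply(rev_pe$paths$path, function(p)
                    path_key(rev(p)), character(1)))
  # total weight of the optimal path = -log of the product of |C| edges
  p <- pe$optimal_path
  prod_c <- prod(vapply(seq_len(length(p) - 1), function(e)
    abs(C[p[e], p[e + 1]]), numeric(1)))
  expect_equal(pe$optimal_weight, -log(prod_c))
})

test_that("windowed analysis samples 25 frames per 10-ns window at 400-ps stride", {
  C <- factor_correlation(c(rep(0.9, 5), 0, 0))
  spec <- correlation_spec(C, mean_positions = cbind(3.5 * (1:7), 0, 0),
                           fluctuation_sd = 0.3)
  traj <- generate_correlated_trajectory(spec, 75, seed = 105,
                                         frame_interval_ns = 0.4)
  res <- windowed_network_analysis(traj, 1, 5, window_ns = 10,
                                   stride_ns = 0.4)
  expect_equal(res$frames_per_window, 25)
  expect_equal(res$n_windows, 3)
  # denser storage, same sampling rule
  traj2 <- generate_correlated_trajectory(spec, 300, seed = 106,
                                          frame_interval_ns = 0.1)
  res2 <- windowed_network_analysis(traj2, 1, 5, window_ns = 10,
                                    stride_ns = 0.4)
  expect_equal(res2$frames_per_window, 25)
  expect_error(windowed_network_analysis(traj, 1, 5, window_ns = 10,
                                         stride_ns = 20))
})

test_that("a designed correlation chain dominates pooled edge usage", {
  # nodes 1..5 share a strong latent mode; 6..8 are noise; contacts only
  # couple spatial neighbours, so the designed chain is the only
  # low-weight route from 1 to 5
  C <- factor_correlation(c(rep(0.92, 5), 0, 0, 0))
  spec <- correlation_spec(C, mean_positions = cbind(3.5 * (1:8), 0, 0),
                           fluctuation_sd = 0.3)
  traj <- generate_correlated_trajectory(spec, 100, seed = 107,
                                         frame_interval_ns = 0.4)
  res <- windowed_network_analysis(traj, 1, 5, window_ns = 10,
                                   stride_ns = 0.4)
  top <- res$pooled_edge_usage[1:4, ]
  keys <- sprintf("%d-%d", top$from, top$to)
  expect_setequal(keys, c("1-2", "2-3", "3-4", "4-5"))
  # stationary input: adjacency identical across windows
  adjs <- lapply(seq_len(res$n_windows), function(w) {
    frames <- seq((w - 1) * 25 + 1, w * 25)
    a <- contact_map(traj, frames = frames)
    attr(a, "fraction") <- NULL
    a
  })
  expect_identical(adjs[[1]], adjs[[2]])
  expect_identical(adjs[[2]], adjs[[3]])
})
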