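test_that("smd_rupture takes the global maximum and fits the preceding window", {
  out <- smd_rupture(c(0, 100, 300, 500, 50), frame_interval_ns = 1,
                     fit_window_ns = 10)
  expect_equal(out$rupture_force, 500)
  expect_equal(out$rupture_frame, 4L)
  # exact ramp: 10 pN per 1-ns frame = 1e10 pN/s
  ramp <- seq(0, 500, by = 10)
  out2 <- smd_rupture(ramp, frame_interval_ns = 1, fit_window_ns = 10)
  expect_equal(out2$loading_rate, 1e10, tolerance = 1e-9)
  # ties resolve to the first occurrence
  out3 <- smd_rupture(c(1, 5, 5, 2), frame_interval_ns = 1)
  expect_equal(out3$rupture_frame, 2L)
  # series shorter than the fit window: rate undefined
  out4 <- smd_rupture(c(3, 1), frame_interval_ns = 1, fit_window_ns = 10)
  expect_true(is.na(out4$loading_rate))
})

test_that("toy pulling rupture frame matches the generator event log", {
  traj <- generate_smd_pull_trajectory(toy_pull_model(), 200, seed = 71)
  out <- smd_rupture(traj)
  expect_equal(out$rupture_frame, traj$metadata$rupture_frame)
})

test_that("pair distances are Euclidean and selections must be unique", {
  frames <- replicate(4, rbind(c(0, 0, 0), c(3, 4, 0)), simplify = FALSE)
  traj <- manual_trajectory(frames)
  ser <- pair_distance_series(traj, 1, 2)
  expect_equal(ser$value, rep(0.5, 4))  # 5 Angstrom = 0.5 nm
  # ambiguous selection: two CA atoms share the residue filter
  traj2 <- manual_trajectory(frames, names = c("CA", "CA"))
  traj2$atoms$resid <- c(1, 1)
  expect_error(pair_distance_series(traj2, list(resid = 1, name = "CA"), 1),
               class = "pullgeom_selection_error")
})

test_that("angles hit the textbook values and flag degenerate frames", {
  tri <- list(rbind(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)),
              rbind(c(2, 0, 0), c(0, 0, 0), c(0, 3, 0)))
  traj <- manual_trajectory(tri)
  expect_equal(angle_series(traj, 1, 2, 3)$value, c(90, 90))
  lin <- manual_trajectory(list(rbind(c(-1, 0, 0), c(0, 0, 0), c(2, 0, 0))))
  expect_equal(angle_series(lin, 1, 2, 3)$value, 180)
  dg <- manual_trajectory(list(rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0))))
  expect_true(is.na(angle_series(dg, 1, 2, 3)$value))
})

test_that("metrics are invariant under rigid rotation plus translation", {
  set.seed(72)
  traj <- generate_smd_pull_trajectory(toy_pull_model(), 60, seed = 72)
  # random rotation (QR of a Gaussian matrix) and translation
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  shift <- c(10, -5, 3)
  moved <- traj
  for (f in seq_len(dim(traj$coords)[1])) {
    moved$coords[f, , ] <- sweep(traj$coords[f, , ] %*% t(Q), 2, -shift)
  }
  d0 <- pair_distance_series(traj, 1, 5)$value
  d1 <- pair_distance_series(moved, 1, 5)$value
  expect_lt(max(abs(d1 - d0) / d0), 1e-9)
  a0 <- angle_series(traj, 1, 5, 9)$value
  a1 <- angle_series(moved, 1, 5, 9)$value
  expect_lt(max(abs(a1 - a0)), 1e-7)
})

test_that("window histograms share bins, conserve counts, and see programmed shifts", {
  traj <- generate_smd_pull_trajectory(toy_pull_model(), 200, seed = 73)
  ser <- pair_distance_series(traj, traj$metadata$lid_pair[1],
                              traj$metadata$lid_pair[2])
  rup <- smd_rupture(traj)$rupture_frame
  wh <- window_histograms(ser, rup, window_ns = 10)
  expect_equal(sum(wh$unloaded$count), wh$window_frames)
  expect_equal(sum(wh$loaded$count), wh$window_frames)
  expect_equal(wh$unloaded$mid, wh$loaded$mid)
  # programmed opening of 8 Angstrom = 0.8 nm
  expect_lt(abs(wh$shift - 0.8), 0.1)
  # stationary series: shift within noise
  set.seed(74)
  flat <- rnorm(200, 10, 0.2)
  wh0 <- window_histograms(flat, 180, window_ns = 10,
                           frame_interval_ns = 0.4)
  expect_lt(abs(wh0$shift), 3 * 0.2 * sqrt(2 / 25))
  # windows must not overlap
  expect_error(window_histograms(flat, 20, window_ns = 10,
                                 frame_interval_ns = 0.4))
})

test_that("replica summaries pool opening ensembles and respect the null", {
  open <- lapply(1:8, function(s)
    generate_smd_pull_trajectory(toy_pull_model(), 200, seed = 80 + s))
  summ <- replica_ensemble_summary(open)
  expect_equal(nrow(summ), 8)
  pooled <- attr(summ, "pooled")$all
  # one-sided permutation test: loaded mean exceeds unloaded mean
  obs <- mean(pooled$loaded) - mean(pooled$unloaded)
  all_v <- c(pooled$unloaded, pooled$loaded)
  n1 <- length(pooled$unloaded)
  set.seed(85)
  perm <- replicate(999, {
    idx <- sample(length(all_v), n1)
    mean(all_v[-idx]) - mean(all_v[idx])
  })
  expect_lt(mean(perm >= obs), 0.01)
  # non-opening model: per-replica shifts consistent with zero
  closed <- lapply(1:8, function(s)
    generate_smd_pull_trajectory(toy_pull_model(loop_open_force = Inf),
                                 200, seed = 90 + s))
  summ0 <- replica_ensemble_summary(closed)
  sh <- summ0$shift[is.finite(summ0$shift)]
  expect_lt(abs(mean(sh)), 3 * sd(sh) / sqrt(length(sh)))
  # single replica: one-row table, no crash
  one <- replica_ensemble_summary(open[1])
  expect_equal(nrow(one), 1)
})
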