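test_that("correlation spec validates its matrix", {
  expect_error(correlation_spec(matrix(c(1, 0.5, 0.4, 1), 2, 2)),
               class = "pullgeom_validation_error")  # asymmetric
  C <- matrix(c(1, 0.99, -0.99, 0.99, 1, 0.99, -0.99, 0.99, 1), 3, 3)
  expect_error(correlation_spec(C),
               class = "pullgeom_validation_error")  # not PSD
  expect_s3_class(correlation_spec(diag(4)), "correlation_spec")
})

test_that("correlated generator reproduces the target correlation", {
  # identity target: off-diagonal empirical correlations vanish
  traj0 <- generate_correlated_trajectory(correlation_spec(diag(5)),
                                          10000, seed = 61)
  C0 <- correlation_matrix(traj0)
  expect_lt(max(abs(C0[upper.tri(C0)])), 0.05)
  # programmed C_12 = 0.9 recovered within the Fisher-z band
  C <- diag(6); C[1, 2] <- C[2, 1] <- 0.9
  traj <- generate_correlated_trajectory(correlation_spec(C), 10000,
                                         seed = 62)
  Ce <- correlation_matrix(traj)
  expect_lt(abs(Ce[1, 2] - 0.9), 0.05)
  # single frame: correlation undefined
  expect_error(generate_correlated_trajectory(correlation_spec(diag(3)), 1),
               class = "pullgeom_validation_error")
  # determinism
  a <- generate_correlated_trajectory(correlation_spec(diag(3)), 50,
                                      seed = 63)
  b <- generate_correlated_trajectory(correlation_spec(diag(3)), 50,
                                      seed = 63)
  expect_identical(a$coords, b$coords)
})

test_that("an unloaded toy run shows no ramp, only the chain's entropic tension", {
  # without pulling, the spring reads the small thermal (entropic) chain
  # tension, far below the event thresholds, and shows no trend
  m <- toy_pull_model(pull_velocity = 0)
  traj <- generate_smd_pull_trajectory(m, 100, seed = 64)
  expect_lt(abs(mean(traj$force_pN)), 0.25 * m$loop_open_force)
  first_half <- mean(traj$force_pN[1:50])
  second_half <- mean(traj$force_pN[51:100])
  expect_lt(abs(second_half - first_half), 25)
  expect_true(is.na(traj$metadata$loop_open_frame))
  expect_true(is.na(traj$metadata$rupture_frame))
})

test_that("disabled lid opening keeps the pair distance stationary", {
  m <- toy_pull_model(loop_open_force = Inf, detach_force = Inf)
  traj <- generate_smd_pull_trajectory(m, 150, seed = 65)
  ser <- pair_distance_series(traj, traj$metadata$lid_pair[1],
                              traj$metadata$lid_pair[2])
  first <- ser$value[1:50]
  last <- ser$value[101:150]
  expect_lt(abs(mean(last) - mean(first)), 0.05)  # nm
})

test_that("the lid opens before the pulled bond ruptures, as constructed", {
  traj <- generate_smd_pull_trajectory(toy_pull_model(), 200, seed = 66)
  md <- traj$metadata
  expect_false(is.na(md$loop_open_frame))
  expect_false(is.na(md$rupture_frame))
  expect_lt(md$loop_open_frame, md$rupture_frame)
  # event log is reproducible bitwise under the same seed
  again <- generate_smd_pull_trajectory(toy_pull_model(), 200, seed = 66)
  expect_identical(md$loop_open_frame, again$metadata$loop_open_frame)
  expect_identical(traj$force_pN, again$force_pN)
})
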