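# helper: Bell-Evans parameters with a prescribed modal force at rate r
params_for_mode <- function(Fstar, x, r, kBT = 4.14) {
  bell_evans_params((x * r / kBT) * exp(-Fstar * x / kBT), x, kBT)
}

test_that("single-component fits recover the generating modal force", {
  r <- 3e4
  p <- params_for_mode(210, 0.35, r)
  f <- sample_rupture_forces(p, r, 2000, seed = 41)
  fit <- fit_mixture(f, r, n_components = 1, seed = 1)
  expect_true(fit$converged)
  expect_lt(abs(fit$components$modal_force - 210) / 210, 0.03)
})

test_that("modal-force recovery is nearly unbiased over repetitions", {
  r <- 3e4
  p <- params_for_mode(210, 0.35, r)
  modes <- vapply(1:20, function(i) {
    f <- sample_rupture_forces(p, r, 5000, seed = 500 + i)
    fit_mixture(f, r, n_components = 1, seed = 1)$components$modal_force
  }, numeric(1))
  expect_lt(abs(mean(modes) - 210) / 210, 0.02)
})

test_that("three-component fits resolve well-separated modes", {
  r <- 3e4
  ps <- list(params_for_mode(100, 0.40, r), params_for_mode(210, 0.35, r),
             params_for_mode(440, 0.30, r))
  set.seed(42)
  comp <- sample(1:3, 3000, TRUE, c(0.4, 0.4, 0.2))
  f <- vapply(comp, function(c) sample_rupture_forces(ps[[c]], r, 1),
              numeric(1))
  fit <- fit_mixture(f, r, n_components = 3, seed = 1)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$components$modal_force - c(100, 210, 440)) /
                  c(100, 210, 440)), 0.05)
  expect_equal(sum(fit$components$weight), 1)
  # components are reported in increasing modal-force order
  expect_true(all(diff(fit$components$modal_force) > 0))
})

test_that("degenerate zero-variance input is flagged without crashing", {
  fit <- fit_mixture(rep(100, 60), 1e4)
  expect_true(fit$degenerate)
  expect_false(fit$converged)
})

test_that("fits are scale-consistent between pN and nN conventions", {
  r <- 3e4
  p <- params_for_mode(210, 0.35, r)
  f <- sample_rupture_forces(p, r, 1500, seed = 43)
  fit_pN <- fit_mixture(f, r, n_components = 1, seed = 1)
  # same data expressed in nN with kBT in nN nm and rate in nN/s
  fit_nN <- fit_mixture(f / 1000, r / 1000, n_components = 1, seed = 1,
                        kBT = 4.14e-3)
  expect_lt(abs(fit_nN$components$modal_force * 1000 -
                  fit_pN$components$modal_force) /
              fit_pN$components$modal_force, 1e-3)
})

test_that("tidy and glance summarize mixture fits", {
  f <- sample_rupture_forces(params_for_mode(210, 0.35, 3e4), 3e4, 300,
                             seed = 44)
  fit <- fit_mixture(f, 3e4, n_components = 2, seed = 1)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 2)
  expect_named(td, c("component", "k0", "x_dagger", "kBT", "weight",
                     "modal_force"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n, 300)
})

test_that("BIC order selection identifies the generating component count", {
  r <- 3e4
  f1 <- sample_rupture_forces(params_for_mode(440, 0.30, r), r, 1000,
                              seed = 45)
  expect_equal(fit_mixture(f1, r, seed = 1)$n_components, 1)
  set.seed(46)
  comp <- sample(1:2, 1200, TRUE, c(0.55, 0.45))
  ps <- list(params_for_mode(100, 0.40, r), params_for_mode(210, 0.35, r))
  f2 <- vapply(comp, function(c) sample_rupture_forces(ps[[c]], r, 1),
               numeric(1))
  expect_equal(fit_mixture(f2, r, seed = 1)$n_components, 2)
})

test_that("a free triple fit matches a fixed 1SA+3SA combination on union data", {
  r <- 3e4
  pD <- params_for_mode(440, 0.30, r)
  pA <- params_for_mode(100, 0.40, r)
  pB <- params_for_mode(210, 0.35, r)
  f1 <- sample_rupture_forces(pD, r, 1500, seed = 47)
  set.seed(48)
  comp3 <- sample(1:2, 1500, TRUE, c(0.6, 0.4))
  f3 <- vapply(comp3, function(c)
    sample_rupture_forces(list(pA, pB)[[c]], r, 1), numeric(1))
  fit1 <- fit_mixture(f1, r, n_components = 1, seed = 1)
  fit3 <- fit_mixture(f3, r, n_components = 2, seed = 1)
  # tetravalent sample drawn from the union of the two processes
  set.seed(49)
  take1 <- runif(2000) < 0.35
  f4 <- ifelse(take1, sample_rupture_forces(pD, r, 2000),
               vapply(sample(1:2, 2000, TRUE, c(0.6, 0.4)), function(c)
                 sample_rupture_forces(list(pA, pB)[[c]], r, 1),
                 numeric(1)))
  cmp <- compare_mixture_vs_fixed_combination(f4, fit1, fit3, seed = 1)
  expect_lt(abs(cmp$delta_loglik_per_obs), 0.05)
  # mismatched fixed components (shifted +100 pN): the free fit dominates
  fit1_shift <- fit_mixture(f1 + 100, r, n_components = 1, seed = 1)
  fit3_shift <- fit_mixture(f3 + 100, r, n_components = 2, seed = 1)
  cmp_bad <- compare_mixture_vs_fixed_combination(f4, fit1_shift,
                                                  fit3_shift, seed = 1)
  expect_gt(cmp_bad$delta_loglik_per_obs, 0.05)
  expect_error(compare_mixture_vs_fixed_combination(numeric(0), fit1, fit3),
               class = "pullgeom_validation_error")
})
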