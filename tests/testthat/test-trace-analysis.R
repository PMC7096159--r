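test_that("raw-channel conversion applies calibration and bending correction", {
  # zero deflection: no force, extension tracks the piezo
  tr <- convert_raw(rep(0, 50), seq(0, 1, length.out = 50),
                    invols = 50, piezo_sensitivity = 100, k_c = 0.15)
  expect_equal(tr$force_pN, rep(0, 50))
  expect_equal(tr$extension_nm, seq(0, 100, length.out = 50))
  # rigid contact: deflection equal to piezo displacement gives constant
  # zero extension
  piezo_V <- seq(0, 1, length.out = 50)
  defl_V <- piezo_V * 100 / 50
  tr <- convert_raw(defl_V, piezo_V, 50, 100, 0.15)
  expect_equal(tr$extension_nm, rep(0, 50))
  # synthetic raw channels produced by inverting the formulas round-trip
  set.seed(21)
  force <- runif(200, 0, 400)
  ext <- runif(200, 0, 80)
  defl_nm <- force / (0.15 * 1000)
  defl_V <- defl_nm / 50
  piezo_V <- (ext + defl_nm) / 100
  tr <- convert_raw(defl_V, piezo_V, 50, 100, 0.15)
  expect_lt(max(abs(tr$force_pN - force) / pmax(force, 1e-12)), 1e-9)
  expect_lt(max(abs(tr$extension_nm - ext) / pmax(ext, 1e-12)), 1e-9)
  expect_error(convert_raw(1:5, 1:4, 50, 100, 0.15))
})

make_offset_trace <- function(force_offset = 5, distance_offset = 8,
                              noise = 1, seed = 22) {
  # pulling curve preceded by a linear contact ramp crossing zero at the
  # known contact point
  set.seed(seed)
  base <- simulate_trace(plain_tether(), default_subunit_params()$B,
                         acquisition_protocol(force_noise_sd = 0), seed = seed)
  n_c <- 120
  contact_ext <- seq(0, distance_offset, length.out = n_c)
  contact_force <- 60 * (1 - contact_ext / distance_offset)
  dt <- diff(base$time_s[1:2])
  fe_trace(c(seq_len(n_c) * dt, base$time_s + (n_c + 1) * dt),
           c(contact_ext, base$extension_nm + distance_offset),
           c(contact_force, base$force_pN) + force_offset +
             rnorm(n_c + nrow(base), sd = noise))
}

test_that("zero points recover injected force and distance offsets", {
  tr <- make_offset_trace(force_offset = 5, distance_offset = 8)
  zp <- determine_zero_points(tr)
  expect_false(zp$excluded)
  expect_lt(abs(zp$force_offset - 5), 0.5)
  expect_lt(abs(zp$distance_offset - 8), 1.0)
  # already-zeroed noiseless trace: both offsets vanish
  tr0 <- simulate_trace(plain_tether(), default_subunit_params()$B,
                        acquisition_protocol(force_noise_sd = 0), seed = 23)
  zp0 <- determine_zero_points(tr0)
  expect_equal(zp0$force_offset, 0)
  expect_equal(zp0$distance_offset, 0)
  # all-contact trace (steep contact slope to the very end, no detached
  # baseline): flagged for exclusion
  n <- 500
  allc <- fe_trace(seq_len(n) / 1e4, seq_len(n) / 10,
                   seq(3000, 0, length.out = n))
  expect_true(determine_zero_points(allc)$excluded)
})

test_that("boxcar denoising is length-preserving, identity at window 1, and averages noise", {
  tr <- fe_trace(1:100 / 1e4, 1:100 / 10, rnorm(100))
  expect_identical(denoise(tr, 1)$force_pN, tr$force_pN)
  const <- fe_trace(1:100 / 1e4, 1:100 / 10, rep(7, 100))
  expect_equal(denoise(const, 11)$force_pN, rep(7, 100))
  set.seed(24)
  noisy <- fe_trace(1:10000 / 1e4, 1:10000 / 10, rnorm(10000, sd = 3))
  sm <- denoise(noisy, 9)$force_pN
  core <- sm[10:9990]
  expect_lt(abs(sd(core) - 3 / sqrt(9)) / (3 / sqrt(9)), 0.2)
  expect_error(denoise(tr, 4))
  expect_error(denoise(tr, 101))
})

test_that("contour-length transform inverts pure WLC curves and masks low force", {
  ext <- seq(1, 55, length.out = 300)
  F <- wlc_force(ext, 60, 0.38)
  tr <- fe_trace(seq_along(ext) / 1e4, ext, F)
  out <- contour_length_transform(tr, Lp = 0.38, min_force = 10)
  ok <- !is.na(out$Lc_nm)
  expect_true(all(F[!ok] < 10))
  expect_lt(max(abs(out$Lc_nm[ok] - 60) / 60), 1e-6)
  # two-plateau curve maps onto a bimodal contour-length histogram
  ext2 <- c(ext, seq(30, 70, length.out = 300))
  F2 <- c(F, wlc_force(seq(30, 70, length.out = 300), 75, 0.38))
  tr2 <- fe_trace(seq_along(ext2) / 1e4, ext2, F2)
  out2 <- contour_length_transform(tr2, Lp = 0.38, min_force = 10)
  lc <- out2$Lc_nm[!is.na(out2$Lc_nm)]
  expect_lt(min(abs(sort(unique(round(lc))) - 60)), 1)
  expect_lt(min(abs(sort(unique(round(lc))) - 75)), 1)
})

test_that("event detection finds programmed unfoldings and ignores ramps", {
  # monotone ramp: no events
  ramp <- fe_trace(1:500 / 1e4, seq(1, 39, length.out = 500),
                   seq(0, 300, length.out = 500))
  ramp <- contour_length_transform(ramp, Lp = 0.38)
  expect_equal(nrow(detect_unfolding_events(ramp, smooth_window = 1)), 0)
  # noiseless simulated fingerprint trace: two unfolding events with the
  # programmed increments, then the terminal detachment
  tr <- simulate_trace(tether_model(), default_subunit_params()$B,
                       acquisition_protocol(force_noise_sd = 0), seed = 26)
  truth <- trace_events(tr)
  expect_equal(sum(grepl("unfold", truth$event)), 2)
  expect_true("rupture" %in% truth$event)
  tl <- contour_length_transform(tr, Lp = 0.38)
  ev <- detect_unfolding_events(tl, smooth_window = 1)
  unf <- ev[!ev$is_terminal, ]
  expect_equal(nrow(unf), 2)
  expect_lt(max(abs(unf$delta_Lc - c(15, 16))), 1)
  expect_equal(sum(ev$is_terminal), 1)
  # drops whose peak sits below min_peak_force are ignored
  ev_hi <- detect_unfolding_events(tl, min_peak_force = 1e4,
                                   smooth_window = 1)
  expect_equal(nrow(ev_hi), 0)
})

test_that("fingerprint classification demands ordered matching increments", {
  ev <- function(dl, term = TRUE) {
    k <- length(dl)
    tibble::tibble(index = seq_len(k + term), time_s = seq_len(k + term),
                   peak_force = 100,
                   Lc_before = 0, Lc_after = 0,
                   delta_Lc = c(dl, if (term) NA_real_),
                   is_terminal = c(rep(FALSE, k), if (term) TRUE))
  }
  expect_true(classify_fingerprint(ev(c(15, 16)), c(15, 16), 2))
  expect_true(classify_fingerprint(ev(c(14.2, 17.5)), c(15, 16), 2))
  expect_false(classify_fingerprint(ev(16), c(15, 16), 2))
  expect_false(classify_fingerprint(ev(c(16, 15)), c(16.8, 16.8), 1))
  expect_false(classify_fingerprint(ev(c(15, 16), term = FALSE), c(15, 16), 2))
  expect_false(classify_fingerprint(ev(numeric(0)), c(15, 16), 2))
})

test_that("rupture extraction is exact on a noiseless linear ramp", {
  # 400 pN ramp at 1e4 pN/s, then detachment
  dt <- 1 / 12000
  n_up <- 480
  f <- c(seq_len(n_up) * 1e4 * dt, rep(0, 200))
  tr <- fe_trace(seq_along(f) * dt, seq_along(f) * 0.05, f)
  tl <- contour_length_transform(tr, Lp = 0.38)
  ev <- detect_unfolding_events(tl, smooth_window = 1)
  ru <- extract_rupture(tr, ev, smooth_window = 1)
  expect_true(ru$valid)
  expect_equal(ru$rupture_force, 400, tolerance = 1e-9)
  expect_equal(ru$loading_rate, 1e4, tolerance = 1e-9)
  # a trace that never detaches is flagged
  ramp <- fe_trace(seq_len(300) * dt, seq_len(300) * 0.05,
                   seq_len(300) * 1e4 * dt)
  rampL <- contour_length_transform(ramp, Lp = 0.38)
  ev2 <- detect_unfolding_events(rampL, smooth_window = 1)
  ru2 <- extract_rupture(ramp, ev2, smooth_window = 1)
  expect_false(ru2$valid)
})

test_that("loading-rate estimate tracks the generator's flank rate at default noise", {
  errs <- c()
  for (s in 1:25) {
    tr <- simulate_trace(tether_model(), default_subunit_params()$B,
                         acquisition_protocol(), seed = 300 + s)
    ev <- trace_events(tr)
    if (!"rupture" %in% ev$event) next
    res <- analyze_trace(tr)
    if (!res$valid) next
    truth <- ev$loading_rate_local[ev$event == "rupture"]
    errs <- c(errs, abs(res$loading_rate / truth - 1))
  }
  expect_gt(length(errs), 15)
  expect_lt(median(errs), 0.10)
})

test_that("force filtering keeps traces above threshold and logs counts", {
  mk <- function(fmax) {
    fe_trace(1:200 / 1e4, 1:200 / 10, seq(0, fmax, length.out = 200))
  }
  set <- tibble::tibble(trace_id = c("a", "b", "c"),
                        trace = list(mk(49), mk(120), mk(30)))
  out <- filter_traces(set, 50, smooth_window = 1)
  expect_equal(out$trace_id, "b")
  expect_equal(attr(out, "counts"),
               list(input = 3L, kept = 1L, discarded = 2L))
  # zero threshold keeps everything
  expect_equal(nrow(filter_traces(set, 0, smooth_window = 1)), 3)
})

test_that("trace analysis is deterministic for a fixed trace set", {
  cfg <- variant_config("3SA", fingerprint_attach_rate = 0.7)
  set <- generate_variant_dataset(cfg, 12, fast_protocol(), seed = 29)
  r1 <- pipeline_smfs(set, fit = FALSE)
  r2 <- pipeline_smfs(set, fit = FALSE)
  expect_identical(r1$rupture_events, r2$rupture_events)
  expect_identical(r1$config_hash, r2$config_hash)
})
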