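test_that("phase correlation recovers planted integer shifts exactly", {
  set.seed(21)
  sh <- matrix(0L, 40, 2)
  sh[31:40, ] <- cbind(sample(-8:8, 10, TRUE), sample(-8:8, 10, TRUE))
  st <- generate_frame_stack(40, sh, seed = 22)
  reg <- register_frames(st)
  expect_identical(unname(reg$displacement), unname(sh))
  # agreement with the exhaustive cross-correlation oracle
  oracle <- t(vapply(31:40, function(f)
    xcorr_shift_oracle(reg$reference, st[, , f]), integer(2)))
  expect_identical(unname(reg$displacement[31:40, ]), oracle)
})

test_that("registration handles degenerate and zero-shift inputs", {
  st0 <- generate_frame_stack(6, seed = 23)
  reg <- register_frames(st0)
  expect_true(all(reg$displacement == 0L))
  zeros <- array(0, dim = c(8, 8, 3))
  expect_error(register_frames(zeros), "zero")
  expect_error(register_frames(array(1, dim = c(8, 8, 1))), "frames")
})

test_that("large-motion flagging applies both threshold rules", {
  mk <- function(disp) structure(list(displacement = disp),
                                 class = "registration_result")
  expect_length(flag_large_motion(mk(matrix(0, 20, 2))), 0L)
  disp <- matrix(0, 20, 2); disp[7, ] <- c(12, 0)
  expect_identical(flag_large_motion(mk(disp), threshold_px = 10), 7L)
  expect_length(flag_large_motion(mk(disp), threshold_px = Inf, auto = FALSE),
                0L)
  # adaptive rule catches outliers below the absolute threshold
  disp2 <- matrix(rnorm(40, 0, 0.1), 20, 2); disp2[3, ] <- c(6, 0)
  expect_true(3L %in% flag_large_motion(mk(disp2), threshold_px = 10))
})

test_that("ROI extraction averages mask pixels per frame", {
  st <- array(0, dim = c(4, 4, 3))
  for (f in 1:3) st[, , f] <- f
  mask <- matrix(FALSE, 4, 4); mask[1:2, 1:2] <- TRUE
  expect_equal(extract_roi_trace(st, mask), c(1, 2, 3))
  # single pixel mask returns that pixel's series
  st[2, 3, ] <- c(9, 8, 7)
  m1 <- matrix(FALSE, 4, 4); m1[2, 3] <- TRUE
  expect_equal(extract_roi_trace(st, m1), c(9, 8, 7))
  # checkerboard of 0/1 averages to 0.5
  cb <- outer(1:4, 1:4, function(i, j) (i + j) %% 2)
  stc <- array(rep(cb, 2), dim = c(4, 4, 2))
  expect_equal(extract_roi_trace(stc, matrix(TRUE, 4, 4)), c(0.5, 0.5))
  expect_error(extract_roi_trace(st, matrix(FALSE, 4, 4)), "empty")
})

test_that("neuropil coefficient is recovered and robust to transients", {
  # transient-free: agrees with least squares, lands near the planted value
  fx <- make_np_fixture(31, r = 0.7, transients = FALSE)
  fit <- subtract_neuropil(fx$cell, fx$np)
  ols <- unname(stats::lm.fit(cbind(1, fx$np), fx$cell)$coefficients[2])
  expect_gt(fit$r_hat, 0.6); expect_lt(fit$r_hat, 0.8)
  expect_lt(abs(fit$r_hat - ols), 0.05)
  expect_equal(fit$corrected, fx$cell - fit$r_hat * fx$np)

  # transient-rich: asymmetric fit less biased than least squares
  bias <- t(vapply(41:48, function(s) {
    fx <- make_np_fixture(s, r = 0.7, transients = TRUE)
    c(ast = subtract_neuropil(fx$cell, fx$np)$r_hat - 0.7,
      ols = unname(stats::lm.fit(cbind(1, fx$np),
                                 fx$cell)$coefficients[2]) - 0.7)
  }, numeric(2)))
  expect_lt(mean(abs(bias[, "ast"])), mean(abs(bias[, "ols"])))
})

test_that("neuropil fit rejects degenerate inputs", {
  expect_error(subtract_neuropil(rnorm(50), rnorm(50)), "100 frames")
  expect_warning(out <- subtract_neuropil(rnorm(200), rep(3, 200)),
                 "unidentifiable")
  expect_equal(out$r_hat, 0)
})

test_that("Gaussian-mixture baseline finds the lower component mean", {
  expect_equal(estimate_f0_gmm(rep(5, 300))$f0, 5)
  for (s in 1:5) {
    set.seed(s)
    x <- c(rnorm(2400, 100, 2), rnorm(600, 200, 10))
    f0 <- estimate_f0_gmm(x)$f0
    expect_gt(f0, 97); expect_lt(f0, 103)
  }
  expect_error(estimate_f0_gmm(rnorm(100)), "200 frames")
  expect_error(estimate_f0_gmm(c(rnorm(250), NA)), "finite")
})

test_that("baseline estimate agrees with an independent mixture fit", {
  set.seed(7)
  x <- c(rnorm(2000, 100, 3), rnorm(500, 180, 15))
  ours <- estimate_f0_gmm(x)$f0
  mclustBIC <- mclust::mclustBIC  # Mclust resolves it in the caller frame
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_lt(abs(ours - min(mc$parameters$mean)), 1)
})

test_that("dF/F and z-scoring follow their definitions exactly", {
  s <- sin(seq(0, 20, length.out = 500))
  out <- compute_dff_z(100 * (1 + s), 100)
  expect_equal(out$dff, s, tolerance = 1e-12)
  expect_lt(abs(mean(out$z_dff)), 1e-9)
  expect_lt(abs(sd(out$z_dff) - 1), 1e-9)
  flat <- compute_dff_z(rep(100, 500), 100)
  expect_true(flat$flagged)
  expect_error(compute_dff_z(rnorm(10), 0), "positive")
  # excluded frames are left out of the normalization statistics
  x <- c(rep(100, 400), rep(500, 10))
  out2 <- compute_dff_z(c(x, 101), 100, exclude_frames = 401:410)
  kept <- (c(x, 101)[-(401:410)] - 100) / 100
  expect_equal(out2$session_mean, mean(kept))
})

test_that("noiseless pipeline z-trace equals the analytic z of the signal", {
  cfg <- small_config(seed = 13)
  trials <- generate_trial_sequence(cfg)
  ev <- generate_events(trials, cfg)
  beh <- flat_behavior(trials, cfg)
  truth <- make_truth(tuning = list(C = 1, A = 0.4, B = 0.3), pe_gain = 0.5)
  traces <- generate_traces(truth, ev, beh, cfg)
  dff <- preprocess_traces(traces, neuropil = FALSE)
  signal <- traces$raw[1, ] / 100 - 1
  z_expected <- (signal - mean(signal)) / sd(signal)
  expect_equal(as.numeric(dff$z[1, ]), z_expected, tolerance = 1e-6)
})
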