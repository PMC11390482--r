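test_that("event response is the baseline-subtracted window mean", {
  dt <- 1 / 7.5
  time <- seq(0, 20, by = dt)
  onset <- 10 * dt * 6  # on-grid onset at 8 s
  z <- numeric(length(time))
  z[time >= onset + 0.4 & time < onset + 2.0] <- 1
  out <- compute_response(z, time, onset)
  expect_equal(out$response, 1)
  # window bookkeeping at 7.5 Hz: 12 response frames, 3-4 baseline frames
  expect_equal(out$n_window, 12L)
  expect_true(out$n_baseline %in% 3:4)
  expect_equal(compute_response(rep(2, length(time)), time, onset)$response, 0)
  expect_true(is.na(compute_response(z, time, max(time) + 5)$response))
})

test_that("kernel-driven responses match the independent window mean", {
  dt <- 1 / 7.5
  time <- seq(0, 40, by = dt)
  tt <- seq(0, 4, by = dt)
  kern <- (exp(-tt / 0.6) - exp(-tt / 0.05)); kern <- kern / max(kern)
  # onset half a frame off the grid: no window boundary lands on a frame
  i0 <- 151L
  onset <- time[i0] - dt / 2
  z <- numeric(length(time))
  z[i0:(i0 + length(kern) - 1L)] <- 3 * kern
  out <- compute_response(z, time, onset)
  # oracle: direct mean over kernel samples falling in the window
  rel <- time - onset
  expected <- mean(z[rel >= 0.4 & rel < 2.0]) - mean(z[rel >= -0.5 & rel < 0])
  expect_equal(out$response, expected, tolerance = 1e-12)
  expect_gt(out$response, 0)
})

test_that("responsiveness thresholds are strict and variant-aware", {
  expect_true(classify_stimulus_responsive(0.51))
  expect_false(classify_stimulus_responsive(0.5))
  expect_false(classify_stimulus_responsive(NA))
  expect_true(classify_stimulus_responsive(0.15, threshold = 0.1))
  expect_false(classify_stimulus_responsive(0.15, threshold = 0.2))
})

test_that("prediction-error rule needs both significance and magnitude", {
  expect_false(classify_pe_responsive(rep(1, 5), rep(1, 5))$flag)
  # significant but sub-threshold difference fails the rule
  set.seed(2)
  a <- rnorm(30, 0.4, 0.05); b <- rnorm(30, 0, 0.05)
  out <- classify_pe_responsive(a, b, min_diff = 0.5)
  expect_lt(out$p_value, 0.001)
  expect_false(out$flag)
  expect_true(classify_pe_responsive(a, b, min_diff = 0.3)$flag)
  # degenerate zero-variance equal samples are not responsive
  expect_false(classify_pe_responsive(rep(2, 4), rep(2, 6))$flag)
})

test_that("prediction-error detection power matches the simulation oracle", {
  hits <- vapply(1:200, function(s) {
    set.seed(s)
    classify_pe_responsive(rnorm(16, 1, 0.5), rnorm(20, 0, 0.5))$flag
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("selectivity follows its formula with clipping", {
  expect_equal(compute_selectivity(0.8, 0.8), 0)
  expect_equal(compute_selectivity(0.5, 0), 1)
  expect_equal(compute_selectivity(0.5, -0.1), 1)  # raw 1.5 clipped
  expect_equal(compute_selectivity(-0.1, 0.5), -1) # raw -1.5 clipped
  expect_true(is.na(compute_selectivity(0.3, -0.3)))
  # antisymmetry wherever the raw value is within the clip range
  set.seed(3)
  a <- runif(50, 0.2, 1); b <- runif(50, 0.2, 1)
  expect_equal(compute_selectivity(a, b), -compute_selectivity(b, a),
               tolerance = 1e-12)
})

test_that("selectivity classes use the printed cutoffs", {
  expect_equal(classify_selectivity_class(0.85, TRUE), "highly-selective")
  expect_equal(classify_selectivity_class(0.59, TRUE), "non-selective")
  expect_equal(classify_selectivity_class(0.7, TRUE), "intermediate")
  expect_equal(classify_selectivity_class(c(0.6, 0.8), c(TRUE, TRUE)),
               c("intermediate", "intermediate"))
  expect_equal(classify_selectivity_class(0.9, FALSE), "unresponsive")
})

test_that("selectivity index equals mean difference over pooled SD", {
  expect_equal(compute_si(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(compute_si(c(0, 1, 2), c(-1, 0, 1)), 1)
  set.seed(4)
  a <- rnorm(17, 1.2, 0.8); b <- rnorm(23, 0.1, 1.3)
  ps <- sqrt((16 * var(a) + 22 * var(b)) / 38)
  expect_equal(compute_si(a, b), (mean(a) - mean(b)) / ps, tolerance = 1e-12)
  expect_warning(inf_si <- compute_si(c(1, 1), c(0, 0)), "infinite")
  expect_identical(inf_si, Inf)
})

test_that("recruitment rule requires one qualifying stimulus condition", {
  same <- list(B4 = rep(1, 6), C4uD4 = rep(0.5, 6))
  expect_false(classify_recruited(same, same)$flag)
  set.seed(5)
  on <- list(B4 = rnorm(10, 1.0, 0.1), C4uD4 = rnorm(10, 0, 0.1))
  off <- list(B4 = rnorm(10, 0.2, 0.1), C4uD4 = rnorm(10, 0, 0.1))
  out <- classify_recruited(on, off)
  expect_true(out$flag)
  expect_lt(out$by_condition$p_value[1], 0.016)
  # a large difference with p above the corrected level does not recruit
  on2 <- list(B4 = c(0.1, 1.9, 0.4, 1.0))
  off2 <- list(B4 = c(0.0, 0.2, 0.1, 0.3))
  p2 <- stats::t.test(on2$B4, off2$B4, var.equal = TRUE)$p.value
  expect_gt(p2, 0.016)
  expect_false(classify_recruited(on2, off2)$flag)
})

test_that("classification trial subsets follow the figure variants", {
  ev <- data.frame(id = 1:6,
                   led_state = c("on", "off", "none", "on", "off", "none"))
  expect_identical(select_classification_trials(ev, "all"), ev)
  expect_identical(select_classification_trials(ev, "led_pooled"), ev)
  off <- select_classification_trials(ev, "led_off_only")
  expect_true(all(off$led_state %in% c("off", "none")))
  expect_equal(nrow(off), 4L)
  expect_error(select_classification_trials(ev, "bogus"))
})

test_that("full classification recovers the planted population structure", {
  cfg <- session_config(n_trials_block1 = 60, n_trials_block2 = 20,
                        n_animals = 2, cells_per_animal = 12, seed = 31)
  ses <- run_simulate(cfg)
  dff <- preprocess_traces(ses$traces)
  rt <- build_response_table(dff, ses$events, cfg)
  cls <- classify_cells(rt, cfg)
  m <- match(cls$cell_id, ses$truth$cell_id)
  planted <- ses$truth$pe_gain[m] > 0
  if (any(planted)) expect_gte(mean(cls$pe_responsive[planted]), 0.75)
  expect_lte(mean(cls$pe_responsive[!planted]), 0.15)
  # unresponsive ground-truth cells are never called highly selective
  expect_false(any(cls$selectivity_class[ses$truth$cell_class[m] ==
                                           "unresponsive"] ==
                     "highly-selective"))
})

test_that("planted exposure decay is recovered from response means", {
  cfg <- session_config(n_trials_block1 = 100, n_trials_block2 = 40,
                        n_animals = 2, cells_per_animal = 5, seed = 41)
  ses <- run_simulate(cfg, p_selective = 1, p_responsive = 0,
                      noise_sd = 2, exposure_decay = 0.9)
  dff <- preprocess_traces(ses$traces)
  rt <- build_response_table(dff, ses$events, cfg)
  amp <- rt[!is.na(rt$exposure_index) &
              rt$cell_id %in% ses$truth$cell_id[ses$truth$pe_gain > 0], ]
  means <- tapply(amp$response, amp$exposure_index, mean)
  fit <- estimate_exposure_decay(as.integer(names(means)),
                                 as.numeric(means))
  expect_lt(abs(fit$lambda - 0.9), 0.1)
})
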