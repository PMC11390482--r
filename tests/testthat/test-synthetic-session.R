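test_that("trial sequence realizes the exact oddball design", {
  cfg <- session_config(seed = 3)
  tr <- generate_trial_sequence(cfg)
  expect_equal(nrow(tr), 200L)
  expect_equal(sum(tr$is_oddball & tr$block == 1L), 16L)
  expect_equal(sum(tr$is_oddball & tr$block == 2L), 40L)
  expect_true(all(tr$stim4[tr$block == 2L] == "C"))
  # block-1 trials precede block-2 trials
  expect_true(max(which(tr$block == 1L)) < min(which(tr$block == 2L)))

  # axonal-bouton variant: shorter block 1, higher oddball rate
  cfg_ax <- session_config(n_trials_block1 = 60, oddball_probability = 0.15,
                           imaging_rate = 15, seed = 3)
  tr_ax <- generate_trial_sequence(cfg_ax)
  expect_equal(sum(tr_ax$is_oddball & tr_ax$block == 1L), 9L)
})

test_that("oddball count equals round(p * n) for every seed", {
  for (s in 1:20) {
    cfg <- session_config(oddball_probability = 0.13, seed = s)
    tr <- generate_trial_sequence(cfg)
    expect_equal(sum(tr$is_oddball & tr$block == 1L), round(0.13 * 160))
  }
})

test_that("trial generation is reproducible and validates its config", {
  cfg <- session_config(seed = 9)
  expect_identical(generate_trial_sequence(cfg), generate_trial_sequence(cfg))
  expect_error(session_config(oddball_position = 5), "position")
  expect_error(session_config(oddball_probability = 1.2), "probability")
  expect_error(session_config(imaging_rate = 0), "imaging_rate")
})

test_that("events flatten trials with correct labels and timing", {
  cfg <- session_config(seed = 4)
  ev <- generate_events(generate_trial_sequence(cfg), cfg)
  expect_equal(nrow(ev), 800L)
  expect_true(all(table(ev$trial_id) == 4L))
  # onsets strictly increasing within each trial
  expect_true(all(tapply(ev$onset, ev$trial_id, function(x) all(diff(x) > 0))))
  # expectation is defined against the trained sequence at each position
  base <- cfg$base_sequence[ev$position]
  expect_identical(ev$expectation,
                   ifelse(ev$identity == base, "expected", "unexpected"))
  # exposure counter covers every oddball presentation, never resets
  expect_equal(max(ev$exposure_index, na.rm = TRUE), 16L + 40L)
  expect_identical(ev$exposure_index[!is.na(ev$exposure_index)],
                   seq_len(56L))
})

test_that("omission oddballs yield flagged, unexpected omission events", {
  cfg <- session_config(oddball_identity = "omission", seed = 5)
  ev <- generate_events(generate_trial_sequence(cfg), cfg)
  om <- ev[ev$is_omission, ]
  expect_gt(nrow(om), 0)
  expect_true(all(om$identity == "omission"))
  expect_true(all(om$expectation == "unexpected"))
  expect_true(all(om$position == 4L))
})

test_that("analysis conditions label block-1 oddballs and late block 2", {
  cfg <- session_config(seed = 6)
  ev <- generate_events(generate_trial_sequence(cfg), cfg)
  cond <- oddball2p:::event_condition(ev, cfg)
  unexp <- which(cond == "unexpected")
  expect_true(all(ev$block[unexp] == 1L))
  expect_equal(length(unexp), 16L)
  expd <- which(cond == "expected")
  # last floor(40/2) = 20 block-2 trials
  expect_equal(length(expd), 20L)
  expect_true(all(ev$trial_id[expd] >= 181L))
})

test_that("forward model matches its closed form exactly when noiseless", {
  cfg <- small_config(seed = 2)
  trials <- generate_trial_sequence(cfg)
  ev <- generate_events(trials, cfg)
  beh <- flat_behavior(trials, cfg)
  truth <- make_truth(tuning = list(C = 1), pe_gain = 1, exposure_decay = 0.8)
  traces <- generate_traces(truth, ev, beh, cfg)

  # independent reconstruction: amplitude 1 + 0.8^(k-1) on the k-th oddball
  # exposure, tuning elsewhere zero, convolved with the kernel definition
  dt <- 1 / cfg$imaging_rate
  nf <- length(traces$time)
  tt <- seq(0, 4, by = dt)
  kern <- exp(-tt / 0.6) - exp(-tt / 0.05)
  kern <- kern / max(kern)
  imp <- numeric(nf)
  odd <- ev[!is.na(ev$exposure_index), ]
  for (i in seq_len(nrow(odd))) {
    fr <- round(odd$onset[i] / dt) + 1L
    imp[fr] <- imp[fr] + 1 * (1 + 1 * 0.8^(odd$exposure_index[i] - 1))
  }
  expected_sig <- stats::convolve(imp, rev(kern), type = "open")[seq_len(nf)]
  expect_equal(as.numeric(traces$raw[1, ]), 100 * (1 + expected_sig),
               tolerance = 1e-9)
})

test_that("degenerate generator settings give flat or condition-equal traces", {
  # trial duration chosen so every oddball onset has the same frame phase
  cfg <- small_config(seed = 3, trial_duration = 13.2)
  trials <- generate_trial_sequence(cfg)
  ev <- generate_events(trials, cfg)
  beh <- flat_behavior(trials, cfg)

  # all tunings zero, no noise, no neuropil: constant at f0_true
  flat <- generate_traces(make_truth(), ev, beh, cfg)
  expect_equal(as.numeric(flat$raw[1, ]), rep(100, ncol(flat$raw)),
               tolerance = 1e-12)
  expect_error(generate_traces(make_truth(f0 = -1), ev, beh, cfg), "f0")

  # pe_gain = 0: block-1 oddball responses equal late-block-2 responses
  tr0 <- generate_traces(make_truth(tuning = list(C = 1)), ev, beh, cfg)
  z <- (tr0$raw[1, ] - mean(tr0$raw[1, ])) / sd(tr0$raw[1, ])
  cond <- oddball2p:::event_condition(ev, cfg)
  resp <- vapply(ev$onset, function(o)
    compute_response(z, tr0$time, o)$response, numeric(1))
  expect_equal(mean(resp[which(cond == "unexpected")]),
               mean(resp[which(cond == "expected")]), tolerance = 1e-6)
})

test_that("event-window response is affine and increasing in planted amplitude", {
  cfg <- small_config(seed = 8, trial_duration = 13.2)
  trials <- generate_trial_sequence(cfg)
  ev <- generate_events(trials, cfg)
  beh <- flat_behavior(trials, cfg)
  # a fixed second tuning keeps the z normalization from cancelling the
  # amplitude scaling outright
  amps <- c(0.2, 0.5, 1, 1.5, 2.5)
  resp <- vapply(amps, function(a) {
    tr <- generate_traces(make_truth(tuning = list(C = a, A = 0.6)),
                          ev, beh, cfg)
    z <- (tr$raw[1, ] - mean(tr$raw[1, ])) / sd(tr$raw[1, ])
    cond <- oddball2p:::event_condition(ev, cfg)
    mean(vapply(ev$onset[which(cond == "expected")], function(o)
      compute_response(z, tr$time, o)$response, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(resp) > 0))
})

test_that("frame stacks plant shifts losslessly and reproducibly", {
  sh <- rbind(c(0, 0), c(3, -2), c(0, 0), c(-5, 7), c(0, 0))
  st <- generate_frame_stack(5, sh, seed = 11)
  expect_identical(attr(st, "shifts"), matrix(as.integer(sh), ncol = 2))
  expect_identical(unclass(generate_frame_stack(5, sh, seed = 11))[],
                   unclass(st)[])
  # zero-shift frames agree up to noise
  st0 <- generate_frame_stack(4, seed = 12, snr = 20)
  expect_gt(cor(as.vector(st0[, , 1]), as.vector(st0[, , 2])), 0.9)
  expect_error(generate_frame_stack(2, rbind(c(0, 0), c(40, 0)), seed = 1),
               "quarter")
})

test_that("behavior traces are positive-speed and carry planted pupil outliers", {
  cfg <- small_config(seed = 4)
  trials <- generate_trial_sequence(cfg)
  beh <- generate_behavior(trials, cfg, n_animals = 1)
  expect_true(all(beh$running_speed >= 0))
  expect_equal(nrow(beh), length(flat_behavior(trials, cfg)$time))
  planted <- attr(beh, "planted_outliers")
  expect_equal(length(planted), 5L)
  # planted spikes dominate the trace
  expect_true(all(beh$pupil_area[planted] > 500))
  # multi-animal sessions get one independent trace per animal
  long <- generate_behavior(trials, cfg)
  expect_equal(sort(unique(long$animal_id)), 1:2)
  b1 <- behavior_for_animal(long, 1); b2 <- behavior_for_animal(long, 2)
  expect_equal(nrow(b1), nrow(beh))
  expect_false(identical(b1$running_speed, b2$running_speed))
})
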