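# Independent oracles and fixture builders shared across tests.
# Everything here is deliberately written from first principles (no calls
# into the code paths under test).

# circular roll used by fixtures and the registration oracle
roll2 <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  m[((seq_len(h) - 1 - dy) %% h) + 1, ((seq_len(w) - 1 - dx) %% w) + 1,
    drop = FALSE]
}

# exhaustive cross-correlation registration oracle: best integer shift of
# the reference over a +/- max_shift grid
xcorr_shift_oracle <- function(ref, frame, max_shift = 8) {
  best <- c(0L, 0L); best_score <- -Inf
  for (dy in -max_shift:max_shift) for (dx in -max_shift:max_shift) {
    sc <- sum(roll2(ref, dy, dx) * frame)
    if (sc > best_score) { best_score <- sc; best <- c(dy, dx) }
  }
  best
}

# exhaustive paired sign-flip permutation p-value (two-sided), n <= 12
exhaustive_paired_p <- function(a, b) {
  d <- a - b; n <- length(d)
  obs <- mean(d)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  stats <- as.numeric(signs %*% d) / n
  mean(abs(stats) >= abs(obs) - 1e-12)
}

# exhaustive two-sample label-permutation p-value (two-sided), small n
exhaustive_unpaired_p <- function(a, b) {
  pool <- c(a, b); na <- length(a)
  obs <- mean(a) - mean(b)
  idx <- utils::combn(length(pool), na)
  stats <- apply(idx, 2, function(i) mean(pool[i]) - mean(pool[-i]))
  mean(abs(stats) >= abs(obs) - 1e-12)
}

# ground-truth table builder with explicit per-cell parameters
make_truth <- function(n_cells = 1L, animal_id = rep(1L, n_cells),
                       tuning = list(), pe_gain = 0, exposure_decay = 0.9,
                       r_np = 0, f0 = 100, noise_sd = 0, running_gain = 0,
                       animal_effect = 0) {
  labels <- c("A", "B", "C", "D", "E", "omission")
  tun <- matrix(0, n_cells, length(labels),
                dimnames = list(NULL, paste0("tuning_", labels)))
  for (lab in names(tuning)) tun[, paste0("tuning_", lab)] <- tuning[[lab]]
  cbind(data.frame(animal_id = animal_id, cell_id = seq_len(n_cells),
                   cell_class = "custom",
                   pe_gain = pe_gain, exposure_decay = exposure_decay,
                   neuropil_coefficient = r_np, f0_true = f0,
                   noise_sd = noise_sd, running_gain = running_gain,
                   animal_effect = animal_effect,
                   gt_selectivity = NA_real_),
        as.data.frame(tun))
}

# constant-speed, outlier-free behavior trace matching a trial table
flat_behavior <- function(trials, config, speed = 0) {
  dt <- 1 / config$imaging_rate
  t_end <- max(trials$trial_start) + config$trial_duration
  time <- seq(0, t_end - dt / 2, by = dt)
  data.frame(time = time, running_speed = rep(speed, length(time)),
             pupil_area = rep(100, length(time)))
}

small_config <- function(seed = 1L, ...) {
  session_config(n_trials_block1 = 40L, n_trials_block2 = 16L,
                 n_animals = 2L, cells_per_animal = 6L, seed = seed, ...)
}

# neuropil fixture: cell contaminated by a neuropil trace carrying slow
# shared fluctuations and (optionally) stimulus-locked transients that also
# drive the cell itself -- the regime in which least squares over-estimates r
make_np_fixture <- function(seed, r = 0.7, transients = FALSE, n = 3000) {
  set.seed(seed)
  kern <- exp(-seq(0, 4, by = 1 / 7.5) / 0.6) -
    exp(-seq(0, 4, by = 1 / 7.5) / 0.05)
  kern <- kern / max(kern)
  drive <- numeric(n)
  if (transients) {
    ev <- sort(sample(n - 40L, 120L))
    for (e in ev) {
      ix <- e:(e + length(kern) - 1L)
      drive[ix] <- drive[ix] + kern * runif(1, 0.5, 1)
    }
  }
  slow <- stats::filter(rnorm(n), rep(1, 50) / 50, sides = 1)
  slow[is.na(slow)] <- 0
  slow <- as.numeric(slow) * sqrt(50) * 0.15
  np <- 60 * (1 + 0.1 * drive + slow) + rnorm(n, 0, 2)
  cell <- 100 * (1 + 1.2 * drive) + r * np + rnorm(n, 0, 2)
  list(cell = cell, np = np, r = r)
}

# baseline-plus-transients trace for F0 recovery: a known fraction of frames
# carries positive transient excursions
make_f0_fixture <- function(seed, transient_frac, noise_sd = 2, n = 3000,
                            f0 = 100) {
  set.seed(seed)
  x <- rnorm(n, f0, noise_sd)
  n_tr <- round(transient_frac * n)
  idx <- sample.int(n, n_tr)
  x[idx] <- x[idx] + f0 * runif(n_tr, 0.3, 1.5)
  list(trace = x, f0 = f0)
}
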