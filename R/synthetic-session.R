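#' Generate the trial table of an oddball session
#'
#' Block 1 contains exactly `round(oddball_probability * n_trials_block1)`
#' oddball trials at uniformly random positions in the trial order; in block 2
#' every trial carries the oddball identity at the oddball position. When
#' `led_fraction > 0`, LED-on trials are drawn separately within each
#' block-by-oddball stratum (optogenetic stimulation is interleaved within
#' trial types), again as an exact count.
#'
#' @param config A [session_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A data.frame with one row per trial: `trial_id`, `block`,
#'   `stim1`..`stim4` (stimulus identity at each corridor position),
#'   `is_oddball`, `led_state` (`"on"`, `"off"` or `"none"`), `trial_start`
#'   (seconds). Block-1 trials precede block-2 trials.
#' @export
generate_trial_sequence <- function(config, seed = config$seed) {
  validate_session_config(config)
  set.seed(seed)
  n1 <- config$n_trials_block1
  n2 <- config$n_trials_block2
  n <- n1 + n2
  n_pos <- length(config$base_sequence)

  stim <- matrix(rep(config$base_sequence, each = n), nrow = n)
  is_oddball <- logical(n)
  n_odd1 <- round(config$oddball_probability * n1)
  odd1 <- sample.int(n1, n_odd1)
  is_oddball[odd1] <- TRUE
  if (n2 > 0L) is_oddball[(n1 + 1L):n] <- TRUE
  stim[is_oddball, config$oddball_position] <- config$oddball_identity

  led_state <- rep("none", n)
  if (config$led_fraction > 0) {
    block <- rep(c(1L, 2L), c(n1, n2))
    for (b in unique(block)) for (odd in c(TRUE, FALSE)) {
      idx <- which(block == b & is_oddball == odd)
      if (length(idx) == 0L) next
      n_on <- round(config$led_fraction * length(idx))
      led_state[idx] <- "off"
      led_state[sample(idx, n_on)] <- "on"
    }
  }

  out <- data.frame(
    trial_id = seq_len(n),
    block = rep(c(1L, 2L), c(n1, n2)),
    is_oddball = is_oddball,
    led_state = led_state,
    trial_start = (seq_len(n) - 1) * config$trial_duration
  )
  colnames(stim) <- paste0("stim", seq_len(n_pos))
  cbind(out, as.data.frame(stim))
}

#' Flatten a trial table into per-stimulus events
#'
#' Each trial yields one event per corridor position. An event is labeled
#' `"unexpected"` when its identity differs from the trained sequence at that
#' position, `"expected"` otherwise; the analysis-level "expected oddball"
#' condition (late block 2) is selected downstream. Omission events are
#' flagged and carry no stimulus drive in the forward model.
#' `exposure_index` counts, 1-based and never resetting, the presentations of
#' the oddball identity at the oddball position up to and including the event
#' (NA for all other events); it drives the exposure-dependent decay of the
#' prediction-error amplification.
#'
#' @param trials Output of [generate_trial_sequence()].
#' @param config The matching [session_config()].
#' @return A data.frame with one row per event: `trial_id`, `block`,
#'   `position`, `identity`, `onset`, `duration`, `expectation`,
#'   `is_omission`, `exposure_index`, `led_state`.
#' @export
generate_events <- function(trials, config) {
  n_pos <- length(config$base_sequence)
  n <- nrow(trials)
  ev <- data.frame(
    trial_id = rep(trials$trial_id, each = n_pos),
    block = rep(trials$block, each = n_pos),
    position = rep(seq_len(n_pos), times = n),
    led_state = rep(trials$led_state, each = n_pos)
  )
  stim <- as.matrix(trials[, paste0("stim", seq_len(n_pos)), drop = FALSE])
  ev$identity <- as.vector(t(stim))
  # first onset 1 s after trial start, then every inter_onset seconds
  ev$onset <- rep(trials$trial_start, each = n_pos) +
    1 + (ev$position - 1) * config$inter_onset
  ev$duration <- config$stimulus_duration
  ev$expectation <- ifelse(ev$identity == config$base_sequence[ev$position],
                           "expected", "unexpected")
  ev$is_omission <- ev$identity == "omission"
  odd_ev <- ev$position == config$oddball_position &
    ev$identity == config$oddball_identity
  ev$exposure_index <- NA_integer_
  ev$exposure_index[odd_ev] <- seq_len(sum(odd_ev))
  ev
}

#' Double-exponential calcium impulse response
#'
#' Kernel `exp(-t/tau_decay) - exp(-t/tau_rise)` sampled at the imaging rate
#' and normalized to unit peak, on a GCaMP6f-like time scale. The forward
#' model convolves event amplitudes with this kernel; the analysis never
#' assumes it.
#'
#' @param imaging_rate Frames per second.
#' @param tau_rise,tau_decay Rise and decay time constants, seconds.
#' @param length_s Kernel support, seconds.
#' @return Numeric vector of kernel samples (first sample at t = 0).
#' @export
calcium_kernel <- function(imaging_rate, tau_rise = 0.05, tau_decay = 0.6,
                           length_s = 4) {
  t <- seq(0, length_s, by = 1 / imaging_rate)
  k <- exp(-t / tau_decay) - exp(-t / tau_rise)
  k / max(k)
}

#' Simulate behavioral traces for a session
#'
#' Running speed is smoothed positive noise around a baseline speed, with an
#' optional stimulus-triggered deceleration on oddball trials (a transient
#' speed dip after the oddball onset) used to probe running-speed confounds.
#' Pupil area is a slow drift with planted outlier spikes whose indices are
#' recorded in `attr(, "planted_outliers")` for filter-recovery tests.
#' Each animal gets its own independent traces (animals run and blink
#' independently); with `n_animals > 1` the result is in long format with an
#' `animal_id` column, otherwise a single plain trace.
#'
#' @param trials,config Trial table and configuration.
#' @param seed Integer seed.
#' @param mean_speed Baseline running speed, cm/s.
#' @param speed_sd Standard deviation of the smoothed speed fluctuations, cm/s.
#' @param oddball_deceleration Depth of the transient speed dip on oddball
#'   trials, cm/s (0 disables it).
#' @param n_pupil_outliers Number of planted pupil outliers per animal.
#' @param n_animals Number of independent behavior traces.
#' @return A data.frame `time`, `running_speed`, `pupil_area` sampled at the
#'   imaging rate over the whole session, with an `animal_id` column when
#'   `n_animals > 1`. Planted pupil-outlier indices (per animal, relative to
#'   that animal's rows) are in `attr(, "planted_outliers")`.
#' @export
generate_behavior <- function(trials, config, seed = config$seed + 1L,
                              mean_speed = 15, speed_sd = 4,
                              oddball_deceleration = 0,
                              n_pupil_outliers = 5L,
                              n_animals = config$n_animals) {
  set.seed(seed)
  dt <- 1 / config$imaging_rate
  t_end <- max(trials$trial_start) + config$trial_duration
  time <- seq(0, t_end - dt / 2, by = dt)
  nf <- length(time)

  one_animal <- function() {
    # smoothed AR-like fluctuations around the mean speed
    w <- stats::filter(stats::rnorm(nf), rep(1, 30) / 30, sides = 1)
    w[is.na(w)] <- 0
    speed <- mean_speed + speed_sd * as.numeric(w) * sqrt(30)
    if (oddball_deceleration > 0) {
      odd <- trials[trials$is_oddball, , drop = FALSE]
      onset <- odd$trial_start + 1 +
        (config$oddball_position - 1) * config$inter_onset
      dip <- exp(-seq(0, 3, by = dt) / 1)  # ~1 s recovery
      for (o in onset) {
        i0 <- which.min(abs(time - o))
        idx <- i0:min(nf, i0 + length(dip) - 1L)
        speed[idx] <- speed[idx] - oddball_deceleration * dip[seq_along(idx)]
      }
    }
    speed <- pmax(speed, 0)
    pupil <- 100 + 10 * sin(2 * pi * time / 120) +
      as.numeric(stats::filter(stats::rnorm(nf, sd = 2), rep(1, 15) / 15,
                               sides = 1, circular = TRUE))
    out_idx <- sort(sample.int(nf - 20L, n_pupil_outliers) + 10L)
    pupil[out_idx] <- pupil[out_idx] + 10 * 100  # 10x-amplitude spikes
    list(df = data.frame(time = time, running_speed = speed,
                         pupil_area = pupil),
         outliers = out_idx)
  }

  per_animal <- lapply(seq_len(n_animals), function(a) one_animal())
  if (n_animals == 1L) {
    beh <- per_animal[[1]]$df
    attr(beh, "planted_outliers") <- per_animal[[1]]$outliers
    return(beh)
  }
  beh <- do.call(rbind, lapply(seq_len(n_animals), function(a)
    cbind(animal_id = a, per_animal[[a]]$df)))
  attr(beh, "planted_outliers") <-
    data.frame(animal_id = rep(seq_len(n_animals), each = n_pupil_outliers),
               index = unlist(lapply(per_animal, `[[`, "outliers")))
  beh
}

#' Extract one animal's behavior trace
#'
#' Returns the single-animal trace from a (possibly long-format) behavior
#' table; a table without an `animal_id` column is returned unchanged.
#'
#' @param behavior Behavior table from [generate_behavior()].
#' @param animal Animal id.
#' @return A data.frame `time`, `running_speed`, `pupil_area`.
#' @export
behavior_for_animal <- function(behavior, animal) {
  if (!"animal_id" %in% names(behavior)) return(behavior)
  out <- behavior[behavior$animal_id == animal,
                  c("time", "running_speed", "pupil_area")]
  rownames(out) <- NULL
  out
}

#' Draw ground-truth cell parameters
#'
#' Cells are assigned to one of three populations: oddball-selective
#' (strongly tuned to the oddball identity, weakly to the trained gratings),
#' non-selective responsive (similarly tuned to all gratings), and
#' unresponsive. Prediction-error amplification (`pe_gain`) is planted only
#' in cells whose ground-truth selectivity, computed from the tuning
#' amplitudes with the same contrast used by the analysis, exceeds
#' `pe_selectivity_floor`. Animal-level offsets give the nesting structure
#' the hierarchical bootstrap assumes.
#'
#' @param config A [session_config()].
#' @param seed Integer seed.
#' @param p_selective,p_responsive Population fractions (remainder is
#'   unresponsive).
#' @param pe_gain Multiplicative prediction-error amplification planted in
#'   selective cells (response factor `1 + pe_gain * exposure_decay^(k-1)` on
#'   the k-th oddball exposure).
#' @param exposure_decay Per-exposure decay of the amplification, in (0, 1].
#' @param pe_selectivity_floor Ground-truth selectivity above which a cell
#'   receives `pe_gain`.
#' @param noise_sd Per-frame fluorescence noise SD, a.u.
#' @param running_gain Response amplitude added per cm/s of running speed.
#' @param animal_sd SD of the additive animal-level amplitude offset.
#' @return A data.frame with one row per cell: `animal_id`, `cell_id`,
#'   `cell_class`, `tuning_A` .. `tuning_E`, `tuning_omission`, `pe_gain`,
#'   `exposure_decay`, `neuropil_coefficient`, `f0_true`, `noise_sd`,
#'   `running_gain`, `animal_effect`, `gt_selectivity`.
#' @export
generate_ground_truth <- function(config, seed = config$seed + 2L,
                                  p_selective = 0.25, p_responsive = 0.45,
                                  pe_gain = 1.0, exposure_decay = 0.9,
                                  pe_selectivity_floor = 0.8,
                                  noise_sd = 5, running_gain = 0.002,
                                  animal_sd = 0.15) {
  set.seed(seed)
  n_cells <- config$n_animals * config$cells_per_animal
  animal_id <- rep(seq_len(config$n_animals), each = config$cells_per_animal)
  cls <- sample(c("selective", "responsive", "unresponsive"), n_cells,
                replace = TRUE,
                prob = c(p_selective, p_responsive,
                         max(0, 1 - p_selective - p_responsive)))
  labels <- c("A", "B", "C", "D", "E", "omission")
  tun <- matrix(0, n_cells, length(labels),
                dimnames = list(NULL, paste0("tuning_", labels)))
  odd_col <- paste0("tuning_", config$oddball_identity)
  base_cols <- paste0("tuning_", unique(config$base_sequence))
  sel <- cls == "selective"
  rsp <- cls == "responsive"
  tun[sel, odd_col] <- stats::rnorm(sum(sel), 1.5, 0.2)
  for (bc in base_cols)
    tun[sel, bc] <- pmax(stats::rnorm(sum(sel), 0.05, 0.03), 0)
  for (cc in unique(c(odd_col, base_cols)))
    tun[rsp, cc] <- pmax(stats::rnorm(sum(rsp), 0.8, 0.15), 0.1)
  tun[] <- pmax(tun, 0)

  # ground-truth selectivity: oddball tuning against trained-grating tuning,
  # same contrast the analysis computes from late-block-2 responses
  t_ref <- rowMeans(tun[, base_cols, drop = FALSE])
  gt_sel <- ifelse(tun[, odd_col] + t_ref > 0,
                   (tun[, odd_col] - t_ref) / (tun[, odd_col] + t_ref), NA)
  gt_sel <- pmin(pmax(gt_sel, -1), 1)

  animal_effect <- stats::rnorm(config$n_animals, 0, animal_sd)[animal_id]
  truth <- data.frame(
    animal_id = animal_id,
    cell_id = seq_len(n_cells),
    cell_class = cls,
    pe_gain = ifelse(!is.na(gt_sel) & gt_sel > pe_selectivity_floor, pe_gain, 0),
    exposure_decay = exposure_decay,
    neuropil_coefficient = stats::runif(n_cells, 0.4, 0.8),
    f0_true = stats::runif(n_cells, 80, 120),
    noise_sd = noise_sd,
    running_gain = running_gain,
    animal_effect = animal_effect,
    gt_selectivity = gt_sel
  )
  cbind(truth, as.data.frame(tun))
}

#' Forward-model fluorescence traces from ground truth
#'
#' For each cell, every stimulus event contributes an amplitude
#' `tuning(identity) * (1 + pe_gain * exposure_decay^(k-1))` on its k-th
#' oddball exposure (amplification applies only to oddball-identity events at
#' the oddball position), plus `running_gain * speed(onset)` and the additive
#' animal offset for non-omission events. Amplitudes are convolved with the
#' double-exponential calcium kernel; the cell trace is
#' `f0_true * (1 + signal) + noise`, and the measured trace is contaminated
#' as `F_meas = F_cell + r_np * F_neuropil`, where the neuropil trace mixes a
#' slow animal-shared fluctuation with a weak population stimulus drive.
#'
#' @param truth Ground-truth table from [generate_ground_truth()].
#' @param events Event table from [generate_events()].
#' @param behavior Behavioral traces from [generate_behavior()].
#' @param config The [session_config()].
#' @param seed Integer seed.
#' @return An object of class `"raw_trace_set"`: list with `time` (frame
#'   timestamps), `raw` and `neuropil` (cells x frames matrices, a.u.),
#'   `animal_id`, `cell_id`, `session_id`.
#' @export
generate_traces <- function(truth, events, behavior, config,
                            seed = config$seed + 3L,
                            session_id = "synthetic") {
  if (any(truth$f0_true <= 0))
    stop("f0_true must be positive for every cell", call. = FALSE)
  set.seed(seed)
  time <- behavior_for_animal(behavior, 1L)$time
  nf <- length(time)
  dt <- 1 / config$imaging_rate
  kern <- calcium_kernel(config$imaging_rate)
  n_cells <- nrow(truth)

  ev <- events
  ev$frame <- pmin(pmax(round(ev$onset / dt) + 1L, 1L), nf)
  # per-animal running speed at each event onset
  animals <- sort(unique(truth$animal_id))
  speed_at_onset <- lapply(animals, function(a)
    behavior_for_animal(behavior, a)$running_speed[ev$frame])
  names(speed_at_onset) <- as.character(animals)
  amp_odd <- !is.na(ev$exposure_index)
  expo_k <- ifelse(amp_odd, ev$exposure_index - 1L, 0L)  # NA-safe exponent

  # shared slow neuropil fluctuation per animal + weak population drive
  pop_drive <- numeric(nf)
  mean_tun <- colMeans(truth[, paste0("tuning_",
                                      c("A", "B", "C", "D", "E", "omission"))])
  pop_amp <- mean_tun[paste0("tuning_", ev$identity)]
  pop_amp[ev$is_omission] <- 0
  imp <- numeric(nf)
  for (i in seq_len(nrow(ev))) imp[ev$frame[i]] <- imp[ev$frame[i]] + pop_amp[i]
  pop_drive <- conv_kernel(imp, kern)
  slow <- lapply(seq_len(config$n_animals), function(a) {
    s <- stats::filter(stats::rnorm(nf), rep(1, 50) / 50, sides = 1)
    s[is.na(s)] <- 0
    as.numeric(s) * sqrt(50) * 0.15
  })

  raw <- matrix(0, n_cells, nf)
  npil <- matrix(0, n_cells, nf)
  tun_mat <- as.matrix(truth[, paste0("tuning_",
                                      c("A", "B", "C", "D", "E", "omission"))])
  colnames(tun_mat) <- c("A", "B", "C", "D", "E", "omission")
  for (c_i in seq_len(n_cells)) {
    tu <- tun_mat[c_i, ev$identity]
    amp <- tu * (1 + truth$pe_gain[c_i] * amp_odd *
                   truth$exposure_decay[c_i]^expo_k)
    extra <- truth$running_gain[c_i] *
      speed_at_onset[[as.character(truth$animal_id[c_i])]] +
      truth$animal_effect[c_i]
    amp <- amp + ifelse(ev$is_omission, 0, extra)
    imp <- numeric(nf)
    for (i in seq_len(nrow(ev))) imp[ev$frame[i]] <- imp[ev$frame[i]] + amp[i]
    signal <- conv_kernel(imp, kern)
    f_cell <- truth$f0_true[c_i] * (1 + signal) +
      stats::rnorm(nf, 0, truth$noise_sd[c_i])
    f0_np <- 0.7 * truth$f0_true[c_i]
    f_np <- f0_np * (1 + 0.05 * pop_drive + slow[[truth$animal_id[c_i]]]) +
      stats::rnorm(nf, 0, truth$noise_sd[c_i] / 2)
    raw[c_i, ] <- f_cell + truth$neuropil_coefficient[c_i] * f_np
    npil[c_i, ] <- f_np
  }
  structure(list(time = time, raw = raw, neuropil = npil,
                 animal_id = truth$animal_id, cell_id = truth$cell_id,
                 session_id = session_id),
            class = "raw_trace_set")
}

# causal convolution of an impulse train with a finite kernel
conv_kernel <- function(x, kern) {
  n <- length(x)
  out <- stats::convolve(x, rev(kern), type = "open")[seq_len(n)]
  out
}

#' Generate a textured frame stack with planted rigid shifts
#'
#' Frames are integer-pixel circular translations of a smooth random texture
#' plus Gaussian noise; the planted per-frame shifts are recorded losslessly
#' in `attr(, "shifts")` so registration can be scored exactly.
#'
#' @param n_frames Number of frames.
#' @param shifts Integer matrix `n_frames x 2` of planted `(dy, dx)` shifts.
#' @param seed Integer seed.
#' @param height,width Frame size in pixels.
#' @param snr Peak texture amplitude over noise SD.
#' @return A `height x width x n_frames` array of class `"frame_stack"`.
#' @export
generate_frame_stack <- function(n_frames, shifts = NULL, seed = 1L,
                                 height = 64L, width = 64L, snr = 10) {
  set.seed(seed)
  if (is.null(shifts)) shifts <- matrix(0L, n_frames, 2L)
  shifts <- matrix(as.integer(shifts), ncol = 2L)
  stopifnot(nrow(shifts) == n_frames)
  if (any(abs(shifts) >= min(height, width) / 4))
    stop("planted shifts must stay below a quarter of the frame size",
         call. = FALSE)
  # smooth texture: low-pass filtered white noise
  tmpl <- matrix(stats::rnorm(height * width), height, width)
  k <- stats::dnorm(-4:4, sd = 1.5)
  tmpl <- t(apply(tmpl, 1, function(r) stats::filter(r, k, circular = TRUE)))
  tmpl <- apply(tmpl, 2, function(cc) stats::filter(cc, k, circular = TRUE))
  tmpl <- tmpl / max(abs(tmpl))
  noise_sd <- 1 / snr
  stack <- array(0, dim = c(height, width, n_frames))
  for (f in seq_len(n_frames)) {
    stack[, , f] <- roll_matrix(tmpl, shifts[f, 1], shifts[f, 2]) +
      matrix(stats::rnorm(height * width, 0, noise_sd), height, width)
  }
  attr(stack, "shifts") <- shifts
  class(stack) <- "frame_stack"
  stack
}

# circular shift: positive dy moves content down, positive dx moves it right
roll_matrix <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  ri <- ((seq_len(h) - 1 - dy) %% h) + 1
  ci <- ((seq_len(w) - 1 - dx) %% w) + 1
  m[ri, ci, drop = FALSE]
}
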