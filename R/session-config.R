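#' Session configuration for the virtual-corridor oddball paradigm
#'
#' Bundles the trial-structure, imaging and simulation parameters of one
#' oddball session. Defaults reproduce the standard design: a 160-trial
#' conditioning block in which a randomly chosen 10% of traversals carry the
#' oddball stimulus at corridor position 4, followed by a 40-trial block in
#' which every traversal carries it. The trained sequence of gratings along
#' the corridor is A-B-A-B; the oddball identity may be a novel grating
#' ("C" or "D"), the familiar grating "A", or "omission" (no stimulus).
#'
#' @param n_trials_block1 Number of trials in block 1 (conditioning block).
#' @param n_trials_block2 Number of trials in block 2 (all-oddball block).
#' @param oddball_probability Fraction of block-1 trials carrying the oddball;
#'   the realized count is exactly `round(oddball_probability * n_trials_block1)`.
#' @param oddball_position Corridor position (1-4) at which the oddball replaces
#'   the trained stimulus.
#' @param oddball_identity One of `"C"`, `"D"`, `"A"`, `"E"` or `"omission"`.
#' @param base_sequence Trained stimulus labels at the four corridor positions.
#' @param imaging_rate Imaging frame rate in Hz (7.5 for somatic recordings,
#'   15 for axonal boutons).
#' @param stimulus_duration Grating presentation duration in seconds.
#' @param inter_onset Time between consecutive stimulus onsets within a trial,
#'   seconds.
#' @param trial_duration Corridor traversal duration in seconds (one trial).
#' @param n_animals Number of simulated animals.
#' @param cells_per_animal Number of simulated cells per animal.
#' @param led_fraction Fraction of trials (per trial type) with the optogenetic
#'   LED on; 0 disables the LED arm entirely (`led_state = "none"`).
#' @param seed Integer seed governing every random draw of the generator.
#' @return An object of class `"session_config"` (a named list).
#' @export
#' @examples
#' cfg <- session_config()
#' cfg$n_trials_block1
session_config <- function(n_trials_block1 = 160L,
                           n_trials_block2 = 40L,
                           oddball_probability = 0.10,
                           oddball_position = 4L,
                           oddball_identity = "C",
                           base_sequence = c("A", "B", "A", "B"),
                           imaging_rate = 7.5,
                           stimulus_duration = 2,
                           inter_onset = 3,
                           trial_duration = 13.2,
                           n_animals = 6L,
                           cells_per_animal = 40L,
                           led_fraction = 0,
                           seed = 1L) {
  cfg <- list(
    n_trials_block1 = as.integer(n_trials_block1),
    n_trials_block2 = as.integer(n_trials_block2),
    oddball_probability = oddball_probability,
    oddball_position = as.integer(oddball_position),
    oddball_identity = oddball_identity,
    base_sequence = as.character(base_sequence),
    imaging_rate = imaging_rate,
    stimulus_duration = stimulus_duration,
    inter_onset = inter_onset,
    trial_duration = trial_duration,
    n_animals = as.integer(n_animals),
    cells_per_animal = as.integer(cells_per_animal),
    led_fraction = led_fraction,
    seed = as.integer(seed)
  )
  class(cfg) <- "session_config"
  validate_session_config(cfg)
  cfg
}

validate_session_config <- function(cfg) {
  stopifnot(inherits(cfg, "session_config"))
  if (cfg$oddball_probability < 0 || cfg$oddball_probability > 1)
    stop("oddball_probability must lie in [0, 1]", call. = FALSE)
  if (cfg$n_trials_block1 < 1L || cfg$n_trials_block2 < 0L)
    stop("n_trials_block1 must be >= 1 and n_trials_block2 >= 0", call. = FALSE)
  if (cfg$oddball_position < 1L || cfg$oddball_position > length(cfg$base_sequence))
    stop("oddball_position must index a corridor position (1-",
         length(cfg$base_sequence), ")", call. = FALSE)
  if (cfg$imaging_rate <= 0)
    stop("imaging_rate must be positive", call. = FALSE)
  if (!cfg$oddball_identity %in% c("A", "B", "C", "D", "E", "omission"))
    stop("oddball_identity must be one of A, B, C, D, E, omission", call. = FALSE)
  if (cfg$led_fraction < 0 || cfg$led_fraction > 1)
    stop("led_fraction must lie in [0, 1]", call. = FALSE)
  if (cfg$inter_onset <= cfg$stimulus_duration * 0)
    stopifnot(cfg$inter_onset > 0)
  n_stim_span <- (length(cfg$base_sequence) - 1) * cfg$inter_onset +
    cfg$stimulus_duration
  if (cfg$trial_duration <= n_stim_span)
    stop("trial_duration too short to fit ", length(cfg$base_sequence),
         " stimulus presentations", call. = FALSE)
  invisible(cfg)
}

#' @export
print.session_config <- function(x, ...) {
  n_odd <- round(x$oddball_probability * x$n_trials_block1)
  cat("Oddball session configuration\n")
  cat(sprintf("  block 1: %d trials (%d oddballs, p = %.2f)\n",
              x$n_trials_block1, n_odd, x$oddball_probability))
  cat(sprintf("  block 2: %d trials (all oddball)\n", x$n_trials_block2))
  cat(sprintf("  sequence %s; oddball '%s' at position %d\n",
              paste(x$base_sequence, collapse = "-"),
              x$oddball_identity, x$oddball_position))
  cat(sprintf("  imaging %.1f Hz; %d animals x %d cells; seed %d\n",
              x$imaging_rate, x$n_animals, x$cells_per_animal, x$seed))
  invisible(x)
}
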