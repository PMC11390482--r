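#' Event-aligned response strength
#'
#' Mean z-scored dF/F over the response window (default 0.4-2.0 s after
#' stimulus onset, half-open at the right edge) minus the mean over the
#' baseline window (default the 0.5 s before onset, half-open at onset).
#'
#' @param z_dff Numeric z-scored dF/F trace.
#' @param time Frame timestamps, seconds.
#' @param onset Event onset, seconds.
#' @param window,baseline Window bounds relative to onset; both half-open on
#'   the right.
#' @param exclude_frames Frame indices (e.g. motion-flagged) treated as
#'   missing.
#' @return List with `response` (baseline-subtracted window mean), `baseline`
#'   (baseline-window mean), and the frame counts used; `response` is NA when
#'   either window is empty.
#' @export
compute_response <- function(z_dff, time, onset, window = c(0.4, 2.0),
                             baseline = c(-0.5, 0), exclude_frames = integer(0)) {
  keep <- rep(TRUE, length(time))
  keep[exclude_frames] <- FALSE
  # half-open windows with a small guard so frames landing exactly on a
  # boundary are assigned deterministically despite floating-point jitter
  eps <- 1e-9
  win <- which(time >= onset + window[1] - eps &
                 time < onset + window[2] - eps & keep)
  base <- which(time >= onset + baseline[1] - eps &
                  time < onset + baseline[2] - eps & keep)
  if (length(win) == 0L || length(base) == 0L)
    return(list(response = NA_real_, baseline = NA_real_,
                n_window = length(win), n_baseline = length(base)))
  b <- mean(z_dff[base])
  list(response = mean(z_dff[win]) - b, baseline = b,
       n_window = length(win), n_baseline = length(base))
}

#' Build the per-cell, per-event response table
#'
#' Computes the baseline-subtracted window response of every cell to every
#' stimulus event, and attaches the analysis condition: `"unexpected"` for
#' block-1 oddball-identity events at the oddball position, `"expected"` for
#' the same events in the second half of block 2 (the "late block 2"
#' operationalization of an expected presentation), NA otherwise. Events
#' whose response window loses more than half of its frames to motion
#' flagging are dropped.
#'
#' @param dff A `"dff_trace_set"`.
#' @param events Event table from [generate_events()] (or equivalent).
#' @param config The [session_config()].
#' @param window,baseline Response and baseline windows, seconds relative to
#'   onset.
#' @param late_block2_fraction Fraction of block-2 trials (from the end)
#'   counted as "late block 2"; the default takes the last half, rounded
#'   down.
#' @return A data.frame with one row per (cell, event): `cell_id`,
#'   `animal_id`, `trial_id`, `block`, `position`, `identity`, `onset`,
#'   `expectation`, `exposure_index`, `led_state`, `condition`, `response`,
#'   `baseline`.
#' @export
build_response_table <- function(dff, events, config,
                                 window = c(0.4, 2.0), baseline = c(-0.5, 0),
                                 late_block2_fraction = 0.5) {
  stopifnot(inherits(dff, "dff_trace_set"))
  time <- dff$time
  keep <- rep(TRUE, length(time))
  keep[dff$excluded_frames] <- FALSE

  eps <- 1e-9
  win_idx <- lapply(events$onset, function(o)
    which(time >= o + window[1] - eps & time < o + window[2] - eps))
  base_idx <- lapply(events$onset, function(o)
    which(time >= o + baseline[1] - eps & time < o + baseline[2] - eps))
  frac_lost <- vapply(win_idx, function(ix)
    if (length(ix) == 0L) 1 else mean(!keep[ix]), numeric(1))
  ok <- frac_lost <= 0.5 &
    vapply(base_idx, function(ix) any(keep[ix]), logical(1))
  win_idx <- lapply(win_idx, function(ix) ix[keep[ix]])
  base_idx <- lapply(base_idx, function(ix) ix[keep[ix]])

  cond <- event_condition(events, config, late_block2_fraction)
  cells <- setdiff(seq_len(nrow(dff$z)), dff$flagged_cells)
  n_ev <- nrow(events)
  rows <- vector("list", length(cells))
  for (j in seq_along(cells)) {
    ci <- cells[j]
    zt <- dff$z[ci, ]
    resp <- base <- rep(NA_real_, n_ev)
    for (e in which(ok)) {
      b <- mean(zt[base_idx[[e]]])
      resp[e] <- mean(zt[win_idx[[e]]]) - b
      base[e] <- b
    }
    rows[[j]] <- data.frame(
      cell_id = dff$cell_id[ci], animal_id = dff$animal_id[ci],
      trial_id = events$trial_id, block = events$block,
      position = events$position, identity = events$identity,
      onset = events$onset, expectation = events$expectation,
      exposure_index = events$exposure_index, led_state = events$led_state,
      condition = cond, response = resp, baseline = base
    )
  }
  out <- do.call(rbind, rows)
  out[!is.na(out$response), , drop = FALSE]
}

# "unexpected" = block-1 oddball events; "expected" = late-block-2 oddball
# events; NA otherwise
event_condition <- function(events, config, late_block2_fraction = 0.5) {
  odd_ev <- events$position == config$oddball_position &
    events$identity == config$oddball_identity
  n2 <- config$n_trials_block2
  n_late <- floor(n2 * late_block2_fraction)
  first_late <- config$n_trials_block1 + n2 - n_late + 1L
  cond <- rep(NA_character_, nrow(events))
  cond[odd_ev & events$block == 1L] <- "unexpected"
  cond[odd_ev & events$block == 2L & events$trial_id >= first_late] <- "expected"
  cond
}

#' Stimulus-responsiveness threshold rule
#'
#' A cell is responsive to a stimulus when its mean response exceeds the
#' threshold (strict inequality): 0.5 z-scored dF/F for somatic recordings,
#' 0.2 for raw dF/F analyses, 0.1 for axonal boutons.
#'
#' @param mean_response Mean response of the cell to that stimulus.
#' @param threshold Threshold in the same units as `mean_response`.
#' @return Logical flag.
#' @export
classify_stimulus_responsive <- function(mean_response, threshold = 0.5) {
  !is.na(mean_response) & mean_response > threshold
}

#' Prediction-error responsiveness rule
#'
#' A cell is prediction-error-responsive when the responses to unexpected
#' oddball presentations (block 1) differ significantly from responses to
#' expected presentations (second half of block 2; two-sided two-sample
#' t-test at level `alpha`) AND the mean difference exceeds `min_diff`
#' z-scored dF/F. The equal-variance Student t-test is the default; Welch by
#' `var_equal = FALSE`.
#'
#' @param unexpected,expected Numeric response samples for the two
#'   conditions.
#' @param alpha Test level.
#' @param min_diff Minimum mean difference (unexpected minus expected).
#' @param var_equal Equal-variance t-test (default) or Welch.
#' @return List with `flag`, `p_value`, `diff`.
#' @export
classify_pe_responsive <- function(unexpected, expected, alpha = 0.05,
                                   min_diff = 0.5, var_equal = TRUE) {
  unexpected <- unexpected[!is.na(unexpected)]
  expected <- expected[!is.na(expected)]
  if (length(unexpected) < 2L || length(expected) < 2L)
    return(list(flag = FALSE, p_value = NA_real_, diff = NA_real_))
  d <- mean(unexpected) - mean(expected)
  if (stats::sd(unexpected) == 0 && stats::sd(expected) == 0) {
    # degenerate: no variability; differ iff the constants differ
    p <- if (d == 0) 1 else 0
  } else {
    p <- stats::t.test(unexpected, expected, var.equal = var_equal)$p.value
  }
  list(flag = (p < alpha) && (d > min_diff), p_value = p, diff = d)
}

#' Response selectivity
#'
#' `(r_target - r_reference) / (r_target + r_reference)`, clipped to
#' \[-1, 1\]. Inputs are late-block-2 mean responses to the oddball stimulus
#' (target) and to the trained gratings (reference). A zero denominator
#' leaves selectivity undefined (NA) and the cell is excluded from
#' selectivity analyses.
#'
#' @param r_target,r_reference Mean responses.
#' @return Selectivity in \[-1, 1\], or NA.
#' @export
compute_selectivity <- function(r_target, r_reference) {
  den <- r_target + r_reference
  out <- ifelse(den == 0, NA_real_, (r_target - r_reference) / den)
  pmin(pmax(out, -1), 1)
}

#' Selectivity class from the printed cutoffs
#'
#' Responsive cells with selectivity below 0.6 are non-selective, above 0.8
#' highly selective, in between intermediate; unresponsive cells are their
#' own class.
#'
#' @param selectivity Clipped selectivity value (may be NA).
#' @param responsive Logical responsiveness flag for the target stimulus.
#' @param cutoffs Lower/upper selectivity cutoffs.
#' @return Character class label.
#' @export
classify_selectivity_class <- function(selectivity, responsive,
                                       cutoffs = c(0.6, 0.8)) {
  out <- rep(NA_character_, length(selectivity))
  responsive <- rep_len(responsive, length(selectivity))
  out[!responsive] <- "unresponsive"
  def <- responsive & !is.na(selectivity)
  out[def & selectivity < cutoffs[1]] <- "non-selective"
  out[def & selectivity > cutoffs[2]] <- "highly-selective"
  out[def & selectivity >= cutoffs[1] & selectivity <= cutoffs[2]] <-
    "intermediate"
  out
}

#' Selectivity index (SI)
#'
#' Difference between the two mean responses divided by the pooled standard
#' deviation (variances weighted by n - 1); the variant used for noisy
#' axonal bouton traces. A zero pooled SD yields 0 when the means are equal
#' and a signed infinity (flagged by a warning) otherwise.
#'
#' @param responses_a,responses_b Response samples (>= 2 each).
#' @return SI value.
#' @export
compute_si <- function(responses_a, responses_b) {
  responses_a <- responses_a[!is.na(responses_a)]
  responses_b <- responses_b[!is.na(responses_b)]
  stopifnot(length(responses_a) >= 2L, length(responses_b) >= 2L)
  ps <- pooled_sd(responses_a, responses_b)
  d <- mean(responses_a) - mean(responses_b)
  if (ps == 0) {
    if (d == 0) return(0)
    warning("zero pooled SD with unequal means: SI is infinite")
    return(sign(d) * Inf)
  }
  d / ps
}

pooled_sd <- function(a, b) {
  na <- length(a); nb <- length(b)
  sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2))
}

#' Optogenetic recruitment rule
#'
#' A cell is "recruited" when, for at least one of the tested stimulus
#' conditions, its responses with and without LED stimulation differ
#' significantly (two-sided t-test at `alpha = 0.016`) and the mean
#' difference (on minus off) exceeds `min_diff = 0.3` z-scored dF/F.
#'
#' @param on_by_condition,off_by_condition Named lists of response samples
#'   per stimulus condition (matching names).
#' @param alpha Test level (Bonferroni-style 0.05/3 for three conditions).
#' @param min_diff Minimum LED-on minus LED-off mean difference.
#' @param var_equal Equal-variance t-test (default) or Welch.
#' @return List with `flag` and a per-condition data.frame of `p_value` and
#'   `diff`.
#' @export
classify_recruited <- function(on_by_condition, off_by_condition,
                               alpha = 0.016, min_diff = 0.3,
                               var_equal = TRUE) {
  conds <- intersect(names(on_by_condition), names(off_by_condition))
  res <- data.frame(condition = conds, p_value = NA_real_, diff = NA_real_)
  for (i in seq_along(conds)) {
    a <- on_by_condition[[conds[i]]]
    b <- off_by_condition[[conds[i]]]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2L || length(b) < 2L) next
    res$diff[i] <- mean(a) - mean(b)
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      res$p_value[i] <- if (res$diff[i] == 0) 1 else 0
    } else {
      res$p_value[i] <- stats::t.test(a, b, var.equal = var_equal)$p.value
    }
  }
  flag <- any(!is.na(res$p_value) & res$p_value < alpha &
                !is.na(res$diff) & res$diff > min_diff)
  list(flag = flag, by_condition = res)
}

#' Select events for a figure-variant classification rule
#'
#' `"all"` keeps every event; `"led_pooled"` keeps LED-on and LED-off events
#' (used to avoid selection bias toward LED-off trials); `"led_off_only"`
#' keeps LED-off (or LED-free) events only, used when opsin-expressing cells
#' would otherwise be selected by direct activation.
#'
#' @param events Event or response table carrying a `led_state` column.
#' @param mode One of `"all"`, `"led_pooled"`, `"led_off_only"`.
#' @return The selected subset (same type as `events`).
#' @export
select_classification_trials <- function(events,
                                         mode = c("all", "led_pooled",
                                                  "led_off_only")) {
  mode <- match.arg(mode)
  switch(mode,
         all = events,
         led_pooled = events[events$led_state %in% c("on", "off", "none"), ,
                             drop = FALSE],
         led_off_only = events[events$led_state %in% c("off", "none"), ,
                               drop = FALSE])
}

#' Per-cell classification from a response table
#'
#' Applies the full classification chain to every cell: stimulus
#' responsiveness (late-block-2 mean response to the oddball stimulus and
#' pooled responses to the trained gratings), prediction-error
#' responsiveness (unexpected block-1 vs expected late-block-2), selectivity
#' and its class, and the SI variant.
#'
#' @param rt Response table from [build_response_table()].
#' @param config The [session_config()].
#' @param responsive_threshold,pe_alpha,pe_min_diff,selectivity_cutoffs
#'   Classification thresholds.
#' @param trial_mode Event subset rule, see
#'   [select_classification_trials()].
#' @param responsive_pool `"either"` classifies a cell as target-responsive
#'   if responsive in the unexpected or the expected condition (the default);
#'   `"expected"` uses late-block-2 responses only.
#' @return A data.frame with one row per cell: responsiveness flags, PE
#'   flag with p-value and difference, selectivity, SI, class label and the
#'   per-condition mean responses.
#' @export
classify_cells <- function(rt, config, responsive_threshold = 0.5,
                           pe_alpha = 0.05, pe_min_diff = 0.5,
                           selectivity_cutoffs = c(0.6, 0.8),
                           trial_mode = "all",
                           responsive_pool = c("either", "expected")) {
  responsive_pool <- match.arg(responsive_pool)
  rt <- select_classification_trials(rt, trial_mode)

  out <- do.call(rbind, lapply(split(rt, rt$cell_id), function(d) {
    unexp <- d$response[!is.na(d$condition) & d$condition == "unexpected"]
    expd <- d$response[!is.na(d$condition) & d$condition == "expected"]
    r_target <- mean(expd)
    r_ref <- mean(ref_late(d, config), na.rm = TRUE)
    resp_exp <- classify_stimulus_responsive(r_target, responsive_threshold)
    resp_unexp <- classify_stimulus_responsive(mean(unexp),
                                               responsive_threshold)
    responsive <- switch(responsive_pool,
                         either = isTRUE(resp_exp) || isTRUE(resp_unexp),
                         expected = isTRUE(resp_exp))
    pe <- classify_pe_responsive(unexp, expd, pe_alpha, pe_min_diff)
    sel <- compute_selectivity(r_target, r_ref)
    si <- if (sum(!is.na(expd)) >= 2L && sum(!is.na(ref_late(d, config))) >= 2L)
      compute_si(expd, ref_late(d, config)) else NA_real_
    data.frame(
      cell_id = d$cell_id[1], animal_id = d$animal_id[1],
      mean_unexpected = mean(unexp), mean_expected = r_target,
      mean_reference = r_ref,
      stimulus_responsive = responsive,
      pe_responsive = pe$flag, pe_p_value = pe$p_value, pe_diff = pe$diff,
      selectivity = sel, si = si,
      selectivity_class = classify_selectivity_class(sel, responsive,
                                                     selectivity_cutoffs)
    )
  }))
  rownames(out) <- NULL
  out[order(out$cell_id), , drop = FALSE]
}

# late-block-2 presentations of the trained gratings at the non-oddball
# positions (the "A3 or B2" reference of the selectivity measure)
reference_rows <- function(rt, config) {
  n2 <- config$n_trials_block2
  first_late <- config$n_trials_block1 + n2 - floor(n2 * 0.5) + 1L
  rt$position != config$oddball_position &
    rt$identity == config$base_sequence[rt$position] &
    rt$block == 2L & rt$trial_id >= first_late
}

ref_late <- function(d, config) {
  d$response[reference_rows(d, config)]
}

#' Recover the exposure decay of prediction-error amplification
#'
#' Fits `response_k = a * (1 + g * lambda^(k-1))` to per-exposure mean
#' responses of the oddball stimulus by robust nonlinear least squares and
#' returns the decay `lambda`. Used to check that the generated sessions
#' carry the planted per-exposure decay.
#'
#' @param exposure_index Integer exposure indices (k >= 1).
#' @param responses Responses (or response means) at those exposures.
#' @return List with `lambda`, `gain` and `asymptote` estimates.
#' @export
estimate_exposure_decay <- function(exposure_index, responses) {
  ok <- !is.na(exposure_index) & !is.na(responses)
  k <- exposure_index[ok]; r <- responses[ok]
  stopifnot(length(unique(k)) >= 4L)
  a0 <- mean(r[k >= stats::quantile(k, 0.75)])
  g0 <- max((mean(r[k <= stats::quantile(k, 0.25)]) - a0) / max(a0, 1e-6), 0.1)
  fit <- minpack.lm::nlsLM(r ~ a * (1 + g * lambda^(k - 1)),
                           start = list(a = a0, g = g0, lambda = 0.8),
                           lower = c(a = -Inf, g = 0, lambda = 1e-6),
                           upper = c(a = Inf, g = Inf, lambda = 1),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  co <- stats::coef(fit)
  list(lambda = unname(co["lambda"]), gain = unname(co["g"]),
       asymptote = unname(co["a"]))
}
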