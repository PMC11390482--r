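#' Mean running speed in the event window
#'
#' Window mean of running speed over \[onset + 0.4, onset + 2.0) seconds,
#' the same window used for calcium responses.
#'
#' @param onsets Event onsets, seconds.
#' @param behavior Behavioral trace data.frame (`time`, `running_speed`).
#' @param window Window bounds relative to onset, half-open on the right.
#' @return Numeric vector of window-mean speeds, one per onset.
#' @export
event_window_speed <- function(onsets, behavior, window = c(0.4, 2.0)) {
  vapply(onsets, function(o) {
    ix <- behavior$time >= o + window[1] - 1e-9 &
      behavior$time < o + window[2] - 1e-9
    if (!any(ix)) return(NA_real_)
    mean(behavior$running_speed[ix])
  }, numeric(1))
}

#' Split events into fast and slow running trials
#'
#' Median split of the event-window mean running speeds: the bottom half of
#' events is "slow", the top half "fast". Ties are broken by event order
#' (stable sort), and with an odd number of events the extra event goes to
#' the fast set. The two sets always partition the input exactly.
#'
#' @param speeds Event-window mean speeds (one per qualifying event).
#' @return List with integer index vectors `slow` and `fast`.
#' @export
split_fast_slow <- function(speeds) {
  n <- length(speeds)
  stopifnot(n >= 2L)
  ord <- order(speeds, seq_len(n))  # stable: ties broken by event order
  n_slow <- floor(n / 2)
  list(slow = sort(ord[seq_len(n_slow)]),
       fast = sort(ord[(n_slow + 1L):n]))
}

#' Correlation of running speed and neuronal activity
#'
#' Pearson correlation across trials between the trial-window mean response
#' and the trial-window mean running speed; the squared coefficient R^2
#' quantifies running modulation of the cell across the session.
#'
#' @param responses Per-trial mean responses (dF/F or z-scored).
#' @param speeds Per-trial mean running speeds.
#' @return List with `pearson_r` and `r_squared` (NA with a warning when the
#'   speed has zero variance).
#' @export
running_activity_correlation <- function(responses, speeds) {
  ok <- !is.na(responses) & !is.na(speeds)
  responses <- responses[ok]; speeds <- speeds[ok]
  stopifnot(length(responses) >= 3L)
  if (stats::sd(speeds) == 0 || stats::sd(responses) == 0) {
    warning("zero variance: running correlation undefined")
    return(list(pearson_r = NA_real_, r_squared = NA_real_))
  }
  r <- stats::cor(responses, speeds)
  list(pearson_r = r, r_squared = r^2)
}

#' Detect the pupil in a single eye-camera frame
#'
#' Binarizes the frame at `threshold` (pixels below threshold are pupil,
#' i.e. a dark pupil on a bright field), labels connected regions, and
#' returns the pixel area and centre of mass of the largest region.
#'
#' @param frame Grayscale image matrix.
#' @param threshold Intensity threshold.
#' @return List with `center_y`, `center_x`, `area`; all NA when nothing is
#'   detected.
#' @export
detect_pupil <- function(frame, threshold) {
  frame <- as.matrix(frame)
  mask <- frame < threshold
  if (!any(mask))
    return(list(center_y = NA_real_, center_x = NA_real_, area = NA_real_))
  lab <- EBImage::bwlabel(mask)
  counts <- tabulate(lab[lab > 0])
  biggest <- which.max(counts)
  px <- which(lab == biggest, arr.ind = TRUE)
  list(center_y = mean(px[, 1]), center_x = mean(px[, 2]),
       area = as.numeric(counts[biggest]))
}

#' Remove outliers from a pupil-area trace
#'
#' Hampel filter: a sample further than `n_mad` scaled MADs from the median
#' of its `window`-sample neighborhood (MAD computed in the same window) is
#' an outlier, replaced by linear interpolation between the surrounding
#' clean samples (nearest clean value at the trace edges).
#'
#' @param area_trace Numeric trace (>= 10 samples).
#' @param window Moving window length (odd).
#' @param n_mad Outlier threshold in scaled-MAD units.
#' @return Filtered trace of the same length.
#' @export
filter_pupil_trace <- function(area_trace, window = 11L, n_mad = 3) {
  n <- length(area_trace)
  stopifnot(n >= 10L, window %% 2 == 1)
  half <- window %/% 2
  med <- mad_w <- numeric(n)
  for (i in seq_len(n)) {
    w <- area_trace[max(1L, i - half):min(n, i + half)]
    med[i] <- stats::median(w)
    mad_w[i] <- 1.4826 * stats::median(abs(w - med[i]))
  }
  out <- abs(area_trace - med) > n_mad * pmax(mad_w, .Machine$double.eps)
  if (!any(out)) return(area_trace)
  clean <- which(!out)
  if (length(clean) < 2L) return(rep(stats::median(area_trace), n))
  filled <- area_trace
  filled[out] <- stats::approx(clean, area_trace[clean], xout = which(out),
                               rule = 2)$y
  filled
}
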