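#' Rigid motion registration by phase correlation
#'
#' Estimates an integer-pixel displacement per frame against a reference
#' image using phase correlation. The reference is the average of 30 evenly
#' spaced batches of 40 frames (1,200 frames) when the stack is long enough,
#' otherwise the mean of all frames. Registration is integer-pixel only.
#'
#' @param stack A `height x width x n_frames` array (e.g. from
#'   [generate_frame_stack()] or [read_frame_stack()]).
#' @param batch_size,n_batches Reference construction parameters.
#' @param refine Number of refinement passes: after each pass the reference
#'   is rebuilt from the motion-corrected frames and displacements are
#'   re-estimated, which removes the blur that uncorrected motion leaves in
#'   a plain frame average.
#' @return A list of class `"registration_result"` with `displacement`
#'   (`n_frames x 2` integer matrix of `(dy, dx)`, the planted-shift
#'   convention: the shift that was applied to the reference to produce the
#'   frame) and `reference` (the final reference image).
#' @export
register_frames <- function(stack, batch_size = 40L, n_batches = 30L,
                            refine = 1L) {
  d <- dim(stack)
  if (length(d) != 3L || d[3] < 2L)
    stop("stack must be a height x width x n_frames array with >= 2 frames",
         call. = FALSE)
  nf <- d[3]
  if (all(stack == 0))
    stop("degenerate input: all frames are zero", call. = FALSE)
  if (nf >= batch_size * n_batches) {
    starts <- floor(seq(1, nf - batch_size + 1, length.out = n_batches))
    idx <- unique(unlist(lapply(starts, function(s) s:(s + batch_size - 1L))))
    ref <- apply(stack[, , idx, drop = FALSE], c(1, 2), mean)
  } else {
    ref <- apply(stack, c(1, 2), mean)
  }
  disp <- t(vapply(seq_len(nf), function(f)
    phase_correlate(ref, stack[, , f]), integer(2)))
  for (pass in seq_len(refine)) {
    aligned <- stack
    for (f in seq_len(nf))
      aligned[, , f] <- roll_matrix(stack[, , f], -disp[f, 1], -disp[f, 2])
    ref <- apply(aligned, c(1, 2), mean)
    disp <- t(vapply(seq_len(nf), function(f)
      phase_correlate(ref, stack[, , f]), integer(2)))
  }
  colnames(disp) <- c("dy", "dx")
  structure(list(displacement = disp, reference = ref),
            class = "registration_result")
}

# displacement (dy, dx) such that rolling `ref` by it best matches `frame`.
# The cross-power normalization is regularized so noise-dominated frequency
# bins do not receive full weight after whitening.
phase_correlate <- function(ref, frame, lambda = 0.1) {
  h <- nrow(ref); w <- ncol(ref)
  f1 <- stats::fft(ref)
  f2 <- stats::fft(frame)
  r <- f2 * Conj(f1)
  m <- Mod(r)
  r <- r / (m + lambda * mean(m) + 1e-300)
  cc <- Re(stats::fft(r, inverse = TRUE)) / (h * w)
  peak <- which.max(cc)
  py <- (peak - 1) %% h
  px <- (peak - 1) %/% h
  dy <- if (py > h / 2) py - h else py
  dx <- if (px > w / 2) px - w else px
  as.integer(c(dy, dx))
}

#' Flag frames with large motion
#'
#' Frames whose displacement magnitude exceeds `threshold_px`, or (when
#' `auto = TRUE`) the session mean plus 3 SD of displacement magnitudes,
#' are flagged; callers exclude them from all downstream trace statistics.
#'
#' @param reg A `"registration_result"`.
#' @param threshold_px Absolute displacement threshold in pixels.
#' @param auto Also apply the adaptive mean + 3 SD rule.
#' @return Integer vector of flagged frame indices (possibly empty).
#' @export
flag_large_motion <- function(reg, threshold_px = 10, auto = TRUE) {
  mag <- sqrt(rowSums(reg$displacement^2))
  flagged <- mag > threshold_px
  if (auto) {
    s <- stats::sd(mag)
    if (is.finite(s) && s > 0) flagged <- flagged | mag > mean(mag) + 3 * s
  }
  which(flagged)
}

#' Extract an ROI time course from a frame stack
#'
#' All pixels within the ROI are averaged (unweighted) per frame.
#'
#' @param stack A `height x width x n_frames` array.
#' @param roi_mask Logical matrix of the same height/width.
#' @return Numeric vector, one value per frame.
#' @export
extract_roi_trace <- function(stack, roi_mask) {
  d <- dim(stack)
  roi_mask <- as.matrix(roi_mask)
  if (!any(roi_mask)) stop("ROI mask is empty", call. = FALSE)
  if (nrow(roi_mask) != d[1] || ncol(roi_mask) != d[2])
    stop("ROI mask does not match frame size", call. = FALSE)
  idx <- which(roi_mask)
  mat <- matrix(stack, d[1] * d[2], d[3])
  colMeans(mat[idx, , drop = FALSE])
}

#' Robust neuropil decontamination with an asymmetric Student-t model
#'
#' Estimates the contamination fraction r in
#' `F_meas = F_cell + r * F_neuropil` by fitting
#' `F_meas = a + r * F_neuropil + e` with a heavy-tailed asymmetric residual
#' model: residuals are Student-t (df `nu`) with scale `s` for negative
#' residuals and `asymmetry * s` for positive ones, so calcium transients
#' (large positive excursions) are down-weighted less than negative dips and
#' do not drag the slope upward the way least squares does. Fitted by
#' coordinate ascent over (r, a, s); r is clipped to [0, 1).
#'
#' @param cell_trace,neuropil_trace Equal-length numeric traces (>= 100
#'   frames).
#' @param nu Student-t degrees of freedom.
#' @param asymmetry Scale multiplier for positive residuals (> 1 favors
#'   transients).
#' @param max_iter,tol Coordinate-ascent controls.
#' @return A list with `corrected` (`cell_trace - r_hat * neuropil_trace`)
#'   and `r_hat`.
#' @export
subtract_neuropil <- function(cell_trace, neuropil_trace, nu = 5,
                              asymmetry = 3, max_iter = 25L, tol = 1e-8) {
  stopifnot(length(cell_trace) == length(neuropil_trace))
  if (length(cell_trace) < 100L)
    stop("need at least 100 frames to estimate the neuropil coefficient",
         call. = FALSE)
  if (stats::sd(neuropil_trace) == 0) {
    warning("constant neuropil trace: contamination unidentifiable, r_hat = 0")
    return(list(corrected = cell_trace, r_hat = 0))
  }
  negll <- function(r, a, s)
    ast_negll_cpp(cell_trace, neuropil_trace, r, a, s, nu, asymmetry)
  # init from least squares
  ols <- stats::lm.fit(cbind(1, neuropil_trace), cell_trace)
  a <- ols$coefficients[1]
  r <- min(max(ols$coefficients[2], 0), 1 - 1e-6)
  s <- max(stats::sd(ols$residuals), 1e-9)
  prev <- negll(r, a, s)
  a_scale <- max(stats::sd(cell_trace), 1e-6)
  for (it in seq_len(max_iter)) {
    r_old <- r
    r <- stats::optimize(function(x) negll(x, a, s), c(0, 1 - 1e-9),
                         tol = 1e-5)$minimum
    rng_a <- range(cell_trace - r * neuropil_trace)
    a <- stats::optimize(function(x) negll(r, x, s), rng_a,
                         tol = a_scale * 1e-4)$minimum
    s <- stats::optimize(function(x) negll(r, a, x),
                         c(1e-9, 10 * s + 1e-6), tol = s * 1e-4)$minimum
    cur <- negll(r, a, s)
    if (abs(prev - cur) < tol * (abs(prev) + 1) || abs(r - r_old) < 1e-5)
      break
    prev <- cur
  }
  r <- min(max(r, 0), 1 - 1e-12)
  list(corrected = cell_trace - r * neuropil_trace, r_hat = r)
}

#' Baseline fluorescence from a two-component Gaussian mixture
#'
#' Fits a two-component Gaussian mixture to the sample distribution of trace
#' values by EM (deterministic initialization at the 25th and 90th
#' percentiles; at most `max_iter` iterations or a log-likelihood change
#' below `tol`). The baseline F0 is the mean of the lower component.
#'
#' @param trace Numeric fluorescence trace (>= 200 frames).
#' @param max_iter,tol EM controls.
#' @return A list with `f0`, component `means`, `sds`, `weights` and the
#'   number of EM iterations used.
#' @export
estimate_f0_gmm <- function(trace, max_iter = 50L, tol = 1e-6) {
  if (length(trace) < 200L)
    stop("need at least 200 frames to estimate F0", call. = FALSE)
  if (!all(is.finite(trace))) stop("trace contains non-finite values",
                                   call. = FALSE)
  if (stats::sd(trace) == 0)
    return(list(f0 = trace[1], means = c(trace[1], trace[1]),
                sds = c(0, 0), weights = c(0.5, 0.5), iterations = 0L))
  mu <- stats::quantile(trace, c(0.25, 0.90), names = FALSE)
  if (mu[1] == mu[2]) mu[2] <- mu[2] + stats::sd(trace)
  sig_floor <- max(stats::sd(trace) * 1e-4, 1e-12)
  fit <- gmm2_em_cpp(trace, mu[1], mu[2], stats::sd(trace) / 2,
                     stats::sd(trace) / 2, 0.5, as.integer(max_iter), tol,
                     sig_floor)
  list(f0 = min(fit$means), means = fit$means, sds = fit$sds,
       weights = fit$weights, iterations = fit$iterations)
}

#' Compute dF/F and its session z-score
#'
#' `dff = (trace - F0) / F0`; the z-scored trace subtracts the session mean
#' of dF/F and divides by its SD. Frames listed in `exclude_frames` are
#' omitted from the mean/SD (but still transformed), so motion-flagged
#' frames do not bias the normalization. A zero-SD cell is flagged and its
#' z trace set to NA.
#'
#' @param trace Fluorescence trace (a.u.).
#' @param f0 Baseline fluorescence, must be positive.
#' @param exclude_frames Integer indices excluded from the normalization
#'   statistics.
#' @return A list with `dff`, `z_dff`, `session_mean`, `session_sd`,
#'   `flagged` (TRUE when the z-score is undefined).
#' @export
compute_dff_z <- function(trace, f0, exclude_frames = integer(0)) {
  if (!is.finite(f0) || f0 <= 0) stop("F0 must be positive", call. = FALSE)
  dff <- (trace - f0) / f0
  keep <- setdiff(seq_along(dff), exclude_frames)
  m <- mean(dff[keep])
  s <- stats::sd(dff[keep])
  if (!is.finite(s) || s == 0)
    return(list(dff = dff, z_dff = rep(NA_real_, length(dff)),
                session_mean = m, session_sd = s, flagged = TRUE))
  list(dff = dff, z_dff = (dff - m) / s, session_mean = m, session_sd = s,
       flagged = FALSE)
}

#' Preprocess a raw trace set into z-scored dF/F
#'
#' Runs the per-cell chain: neuropil subtraction (asymmetric Student-t),
#' Gaussian-mixture baseline, dF/F and session z-scoring. By default F0 is
#' estimated on the decontaminated trace; `f0_on_raw = TRUE` estimates it on
#' the raw measured trace instead (the literal pre-processing order of some
#' descriptions).
#'
#' @param traces A `"raw_trace_set"`.
#' @param exclude_frames Motion-flagged frame indices excluded from
#'   normalization statistics.
#' @param f0_on_raw Estimate F0 on the raw rather than decontaminated trace.
#' @param neuropil Set to `FALSE` to skip neuropil subtraction.
#' @return An object of class `"dff_trace_set"`: list with `time`, `z`
#'   (cells x frames z-scored dF/F), `dff`, `f0`, `r_hat`, `session_mean`,
#'   `session_sd`, `flagged_cells`, `animal_id`, `cell_id`,
#'   `excluded_frames`.
#' @export
preprocess_traces <- function(traces, exclude_frames = integer(0),
                              f0_on_raw = FALSE, neuropil = TRUE) {
  stopifnot(inherits(traces, "raw_trace_set"))
  n_cells <- nrow(traces$raw)
  nf <- ncol(traces$raw)
  z <- matrix(NA_real_, n_cells, nf)
  dff <- matrix(NA_real_, n_cells, nf)
  f0 <- r_hat <- mu <- sdv <- numeric(n_cells)
  flagged <- logical(n_cells)
  for (i in seq_len(n_cells)) {
    raw_i <- traces$raw[i, ]
    if (neuropil) {
      np <- subtract_neuropil(raw_i, traces$neuropil[i, ])
      corrected <- np$corrected
      r_hat[i] <- np$r_hat
    } else {
      corrected <- raw_i
      r_hat[i] <- 0
    }
    fit <- estimate_f0_gmm(if (f0_on_raw) raw_i else corrected)
    f0[i] <- fit$f0
    dz <- compute_dff_z(corrected, f0[i], exclude_frames)
    z[i, ] <- dz$z_dff
    dff[i, ] <- dz$dff
    mu[i] <- dz$session_mean
    sdv[i] <- dz$session_sd
    flagged[i] <- dz$flagged
  }
  structure(list(time = traces$time, z = z, dff = dff, f0 = f0, r_hat = r_hat,
                 session_mean = mu, session_sd = sdv,
                 flagged_cells = which(flagged),
                 animal_id = traces$animal_id, cell_id = traces$cell_id,
                 excluded_frames = as.integer(exclude_frames)),
            class = "dff_trace_set")
}
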