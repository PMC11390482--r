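#' Write a synthetic session to a session directory
#'
#' Persists a complete session as a plain-text directory: `config.json`,
#' `trials.tsv`, `events.tsv`, `behavior.tsv`, `ground_truth.tsv`,
#' `traces_raw.tsv` / `traces_neuropil.tsv` (frames x cells, one column per
#' cell, first column `time`), and `meta.json` (cell/animal map, session id,
#' seed). All times are seconds; floats are written with full precision.
#'
#' @param dir Target directory (created; must not exist unless
#'   `force = TRUE`).
#' @param config,trials,events,behavior,truth,traces Session components.
#' @param force Overwrite an existing directory.
#' @return `dir`, invisibly.
#' @export
write_session <- function(dir, config, trials, events, behavior, truth,
                          traces, force = FALSE) {
  if (dir.exists(dir)) {
    if (!force) stop("session directory exists; use force = TRUE", call. = FALSE)
    unlink(dir, recursive = TRUE)
  }
  dir.create(dir, recursive = TRUE)
  tsv <- function(x, f)
    data.table::fwrite(x, file.path(dir, f), sep = "\t", quote = FALSE)
  jsonlite::write_json(unclass(config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  tsv(trials, "trials.tsv")
  tsv(events, "events.tsv")
  tsv(behavior, "behavior.tsv")
  tsv(truth, "ground_truth.tsv")
  tr <- data.frame(time = traces$time, t(traces$raw))
  names(tr) <- c("time", paste0("cell_", traces$cell_id))
  tsv(tr, "traces_raw.tsv")
  np <- data.frame(time = traces$time, t(traces$neuropil))
  names(np) <- names(tr)
  tsv(np, "traces_neuropil.tsv")
  jsonlite::write_json(
    list(session_id = traces$session_id, cell_id = traces$cell_id,
         animal_id = traces$animal_id, seed = config$seed,
         package_version = as.character(utils::packageVersion("oddball2p"))),
    file.path(dir, "meta.json"), auto_unbox = FALSE, digits = NA)
  invisible(dir)
}

#' Read a session directory written by [write_session()]
#'
#' @param dir Session directory.
#' @return A list with `config` (a `session_config`), `trials`, `events`,
#'   `behavior`, `truth` and `traces` (a `"raw_trace_set"`).
#' @export
read_session <- function(dir) {
  if (!dir.exists(dir)) stop("no such session directory: ", dir, call. = FALSE)
  tsv <- function(f) {
    path <- file.path(dir, f)
    if (!file.exists(path)) stop("missing session file: ", path, call. = FALSE)
    as.data.frame(data.table::fread(path, sep = "\t"))
  }
  cj <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  config <- do.call(session_config,
                    cj[intersect(names(cj), names(formals(session_config)))])
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  tr <- tsv("traces_raw.tsv")
  np <- tsv("traces_neuropil.tsv")
  traces <- structure(
    list(time = tr$time,
         raw = t(as.matrix(tr[, -1, drop = FALSE])),
         neuropil = t(as.matrix(np[, -1, drop = FALSE])),
         animal_id = as.integer(meta$animal_id),
         cell_id = as.integer(meta$cell_id),
         session_id = meta$session_id[[1]]),
    class = "raw_trace_set")
  dimnames(traces$raw) <- dimnames(traces$neuropil) <- NULL
  list(config = config, trials = tsv("trials.tsv"), events = tsv("events.tsv"),
       behavior = tsv("behavior.tsv"), truth = tsv("ground_truth.tsv"),
       traces = traces)
}

#' Write / read a frame stack as multi-page TIFF
#'
#' Frames are rescaled to the 16-bit range on write; planted shifts (if
#' present) are written alongside as `<file>.shifts.tsv` so registration
#' oracles survive the round trip.
#'
#' @param stack A `height x width x n_frames` array.
#' @param path TIFF file path.
#' @return `path` (write) or a `"frame_stack"` array (read).
#' @export
write_frame_stack <- function(stack, path) {
  d <- dim(stack)
  rng <- range(stack)
  scaled <- (stack - rng[1]) / max(rng[2] - rng[1], 1e-12)
  pages <- lapply(seq_len(d[3]), function(f) scaled[, , f])
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  sh <- attr(stack, "shifts")
  if (!is.null(sh))
    utils::write.table(data.frame(dy = sh[, 1], dx = sh[, 2]),
                       paste0(path, ".shifts.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_frame_stack
#' @export
read_frame_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  stack <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (f in seq_along(pages)) stack[, , f] <- pages[[f]]
  shf <- paste0(path, ".shifts.tsv")
  if (file.exists(shf)) {
    sh <- utils::read.table(shf, header = TRUE, sep = "\t")
    attr(stack, "shifts") <- as.matrix(sh)
  }
  class(stack) <- "frame_stack"
  stack
}
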