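#' Simulate a full oddball session
#'
#' Generates the trial table, stimulus events, behavioral traces,
#' ground-truth cell parameters and forward-modeled fluorescence for one
#' session, optionally writing everything to a session directory (and a
#' small registration fixture stack as multi-page TIFF).
#'
#' @param config A [session_config()].
#' @param out_dir Optional output directory; NULL keeps the session in
#'   memory only.
#' @param force Overwrite an existing directory.
#' @param write_stack Also write a 64x64 frame stack with planted shifts.
#' @param ... Passed to [generate_ground_truth()] (population fractions,
#'   gains, noise).
#' @return The in-memory session: list with `config`, `trials`, `events`,
#'   `behavior`, `truth`, `traces`.
#' @export
run_simulate <- function(config = session_config(), out_dir = NULL,
                         force = FALSE, write_stack = FALSE, ...) {
  trials <- generate_trial_sequence(config)
  events <- generate_events(trials, config)
  behavior <- generate_behavior(trials, config)
  truth <- generate_ground_truth(config, ...)
  traces <- generate_traces(truth, events, behavior, config)
  session <- list(config = config, trials = trials, events = events,
                  behavior = behavior, truth = truth, traces = traces)
  if (!is.null(out_dir)) {
    write_session(out_dir, config, trials, events, behavior, truth, traces,
                  force = force)
    if (write_stack) {
      # mostly still frames anchor the reference; 10 carry planted shifts
      set.seed(config$seed + 4L)
      sh <- matrix(0L, 30L, 2L)
      sh[21:30, ] <- cbind(sample(-8:8, 10, replace = TRUE),
                           sample(-8:8, 10, replace = TRUE))
      stack <- generate_frame_stack(30L, sh, seed = config$seed + 5L)
      write_frame_stack(stack, file.path(out_dir, "frame_stack.tiff"))
    }
  }
  invisible(session)
}

#' Analyze a session end to end
#'
#' Runs preprocessing (neuropil subtraction, Gaussian-mixture baseline,
#' z-scored dF/F), event-aligned response extraction, per-cell
#' classification, and the class-wise prediction-error statistics
#' (hierarchical bootstrap of unexpected-vs-expected paired differences,
#' Cohen's d, bootstrap CI) per selectivity class.
#'
#' @param session An in-memory session from [run_simulate()], or a session
#'   directory path.
#' @param n_boot Resamples for the hierarchical bootstrap and CIs.
#' @param seed Seed for the statistics stage.
#' @param out_dir Optional directory for the report tables (TSV).
#' @param responsive_threshold,pe_alpha,pe_min_diff,selectivity_cutoffs,trial_mode
#'   Classification thresholds, see [classify_cells()].
#' @param verbose Log one line per stage.
#' @return An object of class `"report_bundle"`: list with
#'   `cell_classification`, `condition_means`, `stats_table`, `provenance`.
#' @export
run_analyze <- function(session, n_boot = 1000L, seed = 1L, out_dir = NULL,
                        responsive_threshold = 0.5, pe_alpha = 0.05,
                        pe_min_diff = 0.5, selectivity_cutoffs = c(0.6, 0.8),
                        trial_mode = "all", verbose = FALSE) {
  if (is.character(session)) session <- read_session(session)
  cfg <- session$config
  say <- function(...) if (verbose) message(sprintf(...))

  say("preprocess: %d cells x %d frames", nrow(session$traces$raw),
      ncol(session$traces$raw))
  dff <- preprocess_traces(session$traces)
  if (length(dff$flagged_cells))
    say("  %d cell(s) flagged (zero-variance dF/F) and excluded",
        length(dff$flagged_cells))

  say("responses: %d events", nrow(session$events))
  rt <- build_response_table(dff, session$events, cfg)

  say("classification: thresholds resp>%.2g, alpha=%.3g, diff>%.2g",
      responsive_threshold, pe_alpha, pe_min_diff)
  cls <- classify_cells(rt, cfg, responsive_threshold = responsive_threshold,
                        pe_alpha = pe_alpha, pe_min_diff = pe_min_diff,
                        selectivity_cutoffs = selectivity_cutoffs,
                        trial_mode = trial_mode)

  # condition means per selectivity class
  cm <- do.call(rbind, lapply(split(cls, cls$selectivity_class), function(d)
    data.frame(selectivity_class = d$selectivity_class[1], n_cells = nrow(d),
               mean_unexpected = mean(d$mean_unexpected, na.rm = TRUE),
               mean_expected = mean(d$mean_expected, na.rm = TRUE),
               mean_diff = mean(d$mean_unexpected - d$mean_expected,
                                na.rm = TRUE))))
  rownames(cm) <- NULL

  # class-wise hierarchical bootstrap of the paired unexpected-expected
  # difference across cells (animals as the nesting level)
  say("statistics: hierarchical bootstrap, %d resamples", n_boot)
  stats_rows <- lapply(
    intersect(c("highly-selective", "intermediate", "non-selective"),
              unique(cls$selectivity_class)),
    function(klass) {
      d <- cls[cls$selectivity_class == klass &
                 !is.na(cls$mean_unexpected) & !is.na(cls$mean_expected), ]
      if (nrow(d) < 3L || length(unique(d$animal_id)) < 2L) return(NULL)
      nested <- data.frame(animal_id = d$animal_id, cell_id = d$cell_id,
                           value_a = d$mean_unexpected,
                           value_b = d$mean_expected)
      hb <- hierarchical_bootstrap_test(nested, n_boot = n_boot, seed = seed)
      es <- cohens_d(d$mean_unexpected, d$mean_expected)
      ci <- bootstrap_ci(d$mean_unexpected - d$mean_expected,
                         n_boot = max(n_boot, 1000L), seed = seed)
      data.frame(selectivity_class = klass, n_cells = nrow(d),
                 n_animals = length(unique(d$animal_id)),
                 statistic = hb$observed_stat, p_value = hb$p_value,
                 cohens_d = es$cohens_d, ci_low = ci[1], ci_high = ci[2],
                 n_boot = hb$n_boot, seed = seed)
    })
  stats_table <- do.call(rbind, stats_rows)
  if (!is.null(stats_table))
    stats_table$p_adjusted <- bonferroni(stats_table$p_value,
                                         m = nrow(stats_table))

  prov <- list(seed = seed, n_boot = n_boot,
               config_hash = config_hash(cfg),
               thresholds = list(responsive = responsive_threshold,
                                 pe_alpha = pe_alpha, pe_min_diff = pe_min_diff,
                                 selectivity_cutoffs = selectivity_cutoffs,
                                 trial_mode = trial_mode),
               package_version = as.character(utils::packageVersion("oddball2p")))
  bundle <- structure(list(cell_classification = cls, condition_means = cm,
                           stats_table = stats_table, response_table = rt,
                           provenance = prov),
                      class = "report_bundle")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    data.table::fwrite(cls, file.path(out_dir, "cell_classification.tsv"),
                       sep = "\t")
    data.table::fwrite(cm, file.path(out_dir, "condition_means.tsv"),
                       sep = "\t")
    if (!is.null(stats_table))
      data.table::fwrite(stats_table, file.path(out_dir, "stats_table.tsv"),
                         sep = "\t")
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  bundle
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  jsonlite::write_json(unclass(config), f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("Oddball session report\n")
  cat(sprintf("  %d cells classified; config %s, seed %d\n",
              nrow(x$cell_classification), substr(x$provenance$config_hash, 1, 8),
              x$provenance$seed))
  print(x$condition_means)
  if (!is.null(x$stats_table)) print(x$stats_table)
  invisible(x)
}

#' Calibration of the hierarchical bootstrap
#'
#' Simulates nested paired datasets at a grid of paired effect sizes and
#' intraclass correlations and tabulates the rejection rate of
#' [hierarchical_bootstrap_test()] at level `alpha`. With `d = 0` the
#' rejection rate estimates the type-I error; with `d > 0` the power.
#'
#' Each dataset has `n_animals` animals with `cells_per_animal` cells. Both
#' paired condition values of cell i in animal a share the animal's random
#' offset, as they do in the recorded data (one cell is measured in both
#' conditions): `value_b = u_a + e_i`, `value_a = d + u_a + e_i'`, with
#' `u_a ~ N(0, icc)` and `e ~ N(0, 1 - icc)`, so each value has unit
#' variance and `icc` is the animal-level share of the value variance. The
#' shared offset cancels in the paired difference; the hierarchical
#' resampling guards against residual within-animal correlation.
#'
#' @param effects Paired effect sizes (in SD units of the difference).
#' @param iccs Intraclass correlations of the paired difference.
#' @param n_datasets Simulated datasets per grid point.
#' @param n_boot Bootstrap resamples per test.
#' @param n_animals,cells_per_animal Design of each dataset.
#' @param alpha Test level.
#' @param seed Integer seed.
#' @return A data.frame with one row per (effect, icc): `rejection_rate`
#'   and the grid coordinates.
#' @export
run_calibrate <- function(effects = c(0, 1), iccs = c(0, 0.2),
                          n_datasets = 1000L, n_boot = 1000L,
                          n_animals = 5L, cells_per_animal = 40L,
                          alpha = 0.05, seed = 1L) {
  grid <- expand.grid(effect = effects, icc = iccs)
  grid$rejection_rate <- NA_real_
  for (g in seq_len(nrow(grid))) {
    eff <- grid$effect[g]; icc <- grid$icc[g]
    rej <- logical(n_datasets)
    for (i in seq_len(n_datasets)) {
      sim_seed <- as.integer((as.numeric(seed) * 10007 + g * 1009 + i) %%
                               2147483647)
      set.seed(sim_seed)
      u <- stats::rnorm(n_animals, 0, sqrt(icc))
      aid <- rep(seq_len(n_animals), each = cells_per_animal)
      n <- length(aid)
      dat <- data.frame(animal_id = aid, cell_id = seq_len(n),
                        value_a = eff + u[aid] +
                          stats::rnorm(n, 0, sqrt(1 - icc)),
                        value_b = u[aid] + stats::rnorm(n, 0, sqrt(1 - icc)))
      hb <- hierarchical_bootstrap_test(dat, n_boot = n_boot,
                                        seed = sim_seed + 1L)
      rej[i] <- hb$p_value < alpha
    }
    grid$rejection_rate[g] <- mean(rej)
  }
  grid
}
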