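#' Hierarchical bootstrap test for nested paired data
#'
#' Resampling test for paired condition differences measured on cells nested
#' within animals. Each of `n_boot` iterations (i) resamples animals with
#' replacement, (ii) resamples cells with replacement within each drawn
#' animal, to that animal's original cell count, (iii) shuffles the paired
#' data by independently swapping the two condition values within each
#' resampled pair with probability 0.5, and (iv) records the statistic. The
#' two-sided p-value compares the null statistics against the statistic of
#' the original (unresampled) data, with the +1 Monte-Carlo correction, so
#' p is never 0.
#'
#' @param data A data.frame with columns `animal_id`, `cell_id`, `value_a`,
#'   `value_b` (one complete pair per cell).
#' @param statistic Optional function mapping a data.frame with column
#'   `diff` (= value_a - value_b after shuffling) to a scalar; the default
#'   NULL uses the mean paired difference via a fast compiled path.
#' @param n_boot Number of bootstrap iterations.
#' @param seed Integer seed.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return An object of class `"hier_boot"`: list with `observed_stat`,
#'   `null_stats`, `p_value`, `n_boot`, `seed`, `statistic_name`,
#'   `n_animals`, `n_cells`.
#' @export
#' @examples
#' d <- data.frame(animal_id = rep(1:3, each = 5), cell_id = 1:15,
#'                 value_a = rnorm(15, 1), value_b = rnorm(15))
#' hierarchical_bootstrap_test(d, n_boot = 200, seed = 1)
hierarchical_bootstrap_test <- function(data, statistic = NULL,
                                        n_boot = 10000L, seed = 1L,
                                        alternative = c("two.sided",
                                                        "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(all(c("animal_id", "value_a", "value_b") %in% names(data)))
  if (anyNA(data$value_a) || anyNA(data$value_b))
    stop("paired values must be complete", call. = FALSE)
  animals <- unique(data$animal_id)
  if (length(animals) < 2L)
    stop("need >= 2 animals; for a single group use randomization_test()",
         call. = FALSE)
  if (nrow(data) < 2L) stop("need >= 2 cells", call. = FALSE)
  d <- data$value_a - data$value_b
  aid <- match(data$animal_id, animals)

  set.seed(seed)
  if (is.null(statistic)) {
    observed <- mean(d)
    null_stats <- hier_boot_null_meandiff(d, aid, length(animals),
                                          as.integer(n_boot))
    stat_name <- "mean paired difference"
  } else {
    observed <- statistic(data.frame(diff = d))
    by_animal <- split(seq_along(d), aid)
    null_stats <- vapply(seq_len(n_boot), function(b) {
      drawn <- sample.int(length(animals), replace = TRUE)
      idx <- unlist(lapply(drawn, function(a) {
        cc <- by_animal[[a]]
        cc[sample.int(length(cc), replace = TRUE)]
      }), use.names = FALSE)
      sgn <- sample(c(-1, 1), length(idx), replace = TRUE)
      statistic(data.frame(diff = d[idx] * sgn))
    }, numeric(1))
    stat_name <- deparse(substitute(statistic))
  }
  p <- mc_p_value(observed, null_stats, alternative)
  structure(list(observed_stat = observed, null_stats = null_stats,
                 p_value = p, n_boot = as.integer(n_boot),
                 seed = as.integer(seed), statistic_name = stat_name,
                 alternative = alternative,
                 n_animals = length(animals), n_cells = nrow(data)),
            class = "hier_boot")
}

mc_p_value <- function(observed, null_stats, alternative = "two.sided") {
  n <- length(null_stats)
  switch(alternative,
         two.sided = (1 + sum(abs(null_stats) >= abs(observed))) / (n + 1),
         greater = (1 + sum(null_stats >= observed)) / (n + 1),
         less = (1 + sum(null_stats <= observed)) / (n + 1))
}

#' @export
print.hier_boot <- function(x, ...) {
  cat("Hierarchical bootstrap test (", x$statistic_name, ")\n", sep = "")
  cat(sprintf("  %d animals, %d cells; %d resamples (seed %d)\n",
              x$n_animals, x$n_cells, x$n_boot, x$seed))
  cat(sprintf("  observed = %.4g, p (%s) = %.4g\n",
              x$observed_stat, x$alternative, x$p_value))
  invisible(x)
}

#' Randomization (permutation) test
#'
#' Unpaired: condition labels are permuted across the pooled sample.
#' Paired: the two values of each pair are swapped independently with
#' probability 0.5. The default statistic is the difference of means
#' (equivalently the mean paired difference). Two-sided p with the +1
#' correction.
#'
#' @param sample_a,sample_b Numeric samples (equal length when
#'   `paired = TRUE`).
#' @param statistic Optional function `f(a, b)` returning a scalar.
#' @param n_perm Number of permutations.
#' @param paired Paired-swap permutation instead of label permutation.
#' @param seed Integer seed.
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @return List with `observed_stat`, `p_value`, `n_perm`, `seed`.
#' @export
randomization_test <- function(sample_a, sample_b, statistic = NULL,
                               n_perm = 10000L, paired = FALSE, seed = 1L,
                               alternative = c("two.sided", "greater",
                                               "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(sample_a) > 0L, length(sample_b) > 0L)
  if (paired) stopifnot(length(sample_a) == length(sample_b))
  if (is.null(statistic)) statistic <- function(a, b) mean(a) - mean(b)
  set.seed(seed)
  observed <- statistic(sample_a, sample_b)
  null_stats <- if (paired) {
    n <- length(sample_a)
    vapply(seq_len(n_perm), function(i) {
      sw <- stats::runif(n) < 0.5
      a <- ifelse(sw, sample_b, sample_a)
      b <- ifelse(sw, sample_a, sample_b)
      statistic(a, b)
    }, numeric(1))
  } else {
    pool <- c(sample_a, sample_b)
    na <- length(sample_a)
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(length(pool), na)
      statistic(pool[idx], pool[-idx])
    }, numeric(1))
  }
  list(observed_stat = observed,
       p_value = mc_p_value(observed, null_stats, alternative),
       n_perm = as.integer(n_perm), seed = as.integer(seed))
}

#' Bootstrap confidence interval for the mean
#'
#' Bias-corrected and accelerated (BCa) interval by default, delegating to
#' the `boot` package with `n_boot` resamples; `type = "perc"` gives the
#' percentile interval. Constant input yields a zero-width interval at the
#' constant.
#'
#' @param values Numeric sample (>= 2 values).
#' @param level Confidence level.
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed.
#' @param type `"bca"` or `"perc"`.
#' @return Numeric vector `c(low, high)`.
#' @export
bootstrap_ci <- function(values, level = 0.95, n_boot = 10000L, seed = 1L,
                         type = c("bca", "perc")) {
  type <- match.arg(type)
  values <- values[!is.na(values)]
  stopifnot(length(values) >= 2L)
  if (stats::sd(values) == 0) return(c(values[1], values[1]))
  set.seed(seed)
  bt <- boot::boot(values, function(x, i) mean(x[i]), R = n_boot)
  ci <- tryCatch(
    boot::boot.ci(bt, conf = level, type = type),
    error = function(e) boot::boot.ci(bt, conf = level, type = "perc"))
  bounds <- if (!is.null(ci$bca)) ci$bca[1, 4:5] else ci$percent[1, 4:5]
  unname(bounds)
}

#' Cohen's d effect size
#'
#' Difference between the two group means divided by the pooled standard
#' deviation (variances weighted by n - 1).
#'
#' @param sample_a,sample_b Numeric samples (>= 2 each).
#' @return An object of class `"effect_size"`: list with `cohens_d`,
#'   `mean_a`, `mean_b`, `pooled_sd`.
#' @export
cohens_d <- function(sample_a, sample_b) {
  sample_a <- sample_a[!is.na(sample_a)]
  sample_b <- sample_b[!is.na(sample_b)]
  stopifnot(length(sample_a) >= 2L, length(sample_b) >= 2L)
  ps <- pooled_sd(sample_a, sample_b)
  d <- if (ps == 0) {
    if (mean(sample_a) == mean(sample_b)) 0
    else {
      warning("zero pooled SD with unequal means: d undefined")
      NA_real_
    }
  } else (mean(sample_a) - mean(sample_b)) / ps
  structure(list(cohens_d = d, mean_a = mean(sample_a),
                 mean_b = mean(sample_b), pooled_sd = ps),
            class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("Cohen's d = %.4g (means %.4g vs %.4g, pooled SD %.4g)\n",
              x$cohens_d, x$mean_a, x$mean_b, x$pooled_sd))
  invisible(x)
}

#' Bonferroni adjustment
#'
#' `min(1, m * p)` elementwise; `m` defaults to the number of p-values.
#'
#' @param p_values Numeric p-values in \[0, 1\].
#' @param m Number of comparisons.
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE), m >= 1)
  pmin(1, m * p_values)
}
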