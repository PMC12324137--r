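# Natural-variability thresholds via repeated random split-halves.
#
# Repetitions of a single baseline condition are shuffled and partitioned in
# two; the metric is computed between the halves (first half = reference);
# repeating this yields the dispersion of the metric under "no change",
# against which between-condition values can be judged.

#' Natural-variability threshold of a coordination metric
#'
#' For each of `n_splits` iterations, shuffles the dataset's repetitions
#' with the seeded generator and partitions them without replacement into a
#' reference half of `ceiling(k/2)` repetitions and a comparison half of
#' `floor(k/2)` (the reference gets the extra one when `k` is odd), then
#' computes the requested metric between the halves. Per-entry mean, SD and
#' standard error (SD / sqrt(n_splits)) over the iterations are returned.
#'
#' @param ds a [movement_dataset()] with at least 2 repetitions (the
#'   baseline condition).
#' @param metric `"jcvpca"` or `"jsvcrp"`.
#' @param n_splits number of random split-halves (15 is a common choice).
#' @param seed optional integer seed for full reproducibility.
#' @param ... passed to [jcvpca()] (`m`, `task_dof`, ...) or [jsvcrp()]
#'   (`pair`, `G`, `axis`, `noise_range`, ...).
#' @return An object of class `variability_threshold` with fields `metric`,
#'   `mean`, `sd`, `se` (matrices for jcvpca, scalars for jsvcrp),
#'   `samples` (per-split raw values), `n_splits`, `seed`.
#' @export
natural_variability <- function(ds, metric = c("jcvpca", "jsvcrp"),
                                n_splits = 15L, seed = NULL, ...) {
  metric <- match.arg(metric)
  stopifnot(inherits(ds, "movement_dataset"))
  k <- n_repetitions(ds)
  if (k < 2L) stop_jc("need at least 2 repetitions to split, got %d", k)
  if (n_splits < 1L) stop_jc("`n_splits` must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  n_ref <- ceiling(k / 2)
  samples <- vector("list", n_splits)
  for (s in seq_len(n_splits)) {
    perm <- sample.int(k)
    ref <- subset_repetitions(ds, perm[seq_len(n_ref)], name = "split_ref")
    cmp <- subset_repetitions(ds, perm[-seq_len(n_ref)], name = "split_cmp")
    samples[[s]] <- if (metric == "jcvpca") {
      suppressWarnings(jcvpca(ref, cmp, ...)$delta)
    } else {
      as.numeric(jsvcrp(ref, cmp, ...))
    }
  }
  if (metric == "jcvpca") {
    arr <- simplify2array(samples)               # m x n x n_splits
    mu <- apply(arr, c(1, 2), mean)
    sdv <- if (n_splits > 1L) apply(arr, c(1, 2), stats::sd) else mu * 0
  } else {
    v <- unlist(samples)
    mu <- mean(v)
    sdv <- if (n_splits > 1L) stats::sd(v) else 0
  }
  structure(list(metric = metric, mean = mu, sd = sdv,
                 se = sdv / sqrt(n_splits), samples = samples,
                 n_splits = n_splits, seed = seed, k = k),
            class = "variability_threshold")
}

#' @export
print.variability_threshold <- function(x, digits = 4, ...) {
  cat(sprintf("<variability_threshold> %s over %d split-halves of %d repetitions\n",
              x$metric, x$n_splits, x$k))
  cat("mean:\n"); print(round(x$mean, digits))
  cat("sd:\n"); print(round(x$sd, digits))
  cat("se:\n"); print(round(x$se, digits))
  invisible(x)
}

#' Compare a metric value against a natural-variability threshold
#'
#' Flags entries falling outside `mean +/- band`, where the band is the
#' standard error (default) or the standard deviation of the split-half
#' distribution. Values inside the band are indistinguishable from the
#' natural repetition-to-repetition variability of the baseline condition
#' and should not be read as a change in coordination strategy.
#'
#' @param value numeric scalar/matrix with the same shape as the threshold's
#'   `mean` (e.g. a [jcvpca()] `delta` matrix or a [jsvcrp()] area).
#' @param threshold a [natural_variability()] result.
#' @param rule `"se"` (mean +/- standard error, default) or `"sd"`.
#' @return logical scalar/matrix: `TRUE` where the value exceeds the band.
#' @export
exceeds_threshold <- function(value, threshold, rule = c("se", "sd")) {
  rule <- match.arg(rule)
  stopifnot(inherits(threshold, "variability_threshold"))
  value <- if (inherits(value, "jcvpca_result")) value$delta else unclass(value)
  value <- if (is.matrix(value)) value else as.numeric(value)
  if (length(value) != length(threshold$mean))
    stop_jc("value has %d entries but the threshold has %d",
            length(value), length(threshold$mean))
  band <- if (rule == "se") threshold$se else threshold$sd
  value < threshold$mean - band | value > threshold$mean + band
}
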