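## The synthetic benchmark: fixed study conditions under which the
## cascade architecture is compared against its sub-networks.

#' Run the synthetic cascade-vs-sub-network benchmark
#'
#' Generates a synthetic protein set spanning all six length ranges
#' (`n_per_range` proteins per range, lengths uniform within each
#' range), trains a cascade bundle on the first `n_train_per_range`
#' proteins of each range and evaluates the remainder. For every test
#' protein both prediction levels are scored against the geometric
#' contact map at the routed range's separation mask: the routed
#' sub-network alone at its optimized threshold, and the full cascade
#' at its optimized threshold.
#'
#' Two architecture-level quantities are derived, mirroring the known
#' behaviour of cascaded contact predictors: the set-level accuracy
#' gain of the cascade over the average sub-network, and the
#' flattening of the per-protein accuracy-versus-length trend
#' (thin-density problem).
#'
#' @param n_per_range proteins generated per length range
#'   (default 12).
#' @param n_train_per_range proteins per range used for training
#'   (default 6); the rest are the test set.
#' @param msa_rows,mutation_rate synthetic alignment parameters.
#' @param seed master seed for generation, training and evaluation.
#' @param config a [bundle_config()]; its seed is overridden by
#'   `seed`.
#' @return an object of class `benchmark_result`: list with
#'   `per_protein` (data frame: protein, length, subnet id, accuracy
#'   and coverage at both levels), `subnet_range_accuracy` (per-range
#'   macro accuracies), `subnet_mean_accuracy` (their mean, the
#'   "average sub-network" figure), `cascade_accuracy`,
#'   `cascade_coverage`, `subnet_mean_coverage`, the fitted
#'   accuracy-vs-length `slope_subnet` and `slope_cascade`
#'   (percent per residue), and the trained `bundle`.
#' @export
run_benchmark <- function(n_per_range = 12L, n_train_per_range = 6L,
                          msa_rows = 20L, mutation_rate = 0.25,
                          seed = 1L, config = bundle_config()) {
  stopifnot(n_train_per_range < n_per_range)
  part <- length_partition()
  lengths <- with_seed(seed, unlist(lapply(1:6, function(k)
    sample(part$lower[k]:part$upper[k], n_per_range, replace = TRUE))))
  ds <- synth_dataset(synthetic_spec(lengths, msa_rows = msa_rows,
                                     mutation_rate = mutation_rate,
                                     seed = seed))
  range_of <- rep(1:6, each = n_per_range)
  is_train <- unlist(lapply(1:6, function(k)
    seq_len(n_per_range) <= n_train_per_range))
  config$seed <- as.integer(seed)

  bundle <- train_bundle(ds[is_train], config)

  test_idx <- which(!is_train)
  rows <- lapply(test_idx, function(pi) {
    p <- ds[[pi]]
    pm <- predict_map(bundle, p$features)
    truth_idx <- pm$pairs[p$map$cells[pm$pairs] == 1L, , drop = FALSE]
    sc_cas <- contact_scores(pm$pairs[pm$calls, , drop = FALSE], truth_idx)
    sc_sub <- contact_scores(pm$pairs[pm$subnet_calls, , drop = FALSE],
                             truth_idx)
    data.frame(protein = pi, length = p$map$length,
               subnet_id = pm$subnet_id,
               accuracy_cascade = sc_cas$accuracy,
               coverage_cascade = sc_cas$coverage,
               accuracy_subnet = sc_sub$accuracy,
               coverage_subnet = sc_sub$coverage)
  })
  per <- do.call(rbind, rows)

  range_acc <- vapply(1:6, function(k)
    mean(per$accuracy_subnet[per$subnet_id == k], na.rm = TRUE),
    numeric(1L))
  slope <- function(acc) {
    ok <- !is.na(acc)
    unname(stats::coef(stats::lm(acc[ok] ~ per$length[ok]))[2L])
  }
  structure(list(
    per_protein = per,
    subnet_range_accuracy = range_acc,
    subnet_mean_accuracy = mean(range_acc, na.rm = TRUE),
    subnet_mean_coverage = mean(per$coverage_subnet, na.rm = TRUE),
    cascade_accuracy = mean(per$accuracy_cascade, na.rm = TRUE),
    cascade_coverage = mean(per$coverage_cascade, na.rm = TRUE),
    slope_subnet = slope(per$accuracy_subnet),
    slope_cascade = slope(per$accuracy_cascade),
    n_test = nrow(per),
    bundle = bundle
  ), class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("synthetic cascade benchmark (", x$n_test, "test proteins )\n")
  cat(sprintf("  sub-network accuracy (mean of ranges): %.2f%%\n",
              x$subnet_mean_accuracy))
  cat(sprintf("  cascade accuracy:                      %.2f%%\n",
              x$cascade_accuracy))
  cat(sprintf("  coverage: sub-network %.2f%%, cascade %.2f%%\n",
              x$subnet_mean_coverage, x$cascade_coverage))
  cat(sprintf("  accuracy-vs-length slope: sub-network %+.4f, cascade %+.4f %%/res\n",
              x$slope_subnet, x$slope_cascade))
  invisible(x)
}
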