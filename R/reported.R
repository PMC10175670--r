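#' Published HMDD v2.0 benchmark results for this model family
#'
#' Per-fold cross-validation metrics reported for the graph-convolution +
#' dual-autoencoder predictor on the HMDD v2.0 benchmark (495 miRNAs, 383
#' diseases, 5430 curated associations). These published numbers are inputs
#' for aggregate arithmetic (e.g. recomputing the reported means with
#' [aggregate_folds()]); reproducing them from raw data requires the HMDD
#' export itself, which this package does not download.
#'
#' @return list with `cv5_auc` (five 5-fold AUCs), `cv10_auc` (ten 10-fold
#'   AUCs), and `cv5_metrics` (tibble of the five per-fold rows of the
#'   reported metric table, in percent: `auc`, `aupr`, `mcc`, `f1`,
#'   `precision`).
#' @export
hmdd_reported_metrics <- function() {
  list(
    cv5_auc = c(0.867, 0.878, 0.875, 0.878, 0.867),
    cv10_auc = c(0.860, 0.863, 0.877, 0.889, 0.873,
                 0.879, 0.881, 0.882, 0.875, 0.876),
    cv5_metrics = tibble::tibble(
      fold = 1:5,
      auc = c(86.66, 87.80, 87.54, 87.75, 86.73),
      aupr = c(86.80, 88.42, 88.60, 87.99, 87.23),
      mcc = c(55.90, 58.33, 58.77, 57.19, 53.51),
      f1 = c(73.97, 73.61, 74.57, 75.49, 69.86),
      precision = c(85.78, 90.24, 89.33, 85.19, 88.43)
    )
  )
}

#' Shape constants of the HMDD v2.0 benchmark
#'
#' @return list with `n_mirna` (495), `n_disease` (383), `n_associations`
#'   (5430), and `sparsity_pct` (percentage of zero cells, rounded to 2
#'   decimals).
#' @export
hmdd_benchmark_shape <- function() {
  n_m <- 495L; n_d <- 383L; n_assoc <- 5430L
  list(n_mirna = n_m, n_disease = n_d, n_associations = n_assoc,
       sparsity_pct = round(100 * (n_m * n_d - n_assoc) / (n_m * n_d), 2))
}
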