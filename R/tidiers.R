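#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy per-fold cross-validation metrics
#'
#' @param x an `mda_cv` object from [run_cross_validation()].
#' @param ... unused.
#' @return tibble with one row per fold and metric columns.
#' @method tidy mda_cv
#' @export
tidy.mda_cv <- function(x, ...) {
  x$reports
}

#' One-row cross-validation summary
#'
#' @param x an `mda_cv` object.
#' @param ... unused.
#' @return one-row tibble: `k`, `seed`, mean of each metric
#'   (`mean_auc`, `mean_aupr`, ...), and `sd_auc` (sample convention).
#' @method glance mda_cv
#' @export
glance.mda_cv <- function(x, ...) {
  s <- x$summary
  means <- stats::setNames(as.list(s$mean), paste0("mean_", s$metric))
  dplyr::bind_cols(tibble::tibble(k = x$k, seed = x$seed),
                   tibble::as_tibble(means),
                   tibble::tibble(sd_auc = s$sd_sample[s$metric == "auc"]))
}

#' Plot per-fold cross-validation metrics
#'
#' Dot plot of each metric across folds with the fold mean marked.
#'
#' @param object an `mda_cv` object.
#' @param metrics which metric columns to show.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot mda_cv
#' @export
autoplot.mda_cv <- function(object,
                            metrics = c("auc", "aupr", "mcc", "f1",
                                        "precision"), ...) {
  long <- tidy(object) |>
    dplyr::select(dplyr::all_of(c("fold", metrics))) |>
    tidyr::pivot_longer(-"fold", names_to = "metric", values_to = "value")
  means <- long |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.08, height = 0, alpha = 0.7) +
    ggplot2::geom_point(data = means, colour = "red", shape = 95, size = 8) +
    ggplot2::labs(x = NULL, y = "metric value",
                  title = sprintf("%d-fold cross-validation (seed %d)",
                                  object$k, object$seed)) +
    ggplot2::theme_minimal()
}

#' Plot an autoencoder or GCN training loss curve
#'
#' @param object an `mda_autoencoder` or `mda_gcn` object.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot mda_autoencoder
#' @export
autoplot.mda_autoencoder <- function(object, ...) {
  plot_loss_curve(object$loss, "reconstruction loss (sum of squares)")
}

#' @rdname autoplot.mda_autoencoder
#' @method autoplot mda_gcn
#' @export
autoplot.mda_gcn <- function(object, ...) {
  plot_loss_curve(object$loss, "binary cross-entropy")
}

plot_loss_curve <- function(loss, ylab) {
  df <- tibble::tibble(epoch = seq_along(loss), loss = loss)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = ylab) +
    ggplot2::theme_minimal()
}
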