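#' Loss and accuracy curves for one or more training histories
#'
#' @param object an `ae_fit` or a combined history tibble with `epoch`,
#'   `train_loss`, `val_loss`, `train_accuracy`, `val_accuracy` and
#'   optionally `mode` columns.
#' @param ... unused.
#' @return A ggplot: loss (top facet) and accuracy (bottom facet), one
#'   colour per training mode, dotted training / solid validation lines.
#' @export
autoplot.ae_fit <- function(object, ...) {
  h <- dplyr::mutate(object$history, mode = object$config$loss_mode)
  plot_history(h)
}

plot_history <- function(history) {
  if (!"mode" %in% names(history)) history$mode <- "model"
  long <- tidyr::pivot_longer(
    history,
    cols = c("train_loss", "val_loss", "train_accuracy", "val_accuracy"),
    names_to = c("phase", "measure"), names_sep = "_",
    values_to = "value"
  )
  long <- dplyr::filter(long, is.finite(.data$value))
  ggplot2::ggplot(long, ggplot2::aes(.data$epoch, .data$value,
                                     colour = .data$mode,
                                     linetype = .data$phase)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~measure, ncol = 1, scales = "free_y") +
    ggplot2::scale_linetype_manual(values = c(train = "dotted",
                                              val = "solid")) +
    ggplot2::labs(x = "epoch", y = NULL, colour = "mode",
                  linetype = "phase") +
    ggplot2::theme_minimal()
}

#' Violin plots of per-SNP metric distributions
#'
#' @param per_snp tibble of per-SNP metric values with a `mode` column
#'   (e.g. bound from [full_report()] attributes across runs).
#' @return A ggplot.
#' @export
plot_metric_violins <- function(per_snp) {
  long <- tidyr::pivot_longer(
    per_snp, cols = dplyr::where(is.numeric),
    names_to = "metric", values_to = "value"
  )
  long <- dplyr::filter(long, !is.na(.data$value))
  if (nrow(long) == 0L) {
    warn("No finite metric values; violin plot skipped.")
    return(invisible(NULL))
  }
  ggplot2::ggplot(long, ggplot2::aes(.data$mode, .data$value,
                                     fill = .data$mode)) +
    ggplot2::geom_violin(scale = "width") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "score") +
    ggplot2::theme_minimal()
}

#' Histograms of per-SNP metric distributions
#'
#' @inheritParams plot_metric_violins
#' @param bins histogram bin count.
#' @return A ggplot.
#' @export
plot_metric_histograms <- function(per_snp, bins = 30L) {
  long <- tidyr::pivot_longer(
    per_snp, cols = dplyr::where(is.numeric),
    names_to = "metric", values_to = "value"
  )
  long <- dplyr::filter(long, !is.na(.data$value))
  if (nrow(long) == 0L) {
    warn("No finite metric values; histogram skipped.")
    return(invisible(NULL))
  }
  ggplot2::ggplot(long, ggplot2::aes(.data$value, fill = .data$mode)) +
    ggplot2::geom_histogram(bins = bins, position = "identity", alpha = 0.6) +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = "score", y = "SNPs") +
    ggplot2::theme_minimal()
}

#' Write diagnostic figures for an experiment
#'
#' Writes loss/accuracy curves and, when per-SNP metric tables are
#' supplied, violin plots and histograms of the metric distributions.
#' Figure aesthetics are informational, not a contract.
#'
#' @param result a `comparison_result` (or a history tibble).
#' @param dir output directory (created if needed).
#' @param per_snp optional tibble of per-SNP metrics with a `mode` column.
#' @return Character vector of files written.
#' @export
plot_diagnostics <- function(result, dir, per_snp = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  history <- if (inherits(result, "comparison_result")) {
    result$histories
  } else {
    result
  }
  if (!is.null(history) && nrow(history) > 0L) {
    f <- file.path(dir, "loss_accuracy.pdf")
    ggplot2::ggsave(f, plot_history(history), width = 7, height = 6)
    files <- c(files, f)
  }
  if (!is.null(per_snp)) {
    pv <- plot_metric_violins(per_snp)
    if (!is.null(pv)) {
      f <- file.path(dir, "metric_violins.pdf")
      ggplot2::ggsave(f, pv, width = 8, height = 6)
      files <- c(files, f)
    }
    ph <- plot_metric_histograms(per_snp)
    if (!is.null(ph)) {
      f <- file.path(dir, "metric_histograms.pdf")
      ggplot2::ggsave(f, ph, width = 8, height = 6)
      files <- c(files, f)
    }
  }
  files
}
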