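# broom-style tidiers and ggplot2 autoplot methods.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy per-fold cross-validation results
#'
#' @param x An `aie_cv` from [run_cv()].
#' @param ... Unused.
#' @return Tibble with one row per (family, mode, fold): confusion counts
#'   and all metrics at full precision.
#' @export
tidy.aie_cv <- function(x, ...) {
  x$results
}

#' One-row-per-method summary of a cross-validation run
#'
#' @param x An `aie_cv`.
#' @param ... Unused.
#' @return Tibble with mean and sd of train accuracy, test accuracy, AUC
#'   and F1 per (family, mode), plus pooled confusion counts.
#' @export
glance.aie_cv <- function(x, ...) {
  wide <- x$summary |>
    tidyr::pivot_wider(names_from = metric,
                       values_from = c(mean_value, sd_value))
  dplyr::left_join(wide, x$pooled_confusion, by = c("family", "mode"))
}

#' Tidy a fusion model's explained variance
#'
#' @param x A `fusion_model` from [fit_fusion()].
#' @param ... Unused.
#' @return Tibble with `component`, `ratio` and the cumulative ratio.
#' @export
tidy.fusion_model <- function(x, ...) {
  tibble::tibble(
    component = seq_len(x$component_count),
    ratio = x$explained_variance_ratio,
    cumulative = cumsum(x$explained_variance_ratio)
  )
}

#' @export
glance.fusion_model <- function(x, ...) {
  tibble::tibble(
    fingerprint_mode = x$fingerprint_mode,
    component_count = x$component_count,
    quantitative_dims = length(x$column_means),
    fused_dims = x$component_count + length(x$column_means),
    variance_retained = sum(x$explained_variance_ratio)
  )
}

#' Plot mean test metrics of a cross-validation run
#'
#' Bar chart of mean +/- sd test accuracy (or another metric) per
#' (family, mode), ensemble highlighted.
#'
#' @param object An `aie_cv`.
#' @param metric One of `"accuracy"`, `"auc"`, `"f1"`,
#'   `"train_accuracy"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.aie_cv <- function(object, metric = "accuracy", ...) {
  dat <- dplyr::filter(object$summary, .data$metric == !!metric)
  ggplot2::ggplot(dat, ggplot2::aes(x = mode, y = mean_value,
                                    fill = family)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.85),
                      width = 0.8) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = mean_value - sd_value,
                   ymax = mean_value + sd_value),
      position = ggplot2::position_dodge(width = 0.85), width = 0.25) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "feature mode", y = paste("mean", metric),
                  fill = "method") +
    ggplot2::theme_minimal()
}

#' Scree plot of a fusion model
#'
#' @param object A `fusion_model`.
#' @param n_components Number of leading components shown.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fusion_model <- function(object, n_components = 30L, ...) {
  dat <- head(tidy(object), n_components)
  ggplot2::ggplot(dat, ggplot2::aes(x = component, y = ratio)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "principal component",
                  y = "explained variance ratio") +
    ggplot2::theme_minimal()
}

#' ROC curve points for a score vector
#'
#' Sweeps every distinct score threshold and reports (FPR, TPR) pairs,
#' suitable for plotting the ROC curve whose area [compute_auc()]
#' reports.
#'
#' @param scores Numeric positive-class scores.
#' @param labels AIE/ACQ (or 0/1) labels.
#' @return Tibble with `threshold`, `tpr`, `fpr`, ordered by descending
#'   threshold.
#' @export
roc_points <- function(scores, labels) {
  y <- encode_labels(labels)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  npos <- sum(y == 1L)
  nneg <- sum(y == 0L)
  tibble::tibble(
    threshold = thr,
    tpr = vapply(thr, function(t) sum(scores >= t & y == 1L) / npos,
                 numeric(1)),
    fpr = vapply(thr, function(t) sum(scores >= t & y == 0L) / nneg,
                 numeric(1))
  )
}
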