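# ggplot2 autoplot methods for result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a PCoA ordination
#'
#' @param object A `taxrisk_ordination`.
#' @param groups Optional group label per sample (in coordinate order).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.taxrisk_ordination <- function(object, groups = NULL, ...) {
  df <- object$coordinates
  lab <- sprintf("Axis %d (%.1f%%)", 1:2, 100 * object$prop_explained[1:2])
  p <- if (is.null(groups)) {
    ggplot2::ggplot(df, ggplot2::aes(.data$Axis1, .data$Axis2))
  } else {
    df$group <- groups
    ggplot2::ggplot(df, ggplot2::aes(.data$Axis1, .data$Axis2,
                                     colour = .data$group))
  }
  p + ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::labs(x = lab[1], y = lab[2]) +
    ggplot2::theme_minimal()
}

#' Plot cross-validation AUCs as a box plot over iterations
#'
#' @param object A `taxrisk_cv`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.taxrisk_cv <- function(object, ...) {
  df <- object$iterations
  ggplot2::ggplot(df, ggplot2::aes(x = "", y = .data$auc)) +
    ggplot2::geom_boxplot(width = 0.3, outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "AUC",
                  title = sprintf("%d random splits: mean AUC %.3f",
                                  object$summary$n_iter,
                                  object$summary$mean_auc)) +
    ggplot2::theme_minimal()
}

#' Plot ROC curves of the cross-validation iterations
#'
#' @param cv A `taxrisk_cv`.
#' @return A ggplot overlaying every iteration's ROC curve.
#' @export
plot_roc_curves <- function(cv) {
  stopifnot(inherits(cv, "taxrisk_cv"))
  df <- dplyr::bind_rows(lapply(seq_along(cv$rocs), function(i) {
    dplyr::mutate(cv$rocs[[i]]$curve, iteration = i)
  }))
  ggplot2::ggplot(df, ggplot2::aes(1 - .data$specificity, .data$sensitivity,
                                   group = .data$iteration)) +
    ggplot2::geom_line(alpha = 0.3) +
    ggplot2::geom_abline(linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity") +
    ggplot2::theme_minimal()
}

#' Plot top feature importances
#'
#' @param object A `taxrisk_importance` tibble.
#' @param top_n Number of features shown.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.taxrisk_importance <- function(object, top_n = 20L, ...) {
  df <- utils::head(object, top_n)
  df$feature <- stats::reorder(df$feature, df$importance)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$importance, .data$feature))
  if (!all(is.na(df$sd))) {
    p <- p + ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$importance - .data$sd,
                   xmax = .data$importance + .data$sd),
      height = 0.25, colour = "grey50")
  }
  p + ggplot2::geom_col(alpha = 0.8) +
    ggplot2::labs(x = paste0("importance (", df$method[1], ")"), y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot external-cohort risk scores by group
#'
#' @param object A `taxrisk_scores`.
#' @param ... Unused.
#' @return A ggplot with the decision threshold marked.
#' @export
autoplot.taxrisk_scores <- function(object, ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(.data$group, .data$display_score)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = 2,
                        colour = "firebrick") +
    ggplot2::labs(x = NULL, y = "predicted risk score") +
    ggplot2::theme_minimal()
}
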