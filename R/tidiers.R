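# broom-style tidiers for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-iteration cross-validation records
#'
#' @param x A `taxrisk_cv` object.
#' @param ... Unused.
#' @return Tibble with one row per iteration: `iteration`, `seed`, `auc`,
#'   `threshold`, `sensitivity`, `specificity`.
#' @export
tidy.taxrisk_cv <- function(x, ...) x$iterations

#' One-row cross-validation summary
#'
#' @param x A `taxrisk_cv` object.
#' @param ... Unused.
#' @return Tibble with `n_iter`, `mean_auc`, `sd_auc`, `min_auc`, `max_auc`.
#' @export
glance.taxrisk_cv <- function(x, ...) x$summary

#' Tidy a PERMANOVA fit
#'
#' @param x A `taxrisk_permanova` object.
#' @param ... Unused.
#' @return Tibble with the among/within partition, pseudo-F and p-value.
#' @export
tidy.taxrisk_permanova <- function(x, ...) {
  tibble::tibble(
    term = c("among_groups", "within_groups"),
    df = c(x$df_among, x$df_within),
    sum_of_squares = c(x$ss_among, x$ss_within),
    statistic = c(x$f, NA_real_),
    p.value = c(x$p, NA_real_)
  )
}

#' Tidy ordination coordinates
#'
#' @param x A `taxrisk_ordination` object.
#' @param ... Unused.
#' @return Tibble of sample coordinates on the retained axes.
#' @export
tidy.taxrisk_ordination <- function(x, ...) x$coordinates

#' Tidy per-sample risk scores
#'
#' @param x A `taxrisk_scores` object.
#' @param ... Unused.
#' @return Tibble with one row per scored sample.
#' @export
tidy.taxrisk_scores <- function(x, ...) x$scores

#' One-row summary of a scored cohort
#'
#' @param x A `taxrisk_scores` object.
#' @param ... Unused.
#' @return Tibble with sample count, feature coverage and threshold.
#' @export
glance.taxrisk_scores <- function(x, ...) {
  tibble::tibble(n_samples = nrow(x$scores), coverage = x$coverage,
                 threshold = x$threshold,
                 frac_above = mean(x$scores$above_threshold))
}

#' Tidy a fitted risk model (impurity importance)
#'
#' @param x A `taxrisk_model` object.
#' @param ... Unused.
#' @return Tibble `feature`, `importance`, `sd`, `method`.
#' @export
tidy.taxrisk_model <- function(x, ...) feature_importance(x, "impurity")
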