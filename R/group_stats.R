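# Two-group and multi-group differential statistics with BH correction and
# fold-change reporting.

#' F test for equality of two variances
#'
#' `F = s_x^2 / s_y^2` with (n_x - 1, n_y - 1) degrees of freedom and a
#' two-sided p-value; used to gate the choice between the pooled-variance
#' and Welch t tests.
#'
#' @param x,y Numeric vectors, each of length >= 2 with nonzero variance.
#' @return Tibble with `statistic`, `df1`, `df2`, `p`.
#' @export
var_ratio_test <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) stop("need at least 2 values per sample")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance: the variance ratio is degenerate")
  }
  ft <- stats::var.test(x, y)
  tibble::tibble(statistic = unname(ft$statistic),
                 df1 = unname(ft$parameter[1]), df2 = unname(ft$parameter[2]),
                 p = ft$p.value)
}

#' Two-sample t test gated by the variance-ratio F test
#'
#' When `equal_var` is `NULL` (default) the pooled-variance t test is used
#' if the F test does not reject equality of variances at `alpha`,
#' otherwise Welch's t test.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @param equal_var `TRUE`, `FALSE`, or `NULL` to decide by F test.
#' @param alpha Gate level for the F test (default 0.05).
#' @return Tibble with `statistic`, `df`, `p`, `equal_var`.
#' @export
two_sample_t <- function(x, y, equal_var = NULL, alpha = 0.05) {
  if (length(x) < 2L || length(y) < 2L) stop("need at least 2 values per sample")
  if (is.null(equal_var)) {
    equal_var <- if (stats::var(x) == 0 || stats::var(y) == 0) FALSE
                 else var_ratio_test(x, y)$p >= alpha
  }
  tt <- stats::t.test(x, y, var.equal = equal_var)
  tibble::tibble(statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, equal_var = equal_var)
}

#' Pearson chi-squared test on a 2x2 table
#'
#' Without continuity correction by default (the correction is available by
#' flag), df = 1, two-sided.
#'
#' @param tab 2x2 matrix of non-negative integer counts with all margins
#'   positive.
#' @param correct Apply the Yates continuity correction?
#' @return Tibble with `statistic`, `df`, `p`.
#' @export
chi2_2x2 <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("expected a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("table entries must be non-negative integers")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero margin: chi-squared test undefined")
  }
  ct <- stats::chisq.test(tab, correct = correct)
  tibble::tibble(statistic = unname(ct$statistic), df = unname(ct$parameter),
                 p = ct$p.value)
}

mwu_u_stat <- function(rank_sum, nx) rank_sum - nx * (nx + 1) / 2

#' Mann-Whitney U test
#'
#' Reports the U statistic for `x` (ties counted half). For small samples
#' the two-sided p-value is exact, from tie-aware enumeration of all
#' assignments of the pooled ranks:
#' `p = P(|U - n_x n_y / 2| >= |U_obs - n_x n_y / 2|)` under the null.
#' The exact route is taken whenever the enumeration `choose(n, n_x)` stays
#' at or below `max_enum` (so e.g. 8 vs 8 is exact while 9 vs 9 is not);
#' larger designs use the tie-corrected normal approximation with
#' continuity correction.
#'
#' @param x,y Non-empty numeric vectors.
#' @param max_enum Largest enumeration size for the exact route (default
#'   20000, which admits every design with at most 8 observations per side
#'   and all very unbalanced small designs).
#' @return Tibble with `statistic` (U for x), `p`, `method`.
#' @export
mann_whitney_u <- function(x, y, max_enum = 20000L) {
  nx <- length(x); ny <- length(y)
  if (nx == 0L || ny == 0L) stop("empty sample")
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- mwu_u_stat(sum(r[seq_len(nx)]), nx)
  mu <- nx * ny / 2

  if (choose(nx + ny, nx) <= max_enum) {
    idx <- utils::combn(nx + ny, nx)
    rank_sums <- colSums(matrix(r[idx], nrow = nx))
    u_all <- mwu_u_stat(rank_sums, nx)
    eps <- sqrt(.Machine$double.eps)
    p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - eps)
    method <- "exact"
  } else {
    n <- nx + ny
    ties <- table(r)
    sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1  # every pooled value tied
    } else {
      z <- (u_obs - mu - sign(u_obs - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal_approx"
  }
  tibble::tibble(statistic = u_obs, p = p, method = method)
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H with a chi-squared reference on k - 1 df. A completely
#' constant response returns H = 0, p = 1 rather than an error.
#'
#' @param values Numeric vector, or a list of per-group vectors.
#' @param groups Group labels matching `values` (ignored when `values` is a
#'   list).
#' @return Tibble with `statistic`, `df`, `p`.
#' @export
kruskal_wallis <- function(values, groups = NULL) {
  if (is.list(values) && is.null(groups)) {
    groups <- rep(seq_along(values), lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  if (any(lengths(split(values, groups)) == 0L)) stop("empty group")
  k <- length(unique(groups))
  if (k < 2L) stop("need at least two groups")
  if (length(unique(values)) == 1L) {
    return(tibble::tibble(statistic = 0, df = k - 1L, p = 1))
  }
  kt <- stats::kruskal.test(values, factor(groups))
  tibble::tibble(statistic = unname(kt$statistic), df = unname(kt$parameter),
                 p = kt$p.value)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Returns FDR-adjusted p-values in input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Differential-abundance table for a case/control pair
#'
#' One row per taxon at the requested rank, with group means of relative
#' abundance, the case/control fold change, the per-taxon test p-value and
#' its BH adjustment across taxa. Design `"two_group_t"` is the clinical
#' protocol: an F-test-gated t test, flagged significant at raw p < 0.05.
#' Design `"kw_mwu_bh"` is the multi-group (animal-arm) protocol: a
#' Mann-Whitney U test per taxon for the chosen pair, flagged significant
#' at BH-adjusted p < 0.05.
#'
#' @param profile Tibble with `sample_id` + non-negative feature columns
#'   (counts or relative abundances; rows are renormalised to sum to 1),
#'   with a `lineages` attribute if `rank != "genus"`.
#' @param metadata Tibble with `sample_id`, `group` covering all samples.
#' @param rank Taxonomic rank for the comparison.
#' @param design `"two_group_t"` or `"kw_mwu_bh"`.
#' @param control,case Group labels; default first and second group level.
#' @return Tibble: `taxon`, `rank`, `mean_control`, `mean_case`,
#'   `fold_change` (`NA` with `fold_undefined = TRUE` when the control mean
#'   is 0), `test`, `p`, `p_adj`, `significant`, ordered by `p`.
#' @export
diff_abundance <- function(profile, metadata, rank = "genus",
                           design = c("two_group_t", "kw_mwu_bh"),
                           control = NULL, case = NULL) {
  design <- match.arg(design)
  md <- check_metadata(metadata, profile$sample_id)
  lv <- levels(md$group)
  if (is.null(control)) control <- lv[1]
  if (is.null(case)) case <- lv[2]
  if (!all(c(control, case) %in% lv)) stop("case/control not among group levels")

  prof <- collapse_to_rank(profile, rank)
  m <- profile_matrix(prof)
  m <- m / rowSums(m)
  grp <- md$group[match(rownames(m), md$sample_id)]
  mi <- m[grp == control, , drop = FALSE]
  ma <- m[grp == case, , drop = FALSE]
  if (nrow(mi) == 0L || nrow(ma) == 0L) stop("empty case or control group")

  p <- vapply(seq_len(ncol(m)), function(j) {
    xc <- mi[, j]; xa <- ma[, j]
    if (design == "two_group_t") {
      tryCatch(two_sample_t(xa, xc)$p, error = function(e) NA_real_)
    } else {
      mann_whitney_u(xa, xc)$p
    }
  }, numeric(1))
  p_adj <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  p_adj[ok] <- bh_adjust(p[ok])

  mean_control <- colMeans(mi)
  mean_case <- colMeans(ma)
  fc <- ifelse(mean_control > 0, mean_case / mean_control, NA_real_)
  out <- tibble::tibble(
    taxon = colnames(m),
    rank = rank,
    mean_control = unname(mean_control),
    mean_case = unname(mean_case),
    fold_change = unname(fc),
    fold_undefined = mean_control == 0,
    test = if (design == "two_group_t") "t_ftest_gated" else "mann_whitney_u",
    p = p,
    p_adj = p_adj,
    significant = if (design == "two_group_t") !is.na(p) & p < 0.05
                  else !is.na(p_adj) & p_adj < 0.05
  )
  dplyr::arrange(out, .data$p)
}
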