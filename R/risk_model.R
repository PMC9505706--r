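# Gradient-boosted disease-risk model: training, repeated random-split
# evaluation, ROC/importance reporting and cross-cohort transfer scoring.

#' Default boosting hyperparameters
#'
#' Classic least-squares gradient boosting: 500 stages, learning rate 0.1,
#' tree depth 3, no row subsampling. The ensemble regresses the 0/1 class
#' label under squared error, so predictions are continuous risk scores
#' centred on the class means rather than calibrated probabilities.
#'
#' @param n_trees,learning_rate,max_depth,subsample Override any default.
#' @return Named list of hyperparameters.
#' @export
gbm_params <- function(n_trees = 500L, learning_rate = 0.1, max_depth = 3L,
                       subsample = 1.0) {
  list(n_trees = as.integer(n_trees), learning_rate = learning_rate,
       max_depth = as.integer(max_depth), subsample = subsample)
}

#' Drop uninformative features
#'
#' Retains features with nonzero variance and nonzero abundance in at least
#' one sample; the retained count is recorded in the `n_selected`
#' attribute.
#'
#' @param profile Tibble with `sample_id` + numeric feature columns.
#' @return Filtered profile tibble.
#' @export
select_features <- function(profile) {
  m <- profile_matrix(profile)
  if (ncol(m) == 0L || nrow(m) == 0L) stop("empty profile")
  keep <- apply(m, 2L, stats::var) > 0 & colSums(m != 0) > 0
  if (!any(keep)) stop("no informative features retained")
  out <- profile[, c("sample_id", colnames(m)[keep])]
  attr(out, "lineages") <- attr(profile, "lineages")
  attr(out, "n_selected") <- sum(keep)
  out
}

as_binary_labels <- function(labels) {
  if (is.factor(labels) || is.character(labels)) {
    f <- if (is.factor(labels)) labels else factor(labels, levels = unique(labels))
    f <- droplevels(f)
    if (nlevels(f) != 2L) stop("need exactly two classes, found ", nlevels(f))
    y <- as.numeric(f) - 1           # control = first level = 0
    attr(y, "levels") <- levels(f)
    return(y)
  }
  if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0 (control) / 1 (case)")
  y <- as.numeric(labels)
  attr(y, "levels") <- c("0", "1")
  y
}

feature_input <- function(features) {
  if (is.matrix(features)) return(features)
  profile_matrix(features)
}

#' Fit a gradient-boosted risk model
#'
#' Stage-wise boosted regression trees fit to 0/1 class labels under
#' squared error. Refitting with identical data and seed reproduces
#' identical predictions.
#'
#' @param features Tibble (`sample_id` + feature columns) or numeric matrix
#'   (samples x features with column names).
#' @param labels Factor/character (first level = control) or 0/1 vector;
#'   both classes must be present with >= 2 samples each.
#' @param params Hyperparameters from [gbm_params()].
#' @param seed Integer training seed (recorded; the fit itself is
#'   deterministic when `subsample = 1`).
#' @return Object of class `taxrisk_model`.
#' @export
fit_risk_model <- function(features, labels, params = gbm_params(), seed = 1L) {
  X <- feature_input(features)
  if (any(!is.finite(X))) stop("feature matrix must be finite")
  if (anyDuplicated(colnames(X))) stop("duplicate feature names")
  y <- as_binary_labels(labels)
  if (length(y) != nrow(X)) stop("labels length must match sample count")
  if (length(unique(y)) < 2L) stop("need both classes present")
  if (min(table(y)) < 2L) stop("need at least 2 samples in each class")

  booster <- with_seed(seed, {
    dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
    xgboost::xgb.train(
      params = list(objective = "reg:squarederror",
                    eta = params$learning_rate,
                    max_depth = params$max_depth,
                    subsample = params$subsample,
                    nthread = 1),
      data = dtrain, nrounds = params$n_trees, verbose = 0
    )
  })
  structure(list(
    booster_raw = xgboost::xgb.save.raw(booster),
    features = colnames(X),
    params = params,
    seed = seed,
    label_levels = attr(y, "levels")
  ), class = "taxrisk_model")
}

#' @export
print.taxrisk_model <- function(x, ...) {
  cat("<taxrisk risk model> ", length(x$features), " features, ",
      x$params$n_trees, " trees (depth ", x$params$max_depth, ", eta ",
      x$params$learning_rate, ")\n", sep = "")
  cat("  labels: 0 = ", x$label_levels[1], ", 1 = ", x$label_levels[2],
      "\n", sep = "")
  invisible(x)
}

#' Predict continuous risk scores
#'
#' @param object A `taxrisk_model`.
#' @param newdata Profile tibble or matrix; columns are aligned to the
#'   model's feature list via [align_features()].
#' @param ... Unused.
#' @return Numeric vector of raw risk scores (not clipped).
#' @export
predict.taxrisk_model <- function(object, newdata, ...) {
  X <- align_features(object, newdata)
  booster <- xgboost::xgb.load.raw(object$booster_raw)
  as.numeric(stats::predict(booster, X))
}

#' Align an external feature matrix to a model's feature order
#'
#' Reorders columns to the model's feature list, fills features absent from
#' the external cohort with 0 and drops external-only features. The shared
#' fraction is attached as attribute `coverage` and reported via a message
#' when below 1.
#'
#' @param model A `taxrisk_model`.
#' @param profile Profile tibble or numeric matrix.
#' @return Numeric matrix, samples x model features.
#' @export
align_features <- function(model, profile) {
  X <- feature_input(profile)
  shared <- intersect(model$features, colnames(X))
  coverage <- length(shared) / length(model$features)
  if (coverage == 0) stop("no overlap between model features and cohort features")
  out <- matrix(0, nrow = nrow(X), ncol = length(model$features),
                dimnames = list(rownames(X), model$features))
  out[, shared] <- X[, shared]
  if (coverage < 1) {
    message(sprintf("feature alignment: %d/%d model features present (coverage %.2f)",
                    length(shared), length(model$features), coverage))
  }
  attr(out, "coverage") <- coverage
  out
}

#' ROC curve and AUC
#'
#' AUC is the probability that a random case outscores a random control,
#' with half credit for ties (the trapezoidal area under the ROC curve).
#'
#' @param scores Numeric scores.
#' @param labels Two-class labels (first level / 0 = control).
#' @return Object of class `taxrisk_roc`: list with `auc` and `curve`
#'   (tibble of `threshold`, `sensitivity`, `specificity`, descending
#'   thresholds; a sample is called positive when `score >= threshold`).
#' @export
roc_auc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  if (length(scores) != length(y)) stop("scores and labels differ in length")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  th <- sort(unique(scores), decreasing = TRUE)
  sens <- vapply(th, function(t) sum(scores >= t & y == 1) / n1, numeric(1))
  spec <- vapply(th, function(t) sum(scores < t & y == 0) / n0, numeric(1))
  curve <- tibble::tibble(
    threshold = c(Inf, th),
    sensitivity = c(0, sens),
    specificity = c(1, spec)
  )
  structure(list(auc = auc, curve = curve), class = "taxrisk_roc")
}

#' @export
print.taxrisk_roc <- function(x, ...) {
  cat(sprintf("<ROC> AUC = %.4f over %d thresholds\n", x$auc, nrow(x$curve)))
  invisible(x)
}

#' Operating point maximising Youden's J
#'
#' Selects the ROC threshold maximising `sensitivity + specificity - 1`;
#' ties are broken towards the highest (most specific) threshold, so a
#' completely uninformative score set yields the (0, 1) corner.
#'
#' @param roc A `taxrisk_roc` object.
#' @return Tibble with `threshold`, `sensitivity`, `specificity`, `youden`.
#' @export
operating_point <- function(roc) {
  stopifnot(inherits(roc, "taxrisk_roc"))
  cv <- roc$curve
  j <- cv$sensitivity + cv$specificity - 1
  best <- which(j >= max(j) - sqrt(.Machine$double.eps))
  pick <- best[which.max(cv$threshold[best])]
  tibble::tibble(threshold = cv$threshold[pick],
                 sensitivity = cv$sensitivity[pick],
                 specificity = cv$specificity[pick],
                 youden = j[pick])
}

stratified_split <- function(y, train_frac, seed, max_redraw = 100L) {
  for (attempt in seq_len(max_redraw)) {
    idx <- with_seed(seed + (attempt - 1L) * 1000003L, {
      unlist(lapply(unique(y), function(cl) {
        pool <- which(y == cl)
        sample(pool, round(train_frac * length(pool)))
      }))
    })
    test <- setdiff(seq_along(y), idx)
    if (length(unique(y[idx])) == 2L && length(unique(y[test])) == 2L) {
      if (attempt > 1L) message("split redrawn ", attempt - 1L, " time(s)")
      return(list(train = sort(idx), test = test))
    }
  }
  stop("could not draw a split containing both classes in train and test")
}

#' Repeated random-split cross-validation of the risk model
#'
#' Evaluation protocol of the risk model: `n_iter` independent stratified
#' random splits at `train_frac` (default 30 iterations at 7:3), a model
#' fit on each training set and scored on its test set; per-iteration AUC,
#' ROC and Youden operating point are recorded and summarised.
#'
#' @param features Profile tibble or matrix.
#' @param labels Two-class labels.
#' @param n_iter Number of random splits (default 30).
#' @param train_frac Training fraction (default 0.7).
#' @param base_seed Iteration i uses seed `base_seed + i`.
#' @param params Hyperparameters, see [gbm_params()].
#' @param stratified Stratify splits by class (default `TRUE`).
#' @return Object of class `taxrisk_cv`: list with `iterations` (tibble:
#'   `iteration`, `seed`, `auc`, `threshold`, `sensitivity`,
#'   `specificity`), `summary` (mean/sd/min/max AUC), `models` (per-
#'   iteration `taxrisk_model`s), `splits`, and `rocs`.
#' @export
cross_validate_risk <- function(features, labels, n_iter = 30L,
                                train_frac = 0.7, base_seed = 1L,
                                params = gbm_params(), stratified = TRUE) {
  X <- feature_input(features)
  y <- as_binary_labels(labels)
  res <- lapply(seq_len(n_iter), function(i) {
    seed <- base_seed + i
    sp <- if (stratified) stratified_split(y, train_frac, seed)
          else {
            idx <- with_seed(seed, sample(length(y), round(train_frac * length(y))))
            st <- list(train = sort(idx), test = setdiff(seq_along(y), idx))
            if (length(unique(y[st$train])) < 2L || length(unique(y[st$test])) < 2L) {
              sp2 <- stratified_split(y, train_frac, seed)
              message("unstratified split lacked a class; redrawn stratified")
              st <- sp2
            }
            st
          }
    fit <- fit_risk_model(X[sp$train, , drop = FALSE], y[sp$train],
                          params = params, seed = seed)
    scores <- predict(fit, X[sp$test, , drop = FALSE])
    roc <- roc_auc(scores, y[sp$test])
    op <- operating_point(roc)
    list(row = tibble::tibble(iteration = i, seed = seed, auc = roc$auc,
                              threshold = op$threshold,
                              sensitivity = op$sensitivity,
                              specificity = op$specificity),
         model = fit, split = sp, roc = roc)
  })
  iterations <- dplyr::bind_rows(lapply(res, `[[`, "row"))
  structure(list(
    iterations = iterations,
    summary = tibble::tibble(
      n_iter = n_iter,
      mean_auc = mean(iterations$auc),
      sd_auc = if (n_iter > 1L) stats::sd(iterations$auc) else 0,
      min_auc = min(iterations$auc),
      max_auc = max(iterations$auc)
    ),
    models = lapply(res, `[[`, "model"),
    splits = lapply(res, `[[`, "split"),
    rocs = lapply(res, `[[`, "roc"),
    train_frac = train_frac,
    base_seed = base_seed
  ), class = "taxrisk_cv")
}

#' @export
print.taxrisk_cv <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<taxrisk CV> %d iterations at %.0f:%.0f\n", s$n_iter,
              100 * x$train_frac, 100 * (1 - x$train_frac)))
  cat(sprintf("  AUC mean %.4f, sd %.4f, min %.4f, max %.4f\n",
              s$mean_auc, s$sd_auc, s$min_auc, s$max_auc))
  invisible(x)
}

impurity_importance_one <- function(model) {
  if (length(model$features) == 1L) {
    return(stats::setNames(1, model$features))
  }
  booster <- xgboost::xgb.load.raw(model$booster_raw)
  imp <- xgboost::xgb.importance(model = booster)
  out <- stats::setNames(rep(0, length(model$features)), model$features)
  out[imp$Feature] <- imp$Gain
  out
}

#' Feature importance of a fitted risk model
#'
#' `method = "impurity"`: per-feature share of the total split-gain
#' (impurity reduction) across all trees, normalised to sum to 1. Given a
#' `taxrisk_cv` object, the mean and standard deviation across the
#' per-iteration models are reported. `method = "permutation"`: mean AUC
#' drop over `n_repeats` seeded shuffles of each feature column on
#' held-out data (may be negative for irrelevant features).
#'
#' @param x A `taxrisk_model` or `taxrisk_cv` object.
#' @param method `"impurity"` or `"permutation"`.
#' @param data,labels Held-out profile and labels (permutation only; for a
#'   `taxrisk_cv`, the model of the best iteration is evaluated on its own
#'   test split when `data` is omitted and `features`/`labels` were kept).
#' @param n_repeats Shuffles per feature (permutation only).
#' @param seed Seed for the shuffles.
#' @return Tibble `feature`, `importance`, `sd`, `method`, sorted
#'   decreasing.
#' @export
feature_importance <- function(x, method = c("impurity", "permutation"),
                               data = NULL, labels = NULL, n_repeats = 10L,
                               seed = 1L) {
  method <- match.arg(method)
  if (method == "impurity") {
    if (inherits(x, "taxrisk_cv")) {
      mat <- vapply(x$models, impurity_importance_one,
                    numeric(length(x$models[[1]]$features)))
      out <- tibble::tibble(feature = rownames(mat),
                            importance = rowMeans(mat),
                            sd = apply(mat, 1L, stats::sd))
    } else {
      v <- impurity_importance_one(x)
      out <- tibble::tibble(feature = names(v), importance = unname(v),
                            sd = NA_real_)
    }
  } else {
    if (inherits(x, "taxrisk_cv")) x <- x$models[[which.max(x$iterations$auc)]]
    if (is.null(data) || is.null(labels)) {
      stop("permutation importance requires held-out data and labels")
    }
    X <- align_features(x, data)
    y <- as_binary_labels(labels)
    base <- roc_auc(predict(x, X), y)$auc
    drops <- with_seed(seed, {
      vapply(seq_len(ncol(X)), function(j) {
        reps <- vapply(seq_len(n_repeats), function(r) {
          Xp <- X
          Xp[, j] <- Xp[sample(nrow(Xp)), j]
          base - roc_auc(predict(x, Xp), y)$auc
        }, numeric(1))
        c(mean(reps), stats::sd(reps))
      }, numeric(2))
    })
    out <- tibble::tibble(feature = colnames(X), importance = drops[1, ],
                          sd = drops[2, ])
  }
  out$method <- method
  out <- dplyr::arrange(out, dplyr::desc(.data$importance))
  class(out) <- c("taxrisk_importance", class(out))
  out
}

#' Score an external cohort with a trained risk model
#'
#' Aligns the cohort's features to the model (absent features become 0),
#' predicts a continuous risk score per sample, and compares groups with
#' pairwise Mann-Whitney U tests corrected across pairs by
#' Benjamini-Hochberg. Scores are clipped to `[0, 1]` only in
#' `display_score`, for comparison against the conventional 0.5 case/
#' control threshold.
#'
#' @param model A `taxrisk_model`.
#' @param profile Accumulated-profile tibble of the external cohort.
#' @param metadata Tibble `sample_id`, `group` covering all cohort samples.
#' @param threshold Decision threshold in (0, 1); default 0.5.
#' @return Object of class `taxrisk_scores`: list with `scores` (tibble:
#'   `sample_id`, `group`, `score`, `display_score`, `above_threshold`),
#'   `group_summary` (median and quartiles per group), `pairwise` (MWU p
#'   and BH-adjusted p per group pair), `coverage`, `threshold`.
#' @export
score_cohort <- function(model, profile, metadata, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  md <- check_metadata(metadata, profile$sample_id, min_groups = 1L)
  X <- align_features(model, profile)
  if (any(table(md$group) == 0L)) stop("empty group in metadata")
  scores <- predict(model, X)
  tb <- tibble::tibble(
    sample_id = profile$sample_id,
    group = md$group,
    score = scores,
    display_score = pmin(pmax(scores, 0), 1),
    above_threshold = pmin(pmax(scores, 0), 1) > threshold
  )
  gs <- dplyr::summarise(
    dplyr::group_by(tb, .data$group),
    n = dplyr::n(),
    q1 = stats::quantile(.data$score, 0.25),
    median = stats::median(.data$score),
    q3 = stats::quantile(.data$score, 0.75),
    frac_above = mean(.data$above_threshold),
    .groups = "drop"
  )
  lv <- levels(md$group)
  pairs <- if (length(lv) > 1L) utils::combn(lv, 2L, simplify = FALSE) else list()
  pw <- dplyr::bind_rows(lapply(pairs, function(pr) {
    a <- tb$score[tb$group == pr[1]]; b <- tb$score[tb$group == pr[2]]
    tibble::tibble(group1 = pr[1], group2 = pr[2],
                   p = mann_whitney_u(a, b)$p)
  }))
  if (nrow(pw)) pw$p_adj <- bh_adjust(pw$p)
  structure(list(scores = tb, group_summary = gs, pairwise = pw,
                 coverage = attr(X, "coverage"), threshold = threshold),
            class = "taxrisk_scores")
}

#' @export
print.taxrisk_scores <- function(x, ...) {
  cat("<taxrisk cohort scores> ", nrow(x$scores), " samples, coverage ",
      sprintf("%.2f", x$coverage), "\n", sep = "")
  print(x$group_summary)
  invisible(x)
}

#' Persist a risk model as a versioned directory
#'
#' Writes the boosted ensemble (xgboost JSON), the ordered feature list and
#' a JSON metadata file; [load_risk_model()] restores a model whose
#' predictions are bitwise identical.
#'
#' @param model A `taxrisk_model`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_risk_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  booster <- xgboost::xgb.load.raw(model$booster_raw)
  xgboost::xgb.save(booster, file.path(dir, "ensemble.json"))
  writeLines(model$features, file.path(dir, "features.txt"))
  jsonlite::write_json(
    list(format_version = 1L, params = model$params, seed = model$seed,
         label_levels = model$label_levels),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Load a risk model saved by [save_risk_model()]
#'
#' @param dir Model directory.
#' @return A `taxrisk_model`.
#' @export
load_risk_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  booster <- xgboost::xgb.load(file.path(dir, "ensemble.json"))
  structure(list(
    booster_raw = xgboost::xgb.save.raw(booster),
    features = readLines(file.path(dir, "features.txt")),
    params = meta$params,
    seed = meta$seed,
    label_levels = meta$label_levels
  ), class = "taxrisk_model")
}
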