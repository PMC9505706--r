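toy_features <- function(n = 40L, seed = 1L, informative = TRUE) {
  set.seed(seed)
  y <- rep(c(0, 1), each = n / 2)
  x1 <- if (informative) y * 4 + rnorm(n, 0, 0.3) else rnorm(n)
  x2 <- rnorm(n)
  m <- cbind(f1 = x1, f2 = x2)
  rownames(m) <- paste0("s", seq_len(n))
  list(x = m, y = y)
}

test_that("feature selection drops constants and keeps singletons", {
  prof <- tibble::tibble(
    sample_id = paste0("s", 1:4),
    allzero = rep(0, 4),
    constant = rep(2.5, 4),
    singleton = c(0.3, 0, 0, 0),
    varying = c(1, 2, 3, 4)
  )
  sel <- select_features(prof)
  expect_setequal(setdiff(names(sel), "sample_id"), c("singleton", "varying"))
  expect_equal(attr(sel, "n_selected"), 2L)
  expect_error(select_features(prof[, c("sample_id", "allzero")]), "no informative")
})

test_that("feature selection retains exactly the informative half of a fixture", {
  set.seed(5)
  inf <- matrix(runif(20 * 50), 20, dimnames = list(paste0("s", 1:20),
                                                    paste0("inf", 1:50)))
  zero <- matrix(0, 20, 50, dimnames = list(paste0("s", 1:20),
                                            paste0("zero", 1:50)))
  prof <- tibble::add_column(
    tibble::as_tibble(as.data.frame(cbind(inf, zero))),
    sample_id = paste0("s", 1:20), .before = 1L)
  expect_equal(attr(select_features(prof), "n_selected"), 50L)
})

test_that("the boosted model separates a separable toy problem and is deterministic", {
  toy <- toy_features()
  fit <- fit_risk_model(toy$x, toy$y, seed = 3)
  scores <- predict(fit, toy$x)
  expect_equal(roc_auc(scores, toy$y)$auc, 1)

  fit2 <- fit_risk_model(toy$x, toy$y, seed = 3)
  expect_identical(scores, predict(fit2, toy$x))

  # duplicated rows score identically
  dup <- toy$x[c(1, 1, 5, 5), ]
  sd <- predict(fit, dup)
  expect_identical(sd[1], sd[2])
  expect_identical(sd[3], sd[4])

  expect_error(fit_risk_model(toy$x, rep(1, nrow(toy$x))), "two classes|class")
})

test_that("model persistence round-trips predictions bitwise", {
  toy <- toy_features(seed = 9)
  fit <- fit_risk_model(toy$x, toy$y)
  dir <- withr::local_tempdir()
  save_risk_model(fit, dir)
  back <- load_risk_model(dir)
  expect_identical(predict(fit, toy$x), predict(back, toy$x))
  expect_identical(back$features, fit$features)
  expect_equal(back$params, fit$params)
})

test_that("ROC/AUC matches concordant-pair counting and pROC", {
  r <- roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(r$auc, 0.75)

  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_auc(rep(0.7, 6), c(0, 0, 0, 1, 1, 1))$auc, 0.5)

  set.seed(4)
  s <- rnorm(60)
  y <- rbinom(60, 1, 0.5)
  expect_equal(roc_auc(s, y)$auc,
               as.numeric(suppressMessages(pROC::auc(y, s))), tolerance = 1e-12)
  # invariance under strictly monotone transforms
  expect_equal(roc_auc(exp(s), y)$auc, roc_auc(s, y)$auc)
  expect_error(roc_auc(s, rep(0, 60)), "class")
})

test_that("the operating point maximises Youden's J with documented tie-break", {
  perfect <- roc_auc(c(1, 2, 10, 11), c(0, 0, 1, 1))
  op <- operating_point(perfect)
  expect_equal(op$sensitivity, 1)
  expect_equal(op$specificity, 1)

  tied <- operating_point(roc_auc(rep(0.5, 4), c(0, 0, 1, 1)))
  expect_equal(tied$youden, 0)
  expect_equal(c(tied$sensitivity, tied$specificity), c(0, 1))

  toy <- operating_point(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)))
  expect_equal(toy$sensitivity, 0.5)
  expect_equal(toy$specificity, 1)
  expect_gt(toy$threshold, 0.4)
  expect_lte(toy$threshold, 0.8)
})

test_that("cross-validation records are self-consistent", {
  toy <- toy_features(n = 60, seed = 2)
  cv <- cross_validate_risk(toy$x, toy$y, n_iter = 4, base_seed = 10,
                            params = gbm_params(n_trees = 50))
  expect_equal(nrow(cv$iterations), 4L)
  expect_equal(cv$summary$mean_auc, mean(cv$iterations$auc))
  expect_equal(cv$summary$sd_auc, sd(cv$iterations$auc))
  expect_equal(cv$summary$min_auc, min(cv$iterations$auc))
  expect_equal(cv$summary$max_auc, max(cv$iterations$auc))

  one <- cross_validate_risk(toy$x, toy$y, n_iter = 1, base_seed = 3,
                             params = gbm_params(n_trees = 50))
  expect_equal(one$summary$mean_auc, one$iterations$auc)
  expect_equal(one$summary$sd_auc, 0)

  # broom-style accessors
  expect_identical(tidy(cv), cv$iterations)
  expect_identical(glance(cv), cv$summary)
})

test_that("stratified splits preserve the class ratio within one sample", {
  y <- c(rep(0, 30), rep(1, 10))
  cv <- cross_validate_risk(toy_features(40, seed = 6)$x, y, n_iter = 5,
                            base_seed = 1, params = gbm_params(n_trees = 20))
  for (sp in cv$splits) {
    expect_equal(sum(y[sp$train] == 0), 21)
    expect_equal(sum(y[sp$train] == 1), 7)
  }
})

test_that("labels independent of features give chance-level test AUC", {
  toy <- toy_features(n = 200, seed = 11, informative = FALSE)
  cv <- cross_validate_risk(toy$x, toy$y, n_iter = 20, base_seed = 7,
                            params = gbm_params(n_trees = 100))
  expect_gt(cv$summary$mean_auc, 0.4)
  expect_lt(cv$summary$mean_auc, 0.6)
})

test_that("impurity importance is a normalised share and finds the signal", {
  toy <- toy_features(seed = 13)
  fit <- fit_risk_model(toy$x, toy$y)
  imp <- feature_importance(fit, "impurity")
  expect_equal(sum(imp$importance), 1, tolerance = 1e-9)
  expect_equal(imp$feature[1], "f1")

  # single informative feature gets everything
  single <- fit_risk_model(toy$x[, "f1", drop = FALSE], toy$y)
  imp1 <- feature_importance(single, "impurity")
  expect_equal(imp1$importance[imp1$feature == "f1"], 1)
})

test_that("permutation importance is ~0 for an unused feature", {
  toy <- toy_features(n = 80, seed = 17)
  fit <- fit_risk_model(toy$x, toy$y)
  hold <- toy_features(n = 80, seed = 18)
  imp <- feature_importance(fit, "permutation", data = hold$x,
                            labels = hold$y, n_repeats = 10, seed = 2)
  expect_lt(abs(imp$importance[imp$feature == "f2"]), 0.02)
  expect_gt(imp$importance[imp$feature == "f1"], 0.2)
  expect_error(feature_importance(fit, "permutation"), "held-out")
})

test_that("feature alignment fills missing columns and drops extras", {
  toy <- toy_features()
  fit <- fit_risk_model(toy$x, toy$y)

  same <- align_features(fit, toy$x)
  expect_equal(attr(same, "coverage"), 1)
  expect_equal(unname(same), unname(toy$x), ignore_attr = TRUE)

  half <- toy$x[, "f1", drop = FALSE]
  expect_message(a <- align_features(fit, half), "coverage 0.50")
  expect_equal(attr(a, "coverage"), 0.5)
  expect_equal(unname(a[, "f2"]), rep(0, nrow(a)))

  extra <- cbind(toy$x, junk = rnorm(nrow(toy$x)))
  ae <- align_features(fit, extra)
  expect_equal(colnames(ae), fit$features)

  none <- matrix(rnorm(10), 5, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(align_features(fit, none), "no overlap")
})

test_that("scoring the training controls puts the majority below 0.5", {
  sim <- small_sim(seed = 8, n = 40)
  prof <- preprocess_otu(sim$otu)
  fit <- fit_risk_model(select_features(prof), sim$metadata$group)
  sc <- score_cohort(fit, prof, sim$metadata)
  ctrl <- sc$scores[sc$scores$group == "HC", ]
  expect_gt(mean(ctrl$display_score < 0.5), 0.5)
  expect_equal(nrow(sc$scores), nrow(prof))
  expect_true(all(c("p", "p_adj") %in% names(sc$pairwise)))
  expect_error(score_cohort(fit, prof, sim$metadata, threshold = 1.2),
               "threshold")
})
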