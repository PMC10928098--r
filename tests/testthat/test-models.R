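test_that("splits are sized, disjoint, stratified and deterministic", {
  dummy <- data.frame(concentration = rep(c(0, 10, 12, 14, 16, 18, 20),
                                          each = 495),
                      x = seq_len(3465))
  sp <- split_dataset(dummy, seed = 4)
  expect_equal(nrow(sp$train), 2772)
  expect_equal(nrow(sp$test), 693)
  expect_length(intersect(sp$train$x, sp$test$x), 0)
  # stratification: every level contributes 80% to training
  expect_true(all(table(sp$train$concentration) == 396))
  sp2 <- split_dataset(dummy, seed = 4)
  expect_identical(sp$train$x, sp2$train$x)
  tiny <- split_dataset(data.frame(concentration = rep(0, 10),
                                   x = 1:10), seed = 1,
                        stratify_by = NULL)
  expect_equal(c(nrow(tiny$train), nrow(tiny$test)), c(8, 2))
  expect_error(split_dataset(dummy[1:5, ]), "10 rows")
})

test_that("binary label uses a strict 15 mg/dl threshold", {
  expect_equal(as.character(label_binary(c(16, 14, 0, 20, 15))),
               c("jaundice", "normal", "normal", "jaundice", "normal"))
  expect_equal(levels(label_binary(0)), c("normal", "jaundice"))
})

test_that("confusion metrics follow their ratio definitions", {
  perfect <- confusion_metrics(50, 50, 0, 0)
  expect_equal(unlist(perfect[c("accuracy", "precision", "sensitivity",
                                "specificity")]),
               c(accuracy = 1, precision = 1, sensitivity = 1,
                 specificity = 1))
  m <- confusion_metrics(40, 45, 10, 5)
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$precision, 0.8)
  expect_equal(m$sensitivity, 40 / 45)
  expect_equal(m$specificity, 45 / 55)
  deg <- confusion_metrics(0, 10, 0, 0)
  expect_true(is.nan(deg$precision) && is.nan(deg$sensitivity))
  expect_equal(deg$specificity, 1)
  expect_setequal(deg$undefined, c("precision", "sensitivity"))
  expect_error(confusion_metrics(0, 0, 0, 0), "zero")
})

test_that("ROC/AUC matches the reference implementation", {
  set.seed(12)
  lab <- label_binary(sample(c(0, 20), 200, replace = TRUE))
  score <- rnorm(200) + 2 * (lab == "jaundice")
  got <- roc_curve(score, lab)
  ref <- pROC::roc(response = lab, predictor = score,
                   levels = c("normal", "jaundice"), direction = "<",
                   quiet = TRUE)
  expect_equal(got$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-9)
  # random scores: AUC near 1/2 (50 shuffles)
  aucs <- replicate(50, roc_curve(sample(score), lab)$auc)
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
  # curve endpoints
  expect_equal(got$points$fpr[1], 0)
  expect_equal(got$points$tpr[nrow(got$points)], 1)
  expect_error(roc_curve(score, label_binary(rep(0, 200))), "both classes")
})

test_that("noiseless features are perfectly separable by every model", {
  design <- phantom_design(n_replicates = 3, seed = 9)
  design <- design[design$study == "baseline", ]
  calib <- phantom_calibration(sigma_px = 0)
  # silence the scene noise by pushing r2 targets to ~1
  calib$table$r2 <- 1 - 1e-12
  calib$baseline$r2 <- 1 - 1e-12
  feats <- simulate_feature_table(design, calib, wb_correct = "none")
  sp <- split_dataset(feats, seed = 2)
  for (m in c("dt", "knn", "svm")) {
    r <- train_eval(sp$train, sp$test, m, "classification",
                    tuning_grid = bilphantom::default_grid(m,
                      "classification", 17)[1:2, , drop = FALSE],
                    cv_repeats = 0, seed = 5)
    expect_equal(r$accuracy, 1)
    expect_equal(r$auc, 1)
  }
})

test_that("internal KNN agrees with the reference classifier", {
  set.seed(77)
  tr_x <- matrix(rnorm(600), 200, 3)
  tr_y <- label_binary(ifelse(tr_x[, 1] + 0.3 * rnorm(200) > 0, 20, 0))
  te_x <- matrix(rnorm(150), 50, 3)
  for (k in c(3, 7)) {
    sc <- bilphantom:::knn_predict(tr_x, tr_y, te_x, k, "classification")
    mine <- ifelse(sc > 0.5, "jaundice", "normal")
    ref <- as.character(class::knn(tr_x, te_x, tr_y, k = k))
    expect_equal(mine, ref)
  }
})

test_that("train_eval reports the contracted pieces per task", {
  tab <- fixture_table()
  sp <- split_dataset(tab, seed = 6)
  r <- train_eval(sp$train, sp$test, "dt", "classification",
                  cv_repeats = 10, cv_folds = 10, seed = 8)
  expect_s3_class(r, "bil_model_report")
  expect_length(r$cv_scores, 100)
  expect_true(all(r$cv_scores >= 0 & r$cv_scores <= 1))
  expect_true(all(c("accuracy", "precision", "sensitivity",
                    "specificity", "auc") %in% names(r)))
  # accuracy identity against stored confusion counts
  expect_equal(r$accuracy,
               (r$counts[["tp"]] + r$counts[["tn"]]) / sum(r$counts))
  expect_true(r$auc >= 0 && r$auc <= 1)
  rr <- train_eval(sp$train, sp$test, "gbt", "regression",
                   cv_repeats = 2, cv_folds = 5, seed = 8)
  expect_gte(rr$mse, 0)
  expect_length(rr$cv_scores, 10)
  expect_error(train_eval(sp$train, sp$test, "mlp", "regression"),
               "arg")
})

test_that("permutation importance is zero for an ignored feature and stable", {
  tab <- fixture_table()
  tab$noise_col <- 0  # constant column the model cannot use
  sp <- split_dataset(tab, seed = 3)
  r <- train_eval(sp$train, sp$test, "rf", "regression",
                  features = c(bilphantom:::FEATURE_COLS, "noise_col"),
                  tuning_grid = data.frame(ntree = 100, nodesize = 5),
                  cv_repeats = 0, seed = 4)
  imp1 <- permutation_importance(r, sp$test, n_repeats = 5, seed = 21)
  imp2 <- permutation_importance(r, sp$test, n_repeats = 5, seed = 99)
  expect_equal(imp1$importance[imp1$feature == "noise_col"], 0)
  # two seeds agree on the top feature
  expect_equal(imp1$feature[1], imp2$feature[1])
  expect_error(permutation_importance(r, sp$test, n_repeats = 0),
               "n_repeats")
})

test_that("model comparison ranks by CV metric and guards the split", {
  tab <- fixture_table()
  sp <- split_dataset(tab, seed = 13)
  reps <- lapply(c("dt", "rf", "gbt"), function(m)
    train_eval(sp$train, sp$test, m, "regression",
               tuning_grid = bilphantom::default_grid(m, "regression",
                                                      17)[1, , drop = FALSE],
               cv_repeats = 2, cv_folds = 5, seed = 19))
  cmp <- compare_models(reps)
  expect_equal(nrow(cmp$ranking), 3)
  expect_true(all(diff(cmp$ranking$cv_mean) <= 0))
  expect_equal(nrow(cmp$tests$pairwise), 3)
  # ensembles outrank the single tree
  expect_true(which(cmp$ranking$model == "dt") >
                min(which(cmp$ranking$model %in% c("rf", "gbt"))))
  sp2 <- split_dataset(tab, seed = 14)
  other <- train_eval(sp2$train, sp2$test, "dt", "regression",
                      tuning_grid = data.frame(maxdepth = 5),
                      cv_repeats = 2, cv_folds = 5, seed = 19)
  expect_error(compare_models(list(reps[[1]], other)), "mismatched")
})

test_that("adding colour features never hurts the reduced RGB set", {
  tab <- fixture_table()
  sp <- split_dataset(tab, seed = 23)
  grid <- data.frame(ntree = 100, nodesize = 5)
  full <- train_eval(sp$train, sp$test, "rf", "regression",
                     tuning_grid = grid, cv_repeats = 2, cv_folds = 5,
                     seed = 29)
  red <- train_eval(sp$train, sp$test, "rf", "regression",
                    features = c("roi_r", "roi_g", "roi_b", "d_r", "d_g",
                                 "d_b"),
                    tuning_grid = grid, cv_repeats = 2, cv_folds = 5,
                    seed = 29)
  expect_gte(mean(full$cv_scores), mean(red$cv_scores))
  # paired Wilcoxon over the CV folds detects the improvement direction
  wt <- wilcoxon_paired(red$cv_scores, full$cv_scores)
  expect_false(isTRUE(wt$degenerate))
})
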