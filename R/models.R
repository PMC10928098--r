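#' Split a feature table into train and test partitions
#'
#' Deterministic, stratified 80/20 split: within every stratum (by
#' default the concentration level) a fixed fraction of rows is sampled
#' into the training set, so no image appears in both partitions.
#'
#' @param table Feature table (one row per image).
#' @param train_fraction Training fraction (default 0.8).
#' @param seed Shuffle seed.
#' @param stratify_by Column used for stratification, or `NULL` for a
#'   simple random split.
#' @return List with `train` and `test` data.frames; both carry a
#'   `split_id` attribute identifying the partition.
#' @export
split_dataset <- function(table, train_fraction = 0.8, seed = 1L,
                          stratify_by = "concentration") {
  n <- nrow(table)
  if (n < 10) stop("need at least 10 rows to split")
  n_train <- floor(train_fraction * n)
  set.seed(seed)
  if (is.null(stratify_by)) {
    idx <- sample.int(n, n_train)
  } else {
    strata <- split(seq_len(n), table[[stratify_by]])
    idx <- unlist(lapply(strata, function(s)
      sample(s, floor(train_fraction * length(s)))))
    # top up to exactly floor(train_fraction * n) if flooring undershot
    if (length(idx) < n_train) {
      rest <- setdiff(seq_len(n), idx)
      idx <- c(idx, sample(rest, n_train - length(idx)))
    }
  }
  id <- list(seed = seed, n = n, n_train = length(idx),
             checksum = sum(idx))
  train <- table[sort(idx), , drop = FALSE]
  test <- table[setdiff(seq_len(n), idx), , drop = FALSE]
  attr(train, "split_id") <- id
  attr(test, "split_id") <- id
  list(train = train, test = test)
}

#' Binary jaundice label from concentration
#'
#' "jaundice" when the concentration exceeds the clinical screening
#' threshold, "normal" otherwise.
#'
#' @param concentration mg/dl.
#' @param threshold mg/dl (default 15).
#' @return Factor with levels `normal`, `jaundice`.
#' @export
label_binary <- function(concentration, threshold = 15) {
  factor(ifelse(concentration > threshold, "jaundice", "normal"),
         levels = c("normal", "jaundice"))
}

#' Confusion-matrix metrics
#'
#' Accuracy, precision, sensitivity and specificity from the four
#' confusion counts. Ratios with zero denominator are returned as `NaN`
#' and flagged.
#'
#' @param tp,tn,fp,fn Non-negative counts.
#' @return List with the four metrics, the counts, and `undefined` (names
#'   of metrics with zero denominator).
#' @export
confusion_metrics <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (sum(counts) == 0) stop("all counts are zero")
  div <- function(num, den) if (den == 0) NaN else num / den
  out <- list(accuracy = (tp + tn) / sum(counts),
              precision = div(tp, tp + fp),
              sensitivity = div(tp, tp + fn),
              specificity = div(tn, tn + fp),
              counts = counts)
  out$undefined <- names(Filter(is.nan,
                                out[c("accuracy", "precision",
                                      "sensitivity", "specificity")]))
  out
}

#' ROC curve and trapezoidal AUC from decision scores
#'
#' Sweeps the decision threshold over the observed scores (higher score
#' means more jaundice-like) and accumulates true/false positive rates;
#' AUC by the trapezoidal rule.
#'
#' @param scores Numeric decision scores.
#' @param labels Factor from [label_binary()] (or logical, `TRUE` =
#'   jaundice).
#' @return List with `points` (data.frame fpr, tpr, threshold) and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  pos <- if (is.logical(labels)) labels else labels == "jaundice"
  if (!any(pos) || all(pos)) stop("need both classes for a ROC curve")
  ord <- order(scores, decreasing = TRUE)
  pos <- pos[ord]
  tpr <- cumsum(pos) / sum(pos)
  fpr <- cumsum(!pos) / sum(!pos)
  # collapse ties on the score value
  keep <- c(diff(scores[ord]) != 0, TRUE)
  pts <- data.frame(fpr = c(0, fpr[keep]), tpr = c(0, tpr[keep]),
                    threshold = c(Inf, scores[ord][keep]))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                                utils::tail(pts$tpr, -1)) / 2)
  list(points = pts, auc = auc)
}

# model backends -----------------------------------------------------------

MODEL_NAMES <- c("dt", "knn", "rf", "svm", "gbt")

knn_predict <- function(train_x, train_y, new_x, k, task) {
  d2 <- outer(rowSums(new_x^2), rowSums(train_x^2), "+") -
    2 * new_x %*% t(train_x)
  out_score <- numeric(nrow(new_x))
  for (i in seq_len(nrow(new_x))) {
    nb <- order(d2[i, ])[seq_len(k)]
    out_score[i] <- if (task == "classification")
      mean(train_y[nb] == "jaundice") else mean(train_y[nb])
  }
  out_score
}

#' Default hyperparameter grid for a model
#'
#' Grids used by [train_eval()] when none is supplied: tree depth for DT,
#' neighbourhood size for KNN, forest size and leaf size for RF, RBF cost
#' and bandwidth for SVM, rounds and depth for the gradient-boosted
#' trees.
#'
#' @param model Model name.
#' @param task Task name (grids are shared across tasks).
#' @param p Number of features (sets the default RBF gamma `1/p`).
#' @return Data.frame of hyperparameter combinations.
#' @export
default_grid <- function(model, task, p) {
  switch(model,
         dt = expand.grid(maxdepth = c(3, 5, 10, 30)),
         knn = expand.grid(k = c(3, 5, 7, 11)),
         rf = expand.grid(ntree = c(100, 300), nodesize = c(1, 5)),
         svm = expand.grid(cost = c(0.1, 1, 10, 100),
                           gamma = c(1 / p, 0.01, 0.1)),
         gbt = expand.grid(nrounds = c(100, 300), max_depth = c(4, 6)),
         stop("unknown model: ", model))
}

# fit one model; returns list(predict = function(x) list(pred, score))
fit_backend <- function(x, y, model, task, params, seed) {
  set.seed(seed)
  if (model == "dt") {
    df <- data.frame(x, .y = y)
    fit <- rpart::rpart(.y ~ ., data = df,
                        method = if (task == "classification") "class"
                        else "anova",
                        control = rpart::rpart.control(
                          maxdepth = params$maxdepth, cp = 1e-4,
                          xval = 0))
    return(function(newx) {
      nd <- data.frame(newx)
      if (task == "classification") {
        pr <- predict(fit, nd, type = "prob")[, "jaundice"]
        list(pred = factor(ifelse(pr > 0.5, "jaundice", "normal"),
                           levels = levels(y)), score = pr)
      } else {
        p <- predict(fit, nd)
        list(pred = p, score = p)
      }
    })
  }
  if (model == "knn") {
    return(function(newx) {
      sc <- knn_predict(x, y, newx, params$k, task)
      if (task == "classification")
        list(pred = factor(ifelse(sc > 0.5, "jaundice", "normal"),
                           levels = levels(y)), score = sc)
      else list(pred = sc, score = sc)
    })
  }
  if (model == "rf") {
    fit <- randomForest::randomForest(x, y, ntree = params$ntree,
                                      nodesize = params$nodesize)
    return(function(newx) {
      if (task == "classification") {
        pr <- predict(fit, newx, type = "prob")[, "jaundice"]
        list(pred = factor(ifelse(pr > 0.5, "jaundice", "normal"),
                           levels = levels(y)), score = pr)
      } else {
        p <- predict(fit, newx)
        list(pred = unname(p), score = unname(p))
      }
    })
  }
  if (model == "svm") {
    fit <- e1071::svm(x, y, kernel = "radial", cost = params$cost,
                      gamma = params$gamma, scale = FALSE)
    return(function(newx) {
      if (task == "classification") {
        pr <- predict(fit, newx, decision.values = TRUE)
        dv <- attr(pr, "decision.values")
        sc <- as.numeric(dv)
        # orient decision values so larger = more jaundice-like
        if (grepl("^jaundice", colnames(dv)[1])) sc <- -sc
        list(pred = factor(as.character(pr), levels = levels(y)),
             score = -sc)
      } else {
        p <- predict(fit, newx)
        list(pred = unname(p), score = unname(p))
      }
    })
  }
  if (model == "gbt") {
    lab <- if (task == "classification") as.numeric(y == "jaundice") else y
    fit <- xgboost::xgb.train(
      params = list(
        objective = if (task == "classification") "binary:logistic"
        else "reg:squarederror",
        max_depth = params$max_depth, eta = 0.1, nthread = 1,
        seed = seed),
      data = xgboost::xgb.DMatrix(x, label = lab, nthread = 1),
      nrounds = params$nrounds, verbose = 0)
    return(function(newx) {
      sc <- predict(fit, xgboost::xgb.DMatrix(newx, nthread = 1))
      if (task == "classification")
        list(pred = factor(ifelse(sc > 0.5, "jaundice", "normal"),
                           levels = levels(y)), score = sc)
      else list(pred = sc, score = sc)
    })
  }
  stop("unknown model: ", model)
}

make_folds <- function(strata, k, seed) {
  set.seed(seed)
  fold <- integer(length(strata))
  for (s in split(seq_along(strata), strata)) {
    fold[s] <- sample(rep_len(seq_len(k), length(s)))
  }
  fold
}

eval_metric <- function(pred, score, y, task) {
  if (task == "classification") mean(pred == y)
  else -mean((score - y)^2)  # larger-is-better internal orientation
}

#' Train, tune and evaluate one model
#'
#' Grid-searches hyperparameters by k-fold cross-validation on the
#' training partition, refits the best configuration, evaluates on the
#' held-out test partition (confusion metrics and ROC/AUC for
#' classification; MSE and R-squared for regression), and records the
#' repeated cross-validation metric vector used for model comparison
#' (10-fold repeated 10 times = 100 values by default). Features are
#' standardized (train statistics only) for the distance/margin models
#' (KNN, SVM); trees consume raw features.
#'
#' @param train,test Partitions from [split_dataset()].
#' @param model One of "dt", "knn", "rf", "svm", "gbt" (gradient-boosted
#'   trees).
#' @param task "classification" (15 mg/dl jaundice threshold) or
#'   "regression" (concentration, mg/dl).
#' @param features Feature column names (default: all 17).
#' @param tuning_grid Data.frame of hyperparameter combinations; default
#'   [default_grid()].
#' @param threshold Classification threshold, mg/dl.
#' @param cv_repeats,cv_folds Repeated-CV layout for the comparison
#'   vector (`cv_repeats = 0` skips it).
#' @param tune_folds Folds used inside the grid search.
#' @param seed Seed for folds and stochastic learners.
#' @return Object of class `bil_model_report`.
#' @export
train_eval <- function(train, test, model = "svm",
                       task = c("classification", "regression"),
                       features = FEATURE_COLS, tuning_grid = NULL,
                       threshold = 15, cv_repeats = 10, cv_folds = 10,
                       tune_folds = 3, seed = 1L) {
  task <- match.arg(task)
  model <- match.arg(model, MODEL_NAMES)
  stopifnot(all(features %in% names(train)), "concentration" %in% names(train))
  split_id <- attr(train, "split_id")
  x_tr <- as.matrix(train[, features, drop = FALSE])
  x_te <- as.matrix(test[, features, drop = FALSE])
  scaled <- model %in% c("knn", "svm")
  ctr <- rep(0, ncol(x_tr)); scl <- rep(1, ncol(x_tr))
  if (scaled) {
    ctr <- colMeans(x_tr)
    scl <- apply(x_tr, 2, stats::sd)
    scl[scl == 0] <- 1
    x_tr <- scale(x_tr, ctr, scl); x_te <- scale(x_te, ctr, scl)
  }
  y_tr <- if (task == "classification")
    label_binary(train$concentration, threshold) else train$concentration
  y_te <- if (task == "classification")
    label_binary(test$concentration, threshold) else test$concentration

  if (is.null(tuning_grid))
    tuning_grid <- default_grid(model, task, ncol(x_tr))
  fold <- make_folds(train$concentration, tune_folds, seed)
  cv_of <- function(params, folds_vec, nfold) {
    m <- numeric(nfold)
    for (f in seq_len(nfold)) {
      tr <- folds_vec != f
      pr <- fit_backend(x_tr[tr, , drop = FALSE], y_tr[tr], model, task,
                        params, seed + f)(x_tr[!tr, , drop = FALSE])
      m[f] <- eval_metric(pr$pred, pr$score, y_tr[!tr], task)
    }
    mean(m)
  }
  grid_scores <- vapply(seq_len(nrow(tuning_grid)), function(j)
    cv_of(as.list(tuning_grid[j, , drop = FALSE]), fold, tune_folds),
    numeric(1))
  best <- as.list(tuning_grid[which.max(grid_scores), , drop = FALSE])

  predictor <- fit_backend(x_tr, y_tr, model, task, best, seed)
  pr <- predictor(x_te)

  report <- list(model = model, task = task, best_hyperparams = best,
                 grid = cbind(tuning_grid, cv_score = grid_scores),
                 n_train = nrow(train), n_test = nrow(test),
                 split_id = split_id, features = features, seed = seed)
  if (task == "classification") {
    tp <- sum(pr$pred == "jaundice" & y_te == "jaundice")
    tn <- sum(pr$pred == "normal" & y_te == "normal")
    fp <- sum(pr$pred == "jaundice" & y_te == "normal")
    fn <- sum(pr$pred == "normal" & y_te == "jaundice")
    cm <- confusion_metrics(tp, tn, fp, fn)
    roc <- roc_curve(pr$score, y_te)
    report <- c(report, list(accuracy = cm$accuracy,
                             precision = cm$precision,
                             sensitivity = cm$sensitivity,
                             specificity = cm$specificity,
                             counts = cm$counts,
                             roc_points = roc$points, auc = roc$auc))
  } else {
    mse <- mean((pr$score - y_te)^2)
    r2 <- 1 - mse / mean((y_te - mean(y_te))^2)
    report <- c(report, list(mse = mse, r2 = r2))
  }

  if (cv_repeats > 0) {
    cv_scores <- numeric(0)
    for (rep_i in seq_len(cv_repeats)) {
      fold_r <- make_folds(train$concentration, cv_folds,
                           seed + 1000L + rep_i)
      for (f in seq_len(cv_folds)) {
        tr <- fold_r != f
        prf <- fit_backend(x_tr[tr, , drop = FALSE], y_tr[tr], model,
                           task, best, seed + 31L * rep_i + f)(
                             x_tr[!tr, , drop = FALSE])
        cv_scores <- c(cv_scores,
                       if (task == "classification")
                         mean(prf$pred == y_tr[!tr])
                       else 1 - mean((prf$score - y_tr[!tr])^2) /
                         mean((y_tr[!tr] - mean(y_tr[!tr]))^2))
      }
    }
    report$cv_scores <- cv_scores
  }

  report$predict <- function(newdata) {
    nx <- as.matrix(newdata[, features, drop = FALSE])
    if (scaled) nx <- scale(nx, ctr, scl)
    predictor(nx)
  }
  class(report) <- "bil_model_report"
  report
}

#' @export
print.bil_model_report <- function(x, ...) {
  cat(sprintf("Model report: %s (%s), n_train %d / n_test %d\n",
              toupper(x$model), x$task, x$n_train, x$n_test))
  if (x$task == "classification")
    cat(sprintf("  accuracy %.3f | precision %.3f | sensitivity %.3f | specificity %.3f | AUC %.3f\n",
                x$accuracy, x$precision, x$sensitivity, x$specificity,
                x$auc))
  else
    cat(sprintf("  MSE %.3f (mg/dl)^2 | R^2 %.3f\n", x$mse, x$r2))
  if (!is.null(x$cv_scores))
    cat(sprintf("  repeated CV: %d values, mean %.3f\n",
                length(x$cv_scores), mean(x$cv_scores)))
  cat("  best hyperparameters:",
      paste(names(x$best_hyperparams), unlist(x$best_hyperparams),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Permutation feature importance on held-out data
#'
#' Shuffles one feature at a time (`n_repeats` independent permutations)
#' and records the mean degradation of the model's metric: increase in
#' MSE for regression, drop in accuracy for classification.
#'
#' @param report A `bil_model_report`.
#' @param data Held-out feature table with the label column.
#' @param metric "mse" or "accuracy" (defaults to the report's task).
#' @param n_repeats Permutations per feature.
#' @param seed RNG seed.
#' @return Data.frame (feature, importance) sorted by decreasing
#'   importance.
#' @export
permutation_importance <- function(report, data, metric = NULL,
                                   n_repeats = 10, seed = 1L) {
  if (n_repeats < 1) stop("n_repeats must be at least 1")
  if (is.null(metric))
    metric <- if (report$task == "classification") "accuracy" else "mse"
  y <- if (report$task == "classification")
    label_binary(data$concentration) else data$concentration
  measure <- function(d) {
    pr <- report$predict(d)
    if (metric == "accuracy") mean(pr$pred == y)
    else mean((pr$score - y)^2)
  }
  base <- measure(data)
  set.seed(seed)
  imp <- vapply(report$features, function(f) {
    deg <- numeric(n_repeats)
    for (r in seq_len(n_repeats)) {
      d <- data
      d[[f]] <- sample(d[[f]])
      m <- measure(d)
      deg[r] <- if (metric == "accuracy") base - m else m - base
    }
    mean(deg)
  }, numeric(1))
  out <- data.frame(feature = report$features, importance = unname(imp))
  out[order(-out$importance), ]
}

#' Rank model reports and test for performance differences
#'
#' Orders reports by mean repeated-CV metric and attaches a
#' Kruskal-Wallis test with Dunn post-hoc comparisons over the CV metric
#' vectors. All reports must come from the same train/test split.
#'
#' @param reports List of `bil_model_report`s with CV vectors.
#' @return List with `ranking` (data.frame) and `tests`
#'   ([kruskal_dunn()] output).
#' @export
compare_models <- function(reports) {
  if (length(reports) < 2) stop("need at least 2 reports")
  ids <- lapply(reports, function(r) r$split_id)
  if (length(unique(vapply(ids, function(i)
    paste(i$seed, i$n, i$n_train, i$checksum), character(1)))) != 1)
    stop("reports built on mismatched splits")
  cvs <- lapply(reports, function(r) {
    if (is.null(r$cv_scores)) stop("report without CV vector")
    r$cv_scores
  })
  names(cvs) <- vapply(reports, function(r) r$model, character(1))
  rank_df <- data.frame(
    model = names(cvs),
    cv_mean = vapply(cvs, mean, numeric(1)),
    cv_sd = vapply(cvs, stats::sd, numeric(1)),
    test_metric = vapply(reports, function(r)
      if (r$task == "classification") r$accuracy else r$r2, numeric(1)))
  rank_df <- rank_df[order(-rank_df$cv_mean), ]
  rownames(rank_df) <- NULL
  list(ranking = rank_df, tests = kruskal_dunn(cvs))
}
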