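# Supervised classification of leukemia families and FAB subtypes.
# Six tasks (ALLvsAML, L1vsL2, the three one-vs-rest AML binaries and the
# three-class AML problem) are evaluated under stratified 10-fold
# cross-validation with overall accuracy, TPR, TNR and AUC. The learner
# roster spans the instance-based, tree, regression and committee learner
# families used for this problem in practice: kNN, random forest, penalized logistic,
# linear SVM and a seed-varied random committee of forests.

#' Task specifications for leukemia classification
#'
#' @param name One of `ALLvsAML`, `L1vsL2`, `M2vs(M3&M5)`, `M3vs(M2&M5)`,
#'   `M5vs(M2&M3)`, `M2vsM3vsM5`.
#' @return List of class `task_spec` with the label mapping, type and
#'   positive class.
#' @export
leukemia_task <- function(name) {
  tasks <- list(
    "ALLvsAML" = list(map = c(L1 = "ALL", L2 = "ALL", M2 = "AML", M3 = "AML",
                              M5 = "AML"), positive = "ALL", type = "binary"),
    "L1vsL2" = list(map = c(L1 = "L1", L2 = "L2"), positive = "L1",
                    type = "binary"),
    "M2vs(M3&M5)" = list(map = c(M2 = "M2", M3 = "rest", M5 = "rest"),
                         positive = "M2", type = "binary"),
    "M3vs(M2&M5)" = list(map = c(M3 = "M3", M2 = "rest", M5 = "rest"),
                         positive = "M3", type = "binary"),
    "M5vs(M2&M3)" = list(map = c(M5 = "M5", M2 = "rest", M3 = "rest"),
                         positive = "M5", type = "binary"),
    "M2vsM3vsM5" = list(map = c(M2 = "M2", M3 = "M3", M5 = "M5"),
                        positive = NA_character_, type = "multiclass"),
    "subtype" = list(map = c(L1 = "L1", L2 = "L2", M2 = "M2", M3 = "M3",
                             M5 = "M5"), positive = NA_character_,
                     type = "multiclass")
  )
  if (!name %in% names(tasks)) abort(sprintf("unknown task '%s'", name))
  structure(c(list(name = name), tasks[[name]]), class = "task_spec")
}

#' Build a task-specific labelled dataset
#'
#' Applies the task's label mapping (samples whose label the task does not
#' cover, e.g. "No subtype" rows in subtype tasks, are dropped) and the
#' feature-subset filter: `"nc"` keeps the full nucleus + cytoplasm + cell
#' panel, `"cell"` keeps only the cell-region columns of the expanded
#' schema.
#'
#' @param features Tibble with a `class` column plus feature columns.
#' @param task A `task_spec` or task name.
#' @param subset `"nc"` or `"cell"`.
#' @return Tibble with remapped `class` factor and the selected features.
#' @export
build_task_dataset <- function(features, task, subset = c("nc", "cell")) {
  subset <- match.arg(subset)
  if (is.character(task)) task <- leukemia_task(task)
  cls <- as.character(features$class)
  keep <- cls %in% names(task$map)
  mapped <- task$map[cls[keep]]
  present <- unique(task$map)
  missing <- setdiff(present, mapped)
  if (length(missing))
    abort(sprintf("task class(es) absent from the table: %s",
                  paste(missing, collapse = ", ")))
  out <- features[keep, , drop = FALSE]
  out$class <- factor(mapped, levels = present)
  if (subset == "cell") {
    sch <- mdx_feature_schema("expanded")
    cell_cols <- sch$column[sch$region == "cell"]
    found <- intersect(names(out), cell_cols)
    if (!length(found))
      abort("cell-only subset requires expanded-schema feature columns")
    out <- out[, c("class", found)]
  }
  out
}

# --- learners -------------------------------------------------------------
# Each learner returns scores: an n x nlevels matrix of class support used
# both for prediction (argmax) and for AUC.

fit_learner <- function(xtr, ytr, learner, seed, knn_k = 1, ntree = 100) {
  lv <- levels(ytr)
  predictor <- switch(
    learner,
    knn = {
      # support for class c = inverse distance to the nearest class-c
      # training point (inverse-distance-weighted vote, continuous for AUC)
      force(xtr); force(ytr); force(knn_k)
      function(xte) {
        d2 <- outer(rowSums(xte^2), rowSums(xtr^2), "+") - 2 * xte %*% t(xtr)
        d <- sqrt(pmax(d2, 0))
        s <- sapply(lv, function(cl) {
          dc <- d[, ytr == cl, drop = FALSE]
          kk <- min(knn_k, ncol(dc))
          apply(dc, 1, function(row) sum(1 / (sort(row)[seq_len(kk)] + 1e-8)))
        })
        matrix(s, nrow = nrow(xte), dimnames = list(NULL, lv))
      }
    },
    rf = {
      fit <- with_local_seed(seed, randomForest::randomForest(
        x = xtr, y = ytr, ntree = ntree))
      function(xte) predict(fit, xte, type = "prob")[, lv, drop = FALSE]
    },
    logistic = {
      fit <- with_local_seed(seed, nnet::multinom(
        class ~ ., data = data.frame(class = ytr, xtr, check.names = FALSE),
        decay = 0.01, maxit = 200, trace = FALSE, MaxNWts = 50000))
      function(xte) {
        pr <- predict(fit, data.frame(xte, check.names = FALSE), type = "probs")
        if (is.null(dim(pr))) pr <- cbind(1 - pr, pr) # binary multinom
        colnames(pr) <- lv
        pr
      }
    },
    svm = {
      fit <- with_local_seed(seed, e1071::svm(
        x = xtr, y = ytr, kernel = "linear", cost = 1, probability = TRUE))
      function(xte) {
        pr <- attr(predict(fit, xte, probability = TRUE), "probabilities")
        pr[, lv, drop = FALSE]
      }
    },
    rc = {
      # random committee: seed-varied forests with randomized mtry,
      # averaged class-probability votes
      fits <- lapply(seq_len(10), function(m) with_local_seed(seed * 131 + m, {
        randomForest::randomForest(
          x = xtr, y = ytr, ntree = 20,
          mtry = max(1, floor(sqrt(ncol(xtr)) * runif(1, 0.5, 2))))
      }))
      function(xte) {
        acc <- 0
        for (fit in fits)
          acc <- acc + predict(fit, xte, type = "prob")[, lv, drop = FALSE]
        acc / length(fits)
      }
    },
    abort(sprintf("unknown learner '%s'", learner))
  )
  list(levels = lv, predict_scores = predictor)
}

fit_predict_scores <- function(xtr, ytr, xte, learner, seed, knn_k = 1,
                               ntree = 100) {
  fit_learner(xtr, ytr, learner, seed, knn_k, ntree)$predict_scores(xte)
}

# Mann-Whitney (rank) AUC with tie correction.
auc_score <- function(score, positive) {
  npos <- sum(positive); nneg <- sum(!positive)
  if (npos == 0 || nneg == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[positive]) - npos * (npos + 1) / 2) / (npos * nneg)
}

make_folds <- function(y, folds, seed) {
  with_local_seed(seed, {
    fold <- integer(length(y))
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
    fold
  })
}

#' Cross-validate a learner on a task dataset
#'
#' Stratified k-fold cross-validation. Metrics are pooled over folds:
#' overall accuracy, TPR and TNR (positive-class recall/specificity for
#' binary tasks, macro-averages for multiclass) and AUC (Mann-Whitney on the
#' pooled scores; one-vs-rest average for multiclass).
#'
#' @param data Tibble from [build_task_dataset()] (a `class` factor plus
#'   numeric feature columns).
#' @param learner One of `"knn"`, `"rf"`, `"logistic"`, `"svm"`, `"rc"`.
#' @param folds Number of CV folds (default 10).
#' @param seed Seed controlling fold assignment and stochastic learners.
#' @param positive Positive class for binary metrics (defaults to the first
#'   level).
#' @param fold_id Optional precomputed fold assignment (for paired runs).
#' @param ... Learner options (`knn_k`, `ntree`).
#' @return Object of class `leukemia_cv` with the pooled confusion matrix,
#'   per-fold confusions, metrics and predictions.
#' @export
train_and_crossvalidate <- function(data, learner = "rf", folds = 10,
                                    seed = 1, positive = NULL,
                                    fold_id = NULL, ...) {
  y <- droplevels(data$class)
  x <- as.matrix(data[, setdiff(names(data), "class"), drop = FALSE])
  storage.mode(x) <- "double"
  if (min(table(y)) < folds)
    abort(sprintf(
      "class with fewer than %d members; use at most %d folds",
      folds, min(table(y))))
  positive <- positive %||% levels(y)[1]
  fold_id <- fold_id %||% make_folds(y, folds, seed)
  lv <- levels(y)
  scores <- matrix(NA_real_, length(y), length(lv),
                   dimnames = list(NULL, lv))
  fold_conf <- list()
  for (f in seq_len(folds)) {
    te <- which(fold_id == f); tr <- which(fold_id != f)
    s <- fit_predict_scores(x[tr, , drop = FALSE], y[tr],
                            x[te, , drop = FALSE], learner,
                            seed = seed * 1000 + f, ...)
    scores[te, ] <- s
  }
  pred <- factor(lv[max.col(scores, ties.method = "first")], levels = lv)
  conf <- table(truth = y, predicted = pred)
  for (f in seq_len(folds))
    fold_conf[[f]] <- table(truth = y[fold_id == f],
                            predicted = pred[fold_id == f])
  metrics <- confusion_metrics(conf, positive)
  auc <- if (length(lv) == 2) auc_score(scores[, positive], y == positive)
  else mean(vapply(lv, function(cl) auc_score(scores[, cl], y == cl),
                   numeric(1)))
  structure(list(learner = learner, folds = folds, seed = seed,
                 positive = positive, levels = lv, confusion = conf,
                 fold_confusions = fold_conf, fold_id = fold_id,
                 scores = scores, predicted = pred, truth = y,
                 accuracy = metrics$accuracy, tpr = metrics$tpr,
                 tnr = metrics$tnr, auc = auc),
            class = "leukemia_cv")
}

# Accuracy / TPR / TNR from a confusion table (macro-averaged when > 2
# classes); exported so reports can be recomputed from stored confusions.
#' Metrics from a confusion matrix
#' @param conf Square confusion table, truth in rows.
#' @param positive Positive class for binary TPR/TNR.
#' @return List with `accuracy` (percent), `tpr`, `tnr`.
#' @export
confusion_metrics <- function(conf, positive = rownames(conf)[1]) {
  conf <- as.matrix(conf)
  acc <- 100 * sum(diag(conf)) / sum(conf)
  lv <- rownames(conf)
  if (length(lv) == 2) {
    tp <- conf[positive, positive]
    fn <- sum(conf[positive, ]) - tp
    neg <- setdiff(lv, positive)
    tn <- sum(conf[neg, neg, drop = FALSE])
    fp <- sum(conf[neg, ]) - tn
    list(accuracy = acc, tpr = tp / (tp + fn), tnr = tn / (tn + fp))
  } else {
    recalls <- diag(conf) / rowSums(conf)
    specs <- vapply(seq_along(lv), function(k) {
      tn <- sum(conf[-k, -k]); fp <- sum(conf[-k, k])
      tn / (tn + fp)
    }, numeric(1))
    list(accuracy = acc, tpr = mean(recalls), tnr = mean(specs))
  }
}

#' @export
print.leukemia_cv <- function(x, ...) {
  cat(sprintf("%d-fold CV [%s]: accuracy %.2f%%, TPR %.3f, TNR %.3f, AUC %.3f\n",
              x$folds, x$learner, x$accuracy, x$tpr, x$tnr, x$auc))
  invisible(x)
}

#' Compare the full panel against cell-only features
#'
#' Runs [train_and_crossvalidate()] on the nucleus + cytoplasm + cell panel
#' and on the cell-only subset with identical fold assignments, reporting
#' the paired accuracy difference.
#'
#' @param features Expanded-schema feature tibble with a `class` column.
#' @param task Task name or `task_spec`.
#' @param learner,folds,seed As in [train_and_crossvalidate()].
#' @param ... Learner options.
#' @return List with `nc`, `cell` (both `leukemia_cv`) and
#'   `accuracy_difference` (nc minus cell, percentage points).
#' @export
compare_feature_subsets <- function(features, task, learner = "rf",
                                    folds = 10, seed = 1, ...) {
  nc_data <- build_task_dataset(features, task, subset = "nc")
  cell_data <- build_task_dataset(features, task, subset = "cell")
  fold_id <- make_folds(droplevels(nc_data$class), folds, seed)
  nc <- train_and_crossvalidate(nc_data, learner, folds, seed,
                                fold_id = fold_id, ...)
  cell <- train_and_crossvalidate(cell_data, learner, folds, seed,
                                  fold_id = fold_id, ...)
  list(nc = nc, cell = cell,
       accuracy_difference = nc$accuracy - cell$accuracy)
}
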