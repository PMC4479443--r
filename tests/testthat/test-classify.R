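test_that("task datasets map labels and subsets correctly", {
  d <- generate_feature_dataset(10, 2, seed = 1,
                                classes = c("M2", "M3", "M5"))
  d$class <- factor(d$class, levels = c(levels(d$class), "No subtype"))
  extra <- d[1:4, ]; extra$class <- "No subtype"
  d2 <- dplyr::bind_rows(d, extra)

  td <- build_task_dataset(d2, "M2vs(M3&M5)")
  expect_equal(as.vector(table(td$class)), c(10, 20))
  expect_equal(levels(td$class), c("M2", "rest"))
  expect_equal(nrow(td), 30) # "No subtype" rows dropped

  expect_error(build_task_dataset(d2[d2$class != "M3", ], "M3vs(M2&M5)"),
               "absent")

  e <- generate_feature_dataset(5, 2, seed = 2, schema = "expanded",
                                classes = c("L1", "L2"))
  ce <- build_task_dataset(e, "L1vsL2", subset = "cell")
  sch <- mdx_feature_schema("expanded")
  expect_true(all(setdiff(names(ce), "class") %in%
                    sch$column[sch$region == "cell"]))
  expect_false(any(grepl("^nucleus_|^cytoplasm_", names(ce))))
  expect_error(build_task_dataset(d2, "M2vs(M3&M5)", subset = "cell"),
               "expanded")
})

test_that("metric arithmetic is exact on a hand confusion matrix", {
  conf <- matrix(c(8, 1, 2, 9), 2, 2,
                 dimnames = list(truth = c("pos", "neg"),
                                 predicted = c("pos", "neg")))
  # rows: truth pos (TP=8, FN=2), truth neg (FP=1, TN=9)
  conf <- as.table(rbind(pos = c(pos = 8, neg = 2), neg = c(pos = 1, neg = 9)))
  m <- confusion_metrics(conf, positive = "pos")
  expect_equal(m$accuracy, 85)
  expect_equal(m$tpr, 0.8)
  expect_equal(m$tnr, 0.9)
})

test_that("widely separated classes are classified perfectly", {
  d <- generate_feature_dataset(15, 20, seed = 3, classes = c("L1", "L2"))
  cv <- train_and_crossvalidate(build_task_dataset(d, "L1vsL2"), "knn",
                                folds = 10, seed = 1)
  expect_equal(cv$accuracy, 100)
  expect_equal(cv$auc, 1)
  expect_equal(cv$tpr, 1)
  expect_equal(cv$tnr, 1)
})

test_that("every learner in the roster trains and separates clean data", {
  d <- generate_feature_dataset(12, 12, seed = 4,
                                classes = c("M2", "M3", "M5"))
  td <- build_task_dataset(d, "M2vsM3vsM5")
  for (learner in c("knn", "rf", "logistic", "svm", "rc")) {
    cv <- train_and_crossvalidate(td, learner, folds = 4, seed = 2)
    expect_gte(cv$accuracy, 90)
    expect_gte(cv$auc, 0.95)
  }
})

test_that("fold assignment is stratified, seeded and guarded", {
  d <- generate_feature_dataset(25, 2, seed = 5, classes = c("L1", "L2"))
  td <- build_task_dataset(d, "L1vsL2")
  cv1 <- train_and_crossvalidate(td, "knn", folds = 5, seed = 7)
  cv2 <- train_and_crossvalidate(td, "knn", folds = 5, seed = 7)
  expect_identical(glance(cv1), glance(cv2))
  expect_identical(cv1$fold_id, cv2$fold_id)
  for (f in 1:5) {
    tab <- table(td$class[cv1$fold_id == f])
    expect_lte(abs(diff(as.vector(tab))), 1)
  }
  expect_error(train_and_crossvalidate(td[1:30, ], "knn", folds = 25),
               "folds")
})

test_that("pooled metrics recompute exactly from stored confusions", {
  d <- generate_feature_dataset(20, 3, seed = 6, classes = c("L1", "L2"))
  cv <- train_and_crossvalidate(build_task_dataset(d, "L1vsL2"), "rf",
                                folds = 5, seed = 1)
  pooled <- Reduce(`+`, lapply(cv$fold_confusions, as.matrix))
  expect_equal(pooled, as.matrix(cv$confusion), ignore_attr = TRUE)
  m <- confusion_metrics(as.table(pooled), positive = cv$positive)
  expect_equal(m$accuracy, cv$accuracy)
  expect_equal(m$tpr, cv$tpr)
  expect_equal(m$tnr, cv$tnr)
})

test_that("the rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  for (t in 1:5) {
    y <- runif(60) < 0.4
    s <- rnorm(60) + 2 * y
    ours <- marrowdx:::auc_score(s, y)
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("nucleus-borne signal favours the full panel over cell-only", {
  e <- generate_feature_dataset(20, 6, seed = 9, schema = "expanded",
                                signal_regions = "nucleus",
                                classes = c("L1", "L2", "M2", "M3", "M5"))
  cmp <- compare_feature_subsets(e, "ALLvsAML", learner = "rf", folds = 5,
                                 seed = 3)
  expect_gt(cmp$accuracy_difference, 0)
  expect_identical(cmp$nc$fold_id, cmp$cell$fold_id)
  # identical subsets give a zero difference under shared folds
  nc2 <- train_and_crossvalidate(
    build_task_dataset(e, "ALLvsAML"), "rf", folds = 5, seed = 3,
    fold_id = cmp$nc$fold_id)
  expect_equal(nc2$accuracy - cmp$nc$accuracy, 0)
})

test_that("tidiers expose per-class and summary views", {
  d <- generate_feature_dataset(12, 8, seed = 10, classes = c("L1", "L2"))
  cv <- train_and_crossvalidate(build_task_dataset(d, "L1vsL2"), "knn",
                                folds = 4, seed = 1)
  td <- tidy(cv)
  expect_equal(td$class, c("L1", "L2"))
  expect_true(all(td$recall >= 0 & td$recall <= 1))
  g <- glance(cv)
  expect_equal(g$n, 24)
  expect_s3_class(plot_cv_metrics(knn = cv), "ggplot")
})
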