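test_that("confusion counting, tie rule and oracle", {
  y <- c(1, 1, 0, 0)
  p <- c(0.9, 0.8, 0.1, 0.2)
  cc <- confusion(y, p)
  expect_equal(unname(cc[c("TP", "FN", "TN", "FP")]), c(2, 0, 2, 0))
  # probability exactly at threshold counts positive
  cc2 <- confusion(c(1, 0), c(0.5, 0.5), threshold = 0.5)
  expect_equal(unname(cc2["TP"]), 1)
  expect_equal(unname(cc2["FP"]), 1)
  expect_error(confusion(c(1, 0), 0.5), "equal length")
  set.seed(31)
  y <- rbinom(200, 1, 0.5)
  p <- runif(200)
  cc3 <- confusion(y, p, threshold = 0.4)
  tp <- 0; fn <- 0; tn <- 0; fp <- 0
  for (i in 1:200) {
    pred <- p[i] >= 0.4
    if (y[i] == 1 && pred) tp <- tp + 1
    if (y[i] == 1 && !pred) fn <- fn + 1
    if (y[i] == 0 && !pred) tn <- tn + 1
    if (y[i] == 0 && pred) fp <- fp + 1
  }
  expect_equal(unname(cc3[c("TP", "FN", "TN", "FP")]), c(tp, fn, tn, fp))
})

test_that("metric formulas reproduce the balanced independent-test row", {
  # 63 PVP / 63 non-PVP test set with Sn 0.9048 and Sp 0.8889 implies
  # TP 57, FN 6, TN 56, FP 7
  cc <- confusion_counts(TP = 57, FN = 6, TN = 56, FP = 7)
  m <- classification_metrics(cc)
  expect_equal(round(unname(m["Sn"]), 4), 0.9048)
  expect_equal(round(unname(m["Sp"]), 4), 0.8889)
  expect_equal(round(unname(m["ACC"]), 4), 0.8968)
  expect_equal(round(unname(m["Precision"]), 4), 0.8906)
  expect_equal(round(unname(m["F1"]), 4), 0.8976)
  expect_equal(round(unname(m["MCC"]), 4), 0.7938)
})

test_that("metric formulas reproduce the imbalanced 30/64 test row", {
  # 30 PVP / 64 non-PVP with Sn 0.9333 and Sp 0.9062 implies
  # TP 28, FN 2, TN 58, FP 6
  cc <- confusion_counts(TP = 28, FN = 2, TN = 58, FP = 6)
  m <- classification_metrics(cc)
  expect_equal(round(unname(m["ACC"]), 4), 0.9149)
  expect_equal(round(unname(m["Sn"]), 4), 0.9333)
  expect_equal(round(unname(m["MCC"]), 4), 0.8145)
})

test_that("symmetric confusion gives chance-level metrics", {
  cc <- confusion_counts(TP = 5, FN = 5, TN = 5, FP = 5)
  m <- classification_metrics(cc)
  expect_equal(unname(m["ACC"]), 0.5)
  expect_equal(unname(m["MCC"]), 0)
})

test_that("undefined metrics surface as NA sentinels with warnings", {
  cc <- confusion_counts(TP = 0, FN = 0, TN = 5, FP = 5)  # no positives
  warns <- character(0)
  m <- withCallingHandlers(classification_metrics(cc), warning = function(w) {
    warns <<- c(warns, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  expect_true(any(grepl("Sn undefined", warns)))   # Sn and MCC both flagged
  expect_true(any(grepl("MCC undefined", warns)))
  expect_true(is.na(m[["Sn"]]))
  expect_true(is.na(m[["MCC"]]))
  expect_false(is.na(m[["Sp"]]))
})

test_that("label swap maps Sn to Sp and preserves |MCC|", {
  set.seed(32)
  y <- rbinom(100, 1, 0.5)
  p <- runif(100)
  m1 <- suppressWarnings(classification_metrics(confusion(y, p)))
  # swapping classes: labels flip and scores reverse around the threshold
  m2 <- suppressWarnings(classification_metrics(
    confusion(1 - y, 1 - p + 1e-9)))
  expect_equal(unname(m1["Sn"]), unname(m2["Sp"]))
  expect_equal(unname(m1["Sp"]), unname(m2["Sn"]))
  expect_equal(abs(m1[["MCC"]]), abs(m2[["MCC"]]), tolerance = 1e-12)
})

test_that("balanced summary equals (Sn + Sp) / 2 exactly", {
  cc <- confusion_counts(TP = 57, FN = 6, TN = 56, FP = 7)
  m <- classification_metrics(cc)
  expect_equal(balanced_auc(cc), unname((m["Sn"] + m["Sp"]) / 2))
})

test_that("rank-based AUC: closed forms and pairwise oracle", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_equal(roc_auc(c(0, 1, 0, 1), rep(0.5, 4)), 0.5)
  expect_error(roc_auc(c(1, 1), c(0.2, 0.8)), "both classes")
  set.seed(33)
  for (rep in 1:100) {
    n <- 50
    y <- c(rep(0, 25), rep(1, 25))
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # forces ties
    pos <- s[y == 1]; neg <- s[y == 0]
    pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(roc_auc(y, s), mean(pairs))
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(34)
  y <- rbinom(80, 1, 0.5)
  s <- runif(80) + 0.5 * y
  expect_equal(roc_auc(y, s),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))))
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(35)
  y <- rbinom(60, 1, 0.5)
  s <- rnorm(60) + y
  a <- roc_auc(y, s)
  expect_equal(roc_auc(y, exp(s)), a)
  expect_equal(roc_auc(y, 5 * s - 2), a)
  expect_equal(roc_auc(y, atan(s)), a)
})

test_that("ROC curve spans the unit square corners monotonically", {
  set.seed(36)
  y <- rbinom(50, 1, 0.5)
  s <- runif(50) + y
  cur <- roc_curve(y, s)
  expect_equal(cur$fpr[1], 0)
  expect_equal(cur$tpr[1], 0)
  expect_equal(cur$fpr[nrow(cur)], 1)
  expect_equal(cur$tpr[nrow(cur)], 1)
  expect_true(all(diff(cur$fpr) >= 0))
  expect_true(all(diff(cur$tpr) >= 0))
})

test_that("cross-validation: constant builder, determinism, separability", {
  set.seed(37)
  n <- 60
  y <- rep(c(0, 1), each = n / 2)
  X <- matrix(rnorm(n * 5), n, 5)
  colnames(X) <- paste0("f", 1:5)
  fm <- feature_matrix(X, y)
  const_builder <- function(X, y) list(prob = function(newX) {
    rep(1, nrow(newX))
  })
  cv <- suppressWarnings(cross_validate(fm, const_builder, folds = 5,
                                        seed = 2))
  expect_equal(unname(cv$pooled["ACC"]), mean(y == 1))  # majority fraction
  cv2 <- suppressWarnings(cross_validate(fm, const_builder, folds = 5,
                                         seed = 2))
  expect_identical(cv$fold, cv2$fold)
  expect_identical(cv$per_fold, cv2$per_fold)
  # separable data: pooled AUC >= 0.95
  Xs <- X; Xs[, 1] <- Xs[, 1] + 5 * y
  fms <- feature_matrix(Xs, y)
  rf_builder <- function(X, y) {
    m <- randomForest::randomForest(X, factor(y, levels = c(0, 1)),
                                    ntree = 100)
    list(prob = function(newX) predict(m, newX, type = "prob")[, "1"])
  }
  set.seed(3)
  cvs <- cross_validate(fms, rf_builder, folds = 5, seed = 4)
  expect_gte(cvs$pooled_auc, 0.95)
})
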