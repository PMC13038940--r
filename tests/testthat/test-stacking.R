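# Gaussian two-class toy data with controllable separation
gauss_fm <- function(n = 100, d = 6, delta = 5, seed = 7) {
  set.seed(seed)
  y <- rep(c(0L, 1L), each = n / 2)
  X <- matrix(rnorm(n * d), n, d)
  X[, 1:2] <- X[, 1:2] + delta * y
  colnames(X) <- paste0("f", seq_len(d))
  feature_matrix(X, y)
}

fast_spec <- function(...) {
  base_layer_spec(algorithms = c("DT", "RF", "SVM", "KNN"), folds = 5L, ...)
}

test_that("the roster has 12 slots, 10 with installed backends", {
  expect_length(all_algorithms(), 12)
  expect_setequal(setdiff(all_algorithms(), available_algorithms()),
                  c("LightGBM", "CatBoost"))
  expect_error(base_layer_spec(algorithms = c("RF", "Banana")), "unknown")
  expect_error(base_layer_spec(algorithms = c("RF", "RF")), "unique")
})

test_that("requesting an algorithm without a backend errors by name", {
  fm <- gauss_fm(n = 20)
  spec <- base_layer_spec(algorithms = c("RF", "LightGBM", "CatBoost"),
                          folds = 5)
  expect_error(fit_base_layer(fm, spec), "LightGBM, CatBoost")
})

test_that("every available algorithm separates well-separated Gaussians", {
  fm <- gauss_fm(n = 100, delta = 5, seed = 7)
  spec <- base_layer_spec(algorithms = available_algorithms(), folds = 5,
                          seed = 7)
  fit <- fit_base_layer(fm, spec)
  expect_equal(dim(fit$oof), c(100L, 10L))
  expect_false(anyNA(fit$oof))
  expect_true(all(fit$oof >= 0 & fit$oof <= 1))
  acc <- colMeans((fit$oof >= 0.5) == matrix(fm$y, 100, 10))
  expect_true(all(acc >= 0.9), info = paste(names(acc), round(acc, 2),
                                            collapse = ", "))
})

test_that("n equal to folds leaves one sample per fold, no gaps", {
  fm <- gauss_fm(n = 10, delta = 4, seed = 8)
  spec <- base_layer_spec(algorithms = c("DT", "KNN"), folds = 5, seed = 1)
  fit <- fit_base_layer(fm, spec)
  expect_false(anyNA(fit$oof))
  expect_equal(as.numeric(table(fit$folds)), rep(2, 5))
  # boundary: n == folds
  fm1 <- gauss_fm(n = 8, delta = 4, seed = 9)
  spec1 <- base_layer_spec(algorithms = c("KNN"), folds = 8, seed = 1,
                           params = list(KNN = list(k = 3)))
  expect_error(fit1 <- fit_base_layer(fm1, spec1), NA)
  expect_false(anyNA(fit1$oof))
})

test_that("base layer is deterministic under a pinned seed", {
  fm <- gauss_fm(n = 60, delta = 2, seed = 10)
  spec <- fast_spec(seed = 5)
  f1 <- fit_base_layer(fm, spec)
  f2 <- fit_base_layer(fm, spec)
  expect_identical(f1$oof, f2$oof)
  expect_identical(f1$folds, f2$folds)
})

test_that("out-of-fold bookkeeping: fold models never see their own rows", {
  fm <- gauss_fm(n = 40, delta = 3, seed = 11)
  spec <- base_layer_spec(algorithms = "DT", folds = 4, seed = 2)
  fit <- fit_base_layer(fm, spec)
  # reconstruct each fold model independently and confirm the OOF column
  backend <- pvpstack:::learner_backend("DT")
  for (f in 1:4) {
    tr <- fit$folds != f
    model_f <- backend$fit(fm$X[tr, , drop = FALSE], fm$y[tr],
                           pvpstack:::learner_seed(2L, 1L, f), list())
    expect_equal(unname(fit$oof[!tr, "DT"]),
                 unname(backend$prob(model_f, fm$X[!tr, , drop = FALSE])))
  }
  # the fold plan is a partition
  expect_setequal(unique(fit$folds), 1:4)
  expect_equal(length(fit$folds), 40)
})

test_that("meta-feature assembly fixes block order and widths", {
  ids <- paste0("s", 1:5)
  blk <- function(v) matrix(v, 5, 12, dimnames = list(ids, all_algorithms()))
  one <- assemble_meta_features(list(F = blk(0.1)))
  expect_equal(ncol(one), 12)
  two <- assemble_meta_features(list(RFECV = blk(0.2), F = blk(0.1)))
  expect_equal(ncol(two), 24)
  expect_equal(colnames(two)[1], "F.DT")      # F block always first
  three <- assemble_meta_features(list(Var = blk(0.3), F = blk(0.1),
                                       RFECV = blk(0.2)))
  expect_equal(ncol(three), 36)
  bad <- blk(0.2); rownames(bad) <- rev(ids)
  expect_error(assemble_meta_features(list(F = blk(0.1), Var = bad)),
               "ids")
})

test_that("meta-classifiers fit separable and constant meta-features", {
  set.seed(12)
  y <- rep(c(0L, 1L), each = 30)
  meta_X <- matrix(runif(60 * 4, 0, 0.3) + 0.6 * y, 60, 4,
                   dimnames = list(NULL, paste0("F.", c("DT", "RF", "SVM",
                                                       "KNN"))))
  for (tag in c("RF", "LR", "SVM")) {
    mf <- fit_meta(meta_X, y, tag, seed = 1)
    expect_gte(roc_auc(y, mf$prob(meta_X)), 0.95)
  }
  # constant meta-features: majority class, chance-level AUC
  const_X <- matrix(0.5, 60, 4,
                    dimnames = list(NULL, colnames(meta_X)))
  mf <- fit_meta(const_X, c(rep(0L, 40), rep(1L, 20)), "RF", seed = 1)
  p <- mf$prob(const_X)
  expect_true(all(p < 0.5))                  # majority class is negative
  expect_equal(roc_auc(c(rep(0L, 40), rep(1L, 20)), p), 0.5)
  mf2 <- fit_meta(const_X, c(rep(0L, 40), rep(1L, 20)), "RF", seed = 1)
  expect_equal(mf$prob(const_X), mf2$prob(const_X))
})

test_that("stacked model predicts sanely and reproducibly", {
  fm <- gauss_fm(n = 60, delta = 3, seed = 13)
  model <- pvp_stack(fm, selectors = "F", meta = "RF",
                     spec = fast_spec(seed = 4), f_k = 4)
  pred <- predict(model, fm)
  expect_true(all(pred$probability >= 0 & pred$probability <= 1))
  expect_true(all(pred$label %in% c(0L, 1L)))
  # optimism: re-predicting training data is at least as accurate as OOF
  oof_prob <- model$meta_fit$prob(model$meta_features)
  acc_oof <- mean((oof_prob >= 0.5) == fm$y)
  acc_train <- mean(pred$label == fm$y)
  expect_gte(acc_train, acc_oof)
  # batch prediction equals the per-sample loop
  per_row <- vapply(seq_len(nrow(fm$X)), function(i) {
    predict(model, fm$X[i, , drop = FALSE])$probability
  }, numeric(1))
  expect_equal(pred$probability, per_row)
  # end-to-end reproducibility with pinned seeds
  model2 <- pvp_stack(fm, selectors = "F", meta = "RF",
                      spec = fast_spec(seed = 4), f_k = 4)
  expect_identical(predict(model2, fm)$probability, pred$probability)
})

test_that("experiment grid enumerates 7 combinations, 21 stacks, 36 bases", {
  grid <- enumerate_grid()
  expect_equal(length(unique(grid$stacked$combination)), 7)  # 2^3 - 1
  expect_equal(nrow(grid$stacked), 21)
  expect_equal(nrow(grid$base), 36)
  expect_equal(sort(unique(grid$base$algorithm)), sort(all_algorithms()))
})

test_that("grid runner covers all configurations on toy data", {
  fm <- gauss_fm(n = 70, d = 8, delta = 4, seed = 14)
  parts <- split_feature_matrix(fm, 0.3, seed = 1)
  res <- run_grid(parts$train, parts$test,
                  spec = base_layer_spec(algorithms = c("DT", "KNN"),
                                         folds = 5, seed = 2),
                  rfecv_args = list(cv_folds = 3, step = 2))
  expect_equal(nrow(res$stacked), 21)
  expect_equal(nrow(res$base), 2 * 3)
  expect_true(all(res$stacked$AUC >= 0 & res$stacked$AUC <= 1))
  # stacking does not catastrophically degrade on separable data
  expect_gte(max(res$stacked$AUC), mean(res$base$AUC) - 0.02)
})

test_that("default stack configuration is F + RFECV blocks with RF meta", {
  expect_equal(eval(formals(pvp_stack)$selectors), c("F", "RFECV"))
  expect_equal(eval(formals(pvp_stack)$meta), "RF")
  fm <- gauss_fm(n = 50, d = 5, delta = 4, seed = 15)
  model <- pvp_stack(fm, spec = fast_spec(seed = 3),
                     rfecv_args = list(cv_folds = 3))
  expect_equal(model$selectors, c("F", "RFECV"))
  expect_equal(model$meta_fit$meta, "RF")
  expect_equal(ncol(model$meta_features), 4 * 2)
})
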