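make_fm <- function(X, y) {
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  feature_matrix(X, y)
}

test_that("F statistic sentinels: constant, perfectly separating", {
  y <- rep(c(0, 1), each = 5)
  X <- cbind(rep(2, 10),              # constant -> F = 0
             y,                       # within-class constant, means differ
             rnorm(10))
  f <- f_score_rank(make_fm(X, y))
  expect_equal(unname(f[1]), 0)
  expect_equal(unname(f[2]), Inf)
  expect_true(is.finite(f[3]))
  expect_error(f_score_rank(make_fm(X, rep(1, 10))), "both classes")
})

test_that("F statistic matches the one-way ANOVA oracle", {
  set.seed(21)
  for (rep in 1:100) {
    n <- sample(10:30, 1)
    y <- c(rep(0, floor(n / 2)), rep(1, ceiling(n / 2)))
    X <- matrix(rnorm(n * 5, mean = y), n, 5)
    f <- f_score_rank(make_fm(X, y))
    for (j in 1:5) {
      oracle <- anova(lm(X[, j] ~ factor(y)))[["F value"]][1]
      expect_equal(unname(f[j]), oracle, tolerance = 1e-10)
    }
  }
})

test_that("variance selection matches a brute-force scan", {
  set.seed(22)
  n <- 40
  X <- cbind(matrix(rnorm(n * 9), n, 9), rep(5, n))
  y <- rep(c(0, 1), n / 2)
  fm <- make_fm(X, y)
  # constant feature is dropped for any positive threshold
  sel <- variance_select(fm, threshold = 1e-9)
  expect_false("f10" %in% sel$kept_names)
  # threshold 0 keeps everything in original order
  sel0 <- variance_select(fm, threshold = 0)
  expect_equal(sel0$kept_names, colnames(fm$X))
  # median-threshold kept set equals the direct scan (population variance)
  v <- apply(X, 2, function(x) mean((x - mean(x))^2))
  thr <- median(v)
  sel_m <- variance_select(fm, threshold = thr)
  expect_equal(sel_m$kept_names, colnames(fm$X)[v >= thr])
  expect_error(variance_select(fm, threshold = -1), "non-negative")
})

test_that("top-k F selection orders by F and breaks ties by index", {
  set.seed(23)
  y <- rep(c(0, 1), each = 20)
  X <- matrix(rnorm(40 * 6), 40, 6)
  fm <- make_fm(X, y)
  sel <- f_select(fm, k = 6)
  f <- f_score_rank(fm)
  expect_equal(sel$kept_names, names(sort(f, decreasing = TRUE)))
  # all-constant features: ties broken by original order
  Xc <- matrix(1, 40, 5)
  selc <- f_select(make_fm(Xc, y), k = 3)
  expect_equal(selc$kept_names, c("f1", "f2", "f3"))
  expect_error(f_select(fm, k = 7), "k must be")
})

test_that("a strong informative feature wins k = 1 selection", {
  set.seed(24)
  n <- 200
  y <- rep(c(0, 1), each = n / 2)
  X <- matrix(rnorm(n * 10), n, 10)
  X[, 4] <- X[, 4] + 3 * y            # delta = 3 s.d.
  sel <- f_select(make_fm(X, y), k = 1)
  expect_equal(sel$kept_names, "f4")
})

test_that("RFECV keeps a lone feature and is deterministic", {
  set.seed(25)
  y <- rep(c(0, 1), each = 15)
  X1 <- matrix(rnorm(30) + y, 30, 1)
  sel1 <- rfecv_select(make_fm(X1, y), cv_folds = 5, seed = 3)
  expect_equal(sel1$kept_names, "f1")
  X <- matrix(rnorm(30 * 6), 30, 6)
  X[, 2] <- X[, 2] + 2 * y
  fm <- make_fm(X, y)
  a <- rfecv_select(fm, cv_folds = 5, seed = 9)
  b <- rfecv_select(fm, cv_folds = 5, seed = 9)
  expect_identical(a$kept_names, b$kept_names)
  expect_identical(a$scores, b$scores)
})

test_that("RFECV recovers planted informative features", {
  # 3 informative + 17 noise, n = 300, delta = 2 s.d.
  hits <- 0L
  n_rep <- 20L
  for (r in seq_len(n_rep)) {
    set.seed(3000 + r)
    n <- 300
    y <- rep(c(0, 1), each = n / 2)
    X <- matrix(rnorm(n * 20), n, 20)
    X[, 1:3] <- X[, 1:3] + 2 * y
    sel <- rfecv_select(make_fm(X, y), cv_folds = 5, step = 2,
                        seed = 100 + r)
    if (all(c("f1", "f2", "f3") %in% sel$kept_names)) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("selections replay by name on reordered matrices", {
  set.seed(26)
  y <- rep(c(0, 1), each = 10)
  X <- matrix(rnorm(20 * 8), 20, 8)
  fm <- make_fm(X, y)
  sel <- f_select(fm, k = 4)
  # identity when keeping all
  all_sel <- f_select(fm, k = 8)
  expect_equal(sort(colnames(apply_selection(fm, all_sel)$X)),
               sort(colnames(fm$X)))
  # shuffled column order yields identical kept content
  perm <- sample(8)
  fm2 <- feature_matrix(fm$X[, perm], y, fm$ids)
  expect_equal(apply_selection(fm2, sel)$X, apply_selection(fm, sel)$X)
  # absent feature errors by name
  fm3 <- feature_matrix(fm$X[, 1:3], y, fm$ids)
  expect_error(apply_selection(fm3, sel), "missing")
})

test_that("selection round-trips through its text serialization", {
  set.seed(27)
  y <- rep(c(0, 1), each = 10)
  fm <- make_fm(matrix(rnorm(20 * 5), 20, 5), y)
  sel <- f_select(fm, k = 3)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_selection(sel, f)
  back <- read_selection(f)
  expect_equal(back$method, sel$method)
  expect_equal(back$kept_names, sel$kept_names)
})

test_that("train-time selection applied to held-out data cannot leak", {
  set.seed(28)
  y_tr <- rep(c(0, 1), each = 20)
  fm_tr <- make_fm(matrix(rnorm(40 * 6), 40, 6), y_tr)
  sel <- f_select(fm_tr, k = 3)
  # held-out data with wildly different statistics: selection is unchanged
  fm_te <- make_fm(matrix(rnorm(10 * 6, mean = 100), 10, 6),
                   rep(c(0, 1), 5))
  before <- sel$kept_names
  reduced <- apply_selection(fm_te, sel)
  expect_identical(sel$kept_names, before)
  expect_equal(colnames(reduced$X), before)
})
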