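test_that("pair features are an order-sensitive concatenation", {
  expect_identical(pairFeatures(c(1, 2), c(3, 4)), c(1, 2, 3, 4))
  f <- runif(5)
  pf <- pairFeatures(f, f)
  expect_identical(pf[1:5], pf[6:10])
  for (i in 1:100) {
    d <- sample(1:20, 1)
    expect_length(pairFeatures(runif(d), runif(d)), 2 * d)
  }
  expect_error(pairFeatures(1:2, 1:3), "mismatch")
})

test_that("ordered target statistic matches prefix counting", {
  # first visited item gets the pure prior whatever its category
  expect_equal(orderedTargetStatistic("a", 1, priorP = 0.5, priorWeight = 1,
                                      permutation = 1), 0.5)
  # worked example
  expect_equal(orderedTargetStatistic(c("c", "c", "d"), c(1, 0, 1),
                                      priorP = 0.5, priorWeight = 1,
                                      permutation = 1:3),
               c(0.5, 0.75, 0.5))
  # long run of one all-positive category approaches 1 as (k + 1/2)/(k + 1)
  n <- 40
  v <- orderedTargetStatistic(rep("c", n), rep(1, n), priorP = 0.5,
                              priorWeight = 1, permutation = 1:n)
  expect_equal(v, (seq_len(n) - 1 + 0.5) / (seq_len(n) - 1 + 1))
  expect_true(all(diff(v) > 0))

  # random instances against the brute-force oracle
  set.seed(10)
  for (i in 1:50) {
    n <- sample(2:25, 1)
    cats <- sample(letters[1:4], n, replace = TRUE)
    labs <- sample(0:1, n, replace = TRUE)
    perm <- sample(n)
    p0 <- runif(1); a0 <- runif(1, 0.1, 3)
    expect_equal(orderedTargetStatistic(cats, labs, p0, a0, perm),
                 prefixCountOTS(cats, labs, perm, p0, a0),
                 tolerance = 1e-12)
  }

  expect_error(orderedTargetStatistic(c("a", "b"), c(1, 0),
                                      permutation = c(1, 1)), "bijection")
  expect_error(orderedTargetStatistic(c("a", "b"), 1), "mismatch")
})

test_that("confusion counts partition the sample", {
  cc <- confusionCounts(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_identical(c(cc@TP, cc@TN, cc@FP, cc@FN), c(2L, 2L, 0L, 0L))
  cc <- confusionCounts(c(1, 1, 0, 0), c(0, 0, 1, 1))
  expect_identical(c(cc@TP, cc@TN), c(0L, 0L))
  set.seed(2)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    l <- sample(0:1, n, replace = TRUE); p <- sample(0:1, n, replace = TRUE)
    cc <- confusionCounts(l, p)
    tp <- 0; tn <- 0; fp <- 0; fn <- 0
    for (j in seq_len(n)) {
      if (l[j] == 1 && p[j] == 1) tp <- tp + 1
      if (l[j] == 0 && p[j] == 0) tn <- tn + 1
      if (l[j] == 0 && p[j] == 1) fp <- fp + 1
      if (l[j] == 1 && p[j] == 0) fn <- fn + 1
    }
    expect_identical(c(cc@TP, cc@TN, cc@FP, cc@FN),
                     as.integer(c(tp, tn, fp, fn)))
    expect_identical(cc@TP + cc@TN + cc@FP + cc@FN, as.integer(n))
  }
})

test_that("metrics follow their formulas with flagged degenerate cases", {
  m <- classMetrics(new("ConfusionCounts", TP = 25L, TN = 25L, FP = 25L, FN = 25L))
  expect_equal(unname(m), c(0.5, 0.5, 0.5, 0))

  m <- classMetrics(new("ConfusionCounts", TP = 50L, TN = 40L, FP = 10L, FN = 0L))
  expect_equal(m[["ACC"]], 0.9)
  expect_equal(m[["PE"]], 50 / 60)
  expect_equal(m[["SN"]], 1.0)
  expect_equal(m[["MCC"]], phiFromCounts(50, 40, 10, 0), tolerance = 1e-10)

  m <- classMetrics(new("ConfusionCounts", TP = 7L, TN = 9L, FP = 0L, FN = 0L))
  expect_equal(m[["ACC"]], 1)
  expect_equal(m[["MCC"]], 1)

  # degenerate denominators come back flagged, not as exceptions
  m <- classMetrics(new("ConfusionCounts", TP = 0L, TN = 10L, FP = 0L, FN = 5L))
  expect_true(is.nan(m[["PE"]]))
  expect_error(classMetrics(new("ConfusionCounts", TP = 0L, TN = 0L,
                                FP = 0L, FN = 0L)), "zero")
})

test_that("ROC/AUC handle separation, ties and small samples exactly", {
  sep <- rocAuc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))
  expect_equal(sep$auc, 1)
  expect_identical(sep$points$fpr[1], 0)
  expect_identical(tail(sep$points$tpr, 1), 1)

  tied <- rocAuc(c(1, 0, 1, 0), rep(0.5, 4))
  expect_equal(tied$auc, 0.5)

  set.seed(12)
  for (i in 1:25) {
    n <- 12
    l <- c(rep(1, 5), rep(0, 7))[sample(n)]
    s <- round(runif(n), 1)             # force some ties
    expect_equal(rocAuc(l, s)$auc, pairCountAUC(l, s), tolerance = 1e-12)
  }
  expect_error(rocAuc(rep(1, 4), runif(4)), "both classes")
})

separableToy <- function(n = 60, seed = 1) {
  set.seed(seed)
  y <- rep(0:1, each = n / 2)
  X <- cbind(rnorm(n, mean = 3 * y), rnorm(n))
  list(X = X, y = y)
}

test_that("classifier kinds train, predict probabilities and are seeded", {
  toy <- separableToy()
  for (kind in c("gbdt", "nb", "lda", "svm", "dt", "knn")) {
    m <- trainClassifier(toy$X, toy$y, kind = kind, seed = 3)
    p <- predictProba(m, toy$X)
    expect_true(all(p >= 0 & p <= 1))
    expect_length(p, nrow(toy$X))
    # row permutation permutes scores identically
    perm <- sample(nrow(toy$X))
    expect_equal(predictProba(m, toy$X[perm, ]), p[perm], tolerance = 1e-12)
  }

  m <- trainClassifier(toy$X, toy$y, kind = "gbdt", seed = 3)
  acc <- mean(as.integer(predictProba(m, toy$X) >= 0.5) == toy$y)
  expect_equal(acc, 1.0)

  for (kind in c("gbdt", "dt")) {
    p1 <- predictProba(trainClassifier(toy$X, toy$y, kind, seed = 5), toy$X)
    p2 <- predictProba(trainClassifier(toy$X, toy$y, kind, seed = 5), toy$X)
    expect_identical(p1, p2)
  }

  # hard labels at 0.5 equal a manual threshold
  p <- predictProba(m, toy$X)
  expect_identical(as.integer(p >= 0.5),
                   vapply(p, function(v) if (v >= 0.5) 1L else 0L, integer(1)))

  expect_error(trainClassifier(toy$X, rep(1, nrow(toy$X))), "both classes")
  bad <- toy$X; bad[1, 1] <- NaN
  expect_error(trainClassifier(bad, toy$y), "non-finite")
  expect_error(predictProba(m, toy$X[, 1, drop = FALSE]), "width mismatch")
})

test_that("label-permuted training yields chance-level cross-validation", {
  set.seed(20)
  n <- 400
  X <- matrix(rnorm(n * 8), n, 8)
  y <- rep(0:1, each = n / 2)[sample(n)]   # labels independent of X
  fold <- rep(1:2, length.out = n)[sample(n)]
  accs <- vapply(1:2, function(k) {
    m <- trainClassifier(X[fold != k, ], y[fold != k], kind = "gbdt",
                         params = list(nrounds = 60), seed = k)
    mean(as.integer(predictProba(m, X[fold == k, ]) >= 0.5) == y[fold == k])
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.07)
})
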