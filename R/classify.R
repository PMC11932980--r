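#' Concatenate two protein feature vectors into a pair feature
#'
#' @param fa,fb Numeric per-protein feature vectors of equal length d.
#' @return Numeric vector \code{c(fa, fb)} of length 2d. Concatenation is
#'   order-sensitive; the cross-validation harness repairs the symmetry by
#'   training on both orders and averaging both orders at prediction time.
#' @export
pairFeatures <- function(fa, fb) {
  if (length(fa) != length(fb)) {
    stop("feature length mismatch: ", length(fa), " vs ", length(fb))
  }
  c(fa, fb)
}

#' Ordered target statistic for a categorical feature
#'
#' Leakage-free numerical encoding of a categorical column as used by
#' ordered boosting: the data are visited in a random permutation and each
#' item's category is replaced by the smoothed mean label of the items of
#' the same category occurring *earlier* in the permutation,
#' \deqn{(\sum_{j < p,\, c_j = c} y_j + \alpha p_0) / (n_{<p,c} + \alpha),}
#' with prior \eqn{p_0} and prior weight \eqn{\alpha}. The first
#' occurrence of any category therefore receives the pure prior.
#'
#' @param categories Vector of category values.
#' @param labels Binary 0/1 labels of equal length.
#' @param priorP Prior value \eqn{p_0} in [0, 1].
#' @param priorWeight Positive prior weight \eqn{\alpha}.
#' @param permutation Visiting order: a permutation of \code{seq_along(categories)}.
#'   If \code{NULL}, a random permutation is drawn (seeded via \code{seed}).
#' @param seed Optional seed used only when \code{permutation} is \code{NULL}.
#' @return Numeric encodings, returned in the original index order.
#' @export
#' @examples
#' orderedTargetStatistic(c("c", "c", "d"), c(1, 0, 1),
#'                        permutation = 1:3)  # 0.5 0.75 0.5
orderedTargetStatistic <- function(categories, labels, priorP = 0.5,
                                   priorWeight = 1, permutation = NULL,
                                   seed = NULL) {
  n <- length(categories)
  if (length(labels) != n) stop("categories and labels length mismatch")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  if (priorP < 0 || priorP > 1) stop("priorP must lie in [0, 1]")
  if (priorWeight <= 0) stop("priorWeight must be > 0")
  if (is.null(permutation)) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    permutation <- sample.int(n)
  }
  if (length(permutation) != n || !setequal(permutation, seq_len(n))) {
    stop("permutation must be a bijection on 1..", n)
  }
  counts <- new.env(parent = emptyenv())
  sums <- new.env(parent = emptyenv())
  out <- numeric(n)
  for (pos in seq_len(n)) {
    i <- permutation[pos]
    key <- as.character(categories[i])
    cnt <- get0(key, counts, ifnotfound = 0)
    sm <- get0(key, sums, ifnotfound = 0)
    out[i] <- (sm + priorWeight * priorP) / (cnt + priorWeight)
    assign(key, cnt + 1, counts)
    assign(key, sm + labels[i], sums)
  }
  out
}

.classifierKinds <- c("gbdt", "nb", "lda", "svm", "dt", "knn")

#' Train a binary pair classifier
#'
#' One surface over the gradient-boosted tree model (the main classifier)
#' and the five comparison classifiers. Defaults: boosted trees with 500
#' iterations, depth 6, learning rate 0.05; KNN with k = 5; SVM with RBF
#' kernel and probability outputs; others at library defaults.
#'
#' @param X Numeric feature matrix, one row per pair.
#' @param y Binary 0/1 labels; both classes must be present.
#' @param kind One of \code{"gbdt"} (gradient-boosted trees),
#'   \code{"nb"}, \code{"lda"}, \code{"svm"}, \code{"dt"}, \code{"knn"}.
#' @param params Named list of hyper-parameter overrides (\code{nrounds},
#'   \code{maxDepth}, \code{eta} for gbdt; \code{k} for knn; \code{cost},
#'   \code{gamma} for svm).
#' @param seed Integer seed (controls the tree-based learners).
#' @return A fitted \linkS4class{PPIClassifier}.
#' @export
trainClassifier <- function(X, y, kind = "gbdt", params = list(), seed = 1L) {
  kind <- match.arg(kind, .classifierKinds)
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("X rows must match length(y)")
  if (!all(y %in% c(0, 1))) stop("labels must be 0/1")
  if (length(unique(y)) < 2L) stop("both classes must be present in y")
  if (any(!is.finite(X))) stop("non-finite feature values")
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  fullWidth <- ncol(X)
  set.seed(as.integer(seed))

  # lda/nb cannot digest features that are constant within a class
  # (structural zeros from zero-padding or empty HOG blocks); screen them
  # out and remember the kept columns for prediction time.
  keep <- seq_len(ncol(X))
  if (kind %in% c("lda", "nb")) {
    ctr <- X
    for (cls in c(0, 1)) {
      rows <- y == cls
      ctr[rows, ] <- scale(X[rows, , drop = FALSE], center = TRUE,
                           scale = FALSE)
    }
    withinSd <- apply(ctr, 2, stats::sd)
    keep <- which(withinSd > 2e-4)   # margin above MASS::lda's 1e-4 tol
    if (length(keep) == 0L) stop("all features are constant within classes")
    X <- X[, keep, drop = FALSE]
  }

  fit <- switch(kind,
    gbdt = {
      xgboost::xgboost(
        x = X, y = factor(y, levels = c(0, 1)),
        nrounds = params$nrounds %||% 500,
        max_depth = params$maxDepth %||% 6,
        learning_rate = params$eta %||% 0.05,
        objective = "binary:logistic",
        nthreads = 1, verbosity = 0,
        seed = as.integer(seed))
    },
    nb = e1071::naiveBayes(x = as.data.frame(X), y = factor(y, levels = c(0, 1))),
    lda = withCallingHandlers(
      MASS::lda(x = X, grouping = factor(y, levels = c(0, 1))),
      # expected with near-duplicate profile features; lda still fits
      warning = function(w) {
        if (grepl("collinear", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }),
    svm = e1071::svm(x = X, y = factor(y, levels = c(0, 1)),
                     kernel = "radial", probability = TRUE,
                     cost = params$cost %||% 1,
                     gamma = params$gamma %||% (1 / ncol(X))),
    dt = {
      df <- data.frame(.y = factor(y, levels = c(0, 1)), X)
      rpart::rpart(.y ~ ., data = df, method = "class")
    },
    knn = list(train = X, y = y, k = params$k %||% 5)
  )
  params$.keep <- keep
  new("PPIClassifier", kind = kind, fit = fit,
      featureWidth = fullWidth, params = params)
}

#' @describeIn predictProba Probability of the positive class from any
#'   classifier kind.
#' @export
setMethod("predictProba", "PPIClassifier", function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model@featureWidth) {
    stop("feature width mismatch: model expects ", model@featureWidth,
         ", got ", ncol(X))
  }
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  keep <- model@params$.keep
  if (!is.null(keep) && length(keep) < ncol(X)) {
    X <- X[, keep, drop = FALSE]
  }
  p <- switch(model@kind,
    gbdt = stats::predict(model@fit, X),
    nb = stats::predict(model@fit, as.data.frame(X), type = "raw")[, "1"],
    lda = stats::predict(model@fit, X)$posterior[, "1"],
    svm = {
      pr <- stats::predict(model@fit, X, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    },
    dt = stats::predict(model@fit, data.frame(X), type = "prob")[, "1"],
    knn = {
      kn <- model@fit
      pred <- class::knn(kn$train, X, cl = factor(kn$y, levels = c(0, 1)),
                         k = kn$k, prob = TRUE)
      win <- attr(pred, "prob")
      ifelse(pred == "1", win, 1 - win)
    })
  p <- as.numeric(p)
  pmin(pmax(p, 0), 1)
})

#' Confusion counts of a binary prediction
#'
#' @param labels True 0/1 labels.
#' @param predicted Predicted 0/1 labels, same length.
#' @return A \linkS4class{ConfusionCounts}. TP counts true interacting
#'   pairs predicted to interact, TN true non-interacting pairs predicted
#'   non-interacting, FP/FN the two error types.
#' @export
confusionCounts <- function(labels, predicted) {
  if (length(labels) != length(predicted)) stop("length mismatch")
  if (!all(labels %in% c(0, 1)) || !all(predicted %in% c(0, 1))) {
    stop("labels and predictions must be 0/1")
  }
  new("ConfusionCounts",
      TP = sum(labels == 1 & predicted == 1),
      TN = sum(labels == 0 & predicted == 0),
      FP = sum(labels == 0 & predicted == 1),
      FN = sum(labels == 1 & predicted == 0))
}

#' Classification metrics from confusion counts
#'
#' Accuracy, precision, sensitivity and Matthews correlation coefficient:
#' \deqn{ACC = (TN + TP) / (TN + TP + FN + FP)}
#' \deqn{PE = TP / (FP + TP)}
#' \deqn{SN = TP / (TP + FN)}
#' \deqn{MCC = (TP \cdot TN - FP \cdot FN) /
#'   \sqrt{(TP+FP)(TN+FN)(TN+FP)(TP+FN)}}
#' A metric whose denominator is zero is returned as \code{NaN} (flagged
#' undefined) rather than raising an error, so fold aggregation can skip
#' it explicitly.
#'
#' @param counts A \linkS4class{ConfusionCounts} with at least one
#'   evaluated pair.
#' @return Named numeric vector with entries ACC, PE, SN, MCC.
#' @export
classMetrics <- function(counts) {
  stopifnot(is(counts, "ConfusionCounts"))
  TP <- as.numeric(counts@TP); TN <- as.numeric(counts@TN)
  FP <- as.numeric(counts@FP); FN <- as.numeric(counts@FN)
  total <- TP + TN + FP + FN
  if (total == 0) stop("no evaluated pairs (all counts zero)")
  safeDiv <- function(num, den) if (den == 0) NaN else num / den
  mccDen <- sqrt((TP + FP) * (TN + FN) * (TN + FP) * (TP + FN))
  c(ACC = (TN + TP) / total,
    PE = safeDiv(TP, FP + TP),
    SN = safeDiv(TP, TP + FN),
    MCC = if (mccDen == 0) NaN else (TP * TN - FP * FN) / mccDen)
}

#' ROC curve and AUC
#'
#' The ROC curve is traced over all score thresholds (one step per unique
#' score, descending) and the AUC computed by trapezoidal integration,
#' which is equivalent to the probability that a random positive outscores
#' a random negative with ties counted one half.
#'
#' @param labels True 0/1 labels; both classes must be present.
#' @param scores Numeric scores, higher = more likely positive.
#' @return List with \code{auc} (scalar) and \code{points} (data frame of
#'   fpr/tpr, from (0,0) to (1,1)).
#' @export
rocAuc <- function(labels, scores) {
  if (length(labels) != length(scores)) stop("length mismatch")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  nPos <- sum(labels == 1); nNeg <- sum(labels == 0)
  if (nPos == 0 || nNeg == 0) {
    stop("both classes must be present to compute a ROC curve")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  # one ROC vertex after each distinct score value
  lastOfTie <- c(s[-1] != s[-length(s)], TRUE)
  cumTP <- cumsum(l == 1)[lastOfTie]
  cumFP <- cumsum(l == 0)[lastOfTie]
  tpr <- c(0, cumTP / nPos)
  fpr <- c(0, cumFP / nNeg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(auc = auc, points = data.frame(fpr = fpr, tpr = tpr))
}
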