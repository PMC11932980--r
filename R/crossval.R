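#' Pipeline configuration for evaluation runs
#'
#' Bundles the choices that define one experimental arm: fixed-size
#' transform, feature extractor, classifier, and their settings.
#'
#' @param transform \code{"equal_size"} or \code{"zero_pad"}.
#' @param extractor \code{"dae"}, \code{"hog"}, or \code{"none"} (flattened
#'   400-entry matrix used directly).
#' @param classifier One of \code{"gbdt"}, \code{"nb"}, \code{"lda"},
#'   \code{"svm"}, \code{"dt"}, \code{"knn"}.
#' @param daeConfig \linkS4class{DAEConfig} for the autoencoder arm.
#' @param hogConfig \linkS4class{HOGConfig} for the HOG arm.
#' @param classifierParams Named list passed to \code{\link{trainClassifier}}.
#' @param augmentOrders Train on both pair orders and average both orders
#'   at prediction time (symmetry repair for the order-sensitive
#'   concatenation encoding).
#' @param threshold Hard-label probability threshold.
#' @return A named list of class \code{"ppiPipelineConfig"}.
#' @export
pipelineConfig <- function(transform = "equal_size", extractor = "dae",
                           classifier = "gbdt", daeConfig = DAEConfig(),
                           hogConfig = HOGConfig(), classifierParams = list(),
                           augmentOrders = TRUE, threshold = 0.5) {
  transform <- match.arg(transform, c("equal_size", "zero_pad"))
  extractor <- match.arg(extractor, c("dae", "hog", "none"))
  classifier <- match.arg(classifier, .classifierKinds)
  structure(list(transform = transform, extractor = extractor,
                 classifier = classifier, daeConfig = daeConfig,
                 hogConfig = hogConfig, classifierParams = classifierParams,
                 augmentOrders = augmentOrders, threshold = threshold),
            class = "ppiPipelineConfig")
}

.checkPairs <- function(pairs) {
  need <- c("id_a", "id_b", "label")
  if (!all(need %in% names(pairs))) {
    stop("pairs must have columns id_a, id_b, label")
  }
  if (!all(pairs$label %in% c(0, 1))) stop("pair labels must be 0/1")
  pairs
}

## Stratified fold assignment: shuffle within class, deal out cyclically.
.stratifiedFolds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

## Per-protein features for one (transform, extractor) arm. `matrices` is
## the named list of scaled FixedMatrix; for the DAE arm the model is
## trained on `trainIds` only (leakage-free) and applied to every protein.
.armFeatures <- function(matrices, extractor, trainIds, daeConfig, hogConfig) {
  switch(extractor,
    dae = {
      model <- trainDAE(matrices[trainIds], daeConfig)
      extractFeatures(model, matrices)
    },
    hog = .hogFeatureMatrix(matrices, hogConfig),
    none = {
      X <- t(vapply(matrices, .flattenFixed, numeric(400)))
      rownames(X) <- vapply(matrices, proteinId, character(1))
      X
    })
}

.pairDesign <- function(features, pairs, augment) {
  A <- features[pairs$id_a, , drop = FALSE]
  B <- features[pairs$id_b, , drop = FALSE]
  X <- cbind(A, B)
  y <- pairs$label
  if (augment) {
    X <- rbind(X, cbind(B, A))
    y <- c(y, y)
  }
  rownames(X) <- NULL
  list(X = X, y = y)
}

.pairScores <- function(model, features, pairs, augment) {
  A <- features[pairs$id_a, , drop = FALSE]
  B <- features[pairs$id_b, , drop = FALSE]
  if (augment) {
    (predictProba(model, cbind(A, B)) + predictProba(model, cbind(B, A))) / 2
  } else {
    predictProba(model, cbind(A, B))
  }
}

## Fit + evaluate one fold given per-protein features. Returns the metric
## row and the ROC points.
.evalFold <- function(features, trainPairs, testPairs, classifier,
                      classifierParams, augment, threshold, seed) {
  des <- .pairDesign(features, trainPairs, augment)
  model <- trainClassifier(des$X, des$y, kind = classifier,
                           params = classifierParams, seed = seed)
  scores <- .pairScores(model, features, testPairs, augment)
  preds <- as.integer(scores >= threshold)
  met <- classMetrics(confusionCounts(testPairs$label, preds))
  roc <- rocAuc(testPairs$label, scores)
  list(metrics = c(met, AUC = roc$auc), roc = roc$points, scores = scores)
}

#' Stratified k-fold cross-validated evaluation
#'
#' Splits the labeled pairs into k stratified folds; within each fold the
#' feature extractor (for the autoencoder arm) and the classifier are
#' trained on the training folds only, so no feature-learning leakage
#' reaches the held-out pairs. Reports per-fold and mean +/- sd ACC, PE,
#' SN, MCC and AUC plus per-fold ROC curves.
#'
#' @param pssms List of \linkS4class{PSSM} objects covering every protein
#'   referenced in \code{pairs}.
#' @param pairs Data frame with columns \code{id_a}, \code{id_b},
#'   \code{label} (0/1).
#' @param k Number of folds (>= 2; each class needs >= k pairs).
#' @param config A \code{\link{pipelineConfig}}.
#' @param seed Integer seed controlling fold assignment and, derived from
#'   it, per-fold extractor/classifier training.
#' @return An \linkS4class{EvalReport}.
#' @export
crossValidate <- function(pssms, pairs, k = 5, config = pipelineConfig(),
                          seed = 1L) {
  pairs <- .checkPairs(pairs)
  if (k < 2) stop("k must be >= 2")
  if (min(table(pairs$label)) < k) {
    stop("need at least k pairs in each class")
  }
  matrices <- .fixedFeatureMatrices(pssms, config$transform)
  names(matrices) <- vapply(matrices, proteinId, character(1))
  missing <- setdiff(unique(c(pairs$id_a, pairs$id_b)), names(matrices))
  if (length(missing)) {
    stop("pairs reference proteins without a PSSM: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }

  set.seed(as.integer(seed))
  fold <- .stratifiedFolds(pairs$label, k)
  perFold <- vector("list", k)
  rocs <- vector("list", k)
  for (i in seq_len(k)) {
    testPairs <- pairs[fold == i, , drop = FALSE]
    trainPairs <- pairs[fold != i, , drop = FALSE]
    if (length(unique(testPairs$label)) < 2 ||
        length(unique(trainPairs$label)) < 2) {
      stop("a class is absent from fold ", i)
    }
    daeCfg <- config$daeConfig
    daeCfg@seed <- as.integer(seed) + i
    trainIds <- unique(c(trainPairs$id_a, trainPairs$id_b))
    features <- .armFeatures(matrices, config$extractor, trainIds,
                             daeCfg, config$hogConfig)
    res <- .evalFold(features, trainPairs, testPairs, config$classifier,
                     config$classifierParams, config$augmentOrders,
                     config$threshold, seed = as.integer(seed) + i)
    perFold[[i]] <- res$metrics
    rocs[[i]] <- res$roc
  }
  perFoldDf <- cbind(data.frame(fold = seq_len(k)),
                     as.data.frame(do.call(rbind, perFold)))
  metricNames <- c("ACC", "PE", "SN", "MCC", "AUC")
  summaryDf <- data.frame(
    metric = metricNames,
    mean = vapply(metricNames, function(mn) mean(perFoldDf[[mn]][is.finite(perFoldDf[[mn]])]),
                  numeric(1)),
    sd = vapply(metricNames, function(mn) stats::sd(perFoldDf[[mn]][is.finite(perFoldDf[[mn]])]),
                numeric(1)),
    row.names = NULL)
  new("EvalReport", perFold = perFoldDf, metricSummary = summaryDf,
      rocPoints = rocs,
      config = list(transform = config$transform, extractor = config$extractor,
                    classifier = config$classifier, k = k,
                    seed = as.integer(seed),
                    augmentOrders = config$augmentOrders,
                    threshold = config$threshold))
}

#' Rank candidate pairs by predicted interaction probability
#'
#' Case-study mode: a model trained on one dataset scores candidate pairs
#' from another; candidates are returned sorted by descending score, ties
#' broken by (id_a, id_b) lexicographic order for determinism.
#'
#' @param model A fitted \linkS4class{PPIClassifier}.
#' @param features Per-protein feature matrix (row names = protein ids)
#'   from the same extractor the model was trained on.
#' @param candidates Data frame with columns \code{id_a}, \code{id_b}.
#' @param topN Optionally keep only the first \code{topN} rows.
#' @param augmentOrders Average the two pair orders (default TRUE).
#' @return Data frame with columns rank, id_a, id_b, score.
#' @export
rankPredictions <- function(model, features, candidates, topN = NULL,
                            augmentOrders = TRUE) {
  if (nrow(candidates) == 0) stop("no candidate pairs")
  scores <- .pairScores(model, features, candidates, augmentOrders)
  ord <- order(-scores, candidates$id_a, candidates$id_b)
  out <- data.frame(rank = seq_along(ord),
                    id_a = candidates$id_a[ord],
                    id_b = candidates$id_b[ord],
                    score = scores[ord],
                    row.names = NULL)
  if (!is.null(topN)) out <- utils::head(out, topN)
  out
}

#' Run the transform x extractor x classifier ablation grid
#'
#' Evaluates every combination on the same stratified folds, sharing the
#' per-fold extracted features across classifiers so the grid stays cheap.
#' Mirrors the layout of the usual method-comparison tables (mean +/- sd
#' per metric and arm).
#'
#' @param pssms,pairs,k,seed As in \code{\link{crossValidate}}.
#' @param transforms,extractors,classifiers Character vectors of arms to run.
#' @param daeConfig,hogConfig,classifierParams Shared arm settings.
#' @param augmentOrders,threshold As in \code{\link{pipelineConfig}}.
#' @return List with \code{summary} (one row per arm and metric mean/sd)
#'   and \code{perFold} (full per-fold metric table).
#' @export
runAblation <- function(pssms, pairs, transforms = c("equal_size", "zero_pad"),
                        extractors = c("dae", "hog"),
                        classifiers = .classifierKinds, k = 5, seed = 1L,
                        daeConfig = DAEConfig(), hogConfig = HOGConfig(),
                        classifierParams = list(), augmentOrders = TRUE,
                        threshold = 0.5) {
  pairs <- .checkPairs(pairs)
  set.seed(as.integer(seed))
  fold <- .stratifiedFolds(pairs$label, k)

  rows <- list()
  for (tr in transforms) {
    matrices <- .fixedFeatureMatrices(pssms, tr)
    names(matrices) <- vapply(matrices, proteinId, character(1))
    for (ex in extractors) {
      for (i in seq_len(k)) {
        testPairs <- pairs[fold == i, , drop = FALSE]
        trainPairs <- pairs[fold != i, , drop = FALSE]
        daeCfg <- daeConfig
        daeCfg@seed <- as.integer(seed) + i
        trainIds <- unique(c(trainPairs$id_a, trainPairs$id_b))
        features <- .armFeatures(matrices, ex, trainIds, daeCfg, hogConfig)
        for (cl in classifiers) {
          res <- .evalFold(features, trainPairs, testPairs, cl,
                           classifierParams, augmentOrders, threshold,
                           seed = as.integer(seed) + i)
          rows[[length(rows) + 1L]] <- data.frame(
            transform = tr, extractor = ex, classifier = cl, fold = i,
            t(res$metrics))
        }
      }
    }
  }
  perFold <- do.call(rbind, rows)
  metricNames <- c("ACC", "PE", "SN", "MCC", "AUC")
  agg <- do.call(rbind, lapply(
    split(perFold, perFold[c("transform", "extractor", "classifier")],
          drop = TRUE),
    function(d) {
      out <- d[1, c("transform", "extractor", "classifier")]
      for (mn in metricNames) {
        v <- d[[mn]][is.finite(d[[mn]])]
        out[[paste0(mn, "_mean")]] <- mean(v)
        out[[paste0(mn, "_sd")]] <- stats::sd(v)
      }
      out
    }))
  rownames(agg) <- NULL
  list(summary = agg, perFold = perFold)
}

#' Format an ablation summary as an aligned text table
#'
#' @param summary The \code{summary} element of \code{\link{runAblation}},
#'   or a subset of its rows.
#' @param percent Print metrics as percentages (default TRUE).
#' @return Character vector of table lines, invisibly printed with
#'   \code{cat} when \code{print = TRUE}.
#' @param print Emit the table to the console.
#' @export
formatAblationTable <- function(summary, percent = TRUE, print = TRUE) {
  metricNames <- c("ACC", "PE", "SN", "MCC", "AUC")
  f <- function(m, s) {
    if (percent) sprintf("%6.2f +/- %.2f", 100 * m, 100 * s)
    else sprintf("%.4f +/- %.4f", m, s)
  }
  hdr <- sprintf("%-10s %-9s %-10s %s", "Transform", "Extractor", "Classifier",
                 paste(sprintf("%-16s", metricNames), collapse = " "))
  lines <- vapply(seq_len(nrow(summary)), function(i) {
    cells <- vapply(metricNames, function(mn) {
      f(summary[[paste0(mn, "_mean")]][i], summary[[paste0(mn, "_sd")]][i])
    }, character(1))
    sprintf("%-10s %-9s %-10s %s", summary$transform[i], summary$extractor[i],
            summary$classifier[i], paste(sprintf("%-16s", cells), collapse = " "))
  }, character(1))
  out <- c(hdr, lines)
  if (print) cat(out, sep = "\n")
  invisible(out)
}

#' Write an evaluation report to disk
#'
#' Emits three artifacts: \code{<prefix>_report.json} (per-fold metrics,
#' summary, config), \code{<prefix>_report.txt} (aligned table), and
#' \code{<prefix>_roc.csv} (fold, fpr, tpr).
#'
#' @param report An \linkS4class{EvalReport}.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Character vector of the written paths, invisibly.
#' @export
writeEvalReport <- function(report, dir, prefix = "eval") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonPath <- file.path(dir, paste0(prefix, "_report.json"))
  jsonlite::write_json(
    list(perFold = report@perFold, summary = report@metricSummary,
         config = report@config),
    jsonPath, auto_unbox = TRUE, digits = NA, na = "string")

  txtPath <- file.path(dir, paste0(prefix, "_report.txt"))
  s <- report@metricSummary
  lines <- c(sprintf("%-8s %-10s %-10s", "metric", "mean", "sd"),
             sprintf("%-8s %-10.4f %-10.4f", s$metric, s$mean, s$sd))
  writeLines(lines, txtPath)

  rocPath <- file.path(dir, paste0(prefix, "_roc.csv"))
  roc <- do.call(rbind, lapply(seq_along(report@rocPoints), function(i) {
    cbind(fold = i, report@rocPoints[[i]])
  }))
  utils::write.csv(roc, rocPath, row.names = FALSE)
  invisible(c(jsonPath, txtPath, rocPath))
}
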