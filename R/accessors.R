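#' @describeIn PSSM-class Score matrix accessor.
#' @export
setMethod("pssmScores", "PSSM", function(object) object@scores)

#' @describeIn PSSM-class Identifier accessor.
#' @export
setMethod("proteinId", "PSSM", function(object) object@proteinId)

#' @describeIn FixedMatrix-class Identifier accessor.
#' @export
setMethod("proteinId", "FixedMatrix", function(object) object@proteinId)

#' @describeIn PSSM-class Query sequence spelled by the row residues.
#' @export
setMethod("querySequence", "PSSM",
          function(object) paste(rownames(object@scores), collapse = ""))

#' @describeIn FixedMatrix-class Value matrix accessor.
#' @export
setMethod("fixedValues", "FixedMatrix", function(object) object@values)

#' @describeIn DAEModel-class Per-epoch loss accessor.
#' @export
setMethod("lossHistory", "DAEModel", function(object) object@lossHistory)

#' @describeIn DAEModel-class Latent width (last encoder layer size).
#' @export
setMethod("latentWidth", "DAEModel", function(object) {
  nrow(object@encoderWeights[[length(object@encoderWeights)]])
})

#' @describeIn EvalReport-class Per-fold metric accessor.
#' @export
setMethod("perFoldMetrics", "EvalReport", function(object) object@perFold)

#' @describeIn EvalReport-class Metric mean/sd accessor.
#' @export
setMethod("metricSummary", "EvalReport", function(object) object@metricSummary)

#' @describeIn EvalReport-class ROC point accessor.
#' @export
setMethod("rocPoints", "EvalReport", function(object) object@rocPoints)

setMethod("show", "PSSM", function(object) {
  cat("PSSM for", object@proteinId, "—", nrow(object@scores),
      "positions x 20 amino acids\n")
  cat("  sequence:", substr(querySequence(object), 1, 60),
      if (nrow(object@scores) > 60) "...\n" else "\n")
})

setMethod("show", "FixedMatrix", function(object) {
  cat(sprintf("FixedMatrix (%s%s) for %s: 20 x 20, range [%.3g, %.3g]\n",
              object@method, if (object@scaled) ", scaled" else "",
              object@proteinId, min(object@values), max(object@values)))
})

setMethod("show", "DAEModel", function(object) {
  widths <- vapply(object@encoderWeights, nrow, integer(1))
  cat("Denoising autoencoder: 400 ->", paste(widths, collapse = " -> "),
      "(mirrored decoder)\n")
  lh <- object@lossHistory
  if (length(lh)) {
    cat(sprintf("  trained %d epochs; loss %.4g -> %.4g\n",
                length(lh), lh[1], lh[length(lh)]))
  }
})

setMethod("show", "PPIClassifier", function(object) {
  cat("PPIClassifier kind =", object@kind,
      "| feature width =", object@featureWidth, "\n")
})

setMethod("show", "EvalReport", function(object) {
  cat(nrow(object@perFold), "fold cross-validated evaluation\n")
  s <- object@metricSummary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-4s %.4f +/- %.4f\n", s$metric[i], s$mean[i], s$sd[i]))
  }
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf("SyntheticSpec: %d proteins, %d+/%d- pairs, %d clusters, separation %.2g, seed %d\n",
              object@nProteins, object@nPositive, object@nNegative,
              object@nClusters, object@separation, as.integer(object@seed)))
})
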