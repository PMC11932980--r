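#' Encode input vectors through the trained encoder
#'
#' Applies every encoder layer as \code{sigmoid(W v + b)}. Inference is
#' always on clean (uncorrupted) input.
#'
#' @param model A trained \linkS4class{DAEModel}.
#' @param x Numeric vector of length 400, or a matrix with one input per row.
#' @return Numeric vector (or matrix) of latent activations.
#' @export
setGeneric("encode", function(model, x) standardGeneric("encode"))

#' Decode latent vectors through the decoder
#'
#' Mirror of \code{\link{encode}}: applies every decoder layer as
#' \code{sigmoid(W' y + b')}, producing a reconstruction in (0, 1)^400.
#'
#' @param model A trained \linkS4class{DAEModel}.
#' @param y Numeric latent vector, or a matrix with one latent per row.
#' @return Numeric reconstruction vector (or matrix).
#' @export
setGeneric("decode", function(model, y) standardGeneric("decode"))

#' Extract per-protein latent features
#'
#' @param model A trained \linkS4class{DAEModel}.
#' @param matrices List of scaled \linkS4class{FixedMatrix} objects.
#' @param ... Further arguments for methods.
#' @return Numeric matrix, one row per input matrix (row names = protein
#'   ids), one column per latent dimension.
#' @export
setGeneric("extractFeatures",
           function(model, matrices, ...) standardGeneric("extractFeatures"))

#' Predicted interaction probabilities
#'
#' @param model A fitted \linkS4class{PPIClassifier}.
#' @param X Feature matrix with the training-time column count.
#' @return Numeric vector of probabilities in [0, 1], one per row of \code{X}.
#' @export
setGeneric("predictProba", function(model, X) standardGeneric("predictProba"))

#' @rdname PSSM-class
#' @param object A PSSM (or other package object, for the accessors below).
#' @return \code{pssmScores}: the L x 20 numeric score matrix.
#' @export
setGeneric("pssmScores", function(object) standardGeneric("pssmScores"))

#' @rdname PSSM-class
#' @return \code{proteinId}: the protein identifier.
#' @export
setGeneric("proteinId", function(object) standardGeneric("proteinId"))

#' @rdname PSSM-class
#' @return \code{querySequence}: the residue string spelled by the PSSM rows.
#' @export
setGeneric("querySequence", function(object) standardGeneric("querySequence"))

#' @rdname FixedMatrix-class
#' @param object A FixedMatrix.
#' @return \code{fixedValues}: the 20 x 20 numeric matrix.
#' @export
setGeneric("fixedValues", function(object) standardGeneric("fixedValues"))

#' @rdname DAEModel-class
#' @param object A DAEModel.
#' @return \code{lossHistory}: numeric vector of per-epoch mean losses.
#' @export
setGeneric("lossHistory", function(object) standardGeneric("lossHistory"))

#' @rdname DAEModel-class
#' @return \code{latentWidth}: the latent feature dimension.
#' @export
setGeneric("latentWidth", function(object) standardGeneric("latentWidth"))

#' @rdname EvalReport-class
#' @param object An EvalReport.
#' @return \code{perFoldMetrics}: data frame of per-fold metrics.
#' @export
setGeneric("perFoldMetrics", function(object) standardGeneric("perFoldMetrics"))

#' @rdname EvalReport-class
#' @return \code{metricSummary}: data frame of mean/sd per metric.
#' @export
setGeneric("metricSummary", function(object) standardGeneric("metricSummary"))

#' @rdname EvalReport-class
#' @return \code{rocPoints}: list of per-fold ROC point data frames.
#' @export
setGeneric("rocPoints", function(object) standardGeneric("rocPoints"))
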