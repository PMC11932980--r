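#' @import methods
NULL

#' Canonical amino-acid column order
#'
#' The 20 standard amino acids in the native PSI-BLAST PSSM column order.
#' Every PSSM handled by this package has its columns in this order;
#' files with a permuted header are re-mapped on read.
#'
#' @return Character vector of 20 one-letter amino-acid codes.
#' @export
#' @examples
#' aminoAcidOrder()
aminoAcidOrder <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

## Ambiguity/non-standard letters tolerated on read when explicitly allowed.
.extendedAminoAcids <- function() c("B", "Z", "X", "U", "O", "J", "*")

#' PSSM: a position-specific scoring matrix
#'
#' An L x 20 profile of log-odds scores for one protein, one row per
#' residue and one column per standard amino acid (columns fixed to
#' \code{aminoAcidOrder()}). Row names hold the query residue letters, so
#' the query sequence is recoverable from the object.
#'
#' @slot proteinId Single non-empty identifier without whitespace.
#' @slot scores Numeric L x 20 matrix of log-odds scores; column names are
#'   the canonical amino-acid order, row names the residue letters.
#'
#' @export
setClass("PSSM", representation(proteinId = "character", scores = "matrix"))

setValidity("PSSM", function(object) {
  msg <- character()
  id <- object@proteinId
  if (length(id) != 1L || !nzchar(id)) {
    msg <- c(msg, "proteinId must be a single non-empty string")
  } else if (grepl("\\s", id)) {
    msg <- c(msg, "proteinId must not contain whitespace")
  }
  sc <- object@scores
  if (!is.numeric(sc) || is.null(dim(sc))) {
    msg <- c(msg, "scores must be a numeric matrix")
  } else {
    if (ncol(sc) != 20L) msg <- c(msg, "scores must have exactly 20 columns")
    if (nrow(sc) < 1L) msg <- c(msg, "scores must have at least one row")
    if (!identical(colnames(sc), aminoAcidOrder())) {
      msg <- c(msg, "scores columns must be named in the canonical amino-acid order")
    }
    if (any(!is.finite(sc))) msg <- c(msg, "scores must be finite")
    rn <- rownames(sc)
    if (is.null(rn) || any(nchar(rn) != 1L)) {
      msg <- c(msg, "scores row names must hold one residue letter per position")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PSSM object
#'
#' @param proteinId Protein identifier (no whitespace).
#' @param scores Numeric L x 20 matrix; columns in canonical order (column
#'   names are set if absent), row names the residue letters.
#' @param sequence Optional residue string of length L used to set row
#'   names when \code{scores} has none.
#' @return A \linkS4class{PSSM}.
#' @export
#' @examples
#' PSSM("p1", matrix(0, 3, 20), sequence = "MKV")
PSSM <- function(proteinId, scores, sequence = NULL) {
  scores <- as.matrix(scores)
  storage.mode(scores) <- "double"
  if (is.null(colnames(scores)) && ncol(scores) == 20L) {
    colnames(scores) <- aminoAcidOrder()
  }
  if (!is.null(sequence)) {
    if (nchar(sequence) != nrow(scores)) {
      stop("sequence length (", nchar(sequence), ") does not match score rows (",
           nrow(scores), ")")
    }
    rownames(scores) <- strsplit(toupper(sequence), "")[[1]]
  }
  new("PSSM", proteinId = proteinId, scores = scores)
}

#' FixedMatrix: a 20 x 20 fixed-size protein profile
#'
#' Length-free summary of a PSSM, produced either by the Gram ("equal
#' size", t(P) %*% P) transform or by truncation/zero-padding to the first
#' 20 rows. The equal-size matrix is symmetric positive semi-definite by
#' construction; min-max scaling (see \code{\link{scaleMatrix}}) preserves
#' symmetry but not semidefiniteness, so the PSD validity check applies to
#' unscaled matrices only.
#'
#' @slot proteinId Protein identifier.
#' @slot values Numeric 20 x 20 matrix.
#' @slot method Either \code{"equal_size"} or \code{"zero_pad"}.
#' @slot scaled Logical; \code{TRUE} once entries are min-max scaled to [0, 1].
#'
#' @export
setClass("FixedMatrix",
         representation(proteinId = "character", values = "matrix",
                        method = "character", scaled = "logical"))

setValidity("FixedMatrix", function(object) {
  msg <- character()
  v <- object@values
  if (!is.numeric(v) || !identical(dim(v), c(20L, 20L))) {
    msg <- c(msg, "values must be a numeric 20 x 20 matrix")
    return(msg)
  }
  if (any(!is.finite(v))) msg <- c(msg, "values must be finite")
  if (!object@method %in% c("equal_size", "zero_pad")) {
    msg <- c(msg, "method must be 'equal_size' or 'zero_pad'")
  }
  if (identical(object@method, "equal_size")) {
    if (max(abs(v - t(v))) > 1e-9) {
      msg <- c(msg, "equal_size matrix must be symmetric")
    }
    if (!object@scaled) {
      ev <- eigen(v, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < -1e-8 * max(abs(ev), 1)) {
        msg <- c(msg, "equal_size matrix must be positive semi-definite")
      }
    }
  }
  if (isTRUE(object@scaled) && (min(v) < 0 || max(v) > 1)) {
    msg <- c(msg, "scaled matrix entries must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Configuration of the denoising autoencoder
#'
#' @slot layerSizes Encoder widths, input (400) excluded; the last entry is
#'   the latent feature dimension and must be below 400.
#' @slot noiseSigma Standard deviation of the additive Gaussian corruption
#'   applied to training inputs (0 = plain autoencoder).
#' @slot noiseType \code{"gaussian"} (additive) or \code{"masking"}
#'   (randomly zeroed entries with probability \code{noiseSigma}).
#' @slot epochs,batchSize,learningRate Training hyper-parameters.
#' @slot seed Integer seed controlling weight init, shuffling and noise.
#'
#' @export
setClass("DAEConfig",
         representation(layerSizes = "numeric", noiseSigma = "numeric",
                        noiseType = "character", epochs = "numeric",
                        batchSize = "numeric", learningRate = "numeric",
                        seed = "numeric"))

setValidity("DAEConfig", function(object) {
  msg <- character()
  ls <- object@layerSizes
  if (length(ls) < 1L || any(ls < 1) || any(ls != round(ls))) {
    msg <- c(msg, "layerSizes must be positive integers")
  } else if (ls[length(ls)] >= 400) {
    msg <- c(msg, "last layer size must be < 400 (the model must compress)")
  }
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
  if (!object@noiseType %in% c("gaussian", "masking")) {
    msg <- c(msg, "noiseType must be 'gaussian' or 'masking'")
  }
  if (object@epochs < 1) msg <- c(msg, "epochs must be >= 1")
  if (object@batchSize < 1) msg <- c(msg, "batchSize must be >= 1")
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
  if (length(msg)) msg else TRUE
})

#' @rdname DAEConfig-class
#' @param layerSizes,noiseSigma,noiseType,epochs,batchSize,learningRate,seed
#'   See the class slots.
#' @return A \linkS4class{DAEConfig}.
#' @export
#' @examples
#' DAEConfig(layerSizes = c(64, 16), epochs = 20)
DAEConfig <- function(layerSizes = c(256, 128), noiseSigma = 0.1,
                      noiseType = "gaussian", epochs = 100, batchSize = 64,
                      learningRate = 1e-3, seed = 1L) {
  new("DAEConfig", layerSizes = layerSizes, noiseSigma = noiseSigma,
      noiseType = noiseType, epochs = epochs, batchSize = batchSize,
      learningRate = learningRate, seed = seed)
}

#' Trained denoising-autoencoder model
#'
#' Encoder layers map the flattened 400-entry profile through
#' sigmoid(W v + b) down to the latent width; decoder layers mirror the
#' encoder shapes transposed and reconstruct the 400-entry input.
#'
#' @slot encoderWeights,encoderBiases Per-layer encoder parameters.
#' @slot decoderWeights,decoderBiases Per-layer decoder parameters.
#' @slot config The \linkS4class{DAEConfig} used for training.
#' @slot lossHistory Mean reconstruction loss per epoch.
#'
#' @export
setClass("DAEModel",
         representation(encoderWeights = "list", encoderBiases = "list",
                        decoderWeights = "list", decoderBiases = "list",
                        config = "DAEConfig", lossHistory = "numeric"))

setValidity("DAEModel", function(object) {
  msg <- character()
  ne <- length(object@encoderWeights)
  if (ne != length(object@decoderWeights)) {
    msg <- c(msg, "decoder must mirror encoder layer count")
  } else if (ne > 0) {
    for (i in seq_len(ne)) {
      We <- object@encoderWeights[[i]]
      Wd <- object@decoderWeights[[ne - i + 1L]]
      if (!identical(dim(We), rev(dim(Wd)))) {
        msg <- c(msg, sprintf("decoder layer %d shape must be the transpose of encoder layer %d",
                              ne - i + 1L, i))
      }
      if (nrow(We) != length(object@encoderBiases[[i]])) {
        msg <- c(msg, sprintf("encoder bias %d length must match layer width", i))
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Fitted pair classifier
#'
#' Thin wrapper holding a fitted binary classifier together with its kind
#' and expected feature width, so every classifier exposes the same
#' \code{\link{predictProba}} surface.
#'
#' @slot kind One of \code{"gbdt"}, \code{"nb"}, \code{"lda"},
#'   \code{"svm"}, \code{"dt"}, \code{"knn"}.
#' @slot fit The underlying fitted model object.
#' @slot featureWidth Number of feature columns seen at training time.
#' @slot params Hyper-parameters used.
#'
#' @export
setClass("PPIClassifier",
         representation(kind = "character", fit = "ANY",
                        featureWidth = "integer", params = "list"))

#' Confusion counts for a binary prediction
#'
#' @slot TP,TN,FP,FN Non-negative integer counts partitioning the
#'   evaluated pairs.
#' @export
setClass("ConfusionCounts",
         representation(TP = "integer", TN = "integer",
                        FP = "integer", FN = "integer"))

setValidity("ConfusionCounts", function(object) {
  counts <- c(object@TP, object@TN, object@FP, object@FN)
  if (any(counts < 0)) "counts must be non-negative" else TRUE
})

#' Cross-validated evaluation report
#'
#' @slot perFold Data frame with one row per fold and columns fold, ACC,
#'   PE, SN, MCC, AUC (NaN marks an undefined metric in that fold).
#' @slot metricSummary Data frame with metric, mean and sd columns
#'   (aggregated over folds, skipping undefined values).
#' @slot rocPoints List (one per fold) of data frames with fpr/tpr columns.
#' @slot config Snapshot of the pipeline configuration used.
#' @export
setClass("EvalReport",
         representation(perFold = "data.frame", metricSummary = "data.frame",
                        rocPoints = "list", config = "list"))

setValidity("EvalReport", function(object) {
  msg <- character()
  need <- c("fold", "ACC", "PE", "SN", "MCC", "AUC")
  if (!all(need %in% names(object@perFold))) {
    msg <- c(msg, "perFold must have fold, ACC, PE, SN, MCC, AUC columns")
  }
  if (length(object@rocPoints) != nrow(object@perFold)) {
    msg <- c(msg, "one ROC curve per fold is required")
  }
  if (length(msg)) msg else TRUE
})

#' Synthetic benchmark specification
#'
#' Describes a download-free benchmark emulating curated PPI datasets:
#' proteins carry a latent compatibility vector and a cluster (a stand-in
#' for subcellular localization); positive pairs are sampled within
#' clusters among high-affinity latent pairs, negatives strictly across
#' clusters, and each protein's amino-acid composition is biased by its
#' latent vector with strength \code{separation} so the signal is
#' recoverable from PSSM statistics.
#'
#' @slot nProteins,nPositive,nNegative Dataset sizes.
#' @slot latentDim Latent compatibility dimension.
#' @slot separation Composition signal strength (0 = no signal).
#' @slot nClusters Number of localization-mimic clusters (>= 2).
#' @slot lengthRange Min/max sequence length in residues (min >= 50,
#'   mirroring the usual short-protein filter in curated PPI sets).
#' @slot seed Integer seed; the whole benchmark is a pure function of the
#'   spec.
#' @export
setClass("SyntheticSpec",
         representation(nProteins = "numeric", nPositive = "numeric",
                        nNegative = "numeric", latentDim = "numeric",
                        separation = "numeric", nClusters = "numeric",
                        lengthRange = "numeric", seed = "numeric"))

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  n <- object@nProteins
  if (n < 2) msg <- c(msg, "nProteins must be >= 2")
  if (object@nPositive < 1 || object@nNegative < 1) {
    msg <- c(msg, "pair counts must be positive")
  }
  if (object@nPositive + object@nNegative > n * (n - 1) / 2) {
    msg <- c(msg, "requested pairs exceed the number of distinct unordered pairs")
  }
  if (object@nClusters < 2) msg <- c(msg, "nClusters must be >= 2")
  if (object@latentDim < 1) msg <- c(msg, "latentDim must be >= 1")
  if (object@separation < 0) msg <- c(msg, "separation must be >= 0")
  lr <- object@lengthRange
  if (length(lr) != 2L || lr[1] > lr[2]) {
    msg <- c(msg, "lengthRange must be c(min, max) with min <= max")
  } else if (lr[1] < 50) {
    msg <- c(msg, "minimum sequence length must be >= 50 residues")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname SyntheticSpec-class
#' @param nProteins,nPositive,nNegative,latentDim,separation,nClusters,lengthRange,seed
#'   See the class slots.
#' @return A \linkS4class{SyntheticSpec}.
#' @export
#' @examples
#' syntheticSpec(nProteins = 30, nPositive = 40, nNegative = 40, seed = 1)
syntheticSpec <- function(nProteins, nPositive, nNegative, latentDim = 4,
                          separation = 2.0, nClusters = 3,
                          lengthRange = c(50, 300), seed = 1L) {
  new("SyntheticSpec", nProteins = nProteins, nPositive = nPositive,
      nNegative = nNegative, latentDim = latentDim, separation = separation,
      nClusters = nClusters, lengthRange = lengthRange, seed = seed)
}
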