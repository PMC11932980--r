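#' Numerically stable logistic function
#'
#' @param x Numeric vector or matrix.
#' @return \code{1 / (1 + exp(-x))}, saturating cleanly at 0/1 for large
#'   magnitudes.
#' @export
#' @examples
#' sigmoid(0)      # 0.5
#' sigmoid(1000)   # 1, no overflow
sigmoid <- function(x) {
  out <- x
  pos <- x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  out
}

#' Corrupt an input vector for denoising training
#'
#' Additive Gaussian corruption (the default) adds i.i.d.
#' \eqn{N(0, \sigma^2)} noise; masking corruption zeroes each entry
#' independently with probability \code{noiseSigma}. Draws come from the
#' current R random stream, so callers seed for reproducibility.
#'
#' @param x Numeric vector or matrix (corrupted elementwise).
#' @param noiseSigma Non-negative noise level (sd for gaussian, drop
#'   probability for masking).
#' @param type \code{"gaussian"} or \code{"masking"}.
#' @return Corrupted copy of \code{x}, same shape.
#' @export
corruptInput <- function(x, noiseSigma, type = c("gaussian", "masking")) {
  type <- match.arg(type)
  if (noiseSigma < 0) stop("noiseSigma must be >= 0")
  if (noiseSigma == 0) return(x)
  if (type == "gaussian") {
    x + array(stats::rnorm(length(x), 0, noiseSigma), dim = dim(x) %||% length(x))
  } else {
    if (noiseSigma > 1) stop("masking probability must be <= 1")
    keep <- array(stats::runif(length(x)) >= noiseSigma,
                  dim = dim(x) %||% length(x))
    x * keep
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Squared-error reconstruction loss
#'
#' \eqn{L(x, z) = \lVert x - z \rVert^2}, the per-vector training
#' objective of the autoencoder.
#'
#' @param x,z Numeric vectors of equal length.
#' @return Non-negative scalar; 0 iff \code{x == z}.
#' @export
reconstructionLoss <- function(x, z) {
  if (length(x) != length(z)) {
    stop("length mismatch: ", length(x), " vs ", length(z))
  }
  sum((x - z)^2)
}

## One affine+sigmoid pass of a weight list over a batch matrix (n x in).
.forwardLayers <- function(X, weights, biases) {
  acts <- vector("list", length(weights) + 1L)
  acts[[1L]] <- X
  for (l in seq_along(weights)) {
    Z <- acts[[l]] %*% t(weights[[l]])
    Z <- sweep(Z, 2L, biases[[l]], "+")
    acts[[l + 1L]] <- sigmoid(Z)
  }
  acts
}

.asBatch <- function(x, width, what) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != width) {
    stop(what, " width mismatch: expected ", width, ", got ", ncol(x))
  }
  x
}

#' @describeIn encode Encoder forward pass; vector in, vector out (matrix
#'   in, matrix out).
#' @export
setMethod("encode", "DAEModel", function(model, x) {
  vec <- is.null(dim(x))
  X <- .asBatch(x, ncol(model@encoderWeights[[1L]]), "encoder input")
  acts <- .forwardLayers(X, model@encoderWeights, model@encoderBiases)
  out <- acts[[length(acts)]]
  if (vec) as.vector(out) else out
})

#' @describeIn decode Decoder forward pass, mirror of \code{encode}.
#' @export
setMethod("decode", "DAEModel", function(model, y) {
  vec <- is.null(dim(y))
  Y <- .asBatch(y, ncol(model@decoderWeights[[1L]]), "decoder input")
  acts <- .forwardLayers(Y, model@decoderWeights, model@decoderBiases)
  out <- acts[[length(acts)]]
  if (vec) as.vector(out) else out
})

## Glorot-style uniform init scaled for sigmoid units.
.initLayer <- function(nOut, nIn) {
  lim <- 4 * sqrt(6 / (nIn + nOut))
  matrix(stats::runif(nOut * nIn, -lim, lim), nrow = nOut)
}

#' Train a denoising autoencoder on fixed protein matrices
#'
#' Each scaled 20 x 20 matrix is flattened to a 400-vector; per epoch a
#' fresh corrupted copy of every input is made, and mini-batch gradient
#' descent (Adam) minimizes the mean squared reconstruction error between
#' the clean inputs and the reconstructions of the corrupted inputs. All
#' layers (including the latent) are sigmoid, so inputs must be scaled to
#' [0, 1] (see \code{\link{scaleMatrix}}).
#'
#' @param data List of scaled \linkS4class{FixedMatrix} objects, or a
#'   numeric matrix with one 400-entry row per protein and entries in
#'   [0, 1].
#' @param config A \linkS4class{DAEConfig}; \code{config@seed} fixes
#'   weight initialisation, batch shuffling and noise draws, making
#'   training bit-reproducible.
#' @return A trained \linkS4class{DAEModel} with per-epoch
#'   \code{lossHistory}.
#' @export
trainDAE <- function(data, config = DAEConfig()) {
  stopifnot(is(config, "DAEConfig"))
  if (is.list(data)) {
    if (length(data) == 0L) stop("empty training data")
    X <- t(vapply(data, .flattenFixed, numeric(400)))
    rownames(X) <- vapply(data, proteinId, character(1))
  } else {
    X <- as.matrix(data)
    if (nrow(X) == 0L) stop("empty training data")
    if (ncol(X) != 400L) stop("training rows must have 400 entries")
    if (min(X) < 0 || max(X) > 1) {
      stop("training inputs must be scaled to [0, 1]")
    }
  }

  set.seed(as.integer(config@seed))
  widths <- c(400L, as.integer(config@layerSizes))
  nL <- length(widths) - 1L
  W <- vector("list", nL); b <- vector("list", nL)
  for (l in seq_len(nL)) {
    W[[l]] <- .initLayer(widths[l + 1L], widths[l])
    b[[l]] <- numeric(widths[l + 1L])
  }
  Wd <- vector("list", nL); bd <- vector("list", nL)
  for (l in seq_len(nL)) {  # decoder layer l undoes encoder layer nL - l + 1
    Wd[[l]] <- .initLayer(widths[nL - l + 1L], widths[nL - l + 2L])
    bd[[l]] <- numeric(widths[nL - l + 1L])
  }

  allW <- c(W, Wd); allb <- c(b, bd)
  mW <- lapply(allW, function(w) w * 0); vW <- mW
  mb <- lapply(allb, function(x) x * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; tAdam <- 0
  lr <- config@learningRate

  n <- nrow(X)
  bs <- min(as.integer(config@batchSize), n)
  lossHistory <- numeric(as.integer(config@epochs))

  for (epoch in seq_len(as.integer(config@epochs))) {
    Xn <- corruptInput(X, config@noiseSigma, config@noiseType)
    ord <- sample.int(n)
    epochLoss <- 0; seen <- 0
    for (start in seq(1L, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1L, n)]
      Xb <- X[idx, , drop = FALSE]
      acts <- .forwardLayers(Xn[idx, , drop = FALSE], allW, allb)
      Z <- acts[[length(acts)]]
      m <- length(idx)
      epochLoss <- epochLoss + sum((Xb - Z)^2)
      seen <- seen + m

      # backprop of mean_i ||x_i - z_i||^2 through sigmoid stacks
      delta <- (2 / m) * (Z - Xb) * Z * (1 - Z)
      tAdam <- tAdam + 1
      for (l in rev(seq_along(allW))) {
        gW <- t(delta) %*% acts[[l]]
        gb <- colSums(delta)
        if (l > 1L) {
          A <- acts[[l]]
          delta <- (delta %*% allW[[l]]) * A * (1 - A)
        }
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
        mhW <- mW[[l]] / (1 - beta1^tAdam); vhW <- vW[[l]] / (1 - beta2^tAdam)
        mhb <- mb[[l]] / (1 - beta1^tAdam); vhb <- vb[[l]] / (1 - beta2^tAdam)
        allW[[l]] <- allW[[l]] - lr * mhW / (sqrt(vhW) + eps)
        allb[[l]] <- allb[[l]] - lr * mhb / (sqrt(vhb) + eps)
      }
    }
    lossHistory[epoch] <- epochLoss / seen
  }

  new("DAEModel",
      encoderWeights = allW[seq_len(nL)],
      encoderBiases = allb[seq_len(nL)],
      decoderWeights = allW[nL + seq_len(nL)],
      decoderBiases = allb[nL + seq_len(nL)],
      config = config, lossHistory = lossHistory)
}

#' @describeIn extractFeatures Encode a list of scaled fixed matrices with
#'   clean (uncorrupted) inputs, preserving order; row names are the
#'   protein ids.
#' @export
setMethod("extractFeatures", "DAEModel", function(model, matrices, ...) {
  if (length(matrices) == 0L) stop("no matrices to encode")
  X <- t(vapply(matrices, .flattenFixed, numeric(400)))
  out <- encode(model, X)
  rownames(out) <- vapply(matrices, proteinId, character(1))
  out
})

.daeFormatVersion <- "profileppi-dae-1"

#' Serialize / load a trained autoencoder
#'
#' Models are stored as portable JSON (format version, config, layer
#' shapes, flat weight arrays). \code{loadDAEModel} refuses files written
#' under a different format version.
#'
#' @param model A \linkS4class{DAEModel}.
#' @param path File path.
#' @return \code{saveDAEModel}: \code{path} invisibly;
#'   \code{loadDAEModel}: the restored \linkS4class{DAEModel}.
#' @export
saveDAEModel <- function(model, path) {
  stopifnot(is(model, "DAEModel"))
  cf <- model@config
  payload <- list(
    format = .daeFormatVersion,
    config = list(layerSizes = cf@layerSizes, noiseSigma = cf@noiseSigma,
                  noiseType = cf@noiseType, epochs = cf@epochs,
                  batchSize = cf@batchSize, learningRate = cf@learningRate,
                  seed = cf@seed),
    lossHistory = model@lossHistory,
    encoder = lapply(model@encoderWeights, function(w)
      list(dim = dim(w), values = as.vector(w))),
    encoderBias = model@encoderBiases,
    decoder = lapply(model@decoderWeights, function(w)
      list(dim = dim(w), values = as.vector(w))),
    decoderBias = model@decoderBiases)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveDAEModel
#' @export
loadDAEModel <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, .daeFormatVersion)) {
    stop("unsupported model format version: ",
         payload$format %||% "<missing>")
  }
  remat <- function(lst) {
    lapply(seq_len(nrow_or_len(lst)), function(i) {
      el <- if (is.data.frame(lst)) lst[i, ] else lst[[i]]
      matrix(unlist(el$values), nrow = unlist(el$dim)[1])
    })
  }
  nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
  cf <- payload$config
  config <- DAEConfig(layerSizes = cf$layerSizes, noiseSigma = cf$noiseSigma,
                      noiseType = cf$noiseType, epochs = cf$epochs,
                      batchSize = cf$batchSize, learningRate = cf$learningRate,
                      seed = cf$seed)
  asBias <- function(x) if (is.list(x)) lapply(x, unlist) else list(unlist(x))
  new("DAEModel",
      encoderWeights = remat(payload$encoder),
      encoderBiases = asBias(payload$encoderBias),
      decoderWeights = remat(payload$decoder),
      decoderBiases = asBias(payload$decoderBias),
      config = config,
      lossHistory = as.numeric(payload$lossHistory))
}
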