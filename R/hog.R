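#' Histogram-of-oriented-gradients configuration
#'
#' Standard HOG recipe adapted to a 20 x 20 matrix treated as a grayscale
#' image: square cells of \code{cellSize} pixels (must divide 20), sliding
#' blocks of \code{blockSize} x \code{blockSize} cells with stride one
#' cell, \code{nOrientations} orientation bins over 180 degrees (unsigned)
#' or 360 degrees (signed), L2 normalization per block.
#'
#' @slot cellSize Cell side in pixels (default 5).
#' @slot blockSize Block side in cells (default 2).
#' @slot nOrientations Orientation bins (default 9).
#' @slot signedGradients Use the full 0..360 degree range (default FALSE).
#' @export
setClass("HOGConfig",
         representation(cellSize = "numeric", blockSize = "numeric",
                        nOrientations = "numeric", signedGradients = "logical"))

setValidity("HOGConfig", function(object) {
  msg <- character()
  cs <- object@cellSize
  if (cs < 1 || cs != round(cs) || 20 %% cs != 0) {
    msg <- c(msg, "cellSize must be a positive integer dividing 20")
  } else if (object@blockSize < 1 || object@blockSize > 20 / cs) {
    msg <- c(msg, "blockSize (in cells) must fit within the cell grid")
  }
  if (object@nOrientations < 1) msg <- c(msg, "nOrientations must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @rdname HOGConfig-class
#' @param cellSize,blockSize,nOrientations,signedGradients See slots.
#' @return A \linkS4class{HOGConfig}.
#' @export
HOGConfig <- function(cellSize = 5, blockSize = 2, nOrientations = 9,
                      signedGradients = FALSE) {
  new("HOGConfig", cellSize = cellSize, blockSize = blockSize,
      nOrientations = nOrientations, signedGradients = signedGradients)
}

#' Descriptor length implied by a HOG configuration
#'
#' @param config A \linkS4class{HOGConfig}.
#' @return Integer length of the descriptor \code{\link{hogFeatures}}
#'   produces: \code{nBlocks * blockSize^2 * nOrientations}.
#' @export
hogDescriptorLength <- function(config) {
  nCells <- 20 %/% config@cellSize
  nBlocksSide <- nCells - config@blockSize + 1
  as.integer(nBlocksSide^2 * config@blockSize^2 * config@nOrientations)
}

#' HOG descriptor of a fixed protein matrix
#'
#' Gradients are taken by central differences with edge replication;
#' each pixel's gradient magnitude votes into the orientation bin
#' containing its gradient direction (hard assignment); cell histograms
#' are grouped into overlapping blocks and L2-normalized per block (an
#' all-zero block stays zero, so a constant matrix yields an all-zero
#' descriptor).
#'
#' @param m A scaled 20 x 20 \linkS4class{FixedMatrix}.
#' @param config A \linkS4class{HOGConfig}.
#' @return Numeric descriptor of length
#'   \code{\link{hogDescriptorLength}(config)}.
#' @export
hogFeatures <- function(m, config = HOGConfig()) {
  stopifnot(is(m, "FixedMatrix"), is(config, "HOGConfig"))
  if (!m@scaled) stop("HOG expects a scaled matrix")
  I <- m@values
  n <- nrow(I)

  # central differences, edges replicated
  right <- I[, c(2:n, n)]; left <- I[, c(1, 1:(n - 1))]
  down <- I[c(2:n, n), ]; up <- I[c(1, 1:(n - 1)), ]
  gx <- (right - left) / 2
  gy <- (down - up) / 2
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx) * 180 / pi           # (-180, 180]
  if (config@signedGradients) {
    ang <- (ang + 360) %% 360
    span <- 360
  } else {
    ang <- ang %% 180
    span <- 180
  }
  nb <- as.integer(config@nOrientations)
  bin <- pmin(floor(ang / (span / nb)) + 1L, nb)

  cs <- as.integer(config@cellSize)
  nCells <- n %/% cs
  cellHist <- array(0, dim = c(nCells, nCells, nb))
  cellRow <- (row(I) - 1L) %/% cs + 1L
  cellCol <- (col(I) - 1L) %/% cs + 1L
  for (k in seq_along(I)) {
    if (mag[k] > 0) {
      cellHist[cellRow[k], cellCol[k], bin[k]] <-
        cellHist[cellRow[k], cellCol[k], bin[k]] + mag[k]
    }
  }

  bsz <- as.integer(config@blockSize)
  nBlocksSide <- nCells - bsz + 1L
  out <- numeric(0)
  for (bi in seq_len(nBlocksSide)) {
    for (bj in seq_len(nBlocksSide)) {
      v <- as.vector(cellHist[bi:(bi + bsz - 1L), bj:(bj + bsz - 1L), ,
                              drop = FALSE])
      nv <- sqrt(sum(v^2))
      if (nv > 0) v <- v / nv
      out <- c(out, v)
    }
  }
  out
}

## HOG features for a list of scaled FixedMatrix objects -> matrix with
## protein ids as row names (same shape contract as extractFeatures()).
.hogFeatureMatrix <- function(matrices, config = HOGConfig()) {
  X <- t(vapply(matrices, hogFeatures, numeric(hogDescriptorLength(config)),
                config = config))
  rownames(X) <- vapply(matrices, proteinId, character(1))
  X
}
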