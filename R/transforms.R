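#' Equal-size (Gram) transform of a PSSM
#'
#' Compresses an L x 20 PSSM \eqn{P} into the fixed 20 x 20 matrix
#' \eqn{P^T P}, i.e. \eqn{v_{jk} = \sum_i P_{ij} P_{ik}}. The result is
#' independent of sequence length and of row order, and is symmetric
#' positive semi-definite by construction.
#'
#' @param pssm A \linkS4class{PSSM}.
#' @return An unscaled \linkS4class{FixedMatrix} with
#'   \code{method = "equal_size"}.
#' @export
#' @examples
#' p <- pseudoPSSM("MKVLA", "p1")
#' equalSizeTransform(p)
equalSizeTransform <- function(pssm) {
  stopifnot(is(pssm, "PSSM"))
  sc <- pssmScores(pssm)
  if (nrow(sc) < 1L) stop("empty PSSM")
  v <- crossprod(sc)            # t(P) %*% P
  v <- (v + t(v)) / 2           # kill last-bit asymmetry from BLAS
  dimnames(v) <- NULL
  new("FixedMatrix", proteinId = proteinId(pssm), values = v,
      method = "equal_size", scaled = FALSE)
}

#' Zero-padding / truncation transform of a PSSM
#'
#' Baseline fixed-size transform: proteins longer than 20 residues keep
#' only their N-terminal 20 PSSM rows; shorter proteins are padded with
#' all-zero rows up to 20.
#'
#' @param pssm A \linkS4class{PSSM}.
#' @return An unscaled \linkS4class{FixedMatrix} with
#'   \code{method = "zero_pad"}.
#' @export
zeroPadTransform <- function(pssm) {
  stopifnot(is(pssm, "PSSM"))
  sc <- pssmScores(pssm)
  L <- nrow(sc)
  if (L < 1L) stop("empty PSSM")
  v <- matrix(0, 20L, 20L)
  keep <- min(L, 20L)
  v[seq_len(keep), ] <- sc[seq_len(keep), ]
  new("FixedMatrix", proteinId = proteinId(pssm), values = v,
      method = "zero_pad", scaled = FALSE)
}

#' Min-max scale a fixed matrix to [0, 1]
#'
#' Per-matrix scaling so every entry lies in the sigmoid output range the
#' autoencoder reconstructs into. A constant matrix maps to all 0.5 (the
#' scaling is otherwise undefined).
#'
#' @param m An unscaled \linkS4class{FixedMatrix}.
#' @return The scaled \linkS4class{FixedMatrix} (method preserved).
#' @export
scaleMatrix <- function(m) {
  stopifnot(is(m, "FixedMatrix"))
  if (m@scaled) stop("matrix is already scaled")
  v <- m@values
  if (any(!is.finite(v))) stop("non-finite entries in matrix")
  lo <- min(v); hi <- max(v)
  v <- if (hi > lo) (v - lo) / (hi - lo) else array(0.5, dim(v))
  new("FixedMatrix", proteinId = m@proteinId, values = v,
      method = m@method, scaled = TRUE)
}

## Flatten a scaled FixedMatrix column-major into the 400-vector the
## autoencoder consumes.
.flattenFixed <- function(m) {
  if (!m@scaled) stop("matrix must be scaled before feature extraction")
  as.vector(m@values)
}

## Transform + scale a list of PSSMs with one of the two methods.
.fixedFeatureMatrices <- function(pssms, transform = c("equal_size", "zero_pad")) {
  transform <- match.arg(transform)
  f <- if (transform == "equal_size") equalSizeTransform else zeroPadTransform
  lapply(pssms, function(p) scaleMatrix(f(p)))
}
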