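# Independent oracles and fixture builders shared across tests. All
# oracles are deliberately naive (loops, exhaustive enumeration, closed
# forms) and never call the code paths they check.

# random integer-valued PSSM, entries in [-5, 5]
randomPSSM <- function(L, seed, id = paste0("p", seed)) {
  set.seed(seed)
  seqs <- paste(sample(aminoAcidOrder(), L, replace = TRUE), collapse = "")
  m <- matrix(sample(-5:5, L * 20, replace = TRUE), nrow = L)
  PSSM(id, m, sequence = seqs)
}

# brute-force t(P) %*% P by triple loop
tripleLoopGram <- function(scores) {
  L <- nrow(scores)
  out <- matrix(0, 20, 20)
  for (j in 1:20) for (k in 1:20) {
    acc <- 0
    for (i in seq_len(L)) acc <- acc + scores[i, j] * scores[i, k]
    out[j, k] <- acc
  }
  out
}

# exhaustive AUC: P(score+ > score-) + 0.5 P(equal) over all pos x neg pairs
pairCountAUC <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# MCC as the Pearson (phi) correlation of reconstructed binary vectors
phiFromCounts <- function(TP, TN, FP, FN) {
  truth <- c(rep(1, TP), rep(0, TN), rep(0, FP), rep(1, FN))
  pred <- c(rep(1, TP), rep(0, TN), rep(1, FP), rep(0, FN))
  suppressWarnings(stats::cor(truth, pred))
}

# ordered target statistic by direct prefix counting
prefixCountOTS <- function(categories, labels, permutation, priorP, priorWeight) {
  n <- length(categories)
  out <- numeric(n)
  for (pos in seq_len(n)) {
    i <- permutation[pos]
    s <- 0; cnt <- 0
    if (pos > 1) {
      for (q in seq_len(pos - 1)) {
        j <- permutation[q]
        if (identical(categories[j], categories[i])) {
          s <- s + labels[j]
          cnt <- cnt + 1
        }
      }
    }
    out[i] <- (s + priorWeight * priorP) / (cnt + priorWeight)
  }
  out
}

# affine + logistic forward pass, scalar loops only
affineSigmoidOracle <- function(weights, biases, x) {
  v <- x
  for (l in seq_along(weights)) {
    W <- weights[[l]]; b <- biases[[l]]
    out <- numeric(nrow(W))
    for (r in seq_len(nrow(W))) {
      acc <- b[r]
      for (c in seq_len(ncol(W))) acc <- acc + W[r, c] * v[c]
      out[r] <- 1 / (1 + exp(-acc))
    }
    v <- out
  }
  v
}

# n random scaled equal-size FixedMatrix objects
randomScaledMatrices <- function(n, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    p <- randomPSSM(sample(30:80, 1), seed * 1000 + i,
                    id = sprintf("m%03d", i))
    scaleMatrix(equalSizeTransform(p))
  })
}

# small planted benchmark for harness tests
tinyBenchmark <- function(seed = 5, separation = 2) {
  generateBenchmark(syntheticSpec(nProteins = 40, nPositive = 60,
                                  nNegative = 60, separation = separation,
                                  lengthRange = c(50, 120), seed = seed))
}

# light pipeline config for harness tests (keeps CV runs fast)
lightConfig <- function(extractor = "dae", classifier = "gbdt") {
  pipelineConfig(extractor = extractor, classifier = classifier,
                 daeConfig = DAEConfig(layerSizes = c(64, 32), epochs = 30),
                 classifierParams = list(nrounds = 100))
}

# random hand-built model with independent weights (no training)
makeHandModel <- function(seed, widths = c(8L, 3L)) {
  set.seed(seed)
  sizes <- c(400L, widths)
  nL <- length(widths)
  W <- lapply(seq_len(nL), function(l)
    matrix(rnorm(sizes[l + 1] * sizes[l], 0, 0.3), nrow = sizes[l + 1]))
  b <- lapply(seq_len(nL), function(l) rnorm(sizes[l + 1], 0, 0.1))
  Wd <- lapply(seq_len(nL), function(l)
    matrix(rnorm(sizes[nL - l + 1] * sizes[nL - l + 2], 0, 0.3),
           nrow = sizes[nL - l + 1]))
  bd <- lapply(seq_len(nL), function(l) rnorm(sizes[nL - l + 1], 0, 0.1))
  new("DAEModel", encoderWeights = W, encoderBiases = b,
      decoderWeights = Wd, decoderBiases = bd,
      config = DAEConfig(layerSizes = widths), lossHistory = 1)
}
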