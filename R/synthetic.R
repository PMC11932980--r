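#' Generate a synthetic planted-signal PPI benchmark
#'
#' Builds a download-free stand-in for curated PPI datasets. Each protein
#' gets a cluster (mimicking a subcellular localization) and a latent
#' compatibility vector centred on its cluster; its amino-acid composition
#' is biased by the latent vector through a fixed random projection with
#' strength \code{separation}, so the planted structure is recoverable
#' from pseudo-PSSM row statistics. Positive pairs are drawn from
#' same-cluster pairs with high latent affinity (dot product above the
#' same-cluster median); negative pairs strictly span distinct clusters,
#' mirroring the differing-localization heuristic used to build negative
#' sets. Pairs are unordered, deduplicated and self-pair free. The whole
#' bundle is a pure function of \code{spec} (byte-identical across runs).
#'
#' @param spec A \linkS4class{SyntheticSpec}.
#' @return List with \code{records} (named
#'   \code{\link[Biostrings]{AAStringSet}}), \code{pssms} (named list of
#'   \linkS4class{PSSM}), \code{pairs} (data frame id_a, id_b, label) and
#'   \code{truth} (ground-truth sidecar: latents, clusters, projection —
#'   written for test assertions, never read by the pipeline).
#' @export
#' @examples
#' b <- generateBenchmark(syntheticSpec(30, 40, 40, seed = 7))
#' head(b$pairs)
generateBenchmark <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  set.seed(as.integer(spec@seed))
  n <- as.integer(spec@nProteins)
  d <- as.integer(spec@latentDim)
  nC <- as.integer(spec@nClusters)
  aa <- aminoAcidOrder()

  ids <- sprintf("prot%04d", seq_len(n))
  clusters <- sample(rep_len(seq_len(nC), n))
  centers <- matrix(stats::rnorm(nC * d), nrow = nC)
  latents <- centers[clusters, , drop = FALSE] +
    0.35 * matrix(stats::rnorm(n * d), nrow = n)
  rownames(latents) <- ids
  projection <- matrix(stats::rnorm(20 * d), nrow = 20) / sqrt(d)

  lens <- sample(seq(spec@lengthRange[1], spec@lengthRange[2]), n,
                 replace = TRUE)
  protSeeds <- sample.int(.Machine$integer.max - 1L, n)
  seqs <- character(n)
  pssms <- vector("list", n)
  for (i in seq_len(n)) {
    logits <- spec@separation * as.vector(projection %*% latents[i, ])
    probs <- exp(logits - max(logits))
    probs <- probs / sum(probs)
    seqs[i] <- paste(sample(aa, lens[i], replace = TRUE, prob = probs),
                     collapse = "")
    pssms[[i]] <- pseudoPSSM(seqs[i], ids[i], seed = protSeeds[i])
  }
  names(pssms) <- ids
  records <- Biostrings::AAStringSet(seqs)
  names(records) <- ids

  # candidate same-cluster pairs, ranked by latent affinity
  allPairs <- utils::combn(n, 2)
  sameCluster <- clusters[allPairs[1, ]] == clusters[allPairs[2, ]]
  affinity <- rowSums(latents[allPairs[1, ], , drop = FALSE] *
                      latents[allPairs[2, ], , drop = FALSE])
  posCand <- which(sameCluster & affinity >= stats::median(affinity[sameCluster]))
  negCand <- which(!sameCluster)
  nPos <- as.integer(spec@nPositive)
  nNeg <- as.integer(spec@nNegative)
  if (length(posCand) < nPos) {
    # small benchmarks: widen the pool to the top-affinity same-cluster
    # pairs so "high affinity" still holds as far as the counts allow
    sc <- which(sameCluster)
    if (length(sc) < nPos) {
      stop("infeasible: only ", length(sc),
           " same-cluster pairs available for ", nPos, " positives")
    }
    posCand <- sc[order(affinity[sc], decreasing = TRUE)][seq_len(nPos)]
  }
  if (length(negCand) < nNeg) {
    stop("infeasible: only ", length(negCand),
         " cross-cluster pairs available for ", nNeg, " negatives")
  }
  posIdx <- sample(posCand, nPos)

  # Degree-balanced negative sampling: draw cross-cluster pairs with
  # probability tilted toward proteins whose positive degree is not yet
  # matched by their negative degree. Without this, high-affinity proteins
  # appear mostly in positives and a classifier can score above chance by
  # memorizing per-protein label bias even when separation = 0.
  posDeg <- tabulate(c(allPairs[1, posIdx], allPairs[2, posIdx]), nbins = n)
  need <- as.numeric(posDeg)
  negIdx <- integer(nNeg)
  avail <- negCand
  for (t in seq_len(nNeg)) {
    w <- (pmax(need[allPairs[1, avail]], 0) + 0.1) *
         (pmax(need[allPairs[2, avail]], 0) + 0.1)
    pick <- avail[sample.int(length(avail), 1L, prob = w)]
    negIdx[t] <- pick
    avail <- avail[avail != pick]
    need[allPairs[1, pick]] <- need[allPairs[1, pick]] - 1
    need[allPairs[2, pick]] <- need[allPairs[2, pick]] - 1
  }
  pairIdx <- c(posIdx, negIdx)
  pairs <- data.frame(
    id_a = ids[allPairs[1, pairIdx]],
    id_b = ids[allPairs[2, pairIdx]],
    label = rep(c(1L, 0L), c(nPos, nNeg)),
    stringsAsFactors = FALSE)

  list(records = records, pssms = pssms, pairs = pairs,
       truth = list(clusters = stats::setNames(clusters, ids),
                    latents = latents, projection = projection,
                    separation = spec@separation,
                    seed = as.integer(spec@seed)))
}

#' Write a synthetic benchmark bundle to disk
#'
#' Emits \code{proteins.fasta}, one ASCII PSSM file per protein
#' (\code{<id>.pssm}), \code{pairs.tsv} (columns id_a, id_b, label) and
#' the ground-truth sidecar \code{truth.json} (synthetic latents and
#' clusters; for assertions only — the pipeline never reads it). All
#' files round-trip through the package's own readers.
#'
#' @param bundle A bundle from \code{\link{generateBenchmark}}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeBenchmark <- function(bundle, dir) {
  if (is.null(bundle$records) || length(bundle$records) == 0L) {
    stop("empty benchmark bundle")
  }
  ok <- dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  Biostrings::writeXStringSet(bundle$records, file.path(dir, "proteins.fasta"))
  for (id in names(bundle$pssms)) {
    writePSSM(bundle$pssms[[id]], file.path(dir, paste0(id, ".pssm")))
  }
  utils::write.table(bundle$pairs, file.path(dir, "pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$truth)) {
    tr <- bundle$truth
    jsonlite::write_json(
      list(clusters = as.list(tr$clusters),
           latents = apply(tr$latents, 1, identity, simplify = FALSE),
           separation = tr$separation, seed = tr$seed),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a benchmark bundle written by \code{\link{writeBenchmark}}
#'
#' @param dir Directory holding \code{proteins.fasta}, \code{pairs.tsv}
#'   and one \code{<id>.pssm} per protein.
#' @return List with \code{records}, \code{pssms} and \code{pairs} (the
#'   ground-truth sidecar is deliberately not loaded here).
#' @export
readBenchmark <- function(dir) {
  records <- readFastaProteins(file.path(dir, "proteins.fasta"))
  pssms <- lapply(names(records), function(id) {
    parsePSSM(file.path(dir, paste0(id, ".pssm")), proteinId = id)
  })
  names(pssms) <- names(records)
  pairs <- utils::read.table(file.path(dir, "pairs.tsv"), header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE,
                             colClasses = c("character", "character", "integer"))
  list(records = records, pssms = pssms, pairs = pairs)
}
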