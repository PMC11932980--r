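## Package-local cache (default substitution table).
.pkgCache <- new.env(parent = emptyenv())

#' Read protein sequences from a FASTA file
#'
#' Reads a multi-record FASTA file (wrapped or unwrapped lines) into an
#' \code{\link[Biostrings]{AAStringSet}}. Record identifiers are the first
#' whitespace-delimited token of each header; sequences are uppercased.
#' Ambiguity letters (B, Z, X, U, O, J) are tolerated and flagged with a
#' warning; anything outside the extended amino-acid alphabet is an error.
#'
#' @param path Path to a FASTA file.
#' @return A named \code{AAStringSet}, one entry per record, in file order.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1", "MKV", ">p2", "ARND"), fa)
#' readFastaProteins(fa)
readFastaProteins <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0) stop("FASTA file is empty: ", path)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("FASTA file contains no records: ", path)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  if (any(!nzchar(ids) | is.na(ids))) stop("FASTA record with empty identifier")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate FASTA identifiers: ", paste(dup, collapse = ", "))
  }
  chars <- toupper(as.character(seqs))
  if (any(nchar(chars) == 0)) {
    stop("empty sequence for record(s): ",
         paste(ids[nchar(chars) == 0], collapse = ", "))
  }
  legal <- c(aminoAcidOrder(), .extendedAminoAcids())
  lets <- strsplit(chars, "")
  bad <- lapply(lets, function(x) setdiff(unique(x), legal))
  if (any(lengths(bad) > 0)) {
    off <- sort(unique(unlist(bad)))
    stop("sequence characters outside the extended amino-acid alphabet: ",
         paste(off, collapse = ", "))
  }
  ambiguous <- vapply(lets, function(x) any(x %in% .extendedAminoAcids()), logical(1))
  if (any(ambiguous)) {
    warning("non-standard amino-acid letters in record(s): ",
            paste(ids[ambiguous], collapse = ", "))
  }
  out <- Biostrings::AAStringSet(chars)
  names(out) <- ids
  out
}

#' Parse a PSI-BLAST ASCII PSSM file
#'
#' Reads the dialect emitted by PSI-BLAST's \code{-out_ascii_pssm} option:
#' header lines, a column-header row of amino-acid letters (20 for the
#' log-odds block, repeated for the percentage block), then one row per
#' residue holding the position, the residue letter, 20 integer log-odds
#' scores, 20 weighted-percentage columns and two trailing per-position
#' statistics. Only the first (log-odds) block is retained. Files whose
#' header permutes the amino-acid order are re-mapped to the canonical
#' order of \code{aminoAcidOrder()}.
#'
#' @param path Path to the PSSM file.
#' @param proteinId Identifier for the resulting object; defaults to the
#'   file name without extension.
#' @return A \linkS4class{PSSM}.
#' @export
parsePSSM <- function(path, proteinId = NULL) {
  if (!file.exists(path)) stop("PSSM file not found: ", path)
  if (is.null(proteinId)) {
    proteinId <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path, warn = FALSE)
  std <- aminoAcidOrder()

  headerAt <- NA_integer_
  headerLetters <- NULL
  for (i in seq_along(lines)) {
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(toks) %in% c(20L, 40L) && all(nchar(toks) == 1L) &&
        all(toks %in% LETTERS)) {
      headerAt <- i
      headerLetters <- toks
      break
    }
  }
  if (is.na(headerAt)) stop("no amino-acid column header found in ", path)
  block1 <- headerLetters[seq_len(20L)]
  if (!setequal(block1, std) || anyDuplicated(block1)) {
    stop("PSSM column header is not a permutation of the 20 standard amino acids")
  }
  nTok <- if (length(headerLetters) == 40L) 44L else 22L

  scores <- list()
  residues <- character()
  started <- FALSE
  for (i in seq((headerAt + 1L), length(lines))) {
    if (i > length(lines)) break
    ln <- trimws(lines[i])
    if (!grepl("^[0-9]+\\s", ln)) {
      if (started) break else next
    }
    started <- TRUE
    toks <- strsplit(ln, "\\s+")[[1]]
    if (length(toks) != nTok) {
      stop("malformed PSSM row at line ", i, ": expected ", nTok,
           " fields, found ", length(toks))
    }
    vals <- suppressWarnings(as.numeric(toks[3:22]))
    if (any(is.na(vals))) {
      stop("non-numeric log-odds score at line ", i)
    }
    scores[[length(scores) + 1L]] <- vals
    residues <- c(residues, toks[2L])
  }
  if (length(scores) == 0L) stop("no PSSM rows found in ", path)
  m <- do.call(rbind, scores)
  colnames(m) <- block1
  m <- m[, std, drop = FALSE]  # re-map any permuted header to canonical order
  rownames(m) <- residues
  new("PSSM", proteinId = proteinId, scores = m)
}

#' Write a PSSM as a PSI-BLAST style ASCII file
#'
#' Emits the \code{-out_ascii_pssm} dialect that \code{\link{parsePSSM}}
#' reads back bit-exactly (ASCII log-odds are integers, so the scores must
#' be integer-valued). The weighted-percentage block is written as zeros;
#' only the log-odds block is meaningful for this package.
#'
#' @param pssm A \linkS4class{PSSM} with integer-valued scores.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
writePSSM <- function(pssm, path) {
  stopifnot(is(pssm, "PSSM"))
  sc <- pssmScores(pssm)
  if (any(sc != round(sc))) {
    stop("ASCII PSSM stores integer log-odds; scores must be integer-valued")
  }
  std <- aminoAcidOrder()
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("", con)
  writeLines(paste("Last position-specific scoring matrix computed,",
                   "weighted observed percentages rounded down,",
                   "information per position, and relative weight of",
                   "gapless real matches to pseudocounts"), con)
  writeLines(paste0("          ",
                    paste(sprintf("%3s", c(std, std)), collapse = " ")), con)
  res <- rownames(sc)
  for (i in seq_len(nrow(sc))) {
    writeLines(paste0(sprintf("%5d %s  ", i, res[i]),
                      paste(sprintf("%3d", as.integer(round(sc[i, ]))), collapse = " "),
                      " ",
                      paste(sprintf("%3d", integer(20)), collapse = " "),
                      "  0.00 0.00"), con)
  }
  writeLines("", con)
  writeLines("                      K         Lambda", con)
  writeLines("Standard Ungapped    0.1337     0.3176", con)
  invisible(path)
}

#' Default amino-acid substitution table
#'
#' The BLOSUM62 log-odds matrix restricted to the 20 standard amino acids,
#' rows and columns in the canonical PSI-BLAST order. Used as the
#' deterministic backbone for \code{\link{pseudoPSSM}}.
#'
#' @return Numeric 20 x 20 matrix.
#' @export
defaultSubstitutionTable <- function() {
  if (is.null(.pkgCache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkgCache$blosum62 <- e$BLOSUM62[aminoAcidOrder(), aminoAcidOrder()]
  }
  .pkgCache$blosum62
}

#' Generate a pseudo-PSSM from a sequence
#'
#' Database-free stand-in for a PSI-BLAST profile: row \eqn{i} of the
#' result is the substitution-table row of residue \eqn{i}, optionally
#' perturbed by integer-rounded Gaussian noise (reproducible given
#' \code{seed}). The result carries the sequence's composition signal into
#' PSSM row statistics without any homology search.
#'
#' @param sequence Amino-acid sequence string.
#' @param proteinId Identifier for the resulting PSSM.
#' @param substitutionTable 20 x 20 table indexed by the canonical
#'   amino-acid order; defaults to \code{\link{defaultSubstitutionTable}}.
#' @param seed Integer seed for the perturbations, or \code{NULL} for the
#'   deterministic noise-free profile.
#' @param noiseSd Standard deviation of the Gaussian perturbation before
#'   rounding (ignored when \code{seed} is \code{NULL}).
#' @param allowAmbiguous If \code{TRUE}, ambiguity letters (B, Z, X, U, O,
#'   J) map to an all-zero row instead of raising an error.
#' @return A \linkS4class{PSSM} with integer-valued scores.
#' @export
#' @examples
#' pseudoPSSM("MKV", "p1")
pseudoPSSM <- function(sequence, proteinId,
                       substitutionTable = defaultSubstitutionTable(),
                       seed = NULL, noiseSd = 1, allowAmbiguous = FALSE) {
  std <- aminoAcidOrder()
  if (!identical(rownames(substitutionTable)[seq_len(20)], std) ||
      !identical(colnames(substitutionTable)[seq_len(20)], std)) {
    stop("substitutionTable must be indexed by the canonical amino-acid order")
  }
  lets <- strsplit(toupper(sequence), "")[[1]]
  if (length(lets) == 0L) stop("empty sequence")
  m <- matrix(0, nrow = length(lets), ncol = 20L,
              dimnames = list(lets, std))
  for (i in seq_along(lets)) {
    a <- lets[i]
    if (a %in% std) {
      m[i, ] <- as.numeric(substitutionTable[a, std])
    } else if (allowAmbiguous && a %in% .extendedAminoAcids()) {
      m[i, ] <- 0  # ambiguity letters carry no profile information
    } else {
      stop("residue '", a, "' at position ", i,
           " is not a standard amino acid")
    }
  }
  if (!is.null(seed)) {
    set.seed(as.integer(seed))
    m <- m + matrix(round(stats::rnorm(length(m), 0, noiseSd)),
                    nrow = nrow(m))
    dimnames(m) <- list(lets, std)
  }
  new("PSSM", proteinId = proteinId, scores = m)
}
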