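test_that("FASTA reading preserves records, order and case", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1 some description", "MKV", ">p2", "arnd", "cqeg"), fa)
  recs <- readFastaProteins(fa)
  expect_length(recs, 2)
  expect_identical(names(recs), c("p1", "p2"))
  expect_identical(as.character(recs[["p1"]]), "MKV")
  expect_identical(as.character(recs[["p2"]]), "ARNDCQEG")  # wrapped + uppercased
})

test_that("FASTA contract violations raise informative errors", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1", "MKV", ">p1", "ARN"), fa)
  expect_error(readFastaProteins(fa), "p1")

  writeLines(c(">q1", "MK8V"), fa)
  expect_error(readFastaProteins(fa), "8")

  writeLines(character(), fa)
  expect_error(readFastaProteins(fa), "empty")
})

test_that("ambiguity letters are tolerated but flagged", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1", "MKXV"), fa)
  expect_warning(recs <- readFastaProteins(fa), "p1")
  expect_identical(as.character(recs[[1]]), "MKXV")
})

test_that("ASCII PSSM writer output is re-read bit-exactly", {
  f <- withr::local_tempfile(fileext = ".pssm")
  p <- randomPSSM(3, seed = 11, id = "fix1")
  writePSSM(p, f)
  q <- parsePSSM(f, proteinId = "fix1")
  expect_identical(pssmScores(q), pssmScores(p))
  expect_identical(querySequence(q), querySequence(p))
  expect_equal(nrow(pssmScores(q)), 3)
  expect_equal(ncol(pssmScores(q)), 20)
})

test_that("round-trip identity holds over many random PSSMs", {
  f <- withr::local_tempfile(fileext = ".pssm")
  for (i in 1:100) {
    p <- randomPSSM(sample(1:60, 1), seed = 7000 + i)
    writePSSM(p, f)
    expect_identical(pssmScores(parsePSSM(f, proteinId(p))), pssmScores(p))
  }
})

test_that("malformed PSSM rows are rejected with the line number", {
  f <- withr::local_tempfile(fileext = ".pssm")
  p <- randomPSSM(4, seed = 3)
  writePSSM(p, f)
  lines <- readLines(f)
  rowAt <- grep("^\\s*2\\s", lines)[1]
  lines[rowAt] <- substr(lines[rowAt], 1, 40)  # truncate a data row
  writeLines(lines, f)
  expect_error(parsePSSM(f), as.character(rowAt))
})

test_that("a permuted column header is re-mapped to canonical order", {
  f <- withr::local_tempfile(fileext = ".pssm")
  p <- randomPSSM(5, seed = 9)
  writePSSM(p, f)
  lines <- readLines(f)
  std <- aminoAcidOrder()
  perm <- c(20:1)
  hdrAt <- 3
  lines[hdrAt] <- paste0("          ",
                         paste(sprintf("%3s", c(std[perm], std[perm])),
                               collapse = " "))
  # permute the score columns consistently so content is unchanged
  sc <- pssmScores(p)[, perm, drop = FALSE]
  rowsAt <- grep("^\\s*[0-9]+\\s", lines)
  for (i in seq_along(rowsAt)) {
    lines[rowsAt[i]] <- paste0(sprintf("%5d %s  ", i, rownames(pssmScores(p))[i]),
                               paste(sprintf("%3d", as.integer(sc[i, ])), collapse = " "),
                               " ", paste(sprintf("%3d", integer(20)), collapse = " "),
                               "  0.00 0.00")
  }
  writeLines(lines, f)
  q <- parsePSSM(f, "perm")
  expect_identical(unname(pssmScores(q)), unname(pssmScores(p)))

  # header that is not a permutation of the standards is an error
  lines[hdrAt] <- paste0("          ",
                         paste(sprintf("%3s", rep(c(std[1:19], "A"), 2)),
                               collapse = " "))
  writeLines(lines, f)
  expect_error(parsePSSM(f), "permutation")
})

test_that("pseudo-PSSM rows are substitution-table lookups", {
  idTab <- diag(20)
  dimnames(idTab) <- list(aminoAcidOrder(), aminoAcidOrder())
  p <- pseudoPSSM("AA", "pA", substitutionTable = idTab)
  expect_equal(unname(pssmScores(p)),
               matrix(rep(c(1, rep(0, 19)), 2), nrow = 2, byrow = TRUE))

  b62 <- defaultSubstitutionTable()
  q <- pseudoPSSM("ARN", "pq")
  expect_equal(unname(pssmScores(q)),
               unname(rbind(b62["A", ], b62["R", ], b62["N", ])))
})

test_that("pseudo-PSSM perturbations are seed-reproducible and shape-safe", {
  a <- pseudoPSSM("MKVLH", "x", seed = 42)
  b <- pseudoPSSM("MKVLH", "x", seed = 42)
  expect_identical(pssmScores(a), pssmScores(b))
  expect_false(identical(pssmScores(a),
                         pssmScores(pseudoPSSM("MKVLH", "x", seed = 43))))

  for (L in c(1, 5, 37)) {
    s <- paste(sample(aminoAcidOrder(), L, replace = TRUE), collapse = "")
    p <- pseudoPSSM(s, "len", seed = L)
    expect_equal(dim(pssmScores(p)), c(L, 20))
  }
})

test_that("pseudo-PSSM rejects or maps non-standard residues as configured", {
  expect_error(pseudoPSSM("MXV", "p"), "position 2")
  expect_error(pseudoPSSM("MXV", "p"), "X")
  p <- pseudoPSSM("MXV", "p", allowAmbiguous = TRUE)
  expect_equal(unname(pssmScores(p)[2, ]), rep(0, 20))
})
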