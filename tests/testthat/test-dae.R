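test_that("sigmoid matches the closed form and is stable at extremes", {
  expect_equal(sigmoid(0), 0.5)
  expect_equal(sigmoid(1), 0.7310585786, tolerance = 1e-9)
  for (x in c(0.5, 2, 10)) {
    expect_equal(sigmoid(-x), 1 - sigmoid(x), tolerance = 1e-12)
  }
  expect_equal(sigmoid(1000), 1)
  expect_equal(sigmoid(-1000), 0)
  expect_true(all(is.finite(sigmoid(c(-1e3, 1e3)))))
})

test_that("corruption is the identity at zero noise and seed-reproducible", {
  x <- runif(50)
  expect_identical(corruptInput(x, 0), x)

  set.seed(31); a <- corruptInput(x, 0.2)
  set.seed(31); b <- corruptInput(x, 0.2)
  expect_identical(a, b)
  expect_error(corruptInput(x, -0.1), ">= 0")

  # law of large numbers: additive noise has the requested moments
  set.seed(8)
  big <- corruptInput(numeric(10000), 0.1)
  expect_lt(abs(mean(big)), 0.005)
  expect_lt(abs(sd(big) - 0.1), 0.01)

  # masking corruption zeroes approximately the requested fraction
  set.seed(9)
  masked <- corruptInput(rep(1, 10000), 0.3, type = "masking")
  expect_lt(abs(mean(masked == 0) - 0.3), 0.02)
})

test_that("reconstruction loss is the squared Euclidean distance", {
  expect_equal(reconstructionLoss(c(1, 2), c(1, 2)), 0)
  expect_equal(reconstructionLoss(c(1, 0), c(0, 1)), 2)
  set.seed(4)
  x <- rnorm(30); z <- rnorm(30)
  acc <- 0
  for (i in seq_along(x)) acc <- acc + (x[i] - z[i])^2
  expect_equal(reconstructionLoss(x, z), acc, tolerance = 1e-12)
  expect_error(reconstructionLoss(1:3, 1:4), "mismatch")
})


test_that("encode/decode agree with an elementwise affine+sigmoid oracle", {
  for (seed in 1:5) {
    m <- makeHandModel(seed)
    x <- runif(400)
    expect_equal(encode(m, x),
                 affineSigmoidOracle(m@encoderWeights, m@encoderBiases, x),
                 tolerance = 1e-10)
    y <- runif(latentWidth(m))
    expect_equal(decode(m, y),
                 affineSigmoidOracle(m@decoderWeights, m@decoderBiases, y),
                 tolerance = 1e-10)
  }
})

test_that("encoder saturates as the affine map dictates", {
  m <- makeHandModel(1, widths = c(6L))
  m@encoderWeights[[1]][] <- 0
  m@encoderBiases[[1]][] <- 0
  expect_equal(encode(m, runif(400)), rep(0.5, 6))
  m@encoderBiases[[1]][] <- 50
  expect_equal(encode(m, runif(400)), rep(1, 6), tolerance = 1e-12)
  expect_error(encode(m, runif(10)), "width mismatch")
  expect_error(decode(m, runif(10)), "width mismatch")
})

test_that("training reduces the reconstruction loss and is deterministic", {
  mats <- randomScaledMatrices(60, seed = 2)
  cfg <- DAEConfig(layerSizes = c(32, 8), epochs = 30, batchSize = 16,
                   learningRate = 2e-3, seed = 7)
  m1 <- trainDAE(mats, cfg)
  lh <- lossHistory(m1)
  expect_length(lh, 30)
  expect_lt(lh[length(lh)], lh[1])
  expect_lt(mean(tail(lh, 10)), mean(head(lh, 10)))

  m2 <- trainDAE(mats, cfg)
  expect_identical(lossHistory(m2), lh)
  expect_identical(extractFeatures(m2, mats), extractFeatures(m1, mats))
})

test_that("a noise-free autoencoder reconstructs rank-limited data", {
  set.seed(1)
  U <- matrix(runif(400 * 4), 400, 4)
  C <- matrix(runif(4 * 200), 4, 200)
  X <- t(U %*% C)
  X <- (X - min(X)) / (max(X) - min(X))
  m <- trainDAE(X, DAEConfig(layerSizes = c(64, 16), noiseSigma = 0,
                             epochs = 300, batchSize = 32,
                             learningRate = 2e-3, seed = 7))
  Z <- decode(m, encode(m, X))
  expect_lt(mean((X - Z)^2), 0.01)
})

test_that("feature extraction encodes clean inputs in order", {
  mats <- randomScaledMatrices(12, seed = 6)
  m <- trainDAE(mats, DAEConfig(layerSizes = c(16, 4), epochs = 10, seed = 1))
  F1 <- extractFeatures(m, mats)
  expect_equal(dim(F1), c(12, 4))
  expect_identical(rownames(F1), vapply(mats, proteinId, character(1)))
  # equals encode applied one matrix at a time
  for (i in c(1, 5, 12)) {
    expect_equal(unname(F1[i, ]),
                 encode(m, as.vector(fixedValues(mats[[i]]))),
                 tolerance = 1e-12)
  }
  # identical matrices give identical features
  expect_identical(unname(extractFeatures(m, mats[c(3, 3)])[1, ]),
                   unname(extractFeatures(m, mats[c(3, 3)])[2, ]))
  # unscaled input is refused
  raw <- equalSizeTransform(randomPSSM(25, seed = 3))
  expect_error(extractFeatures(m, list(raw)), "scaled")
})

test_that("model serialization round-trips and rejects foreign versions", {
  mats <- randomScaledMatrices(10, seed = 8)
  m <- trainDAE(mats, DAEConfig(layerSizes = c(12, 5), epochs = 5, seed = 2))
  f <- withr::local_tempfile(fileext = ".json")
  saveDAEModel(m, f)
  m2 <- loadDAEModel(f)
  x <- runif(400)
  expect_equal(encode(m2, x), encode(m, x), tolerance = 1e-12)
  expect_equal(lossHistory(m2), lossHistory(m))

  payload <- jsonlite::read_json(f)
  payload$format <- "somebody-elses-format"
  jsonlite::write_json(payload, f, auto_unbox = TRUE)
  expect_error(loadDAEModel(f), "format version")
})
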