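#' Resolve a pipeline run configuration
#'
#' Merges package defaults, an optional YAML configuration file, and
#' flat overrides (e.g. command-line flags), in that order of precedence.
#' Enumerated fields are validated with messages naming the field and the
#' valid choices. Used by the command-line entry point
#' (\code{system.file("scripts", "profileppi.R", package = "ProfilePPI")})
#' but callable directly.
#'
#' @param configFile Optional path to a YAML file with any of the fields
#'   below (requires the \pkg{yaml} package).
#' @param overrides Named list of overrides; \code{NULL} entries are
#'   ignored. Recognised fields: \code{transform}, \code{extractor},
#'   \code{classifier}, \code{cvFolds}, \code{seed}, and nested
#'   \code{dae}/\code{hog} lists of hyper-parameters.
#' @return Named list with the resolved fields plus ready-built
#'   \code{daeConfig} and \code{hogConfig} objects.
#' @export
resolveRunConfig <- function(configFile = NULL, overrides = list()) {
  cfg <- list(
    transform = "equal_size", extractor = "dae", classifier = "gbdt",
    cvFolds = 5L, seed = 1L,
    dae = list(layerSizes = c(256, 128), noiseSigma = 0.1,
               noiseType = "gaussian", epochs = 100, batchSize = 64,
               learningRate = 1e-3),
    hog = list(cellSize = 5, blockSize = 2, nOrientations = 9,
               signedGradients = FALSE))

  mergeInto <- function(base, upd) {
    for (nm in names(upd)) {
      if (is.null(upd[[nm]])) next
      if (is.list(upd[[nm]]) && is.list(base[[nm]])) {
        base[[nm]] <- mergeInto(base[[nm]], upd[[nm]])
      } else {
        base[[nm]] <- upd[[nm]]
      }
    }
    base
  }
  if (!is.null(configFile)) {
    if (!file.exists(configFile)) stop("config file not found: ", configFile)
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required to read config files")
    }
    cfg <- mergeInto(cfg, yaml::read_yaml(configFile))
  }
  cfg <- mergeInto(cfg, overrides)

  checkEnum <- function(value, field, choices) {
    if (!value %in% choices) {
      stop("invalid ", field, " '", value, "'; valid choices: ",
           paste(choices, collapse = ", "))
    }
    value
  }
  cfg$transform <- checkEnum(cfg$transform, "transform",
                             c("equal_size", "zero_pad"))
  cfg$extractor <- checkEnum(cfg$extractor, "extractor",
                             c("dae", "hog", "none"))
  cfg$classifier <- checkEnum(cfg$classifier, "classifier", .classifierKinds)
  if (cfg$cvFolds < 2) stop("cvFolds must be >= 2")
  cfg$seed <- as.integer(cfg$seed)

  cfg$daeConfig <- DAEConfig(layerSizes = cfg$dae$layerSizes,
                             noiseSigma = cfg$dae$noiseSigma,
                             noiseType = cfg$dae$noiseType %||% "gaussian",
                             epochs = cfg$dae$epochs,
                             batchSize = cfg$dae$batchSize,
                             learningRate = cfg$dae$learningRate,
                             seed = cfg$seed)
  cfg$hogConfig <- HOGConfig(cellSize = cfg$hog$cellSize,
                             blockSize = cfg$hog$blockSize,
                             nOrientations = cfg$hog$nOrientations,
                             signedGradients = isTRUE(cfg$hog$signedGradients))
  cfg
}
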