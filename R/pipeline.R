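#' @include io.R
NULL

.defaultConfig <- function() {
  list(
    seed = 1L,
    model = list(type = "tuned", n_neurons = 16, base_mean = 2,
                 class_separation = 0.5, tuning_amplitude = 0.3,
                 noise_sd = 0.1, shared_gain_sd = 0, event_rate = 0.5),
    tasks = c("classes", "directions"),
    decoder = list(classifier = "svm"),
    scaling = list(enabled = FALSE, n_resamples = 10),
    synergy = list(enabled = FALSE, n_replicates = 10, n_shuffles = 10),
    selectivity = list(enabled = TRUE),
    out_dir = NULL)
}

.mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- .mergeConfig(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read a pipeline configuration
#'
#' Loads a YAML configuration and fills unset fields with defaults. See
#' \code{\link{runPipeline}} for the recognized fields.
#'
#' @param path YAML file path.
#' @return Configuration list.
#' @export
readPipelineConfig <- function(path) {
  .mergeConfig(.defaultConfig(), yaml::read_yaml(path))
}

.modelFromConfig <- function(cfg) {
  m <- cfg$model
  if (identical(m$type, "label_independent"))
    labelIndependentModel(m$n_neurons, baseMean = m$base_mean,
                          noiseSd = m$noise_sd,
                          sharedGainSd = m$shared_gain_sd,
                          eventRate = m$event_rate)
  else
    tunedPopulationModel(m$n_neurons, seed = cfg$seed,
                         baseMean = m$base_mean,
                         classSeparation = m$class_separation,
                         tuningAmplitude = m$tuning_amplitude,
                         noiseSd = m$noise_sd,
                         sharedGainSd = m$shared_gain_sd,
                         eventRate = m$event_rate)
}

## tiny stable checksum of the configuration (polynomial hash of its deparse)
.configChecksum <- function(cfg) {
  bytes <- utf8ToInt(paste(deparse(cfg), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2^31
  sprintf("%08x", h)
}

#' Run the full decoding pipeline on simulated sessions
#'
#' Simulates the three-session recording defined by the configuration,
#' preprocesses it into feature datasets, and runs the requested analyses:
#' stimulus-class decoding (5-fold balanced scheme on the neurons common to
#' all sessions), direction decoding (80/20 holdout on the grating session),
#' and optionally the population-size scaling curve, the joint-versus-blind
#' synergy comparison, and the selectivity table. All stage seeds derive from
#' the single configuration seed; a rerun with the same configuration
#' reproduces the same numbers.
#'
#' Configuration fields (YAML or list): \code{seed}; \code{model}
#' (\code{type} = \code{"tuned"} or \code{"label_independent"},
#' \code{n_neurons}, \code{base_mean}, \code{class_separation},
#' \code{tuning_amplitude}, \code{noise_sd}, \code{shared_gain_sd});
#' \code{tasks} (subset of \code{"classes"}, \code{"directions"});
#' \code{decoder} (\code{classifier}); \code{scaling}, \code{synergy},
#' \code{selectivity} (\code{enabled} plus sizes); \code{out_dir}
#' (optional: artifacts are written there as CSV/JSON with a manifest).
#'
#' @param config configuration list (missing fields filled with defaults) or
#'   path to a YAML file.
#' @return List with elements \code{features} (per task),
#'   \code{decoding} (per task \linkS4class{DecodingResult}), and when
#'   enabled \code{curve}, \code{synergy}, \code{selectivity}, plus
#'   \code{manifest}.
#' @export
#' @examples
#' \donttest{
#' res <- runPipeline(list(seed = 7,
#'   model = list(n_neurons = 8, class_separation = 0.4),
#'   tasks = "classes"))
#' accuracy(res$decoding$classes)
#' }
runPipeline <- function(config = list()) {
  if (is.character(config)) config <- readPipelineConfig(config)
  else config <- .mergeConfig(.defaultConfig(), config)
  cfg <- config
  seed <- as.integer(cfg$seed)
  model <- .modelFromConfig(cfg)
  specs <- defaultSessionSpecs()
  stageSeeds <- withr::with_seed(seed, sample.int(2^30, 8))

  sims <- list(A = simulateRecording(model, specs$A, seed = stageSeeds[1]),
               B = simulateRecording(model, specs$B, seed = stageSeeds[2]),
               C = simulateRecording(model, specs$C, seed = stageSeeds[3]))

  out <- list(features = list(), decoding = list())

  if ("classes" %in% cfg$tasks) {
    dsets <- lapply(sims, function(s) {
      dff <- computeDFF(s$recording)
      segmentClassEpochs(dff, timestamps(s$recording), s$epochs,
                         sessionId = sessionId(s$recording))
    })
    dsC <- zscoreFeatures(combineFeatureDatasets(dsets))
    out$features$classes <- dsC
    specC <- decoderSpec(cfg$decoder$classifier, scheme = "epochs")
    out$decoding$classes <- decode(dsC, specC, seed = stageSeeds[4])
    if (isTRUE(cfg$scaling$enabled))
      out$curve <- fitAccuracyCurve(subsampleCurve(
        dsC, specC, nResamples = cfg$scaling$n_resamples,
        seed = stageSeeds[5]))
  }

  if ("directions" %in% cfg$tasks) {
    simA <- sims$A
    dff <- computeDFF(simA$recording)
    dsG <- segmentGratingTrials(dff, timestamps(simA$recording), simA$trials,
                                sessionId = "A")
    dsGz <- zscoreFeatures(dsG)
    out$features$directions <- dsGz
    specD <- decoderSpec(cfg$decoder$classifier, scheme = "holdout")
    out$decoding$directions <- decode(dsGz, specD, seed = stageSeeds[6])
    if (isTRUE(cfg$synergy$enabled))
      out$synergy <- compareJointVsIndependent(
        dsGz, specD, seed = stageSeeds[7],
        nReplicates = cfg$synergy$n_replicates,
        nShuffles = cfg$synergy$n_shuffles)
    if (isTRUE(cfg$selectivity$enabled))
      out$selectivity <- selectivityTable(dsG)
  }

  out$manifest <- list(
    package = "popdecode",
    version = as.character(utils::packageVersion("popdecode")),
    seed = seed, stage_seeds = stageSeeds,
    config_checksum = .configChecksum(cfg), config = cfg)

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(...) file.path(cfg$out_dir, ...)
    for (nm in names(out$features))
      writeFeatureDataset(out$features[[nm]], p(paste0("features_", nm)))
    for (nm in names(out$decoding))
      writeResultJson(out$decoding[[nm]], p(paste0("decoding_", nm, ".json")))
    if (!is.null(out$curve)) writeResultJson(out$curve, p("curve.json"))
    if (!is.null(out$synergy))
      writeResultJson(out$synergy, p("synergy.json"))
    if (!is.null(out$selectivity))
      write.csv(out$selectivity, p("selectivity.csv"), row.names = FALSE)
    jsonlite::write_json(out$manifest, p("manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
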