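# File-based pipeline: hierarchical YAML configuration with schema
# validation, timestamped logging, and the run modes tying the stages
# together (simulate / preprocess / train / denoise / evaluate / end2end).
# Every artifact-producing run writes a manifest (full configuration, its
# MD5, the seed, versions and per-stage wall times) sufficient to reproduce
# it.

# Timestamped, leveled logging to stderr; mirrored to the file named by
# option "despeckle.logFile" (set via runPipeline's paths$log) when present.
logMsg <- function(..., level = "INFO", quiet = FALSE) {
  line <- sprintf("[%s] %s %s", level,
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"), paste0(...))
  logFile <- getOption("despeckle.logFile")
  if (!is.null(logFile)) cat(line, "\n", file = logFile, append = TRUE,
                             sep = "")
  if (!quiet) message(line)
}

#' Default pipeline configuration
#'
#' The full nested parameter set of the pipeline with its documented
#' defaults. Configuration files must use a subset of exactly these keys;
#' unknown keys are rejected by name.
#'
#' @return nested named list.
#' @export
defaultPipelineConfig <- function() {
  list(
    seed = 0L,
    phantom = list(height = 128L, width = 128L, nLesions = 3L,
                   backgroundLevel = 120, lesionContrast = 60,
                   textureScale = 8),
    noise = list(kind = "speckle", looks = 4, snrDb = 25),
    dataset = list(nTrain = 800L, nTest = 200L),
    contrast = list(aLog = 255 / log(256), bLog = 1, cLog = 0,
                    aExp = 1, bExp = 256, cExp = 0,
                    tLow = 100, tHigh = 180, tMax = 260),
    guided = list(radius = 2L, epsilon = 0.01, detailGain = 2),
    lprnn = list(patchSize = 32L, convKernel = 5L, poolSize = 2L,
                 featureChannels = 8L, recurrentSteps = 3L),
    loss = list(l1Weight = 1, edgeWeight = 0.1, advWeight = 0),
    train = list(iterations = 100L, batchSize = 16L, learningRate = 1e-3,
                 augment = TRUE),
    metrics = list(frrTolerance = 5),
    preprocessInference = FALSE
  )
}

validateAgainst <- function(cfg, ref, path = "") {
  if (!is.list(cfg)) {
    stop("configuration section '", path, "' must be a mapping", call. = FALSE)
  }
  unknown <- setdiff(names(cfg), names(ref))
  if (length(unknown)) {
    stop("unknown configuration key(s): ",
         paste0(path, unknown, collapse = ", "), call. = FALSE)
  }
  for (nm in names(cfg)) {
    if (is.list(ref[[nm]])) {
      validateAgainst(cfg[[nm]], ref[[nm]], paste0(path, nm, "."))
    }
  }
  invisible(TRUE)
}

mergeConfig <- function(ref, cfg) {
  for (nm in names(cfg)) {
    ref[[nm]] <- if (is.list(ref[[nm]])) {
      mergeConfig(ref[[nm]], cfg[[nm]])
    } else {
      cfg[[nm]]
    }
  }
  ref
}

#' Read and validate a pipeline configuration
#'
#' Parses a YAML configuration file, rejects unknown keys (naming them), and
#' fills unset values from [defaultPipelineConfig()].
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param overrides named list applied on top of the file (e.g. from
#'   command-line flags), validated the same way.
#' @return complete validated configuration list.
#' @export
readPipelineConfig <- function(path = NULL, overrides = list()) {
  ref <- defaultPipelineConfig()
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  validateAgainst(cfg, ref)
  validateAgainst(overrides, ref)
  mergeConfig(mergeConfig(ref, cfg), overrides)
}

# Build the S4 parameter objects a run needs from the plain config list.
configObjects <- function(config) {
  list(
    phantom = PhantomSpec(height = config$phantom$height,
                          width = config$phantom$width,
                          nLesions = config$phantom$nLesions,
                          backgroundLevel = config$phantom$backgroundLevel,
                          lesionContrast = config$phantom$lesionContrast,
                          textureScale = config$phantom$textureScale,
                          seed = config$seed),
    noise = NoiseSpec(kind = config$noise$kind, looks = config$noise$looks,
                      snrDb = config$noise$snrDb, seed = config$seed),
    contrast = ContrastParams(aLog = config$contrast$aLog,
                              bLog = config$contrast$bLog,
                              cLog = config$contrast$cLog,
                              aExp = config$contrast$aExp,
                              bExp = config$contrast$bExp,
                              cExp = config$contrast$cExp,
                              tLow = config$contrast$tLow,
                              tHigh = config$contrast$tHigh,
                              tMax = config$contrast$tMax),
    guided = GuidedFilterParams(radius = config$guided$radius,
                                epsilon = config$guided$epsilon,
                                detailGain = config$guided$detailGain),
    denoiser = DenoiserConfig(patchSize = config$lprnn$patchSize,
                              convKernel = config$lprnn$convKernel,
                              poolSize = config$lprnn$poolSize,
                              featureChannels = config$lprnn$featureChannels,
                              recurrentSteps = config$lprnn$recurrentSteps,
                              seed = config$seed),
    loss = LossWeights(l1Weight = config$loss$l1Weight,
                       edgeWeight = config$loss$edgeWeight,
                       advWeight = config$loss$advWeight),
    train = TrainConfig(iterations = config$train$iterations,
                        batchSize = config$train$batchSize,
                        learningRate = config$train$learningRate,
                        augment = config$train$augment,
                        seed = config$seed)
  )
}

configMd5 <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

writeManifest <- function(dir, mode, config, stageTimes) {
  manifest <- list(mode = mode,
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   package = "despeckle",
                   packageVersion = as.character(utils::packageVersion("despeckle")),
                   rVersion = R.version.string,
                   seed = config$seed,
                   configMd5 = configMd5(config),
                   stageTimesSec = as.list(stageTimes),
                   destructionTimeSec = destructionTime(unlist(stageTimes)),
                   config = config)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

writePairs <- function(pairs, dir, quiet = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(pairs)) {
    writeGrayImage(pairs[[i]]$clean,
                   file.path(dir, sprintf("clean_%04d.png", i)))
    suppressWarnings(  # noisy images legitimately exceed [0, 255]
      writeGrayImage(pairs[[i]]$noisy,
                     file.path(dir, sprintf("noisy_%04d.png", i))))
  }
  invisible(dir)
}

readPairs <- function(dir) {
  cleanFiles <- sort(list.files(dir, "^clean_[0-9]+\\.png$",
                                full.names = TRUE))
  noisyFiles <- sort(list.files(dir, "^noisy_[0-9]+\\.png$",
                                full.names = TRUE))
  if (length(cleanFiles) == 0L || length(cleanFiles) != length(noisyFiles)) {
    stop("directory does not contain matching clean_/noisy_ PNG pairs: ", dir,
         call. = FALSE)
  }
  Map(function(cf, nf) list(clean = readGrayImage(cf),
                            noisy = readGrayImage(nf)),
      cleanFiles, noisyFiles, USE.NAMES = FALSE)
}

requirePath <- function(paths, key, mode) {
  p <- paths[[key]]
  if (is.null(p)) {
    stop(sprintf("mode '%s' requires paths$%s", mode, key), call. = FALSE)
  }
  p
}

timeStage <- function(expr) {
  t0 <- proc.time()[["elapsed"]]
  value <- force(expr)
  list(value = value, sec = proc.time()[["elapsed"]] - t0)
}

#' Run the despeckling pipeline
#'
#' Drives the pipeline end to end or stage by stage. Every run validates the
#' configuration, logs parameters and per-stage wall times, and writes a
#' `manifest.json` (configuration, its MD5 hash, seed, versions, stage times)
#' next to its artifacts.
#'
#' Modes and their `paths` entries:
#' \describe{
#'   \item{simulate}{`out` output directory; writes `train/` and `test/`
#'     clean/noisy PNG pairs.}
#'   \item{preprocess}{`input`, `output` image paths; optional
#'     `intermediatesDir` to save the three stage images.}
#'   \item{train}{`data` dataset directory (as written by simulate; the
#'     `train/` subdirectory is used if present), `model` output JSON;
#'     optional `history` CSV.}
#'   \item{denoise}{`model`, `input`, `output`.}
#'   \item{evaluate}{`clean`, `noisy`, `denoised`, `report` (JSON).}
#'   \item{end2end}{`out` output directory; simulates, trains, denoises the
#'     test images and writes the model, per-image metrics and a median
#'     report.}
#' }
#'
#' @param config configuration list from [readPipelineConfig()], or a path to
#'   a YAML file.
#' @param mode one of `"simulate"`, `"preprocess"`, `"train"`, `"denoise"`,
#'   `"evaluate"`, `"end2end"`.
#' @param paths named list of input/output paths (see Details). The optional
#'   entry `log` names a file that receives a copy of all log lines.
#' @param quiet suppress log messages.
#' @return invisibly, a list of the run's in-memory artifacts (mode
#'   dependent).
#' @export
runPipeline <- function(config = readPipelineConfig(),
                        mode = c("simulate", "preprocess", "train", "denoise",
                                 "evaluate", "end2end"),
                        paths = list(), quiet = FALSE) {
  mode <- match.arg(mode)
  if (is.character(config)) config <- readPipelineConfig(config)
  validateAgainst(config, defaultPipelineConfig())
  if (!is.null(paths$log)) {
    withr::local_options(despeckle.logFile = paths$log)
    paths$log <- NULL
  }
  obj <- configObjects(config)
  stageTimes <- list()
  logMsg(sprintf("mode '%s', seed %d, config %s", mode, config$seed,
                 configMd5(config)), quiet = quiet)
  result <- switch(mode,
    simulate = {
      out <- requirePath(paths, "out", mode)
      st <- timeStage({
        ds <- makeDataset(config$dataset$nTrain, config$dataset$nTest,
                          obj$phantom, obj$noise, seed = config$seed)
        writePairs(ds$train, file.path(out, "train"), quiet)
        writePairs(ds$test, file.path(out, "test"), quiet)
        ds
      })
      stageTimes$simulate <- st$sec
      logMsg(sprintf("wrote %d train + %d test pairs to %s",
                     length(st$value$train), length(st$value$test), out),
             quiet = quiet)
      writeManifest(out, mode, config, stageTimes)
      list(dataset = st$value, dir = out)
    },
    preprocess = {
      input <- requirePath(paths, "input", mode)
      output <- requirePath(paths, "output", mode)
      img <- readGrayImage(input)
      st <- timeStage(preprocessImage(img, obj$contrast, obj$guided))
      stageTimes$preprocess <- st$sec
      pre <- st$value
      dir.create(dirname(output), recursive = TRUE, showWarnings = FALSE)
      suppressWarnings(writeGrayImage(pre, output))
      if (!is.null(paths$intermediatesDir)) {
        dir.create(paths$intermediatesDir, recursive = TRUE,
                   showWarnings = FALSE)
        ims <- attr(pre, "intermediates")
        for (nm in names(ims)) {
          suppressWarnings(writeGrayImage(
            ims[[nm]], file.path(paths$intermediatesDir,
                                 paste0(nm, ".png"))))
        }
      }
      writeManifest(dirname(output), mode, config, stageTimes)
      list(preprocessed = pre)
    },
    train = {
      data <- requirePath(paths, "data", mode)
      modelOut <- requirePath(paths, "model", mode)
      trainDir <- if (dir.exists(file.path(data, "train"))) {
        file.path(data, "train")
      } else {
        data
      }
      pairs <- readPairs(trainDir)
      if (config$preprocessInference) {
        pairs <- lapply(pairs, function(p) {
          p$noisy <- preprocessImage(p$noisy, obj$contrast, obj$guided)
          p
        })
      }
      logMsg(sprintf("training on %d pairs, %d iterations",
                     length(pairs), obj$train@iterations), quiet = quiet)
      model <- buildDenoiser(obj$denoiser)
      st <- timeStage(trainDenoiser(model, pairs, obj$loss, obj$train))
      stageTimes$train <- st$sec
      dir.create(dirname(modelOut), recursive = TRUE, showWarnings = FALSE)
      writeDenoiser(st$value$model, modelOut)
      if (!is.null(paths$history)) {
        utils::write.csv(st$value$history, paths$history, row.names = FALSE)
      }
      logMsg(sprintf("final monitoring MSE %.3f gray^2",
                     utils::tail(st$value$history$mse, 1L)), quiet = quiet)
      writeManifest(dirname(modelOut), mode, config, stageTimes)
      st$value
    },
    denoise = {
      modelPath <- requirePath(paths, "model", mode)
      input <- requirePath(paths, "input", mode)
      output <- requirePath(paths, "output", mode)
      model <- readDenoiser(modelPath)
      img <- readGrayImage(input)
      if (config$preprocessInference) {
        img <- preprocessImage(img, obj$contrast, obj$guided)
      }
      st <- timeStage(denoise(model, img))
      stageTimes$denoise <- st$sec
      dir.create(dirname(output), recursive = TRUE, showWarnings = FALSE)
      suppressWarnings(writeGrayImage(st$value, output))
      writeManifest(dirname(output), mode, config, stageTimes)
      list(denoised = st$value)
    },
    evaluate = {
      clean <- readGrayImage(requirePath(paths, "clean", mode))
      noisy <- readGrayImage(requirePath(paths, "noisy", mode))
      denoised <- readGrayImage(requirePath(paths, "denoised", mode))
      reportOut <- requirePath(paths, "report", mode)
      st <- timeStage(evaluateDenoising(clean, noisy, denoised,
                                        tolGray = config$metrics$frrTolerance))
      stageTimes$evaluate <- st$sec
      report <- st$value
      report@tDes <- destructionTime(unlist(stageTimes))
      dir.create(dirname(reportOut), recursive = TRUE, showWarnings = FALSE)
      writeReport(report, reportOut)
      writeManifest(dirname(reportOut), mode, config, stageTimes)
      list(report = report)
    },
    end2end = {
      out <- requirePath(paths, "out", mode)
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      st <- timeStage(makeDataset(config$dataset$nTrain, config$dataset$nTest,
                                  obj$phantom, obj$noise,
                                  seed = config$seed))
      stageTimes$simulate <- st$sec
      ds <- st$value
      logMsg(sprintf("simulated %d train + %d test pairs",
                     length(ds$train), length(ds$test)), quiet = quiet)
      model <- buildDenoiser(obj$denoiser)
      st <- timeStage(trainDenoiser(model, ds$train, obj$loss, obj$train))
      stageTimes$train <- st$sec
      fit <- st$value
      writeDenoiser(fit$model, file.path(out, "model.json"))
      utils::write.csv(fit$history, file.path(out, "history.csv"),
                       row.names = FALSE)
      st <- timeStage(lapply(ds$test, function(p) denoise(fit$model,
                                                          p$noisy)))
      stageTimes$denoise <- st$sec
      denoised <- st$value
      st <- timeStage({
        reports <- Map(function(p, d) {
          evaluateDenoising(p$clean, p$noisy, d,
                            tolGray = config$metrics$frrTolerance)
        }, ds$test, denoised)
        do.call(rbind, lapply(reports, function(r) {
          as.data.frame(reportAsList(r))
        }))
      })
      stageTimes$evaluate <- st$sec
      perImage <- st$value
      utils::write.csv(perImage, file.path(out, "metrics.csv"),
                       row.names = FALSE)
      median <- vapply(perImage, stats::median, numeric(1))
      medReport <- new("EvalReport", mse = median[["mse"]],
                       snrDb = median[["snrDb"]], psnrDb = median[["psnrDb"]],
                       epi = median[["epi"]],
                       falseRecognitionRate = median[["falseRecognitionRate"]],
                       tDes = destructionTime(unlist(stageTimes)))
      writeReport(medReport, file.path(out, "report.json"))
      logMsg(sprintf("median test PSNR %.2f dB, EPI %.3f",
                     medReport@psnrDb, medReport@epi), quiet = quiet)
      writeManifest(out, mode, config, stageTimes)
      list(model = fit$model, history = fit$history, perImage = perImage,
           report = medReport)
    })
  invisible(result)
}
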