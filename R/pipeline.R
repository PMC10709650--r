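## End-to-end orchestration: simulate -> decode -> stats -> rsa -> group.

.pipelineDefaults <- function() list(
  scenario = "accumulation",
  nConcepts = 60, nCategories = 7, nChannels = 204, nBins = 50, binMs = 20,
  nParticipants = 19, nFeatureDims = 300, categorySpread = 2, noiseSd = 0.5,
  seed = 1L,
  nLayers = 0, layerMix = 0.5, jitterBins = 1,
  ridgePenalty = 1, widthBins = 1, stepBins = 1,
  nPerm = 1000, alpha = 0.05,
  plateauThreshold = 0.05, plateauLevel = "concept",
  ctCells = "consecutive",
  rsa = TRUE, rsaRadius = 1.5, rsaWindowEndBins = NULL,
  clusterAlpha = 0.01, clusterWideAlpha = 0.05, clusterPerm = 500
)

## validate + merge with defaults; errors carry the offending field path
.validatePipelineConfig <- function(config) {
  def <- .pipelineDefaults()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    stop("unknown config field(s): ", paste0("config$", unknown, collapse = ", "))
  cfg <- utils::modifyList(def, config)
  chk <- function(field, ok, what) {
    if (!ok) stop("config$", field, ": ", what)
  }
  for (f in c("nConcepts", "nCategories", "nChannels", "nBins",
              "nParticipants", "nFeatureDims"))
    chk(f, is.numeric(cfg[[f]]) && cfg[[f]] >= 1, "must be a count >= 1")
  chk("nPerm", is.numeric(cfg$nPerm) && cfg$nPerm >= 1, "must be >= 1")
  chk("clusterPerm", cfg$clusterPerm >= 1, "must be >= 1")
  chk("alpha", cfg$alpha > 0 && cfg$alpha < 1, "must be in (0, 1)")
  chk("plateauThreshold", cfg$plateauThreshold >= 0 && cfg$plateauThreshold < 1,
      "must be in [0, 1)")
  chk("noiseSd", cfg$noiseSd >= 0, "must be >= 0")
  chk("ridgePenalty", cfg$ridgePenalty >= 0, "must be >= 0")
  chk("scenario", cfg$scenario %in% c("accumulation", "maintenance",
                                      "transient", "null"),
      "unknown scenario name")
  chk("plateauLevel", cfg$plateauLevel %in% c("concept", "mean"),
      "must be 'concept' or 'mean'")
  chk("ctCells", cfg$ctCells %in% c("all", "consecutive"),
      "must be 'all' or 'consecutive'")
  cfg
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path a `.yaml`/`.yml` or `.json` file of configuration fields;
#'   missing fields take their defaults.
#' @return validated configuration list.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  .validatePipelineConfig(as.list(cfg))
}

.gridDims <- function(n) {
  ## factor pair closest to square (falls back to n x 1 for primes)
  best <- c(n, 1L)
  for (a in seq_len(floor(sqrt(n)))) {
    if (n %% a == 0L) best <- c(n %/% a, a)
  }
  best
}

.writeTable <- function(df, dir, name) {
  utils::write.csv(df, file.path(dir, paste0(name, ".csv")), row.names = FALSE)
}

#' Run the full analysis pipeline on a synthetic scenario
#'
#' Orchestrates: scenario simulation, per-participant sliding and
#' cumulative zero-shot decoding for every feature model, grand-average
#' cross-temporal decoding with permutation significance and
#' generalization-window onset, chance-level permutation tests,
#' sliding-vs-cumulative paired comparison, plateau tabulation, group
#' modelling (mixed model when >= 2 feature models, between-participant
#' SD time course and plateau correlations when the design supports
#' them) and searchlight RSA with cluster permutation. All tables are
#' written as CSV under `outDir` together with a `manifest.json`
#' recording the configuration, seed, package version and the
#' degrees-of-freedom method, and a plain-text `report.txt`. The run is
#' a deterministic function of the configuration (including its seed).
#'
#' @param config configuration list (see [readPipelineConfig()] for the
#'   file-based variant); missing fields take their defaults.
#' @param outDir output directory.
#' @param overwrite allow writing into a non-empty directory; partial
#'   results are never silently overwritten.
#' @return (invisibly) a list with the main in-memory results.
#' @export
runPipeline <- function(config = list(), outDir, overwrite = FALSE) {
  cfg <- .validatePipelineConfig(config)
  if (dir.exists(outDir) && length(dir(outDir)) && !overwrite)
    stop("output directory not empty (set overwrite = TRUE): ", outDir)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  timings <- c()
  tic <- function() Sys.time()
  lap <- function(stage, start) {
    timings[[stage]] <<- as.numeric(difftime(Sys.time(), start, units = "secs"))
  }

  ## -- simulate ------------------------------------------------------
  s <- tic()
  gcfg <- generatorConfig(
    nConcepts = cfg$nConcepts, nCategories = cfg$nCategories,
    nChannels = cfg$nChannels, nBins = cfg$nBins, binMs = cfg$binMs,
    nParticipants = cfg$nParticipants, nFeatureDims = cfg$nFeatureDims,
    categorySpread = cfg$categorySpread, noiseSd = cfg$noiseSd,
    seed = cfg$seed)
  ds <- makeScenario(cfg$scenario, gcfg, nLayers = cfg$nLayers,
                     layerMix = cfg$layerMix, jitterBins = cfg$jitterBins)
  lap("simulate", s)

  ## -- decode --------------------------------------------------------
  s <- tic()
  models <- names(ds@features)
  slidingList <- list(); cumulativeList <- list()
  for (rt in ds@responses) {
    for (m in models) {
      key <- paste(rt@participant, m, sep = ".")
      slidingList[[key]] <- slidingDecode(rt, ds@features[[m]],
                                          cfg$widthBins, cfg$ridgePenalty)
      cumulativeList[[key]] <- cumulativeDecode(rt, ds@features[[m]],
                                                cfg$stepBins, cfg$ridgePenalty)
    }
  }
  tidyDistances <- do.call(rbind, lapply(c(slidingList, cumulativeList),
    function(dsr) {
      D <- dsr@distances
      data.frame(participant = dsr@participant, model = dsr@modelName,
                 windowKind = dsr@windowKind,
                 windowEndMs = rep(dsr@windowEndMs, each = nrow(D)),
                 concept = rep(rownames(D), ncol(D)),
                 distance = as.vector(D))
    }))
  .writeTable(tidyDistances, outDir, "distances")
  lap("decode", s)

  ## -- grand-average cross-temporal + onset --------------------------
  s <- tic()
  ga <- grandAverageTensor(ds@responses)
  ct <- crossTemporalPvalues(ga, ds@features$semantic, nPerm = cfg$nPerm,
                             seed = cfg$seed + 1L,
                             ridgePenalty = cfg$ridgePenalty,
                             alpha = cfg$alpha, cells = cfg$ctCells)
  onsetBin <- generalizationOnset(ct)
  onsetMs <- if (is.na(onsetBin)) NA_real_ else ct@windowEndMs[onsetBin]
  ctLong <- data.frame(
    trainEndMs = rep(ct@windowEndMs, times = length(ct@windowEndMs)),
    testEndMs = rep(ct@windowEndMs, each = length(ct@windowEndMs)),
    meanDistance = as.vector(ct@meanDistance),
    p = as.vector(ct@pValues), pAdj = as.vector(ct@adjPValues),
    significant = as.vector(ct@significant))
  .writeTable(ctLong, outDir, "cross_temporal")
  lap("cross_temporal", s)

  ## -- chance-level significance + paired comparison (grand average) -
  s <- tic()
  sigRows <- list(); pairedRows <- list()
  for (m in models) {
    for (kind in c("sliding", "cumulative")) {
      sig <- permutationPvaluesDecoding(ga, ds@features[[m]], kind = kind,
        widthBins = cfg$widthBins, stepBins = cfg$stepBins,
        nPerm = cfg$nPerm, seed = cfg$seed + 2L,
        ridgePenalty = cfg$ridgePenalty, alpha = cfg$alpha)
      sigRows[[paste(m, kind)]] <- cbind(model = m, windowKind = kind, sig)
    }
    cmp <- pairedModelComparison(
      slidingDecode(ga, ds@features[[m]], cfg$widthBins, cfg$ridgePenalty),
      cumulativeDecode(ga, ds@features[[m]], cfg$stepBins, cfg$ridgePenalty),
      nPerm = cfg$nPerm, seed = cfg$seed + 3L, alpha = cfg$alpha,
      null = "label-shuffle", tensor = ga, features = ds@features[[m]],
      ridgePenalty = cfg$ridgePenalty)
    pairedRows[[m]] <- cbind(model = m, cmp)
  }
  .writeTable(do.call(rbind, sigRows), outDir, "significance")
  .writeTable(do.call(rbind, pairedRows), outDir, "paired_comparison")
  lap("significance", s)

  ## -- plateaus + group ----------------------------------------------
  s <- tic()
  plat <- plateauTable(cumulativeList, cfg$plateauThreshold,
                       level = cfg$plateauLevel)
  .writeTable(plat, outDir, "plateaus")
  lmmFit <- NULL
  if (length(models) >= 2L && cfg$plateauLevel == "concept") {
    lmmFit <- fitPlateauLmm(plat, fixed = intersect(
      c("model", if (cfg$nParticipants >= 2) "participant"),
      c("model", "participant")))
    .writeTable(lmmFit$anova, outDir, "lmm_anova")
    .writeTable(lmmFit$emmeans, outDir, "lmm_emmeans")
    .writeTable(lmmFit$contrasts, outDir, "lmm_contrasts")
  }
  if (cfg$nParticipants >= 2L) {
    semCum <- cumulativeList[paste(vapply(ds@responses, slot, character(1),
                                          "participant"),
                                   "semantic", sep = ".")]
    .writeTable(participantSdTimecourse(semCum), outDir, "participant_sd")
    if (length(models) >= 2L && cfg$nParticipants >= 3L) {
      meanPlat <- plateauTable(cumulativeList, cfg$plateauThreshold, "mean")
      corR <- tryCatch(plateauModelCorrelations(meanPlat),
                       error = function(e) NULL)
      if (!is.null(corR))
        .writeTable(data.frame(model = rownames(corR), corR,
                               check.names = FALSE),
                    outDir, "plateau_correlations")
    }
  }
  lap("group", s)

  ## -- searchlight RSA + clusters ------------------------------------
  clusterTab <- NULL
  if (isTRUE(cfg$rsa)) {
    s <- tic()
    gd <- .gridDims(cfg$nChannels)
    units <- makeGridUnits(gd[1], gd[2])
    endBins <- cfg$rsaWindowEndBins
    if (is.null(endBins)) endBins <- cfg$nBins
    windows <- lapply(endBins, function(e) windowSpec("cumulative", 0, e))
    maps <- searchlightRsa(ds@responses, units, cfg$rsaRadius,
                           modelDsm(ds@features$semantic), windows)
    mapLong <- do.call(rbind, lapply(seq_along(windows), function(wi) {
      data.frame(participant = rep(dimnames(maps)[[1]], times = dim(maps)[2]),
                 unit = rep(dimnames(maps)[[2]], each = dim(maps)[1]),
                 windowEndMs = endBins[wi] * cfg$binMs,
                 score = as.vector(maps[, , wi]))
    }))
    .writeTable(mapLong, outDir, "rsa_scores")
    if (cfg$nParticipants >= 2L) {
      clRows <- lapply(seq_along(windows), function(wi) {
        cl <- clusterPermutation1Samp(maps, units,
          clusterAlpha = cfg$clusterAlpha,
          clusterWideAlpha = cfg$clusterWideAlpha,
          nPerm = cfg$clusterPerm, seed = cfg$seed + 4L, window = wi)
        if (nrow(cl$clusters))
          cbind(windowEndMs = endBins[wi] * cfg$binMs, cl$clusters)
        else NULL
      })
      clusterTab <- do.call(rbind, clRows)
      if (is.null(clusterTab))
        clusterTab <- data.frame(windowEndMs = numeric(0), cluster = integer(0),
                                 nUnits = integer(0), statistic = numeric(0),
                                 p = numeric(0), significant = logical(0))
      .writeTable(clusterTab, outDir, "rsa_clusters")
    }
    lap("rsa", s)
  }

  ## -- plateau vs onset summary + manifest + report ------------------
  gaCumSem <- cumulativeDecode(ga, ds@features$semantic, cfg$stepBins,
                               cfg$ridgePenalty)
  gaPlat <- detectStabilizationPoint(conceptMeans(gaCumSem),
                                     cfg$plateauThreshold,
                                     gaCumSem@windowEndMs)
  summaryTab <- data.frame(
    scenario = cfg$scenario,
    plateauMs = gaPlat$timeMs, plateauBin = gaPlat$index,
    onsetMs = onsetMs, onsetBin = onsetBin,
    plateauAfterOnset = if (is.na(onsetBin)) NA else gaPlat$index > onsetBin)
  .writeTable(summaryTab, outDir, "summary")

  manifest <- list(
    package = "megaccum",
    version = as.character(utils::packageVersion("megaccum")),
    config = cfg, seed = cfg$seed, dfMethod = "Satterthwaite",
    tables = sort(grep("\\.csv$", dir(outDir), value = TRUE)))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  rpt <- c(
    sprintf("megaccum pipeline report -- scenario '%s'", cfg$scenario),
    sprintf("concepts %d, channels %d, bins %d x %g ms, participants %d",
            cfg$nConcepts, cfg$nChannels, cfg$nBins, cfg$binMs,
            cfg$nParticipants),
    sprintf("feature models: %s", paste(models, collapse = ", ")),
    sprintf("grand-average cumulative plateau (semantic): %s ms",
            format(gaPlat$timeMs)),
    sprintf("generalization-window onset: %s ms", format(onsetMs)),
    if (!is.na(onsetBin) && !is.na(gaPlat$index))
      sprintf("plateau %s generalization onset",
              if (gaPlat$index > onsetBin) "is later than"
              else "does not exceed")
    else "plateau/onset comparison not available",
    sprintf("ground-truth plateau bins: %s",
            paste(ds@truth$plateauBin, collapse = ", ")))
  writeLines(rpt, file.path(outDir, "report.txt"))
  ## wall-clock timings are machine-dependent; kept out of the tables
  writeLines(sprintf("%s: %.2f s", names(timings), unlist(timings)),
             file.path(outDir, "timing.log"))

  invisible(list(dataset = ds, crossTemporal = ct, plateaus = plat,
                 lmm = lmmFit, clusters = clusterTab, summary = summaryTab,
                 outDir = outDir))
}
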