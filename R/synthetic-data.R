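## Synthetic MEG-style data with known encoding dynamics.
##
## The generator works at the averaged, binned tensor level: concepts x
## channels x bins. Signal enters through temporal "components", each
## projecting a subset of feature dimensions into the channels through a
## dense Gaussian loading matrix, with a piecewise-linear temporal gain.
## Ground-truth plateau times follow directly from the schedule.

## Evaluate expr with a temporary RNG seed, restoring the caller's state.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

.conceptIds <- function(n) sprintf("concept_%03d", seq_len(n))

#' Construct a generator configuration
#'
#' @param nConcepts,nCategories,nChannels,nBins number of concepts,
#'   semantic categories, sensor channels and time bins.
#' @param binMs bin duration in ms.
#' @param nParticipants number of simulated participants.
#' @param nFeatureDims dimensionality of the feature vectors.
#' @param categorySpread within-category dispersion of feature vectors
#'   relative to the unit between-category dispersion.
#' @param noiseSd standard deviation of additive Gaussian sensor noise.
#' @param seed integer RNG seed; the whole dataset is a deterministic
#'   function of the config including this seed.
#' @return a [GeneratorConfig][GeneratorConfig-class] object.
#' @examples
#' generatorConfig(nParticipants = 2, seed = 7)
#' @export
generatorConfig <- function(nConcepts = 60, nCategories = 7, nChannels = 204,
                            nBins = 50, binMs = 20, nParticipants = 19,
                            nFeatureDims = 300, categorySpread = 2,
                            noiseSd = 0.5, seed = 1L) {
  new("GeneratorConfig",
    nConcepts = as.integer(nConcepts), nCategories = as.integer(nCategories),
    nChannels = as.integer(nChannels), nBins = as.integer(nBins),
    binMs = as.numeric(binMs), nParticipants = as.integer(nParticipants),
    nFeatureDims = as.integer(nFeatureDims),
    categorySpread = as.numeric(categorySpread),
    noiseSd = as.numeric(noiseSd), seed = as.integer(seed)
  )
}

#' Construct an encoding component schedule
#'
#' @param onsetBin,rampBins,offsetBin,gain equal-length vectors describing
#'   each component: 1-based onset bin, bins from onset to full gain, last
#'   active bin, and full gain. A component with `offsetBin == nBins` is
#'   sustained to the end of the epoch.
#' @param dims list of disjoint integer vectors: the feature dimensions
#'   each component projects into the channels.
#' @return a [ComponentSchedule][ComponentSchedule-class] object.
#' @examples
#' componentSchedule(onsetBin = c(5, 15), rampBins = c(2, 2),
#'                   offsetBin = c(50, 50), gain = c(1, 1),
#'                   dims = list(1:150, 151:300))
#' @export
componentSchedule <- function(onsetBin, rampBins, offsetBin, gain, dims) {
  new("ComponentSchedule",
    onsetBin = as.integer(onsetBin), rampBins = as.integer(rampBins),
    offsetBin = as.integer(offsetBin), gain = as.numeric(gain),
    dims = lapply(dims, as.integer)
  )
}

## category assignment: as even as possible
.categoryOf <- function(nConcepts, nCategories) {
  sort(rep_len(seq_len(nCategories), nConcepts))
}

## one category-structured feature matrix from the current RNG stream
.featureDraw <- function(nConcepts, nCategories, nDims, spread) {
  catOf <- .categoryOf(nConcepts, nCategories)
  centers <- matrix(stats::rnorm(nCategories * nDims), nCategories, nDims)
  v <- centers[catOf, , drop = FALSE] +
    spread * matrix(stats::rnorm(nConcepts * nDims), nConcepts, nDims)
  rownames(v) <- .conceptIds(nConcepts)
  v
}

#' Generate category-structured feature matrices
#'
#' Produces one semantic-style feature matrix (category cluster means plus
#' within-category dispersion) and, optionally, a chain of visual-layer
#' style matrices in which each layer mixes the previous layer with new
#' independent components, so that consecutive layers are more correlated
#' than distant ones -- emulating a hierarchy of visual processing stages.
#'
#' @param config a [GeneratorConfig][GeneratorConfig-class].
#' @param nLayers number of layer matrices to chain (0 for none). With
#'   `nLayers = 4` the layers are named V1, V2, V4, IT.
#' @param layerMix mixing weight in (0, 1] of the new independent
#'   component at each layer; `layerMix = 1` makes adjacent layers
#'   independent.
#' @return named list of [FeatureMatrix][FeatureMatrix-class] objects;
#'   the first element is named "semantic".
#' @examples
#' fs <- makeFeatureSets(generatorConfig(nParticipants = 1))
#' dim(featureVectors(fs$semantic))
#' @export
makeFeatureSets <- function(config, nLayers = 0, layerMix = 0.5) {
  stopifnot(is(config, "GeneratorConfig"))
  validObject(config)
  if (layerMix <= 0 || layerMix > 1) stop("layerMix must be in (0, 1]")
  .withSeed(config@seed, {
    out <- list(semantic = new("FeatureMatrix", modelName = "semantic",
      vectors = .featureDraw(config@nConcepts, config@nCategories,
                             config@nFeatureDims, config@categorySpread)))
    if (nLayers > 0) {
      nm <- if (nLayers == 4) c("V1", "V2", "V4", "IT")
            else paste0("layer", seq_len(nLayers))
      ## chain anchored at the semantic matrix: each layer mixes the
      ## previous one with a fresh independent draw (scale-stabilized),
      ## so consecutive layers correlate more than distant ones and all
      ## layers share signal with the semantic space
      prev <- out$semantic@vectors
      renorm <- sqrt((1 - layerMix)^2 + layerMix^2)
      for (k in seq_len(nLayers)) {
        fresh <- .featureDraw(config@nConcepts, config@nCategories,
                              config@nFeatureDims, config@categorySpread)
        v <- ((1 - layerMix) * prev + layerMix * fresh) / renorm
        prev <- v
        out[[nm[k]]] <- new("FeatureMatrix", modelName = nm[k], vectors = v)
      }
    }
    out
  })
}

## temporal gain of component k at every bin (vector over bins)
.componentGain <- function(onset, ramp, offset, gain, nBins) {
  t <- seq_len(nBins)
  g <- numeric(nBins)
  active <- t >= onset & t <= offset
  if (ramp > 0) {
    g[active] <- gain * pmin(1, (t[active] - onset) / ramp)
  } else {
    g[active] <- gain
  }
  g
}

#' Simulate a response tensor from features and a schedule
#'
#' Forward model: the response at (concept c, channel s, bin t) is the sum
#' over components k of `g_k(t) * A_k[s, ] %*% f_c[dims_k]` plus Gaussian
#' noise of scale `noiseSd`, where `g_k` ramps linearly from 0 at the
#' onset bin to the full gain over `rampBins` bins and is 0 outside
#' `[onsetBin, offsetBin]`. The channel loading matrices `A_k` are dense
#' Gaussian, drawn once per call from the seeded stream with entries of
#' variance `1/|dims_k|` so that the per-channel signal scale is set by
#' the gain alone.
#'
#' @param features a [FeatureMatrix][FeatureMatrix-class].
#' @param schedule a [ComponentSchedule][ComponentSchedule-class]; its
#'   dims must be a subset of the feature dimensions.
#' @param config a [GeneratorConfig][GeneratorConfig-class].
#' @param participant participant label stored in the tensor.
#' @param seed RNG seed for loadings and noise (defaults to the config
#'   seed; pass distinct seeds for distinct participants).
#' @return a [ResponseTensor][ResponseTensor-class].
#' @export
simulateResponses <- function(features, schedule, config,
                              participant = "p01", seed = config@seed) {
  stopifnot(is(features, "FeatureMatrix"), is(schedule, "ComponentSchedule"),
            is(config, "GeneratorConfig"))
  validObject(schedule)
  FV <- features@vectors
  if (nrow(FV) != config@nConcepts)
    stop("feature matrix rows do not match config nConcepts")
  alld <- unlist(schedule@dims)
  if (any(alld < 1L | alld > ncol(FV)))
    stop("schedule dims outside feature dimensions")
  if (any(schedule@offsetBin > config@nBins))
    stop("schedule offsetBin beyond the epoch")
  C <- config@nConcepts; S <- config@nChannels; T <- config@nBins
  .withSeed(seed, {
    resp <- array(0, dim = c(C, S, T))
    for (k in seq_along(schedule@onsetBin)) {
      dk <- schedule@dims[[k]]
      A <- matrix(stats::rnorm(S * length(dk), sd = 1 / sqrt(length(dk))),
                  S, length(dk))
      B <- FV[, dk, drop = FALSE] %*% t(A)            # C x S pattern
      g <- .componentGain(schedule@onsetBin[k], schedule@rampBins[k],
                          schedule@offsetBin[k], schedule@gain[k], T)
      for (t in which(g > 0)) resp[, , t] <- resp[, , t] + g[t] * B
    }
    if (config@noiseSd > 0)
      resp <- resp + config@noiseSd * array(stats::rnorm(C * S * T), dim = c(C, S, T))
    dimnames(resp) <- list(rownames(FV), NULL, NULL)
    new("ResponseTensor", participant = participant, data = resp,
        binMs = config@binMs, t0Ms = 0)
  })
}

#' Ground-truth plateau bin of a schedule
#'
#' The first bin after which no new sustained information enters the
#' signal: the maximum of `onsetBin + rampBins` over sustained components
#' (those active through the last bin of the epoch). If no component is
#' sustained the same maximum is taken over all components and the result
#' is flagged transient. Components with zero gain carry no information
#' and are ignored; a schedule with no informative components has an
#' undefined (NA) plateau.
#'
#' @param schedule a [ComponentSchedule][ComponentSchedule-class].
#' @param nBins epoch length in bins (defines "sustained").
#' @return list with elements `plateauBin` (integer or NA) and
#'   `transient` (logical).
#' @examples
#' sch <- componentSchedule(c(5, 12), c(0, 3), c(50, 50), c(1, 1),
#'                          list(1:10, 11:20))
#' groundTruthPlateau(sch, nBins = 50)  # plateauBin 15
#' @export
groundTruthPlateau <- function(schedule, nBins) {
  stopifnot(is(schedule, "ComponentSchedule"))
  validObject(schedule)
  keep <- schedule@gain > 0
  if (!any(keep)) return(list(plateauBin = NA_integer_, transient = NA))
  sustained <- keep & schedule@offsetBin >= nBins
  full <- schedule@onsetBin + schedule@rampBins
  if (any(sustained)) {
    list(plateauBin = as.integer(max(full[sustained])), transient = FALSE)
  } else {
    list(plateauBin = as.integer(max(full[keep])), transient = TRUE)
  }
}

## base schedule for a named scenario, scaled to the epoch length
.scenarioSchedule <- function(scenario, config) {
  nb <- config@nBins
  D <- config@nFeatureDims
  ramp <- max(1L, round(0.04 * nb))            # ~2 bins at 50
  quarters <- split(seq_len(D), cut(seq_len(D), 4, labels = FALSE))
  switch(scenario,
    accumulation = componentSchedule(
      ## overlapping processes of differing duration: the earliest
      ## component fades late in the epoch while the others are
      ## sustained, so single-bin windows lose early information near
      ## the end of the epoch while cumulative windows retain it; the
      ## plateau is set by the sustained onsets
      onsetBin = round(seq(0.1, 0.4, length.out = 4) * nb),
      rampBins = rep(ramp, 4),
      offsetBin = pmax(round(c(0.8, 1, 1, 1) * nb),
                       round(0.4 * nb) + ramp + 1L),
      gain = rep(1, 4), dims = quarters),
    maintenance = componentSchedule(
      ## all information enters at once (no ramp) and is then maintained
      onsetBin = rep(round(0.1 * nb), 4),
      rampBins = rep(0L, 4), offsetBin = rep(nb, 4),
      gain = rep(1, 4), dims = quarters),
    transient = componentSchedule(
      onsetBin = round(seq(0.1, 0.4, length.out = 4) * nb),
      rampBins = rep(ramp, 4),
      offsetBin = round(seq(0.1, 0.4, length.out = 4) * nb + 0.25 * nb),
      gain = rep(1, 4), dims = quarters),
    null = componentSchedule(
      onsetBin = round(0.1 * nb), rampBins = ramp, offsetBin = nb,
      gain = 0, dims = list(seq_len(D))),
    stop("unknown scenario: ", scenario)
  )
}

## shift a schedule's onsets (and transient offsets) by whole bins
.jitterSchedule <- function(schedule, shift, nBins) {
  on <- pmax(1L, pmin(nBins - 1L, schedule@onsetBin + shift))
  off <- schedule@offsetBin
  transientIdx <- off < nBins
  off[transientIdx] <- pmax(on[transientIdx] + 1L,
                            pmin(nBins, off[transientIdx] + shift))
  componentSchedule(on, schedule@rampBins, off, schedule@gain, schedule@dims)
}

#' Generate a named synthetic scenario
#'
#' Bundles feature matrices, per-participant response tensors and ground
#' truth for one of four named encoding scenarios:
#' \describe{
#'   \item{accumulation}{staggered onsets spanning roughly 10--40% of
#'     the epoch; information keeps entering the signal until the last
#'     component is fully on. The earliest component fades at 80% of
#'     the epoch while the others are sustained (overlapping processes
#'     of differing duration), so fixed-length windows lose early
#'     information near the end of the epoch while cumulative windows
#'     retain it.}
#'   \item{maintenance}{a single shared onset with all components
#'     sustained: all information enters at once and is then maintained.}
#'   \item{transient}{staggered components that switch off before the end
#'     of the epoch.}
#'   \item{null}{zero gain everywhere: pure sensor noise, plateau
#'     undefined (NA).}
#' }
#' Per-participant variability is modelled as an integer onset jitter
#' (uniform on `-jitterBins..jitterBins`) plus independent resampling of
#' the channel loading matrices and noise.
#'
#' @param scenario one of "accumulation", "maintenance", "transient",
#'   "null".
#' @param config a [GeneratorConfig][GeneratorConfig-class].
#' @param nLayers,layerMix passed to [makeFeatureSets()].
#' @param jitterBins maximum absolute per-participant onset shift in bins.
#' @return a [SyntheticDataset][SyntheticDataset-class].
#' @examples
#' ds <- makeScenario("maintenance",
#'                    generatorConfig(nConcepts = 12, nCategories = 3,
#'                                    nChannels = 20, nBins = 15,
#'                                    nParticipants = 2, nFeatureDims = 24))
#' ds@truth
#' @export
makeScenario <- function(scenario = c("accumulation", "maintenance",
                                      "transient", "null"),
                         config = generatorConfig(), nLayers = 0,
                         layerMix = 0.5, jitterBins = 1L) {
  scenario <- match.arg(scenario)
  validObject(config)
  features <- makeFeatureSets(config, nLayers = nLayers, layerMix = layerMix)
  base <- .scenarioSchedule(scenario, config)
  np <- config@nParticipants
  shifts <- .withSeed(config@seed + 1000L, {
    if (jitterBins > 0)
      sample(seq(-jitterBins, jitterBins), np, replace = TRUE)
    else rep(0L, np)
  })
  responses <- vector("list", np)
  schedules <- vector("list", np)
  truth <- data.frame(participant = sprintf("p%02d", seq_len(np)),
                      plateauBin = NA_integer_, onsetBin = NA_integer_,
                      transient = NA)
  for (i in seq_len(np)) {
    sch <- .jitterSchedule(base, shifts[i], config@nBins)
    schedules[[i]] <- sch
    responses[[i]] <- simulateResponses(features$semantic, sch, config,
                                        participant = truth$participant[i],
                                        seed = config@seed + 10L * i)
    gt <- groundTruthPlateau(sch, config@nBins)
    truth$plateauBin[i] <- gt$plateauBin
    truth$transient[i] <- gt$transient
    if (any(sch@gain > 0)) {
      onset <- min(sch@onsetBin[sch@gain > 0])
      truth$onsetBin[i] <- onset + as.integer(any(sch@rampBins[sch@gain > 0] > 0))
    }
  }
  new("SyntheticDataset", scenario = scenario, responses = responses,
      features = features, schedules = schedules, truth = truth,
      config = config)
}

## ---- plain-text serialization ----

#' Write a SyntheticDataset to a directory of CSV files + JSON sidecar
#'
#' Layout: `responses/<participant>.csv` (long format: concept, channel,
#' bin, value), `features/<model>.csv` (concept id column + one column per
#' dimension), `truth.csv`, and `config.json` holding the generator
#' configuration and the per-participant schedules.
#'
#' @param dataset a [SyntheticDataset][SyntheticDataset-class].
#' @param dir output directory (created if needed).
#' @param overwrite allow writing into a non-empty directory.
#' @return `dir`, invisibly.
#' @export
writeSyntheticDataset <- function(dataset, dir, overwrite = FALSE) {
  stopifnot(is(dataset, "SyntheticDataset"))
  if (dir.exists(dir) && length(dir(dir)) && !overwrite)
    stop("directory not empty (set overwrite = TRUE): ", dir)
  dir.create(file.path(dir, "responses"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "features"), showWarnings = FALSE)
  for (rt in dataset@responses) {
    d <- rt@data
    long <- data.frame(
      concept = rep(dimnames(d)[[1]], times = dim(d)[2] * dim(d)[3]),
      channel = rep(rep(seq_len(dim(d)[2]), each = dim(d)[1]), times = dim(d)[3]),
      bin = rep(seq_len(dim(d)[3]), each = dim(d)[1] * dim(d)[2]),
      value = as.vector(d)
    )
    utils::write.csv(long,
      file.path(dir, "responses", paste0(rt@participant, ".csv")),
      row.names = FALSE)
  }
  for (fm in dataset@features) writeFeatureTable(fm,
    file.path(dir, "features", paste0(fm@modelName, ".csv")))
  utils::write.csv(dataset@truth, file.path(dir, "truth.csv"), row.names = FALSE)
  cfg <- dataset@config
  sidecar <- list(
    scenario = dataset@scenario,
    config = list(
      nConcepts = cfg@nConcepts, nCategories = cfg@nCategories,
      nChannels = cfg@nChannels, nBins = cfg@nBins, binMs = cfg@binMs,
      nParticipants = cfg@nParticipants, nFeatureDims = cfg@nFeatureDims,
      categorySpread = cfg@categorySpread, noiseSd = cfg@noiseSd,
      seed = cfg@seed),
    schedules = lapply(dataset@schedules, function(s) list(
      onsetBin = s@onsetBin, rampBins = s@rampBins,
      offsetBin = s@offsetBin, gain = s@gain, dims = s@dims))
  )
  jsonlite::write_json(sidecar, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a long-format response CSV back into a ResponseTensor
#'
#' Inverse of the per-participant CSV written by
#' [writeSyntheticDataset()].
#'
#' @param path CSV with columns concept, channel, bin, value.
#' @param participant participant label.
#' @param binMs,t0Ms time axis metadata.
#' @return a [ResponseTensor][ResponseTensor-class].
#' @export
readResponseTensor <- function(path, participant = "p01", binMs = 20, t0Ms = 0) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("concept", "channel", "bin", "value")
  if (!all(need %in% names(long)))
    stop("response CSV must have columns: ", paste(need, collapse = ", "))
  conceptsU <- unique(long$concept)
  S <- max(long$channel); T <- max(long$bin); C <- length(conceptsU)
  a <- array(NA_real_, dim = c(C, S, T), dimnames = list(conceptsU, NULL, NULL))
  a[cbind(match(long$concept, conceptsU), long$channel, long$bin)] <- long$value
  if (anyNA(a)) stop("response CSV does not cover the full grid")
  new("ResponseTensor", participant = participant, data = a,
      binMs = binMs, t0Ms = t0Ms)
}
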