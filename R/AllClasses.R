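#' @import methods
NULL

#' Configuration for the synthetic MEG dataset generator
#'
#' Holds the dimensions and noise parameters of a simulated picture-naming
#' style experiment: a set of concepts organised into semantic categories,
#' a planar-gradiometer-like sensor array, and an epoch divided into fixed
#' time bins. The defaults mirror a typical whole-head MEG study of visual
#' concept identification: 60 concepts in 7 categories, 204 channels, and
#' 50 bins of 20 ms covering 0--1000 ms after stimulus onset.
#'
#' @slot nConcepts number of concepts (stimuli, after exemplar averaging).
#' @slot nCategories number of semantic categories the concepts fall into.
#' @slot nChannels number of sensor channels.
#' @slot nBins number of time bins in the epoch.
#' @slot binMs duration of one time bin, in milliseconds.
#' @slot nParticipants number of simulated participants.
#' @slot nFeatureDims dimensionality of the concept feature vectors.
#' @slot categorySpread within-category feature dispersion relative to the
#'   between-category dispersion (0 collapses each category onto its mean).
#' @slot noiseSd standard deviation of the additive sensor noise.
#' @slot seed integer seed; identical config + seed gives identical data.
#'
#' @seealso [generatorConfig()] for the user-facing constructor.
#' @export
setClass("GeneratorConfig",
  slots = c(
    nConcepts = "integer", nCategories = "integer", nChannels = "integer",
    nBins = "integer", binMs = "numeric", nParticipants = "integer",
    nFeatureDims = "integer", categorySpread = "numeric",
    noiseSd = "numeric", seed = "integer"
  )
)

setValidity("GeneratorConfig", function(object) {
  msg <- character()
  counts <- c(
    nConcepts = object@nConcepts, nCategories = object@nCategories,
    nChannels = object@nChannels, nBins = object@nBins,
    nParticipants = object@nParticipants, nFeatureDims = object@nFeatureDims
  )
  bad <- names(counts)[counts < 1L]
  if (length(bad)) msg <- c(msg, paste0("counts must be >= 1: ", paste(bad, collapse = ", ")))
  if (object@binMs <= 0) msg <- c(msg, "binMs must be > 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@categorySpread < 0) msg <- c(msg, "categorySpread must be >= 0")
  if (object@nCategories > object@nConcepts)
    msg <- c(msg, "nCategories must not exceed nConcepts")
  if (length(msg)) msg else TRUE
})

#' Concept-by-dimension feature vectors for one feature model
#'
#' A matrix of feature vectors (one row per concept) for a single feature
#' model, e.g. 300-dimensional word-embedding vectors or the reduced output
#' of one layer of a visual processing network. Row names are the concept
#' identifiers; their order is the canonical concept order that response
#' tensors decoded against this model must follow.
#'
#' @slot modelName label of the feature model (e.g. "semantic", "V1").
#' @slot vectors numeric concept x dimension matrix with concept row names.
#' @export
setClass("FeatureMatrix",
  slots = c(modelName = "character", vectors = "matrix")
)

setValidity("FeatureMatrix", function(object) {
  v <- object@vectors
  msg <- character()
  if (is.null(rownames(v))) msg <- c(msg, "vectors must have concept row names")
  else if (anyDuplicated(rownames(v))) msg <- c(msg, "duplicate concept ids")
  if (nrow(v) < 2L) msg <- c(msg, "need at least 2 concepts")
  if (!all(is.finite(v))) msg <- c(msg, "non-finite feature values")
  if (length(msg)) msg else TRUE
})

#' Exemplar-level feature vectors (one row per concept exemplar)
#'
#' Holds feature vectors for multiple exemplars (depictions) of each
#' concept, e.g. the layer outputs of a visual network for five different
#' photographs of the same object. Used as input to the cross-validated
#' PCA reduction that produces one concept-level vector per concept.
#'
#' @slot modelName label of the feature model.
#' @slot vectors numeric row x dimension matrix.
#' @slot conceptIds concept identifier for each row.
#' @slot exemplarIds exemplar identifier for each row.
#' @export
setClass("ExemplarFeatureMatrix",
  slots = c(
    modelName = "character", vectors = "matrix",
    conceptIds = "character", exemplarIds = "character"
  )
)

setValidity("ExemplarFeatureMatrix", function(object) {
  msg <- character()
  n <- nrow(object@vectors)
  if (length(object@conceptIds) != n || length(object@exemplarIds) != n)
    msg <- c(msg, "conceptIds/exemplarIds must match the number of rows")
  if (!all(is.finite(object@vectors))) msg <- c(msg, "non-finite feature values")
  if (anyDuplicated(paste(object@conceptIds, object@exemplarIds, sep = "\r")))
    msg <- c(msg, "duplicate (concept, exemplar) keys")
  if (length(msg)) msg else TRUE
})

#' Per-participant averaged response tensor
#'
#' The concept x channel x time-bin array of averaged evoked responses for
#' one participant (or for a grand average), together with the time axis
#' metadata. This is the tensor that all decoding operations consume; its
#' concept dimension must be named and ordered consistently with the
#' [FeatureMatrix][FeatureMatrix-class] it is decoded against.
#'
#' @slot participant participant label.
#' @slot data numeric 3-d array, concepts x channels x bins, with concept
#'   dimnames on the first margin.
#' @slot binMs bin duration in ms.
#' @slot t0Ms epoch start time in ms (0 = stimulus onset).
#' @export
setClass("ResponseTensor",
  slots = c(
    participant = "character", data = "array",
    binMs = "numeric", t0Ms = "numeric"
  )
)

setValidity("ResponseTensor", function(object) {
  msg <- character()
  d <- object@data
  if (length(dim(d)) != 3L) msg <- c(msg, "data must be a 3-d array")
  else {
    if (is.null(dimnames(d)[[1]])) msg <- c(msg, "concept dimnames required on margin 1")
    if (!all(is.finite(d))) msg <- c(msg, "non-finite response values")
  }
  if (object@binMs <= 0) msg <- c(msg, "binMs must be > 0")
  if (length(msg)) msg else TRUE
})

#' Encoding schedule of temporal signal components
#'
#' Describes how information enters the simulated sensor signal over time
#' as a set of components. Each component projects a subset of feature
#' dimensions into the channels with a gain that ramps up linearly from
#' zero at its onset bin, reaches full gain after `rampBins` bins, and
#' remains active through its offset bin (a component whose offset equals
#' the last bin of the epoch is "sustained"; earlier offsets give
#' transient components). Staggered sustained onsets model information
#' accumulation; a single shared onset models pure maintenance.
#'
#' All bins are 1-based indices into the epoch.
#'
#' @slot onsetBin integer vector of component onset bins.
#' @slot rampBins integer vector: bins from onset to full gain.
#' @slot offsetBin integer vector of last active bins.
#' @slot gain numeric vector of full gains (>= 0).
#' @slot dims list of integer vectors: the feature dimensions each
#'   component projects; disjoint across components.
#' @export
setClass("ComponentSchedule",
  slots = c(
    onsetBin = "integer", rampBins = "integer", offsetBin = "integer",
    gain = "numeric", dims = "list"
  )
)

setValidity("ComponentSchedule", function(object) {
  msg <- character()
  k <- length(object@onsetBin)
  if (k < 1L) msg <- c(msg, "need at least one component")
  lens <- c(length(object@rampBins), length(object@offsetBin),
            length(object@gain), length(object@dims))
  if (any(lens != k)) msg <- c(msg, "component fields must have equal length")
  else {
    if (any(object@onsetBin >= object@offsetBin))
      msg <- c(msg, "onsetBin must be < offsetBin for every component")
    if (any(object@gain < 0)) msg <- c(msg, "gain must be >= 0")
    if (any(object@rampBins < 0)) msg <- c(msg, "rampBins must be >= 0")
    alldims <- unlist(object@dims)
    if (anyDuplicated(alldims)) msg <- c(msg, "component dims must be disjoint")
  }
  if (length(msg)) msg else TRUE
})

#' Prediction-target distance as a function of analysis window
#'
#' Stores, for one participant and one feature model, the zero-shot
#' prediction-target Euclidean distance of every concept at every analysis
#' window, for either the sliding fixed-length or the cumulative window
#' scheme. Windows are half-open in bins; a window ending at bin b
#' (exclusive, 0-based; equivalently covering 1-based bins up to b) is
#' labelled `t0Ms + b * binMs`.
#'
#' @slot participant participant label.
#' @slot modelName feature model label.
#' @slot windowKind "sliding", "cumulative" or "point".
#' @slot distances concept x window matrix of distances (>= 0).
#' @slot windowEndMs numeric window end labels in ms.
#' @export
setClass("DistanceSeries",
  slots = c(
    participant = "character", modelName = "character",
    windowKind = "character", distances = "matrix", windowEndMs = "numeric"
  )
)

setValidity("DistanceSeries", function(object) {
  msg <- character()
  if (ncol(object@distances) != length(object@windowEndMs))
    msg <- c(msg, "one windowEndMs label per window column required")
  if (any(object@distances < 0)) msg <- c(msg, "distances must be >= 0")
  if (!object@windowKind %in% c("sliding", "cumulative", "point"))
    msg <- c(msg, "windowKind must be sliding, cumulative or point")
  if (length(msg)) msg else TRUE
})

#' Temporal generalization (cross-temporal decoding) matrix
#'
#' Mean prediction-target distance for models trained on one time bin and
#' tested on another, optionally with per-cell permutation p-values and
#' FDR-corrected significance flags. Rows index the training bin, columns
#' the testing bin; both axes share the same window labels.
#'
#' @slot meanDistance train-bin x test-bin matrix of concept-mean distances.
#' @slot pValues per-cell raw permutation p-values (NA where untested;
#'   0 x 0 matrix when significance was not computed).
#' @slot adjPValues FDR-adjusted p-values (same shape convention).
#' @slot significant logical flags at the stored alpha.
#' @slot alpha significance level used for the flags.
#' @slot windowEndMs window end labels in ms.
#' @slot nPermutations number of permutations used (0 if none).
#' @export
setClass("CrossTemporalMatrix",
  slots = c(
    meanDistance = "matrix", pValues = "matrix", adjPValues = "matrix",
    significant = "matrix", alpha = "numeric", windowEndMs = "numeric",
    nPermutations = "integer"
  )
)

setValidity("CrossTemporalMatrix", function(object) {
  msg <- character()
  m <- object@meanDistance
  if (nrow(m) != ncol(m)) msg <- c(msg, "meanDistance must be square")
  if (nrow(m) != length(object@windowEndMs))
    msg <- c(msg, "windowEndMs must label both axes")
  for (s in c("pValues", "adjPValues", "significant")) {
    x <- slot(object, s)
    if (length(x) && !all(dim(x) == dim(m)))
      msg <- c(msg, paste0(s, " must match meanDistance dimensions"))
  }
  if (length(msg)) msg else TRUE
})

#' Spatial units for searchlight analysis
#'
#' Abstract spatial layout for the searchlight RSA: unit identifiers,
#' positions in a common coordinate frame, and a symmetric adjacency
#' relation used to form connected clusters. Units typically stand in for
#' sensor channels or source-space vertices; the coordinate unit is
#' whatever the positions use, and searchlight radii are expressed in the
#' same unit.
#'
#' @slot ids character unit identifiers.
#' @slot positions numeric units x coordinates matrix.
#' @slot adjacency 2-column integer matrix of neighbouring unit index
#'   pairs (stored symmetric, no self-pairs).
#' @export
setClass("SpatialUnits",
  slots = c(ids = "character", positions = "matrix", adjacency = "matrix")
)

setValidity("SpatialUnits", function(object) {
  msg <- character()
  n <- length(object@ids)
  if (nrow(object@positions) != n) msg <- c(msg, "one position row per unit required")
  if (!all(is.finite(object@positions))) msg <- c(msg, "positions must be finite")
  if (anyDuplicated(object@ids)) msg <- c(msg, "duplicate unit ids")
  a <- object@adjacency
  if (length(a)) {
    if (ncol(a) != 2L) msg <- c(msg, "adjacency must have 2 columns")
    else {
      if (any(a < 1L | a > n)) msg <- c(msg, "adjacency indices out of range")
      if (any(a[, 1] == a[, 2])) msg <- c(msg, "self-pairs not allowed in adjacency")
      key <- paste(a[, 1], a[, 2])
      rev <- paste(a[, 2], a[, 1])
      if (!all(rev %in% key)) msg <- c(msg, "adjacency must be symmetric")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Bundle of simulated responses, features and ground truth
#'
#' The full output of the synthetic-data generator for one scenario:
#' per-participant response tensors, the feature matrices they encode,
#' the per-participant encoding schedules, and the ground-truth plateau
#' and generalization-onset bins that downstream analyses should recover.
#'
#' @slot scenario scenario name ("accumulation", "maintenance",
#'   "transient" or "null").
#' @slot responses list of [ResponseTensor][ResponseTensor-class], one per
#'   participant.
#' @slot features named list of [FeatureMatrix][FeatureMatrix-class].
#' @slot schedules list of [ComponentSchedule][ComponentSchedule-class],
#'   one per participant.
#' @slot truth data.frame with columns participant, plateauBin,
#'   onsetBin, transient (plateauBin is NA for the null scenario).
#' @slot config the [GeneratorConfig][GeneratorConfig-class] used.
#' @export
setClass("SyntheticDataset",
  slots = c(
    scenario = "character", responses = "list", features = "list",
    schedules = "list", truth = "data.frame", config = "GeneratorConfig"
  )
)

setValidity("SyntheticDataset", function(object) {
  msg <- character()
  cfg <- object@config
  np <- cfg@nParticipants
  if (length(object@responses) != np || length(object@schedules) != np)
    msg <- c(msg, "one response tensor and schedule per participant required")
  for (rt in object@responses) {
    if (!all(dim(rt@data) == c(cfg@nConcepts, cfg@nChannels, cfg@nBins))) {
      msg <- c(msg, "tensor shape inconsistent with config")
      break
    }
  }
  pb <- object@truth$plateauBin
  if (any(!is.na(pb) & (pb < 1L | pb > cfg@nBins)))
    msg <- c(msg, "truth plateau bins out of epoch range")
  if (length(msg)) msg else TRUE
})

## ---- accessors ----

#' @describeIn FeatureMatrix-class concept identifiers, in canonical order.
#' @param object a FeatureMatrix, ExemplarFeatureMatrix or ResponseTensor.
#' @export
setGeneric("concepts", function(object) standardGeneric("concepts"))

#' @rdname FeatureMatrix-class
#' @export
setMethod("concepts", "FeatureMatrix", function(object) rownames(object@vectors))

#' @rdname ExemplarFeatureMatrix-class
#' @export
setMethod("concepts", "ExemplarFeatureMatrix", function(object) unique(object@conceptIds))

#' @rdname ResponseTensor-class
#' @export
setMethod("concepts", "ResponseTensor", function(object) dimnames(object@data)[[1]])

#' Feature model label
#' @param object an object with a model-name slot.
#' @export
setGeneric("modelName", function(object) standardGeneric("modelName"))

#' @rdname modelName
#' @export
setMethod("modelName", "FeatureMatrix", function(object) object@modelName)

#' @rdname modelName
#' @export
setMethod("modelName", "ExemplarFeatureMatrix", function(object) object@modelName)

#' @rdname modelName
#' @export
setMethod("modelName", "DistanceSeries", function(object) object@modelName)

#' Concept feature vectors as a matrix
#' @param object a FeatureMatrix or ExemplarFeatureMatrix.
#' @export
setGeneric("featureVectors", function(object) standardGeneric("featureVectors"))

#' @rdname featureVectors
#' @export
setMethod("featureVectors", "FeatureMatrix", function(object) object@vectors)

#' @rdname featureVectors
#' @export
setMethod("featureVectors", "ExemplarFeatureMatrix", function(object) object@vectors)

#' Response data array
#' @param object a ResponseTensor.
#' @export
setGeneric("responseData", function(object) standardGeneric("responseData"))

#' @rdname responseData
#' @export
setMethod("responseData", "ResponseTensor", function(object) object@data)

#' Per-concept distance matrix of a DistanceSeries
#' @param object a DistanceSeries.
#' @export
setGeneric("distances", function(object) standardGeneric("distances"))

#' @rdname distances
#' @export
setMethod("distances", "DistanceSeries", function(object) object@distances)

#' Window end labels (ms)
#' @param object a DistanceSeries or CrossTemporalMatrix.
#' @export
setGeneric("windowEndMs", function(object) standardGeneric("windowEndMs"))

#' @rdname windowEndMs
#' @export
setMethod("windowEndMs", "DistanceSeries", function(object) object@windowEndMs)

#' @rdname windowEndMs
#' @export
setMethod("windowEndMs", "CrossTemporalMatrix", function(object) object@windowEndMs)

#' Concept-mean distance curve
#'
#' Mean prediction-target distance over concepts at each window; the curve
#' plotted in decoding-over-time figures and the input to plateau/trough
#' detection when working on the mean curve.
#'
#' @param object a DistanceSeries.
#' @return named numeric vector, one value per window.
#' @export
setGeneric("conceptMeans", function(object) standardGeneric("conceptMeans"))

#' @rdname conceptMeans
#' @export
setMethod("conceptMeans", "DistanceSeries", function(object) {
  m <- colMeans(object@distances)
  names(m) <- object@windowEndMs
  m
})

#' Mean-distance matrix of a CrossTemporalMatrix
#' @param object a CrossTemporalMatrix.
#' @export
setGeneric("meanDistance", function(object) standardGeneric("meanDistance"))

#' @rdname meanDistance
#' @export
setMethod("meanDistance", "CrossTemporalMatrix", function(object) object@meanDistance)

#' Per-cell significance flags of a CrossTemporalMatrix
#' @param object a CrossTemporalMatrix.
#' @export
setGeneric("significantCells", function(object) standardGeneric("significantCells"))

#' @rdname significantCells
#' @export
setMethod("significantCells", "CrossTemporalMatrix", function(object) object@significant)

#' Unit identifiers of a SpatialUnits layout
#' @param object a SpatialUnits object.
#' @export
setGeneric("unitIds", function(object) standardGeneric("unitIds"))

#' @rdname unitIds
#' @export
setMethod("unitIds", "SpatialUnits", function(object) object@ids)

#' Unit positions of a SpatialUnits layout
#' @param object a SpatialUnits object.
#' @export
setGeneric("unitPositions", function(object) standardGeneric("unitPositions"))

#' @rdname unitPositions
#' @export
setMethod("unitPositions", "SpatialUnits", function(object) object@positions)

#' Adjacency pairs of a SpatialUnits layout
#' @param object a SpatialUnits object.
#' @export
setGeneric("unitAdjacency", function(object) standardGeneric("unitAdjacency"))

#' @rdname unitAdjacency
#' @export
setMethod("unitAdjacency", "SpatialUnits", function(object) object@adjacency)

## ---- show methods ----

setMethod("show", "GeneratorConfig", function(object) {
  cat("GeneratorConfig:", object@nConcepts, "concepts in", object@nCategories,
      "categories;", object@nChannels, "channels x", object@nBins, "bins of",
      object@binMs, "ms;", object@nParticipants, "participants\n")
  cat("  feature dims:", object@nFeatureDims,
      " categorySpread:", object@categorySpread,
      " noiseSd:", object@noiseSd, " seed:", object@seed, "\n")
})

setMethod("show", "FeatureMatrix", function(object) {
  cat("FeatureMatrix '", object@modelName, "': ", nrow(object@vectors),
      " concepts x ", ncol(object@vectors), " dims\n", sep = "")
})

setMethod("show", "ExemplarFeatureMatrix", function(object) {
  cat("ExemplarFeatureMatrix '", object@modelName, "': ",
      nrow(object@vectors), " exemplar rows (",
      length(unique(object@conceptIds)), " concepts) x ",
      ncol(object@vectors), " dims\n", sep = "")
})

setMethod("show", "ResponseTensor", function(object) {
  d <- dim(object@data)
  cat("ResponseTensor '", object@participant, "': ", d[1], " concepts x ",
      d[2], " channels x ", d[3], " bins of ", object@binMs, " ms (t0 = ",
      object@t0Ms, " ms)\n", sep = "")
})

setMethod("show", "DistanceSeries", function(object) {
  cat("DistanceSeries (", object@windowKind, "): participant '",
      object@participant, "', model '", object@modelName, "', ",
      nrow(object@distances), " concepts x ", ncol(object@distances),
      " windows [", min(object@windowEndMs), "-", max(object@windowEndMs),
      " ms]\n", sep = "")
})

setMethod("show", "CrossTemporalMatrix", function(object) {
  cat("CrossTemporalMatrix: ", nrow(object@meanDistance), " x ",
      ncol(object@meanDistance), " train x test bins", sep = "")
  if (object@nPermutations > 0L)
    cat("; per-cell p-values from", object@nPermutations, "permutations")
  cat("\n")
})

setMethod("show", "SpatialUnits", function(object) {
  cat("SpatialUnits:", length(object@ids), "units in",
      ncol(object@positions), "-d coordinates;",
      nrow(object@adjacency) / 2, "adjacency edges\n")
})

setMethod("show", "SyntheticDataset", function(object) {
  cat("SyntheticDataset '", object@scenario, "': ",
      length(object@responses), " participants, models: ",
      paste(names(object@features), collapse = ", "), "\n", sep = "")
})
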