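## Loading, validating and reducing concept feature-vector tables.

.newFeatureMatrix <- function(modelName, vectors) {
  obj <- new("FeatureMatrix", modelName = modelName, vectors = vectors)
  validObject(obj)
  obj
}

#' Read a feature-vector table
#'
#' Supports the word2vec text format (header line "n dims", then one line
#' per concept: token followed by `dims` numbers) and CSV. A CSV with a
#' `concept` column (or unnamed first id column) yields a
#' [FeatureMatrix][FeatureMatrix-class]; a CSV that additionally has an
#' `exemplar` column yields an
#' [ExemplarFeatureMatrix][ExemplarFeatureMatrix-class] with one row per
#' (concept, exemplar) pair.
#'
#' @param path file to read.
#' @param format "auto" (by extension: `.csv` vs anything else =
#'   word2vec text), "word2vec" or "csv".
#' @param modelName label stored in the returned object (defaults to the
#'   file name without extension).
#' @return a FeatureMatrix or ExemplarFeatureMatrix.
#' @export
readFeatureTable <- function(path, format = c("auto", "word2vec", "csv"),
                             modelName = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(modelName))
    modelName <- sub("\\.[^.]*$", "", basename(path))
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "word2vec"
  if (format == "word2vec") .readWord2vec(path, modelName)
  else .readFeatureCsv(path, modelName)
}

.readWord2vec <- function(path, modelName) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("word2vec file too short: ", path)
  hdr <- suppressWarnings(as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]]))
  if (length(hdr) != 2L || anyNA(hdr))
    stop("word2vec header must be two integers 'n dims': ", path)
  n <- hdr[1]; d <- hdr[2]
  if (length(lines) - 1L != n)
    stop("word2vec header declares ", n, " rows but file has ", length(lines) - 1L)
  toks <- character(n)
  vecs <- matrix(NA_real_, n, d)
  for (i in seq_len(n)) {
    parts <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
    if (length(parts) != d + 1L)
      stop("ragged row ", i, " ('", parts[1], "'): expected ", d,
           " values, found ", length(parts) - 1L)
    toks[i] <- parts[1]
    vals <- suppressWarnings(as.numeric(parts[-1]))
    if (anyNA(vals) || any(!is.finite(vals)))
      stop("non-numeric or non-finite value in row ", i, " ('", parts[1], "')")
    vecs[i, ] <- vals
  }
  if (anyDuplicated(toks))
    stop("duplicate concept id: ", toks[duplicated(toks)][1])
  rownames(vecs) <- toks
  if (n < 2L) stop("need at least 2 concepts, found ", n)
  .newFeatureMatrix(modelName, vecs)
}

.readFeatureCsv <- function(path, modelName) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!ncol(df)) stop("empty CSV: ", path)
  idCol <- if ("concept" %in% names(df)) "concept" else names(df)[1]
  hasEx <- "exemplar" %in% names(df)
  valCols <- setdiff(names(df), c(idCol, if (hasEx) "exemplar"))
  if (!length(valCols)) stop("no feature columns in ", path)
  vals <- as.matrix(df[valCols])
  if (!is.numeric(vals)) {
    bad <- which(!apply(df[valCols], 1, function(r) {
      all(!is.na(suppressWarnings(as.numeric(r))))
    }))[1]
    stop("non-numeric feature value in row for concept '", df[[idCol]][bad], "'")
  }
  if (any(!is.finite(vals))) {
    bad <- which(rowSums(!is.finite(vals)) > 0)[1]
    stop("non-finite feature value in row for concept '", df[[idCol]][bad], "'")
  }
  ids <- as.character(df[[idCol]])
  if (hasEx) {
    obj <- new("ExemplarFeatureMatrix", modelName = modelName,
               vectors = unname(vals), conceptIds = ids,
               exemplarIds = as.character(df$exemplar))
    validObject(obj)
    obj
  } else {
    if (anyDuplicated(ids)) stop("duplicate concept id: ", ids[duplicated(ids)][1])
    if (length(ids) < 2L) stop("need at least 2 concepts, found ", length(ids))
    rownames(vals) <- ids
    .newFeatureMatrix(modelName, vals)
  }
}

#' Write a FeatureMatrix to CSV
#'
#' One row per concept: a `concept` id column followed by the feature
#' dimensions. Round-trips through [readFeatureTable()].
#'
#' @param features a [FeatureMatrix][FeatureMatrix-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeFeatureTable <- function(features, path) {
  stopifnot(is(features, "FeatureMatrix"))
  v <- features@vectors
  df <- data.frame(concept = rownames(v), v, check.names = FALSE,
                   row.names = NULL)
  names(df)[-1] <- paste0("d", seq_len(ncol(v)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Cross-validated PCA reduction with exemplar averaging
#'
#' Reduces exemplar-level feature vectors (e.g. visual network layer
#' outputs for several depictions of each concept) to one concept-level
#' vector per concept, under zero-shot discipline: when a test concept is
#' held out, the principal components are computed on the exemplar rows
#' of the training concepts only, both training and test exemplars are
#' projected onto those components, and the projections are averaged
#' within concept. Centering uses the training-row mean only. The
#' effective number of components is capped at
#' `min(nComponents, nTrainRows - 1, nDims)`.
#'
#' With `testConcept = NULL` (no holdout) the PCA is fitted on all rows
#' and a single concept-level [FeatureMatrix][FeatureMatrix-class] is
#' returned -- the variant used for representational similarity analysis.
#'
#' @param exemplars an [ExemplarFeatureMatrix][ExemplarFeatureMatrix-class].
#' @param testConcept concept id to hold out, or NULL for no holdout.
#' @param nComponents requested number of principal components (>= 1).
#' @param scale standardize each dimension to unit variance (on training
#'   rows) before PCA; default FALSE, i.e. centering only.
#' @return with a holdout: list with `train` (FeatureMatrix over the
#'   training concepts), `test` (named numeric vector for the held-out
#'   concept) and `nComponentsUsed`; without: a FeatureMatrix over all
#'   concepts (with `nComponentsUsed` attribute).
#' @examples
#' ex <- new("ExemplarFeatureMatrix", modelName = "toy",
#'           vectors = matrix(rnorm(60), 12, 5),
#'           conceptIds = rep(c("a", "b", "c", "d"), each = 3),
#'           exemplarIds = as.character(rep(1:3, 4)))
#' out <- crossvalPcaReduce(ex, testConcept = "a", nComponents = 4)
#' out$nComponentsUsed
#' @export
crossvalPcaReduce <- function(exemplars, testConcept = NULL, nComponents,
                              scale = FALSE) {
  stopifnot(is(exemplars, "ExemplarFeatureMatrix"))
  if (nComponents < 1) stop("nComponents must be >= 1")
  V <- exemplars@vectors
  cid <- exemplars@conceptIds
  if (!is.null(testConcept) && !testConcept %in% cid)
    stop("test concept not present: ", testConcept)
  trainRows <- if (is.null(testConcept)) rep(TRUE, nrow(V)) else cid != testConcept
  nTrain <- sum(trainRows)
  if (nTrain < 2L) stop("fewer than 2 training rows")
  k <- min(nComponents, nTrain - 1L, ncol(V))
  mu <- colMeans(V[trainRows, , drop = FALSE])
  sdv <- if (scale) {
    s <- apply(V[trainRows, , drop = FALSE], 2, stats::sd)
    ifelse(s > 0, s, 1)
  } else rep(1, ncol(V))
  Ztr <- sweep(sweep(V[trainRows, , drop = FALSE], 2, mu), 2, sdv, "/")
  sv <- svd(Ztr, nu = 0, nv = k)
  basis <- sv$v                                   # nDims x k
  Zall <- sweep(sweep(V, 2, mu), 2, sdv, "/")
  proj <- Zall %*% basis
  counts <- table(cid)
  avg <- rowsum(proj, cid)                        # grouped by sorted concept id
  avg <- avg / as.vector(counts[rownames(avg)])
  colnames(avg) <- paste0("pc", seq_len(k))
  if (is.null(testConcept)) {
    fm <- .newFeatureMatrix(paste0(exemplars@modelName, "_pca"), avg)
    attr(fm, "nComponentsUsed") <- k
    return(fm)
  }
  trainAvg <- avg[setdiff(rownames(avg), testConcept), , drop = FALSE]
  trainFm <- .newFeatureMatrix(paste0(exemplars@modelName, "_pca"), trainAvg)
  list(train = trainFm, test = avg[testConcept, ], nComponentsUsed = k)
}
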