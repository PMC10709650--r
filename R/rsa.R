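## Representational similarity analysis: model and brain dissimilarity
## matrices, searchlight over an abstract spatial layout, and one-sample
## cluster-based permutation testing across participants.

#' Construct a spatial layout for searchlight analysis
#'
#' @param ids unit identifiers.
#' @param positions numeric units x coordinates matrix.
#' @param adjacency 2-column matrix of neighbouring unit pairs, given as
#'   indices or ids; symmetrized automatically.
#' @return a [SpatialUnits][SpatialUnits-class] object.
#' @export
spatialUnits <- function(ids, positions, adjacency) {
  ids <- as.character(ids)
  positions <- as.matrix(positions)
  adjacency <- as.matrix(adjacency)
  if (is.character(adjacency)) {
    adjacency <- cbind(match(adjacency[, 1], ids), match(adjacency[, 2], ids))
    if (anyNA(adjacency)) stop("adjacency refers to unknown unit ids")
  }
  storage.mode(adjacency) <- "integer"
  adjacency <- unique(rbind(adjacency, adjacency[, 2:1, drop = FALSE]))
  obj <- new("SpatialUnits", ids = ids, positions = positions,
             adjacency = adjacency)
  validObject(obj)
  obj
}

#' Regular 2-d grid layout with rook adjacency
#'
#' Convenience layout for simulations: `nx * ny` units on an integer
#' grid, neighbours sharing a grid edge.
#'
#' @param nx,ny grid dimensions.
#' @param spacing grid spacing (coordinate units).
#' @return a [SpatialUnits][SpatialUnits-class] object.
#' @export
makeGridUnits <- function(nx, ny, spacing = 1) {
  g <- expand.grid(x = seq_len(nx), y = seq_len(ny))
  idx <- function(x, y) (y - 1L) * nx + x
  pairs <- NULL
  for (y in seq_len(ny)) for (x in seq_len(nx)) {
    if (x < nx) pairs <- rbind(pairs, c(idx(x, y), idx(x + 1L, y)))
    if (y < ny) pairs <- rbind(pairs, c(idx(x, y), idx(x, y + 1L)))
  }
  spatialUnits(sprintf("u%03d", seq_len(nx * ny)),
               as.matrix(g) * spacing, pairs)
}

#' Read a spatial layout from CSV files
#'
#' @param posPath CSV with an id column followed by coordinate columns.
#' @param adjPath CSV with two id columns listing neighbouring pairs, or
#'   a JSON file holding an array of two-element arrays.
#' @return a [SpatialUnits][SpatialUnits-class] object.
#' @export
readSpatialUnits <- function(posPath, adjPath) {
  pos <- utils::read.csv(posPath, stringsAsFactors = FALSE)
  ids <- as.character(pos[[1]])
  coords <- as.matrix(pos[-1])
  adj <- if (grepl("\\.json$", adjPath, ignore.case = TRUE)) {
    a <- jsonlite::read_json(adjPath, simplifyVector = TRUE)
    matrix(as.character(a), ncol = 2)
  } else {
    a <- utils::read.csv(adjPath, stringsAsFactors = FALSE)
    cbind(as.character(a[[1]]), as.character(a[[2]]))
  }
  spatialUnits(ids, coords, adj)
}

#' Model dissimilarity matrix (cosine distance)
#'
#' Pairwise cosine distances `1 - cos(v_i, v_j)` between concept feature
#' vectors; entries lie in [0, 2] with a zero diagonal.
#'
#' @param features a [FeatureMatrix][FeatureMatrix-class] with no
#'   zero-norm rows.
#' @return symmetric concept x concept matrix.
#' @export
modelDsm <- function(features) {
  stopifnot(is(features, "FeatureMatrix"))
  V <- features@vectors
  nrm <- sqrt(rowSums(V * V))
  if (any(nrm == 0))
    stop("zero-norm feature vector for concept: ",
         rownames(V)[which(nrm == 0)[1]])
  Vn <- V / nrm
  D <- 1 - tcrossprod(Vn)
  D[D < 0] <- 0
  diag(D) <- 0
  D
}

#' Brain dissimilarity matrix (Pearson correlation distance)
#'
#' Per concept, the response pattern over the selected channels and
#' window bins is flattened; entries are `1 - r` for the pairwise Pearson
#' correlation between concept patterns, in [0, 2] with zero diagonal.
#'
#' @param tensor a [ResponseTensor][ResponseTensor-class].
#' @param window a [windowSpec()] or NULL for the full epoch.
#' @param channels integer subset of channels (default all).
#' @return symmetric concept x concept matrix.
#' @export
brainDsm <- function(tensor, window = NULL, channels = NULL) {
  stopifnot(is(tensor, "ResponseTensor"))
  d <- tensor@data
  nBins <- dim(d)[3]
  if (is.null(window)) window <- windowSpec("cumulative", 0, nBins)
  if (window$endBin > nBins) stop("window beyond the epoch")
  bins <- (window$startBin + 1L):window$endBin
  if (is.null(channels)) channels <- seq_len(dim(d)[2])
  if (length(channels) * length(bins) < 2L)
    stop("patch must contain at least 2 channel x bin samples")
  P <- matrix(d[, channels, bins], nrow = dim(d)[1])   # concepts x features
  sds <- apply(P, 1, stats::sd)
  if (any(sds == 0))
    stop("zero-variance pattern for concept: ",
         dimnames(d)[[1]][which(sds == 0)[1]])
  D <- 1 - stats::cor(t(P))
  D[D < 0] <- 0
  diag(D) <- 0
  rownames(D) <- colnames(D) <- dimnames(d)[[1]]
  D
}

.upperTri <- function(M) M[upper.tri(M)]

#' RSA score: Spearman correlation of two DSMs
#'
#' Spearman rank correlation between the strict upper triangles of a
#' brain and a model dissimilarity matrix (average ranks for ties).
#' Invariant to any strictly monotone transform of either DSM's entries.
#'
#' @param brain,model square dissimilarity matrices over the same
#'   conditions in the same order.
#' @return correlation in [-1, 1].
#' @export
rsaScore <- function(brain, model) {
  if (!all(dim(brain) == dim(model)))
    stop("DSMs must have identical dimensions")
  if (!is.null(rownames(brain)) && !is.null(rownames(model)) &&
      !identical(rownames(brain), rownames(model)))
    stop("DSM condition ids do not match")
  b <- .upperTri(brain); m <- .upperTri(model)
  if (stats::sd(b) == 0 || stats::sd(m) == 0)
    stop("constant upper triangle: Spearman correlation undefined")
  stats::cor(b, m, method = "spearman")
}

#' Searchlight RSA over a spatial layout
#'
#' For every unit, the searchlight patch is the set of units within
#' `radius` (inclusive, Euclidean distance on the positions; radius 0
#' gives the unit alone). Per (participant, unit, window) the brain DSM
#' of the patch is scored against the model DSM with Spearman
#' correlation. Units map to tensor channels by position: unit i is
#' channel i. Degenerate patches (undefined correlations) yield NA
#' rather than an error.
#'
#' @param tensors list of [ResponseTensor][ResponseTensor-class], one per
#'   participant.
#' @param units a [SpatialUnits][SpatialUnits-class]; unit count must
#'   equal the tensor channel count.
#' @param radius searchlight radius in the coordinate unit of the
#'   positions.
#' @param model model DSM from [modelDsm()].
#' @param windows list of [windowSpec()] windows.
#' @return numeric array participants x units x windows with dimnames;
#'   the participant-level RSA maps.
#' @export
searchlightRsa <- function(tensors, units, radius, model, windows) {
  stopifnot(is(units, "SpatialUnits"), length(tensors) >= 1L)
  if (radius < 0) stop("radius must be >= 0")
  nU <- length(units@ids)
  if (nU != dim(tensors[[1]]@data)[2])
    stop("unit count must equal tensor channel count")
  dm <- as.matrix(stats::dist(units@positions))
  patches <- lapply(seq_len(nU), function(u) which(dm[u, ] <= radius))
  nP <- length(tensors); nW <- length(windows)
  out <- array(NA_real_, dim = c(nP, nU, nW),
               dimnames = list(
                 vapply(tensors, function(t) t@participant, character(1)),
                 units@ids, NULL))
  for (pi in seq_len(nP)) {
    for (wi in seq_len(nW)) {
      for (u in seq_len(nU)) {
        sc <- tryCatch(
          rsaScore(brainDsm(tensors[[pi]], windows[[wi]], patches[[u]]), model),
          error = function(e) NA_real_)
        out[pi, u, wi] <- sc
      }
    }
  }
  out
}

## connected components of the supra-threshold units, by declared adjacency
.clustersFromMask <- function(mask, adjacency, nUnits) {
  idx <- which(mask)
  if (!length(idx)) return(list())
  keep <- adjacency[adjacency[, 1] %in% idx & adjacency[, 2] %in% idx, ,
                    drop = FALSE]
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = as.character(keep[, 1]), to = as.character(keep[, 2])),
    directed = FALSE,
    vertices = data.frame(name = as.character(idx)))
  comp <- igraph::components(g)
  split(as.integer(igraph::V(g)$name), comp$membership)
}

.maxClusterStat <- function(tvals, thr, adjacency, nUnits) {
  cl <- .clustersFromMask(!is.na(tvals) & tvals > thr, adjacency, nUnits)
  if (!length(cl)) return(0)
  max(vapply(cl, function(u) sum(tvals[u]), numeric(1)))
}

#' One-sample cluster permutation test across participants
#'
#' Tests participant-level score maps (e.g. searchlight RSA maps) against
#' zero with nonparametric family-wise control: a one-sample t statistic
#' per unit, a cluster-forming threshold at the t quantile of
#' `clusterAlpha` (one-sided, positive, by default -- RSA hypotheses are
#' positive correlations), connected clusters via the declared adjacency,
#' cluster statistic = sum of t within the cluster, and a null of the
#' maximum cluster statistic under random per-participant sign flips.
#' Cluster p-values use the add-one convention; clusters with
#' `p <= clusterWideAlpha` are flagged significant. Units with missing
#' scores are excluded.
#'
#' @param maps participants x units matrix of scores (one analysis
#'   window), or the array returned by [searchlightRsa()] with a
#'   `window` index.
#' @param units a [SpatialUnits][SpatialUnits-class] providing adjacency.
#' @param clusterAlpha cluster-forming threshold (default 0.01).
#' @param clusterWideAlpha cluster-level significance threshold
#'   (default 0.05).
#' @param nPerm number of sign-flip permutations (default 5000).
#' @param seed RNG seed.
#' @param twoSided also form clusters of negative t values (default
#'   FALSE).
#' @param window window index when `maps` is a 3-d array.
#' @return list of class `clusterResult`: `clusters` (data.frame with
#'   cluster id, nUnits, statistic, p, significant), `members` (list of
#'   unit index vectors), `tValues`, `threshold`, `nPerm`.
#' @export
clusterPermutation1Samp <- function(maps, units, clusterAlpha = 0.01,
                                    clusterWideAlpha = 0.05, nPerm = 5000,
                                    seed = 1L, twoSided = FALSE,
                                    window = 1L) {
  stopifnot(is(units, "SpatialUnits"))
  if (length(dim(maps)) == 3L) maps <- maps[, , window, drop = TRUE]
  maps <- as.matrix(maps)
  nP <- nrow(maps); nU <- ncol(maps)
  if (nP < 2L) stop("need at least 2 participants")
  if (nU != length(units@ids)) stop("map units do not match the layout")
  ok <- colSums(is.na(maps)) == 0L
  thr <- stats::qt(1 - clusterAlpha, df = nP - 1)
  tvals <- rep(NA_real_, nU)
  tOf <- function(M) {
    m <- colMeans(M)
    s <- sqrt((colSums(M * M) - nP * m * m) / (nP - 1))
    tt <- m / (s / sqrt(nP))
    tt[s == 0] <- ifelse(m[s == 0] > 0, Inf, ifelse(m[s == 0] < 0, -Inf, 0))
    tt
  }
  tvals[ok] <- tOf(maps[, ok, drop = FALSE])
  sideStats <- function(tv) {
    s <- .maxClusterStat(tv, thr, units@adjacency, nU)
    if (twoSided) max(s, .maxClusterStat(-tv, thr, units@adjacency, nU)) else s
  }
  obsClusters <- .clustersFromMask(!is.na(tvals) & tvals > thr,
                                   units@adjacency, nU)
  if (twoSided) {
    neg <- .clustersFromMask(!is.na(tvals) & tvals < -thr, units@adjacency, nU)
    obsClusters <- c(obsClusters, neg)
  }
  stats <- vapply(obsClusters, function(u) sum(abs(tvals[u])), numeric(1))
  nullMax <- numeric(nPerm)
  .withSeed(seed, {
    for (b in seq_len(nPerm)) {
      signs <- sample(c(-1, 1), nP, replace = TRUE)
      tv <- rep(NA_real_, nU)
      tv[ok] <- tOf(maps[, ok, drop = FALSE] * signs)
      nullMax[b] <- sideStats(tv)
    }
  })
  p <- vapply(stats, function(s) .addOneP(nullMax, s), numeric(1))
  ord <- order(stats, decreasing = TRUE)
  clusters <- data.frame(
    cluster = seq_along(ord),
    nUnits = vapply(obsClusters[ord], length, integer(1)),
    statistic = stats[ord], p = p[ord],
    significant = p[ord] <= clusterWideAlpha
  )
  structure(list(clusters = clusters, members = obsClusters[ord],
                 tValues = tvals, threshold = thr, nPerm = nPerm,
                 clusterAlpha = clusterAlpha,
                 clusterWideAlpha = clusterWideAlpha),
            class = "clusterResult")
}

#' @export
print.clusterResult <- function(x, ...) {
  cat("Cluster permutation test:", nrow(x$clusters), "cluster(s), threshold t >",
      round(x$threshold, 3), "(", x$nPerm, "permutations )\n")
  if (nrow(x$clusters)) print(x$clusters, row.names = FALSE)
  invisible(x)
}
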