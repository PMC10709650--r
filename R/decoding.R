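## Zero-shot ridge decoding of feature vectors from response windows.
##
## All decoding operations share one engine built on the dual (kernel)
## form of multi-response ridge regression. For each leave-one-concept-out
## fold the predictors (channel x bin pairs in the analysis window) are
## standardized using training-fold statistics only, and the fitted
## mapping's prediction for the held-out concept reduces to a fixed linear
## combination of the training feature vectors:
##
##   pred = w' Y_train,   w = h + (1 - sum(h)) / n,
##   h = (Z_tr Z_tr' + lambda I)^{-1} Z_tr z_test
##
## (the second term carries the intercept, i.e. the training-fold mean of
## each feature dimension). The weight vectors w depend only on the
## responses, never on the feature vectors, so label permutations reuse
## them at negligible cost.

#' Euclidean distance between prediction and target vectors
#'
#' The evaluation metric of zero-shot decoding: the L2 distance between a
#' predicted feature vector and the held-out concept's true vector. It
#' matches the squared-error loss minimized by the ridge fit.
#'
#' @param predicted,target equal-length numeric vectors.
#' @return non-negative scalar.
#' @examples
#' euclideanDistance(c(0, 0), c(3, 4))  # 5
#' @export
euclideanDistance <- function(predicted, target) {
  if (length(predicted) != length(target))
    stop("predicted and target must have equal length")
  sqrt(sum((predicted - target)^2))
}

#' Analysis window specification
#'
#' Windows are half-open bin ranges `[startBin, endBin)` in 0-based bin
#' coordinates, equivalently covering 1-based bins `startBin+1 .. endBin`.
#' Cumulative windows are anchored at the epoch start.
#'
#' @param kind "sliding", "cumulative" or "point".
#' @param startBin,endBin 0-based start (inclusive) and end (exclusive)
#'   bin indices.
#' @return list of class `windowSpec`.
#' @export
windowSpec <- function(kind = c("sliding", "cumulative", "point"),
                       startBin, endBin) {
  kind <- match.arg(kind)
  startBin <- as.integer(startBin); endBin <- as.integer(endBin)
  if (startBin < 0L || startBin >= endBin)
    stop("need 0 <= startBin < endBin")
  if (kind == "cumulative" && startBin != 0L)
    stop("cumulative windows must start at bin 0")
  structure(list(kind = kind, startBin = startBin, endBin = endBin),
            class = "windowSpec")
}

## concepts x (channels * bins) predictor matrix; columns grouped by bin
.flattenTensor <- function(tensor) {
  d <- tensor@data
  matrix(d, nrow = dim(d)[1])
}

.checkDecodingInputs <- function(tensor, features, ridgePenalty) {
  stopifnot(is(tensor, "ResponseTensor"), is(features, "FeatureMatrix"))
  if (ridgePenalty < 0) stop("ridgePenalty must be >= 0")
  if (!identical(concepts(tensor), concepts(features)))
    stop("concept ids/order of tensor and features do not match")
}

## Per-fold training statistics and standardized rows.
## Returns Ztr (n x p) and zte (1 x p); columns constant in the training
## fold are mapped to 0 in both (keeps predictor indexing stable).
.foldStandardized <- function(X, testIdx) {
  tr <- setdiff(seq_len(nrow(X)), testIdx)
  n <- length(tr)
  Xtr <- X[tr, , drop = FALSE]
  mu <- colMeans(Xtr)
  ss <- colSums(Xtr * Xtr) - n * mu * mu
  ss[ss < 0] <- 0
  sdv <- sqrt(ss / (n - 1))
  zero <- sdv == 0
  div <- ifelse(zero, 1, sdv)
  Ztr <- sweep(sweep(Xtr, 2, mu), 2, div, "/")
  zte <- (X[testIdx, ] - mu) / div
  if (any(zero)) { Ztr[, zero] <- 0; zte[zero] <- 0 }
  list(train = tr, Ztr = Ztr, zte = zte, mu = mu, sd = sdv)
}

## Build per-fold prediction weights for a list of bin-windows.
## windows: list of 1-based bin index vectors.
.windowWeights <- function(X, nChannels, nBins, windows, ridgePenalty) {
  C <- nrow(X)
  nW <- length(windows)
  folds <- vector("list", C)
  for (ci in seq_len(C)) {
    fs <- .foldStandardized(X, ci)
    n <- length(fs$train)
    Gb <- array(0, c(n, n, nBins))
    Kb <- matrix(0, n, nBins)
    for (t in seq_len(nBins)) {
      cols <- ((t - 1L) * nChannels + 1L):(t * nChannels)
      Zt <- fs$Ztr[, cols, drop = FALSE]
      Gb[, , t] <- tcrossprod(Zt)
      Kb[, t] <- Zt %*% fs$zte[cols]
    }
    W <- matrix(0, n, nW)
    for (w in seq_len(nW)) {
      bins <- windows[[w]]
      G <- if (length(bins) == 1L) Gb[, , bins]
           else rowSums(Gb[, , bins, drop = FALSE], dims = 2)
      k <- if (length(bins) == 1L) Kb[, bins]
           else rowSums(Kb[, bins, drop = FALSE])
      h <- solve(G + diag(ridgePenalty, n), k)
      W[, w] <- h + (1 - sum(h)) / n
    }
    folds[[ci]] <- list(test = ci, train = fs$train, W = W)
  }
  list(folds = folds, nWindows = nW)
}

## Distances for a weight plan under a given feature matrix.
## Returns concepts x windows matrix.
.applyWeights <- function(plan, FV) {
  C <- length(plan$folds)
  out <- matrix(NA_real_, C, plan$nWindows)
  for (f in plan$folds) {
    P <- crossprod(f$W, FV[f$train, , drop = FALSE])   # nW x D
    diffs <- P - matrix(FV[f$test, ], nrow(P), ncol(P), byrow = TRUE)
    out[f$test, ] <- sqrt(rowSums(diffs * diffs))
  }
  out
}

.windowLabel <- function(tensor, endBins) tensor@t0Ms + endBins * tensor@binMs

#' Zero-shot distances for one analysis window
#'
#' For each concept in turn: flatten the window to a concept x
#' (channels x bins) predictor matrix, standardize each predictor using
#' the training concepts only, fit a multi-response ridge regression on
#' the remaining concepts' (response, feature vector) pairs, predict the
#' held-out concept's vector, and return the Euclidean prediction-target
#' distance. Predictors that are constant in the training fold are mapped
#' to 0 after standardization.
#'
#' @param tensor a [ResponseTensor][ResponseTensor-class].
#' @param features a [FeatureMatrix][FeatureMatrix-class] with matching
#'   concept order.
#' @param window a [windowSpec()] (or NULL for the full epoch).
#' @param ridgePenalty ridge penalty on the standardized predictors.
#' @return named numeric vector of per-concept distances.
#' @export
zeroShotWindowDistances <- function(tensor, features, window = NULL,
                                    ridgePenalty = 1) {
  .checkDecodingInputs(tensor, features, ridgePenalty)
  nBins <- dim(tensor@data)[3]
  if (is.null(window)) window <- windowSpec("cumulative", 0, nBins)
  if (window$endBin > nBins) stop("window beyond the epoch")
  bins <- (window$startBin + 1L):window$endBin
  X <- .flattenTensor(tensor)
  plan <- .windowWeights(X, dim(tensor@data)[2], nBins, list(bins), ridgePenalty)
  d <- .applyWeights(plan, features@vectors)[, 1]
  names(d) <- concepts(tensor)
  d
}

.slidingWindows <- function(nBins, widthBins) {
  nW <- nBins %/% widthBins                     # trailing partial dropped
  lapply(seq_len(nW), function(w) ((w - 1L) * widthBins + 1L):(w * widthBins))
}

.cumulativeWindows <- function(nBins, stepBins) {
  ends <- seq(stepBins, nBins, by = stepBins)
  lapply(ends, function(e) seq_len(e))
}

.decodeSeries <- function(tensor, features, windows, kind, ridgePenalty) {
  X <- .flattenTensor(tensor)
  nBins <- dim(tensor@data)[3]
  plan <- .windowWeights(X, dim(tensor@data)[2], nBins, windows, ridgePenalty)
  D <- .applyWeights(plan, features@vectors)
  rownames(D) <- concepts(tensor)
  ends <- vapply(windows, max, integer(1))
  new("DistanceSeries", participant = tensor@participant,
      modelName = features@modelName, windowKind = kind, distances = D,
      windowEndMs = .windowLabel(tensor, ends))
}

#' Sliding fixed-length window decoding
#'
#' Trains and tests one zero-shot model per non-overlapping fixed-width
#' window; each model sees only its own time slice. Trailing bins that do
#' not fill a whole window are dropped.
#'
#' @inheritParams zeroShotWindowDistances
#' @param widthBins window width in bins (default 1, i.e. one 20-ms bin
#'   at the default time resolution).
#' @return a [DistanceSeries][DistanceSeries-class] with
#'   `windowKind = "sliding"`.
#' @export
slidingDecode <- function(tensor, features, widthBins = 1, ridgePenalty = 1) {
  .checkDecodingInputs(tensor, features, ridgePenalty)
  nBins <- dim(tensor@data)[3]
  if (widthBins < 1 || widthBins > nBins) stop("invalid widthBins")
  .decodeSeries(tensor, features, .slidingWindows(nBins, as.integer(widthBins)),
                "sliding", ridgePenalty)
}

#' Cumulative window decoding
#'
#' Trains and tests one zero-shot model per cumulative window anchored at
#' the epoch start, with the end advancing by `stepBins` bins: each model
#' sees all signal up to its end point. The last window covers the whole
#' epoch when `stepBins` divides the bin count.
#'
#' @inheritParams zeroShotWindowDistances
#' @param stepBins window growth per step, in bins.
#' @return a [DistanceSeries][DistanceSeries-class] with
#'   `windowKind = "cumulative"`.
#' @export
cumulativeDecode <- function(tensor, features, stepBins = 1, ridgePenalty = 1) {
  .checkDecodingInputs(tensor, features, ridgePenalty)
  nBins <- dim(tensor@data)[3]
  if (stepBins < 1 || stepBins > nBins) stop("invalid stepBins")
  .decodeSeries(tensor, features, .cumulativeWindows(nBins, as.integer(stepBins)),
                "cumulative", ridgePenalty)
}

## Cross-temporal weight plan for a set of (trainBin, testBin) pairs.
## The standardizer fitted at the training bin travels with the model:
## test-bin data are scaled with the training bin's mu/sd.
.ctWeights <- function(X, nChannels, nBins, pairs, ridgePenalty) {
  C <- nrow(X)
  nP <- nrow(pairs)
  folds <- vector("list", C)
  for (ci in seq_len(C)) {
    fs <- .foldStandardized(X, ci)
    n <- length(fs$train)
    W <- matrix(0, n, nP)
    xteBins <- matrix(X[ci, ], nChannels, nBins)
    for (tt in unique(pairs[, 1])) {
      cols <- ((tt - 1L) * nChannels + 1L):(tt * nChannels)
      Zt <- fs$Ztr[, cols, drop = FALSE]
      G <- tcrossprod(Zt)
      sel <- which(pairs[, 1] == tt)
      testBins <- pairs[sel, 2]
      muT <- fs$mu[cols]; sdT <- fs$sd[cols]
      div <- ifelse(sdT > 0, sdT, 1)
      Zc <- (xteBins[, testBins, drop = FALSE] - muT) / div
      Zc[sdT == 0, ] <- 0
      K <- Zt %*% Zc                               # n x |sel|
      H <- solve(G + diag(ridgePenalty, n), K)
      W[, sel] <- H + rep((1 - colSums(H)) / n, each = n)
    }
    folds[[ci]] <- list(test = ci, train = fs$train, W = W)
  }
  list(folds = folds, nWindows = nP)
}

.allCtPairs <- function(nBins) {
  as.matrix(expand.grid(trainBin = seq_len(nBins), testBin = seq_len(nBins)))
}

#' Cross-temporal (temporal generalization) decoding
#'
#' For every ordered pair of time bins, a zero-shot model is trained on
#' the training concepts at the training bin and evaluated on the
#' held-out concept at the testing bin; the standardizer fitted at the
#' training bin is applied to the testing-bin data. Each cell holds the
#' mean prediction-target distance over concepts. Above-chance
#' off-diagonal cells indicate information shared between time points.
#'
#' @inheritParams zeroShotWindowDistances
#' @return a [CrossTemporalMatrix][CrossTemporalMatrix-class] (without
#'   p-values; see [crossTemporalPvalues()]).
#' @export
crossTemporalDecode <- function(tensor, features, ridgePenalty = 1) {
  .checkDecodingInputs(tensor, features, ridgePenalty)
  nBins <- dim(tensor@data)[3]
  pairs <- .allCtPairs(nBins)
  X <- .flattenTensor(tensor)
  plan <- .ctWeights(X, dim(tensor@data)[2], nBins, pairs, ridgePenalty)
  D <- .applyWeights(plan, features@vectors)       # concepts x pairs
  M <- matrix(colMeans(D), nBins, nBins)           # trainBin x testBin
  lab <- .windowLabel(tensor, seq_len(nBins))
  dimnames(M) <- list(lab, lab)
  new("CrossTemporalMatrix", meanDistance = M,
      pValues = matrix(numeric(0), 0, 0),
      adjPValues = matrix(numeric(0), 0, 0),
      significant = matrix(logical(0), 0, 0),
      alpha = NA_real_, windowEndMs = lab, nPermutations = 0L)
}

#' Average response tensors across participants
#'
#' Element-wise mean of the response arrays, for grand-average analyses.
#' All tensors must share concepts and shape.
#'
#' @param tensors list of [ResponseTensor][ResponseTensor-class].
#' @return a [ResponseTensor][ResponseTensor-class] labelled
#'   "grand_average".
#' @export
grandAverageTensor <- function(tensors) {
  stopifnot(length(tensors) >= 1L)
  ref <- tensors[[1]]
  acc <- ref@data
  for (rt in tensors[-1]) {
    if (!identical(concepts(rt), concepts(ref)) ||
        !all(dim(rt@data) == dim(ref@data)))
      stop("tensors must share concepts and shape")
    acc <- acc + rt@data
  }
  new("ResponseTensor", participant = "grand_average",
      data = acc / length(tensors), binMs = ref@binMs, t0Ms = ref@t0Ms)
}
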