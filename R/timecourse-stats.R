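## Permutation significance, FDR, plateau/trough detection and
## generalization-window onset for decoding time courses.
##
## The permutation null shuffles the concept -> feature-vector assignment
## once per permutation and reuses the shuffle across all windows (or
## cross-temporal cells), preserving the temporal dependence structure of
## the null. Because the fitted decoding weights depend only on the
## responses, each permutation costs one matrix product per fold rather
## than a refit.

.addOneP <- function(nullStats, observed) {
  (1 + sum(nullStats >= observed)) / (1 + length(nullStats))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (with monotonicity enforcement) and the
#' significance mask at `alpha`. Thin validated wrapper around
#' `stats::p.adjust(method = "BH")`.
#'
#' @param pvals numeric p-values in (0, 1].
#' @param alpha significance level for the mask.
#' @return list with `adjusted` and logical `significant`.
#' @examples
#' fdrBH(c(0.01, 0.02, 0.03, 0.04))$adjusted  # all 0.04
#' @export
fdrBH <- function(pvals, alpha = 0.05) {
  if (any(is.na(pvals)) || any(pvals <= 0 | pvals > 1))
    stop("p-values must lie in (0, 1]")
  adj <- stats::p.adjust(pvals, method = "BH")
  list(adjusted = adj, significant = adj <= alpha)
}

## shared permutation driver: stat per window = -mean distance
.permutationNull <- function(plan, FV, nPerm, seed) {
  C <- nrow(FV)
  nullStats <- matrix(NA_real_, nPerm, plan$nWindows)
  .withSeed(seed, {
    for (b in seq_len(nPerm)) {
      Fp <- FV[sample.int(C), , drop = FALSE]
      nullStats[b, ] <- -colMeans(.applyWeights(plan, Fp))
    }
  })
  nullStats
}

#' Permutation significance of decoding against chance
#'
#' Per window, the test statistic is the negated concept-mean
#' prediction-target distance (so larger = better decoding). The null
#' distribution is obtained by shuffling the concept-to-feature-vector
#' assignment once per permutation (the same shuffle across all windows)
#' and re-evaluating the decoder; p-values use the add-one convention
#' `(1 + #{null >= observed}) / (1 + nPerm)` and are FDR-corrected
#' across windows.
#'
#' @inheritParams zeroShotWindowDistances
#' @param kind "sliding" or "cumulative".
#' @param widthBins,stepBins window parameters, as in [slidingDecode()]
#'   and [cumulativeDecode()].
#' @param nPerm number of permutations (>= 1).
#' @param seed RNG seed for the permutations.
#' @param alpha significance level after FDR.
#' @return data.frame with columns windowEndMs, meanDistance, statistic,
#'   p, pAdj, significant; attributes nPerm and seed.
#' @export
permutationPvaluesDecoding <- function(tensor, features,
                                       kind = c("sliding", "cumulative"),
                                       widthBins = 1, stepBins = 1,
                                       nPerm = 1000, seed = 1L,
                                       ridgePenalty = 1, alpha = 0.05) {
  kind <- match.arg(kind)
  .checkDecodingInputs(tensor, features, ridgePenalty)
  if (nPerm < 1) stop("nPerm must be >= 1")
  nBins <- dim(tensor@data)[3]
  windows <- if (kind == "sliding") .slidingWindows(nBins, as.integer(widthBins))
             else .cumulativeWindows(nBins, as.integer(stepBins))
  X <- .flattenTensor(tensor)
  plan <- .windowWeights(X, dim(tensor@data)[2], nBins, windows, ridgePenalty)
  FV <- features@vectors
  obsDist <- colMeans(.applyWeights(plan, FV))
  obs <- -obsDist
  nullStats <- .permutationNull(plan, FV, nPerm, seed)
  p <- vapply(seq_along(obs), function(w) .addOneP(nullStats[, w], obs[w]),
              numeric(1))
  adj <- fdrBH(p, alpha)
  out <- data.frame(
    windowEndMs = .windowLabel(tensor, vapply(windows, max, integer(1))),
    meanDistance = obsDist, statistic = obs, p = p,
    pAdj = adj$adjusted, significant = adj$significant
  )
  attr(out, "nPerm") <- nPerm
  attr(out, "seed") <- seed
  attr(out, "kind") <- kind
  out
}

.consecutivePairs <- function(nBins) {
  t <- seq_len(nBins - 1L)
  cbind(trainBin = c(t, t + 1L), testBin = c(t + 1L, t))
}

#' Per-cell permutation significance of cross-temporal decoding
#'
#' Computes the cross-temporal mean-distance matrix and per-cell
#' permutation p-values using the shared label-shuffle null (one shuffle
#' per permutation, reused across cells), FDR-corrected jointly across
#' all tested cells. `cells = "consecutive"` restricts testing to the
#' (t, t+1) and (t+1, t) cells that determine the generalization-window
#' onset, which is considerably cheaper; untested cells hold NA.
#'
#' @inheritParams zeroShotWindowDistances
#' @param nPerm,seed,alpha as in [permutationPvaluesDecoding()].
#' @param cells "all" or "consecutive".
#' @return a [CrossTemporalMatrix][CrossTemporalMatrix-class] with
#'   p-values, adjusted p-values and significance flags.
#' @export
crossTemporalPvalues <- function(tensor, features, nPerm = 1000, seed = 1L,
                                 ridgePenalty = 1, alpha = 0.05,
                                 cells = c("all", "consecutive")) {
  cells <- match.arg(cells)
  .checkDecodingInputs(tensor, features, ridgePenalty)
  if (nPerm < 1) stop("nPerm must be >= 1")
  nBins <- dim(tensor@data)[3]
  S <- dim(tensor@data)[2]
  X <- .flattenTensor(tensor)
  allPairs <- .allCtPairs(nBins)
  fullPlan <- .ctWeights(X, S, nBins, allPairs, ridgePenalty)
  FV <- features@vectors
  M <- matrix(colMeans(.applyWeights(fullPlan, FV)), nBins, nBins)
  testPairs <- if (cells == "all") allPairs else .consecutivePairs(nBins)
  plan <- if (cells == "all") fullPlan
          else .ctWeights(X, S, nBins, testPairs, ridgePenalty)
  obs <- -M[testPairs]
  nullStats <- .permutationNull(plan, FV, nPerm, seed)
  p <- vapply(seq_along(obs), function(w) .addOneP(nullStats[, w], obs[w]),
              numeric(1))
  adj <- fdrBH(p, alpha)
  P <- matrix(NA_real_, nBins, nBins); P[testPairs] <- p
  A <- matrix(NA_real_, nBins, nBins); A[testPairs] <- adj$adjusted
  Sg <- matrix(NA, nBins, nBins); Sg[testPairs] <- adj$significant
  lab <- .windowLabel(tensor, seq_len(nBins))
  dimnames(M) <- dimnames(P) <- dimnames(A) <- dimnames(Sg) <- list(lab, lab)
  new("CrossTemporalMatrix", meanDistance = M, pValues = P, adjPValues = A,
      significant = Sg, alpha = alpha, windowEndMs = lab,
      nPermutations = as.integer(nPerm))
}

## paired t per column of a concepts x windows difference matrix
.pairedT <- function(M) {
  nC <- nrow(M)
  m <- colMeans(M)
  ss <- colSums(M * M) - nC * m * m
  ss[ss < 0] <- 0
  s <- sqrt(ss / (nC - 1))
  tt <- m / (s / sqrt(nC))
  tt[s == 0 & m == 0] <- 0
  tt
}

#' Paired sliding-vs-cumulative comparison
#'
#' Per window, a paired t statistic across concepts of the distance
#' difference (sliding minus cumulative; positive = cumulative better)
#' is compared to a permutation distribution; two-sided p-values use the
#' add-one convention and are FDR-corrected across windows.
#'
#' Two null distributions are available. The default,
#' `null = "label-shuffle"`, re-evaluates both window schemes under the
#' same concept-to-feature-vector shuffles used by the chance-level test
#' and recomputes the paired t for each; this null carries any
#' systematic, signal-independent difference between the schemes (for
#' instance, wider windows shrink ridge predictions toward the training
#' mean more strongly, which biases raw distances even on pure noise)
#' and is therefore calibrated for the question "does the cumulative
#' scheme decode *signal* better". It requires the response tensor and
#' feature matrix. `null = "sign-flip"` flips the sign of each concept's
#' difference independently per permutation; it needs only the two
#' distance series but tests the stricter hypothesis of a symmetric
#' difference distribution, which pure-noise data violate.
#'
#' @param sliding,cumulative [DistanceSeries][DistanceSeries-class]
#'   objects over the same concepts and window labels.
#' @param nPerm,seed,alpha as in [permutationPvaluesDecoding()].
#' @param null "label-shuffle" (default; needs `tensor` and `features`)
#'   or "sign-flip".
#' @param tensor,features the [ResponseTensor][ResponseTensor-class] and
#'   [FeatureMatrix][FeatureMatrix-class] the two series were decoded
#'   from (label-shuffle null only).
#' @param ridgePenalty ridge penalty used for the original decoding
#'   (label-shuffle null only).
#' @return data.frame with columns windowEndMs, meanDifference, t, p,
#'   pAdj, significant, cumulativeBetter.
#' @export
pairedModelComparison <- function(sliding, cumulative, nPerm = 1000,
                                  seed = 1L, alpha = 0.05,
                                  null = c("label-shuffle", "sign-flip"),
                                  tensor = NULL, features = NULL,
                                  ridgePenalty = 1) {
  null <- match.arg(null)
  stopifnot(is(sliding, "DistanceSeries"), is(cumulative, "DistanceSeries"))
  if (!identical(rownames(sliding@distances), rownames(cumulative@distances)))
    stop("the two series must cover the same concepts")
  if (!isTRUE(all.equal(sliding@windowEndMs, cumulative@windowEndMs)))
    stop("the two series must share window labels")
  D <- sliding@distances - cumulative@distances     # concepts x windows
  nC <- nrow(D)
  if (nC < 2L) stop("paired t undefined for a single concept")
  tObs <- .pairedT(D)
  nW <- ncol(D)
  nullT <- matrix(NA_real_, nPerm, nW)
  if (null == "sign-flip") {
    .withSeed(seed, {
      for (b in seq_len(nPerm)) {
        signs <- sample(c(-1, 1), nC, replace = TRUE)
        nullT[b, ] <- .pairedT(D * signs)
      }
    })
  } else {
    if (is.null(tensor) || is.null(features))
      stop("label-shuffle null requires tensor and features")
    .checkDecodingInputs(tensor, features, ridgePenalty)
    nBins <- dim(tensor@data)[3]
    step <- round((sliding@windowEndMs[1] - tensor@t0Ms) / tensor@binMs)
    X <- .flattenTensor(tensor)
    S <- dim(tensor@data)[2]
    planS <- .windowWeights(X, S, nBins, .slidingWindows(nBins, step),
                            ridgePenalty)
    planC <- .windowWeights(X, S, nBins, .cumulativeWindows(nBins, step),
                            ridgePenalty)
    if (planS$nWindows != nW || planC$nWindows != nW)
      stop("window labels do not match the tensor's bin structure")
    FV <- features@vectors
    .withSeed(seed, {
      for (b in seq_len(nPerm)) {
        Fp <- FV[sample.int(nrow(FV)), , drop = FALSE]
        nullT[b, ] <- .pairedT(.applyWeights(planS, Fp) -
                               .applyWeights(planC, Fp))
      }
    })
  }
  p <- vapply(seq_len(nW), function(w) {
    .addOneP(abs(nullT[, w]), abs(tObs[w]))
  }, numeric(1))
  adj <- fdrBH(p, alpha)
  data.frame(
    windowEndMs = sliding@windowEndMs, meanDifference = colMeans(D),
    t = tObs, p = p, pAdj = adj$adjusted, significant = adj$significant,
    cumulativeBetter = adj$significant & colMeans(D) > 0
  )
}

#' Plateau / trough detection by the 5% rule
#'
#' Locates the point after which a distance curve no longer meaningfully
#' decreases: with first value `d0`, series minimum `dmin` and total
#' reduction `R = d0 - dmin`, returns the earliest window whose value is
#' at most `dmin + threshold * R`. Applied to a cumulative curve the
#' located point is the plateau; applied to a sliding curve it is the
#' trough. If the series never decreases (`R <= 0`) the first window is
#' returned. The rule is invariant to positive affine rescaling of the
#' series.
#'
#' @param values numeric distance values, one per window, in time order.
#' @param threshold residual fraction of the total reduction (default
#'   0.05, i.e. within 5% of the total reduction).
#' @param windowEndMs optional window labels; returned alongside the
#'   index when supplied.
#' @param reference "min" (default) measures the reduction to the series
#'   minimum; "final" measures it to the last value.
#' @return list with `index` (1-based window index) and `timeMs` (NA if
#'   no labels given).
#' @examples
#' detectStabilizationPoint(c(10, 8, 6, 5, 5, 5))$index  # 4
#' @export
detectStabilizationPoint <- function(values, threshold = 0.05,
                                     windowEndMs = NULL,
                                     reference = c("min", "final")) {
  reference <- match.arg(reference)
  if (length(values) < 2L) stop("need at least 2 windows")
  if (threshold < 0 || threshold >= 1) stop("threshold must be in [0, 1)")
  if (!is.null(windowEndMs) && length(windowEndMs) != length(values))
    stop("windowEndMs must match values")
  d0 <- values[1]
  ref <- if (reference == "min") min(values) else values[length(values)]
  R <- d0 - ref
  idx <- if (R <= 0) 1L else which(values <= ref + threshold * R)[1]
  list(index = as.integer(idx),
       timeMs = if (is.null(windowEndMs)) NA_real_ else windowEndMs[idx])
}

#' Onset of the generalization window
#'
#' The earliest time bin after which there is significant cross-temporal
#' generalization between consecutive time points: the first index `t`
#' such that the (t, t+1) and (t+1, t) cells are both significant (or
#' either, with `requireBoth = FALSE`).
#'
#' @param significant square logical matrix of per-cell significance
#'   flags (train bin x test bin), or a
#'   [CrossTemporalMatrix][CrossTemporalMatrix-class] carrying one.
#' @param requireBoth require significance in both train/test directions.
#' @return 1-based bin index, or NA if no such pair exists.
#' @export
generalizationOnset <- function(significant, requireBoth = TRUE) {
  if (is(significant, "CrossTemporalMatrix")) {
    if (!length(significant@significant))
      stop("CrossTemporalMatrix carries no significance flags")
    significant <- significant@significant
  }
  if (!is.matrix(significant) || nrow(significant) != ncol(significant))
    stop("significance flags must form a square matrix")
  n <- nrow(significant)
  if (n < 2L) stop("matrix must be at least 2 x 2")
  for (t in seq_len(n - 1L)) {
    fwd <- isTRUE(significant[t, t + 1L])
    bwd <- isTRUE(significant[t + 1L, t])
    hit <- if (requireBoth) fwd && bwd else fwd || bwd
    if (hit) return(t)
  }
  NA_integer_
}
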