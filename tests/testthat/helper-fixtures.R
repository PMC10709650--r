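# Small fixtures shared across test files. Everything is generated in
# code; sizes are kept small so the whole suite stays fast.

smallConfig <- function(seed = 1L, nParticipants = 1L, noiseSd = 0.5,
                        nConcepts = 20L, nChannels = 24L, nBins = 20L,
                        nFeatureDims = 40L) {
  generatorConfig(
    nConcepts = nConcepts, nCategories = 4, nChannels = nChannels,
    nBins = nBins, binMs = 20, nParticipants = nParticipants,
    nFeatureDims = nFeatureDims, noiseSd = noiseSd, seed = seed
  )
}

# deterministic tiny tensor + matching features, linearly encodable
linearToyData <- function(nConcepts = 30, nChannels = 15, nBins = 6,
                          nDims = 5, noiseSd = 0, seed = 42) {
  fm <- withr::with_seed(seed, {
    v <- matrix(rnorm(nConcepts * nDims), nConcepts, nDims)
    rownames(v) <- sprintf("c%02d", seq_len(nConcepts))
    new("FeatureMatrix", modelName = "toy", vectors = v)
  })
  dat <- withr::with_seed(seed + 1, {
    A <- matrix(rnorm(nChannels * nDims), nChannels, nDims)
    base <- featureVectors(fm) %*% t(A)       # concepts x channels
    arr <- array(rep(base, nBins), dim = c(nConcepts, nChannels, nBins))
    if (noiseSd > 0)
      arr <- arr + noiseSd * array(rnorm(length(arr)), dim = dim(arr))
    dimnames(arr) <- list(rownames(featureVectors(fm)), NULL, NULL)
    arr
  })
  list(
    tensor = new("ResponseTensor", participant = "toy", data = dat,
                 binMs = 20, t0Ms = 0),
    features = fm
  )
}

# brute-force connected components on an adjacency pair list (oracle for
# the igraph-based cluster search)
bruteForceComponents <- function(mask, adjacency) {
  idx <- which(mask)
  if (!length(idx)) return(list())
  nb <- lapply(idx, function(u) {
    cand <- c(adjacency[adjacency[, 1] == u, 2], adjacency[adjacency[, 2] == u, 1])
    intersect(unique(cand), idx)
  })
  names(nb) <- idx
  seen <- integer(0)
  comps <- list()
  for (u in idx) {
    if (u %in% seen) next
    comp <- u
    frontier <- u
    while (length(frontier)) {
      nxt <- unique(unlist(nb[as.character(frontier)]))
      nxt <- setdiff(nxt, comp)
      comp <- c(comp, nxt)
      frontier <- nxt
    }
    comps[[length(comps) + 1L]] <- sort(comp)
    seen <- c(seen, comp)
  }
  comps
}
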