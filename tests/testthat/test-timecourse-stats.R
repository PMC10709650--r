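test_that("BH adjustment matches the hand-computed step-up values", {
  out <- fdrBH(c(0.01, 0.02, 0.03, 0.04), alpha = 0.05)
  expect_equal(out$adjusted, rep(0.04, 4))
  expect_true(all(out$significant))
  expect_equal(fdrBH(0.03)$adjusted, 0.03)
  expect_equal(fdrBH(rep(0.2, 5))$adjusted, rep(0.2, 5))
  # fixed points of the step-up adjustment stay fixed: a constant
  # adjusted vector re-adjusts to itself
  adj <- fdrBH(c(0.01, 0.02, 0.03, 0.04))$adjusted
  expect_equal(fdrBH(adj)$adjusted, adj)
  expect_equal(fdrBH(rep(0.31, 6))$adjusted, rep(0.31, 6))
  expect_error(fdrBH(c(0.5, 0)), "0, 1")
  expect_error(fdrBH(c(0.5, 1.2)), "0, 1")
})

test_that("permutation p-values follow the add-one convention", {
  # decodable signal: observed beats every null draw -> p = 1/(n+1)
  cfg <- smallConfig(seed = 20, noiseSd = 0.3, nConcepts = 16, nBins = 6,
                     nChannels = 16)
  ds <- makeScenario("maintenance", cfg)
  sig <- permutationPvaluesDecoding(ds@responses[[1]], ds@features$semantic,
                                    kind = "cumulative", nPerm = 50, seed = 2)
  expect_true(all(sig$p >= 1 / 51))
  expect_equal(min(sig$p), 1 / 51)       # late windows decode perfectly
  expect_true(all(sig$p <= 1))
  expect_equal(nrow(sig), 6)
  expect_error(permutationPvaluesDecoding(ds@responses[[1]],
    ds@features$semantic, nPerm = 0), "nPerm")
})

test_that("null-scenario p-values are roughly uniform and rarely significant", {
  cfg <- smallConfig(seed = 21, nConcepts = 16, nBins = 10, nChannels = 12)
  ds <- makeScenario("null", cfg)
  sig <- permutationPvaluesDecoding(ds@responses[[1]], ds@features$semantic,
                                    kind = "sliding", nPerm = 120, seed = 3)
  expect_gt(suppressWarnings(ks.test(sig$p, "punif"))$p.value, 0.01)
  expect_lte(mean(sig$significant), 0.1)
})

test_that("paired comparison handles identity, signal and degenerate input", {
  cfg <- smallConfig(seed = 22, noiseSd = 0.6, nBins = 8)
  ds <- makeScenario("accumulation", cfg)
  sl <- slidingDecode(ds@responses[[1]], ds@features$semantic)
  cu <- cumulativeDecode(ds@responses[[1]], ds@features$semantic)
  # identical series under the sign-flip null: t = 0, p = 1 everywhere
  same <- pairedModelComparison(sl, sl, nPerm = 60, seed = 4,
                                null = "sign-flip")
  expect_true(all(same$t == 0))
  expect_true(all(same$p == 1))
  expect_false(any(same$significant))
  cmp <- pairedModelComparison(sl, cu, nPerm = 60, seed = 4,
                               null = "label-shuffle",
                               tensor = ds@responses[[1]],
                               features = ds@features$semantic)
  expect_equal(cmp$meanDifference,
               unname(conceptMeans(sl) - conceptMeans(cu)))
  # label-shuffle null requires the decoding inputs
  expect_error(pairedModelComparison(sl, cu, nPerm = 10), "requires tensor")
  # single concept: paired t undefined
  one <- new("DistanceSeries", participant = "p", modelName = "m",
             windowKind = "sliding",
             distances = matrix(1:3, 1, 3, dimnames = list("c1", NULL)),
             windowEndMs = c(20, 40, 60))
  expect_error(pairedModelComparison(one, one, nPerm = 10,
                                     null = "sign-flip"), "single concept")
  # mismatched windows
  slShort <- new("DistanceSeries", participant = "p", modelName = "m",
                 windowKind = "sliding", distances = distances(sl)[, 1:3],
                 windowEndMs = windowEndMs(sl)[1:3])
  expect_error(pairedModelComparison(slShort, cu, null = "sign-flip"),
               "window labels")
})

test_that("stabilization point reproduces worked examples and invariances", {
  r <- detectStabilizationPoint(c(10, 8, 6, 5, 5, 5), 0.05,
                                windowEndMs = 20 * (1:6))
  expect_equal(r$index, 4L)              # cutoff 5.25; first value <= is pos 4
  expect_equal(r$timeMs, 80)
  expect_equal(detectStabilizationPoint(rep(3, 5))$index, 1L)
  expect_equal(detectStabilizationPoint(1:5)$index, 1L)
  # affine invariance: same index for a*d + b, a > 0
  v <- c(9, 7.5, 4, 3.2, 3.05, 3, 3.01, 3)
  i0 <- detectStabilizationPoint(v)$index
  for (ab in list(c(2, 5), c(0.1, -1), c(7, 0))) {
    expect_equal(detectStabilizationPoint(ab[1] * v + ab[2])$index, i0)
  }
  # reference = "final" variant measures reduction to the last value
  w <- c(10, 4, 2, 4)                    # dips below its final value
  expect_equal(detectStabilizationPoint(w, reference = "min")$index, 3L)
  expect_equal(detectStabilizationPoint(w, reference = "final")$index, 2L)
  expect_error(detectStabilizationPoint(5), "at least 2")
  expect_error(detectStabilizationPoint(c(1, 2), threshold = 1), "threshold")
})

test_that("generalization onset scans consecutive-pair significance", {
  n <- 20
  flags <- matrix(FALSE, n, n)
  flags[12, 13] <- flags[13, 12] <- TRUE
  flags[15, 16] <- flags[16, 15] <- TRUE
  expect_equal(generalizationOnset(flags), 12L)
  expect_true(is.na(generalizationOnset(matrix(FALSE, n, n))))
  expect_equal(generalizationOnset(matrix(TRUE, n, n)), 1L)
  # one-directional variant
  oneWay <- matrix(FALSE, n, n)
  oneWay[5, 6] <- TRUE
  expect_true(is.na(generalizationOnset(oneWay)))
  expect_equal(generalizationOnset(oneWay, requireBoth = FALSE), 5L)
  expect_error(generalizationOnset(matrix(TRUE, 1, 1)), "2 x 2")
})

test_that("cross-temporal significance marks consecutive generalization", {
  cfg <- smallConfig(seed = 23, noiseSd = 0.4, nConcepts = 16, nBins = 12,
                     nChannels = 16)
  ds <- makeScenario("maintenance", cfg)
  ctp <- crossTemporalPvalues(ds@responses[[1]], ds@features$semantic,
                              nPerm = 80, seed = 5, cells = "consecutive")
  on <- generalizationOnset(ctp)
  expect_false(is.na(on))
  # onset close to the ground-truth first-information bin
  expect_lt(abs(on - ds@truth$onsetBin[1]), 4)
  # untested cells are NA, tested cells carry p-values
  expect_true(is.na(ctp@pValues[1, 3]))
  expect_false(is.na(ctp@pValues[1, 2]))
  # "all" mode fills the whole matrix on a tiny problem
  cfg2 <- smallConfig(seed = 24, noiseSd = 0.5, nConcepts = 10, nBins = 5,
                      nChannels = 8, nFeatureDims = 12)
  ds2 <- makeScenario("maintenance", cfg2)
  ctAll <- crossTemporalPvalues(ds2@responses[[1]], ds2@features$semantic,
                                nPerm = 40, seed = 6, cells = "all")
  expect_false(anyNA(ctAll@pValues))
})
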