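test_that("generator is deterministic and shape-consistent", {
  cfg <- smallConfig(seed = 9, nParticipants = 2)
  ds1 <- makeScenario("accumulation", cfg)
  ds2 <- makeScenario("accumulation", cfg)
  expect_identical(responseData(ds1@responses[[1]]),
                   responseData(ds2@responses[[1]]))
  expect_identical(featureVectors(ds1@features$semantic),
                   featureVectors(ds2@features$semantic))
  expect_identical(ds1@truth, ds2@truth)
  for (rt in ds1@responses)
    expect_equal(dim(responseData(rt)), c(20L, 24L, 20L))
  # a different seed changes the data
  ds3 <- makeScenario("accumulation", smallConfig(seed = 10, nParticipants = 2))
  expect_false(identical(responseData(ds1@responses[[1]]),
                         responseData(ds3@responses[[1]])))
})

test_that("feature sets are category-structured and respect the spread", {
  cfg <- smallConfig(seed = 4)
  fs <- makeFeatureSets(cfg)
  V <- featureVectors(fs$semantic)
  expect_equal(dim(V), c(20L, 40L))
  # within-category vectors are more similar than between-category ones
  catOf <- sort(rep_len(seq_len(4), 20))
  D <- as.matrix(dist(V))
  same <- outer(catOf, catOf, "==") & upper.tri(D)
  diff <- outer(catOf, catOf, "!=") & upper.tri(D)
  expect_lt(mean(D[same]), mean(D[diff]))
  # zero dispersion collapses each category onto its mean
  cfg0 <- generatorConfig(nConcepts = 12, nCategories = 3, nChannels = 5,
                          nBins = 5, nParticipants = 1, nFeatureDims = 8,
                          categorySpread = 0, seed = 2)
  V0 <- featureVectors(makeFeatureSets(cfg0)$semantic)
  for (k in 1:3) {
    rows <- which(sort(rep_len(1:3, 12)) == k)
    expect_equal(max(apply(V0[rows, ], 2, function(x) diff(range(x)))), 0)
  }
  expect_error(makeFeatureSets(generatorConfig(nConcepts = 5, nCategories = 9,
                                               nParticipants = 1)),
               "nCategories")
})

test_that("layer chains couple consecutive layers; full mixing decouples", {
  cfg <- smallConfig(seed = 6)
  fs <- makeFeatureSets(cfg, nLayers = 4, layerMix = 0.5)
  expect_named(fs, c("semantic", "V1", "V2", "V4", "IT"))
  r12 <- cor(as.vector(featureVectors(fs$V1)), as.vector(featureVectors(fs$V2)))
  r14 <- cor(as.vector(featureVectors(fs$V1)), as.vector(featureVectors(fs$IT)))
  expect_gt(r12, r14)
  # mixing weight 1: adjacent layers are independent draws
  fs1 <- makeFeatureSets(cfg, nLayers = 3, layerMix = 1)
  r <- cor(as.vector(featureVectors(fs1$layer1)),
           as.vector(featureVectors(fs1$layer2)))
  expect_lt(abs(r), 0.1)
})

test_that("noiseless single-component responses lie in a low-rank subspace", {
  cfg <- generatorConfig(nConcepts = 15, nCategories = 3, nChannels = 12,
                         nBins = 8, nParticipants = 1, nFeatureDims = 20,
                         noiseSd = 0, seed = 5)
  fs <- makeFeatureSets(cfg)
  sch <- componentSchedule(onsetBin = 1, rampBins = 0, offsetBin = 8,
                           gain = 1, dims = list(1:4))
  rt <- simulateResponses(fs$semantic, sch, cfg)
  slice <- responseData(rt)[, , 5]          # concepts x channels
  expect_lte(qr(slice)$rank, 4)
  # zero gain everywhere: pure noise with sd ~ noiseSd
  cfgN <- generatorConfig(nConcepts = 15, nCategories = 3, nChannels = 12,
                          nBins = 8, nParticipants = 1, nFeatureDims = 20,
                          noiseSd = 0.7, seed = 5)
  sch0 <- componentSchedule(1, 0, 8, 0, list(1:4))
  rt0 <- simulateResponses(fs$semantic, sch0, cfgN)
  expect_equal(sd(responseData(rt0)), 0.7, tolerance = 0.05)
})

test_that("simulateResponses validates schedule against features", {
  cfg <- smallConfig()
  fs <- makeFeatureSets(cfg)
  bad <- componentSchedule(1, 0, 20, 1, list(39:41))  # dim 41 > 40
  expect_error(simulateResponses(fs$semantic, bad, cfg), "dims")
  tooLong <- componentSchedule(1, 0, 25, 1, list(1:4))
  expect_error(simulateResponses(fs$semantic, tooLong, cfg), "epoch")
})

test_that("ground-truth plateau follows the schedule definition", {
  mk <- function(on, ramp, off, gain = rep(1, length(on)))
    componentSchedule(on, ramp, off,
                      gain, as.list(split(seq_len(10 * length(on)),
                                          rep(seq_along(on), each = 10))))
  expect_equal(groundTruthPlateau(mk(c(5, 12), c(0, 3), c(50, 50)), 50),
               list(plateauBin = 15L, transient = FALSE))
  # maintenance: shared onset, no ramp
  expect_equal(groundTruthPlateau(mk(c(5, 5), c(0, 0), c(50, 50)), 50)$plateauBin, 5L)
  # transient-only schedule is flagged
  gt <- groundTruthPlateau(mk(c(5, 12), c(2, 2), c(20, 30)), 50)
  expect_equal(gt$plateauBin, 14L)
  expect_true(gt$transient)
  # zero-gain schedule: undefined plateau
  expect_true(is.na(groundTruthPlateau(mk(5, 0, 50, gain = 0), 50)$plateauBin))
})

test_that("named scenarios carry consistent ground truth", {
  cfg <- smallConfig(seed = 3, nParticipants = 3)
  acc <- makeScenario("accumulation", cfg)
  expect_true(all(!acc@truth$transient))
  expect_true(all(acc@truth$plateauBin > acc@truth$onsetBin))
  mnt <- makeScenario("maintenance", cfg)
  # maintenance: plateau equals shared onset + ramp (per-participant jitter)
  for (i in 1:3) {
    sch <- mnt@schedules[[i]]
    expect_equal(mnt@truth$plateauBin[i],
                 unique(sch@onsetBin + sch@rampBins))
  }
  nul <- makeScenario("null", cfg)
  expect_true(all(is.na(nul@truth$plateauBin)))
  expect_equal(sd(responseData(nul@responses[[1]])), cfg@noiseSd,
               tolerance = 0.05)
  trn <- makeScenario("transient", cfg)
  expect_true(all(trn@truth$transient))
  expect_error(makeScenario("bogus", cfg))
})

test_that("dataset round-trips through the CSV/JSON directory layout", {
  cfg <- generatorConfig(nConcepts = 6, nCategories = 2, nChannels = 4,
                         nBins = 5, nParticipants = 1, nFeatureDims = 6,
                         seed = 8)
  ds <- makeScenario("maintenance", cfg)
  dir <- withr::local_tempdir()
  writeSyntheticDataset(ds, dir, overwrite = TRUE)
  expect_true(file.exists(file.path(dir, "config.json")))
  rt <- readResponseTensor(file.path(dir, "responses", "p01.csv"))
  expect_equal(responseData(rt), responseData(ds@responses[[1]]))
  fm <- readFeatureTable(file.path(dir, "features", "semantic.csv"))
  expect_equal(unname(featureVectors(fm)),
               unname(featureVectors(ds@features$semantic)),
               tolerance = 1e-12)
  expect_error(writeSyntheticDataset(ds, dir), "not empty")
})
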