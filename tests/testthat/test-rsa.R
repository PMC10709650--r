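test_that("model DSM is the pairwise cosine distance", {
  v <- rbind(a = c(1, 0), b = c(2, 0), c = c(0, 3), d = c(-1, 0))
  fm <- new("FeatureMatrix", modelName = "toy", vectors = v)
  D <- modelDsm(fm)
  expect_equal(D["a", "b"], 0)           # parallel
  expect_equal(D["a", "c"], 1)           # orthogonal
  expect_equal(D["a", "d"], 2)           # opposite
  expect_equal(D, t(D))
  expect_equal(diag(D), rep(0, 4), ignore_attr = TRUE)
  bad <- new("FeatureMatrix", modelName = "bad",
             vectors = rbind(a = c(0, 0), b = c(1, 1)))
  expect_error(modelDsm(bad), "zero-norm")
})

test_that("brain DSM is the Pearson correlation distance over patterns", {
  pat <- withr::with_seed(5, matrix(rnorm(12), 1, 12))
  dat <- array(0, c(3, 4, 3), dimnames = list(c("a", "b", "c"), NULL, NULL))
  dat[1, , ] <- pat
  dat[2, , ] <- 2 * pat + 3               # positive affine transform -> r = 1
  dat[3, , ] <- -pat                      # anti-correlated -> distance 2
  rt <- new("ResponseTensor", participant = "p", data = dat, binMs = 20,
            t0Ms = 0)
  D <- brainDsm(rt)
  expect_equal(D["a", "b"], 0, tolerance = 1e-12)
  expect_equal(D["a", "c"], 2, tolerance = 1e-12)
  # zero-variance pattern is a degenerate-patch error
  dat[2, , ] <- 7
  rt2 <- new("ResponseTensor", participant = "p", data = dat, binMs = 20,
             t0Ms = 0)
  expect_error(brainDsm(rt2), "zero-variance")
})

test_that("RSA score is a rank correlation with the expected extremes", {
  M <- matrix(0, 4, 4)
  M[upper.tri(M)] <- c(1, 2, 3, 4, 5, 6)
  M <- M + t(M)
  expect_equal(rsaScore(M, M), 1)
  rev <- matrix(0, 4, 4)
  rev[upper.tri(rev)] <- c(6, 5, 4, 3, 2, 1)
  rev <- rev + t(rev)
  expect_equal(rsaScore(M, rev), -1)
  # invariant to strictly monotone transforms
  expect_equal(rsaScore(M, M^3 + 2), 1)
  expect_equal(rsaScore(exp(M), M), 1)
  flat <- matrix(1, 4, 4); diag(flat) <- 0
  expect_error(rsaScore(M, flat), "constant")
  # independently random DSMs: mean score near 0
  scores <- withr::with_seed(8, replicate(40, {
    r1 <- matrix(0, 5, 5); r1[upper.tri(r1)] <- runif(10)
    r2 <- matrix(0, 5, 5); r2[upper.tri(r2)] <- runif(10)
    rsaScore(r1 + t(r1), r2 + t(r2))
  }))
  expect_lt(abs(mean(scores)), 0.15)
})

test_that("spatial unit layouts validate and build grids", {
  u <- makeGridUnits(3, 2)
  expect_length(unitIds(u), 6)
  expect_equal(nrow(unitAdjacency(u)), 2 * 7)    # 7 rook edges, symmetric
  expect_error(spatialUnits(c("a", "a"), matrix(0, 2, 2),
                            cbind(1, 2)), "duplicate")
  expect_error(spatialUnits(c("a", "b"), matrix(0, 2, 2),
                            cbind(1, 1)), "self-pairs")
})

test_that("spatial units round-trip through CSV/JSON readers", {
  posPath <- withr::local_tempfile(fileext = ".csv")
  adjPath <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(id = c("u1", "u2", "u3"), x = c(0, 1, 2),
                       y = c(0, 0, 0)), posPath, row.names = FALSE)
  write.csv(data.frame(from = c("u1", "u2"), to = c("u2", "u3")), adjPath,
            row.names = FALSE)
  u <- readSpatialUnits(posPath, adjPath)
  expect_equal(unitIds(u), c("u1", "u2", "u3"))
  expect_equal(nrow(unitAdjacency(u)), 4)
  jsonPath <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(c("u1", "u2"), c("u2", "u3")), jsonPath)
  u2 <- readSpatialUnits(posPath, jsonPath)
  expect_equal(unitAdjacency(u2), unitAdjacency(u))
})

test_that("searchlight with an all-covering radius equals whole-set RSA", {
  cfg <- smallConfig(seed = 26, noiseSd = 0.5, nConcepts = 14, nBins = 8,
                     nChannels = 12, nFeatureDims = 16)
  ds <- makeScenario("maintenance", cfg)
  units <- makeGridUnits(4, 3)
  model <- modelDsm(ds@features$semantic)
  win <- list(windowSpec("cumulative", 0, 8))
  maps <- searchlightRsa(ds@responses, units, radius = 100, model, win)
  whole <- rsaScore(brainDsm(ds@responses[[1]], win[[1]]), model)
  expect_equal(unname(maps[1, , 1]), rep(whole, 12), tolerance = 1e-12)
  # radius 0: the patch is the unit itself
  maps0 <- searchlightRsa(ds@responses[1], units, radius = 0, model, win)
  solo <- rsaScore(brainDsm(ds@responses[[1]], win[[1]], channels = 5), model)
  expect_equal(maps0[1, 5, 1], solo)
})

test_that("searchlight localizes signal planted on a channel subset", {
  # responses linear in the model features on channels 1:6 only
  cfg <- generatorConfig(nConcepts = 16, nCategories = 4, nChannels = 20,
                         nBins = 6, nParticipants = 1, nFeatureDims = 12,
                         noiseSd = 0.4, seed = 27)
  fs <- makeFeatureSets(cfg)
  sch <- componentSchedule(1, 0, 6, 1, list(1:12))
  rt <- simulateResponses(fs$semantic, sch, cfg)
  dat <- responseData(rt)
  noise <- withr::with_seed(3, array(rnorm(16 * 20 * 6, sd = 0.4),
                                     c(16, 20, 6)))
  dat[, 7:20, ] <- noise[, 7:20, ]        # wipe signal off channels 7:20
  rt <- new("ResponseTensor", participant = "p01", data = dat, binMs = 20,
            t0Ms = 0)
  units <- makeGridUnits(5, 4)            # unit i = channel i
  maps <- searchlightRsa(list(rt), units, radius = 1,
                         modelDsm(fs$semantic),
                         list(windowSpec("cumulative", 0, 6)))
  sc <- maps[1, , 1]
  topHalf <- order(sc, decreasing = TRUE)[1:6]
  expect_gte(sum(topHalf %in% 1:6), 4)    # signal channels dominate the top
  expect_gt(mean(sc[1:6]), mean(sc[7:20]))
})

test_that("cluster search matches a brute-force components oracle", {
  u <- makeGridUnits(5, 4)
  withr::with_seed(11, {
    for (rep in 1:5) {
      tvals <- rnorm(20)
      mask <- tvals > 0.5
      got <- megaccum:::.clustersFromMask(mask, unitAdjacency(u), 20)
      want <- bruteForceComponents(mask, unitAdjacency(u))
      normalize <- function(l) unname(l[order(vapply(l, min, numeric(1)))])
      expect_equal(normalize(lapply(got, sort)), normalize(want))
    }
  })
})

test_that("cluster permutation recovers a planted block and respects nulls", {
  u <- makeGridUnits(6, 5)
  nP <- 12
  block <- c(8, 9, 10, 14, 15, 16)        # contiguous on the grid
  maps <- withr::with_seed(13, {
    m <- matrix(rnorm(nP * 30, sd = 1), nP, 30)
    m[, block] <- m[, block] + 3
    m
  })
  res <- clusterPermutation1Samp(maps, u, nPerm = 300, seed = 2)
  sig <- res$clusters[res$clusters$significant, ]
  expect_equal(nrow(sig), 1)
  expect_setequal(res$members[[1]], block)
  expect_lte(sig$p, 0.05)
  # no supra-threshold units -> empty cluster set
  flat <- withr::with_seed(14, matrix(rnorm(nP * 30, sd = 0.2), nP, 30))
  res0 <- clusterPermutation1Samp(flat, u, nPerm = 100, seed = 3)
  expect_equal(nrow(res0$clusters), 0)
  expect_error(clusterPermutation1Samp(maps[1, , drop = FALSE], u,
                                       nPerm = 10), "2 participants")
})

test_that("cluster detection is invariant to unit relabelling", {
  u <- makeGridUnits(4, 4)
  maps <- withr::with_seed(17, {
    m <- matrix(rnorm(8 * 16), 8, 16)
    m[, c(6, 7, 10, 11)] <- m[, c(6, 7, 10, 11)] + 2.5
    m
  })
  res1 <- clusterPermutation1Samp(maps, u, nPerm = 200, seed = 5)
  perm <- withr::with_seed(18, sample(16))
  inv <- order(perm)
  adjRelab <- cbind(inv[unitAdjacency(u)[, 1]], inv[unitAdjacency(u)[, 2]])
  u2 <- spatialUnits(unitIds(u)[perm], unitPositions(u)[perm, ], adjRelab)
  res2 <- clusterPermutation1Samp(maps[, perm], u2, nPerm = 200, seed = 5)
  expect_equal(sort(res1$clusters$statistic), sort(res2$clusters$statistic),
               tolerance = 1e-9)
  expect_equal(lapply(res1$members, function(m) sort(unitIds(u)[m])),
               lapply(res2$members, function(m) sort(unitIds(u2)[m])))
})
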