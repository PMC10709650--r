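test_that("word2vec text files parse and validate", {
  path <- withr::local_tempfile(fileext = ".vec")
  writeLines(c("3 4",
               "cat 0.1 0.2 0.3 0.4",
               "dog 1 0 0 0",
               "house -1 2 0.5 0"), path)
  fm <- readFeatureTable(path, "word2vec")
  expect_s4_class(fm, "FeatureMatrix")
  expect_equal(dim(featureVectors(fm)), c(3L, 4L))
  expect_equal(concepts(fm), c("cat", "dog", "house"))
  expect_equal(featureVectors(fm)["dog", ], c(1, 0, 0, 0),
               ignore_attr = TRUE)

  writeLines(c("2 3", "cat 1 2 3", "cat 4 5 6"), path)
  expect_error(readFeatureTable(path, "word2vec"), "duplicate")
  writeLines(c("2 3", "cat 1 2", "dog 4 5 6"), path)
  expect_error(readFeatureTable(path, "word2vec"), "ragged")
  writeLines(c("2 3", "cat 1 2 x", "dog 4 5 6"), path)
  expect_error(readFeatureTable(path, "word2vec"), "non-numeric")
  writeLines(c("5 3", "cat 1 2 3"), path)
  expect_error(readFeatureTable(path, "word2vec"), "declares")
})

test_that("CSV feature tables parse, with exemplar support and validation", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(concept = c("a", "b"), d1 = c(1, 2), d2 = c(3, 4)),
            path, row.names = FALSE)
  fm <- readFeatureTable(path)
  expect_equal(concepts(fm), c("a", "b"))

  write.csv(data.frame(concept = "only", d1 = 1), path, row.names = FALSE)
  expect_error(readFeatureTable(path), "at least 2")

  write.csv(data.frame(concept = c("a", "b"), d1 = c(1, NaN)), path,
            row.names = FALSE)
  expect_error(readFeatureTable(path), "'b'")

  write.csv(data.frame(concept = rep(c("a", "b"), each = 2),
                       exemplar = rep(1:2, 2),
                       d1 = 1:4, d2 = 5:8), path, row.names = FALSE)
  ex <- readFeatureTable(path)
  expect_s4_class(ex, "ExemplarFeatureMatrix")
  expect_equal(concepts(ex), c("a", "b"))
})

test_that("feature tables round-trip through writeFeatureTable", {
  v <- matrix(rnorm(12), 4, 3, dimnames = list(letters[1:4], NULL))
  fm <- new("FeatureMatrix", modelName = "toy", vectors = v)
  path <- withr::local_tempfile(fileext = ".csv")
  writeFeatureTable(fm, path)
  back <- readFeatureTable(path)
  expect_equal(unname(featureVectors(back)), unname(v), tolerance = 1e-12)
  expect_equal(concepts(back), letters[1:4])
})

makeExemplars <- function(nConcepts = 12, nEx = 5, nDims = 20, seed = 31,
                          rank = NULL) {
  withr::with_seed(seed, {
    n <- nConcepts * nEx
    V <- if (is.null(rank)) matrix(rnorm(n * nDims), n, nDims)
         else matrix(rnorm(n * rank), n, rank) %*%
              matrix(rnorm(rank * nDims), rank, nDims)
    new("ExemplarFeatureMatrix", modelName = "layers", vectors = V,
        conceptIds = rep(sprintf("c%02d", seq_len(nConcepts)), each = nEx),
        exemplarIds = as.character(rep(seq_len(nEx), nConcepts)))
  })
}

test_that("component count is capped at min(requested, trainRows - 1, dims)", {
  ex <- makeExemplars(nConcepts = 12, nEx = 5, nDims = 100)
  # 11 training concepts x 5 exemplars = 55 training rows -> cap 54
  out <- crossvalPcaReduce(ex, testConcept = "c01", nComponents = 295)
  expect_equal(out$nComponentsUsed, 54)
  expect_equal(ncol(featureVectors(out$train)), 54)
  out2 <- crossvalPcaReduce(ex, testConcept = "c01", nComponents = 10)
  expect_equal(out2$nComponentsUsed, 10)
  expect_error(crossvalPcaReduce(ex, testConcept = "zzz", nComponents = 5),
               "not present")
  expect_error(crossvalPcaReduce(ex, testConcept = "c01", nComponents = 0),
               "nComponents")
})

test_that("held-out exemplars never influence the fitted basis", {
  ex <- makeExemplars(seed = 7)
  out1 <- crossvalPcaReduce(ex, testConcept = "c03", nComponents = 8)
  # perturb the test concept's rows wildly; training projections unchanged
  V2 <- ex@vectors
  V2[ex@conceptIds == "c03", ] <- V2[ex@conceptIds == "c03", ] * 100 + 5
  ex2 <- new("ExemplarFeatureMatrix", modelName = "layers", vectors = V2,
             conceptIds = ex@conceptIds, exemplarIds = ex@exemplarIds)
  out2 <- crossvalPcaReduce(ex2, testConcept = "c03", nComponents = 8)
  expect_equal(featureVectors(out1$train), featureVectors(out2$train))
})

test_that("projection preserves distances when data lie in a k-dim subspace", {
  ex <- makeExemplars(nConcepts = 10, nEx = 4, nDims = 30, rank = 6, seed = 12)
  out <- crossvalPcaReduce(ex, testConcept = "c05", nComponents = 10)
  # concept averages in the original space
  avgOrig <- rowsum(ex@vectors, ex@conceptIds) / 4
  dOrig <- as.matrix(dist(avgOrig))
  avgProj <- rbind(featureVectors(out$train), c05 = out$test)
  avgProj <- avgProj[rownames(dOrig), ]
  dProj <- as.matrix(dist(avgProj))
  expect_equal(dProj, dOrig, tolerance = 1e-8)
})

test_that("averaging commutes with projection (identical-exemplar identity)", {
  # replacing a held-out concept's exemplars by their mean leaves its
  # reduced vector unchanged: mean of projections = projection of mean
  ex <- makeExemplars(nConcepts = 8, nEx = 3, nDims = 10, seed = 9)
  out1 <- crossvalPcaReduce(ex, testConcept = "c02", nComponents = 5)
  V <- ex@vectors
  rows <- ex@conceptIds == "c02"
  V[rows, ] <- matrix(colMeans(V[rows, ]), sum(rows), ncol(V), byrow = TRUE)
  ex2 <- new("ExemplarFeatureMatrix", modelName = "layers", vectors = V,
             conceptIds = ex@conceptIds, exemplarIds = ex@exemplarIds)
  out2 <- crossvalPcaReduce(ex2, testConcept = "c02", nComponents = 5)
  expect_equal(out2$test, out1$test, tolerance = 1e-10)
})

test_that("reconstruction error is non-increasing in the component count", {
  ex <- makeExemplars(nConcepts = 10, nEx = 3, nDims = 12, seed = 21)
  errs <- vapply(c(2, 5, 8, 11), function(k) {
    out <- crossvalPcaReduce(ex, testConcept = NULL, nComponents = k)
    # reconstruction via the fitted basis on the training (= all) rows
    mu <- colMeans(ex@vectors)
    Z <- sweep(ex@vectors, 2, mu)
    B <- svd(Z, nu = 0, nv = k)$v
    sum((Z - Z %*% B %*% t(B))^2)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-8))
})
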