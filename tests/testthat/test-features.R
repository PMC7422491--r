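# The ten-feature bank, standardization and min-max scaling.

test_that("standardization matches hand-computed population values", {
  expect_equal(standardize(c(1, 3)), c(-1, 1))
  z <- standardize(rnorm(100) * 5 + 2)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(mean(z^2), 1, tolerance = 1e-12)
  # idempotence
  expect_equal(standardize(z), z, tolerance = 1e-10)
  expect_error(standardize(c(5, 5, 5)), "degenerate")
})

test_that("hand-evaluated feature examples hold", {
  expect_equal(extractFeatures(c(0, 1, 0, 1))[["aac"]], 0.75)
  expect_equal(extractFeatures(c(3, -4, 3, -4))[["rms"]], sqrt(50 / 4))
  f <- extractFeatures(c(1, -1, 1, -1))
  expect_equal(f[["activity"]], 1)   # population variance
  expect_equal(f[["abs_sum"]], 4)
  e4 <- rep(exp(1), 4)
  expect_warning(f8 <- extractFeatures(e4)[["log_detector"]],
                 "zero-variance")
  expect_equal(f8, exp(1), tolerance = 1e-12)
})

test_that("constant signals give zero crest and unit shape factor", {
  expect_warning(f <- extractFeatures(c(3, 3)), "mobility")
  expect_equal(f[["crest_factor"]], 0)
  expect_equal(f[["shape_factor"]], 1)
  expect_true(is.nan(f[["mobility"]]))
})

test_that("features match the direct-formula oracle on random signals", {
  set.seed(2024)
  worst <- 0
  for (i in 1:200) {
    n <- sample(50:400, 1)
    s <- rnorm(n) * runif(1, 0.1, 50)
    got <- extractFeatures(s)
    want <- oracleFeatures(s)
    rel <- abs(got - want) / pmax(abs(want), 1e-300)
    worst <- max(worst, rel)
  }
  expect_lt(worst, 1e-10)
})

test_that("features scale as their formulas dictate", {
  set.seed(33)
  s <- rnorm(300)
  a <- 3.7
  f1 <- extractFeatures(s)
  fa <- extractFeatures(a * s)
  invariant <- c("crest_factor", "shape_factor", "mobility")
  expect_equal(fa[invariant], f1[invariant], tolerance = 1e-10)
  linear <- c("aac", "rms")
  expect_equal(fa[linear], a * f1[linear], tolerance = 1e-10)
  expect_equal(fa[["activity"]], a^2 * f1[["activity"]],
               tolerance = 1e-10)
})

test_that("activity is 1 after standardization", {
  set.seed(4)
  for (i in 1:20) {
    s <- rnorm(200) * runif(1, 0.01, 100) + runif(1, -5, 5)
    expect_equal(extractFeatures(standardize(s))[["activity"]], 1,
                 tolerance = 1e-9)
  }
})

test_that("feature matrix geometry follows the selection", {
  ds <- smallDataset()
  fs <- buildFeatureSet(ds)
  d <- smallDesign()
  segPerChannel <- nSubjects(d) * 4L * videosPerEmotion(d) *
    segmentsPerVideo(d)
  expect_equal(dim(fs), c(10L, segPerChannel * 2L * 5L))
  expect_equal(nrow(featureValues(fs)), ncol(fs))
  expect_equal(ncol(featureValues(fs)), 10L)

  one <- buildFeatureSet(ds, channels = "FP2-F4", bands = "gamma")
  expect_equal(ncol(one), segPerChannel)
  expect_error(buildFeatureSet(ds, channels = "C3"), "C3")
  expect_error(buildFeatureSet(ds, bands = "mu"), "mu")
})

test_that("feature rows are ordered by provenance with bands innermost", {
  ds <- smallDataset()
  fs <- buildFeatureSet(ds, channels = "FP2-F4")
  cd <- SummarizedExperiment::colData(fs)
  expect_equal(as.character(cd$band[1:5]),
               c("gamma", "beta", "alpha", "theta", "delta"))
  o <- order(cd$subject, as.integer(cd$emotion), cd$video, cd$segment,
             as.integer(cd$channel))
  expect_equal(o, seq_len(ncol(fs)))  # already sorted
})

test_that("min-max scaling follows train statistics only", {
  sc <- minMaxScale(matrix(c(2, 4, 6), ncol = 1))
  expect_equal(sc$train[, 1], c(0, 0.5, 1))
  sc2 <- minMaxScale(matrix(c(2, 4, 6), ncol = 1),
                     matrix(8, ncol = 1))
  expect_equal(sc2$test[1, 1], 1.5)  # outside [0, 1] is allowed
  sc3 <- minMaxScale(matrix(c(7, 7), ncol = 1))
  expect_equal(sc3$train[, 1], c(0, 0))  # constant-column convention
  # full-data mode pools both matrices before fitting
  sc4 <- minMaxScale(matrix(c(2, 4), ncol = 1), matrix(6, ncol = 1),
                     mode = "full-data")
  expect_equal(sc4$train[, 1], c(0, 0.5))
  expect_equal(sc4$test[1, 1], 1)
})

test_that("feature sets survive a text round-trip", {
  ds <- smallDataset()
  fs <- buildFeatureSet(ds, channels = "FP2-F4", bands = "gamma")
  path <- tempfile(fileext = ".csv")
  writeFeatureSet(fs, path)
  back <- readFeatureSet(path)
  expect_equal(featureValues(back), featureValues(fs),
               tolerance = 1e-12)
  expect_equal(as.character(featureLabels(back)),
               as.character(featureLabels(fs)))
})
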