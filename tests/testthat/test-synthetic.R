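# Synthetic EEG generator: design arithmetic, determinism, spectra.

test_that("design validation enforces counts, uniqueness and geometry", {
  d <- datasetDesign()
  expect_equal(nSubjects(d), 44L)
  expect_equal(segmentLength(d), 2560L)
  expect_error(datasetDesign(nSubjects = 0), "counts")
  expect_error(datasetDesign(emotions = c("happy", "happy")), "unique")
  expect_error(datasetDesign(channels = character(0)), "channel")
  expect_error(datasetDesign(samplingRate = 256, segmentSeconds = 1/3),
               "integer")
})

test_that("generated segments have the designed length and determinism", {
  d <- datasetDesign()
  sig <- emotionSignature(c(gamma = 1), noiseLevel = 0.5)
  x1 <- generateSegment(sig, d, seed = 7)
  x2 <- generateSegment(sig, d, seed = 7)
  expect_length(x1, 2560L)
  expect_identical(x1, x2)
  expect_false(identical(x1, generateSegment(sig, d, seed = 8)))
})

test_that("an all-zero signature with zero noise yields silence", {
  sig <- emotionSignature(c(gamma = 0, delta = 0), noiseLevel = 0)
  x <- generateSegment(sig, datasetDesign(), seed = 1)
  expect_identical(x, rep(0, 2560))
})

test_that("unknown band names in a signature are a configuration error", {
  expect_error(emotionSignature(c(sigma = 1)), "sigma")
})

test_that("single-band signatures concentrate spectral energy in band", {
  d <- datasetDesign()
  bands <- list(gamma = c(30, 63), beta = c(13, 30), alpha = c(8, 13),
                theta = c(4, 7), delta = c(0.5, 4))
  for (b in names(bands)) {
    w <- stats::setNames(1, b)
    x <- generateSegment(emotionSignature(w, noiseLevel = 0), d, seed = 3)
    frac <- fftBandEnergyFraction(x, 256, bands[[b]][1], bands[[b]][2])
    expect_gt(frac, 0.8)
  }
})

test_that("dataset counts follow the design arithmetic", {
  ds <- smallDataset()
  d <- smallDesign()
  cd <- SummarizedExperiment::colData(ds)
  perCell <- table(cd$emotion, cd$channel)
  expect_true(all(perCell == nSubjects(d) * videosPerEmotion(d) *
                    segmentsPerVideo(d)))
  expect_equal(ncol(ds), nSubjects(d) * 4L * videosPerEmotion(d) *
                 segmentsPerVideo(d) * 2L)

  u <- generateDataset(unitDesign(), flatSignatures(unitDesign()),
                       seed = 1)
  expect_equal(ncol(u), 4L)  # one segment per emotion
})

test_that("missing signatures are a configuration error", {
  d <- unitDesign()
  sigs <- flatSignatures(d)
  sigs$fear <- NULL
  expect_error(generateDataset(d, sigs, seed = 1), "fear")
})

test_that("equal seeds give bit-identical datasets, unequal seeds differ", {
  d <- unitDesign()
  a <- generateDataset(d, flatSignatures(d), seed = 9)
  b <- generateDataset(d, flatSignatures(d), seed = 9)
  c3 <- generateDataset(d, flatSignatures(d), seed = 10)
  expect_identical(SummarizedExperiment::assay(a),
                   SummarizedExperiment::assay(b))
  expect_false(identical(SummarizedExperiment::assay(a),
                         SummarizedExperiment::assay(c3)))
})

test_that("adding subjects never perturbs earlier subjects' data", {
  d2 <- datasetDesign(nSubjects = 2, videosPerEmotion = 1,
                      segmentsPerVideo = 2, channels = "FP2-F4")
  d3 <- datasetDesign(nSubjects = 3, videosPerEmotion = 1,
                      segmentsPerVideo = 2, channels = "FP2-F4")
  sigs <- flatSignatures(d2)
  a <- generateDataset(d2, sigs, seed = 5)
  b <- generateDataset(d3, sigs, seed = 5)
  cdB <- SummarizedExperiment::colData(b)
  keep <- cdB$subject <= 2
  expect_equal(SummarizedExperiment::assay(a),
               SummarizedExperiment::assay(b)[, keep])
})

test_that("preset signatures plant the contrast on one channel only", {
  d <- smallDesign()
  sigs <- presetSignatures(d, channel = "FP2-F4")
  expect_named(sigs, emotionLabels(d))
  wHappy <- sigs$happy[["FP1-F7"]]@bandWeights
  wFear <- sigs$fear[["FP1-F7"]]@bandWeights
  expect_identical(wHappy, wFear)  # non-discriminative channel
  gHappy <- sigs$happy[["FP2-F4"]]@bandWeights[["gamma"]]
  gSad <- sigs$sad[["FP2-F4"]]@bandWeights[["gamma"]]
  expect_gte((gSad / gHappy)^2, 2)  # adjacent band-power ratio >= 2
  # separation = 0 removes all class structure
  s0 <- presetSignatures(d, separation = 0, channel = "FP2-F4")
  expect_identical(s0$happy[["FP2-F4"]]@bandWeights,
                   s0$neutral[["FP2-F4"]]@bandWeights)
})
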