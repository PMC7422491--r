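# Splits and the three evaluation protocols.

test_that("splits have the designed sizes and determinism", {
  labels <- rep(c("a", "b"), each = 50)
  idx <- stratifiedSplit(labels, splitSpec(seed = 1))
  expect_length(idx$train, 70L)
  expect_length(idx$test, 30L)
  expect_equal(sort(c(idx$train, idx$test)), 1:100)  # disjoint, exhaustive
  expect_equal(sum(labels[idx$train] == "a"), 35L)   # stratified
  expect_identical(idx, stratifiedSplit(labels, splitSpec(seed = 1)))
  expect_false(identical(idx, stratifiedSplit(labels,
                                              splitSpec(seed = 2))))
})

test_that("stratified splitting needs two rows per class", {
  expect_error(stratifiedSplit(c("a", "a", "b"), splitSpec()),
               "fewer than 2")
  # unstratified has no such constraint
  idx <- stratifiedSplit(c("a", "a", "b"),
                         splitSpec(stratified = FALSE, seed = 3))
  expect_length(c(idx$train, idx$test), 3L)
})

test_that("per-class training counts follow round(fraction * n)", {
  labels <- rep(c("a", "b", "c", "d"), each = 25)
  idx <- stratifiedSplit(labels, splitSpec(0.7, TRUE, 9))
  tr <- table(labels[idx$train])
  expect_true(all(tr == round(0.7 * 25)))
})

# shared small experiment fixture: planted contrast on FP2-F4
expDataset <- function() {
  if (is.null(.fixture_env$exp)) {
    d <- datasetDesign(nSubjects = 3, channels = c("FP2-F4", "FP1-F7"))
    sigs <- presetSignatures(d, channel = "FP2-F4")
    .fixture_env$exp <- list(
      design = d,
      features = buildFeatureSet(generateDataset(d, sigs, seed = 77)))
  }
  .fixture_env$exp
}

test_that("channel-wise experiment reports every channel and finds the
          planted one", {
  fx <- expDataset()
  cfg <- runConfig(k = 80, seed = 7)
  cw <- channelWiseExperiment(fx$features, cfg)
  expect_named(cw$reports, c("FP2-F4", "FP1-F7"))
  expect_equal(cw$bestChannel, "FP2-F4")
  expect_gt(cw$accuracy[["FP2-F4"]], cw$accuracy[["FP1-F7"]])
  # pool sizes: emotions x subjects x videos x segments x subbands
  n <- sum(confusion(cw$reports[["FP2-F4"]]))
  total <- 4 * 3 * 3 * 10 * 5
  expect_equal(n, total - 4 * round(0.7 * total / 4))
})

test_that("subband-wise experiment emits the grid and gamma wins on the
          planted channel", {
  fx <- expDataset()
  cfg <- runConfig(k = 80, seed = 7)
  sw <- subbandWiseExperiment(fx$features, cfg)
  expect_equal(dim(sw$grid), c(2L, 5L))
  expect_equal(rownames(sw$grid), c("FP2-F4", "FP1-F7"))
  expect_equal(colnames(sw$grid),
               c("gamma", "beta", "alpha", "theta", "delta"))
  expect_equal(unname(sw$best["channel"]), "FP2-F4")
  expect_equal(names(which.max(sw$grid["FP2-F4", ])), "gamma")
})

test_that("emotion-wise experiment reports the one-vs-rest block", {
  fx <- expDataset()
  cfg <- runConfig(k = 80, seed = 7)
  ew <- emotionWiseExperiment(fx$features, "FP2-F4", "gamma", cfg)
  expect_equal(dim(ew$table), c(5L, 4L))
  expect_equal(rownames(ew$table),
               c("accuracy", "specificity", "sensitivity", "precision",
                 "f1"))
  expect_equal(colnames(ew$table), emotionLabels(fx$design))
  expect_true(all(ew$table >= 0 & ew$table <= 1))
  # per-emotion pool arithmetic: subjects x videos x pages per emotion
  expect_equal(sum(confusion(ew$report)),
               4 * 3 * 3 * 10 - 4 * round(0.7 * 3 * 3 * 10))
  expect_error(emotionWiseExperiment(fx$features, "nope", "gamma", cfg),
               "channel")
  expect_error(emotionWiseExperiment(fx$features, "FP2-F4", "mu", cfg),
               "band")
})

test_that("metric identities hold in every experiment report", {
  fx <- expDataset()
  cfg <- runConfig(k = 80, seed = 7)
  cw <- channelWiseExperiment(fx$features, cfg)
  for (r in cw$reports) {
    expect_equal(accuracy(r), sum(diag(confusion(r))) / sum(confusion(r)))
    expect_equal(microMetrics(r)[["sensitivity"]], accuracy(r))
  }
})

test_that("accuracy does not decrease with signature separation", {
  d <- datasetDesign(nSubjects = 3, channels = "FP2-F4")
  cfg <- runConfig(k = 80, seed = 19)
  acc <- vapply(c(0.25, 0.6, 1.0), function(s) {
    ds <- generateDataset(d, presetSignatures(d, separation = s,
                                              channel = "FP2-F4"),
                          seed = 19)
    cw <- channelWiseExperiment(ds, cfg)
    cw$accuracy[["FP2-F4"]]
  }, numeric(1))
  expect_true(all(diff(acc) >= 0))
})

test_that("the benchmark runner writes its reports and summary", {
  d <- datasetDesign(nSubjects = 2, channels = c("FP2-F4", "FP1-F7"))
  out <- file.path(tempfile(), "bench")
  res <- runBenchmark(config = runConfig(k = 50, seed = 3), design = d,
                      signatures = presetSignatures(d,
                                                    channel = "FP2-F4"),
                      outDir = out)
  expect_true(all(file.exists(res$outputs)))
  summ <- readLines(file.path(out, "run_summary.txt"))
  expect_true(any(grepl("^bestChannel = ", summ)))
  expect_true(any(grepl("^channelAccuracy.FP2-F4 = ", summ)))
  grid <- read.csv(file.path(out, "subband_wise.csv"),
                   check.names = FALSE)
  expect_equal(dim(grid), c(2L, 6L))
})
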