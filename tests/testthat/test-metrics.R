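# Confusion matrices and one-vs-rest metrics.

test_that("a perfect diagonal confusion gives all metrics 1", {
  conf <- diag(c(5L, 7L, 9L))
  dimnames(conf) <- rep(list(c("a", "b", "c")), 2)
  m <- metricsFromConfusion(conf)
  expect_equal(accuracy(m), 1)
  pc <- perClassMetrics(m)
  expect_true(all(pc[, c("sensitivity", "specificity", "precision",
                         "f1")] == 1))
  expect_equal(unname(macroMetrics(m)), rep(1, 4))
  expect_equal(unname(microMetrics(m)), rep(1, 4))
})

test_that("two-class hand evaluation matches", {
  conf <- matrix(c(8, 2, 1, 9), nrow = 2, byrow = TRUE,
                 dimnames = rep(list(c("a", "b")), 2))
  m <- metricsFromConfusion(conf)
  pc <- perClassMetrics(m)
  expect_equal(pc$sensitivity[1], 0.8)
  expect_equal(pc$precision[1], 8 / 9)
  expect_equal(accuracy(m), 0.85)
})

test_that("never-predicted classes report 0 precision with a flag", {
  conf <- matrix(c(5, 0, 3, 0), nrow = 2, byrow = TRUE,
                 dimnames = rep(list(c("a", "b")), 2))
  m <- metricsFromConfusion(conf)
  pc <- perClassMetrics(m)
  expect_equal(pc$precision[2], 0)
  expect_true(pc$flagged[2])
})

test_that("micro-averaged sensitivity equals accuracy on random tables", {
  set.seed(14)
  for (i in 1:20) {
    nc <- sample(2:5, 1)
    conf <- matrix(rpois(nc * nc, 6), nc)
    dimnames(conf) <- rep(list(paste0("c", seq_len(nc))), 2)
    m <- metricsFromConfusion(conf)
    expect_equal(microMetrics(m)[["sensitivity"]], accuracy(m))
    expect_equal(accuracy(m), sum(diag(conf)) / sum(conf))
  }
})

test_that("malformed confusion input is rejected", {
  expect_error(metricsFromConfusion(matrix(1, 2, 3)), "square")
  expect_error(metricsFromConfusion(matrix(c(1, -1, 0, 2), 2)),
               "nonnegative")
})

test_that("confusionCounts cross-tabulates in the declared class order", {
  truth <- c("b", "a", "b", "b")
  pred <- c("b", "b", "a", "b")
  conf <- confusionCounts(truth, pred, classes = c("a", "b"))
  expect_equal(unname(conf), matrix(c(0L, 1L, 1L, 2L), 2))
  expect_error(confusionCounts(truth, c(pred[-4], "z"),
                               classes = c("a", "b")), "class set")
})

test_that("metric tables serialize as percent-valued delimited text", {
  conf <- matrix(c(8, 2, 1, 9), nrow = 2, byrow = TRUE,
                 dimnames = rep(list(c("a", "b")), 2))
  path <- tempfile(fileext = ".csv")
  writeMetricsReport(metricsFromConfusion(conf), path)
  tab <- read.csv(path)
  expect_equal(tab$metric, c("accuracy", "sensitivity", "specificity",
                             "precision", "f1"))
  expect_equal(tab$micro[1], 85)  # accuracy as a percentage
})
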