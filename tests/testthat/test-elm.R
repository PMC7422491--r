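# Extreme learning machine: hidden layer, fit, prediction, persistence.

test_that("hidden layer is deterministic, shaped and uniform on [-1,1]", {
  h1 <- elmInitHidden(10, 3, seed = 1)
  h2 <- elmInitHidden(10, 3, seed = 1)
  expect_identical(h1, h2)
  expect_equal(dim(h1$alpha), c(3L, 10L))
  expect_length(h1$beta, 3L)
  big <- elmInitHidden(1000, 1000, seed = 2)
  expect_lt(abs(mean(big$alpha)), 0.01)   # 10^6 draws, mean near 0
  expect_true(all(abs(big$alpha) <= 1))
  expect_error(elmInitHidden(0, 5, 1), "d must")
  expect_error(elmInitHidden(5, 0, 1), "k must")
})

test_that("the hidden map is the sigmoid of the affine projection", {
  m <- elmHiddenMap(matrix(1), alpha = matrix(1), beta = 1)
  expect_equal(m[1, 1], 1 / (1 + exp(-2)), tolerance = 1e-12)
  # alpha.x + beta = 0 -> 0.5
  m0 <- elmHiddenMap(matrix(c(1, -1), 1), alpha = matrix(c(1, 1), 1),
                     beta = 0)
  expect_equal(m0[1, 1], 0.5)
  set.seed(5)
  m2 <- elmHiddenMap(matrix(rnorm(40), 8), elmInitHidden(5, 7, 3)$alpha,
                     elmInitHidden(5, 7, 3)$beta)
  expect_true(all(m2 > 0 & m2 < 1))
  expect_equal(dim(m2), c(8L, 7L))
  expect_error(elmHiddenMap(matrix(1, 1, 3), matrix(1, 2, 2), c(0, 0)),
               "columns")
})

test_that("an over-parameterized ELM interpolates XOR exactly", {
  xor <- matrix(c(0, 0, 0, 1, 1, 0, 1, 1), ncol = 2, byrow = TRUE)
  y <- c("a", "b", "b", "a")
  fit <- elmFit(xor, y, k = 20, seed = 4)
  expect_equal(as.character(elmPredict(fit, xor)), y)
})

test_that("single-class training data predicts that class everywhere", {
  x <- matrix(rnorm(20), ncol = 2)
  fit <- elmFit(x, rep("only", 10), k = 5, seed = 1)
  expect_true(all(elmPredict(fit, x) == "only"))
})

test_that("fitting is deterministic in the seed", {
  set.seed(99)
  x <- matrix(rnorm(60), ncol = 3)
  y <- rep(c("u", "v"), 10)
  f1 <- elmFit(x, y, k = 15, seed = 8)
  f2 <- elmFit(x, y, k = 15, seed = 8)
  expect_identical(f1@gammaOut, f2@gammaOut)
})

test_that("pseudoinverse weights solve the least-squares problem", {
  # oracle: explicit normal equations on well-conditioned small instances
  set.seed(12)
  for (i in 1:5) {
    x <- matrix(rnorm(40 * 3), ncol = 3)
    y <- sample(c("p", "q", "r"), 40, replace = TRUE)
    fit <- elmFit(x, y, k = 10, seed = i)
    m <- elmHiddenMap(x, fit@alpha, fit@beta)
    l <- outer(y, sort(unique(y)), "==") * 1  # one-hot oracle
    oracle <- solve(t(m) %*% m, t(m) %*% l)
    expect_lt(max(abs(fit@gammaOut - oracle)), 1e-8)
  }
})

test_that("interpolation holds for distinct inputs whenever k >= N", {
  for (seed in 1:20) {
    set.seed(seed + 1000)
    n <- sample(10:50, 1)
    x <- matrix(rnorm(n * 4), ncol = 4)
    y <- sample(c("w", "x", "y", "z"), n, replace = TRUE)
    fit <- elmFit(x, y, k = n + sample(0:20, 1), seed = seed)
    expect_equal(as.character(elmPredict(fit, x)), y)
  }
})

test_that("scores are raw and ties break to the earliest class", {
  x <- matrix(rnorm(12), ncol = 3)
  fit <- elmFit(x, rep(c("a", "b"), 2), k = 6, seed = 2)
  zeroed <- fit
  zeroed@gammaOut[] <- 0
  sc <- elmPredict(zeroed, x, type = "score")
  expect_true(all(sc == 0))
  expect_true(all(elmPredict(zeroed, x) == "a"))
  # scores are raw linear outputs, one column per class
  sc2 <- elmPredict(fit, x, type = "score")
  expect_equal(dim(sc2), c(nrow(x), 2L))
  expect_equal(colnames(sc2), fit@classes)
})

test_that("ridge regularization shrinks the solution but still fits", {
  set.seed(3)
  x <- matrix(rnorm(200), ncol = 2)
  y <- ifelse(x[, 1] + x[, 2] > 0, "pos", "neg")
  plain <- elmFit(x, y, k = 30, seed = 5)
  ridge <- elmFit(x, y, k = 30, seed = 5, ridge = 1e-2)
  expect_lt(sum(ridge@gammaOut^2), sum(plain@gammaOut^2))
  acc <- mean(elmPredict(ridge, x) == y)
  expect_gt(acc, 0.9)
})

test_that("models survive a JSON round-trip with their scaler", {
  x <- matrix(rnorm(40), ncol = 2)
  y <- rep(c("m", "n"), 10)
  sc <- minMaxScale(x)
  fit <- elmFit(sc$train, y, k = 8, seed = 6)
  path <- tempfile(fileext = ".json")
  writeElmModel(fit, path, scaler = sc$ranges)
  back <- readElmModel(path)
  expect_equal(back$model@gammaOut, fit@gammaOut, tolerance = 1e-12)
  expect_equal(back$model@classes, fit@classes)
  expect_equal(unname(back$scaler), unname(sc$ranges),
               tolerance = 1e-12)
  expect_identical(as.character(elmPredict(back$model, sc$train)),
                   as.character(elmPredict(fit, sc$train)))
})

test_that("dimension mismatches and bad inputs are rejected", {
  x <- matrix(rnorm(20), ncol = 2)
  fit <- elmFit(x, rep(c("a", "b"), 5), k = 4, seed = 1)
  expect_error(elmPredict(fit, matrix(1, 2, 3)), "expects")
  xb <- x; xb[1, 1] <- NA
  expect_error(elmFit(xb, rep(c("a", "b"), 5), k = 4, seed = 1),
               "finite")
})
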