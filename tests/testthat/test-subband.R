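# Wavelet subband decomposition: reconstruction, linearity, selectivity.

test_that("the seven bands sum back to the input segment", {
  set.seed(101)
  for (n in c(2560L, 1000L, 777L)) {
    x <- rnorm(n) * 20
    sb <- decomposeSegment(x)
    err <- max(abs(rowSums(bandSignals(sb)) - x))
    expect_lt(err, 1e-8 * max(abs(x)))
  }
})

test_that("a zero segment decomposes to all-zero bands", {
  sb <- decomposeSegment(numeric(2560))
  expect_true(all(bandSignals(sb) == 0))
})

test_that("decomposition is linear", {
  set.seed(7)
  x <- rnorm(512); y <- rnorm(512)
  a <- 2.5; b <- -1.25
  lhs <- bandSignals(decomposeSegment(a * x + b * y))
  rhs <- a * bandSignals(decomposeSegment(x)) +
    b * bandSignals(decomposeSegment(y))
  expect_lt(max(abs(lhs - rhs)), 1e-8 * max(abs(lhs)))
})

test_that("single tones land in the band owning their dyadic range", {
  # dyadic edges at 256 Hz: D1 64-128, D2 32-64, D3 16-32, D4 8-16,
  # D5 4-8, D6 2-4, A6 0-2; tones placed >= 20% away from band edges
  t <- seq(0, 10, length.out = 2560)
  cases <- c(D1 = 90, D2 = 45, D3 = 24, D4 = 11, D5 = 5.8, D6 = 2.9,
             A6 = 1)
  for (code in names(cases)) {
    x <- sin(2 * pi * cases[[code]] * t)
    e <- colSums(bandSignals(decomposeSegment(x))^2)
    expect_equal(names(which.max(e)), code)
  }
})

test_that("segments too short for six levels are rejected", {
  expect_error(decomposeSegment(rnorm(32)), "too short")
})

test_that("retaining brain waves drops exactly the two noise bands", {
  set.seed(11)
  sb <- decomposeSegment(rnorm(2560))
  bw <- retainBrainwaves(sb)
  expect_equal(ncol(bandSignals(sb)), 7L)
  expect_equal(colnames(bw), c("gamma", "beta", "alpha", "theta",
                               "delta"))
  # pass-through: the gamma reconstruction is D3, unchanged
  expect_identical(unname(bw[, "gamma"]),
                   unname(bandSignals(sb)[, "D3"]))
})

test_that("band metadata records both display labels and dyadic edges", {
  sb <- decomposeSegment(rnorm(2560))
  info <- sb@bandInfo
  expect_equal(info$code, c("D1", "D2", "D3", "D4", "D5", "D6", "A6"))
  expect_equal(info$wave[3], "gamma")
  expect_equal(info$nominalLowHz[3], 30)   # display label
  expect_equal(info$dyadicLowHz[3], 16)    # what the transform realizes
  expect_equal(info$dyadicHighHz, c(128, 64, 32, 16, 8, 4, 2))
})

test_that("only the implemented wavelet and boundary are accepted", {
  expect_error(decomposeSegment(rnorm(2560), wavelet = "db4"), "db8")
  expect_error(decomposeSegment(rnorm(2560), boundary = "periodic"),
               "boundary")
})
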