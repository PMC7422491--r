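# Independent oracles and shared fixtures, built in code at test time.

# Fraction of spectral energy inside [lowHz, highHz), computed directly
# from the periodogram -- independent of the generator's filtering path.
fftBandEnergyFraction <- function(x, fs, lowHz, highHz) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  sum(p[f >= lowHz & f < highHz]) / sum(p)
}

# Direct-formula implementation of the ten features, written from the
# defining equations with scalar arithmetic -- deliberately separate from
# the package's implementation.
oracleFeatures <- function(s, eps = 1e-12) {
  C <- length(s)
  peak <- (max(s) - min(s)) / 2
  sumAbsDiff <- 0
  for (i in seq_len(C - 1)) sumAbsDiff <- sumAbsDiff + abs(s[i + 1] - s[i])
  mu <- sum(s) / C
  va <- sum((s - mu)^2) / C
  d <- s[-1] - s[-C]
  mud <- sum(d) / (C - 1)
  vd <- sum((d - mud)^2) / (C - 1)
  rms <- sqrt(sum(s^2) / C)
  meanAbs <- sum(abs(s)) / C
  meanSqrtAbs <- sum(sqrt(abs(s))) / C
  logs <- log(pmax(abs(s), eps))
  c(
    aac = sumAbsDiff / C,
    activity = va,
    abs_sqrt_sum = sum(sqrt(abs(s))),
    clearance_factor = peak / meanSqrtAbs^2,
    rms = rms,
    crest_factor = peak / rms,
    shape_factor = rms / meanAbs,
    log_detector = exp(sum(logs) / C),
    mobility = sqrt(vd) / sqrt(va),
    abs_sum = sum(abs(s))
  )
}

# Tiny designs used across test files.
unitDesign <- function() {
  datasetDesign(nSubjects = 1, videosPerEmotion = 1, segmentsPerVideo = 1,
                channels = "FP1-F7")
}

smallDesign <- function(nSubjects = 2, channels = c("FP2-F4", "FP1-F7")) {
  datasetDesign(nSubjects = nSubjects, videosPerEmotion = 2,
                segmentsPerVideo = 2, channels = channels)
}

# A flat (non-discriminative) signature map for count/IO tests: cheap to
# generate because only two bands are synthesized.
flatSignatures <- function(design) {
  sig <- emotionSignature(c(alpha = 1, beta = 0.5), noiseLevel = 0.3,
                          subjectSd = 0)
  out <- lapply(emotionLabels(design), function(e) sig)
  names(out) <- emotionLabels(design)
  out
}

# Small labeled dataset reused by feature/experiment/io tests; built once
# per test run.
.fixture_env <- new.env(parent = emptyenv())

smallDataset <- function() {
  if (is.null(.fixture_env$ds)) {
    d <- smallDesign()
    .fixture_env$ds <- generateDataset(d, flatSignatures(d), seed = 42L)
  }
  .fixture_env$ds
}
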