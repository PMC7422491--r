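Package: eegbench
Title: Wavelet Subband Features and Extreme Learning Machines for EEG
    Emotion Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable benchmark pipeline for emotion recognition from
    multichannel frontal EEG. Fixed-length segments are decomposed into the
    canonical brain-wave subbands (delta, theta, alpha, beta, gamma) with a
    six-level Daubechies-8 discrete wavelet transform, a ten-feature
    time-domain bank (amplitude change, Hjorth activity and mobility, crest,
    shape and clearance factors, log detector, RMS, absolute sums) is
    computed per subband, and a single-hidden-layer extreme learning machine
    solved in one pseudoinverse step classifies four emotional states.
    Channel-wise, subband-wise and emotion-wise evaluation protocols report
    one-vs-rest confusion-matrix metrics. A seeded synthetic EEG generator
    with controllable per-emotion band-power signatures makes the full
    pipeline testable end to end, and EDF plus delimited-text readers and
    writers cover interchange with recording software.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
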