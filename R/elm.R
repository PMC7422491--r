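# Extreme learning machine: random sigmoid hidden layer, output weights in
# one pseudoinverse step, argmax decoding.

#' Draw the random hidden layer of an ELM
#'
#' Hidden input weights and biases are i.i.d. uniform on `[-1, 1]`,
#' deterministic given the seed. They are never trained.
#'
#' @param d input dimension (>= 1).
#' @param k number of hidden nodes (>= 1).
#' @param seed integer RNG seed.
#' @return list with `alpha` (k x d matrix) and `beta` (length-k vector).
#' @export
elmInitHidden <- function(d, k, seed) {
  d <- as.integer(d); k <- as.integer(k)
  if (!isTRUE(d >= 1L)) stop("input dimension d must be >= 1")
  if (!isTRUE(k >= 1L)) stop("hidden count k must be >= 1")
  withSeed(as.integer(seed), {
    list(alpha = matrix(stats::runif(k * d, -1, 1), nrow = k),
         beta = stats::runif(k, -1, 1))
  })
}

#' Hidden-layer output matrix
#'
#' Applies the sigmoid hidden map `M[i, j] = 1 / (1 + exp(-(alpha_j .
#' x_i + beta_j)))` to every input row. All entries lie strictly in (0, 1).
#'
#' @param x numeric matrix, one input per row (N x d).
#' @param alpha k x d hidden weights.
#' @param beta length-k hidden biases.
#' @return N x k matrix of hidden activations.
#' @export
elmHiddenMap <- function(x, alpha, beta) {
  x <- as.matrix(x)
  if (ncol(x) != ncol(alpha)) {
    stop("input has ", ncol(x), " columns but the hidden layer expects ",
         ncol(alpha))
  }
  z <- x %*% t(alpha)
  z <- sweep(z, 2L, beta, "+")
  1 / (1 + exp(-z))
}

.one_hot <- function(labels, classes) {
  m <- matrix(0, nrow = length(labels), ncol = length(classes),
              dimnames = list(NULL, classes))
  m[cbind(seq_along(labels), match(as.character(labels), classes))] <- 1
  m
}

# Minimum-norm least-squares solve via SVD pseudoinverse; singular values
# below max(dim) * eps * sigma_max are treated as zero (the standard
# cutoff convention).
.pinv_solve <- function(m, l) {
  sv <- svd(m)
  cutoff <- max(dim(m)) * .Machine$double.eps * max(sv$d, 0)
  keep <- sv$d > cutoff
  dinv <- ifelse(keep, 1 / sv$d, 0)
  g <- sv$v %*% (dinv * (t(sv$u) %*% l))
  list(gamma = g, cutoff = cutoff)
}

#' Fit an extreme learning machine classifier
#'
#' Single non-iterative solve: the hidden layer (`alpha`, `beta`) is drawn
#' once from the seed, the one-hot target matrix `L` is built from the
#' labels, and the output weights are `gammaOut = pinv(M) %*% L` with `M`
#' the hidden-layer output matrix (SVD pseudoinverse with the standard
#' singular-value cutoff). With `ridge = lambda > 0` the regularized form
#' `solve(t(M) %*% M + lambda * I, t(M) %*% L)` is used instead.
#'
#' @param x numeric matrix of training inputs, one row per sample.
#' @param labels vector/factor of class labels, one per row.
#' @param k number of hidden nodes (default 500).
#' @param seed integer seed for the hidden layer.
#' @param ridge nonnegative ridge penalty; 0 (default) selects the plain
#'   pseudoinverse.
#' @param classes optional ordered class vector; defaults to factor levels
#'   (or sorted unique labels). Prediction ties break toward the earliest
#'   class in this order.
#' @return an [ElmModel-class].
#' @examples
#' xor <- matrix(c(0, 0, 0, 1, 1, 0, 1, 1), ncol = 2, byrow = TRUE)
#' fit <- elmFit(xor, c("a", "b", "b", "a"), k = 20, seed = 1)
#' elmPredict(fit, xor)
#' @export
elmFit <- function(x, labels, k = 500L, seed = 1L, ridge = 0,
                   classes = NULL) {
  x <- as.matrix(x)
  if (!nrow(x)) stop("no training rows")
  if (nrow(x) != length(labels)) {
    stop("labels must have one entry per training row")
  }
  if (any(!is.finite(x))) stop("non-finite feature values in training data")
  if (is.null(classes)) {
    classes <- if (is.factor(labels)) levels(labels) else
      sort(unique(as.character(labels)))
  }
  if (!all(as.character(labels) %in% classes)) {
    stop("labels outside the declared class set")
  }
  k <- as.integer(k)
  seed <- as.integer(seed)
  hidden <- elmInitHidden(ncol(x), k, seed)
  m <- elmHiddenMap(x, hidden$alpha, hidden$beta)
  l <- .one_hot(labels, classes)
  if (ridge > 0) {
    g <- solve(crossprod(m) + diag(ridge, k), crossprod(m, l))
    cutoff <- 0
  } else {
    sol <- .pinv_solve(m, l)
    g <- sol$gamma
    cutoff <- sol$cutoff
  }
  colnames(g) <- classes
  new("ElmModel", alpha = hidden$alpha, beta = hidden$beta, gammaOut = g,
      classes = classes, k = k, seed = seed, ridge = as.numeric(ridge),
      svCutoff = cutoff)
}

#' Predict classes (or scores) from a fitted ELM
#'
#' Scores are `elmHiddenMap(x) %*% gammaOut` -- raw linear outputs per
#' class, not probabilities (rows are not normalized). The predicted label
#' is the class with the maximal score; exact ties break toward the lowest
#' class index.
#'
#' @param model an [ElmModel-class].
#' @param x numeric matrix of inputs, one row per sample.
#' @param type `"class"` (default) for labels, `"score"` for the raw
#'   N x nClasses score matrix.
#' @return factor of predicted labels, or a score matrix.
#' @export
elmPredict <- function(model, x, type = c("class", "score")) {
  type <- match.arg(type)
  stopifnot(is(model, "ElmModel"))
  x <- as.matrix(x)
  if (ncol(x) != ncol(model@alpha)) {
    stop("input has ", ncol(x), " columns but the model expects ",
         ncol(model@alpha))
  }
  scores <- elmHiddenMap(x, model@alpha, model@beta) %*% model@gammaOut
  if (type == "score") return(scores)
  idx <- max.col(scores, ties.method = "first")
  factor(model@classes[idx], levels = model@classes)
}

#' @describeIn elmPredict standard `predict` method.
#' @param object an [ElmModel-class].
#' @param newdata input matrix.
#' @param ... passed to [elmPredict()].
#' @export
setMethod("predict", "ElmModel",
  function(object, newdata, ...) elmPredict(object, newdata, ...))

setMethod("show", "ElmModel", function(object) {
  cat(sprintf(
    "ElmModel: %d hidden nodes, %d inputs -> %d classes (seed %d%s)\n",
    object@k, ncol(object@alpha), length(object@classes), object@seed,
    if (object@ridge > 0) sprintf(", ridge %g", object@ridge) else ""))
  cat("  classes:", paste(object@classes, collapse = ", "), "\n")
})

.elm_archive_version <- "eegbench-elm-1"

#' Save / load a fitted ELM
#'
#' The archive is a single self-describing JSON document holding the hidden
#' layer, output weights, class list, seed, hidden count, ridge setting,
#' singular-value cutoff and (optionally) feature-scaler statistics,
#' version-stamped for forward compatibility.
#'
#' @param model an [ElmModel-class].
#' @param path file path.
#' @param scaler optional `ranges` matrix from [minMaxScale()], stored with
#'   the model so inputs can be scaled identically at prediction time.
#' @return `writeElmModel`: `path` invisibly; `readElmModel`: a list with
#'   `model` ([ElmModel-class]) and `scaler` (matrix or NULL).
#' @export
writeElmModel <- function(model, path, scaler = NULL) {
  stopifnot(is(model, "ElmModel"))
  doc <- list(
    format = .elm_archive_version,
    k = model@k, seed = model@seed, ridge = model@ridge,
    svCutoff = model@svCutoff, classes = model@classes,
    d = ncol(model@alpha),
    alpha = as.vector(model@alpha), beta = model@beta,
    gammaOut = as.vector(model@gammaOut),
    scaler = if (is.null(scaler)) NULL else
      list(min = unname(scaler["min", ]), max = unname(scaler["max", ]))
  )
  writeLines(jsonlite::toJSON(doc, digits = NA, auto_unbox = TRUE,
                              null = "null"), path)
  invisible(path)
}

#' @rdname writeElmModel
#' @export
readElmModel <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(doc$format, .elm_archive_version)) {
    stop("unrecognized model archive format: ", format(doc$format))
  }
  k <- as.integer(doc$k); d <- as.integer(doc$d)
  model <- new("ElmModel",
    alpha = matrix(doc$alpha, nrow = k, ncol = d),
    beta = as.numeric(doc$beta),
    gammaOut = matrix(doc$gammaOut, nrow = k,
                      dimnames = list(NULL, doc$classes)),
    classes = as.character(doc$classes), k = k,
    seed = as.integer(doc$seed), ridge = as.numeric(doc$ridge),
    svCutoff = as.numeric(doc$svCutoff))
  scaler <- NULL
  if (!is.null(doc$scaler)) {
    scaler <- rbind(min = doc$scaler$min, max = doc$scaler$max)
  }
  list(model = model, scaler = scaler)
}
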