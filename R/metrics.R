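# Confusion matrices and one-vs-rest classification metrics.

#' Cross-tabulate true and predicted labels
#'
#' @param truth vector/factor of true labels.
#' @param predicted vector/factor of predicted labels.
#' @param classes ordered class vector; defaults to the union of factor
#'   levels.
#' @return square integer matrix of counts, true classes in rows.
#' @export
confusionCounts <- function(truth, predicted, classes = NULL) {
  if (is.null(classes)) {
    classes <- if (is.factor(truth)) levels(truth) else
      sort(unique(c(as.character(truth), as.character(predicted))))
  }
  t1 <- factor(as.character(truth), levels = classes)
  t2 <- factor(as.character(predicted), levels = classes)
  if (anyNA(t1) || anyNA(t2)) stop("labels outside the declared class set")
  unclass(table(true = t1, predicted = t2))
}

.safe_ratio <- function(num, den) {
  out <- ifelse(den > 0, num / den, 0)
  flagged <- den == 0
  list(value = out, flagged = flagged)
}

#' Derive one-vs-rest metrics from a confusion matrix
#'
#' For each class treated as positive against the rest: sensitivity
#' (recall) `TP/(TP+FN)`, specificity `TN/(TN+FP)`, precision `TP/(TP+FP)`
#' and F1 `2*prec*sens/(prec+sens)`. Overall accuracy is
#' `trace(confusion)/total`. Ratios of the form 0/0 (e.g. precision of a
#' never-predicted class) are reported as 0 and flagged. Macro aggregates
#' are unweighted class means; micro aggregates pool the one-vs-rest
#' counts, under which sensitivity, precision and F1 all equal the
#' accuracy for single-label multiclass data.
#'
#' @param conf square nonnegative count matrix, true classes in rows.
#' @return a [MetricsReport-class].
#' @examples
#' m <- metricsFromConfusion(matrix(c(8, 1, 2, 9), nrow = 2,
#'                           dimnames = rep(list(c("a", "b")), 2)))
#' accuracy(m)
#' @export
metricsFromConfusion <- function(conf) {
  conf <- as.matrix(conf)
  if (nrow(conf) != ncol(conf)) stop("confusion matrix must be square")
  if (any(conf < 0) || any(conf != round(conf))) {
    stop("confusion matrix must hold nonnegative integer counts")
  }
  classes <- rownames(conf)
  if (is.null(classes)) {
    classes <- paste0("class", seq_len(nrow(conf)))
    dimnames(conf) <- list(classes, classes)
  }
  total <- sum(conf)
  tp <- diag(conf)
  fn <- rowSums(conf) - tp
  fp <- colSums(conf) - tp
  tn <- total - tp - fn - fp

  sens <- .safe_ratio(tp, tp + fn)
  spec <- .safe_ratio(tn, tn + fp)
  prec <- .safe_ratio(tp, tp + fp)
  f1num <- 2 * prec$value * sens$value
  f1den <- prec$value + sens$value
  f1 <- .safe_ratio(f1num, f1den)

  perClass <- data.frame(
    class = classes,
    sensitivity = unname(sens$value),
    specificity = unname(spec$value),
    precision = unname(prec$value),
    f1 = unname(f1$value),
    flagged = unname(sens$flagged | spec$flagged | prec$flagged |
                       f1$flagged),
    stringsAsFactors = FALSE
  )
  acc <- if (total > 0) sum(tp) / total else 0

  macro <- c(sensitivity = mean(perClass$sensitivity),
             specificity = mean(perClass$specificity),
             precision = mean(perClass$precision),
             f1 = mean(perClass$f1))
  microSens <- .safe_ratio(sum(tp), sum(tp + fn))$value
  microSpec <- .safe_ratio(sum(tn), sum(tn + fp))$value
  microPrec <- .safe_ratio(sum(tp), sum(tp + fp))$value
  microF1 <- if (microPrec + microSens > 0) {
    2 * microPrec * microSens / (microPrec + microSens)
  } else 0
  micro <- c(sensitivity = microSens, specificity = microSpec,
             precision = microPrec, f1 = microF1)

  new("MetricsReport", confusion = conf, perClass = perClass,
      accuracy = acc, macro = macro, micro = micro)
}

#' @rdname metrics-accessors
#' @export
setMethod("accuracy", "MetricsReport", function(x) x@accuracy)

#' @rdname metrics-accessors
#' @export
setMethod("perClassMetrics", "MetricsReport", function(x) x@perClass)

#' @rdname metrics-accessors
#' @export
setMethod("macroMetrics", "MetricsReport", function(x) x@macro)

#' @rdname metrics-accessors
#' @export
setMethod("microMetrics", "MetricsReport", function(x) x@micro)

#' @rdname metrics-accessors
#' @export
setMethod("confusion", "MetricsReport", function(x) x@confusion)

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport: %d classes, %d test samples\n",
              nrow(object@confusion), sum(object@confusion)))
  cat(sprintf("  accuracy: %.4f\n", object@accuracy))
  cat(sprintf("  macro: sens %.4f spec %.4f prec %.4f f1 %.4f\n",
              object@macro["sensitivity"], object@macro["specificity"],
              object@macro["precision"], object@macro["f1"]))
  df <- object@perClass
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %-10s sens %.4f spec %.4f prec %.4f f1 %.4f%s\n",
                df$class[i], df$sensitivity[i], df$specificity[i],
                df$precision[i], df$f1[i],
                if (df$flagged[i]) " [0/0 reported as 0]" else ""))
  }
})

#' Write a metrics report as a delimited table
#'
#' One metric per row (accuracy, then sensitivity/specificity/precision/F1)
#' with one column per class plus `macro` and `micro` aggregate columns, in
#' percent.
#'
#' @param report a [MetricsReport-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeMetricsReport <- function(report, path) {
  stopifnot(is(report, "MetricsReport"))
  df <- report@perClass
  tab <- rbind(
    accuracy = c(rep(NA_real_, nrow(df)), report@accuracy,
                 report@accuracy),
    sensitivity = c(df$sensitivity, report@macro["sensitivity"],
                    report@micro["sensitivity"]),
    specificity = c(df$specificity, report@macro["specificity"],
                    report@micro["specificity"]),
    precision = c(df$precision, report@macro["precision"],
                  report@micro["precision"]),
    f1 = c(df$f1, report@macro["f1"], report@micro["f1"])
  )
  colnames(tab) <- c(df$class, "macro", "micro")
  out <- data.frame(metric = rownames(tab),
                    round(tab * 100, 4), check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
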