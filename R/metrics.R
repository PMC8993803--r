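# Confusion-count bookkeeping and the evaluation metric suite:
#   accuracy    = (TP + TN) / (TP + TN + FP + FN)
#   specificity = TN / (TN + FP)
#   sensitivity = TP / (TP + FN)      (= recall)
#   precision   = TP / (TP + FP)
#   F1          = 2 * P * R / (P + R)
# Multiclass evaluation uses per-class one-vs-rest counts with an explicit
# averaging policy: micro pools counts over classes before applying the
# formula (for single-label multiclass this makes precision = recall = F1 =
# accuracy, a useful self-test identity); macro averages per-class values.
# Degenerate denominators yield 0 with a warning, never a silent NaN.

#' Per-class one-vs-rest confusion counts
#'
#' @param y_true,y_pred Equal-length label vectors with values in
#'   `class_set`.
#' @param class_set Ordered class labels.
#' @return A `confusion_counts` object: integer matrix with one row per
#'   class and columns TP, TN, FP, FN. Each row sums to `length(y_true)`.
#' @export
confusion <- function(y_true, y_pred, class_set) {
  if (length(y_true) != length(y_pred) || length(y_true) < 1) {
    stop("y_true and y_pred must have equal positive length")
  }
  if (!all(y_true %in% class_set) || !all(y_pred %in% class_set)) {
    stop("labels outside the class set")
  }
  n <- length(y_true)
  counts <- t(vapply(class_set, function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    c(TP = tp, TN = n - tp - fp - fn, FP = fp, FN = fn)
  }, integer(4)))
  rownames(counts) <- class_set
  structure(counts, class = c("confusion_counts", class(counts)))
}

# Pool counts (micro) or keep per-class rows (macro); both return a matrix.
pool_counts <- function(c, averaging) {
  if (averaging == "micro") matrix(colSums(c), 1,
                                   dimnames = list(NULL, colnames(c)))
  else unclass(c)
}

safe_ratio <- function(num, den, what) {
  out <- ifelse(den > 0, num / den, 0)
  if (any(den == 0)) {
    warning(sprintf("%s has a zero denominator; reporting 0", what))
  }
  out
}

#' @rdname metric-suite
#' @export
accuracy <- function(c, averaging = c("micro", "macro")) {
  averaging <- match.arg(averaging)
  m <- unclass(c)
  if (sum(m) == 0) stop("empty confusion counts")
  if (nrow(m) == 1 || averaging == "macro") {
    # binary count table (or macro policy): (TP + TN) / total per row
    tot <- m[, "TP"] + m[, "TN"] + m[, "FP"] + m[, "FN"]
    return(mean((m[, "TP"] + m[, "TN"]) / tot))
  }
  # micro multiclass: pooled TN double-counts under one-vs-rest, so plain
  # accuracy is the pooled TP share of the samples: sum TP / n
  sum(m[, "TP"]) / sum(m[, "TP"] + m[, "FN"])
}

#' Evaluation metric suite over confusion counts
#'
#' Binary formulas applied per the averaging policy; `sensitivity` and
#' `recall` are the same quantity under two conventional names.
#'
#' @param c A `confusion_counts` object (or any TP/TN/FP/FN count matrix).
#' @param averaging `"micro"` (pool counts over classes first, the default)
#'   or `"macro"` (average per-class values).
#' @return A single numeric value in \[0, 1\].
#' @name metric-suite
NULL

#' @rdname metric-suite
#' @export
specificity <- function(c, averaging = c("micro", "macro")) {
  averaging <- match.arg(averaging)
  m <- pool_counts(c, averaging)
  mean(safe_ratio(m[, "TN"], m[, "TN"] + m[, "FP"], "specificity"))
}

#' @rdname metric-suite
#' @export
sensitivity <- function(c, averaging = c("micro", "macro")) {
  averaging <- match.arg(averaging)
  m <- pool_counts(c, averaging)
  mean(safe_ratio(m[, "TP"], m[, "TP"] + m[, "FN"], "sensitivity"))
}

#' @rdname metric-suite
#' @export
precision <- function(c, averaging = c("micro", "macro")) {
  averaging <- match.arg(averaging)
  m <- pool_counts(c, averaging)
  mean(safe_ratio(m[, "TP"], m[, "TP"] + m[, "FP"], "precision"))
}

#' @rdname metric-suite
#' @export
recall <- function(c, averaging = c("micro", "macro")) {
  sensitivity(c, averaging)
}

#' @rdname metric-suite
#' @export
f1_score <- function(c, averaging = c("micro", "macro")) {
  averaging <- match.arg(averaging)
  m <- pool_counts(c, averaging)
  p <- safe_ratio(m[, "TP"], m[, "TP"] + m[, "FP"], "precision")
  r <- safe_ratio(m[, "TP"], m[, "TP"] + m[, "FN"], "recall")
  mean(ifelse(p + r > 0, 2 * p * r / (p + r), 0))
}

#' Full metrics report for a prediction vector
#'
#' @inheritParams confusion
#' @param averaging Averaging policy, `"micro"` or `"macro"`.
#' @return A `metrics_report` list with `accuracy`, `specificity`,
#'   `precision`, `f1`, `recall`, `sensitivity`, the `averaging` policy and
#'   the `counts`.
#' @export
metrics_report <- function(y_true, y_pred, class_set,
                           averaging = c("micro", "macro")) {
  averaging <- match.arg(averaging)
  cc <- confusion(y_true, y_pred, class_set)
  structure(list(accuracy = accuracy(cc, averaging),
                 specificity = specificity(cc, averaging),
                 precision = precision(cc, averaging),
                 f1 = f1_score(cc, averaging),
                 recall = recall(cc, averaging),
                 sensitivity = sensitivity(cc, averaging),
                 averaging = averaging, counts = cc),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> (%s averaging)\n", x$averaging))
  for (k in c("accuracy", "specificity", "precision", "f1", "recall",
              "sensitivity")) {
    cat(sprintf("  %-12s %.4f\n", k, x[[k]]))
  }
  invisible(x)
}

#' Write a metrics report as CSV or JSON
#'
#' Fixed key order: accuracy, specificity, precision, f1, recall,
#' sensitivity.
#'
#' @param report A `metrics_report`.
#' @param path Output path ending in `.csv` or `.json`.
#' @return Invisibly, `path`.
#' @export
write_metrics <- function(report, path) {
  keys <- c("accuracy", "specificity", "precision", "f1", "recall",
            "sensitivity")
  vals <- unlist(report[keys])
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(as.list(vals), path, auto_unbox = TRUE, digits = NA)
  } else {
    write.csv(data.frame(metric = keys, value = as.numeric(vals)),
              path, row.names = FALSE)
  }
  invisible(path)
}
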