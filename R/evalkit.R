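# Confusion-matrix construction, accuracy / precision / recall / F1, and
# the 5-class -> 3-grade consolidation. Rows are true classes, columns are
# predictions. Multiclass accuracy is trace/total (the standard multiclass
# reading of the binary TP/TN form; equivalent to it for K = 2). Metrics
# with an empty denominator are defined as 0 with a warning so that small
# evaluations never crash.

#' Confusion matrix
#'
#' `counts[i, j]` is the number of samples with true class `i` predicted as
#' class `j`.
#'
#' @param true,pred equal-length label vectors; factors, class-name
#'   characters, or integers in `1..K`
#' @param labels ordered class labels; defaults to [egg_labels()] for
#'   character/factor input or `1..max` for integer input
#' @return a `K x K` integer matrix of class `confusion_matrix`
#' @examples
#' confusion(c(1, 1, 2), c(1, 2, 2), labels = c("a", "b"))
#' @export
confusion <- function(true, pred, labels = NULL) {
  if (length(true) != length(pred)) stop("true and pred must have equal length")
  if (is.null(labels)) {
    labels <- if (is.numeric(true) && is.numeric(pred)) {
      seq_len(max(true, pred))
    } else {
      egg_labels()
    }
  }
  to_idx <- function(v) {
    if (is.numeric(v)) {
      v <- as.integer(v)
      if (any(v < 1L | v > length(labels))) stop("labels out of range 1..K")
      v
    } else {
      i <- match(as.character(v), as.character(labels))
      if (anyNA(i)) stop("labels outside the class set")
      i
    }
  }
  ti <- to_idx(true)
  pi <- to_idx(pred)
  k <- length(labels)
  cm <- matrix(0L, k, k, dimnames = list(true = labels, predicted = labels))
  for (s in seq_along(ti)) cm[ti[s], pi[s]] <- cm[ti[s], pi[s]] + 1L
  structure(cm, class = c("confusion_matrix", "matrix"))
}

check_cm <- function(cm) {
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm), all(cm >= 0))
  invisible(cm)
}

class_index <- function(cm, class) {
  if (is.character(class)) {
    i <- match(class, rownames(cm))
    if (is.na(i)) stop("unknown class: ", class)
    i
  } else {
    as.integer(class)
  }
}

safe_ratio <- function(num, den, what) {
  if (den == 0) {
    warning(what, " undefined (zero denominator); returning 0")
    return(0)
  }
  num / den
}

#' Overall accuracy
#'
#' @param cm a [confusion()] matrix
#' @return trace / total, in `[0, 1]`
#' @export
accuracy <- function(cm) {
  check_cm(cm)
  safe_ratio(sum(diag(cm)), sum(cm), "accuracy")
}

#' Per-class precision (one-vs-rest)
#'
#' @param cm a [confusion()] matrix
#' @param class class name or index
#' @return `TP / (TP + FP)`
#' @export
precision <- function(cm, class) {
  check_cm(cm)
  i <- class_index(cm, class)
  safe_ratio(cm[i, i], sum(cm[, i]), "precision")
}

#' Per-class recall (one-vs-rest)
#'
#' @inheritParams precision
#' @return `TP / (TP + FN)`
#' @export
recall <- function(cm, class) {
  check_cm(cm)
  i <- class_index(cm, class)
  safe_ratio(cm[i, i], sum(cm[i, ]), "recall")
}

#' Per-class F1-score
#'
#' Harmonic mean of precision and recall.
#'
#' @inheritParams precision
#' @return `2 P R / (P + R)`
#' @export
f1 <- function(cm, class) {
  p <- precision(cm, class)
  r <- recall(cm, class)
  if (p + r == 0) return(0)
  2 * p * r / (p + r)
}

#' Consolidate five classes into three grades
#'
#' Sums the PP, BYP and YYP rows and columns into a single SP grade;
#' within-substandard confusions land on the SP diagonal, so grading
#' accuracy is always at least classification accuracy. Counts are
#' conserved.
#'
#' @param cm5 a 5x5 [confusion()] matrix labelled QP/PP/BYP/YYP/IP
#' @return a 3x3 confusion matrix labelled QP/SP/IP
#' @export
consolidate_grades <- function(cm5) {
  check_cm(cm5)
  if (!identical(rownames(cm5), egg_labels())) {
    stop("expected a confusion matrix over classes ", paste(egg_labels(), collapse = ", "))
  }
  g <- as.integer(egg_grade(egg_labels()))
  cm3 <- matrix(0L, 3L, 3L, dimnames = list(true = egg_grades(),
                                            predicted = egg_grades()))
  for (i in 1:5) {
    for (j in 1:5) cm3[g[i], g[j]] <- cm3[g[i], g[j]] + cm5[i, j]
  }
  structure(cm3, class = c("confusion_matrix", "matrix"))
}

#' Classification report
#'
#' Per-class F1 (percent, one decimal) plus overall accuracy, in the layout
#' used by the package's evaluation tables.
#'
#' @param cm a [confusion()] matrix
#' @param model_name row label for the report
#' @param param_count optional parameter count to include
#' @return data.frame of class `peggnet_report`
#' @export
classification_report <- function(cm, model_name = "model", param_count = NULL) {
  check_cm(cm)
  f1s <- vapply(seq_len(nrow(cm)), function(i) f1(cm, i), numeric(1))
  df <- data.frame(Model = model_name, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(param_count)) df[["Parameter"]] <- format_param_count(param_count)
  for (i in seq_len(nrow(cm))) {
    df[[paste0(rownames(cm)[i], " Egg F1/%")]] <- round(100 * f1s[i], 1)
  }
  df[["Accuracy/%"]] <- round(100 * accuracy(cm), 1)
  class(df) <- c("peggnet_report", "data.frame")
  df
}

#' @export
print.peggnet_report <- function(x, ...) {
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}
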