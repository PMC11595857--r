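#' Confusion matrix
#'
#' @param true_labels,predicted_labels integer vectors of equal length
#'   with values in `[0, num_classes)`.
#' @param num_classes number of classes `M`.
#' @return `M x M` integer matrix; entry `(i, j)` counts samples of true
#'   class `i - 1` predicted as class `j - 1`.
#' @export
confusion_matrix <- function(true_labels, predicted_labels, num_classes) {
  assert_positive_int(num_classes, "num_classes")
  if (length(true_labels) != length(predicted_labels))
    stop("label vectors must have equal length", call. = FALSE)
  check_labels(true_labels, num_classes)
  check_labels(predicted_labels, num_classes)
  cm <- matrix(0L, num_classes, num_classes)
  if (length(true_labels)) {
    tab <- table(factor(true_labels, levels = 0:(num_classes - 1)),
                 factor(predicted_labels, levels = 0:(num_classes - 1)))
    cm <- matrix(as.integer(tab), num_classes, num_classes)
  }
  dimnames(cm) <- list(true = 0:(num_classes - 1),
                       predicted = 0:(num_classes - 1))
  cm
}

#' Classification metrics from a confusion matrix
#'
#' Derives one-vs-rest TP/FP/FN/TN per class and computes accuracy
#' (`(TP+TN)/(TP+TN+FP+FN)`, which for single-label multiclass equals
#' `trace/n`), precision (`TP/(TP+FP)`), recall (`TP/(TP+FN)`) and
#' F1 (`2PR/(P+R)`), aggregated by the requested averaging.  A class that
#' is never predicted (`TP+FP = 0`) gets precision 0 with a warning;
#' the same policy applies to recall and F1 denominators.
#'
#' @param confusion `M x M` count matrix (rows = true class).
#' @param averaging `"macro"` (default, unweighted mean over classes),
#'   `"micro"` (aggregate counts; for single-label data this equals
#'   accuracy), or `"weighted"` (support-weighted mean).
#' @return an `evaluation_report`: list with `confusion`, `accuracy`,
#'   `precision`, `recall`, `f1`, `averaging` and a `per_class`
#'   data.frame.
#' @export
classification_metrics <- function(confusion,
                                   averaging = c("macro", "micro",
                                                 "weighted")) {
  averaging <- match.arg(averaging)
  if (!is.matrix(confusion) || nrow(confusion) != ncol(confusion))
    stop("`confusion` must be a square matrix", call. = FALSE)
  if (any(confusion < 0) || any(confusion != floor(confusion)))
    stop("`confusion` must hold non-negative counts", call. = FALSE)
  m <- nrow(confusion)
  n <- sum(confusion)
  tp <- diag(confusion)
  fp <- colSums(confusion) - tp
  fn <- rowSums(confusion) - tp
  tn <- n - tp - fp - fn

  safe_div <- function(num, den, what) {
    bad <- den == 0
    if (any(bad))
      warning(sprintf("%s undefined for class(es) %s; reported as 0", what,
                      paste(which(bad) - 1L, collapse = ", ")),
              call. = FALSE)
    out <- numeric(length(num))
    out[!bad] <- num[!bad] / den[!bad]
    out
  }
  prec_c <- safe_div(tp, tp + fp, "precision")
  rec_c <- safe_div(tp, tp + fn, "recall")
  f1_c <- ifelse(prec_c + rec_c == 0, 0,
                 2 * prec_c * rec_c / (prec_c + rec_c))
  accuracy <- if (n == 0) 0 else sum(tp) / n

  agg <- switch(averaging,
    macro = c(mean(prec_c), mean(rec_c), mean(f1_c)),
    weighted = {
      w <- rowSums(confusion)
      w <- if (sum(w) == 0) rep(1 / m, m) else w / sum(w)
      c(sum(w * prec_c), sum(w * rec_c), sum(w * f1_c))
    },
    micro = {
      p <- if (sum(tp + fp) == 0) 0 else sum(tp) / sum(tp + fp)
      r <- if (sum(tp + fn) == 0) 0 else sum(tp) / sum(tp + fn)
      f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
      c(p, r, f)
    })

  structure(list(confusion = confusion, accuracy = accuracy,
                 precision = agg[1], recall = agg[2], f1 = agg[3],
                 averaging = averaging,
                 per_class = data.frame(class = 0:(m - 1), tp = tp, fp = fp,
                                        fn = fn, tn = tn,
                                        precision = prec_c, recall = rec_c,
                                        f1 = f1_c, support = rowSums(confusion),
                                        row.names = NULL)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Evaluation report (%s averaging, n = %d)\n", x$averaging,
              sum(x$confusion)))
  cat(sprintf("  accuracy  %.4f\n  precision %.4f\n  recall    %.4f\n  F1        %.4f\n",
              x$accuracy, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Write an evaluation report as JSON
#'
#' @param report an `evaluation_report`.
#' @param path output file.
#' @param per_class include the per-class breakdown.
#' @export
write_evaluation_report <- function(report, path, per_class = TRUE) {
  out <- list(accuracy = report$accuracy, precision = report$precision,
              recall = report$recall, f1 = report$f1,
              averaging = report$averaging,
              confusion = unname(apply(report$confusion, 1, as.integer,
                                       simplify = FALSE)))
  if (per_class) out$per_class <- report$per_class
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
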