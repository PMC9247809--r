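#' Positive-class evaluation report
#'
#' Precision, recall and F1 are computed for the positive (VAEM) class
#' only, with the conventions `P = TP/(TP+FP)` when `TP+FP > 0` (else 0),
#' `R = TP/(TP+FN)` when `TP+FN > 0` (else 0), and `F1 = 2PR/(P+R)` when
#' `P+R > 0`, else 0 -- degenerate predictors score 0, never `NaN`.
#'
#' @param tp,fp,fn,tn confusion counts.
#' @param classifier_id,test_set optional identifiers carried in the report.
#' @return a `vaem_eval_report` list with the counts and `precision`,
#'   `recall`, `f1`.
#' @export
eval_report <- function(tp, fp, fn, tn = NA_integer_, classifier_id = "",
                        test_set = "") {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  s <- positive_f1(tp, fp, fn)
  structure(list(classifier_id = classifier_id, test_set = test_set,
                 tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn),
                 precision = unname(s["precision"]),
                 recall = unname(s["recall"]), f1 = unname(s["f1"])),
            class = "vaem_eval_report")
}

#' @export
print.vaem_eval_report <- function(x, ...) {
  # 3-decimal, half-away-from-zero display, table style
  f <- function(v) sprintf("%.3f", round_half_up(v, 3))
  cat(sprintf("%s%s P=%s R=%s F1=%s (TP=%d FP=%d FN=%d TN=%s)\n",
              if (nzchar(x$classifier_id)) paste0(x$classifier_id, " ") else "",
              if (nzchar(x$test_set)) paste0("[", x$test_set, "]") else "",
              f(x$precision), f(x$recall), f(x$f1),
              x$tp, x$fp, x$fn,
              if (is.na(x$tn)) "?" else x$tn))
  invisible(x)
}

#' Evaluate predictions against labels
#'
#' @param pred predicted labels (character or logical).
#' @param truth true labels (character or logical).
#' @param positive the positive-class label (default `"VAEM"`).
#' @param classifier_id,test_set identifiers for the report.
#' @return a [eval_report()].
#' @export
evaluate <- function(pred, truth, positive = "VAEM", classifier_id = "",
                     test_set = "") {
  p <- if (is.logical(pred)) pred else pred == positive
  y <- if (is.logical(truth)) truth else truth == positive
  stopifnot(length(p) == length(y))
  eval_report(tp = sum(p & y), fp = sum(p & !y), fn = sum(!p & y),
              tn = sum(!p & !y), classifier_id = classifier_id,
              test_set = test_set)
}
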