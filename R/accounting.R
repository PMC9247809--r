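#' Percentage with explicit rounding
#'
#' `100 * numerator / denominator`, rounded half away from zero -- the
#' convention used for every displayed percentage in the funnel and
#' effectiveness reports.
#'
#' @param numerator,denominator counts; `denominator` must be positive.
#' @param decimals decimal places (default 2).
#' @return numeric percentage.
#' @export
#' @examples
#' ratio_pct(802018, 811010)  # 98.89
ratio_pct <- function(numerator, denominator, decimals = 2) {
  if (any(denominator <= 0)) stop("denominator must be positive")
  round_half_up(100 * numerator / denominator, decimals)
}

#' Stage-by-stage retention funnel
#'
#' Builds the ordered ledger of record counts through the pipeline: each
#' stage applies a signed delta to the running total and reports the total
#' as a percentage of the initial count (2 decimals, half away from zero).
#' Running totals use exact integer arithmetic and must stay non-negative.
#'
#' @param initial initial record count (> 0).
#' @param deltas named numeric vector of signed stage deltas, in order.
#' @return a `vaem_funnel`: data.frame with columns `stage`, `delta`,
#'   `running_total`, `pct_of_initial`, first row being the initial count.
#' @export
#' @examples
#' build_funnel(811010, c(cleaning = -122653, stage1 = -570383,
#'                        stage2 = -19083))
build_funnel <- function(initial, deltas) {
  stopifnot(is.numeric(initial), initial > 0, is.numeric(deltas))
  if (is.null(names(deltas)) || any(!nzchar(names(deltas)))) {
    stop("every delta must be named")
  }
  total <- as.integer(initial)
  rows <- data.frame(stage = "initial", delta = 0L, running_total = total,
                     pct_of_initial = ratio_pct(total, initial),
                     stringsAsFactors = FALSE)
  for (i in seq_along(deltas)) {
    total <- total + as.integer(deltas[i])
    if (total < 0) {
      stop("inconsistent funnel: running total negative at stage '",
           names(deltas)[i], "'")
    }
    rows <- rbind(rows, data.frame(
      stage = names(deltas)[i], delta = as.integer(deltas[i]),
      running_total = total, pct_of_initial = ratio_pct(total, initial),
      stringsAsFactors = FALSE))
  }
  structure(rows, class = c("vaem_funnel", "data.frame"))
}

#' @export
print.vaem_funnel <- function(x, ...) {
  df <- as.data.frame(x)
  df$running_total <- format(df$running_total, big.mark = ",")
  df$delta <- format(df$delta, big.mark = ",")
  df$pct_of_initial <- sprintf("(%.2f)", df$pct_of_initial)
  print(df, row.names = FALSE)
  invisible(x)
}

#' End-to-end VAEM-capture estimate
#'
#' Extrapolates classifier performance to the whole filtered stream and
#' combines it with the topic-model capture rate:
#' `TP_est = round(r * V)` VAEM correctly classified, predicted positives
#' `round(TP_est / p)`, false positives by difference, and
#' `V_original_est = round(V / c)` VAEM estimated in the raw stream.  When
#' the corresponding counts are known exactly (as when `r` and `p` are
#' themselves rounded for display), pass them via `tp` / `predicted_pos`;
#' the count form is canonical and takes precedence over the re-derivation
#' from rounded rates.
#'
#' @param V labeled VAEM count in the filtered stream.
#' @param N labeled non-VAEM count in the filtered stream.
#' @param r classifier recall on the positive class (0 < r <= 1).
#' @param p classifier precision on the positive class (0 < p <= 1).
#' @param c topic-model capture rate: fraction of all true VAEM that
#'   survive filtering (0 < c <= 1).
#' @param tp optional exact count of correctly classified VAEM.
#' @param predicted_pos optional exact predicted-positive count.
#' @param tp_after_pipeline optional count of VAEM surviving the *whole*
#'   pipeline (defaults to `tp`); numerator of the capture percentage.
#' @param initial optional initial stream size, enabling the elimination
#'   percentage.
#' @return a `vaem_effectiveness` list: `TP_est`, `predicted_pos`,
#'   `FP_est`, `V_original_est`, `V_total_identified`, `tp_pct`,
#'   `missed_pct`, `fp_of_nonvaem_pct`, `capture_pct`, `elimination_pct`
#'   (percentages at 2 decimals, half away from zero).
#' @export
estimate_effectiveness <- function(V, N, r, p, c, tp = NULL,
                                   predicted_pos = NULL,
                                   tp_after_pipeline = NULL,
                                   initial = NULL) {
  stopifnot(V >= 0, N >= 0, r > 0, r <= 1, p > 0, p <= 1, c > 0, c <= 1)
  TP_est <- as.integer(tp %||% round_half_up(r * V))
  if (TP_est > V) stop("estimated true positives exceed labeled VAEM")
  predicted_pos <- as.integer(predicted_pos %||% round_half_up(TP_est / p))
  FP_est <- predicted_pos - TP_est
  if (FP_est < 0) stop("predicted positives below true positives")
  V_original_est <- as.integer(round_half_up(V / c))
  tp_after <- as.integer(tp_after_pipeline %||% TP_est)
  out <- list(
    V = as.integer(V), N = as.integer(N), r = r, p = p, c = c,
    TP_est = TP_est, predicted_pos = predicted_pos, FP_est = FP_est,
    V_original_est = V_original_est, V_total_identified = tp_after,
    tp_pct = ratio_pct(TP_est, V),
    missed_pct = ratio_pct(V - TP_est, V),
    fp_of_nonvaem_pct = if (N > 0) ratio_pct(FP_est, N) else NA_real_,
    capture_pct = ratio_pct(tp_after, V_original_est),
    elimination_pct = if (!is.null(initial))
      ratio_pct(initial - tp_after, initial) else NA_real_,
    identified_of_initial_pct = if (!is.null(initial))
      ratio_pct(tp_after, initial) else NA_real_
  )
  structure(out, class = "vaem_effectiveness")
}

#' @export
print.vaem_effectiveness <- function(x, ...) {
  cat(sprintf("VAEM capture estimate\n"))
  cat(sprintf("  correctly classified: %s/%s (%.2f%%), missed %.2f%%\n",
              format(x$TP_est, big.mark = ","),
              format(x$V, big.mark = ","), x$tp_pct, x$missed_pct))
  cat(sprintf("  predicted positive: %s (FP %s, %.2f%% of non-VAEM)\n",
              format(x$predicted_pos, big.mark = ","),
              format(x$FP_est, big.mark = ","), x$fp_of_nonvaem_pct))
  cat(sprintf("  VAEM in raw stream (est.): %s; end-to-end capture %.2f%%\n",
              format(x$V_original_est, big.mark = ","), x$capture_pct))
  if (!is.na(x$elimination_pct)) {
    cat(sprintf("  eliminated %.2f%% of the stream; identified %.2f%%\n",
                x$elimination_pct, x$identified_of_initial_pct))
  }
  invisible(x)
}
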