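#' Grid search over vectorizer and classifier configurations
#'
#' Trains every vectorizer-config x classifier-spec combination on the
#' training documents and ranks them by positive-class F1 on the
#' validation documents.  Ties break toward fewer features, then the order
#' the configurations were given, so the ranking is deterministic.
#'
#' @param train_tokens,train_labels training documents (token lists) and
#'   labels.
#' @param valid_tokens,valid_labels validation documents and labels.
#' @param vec_grid list of [vectorizer_config()]s.
#' @param specs character vector of classifier specs
#'   (see [train_classifier()]).
#' @param seed integer seed applied to every fit.
#' @return data.frame log, one row per combination, ranked: `rank`, `spec`,
#'   `vec_cfg` (index into `vec_grid`), `f1`, `precision`, `recall`,
#'   `n_features`.
#' @export
grid_search <- function(train_tokens, train_labels, valid_tokens,
                        valid_labels, vec_grid = list(vectorizer_config()),
                        specs = c("logreg_cv", "nbsvm"), seed = 1) {
  stopifnot(length(vec_grid) > 0, length(specs) > 0)
  rows <- list()
  for (vi in seq_along(vec_grid)) {
    vec <- fit_vectorizer(train_tokens, vec_grid[[vi]])
    xtr <- vectorize(vec, train_tokens)
    xva <- vectorize(vec, valid_tokens)
    for (sp in specs) {
      clf <- train_classifier(sp, xtr, train_labels, seed = seed)
      rep <- evaluate(predict(clf, xva), valid_labels,
                      classifier_id = sp, test_set = "validation")
      rows[[length(rows) + 1]] <- data.frame(
        spec = sp, vec_cfg = vi, f1 = rep$f1, precision = rep$precision,
        recall = rep$recall, n_features = ncol(xtr),
        stringsAsFactors = FALSE)
    }
  }
  log <- do.call(rbind, rows)
  ord <- order(-log$f1, log$n_features, seq_len(nrow(log)))
  log <- log[ord, , drop = FALSE]
  log$rank <- seq_len(nrow(log))
  rownames(log) <- NULL
  log[, c("rank", "spec", "vec_cfg", "f1", "precision", "recall",
          "n_features")]
}
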