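#' Build a pruned topic-model vocabulary
#'
#' @param corpus list of token vectors.
#' @param min_doc_count drop tokens appearing in fewer documents (default 5).
#' @param max_doc_frac drop tokens appearing in more than this fraction of
#'   documents (default 0.5).
#' @return character vector of retained vocabulary, lexicographically sorted.
#' @export
build_vocab <- function(corpus, min_doc_count = 5, max_doc_frac = 0.5) {
  stopifnot(is.list(corpus))
  n_docs <- length(corpus)
  df <- table(unlist(lapply(corpus, unique), use.names = FALSE))
  keep <- df >= min_doc_count & df <= max_doc_frac * n_docs
  sort(names(df)[keep])
}

docs_to_ids <- function(corpus, vocab) {
  lapply(corpus, function(t) {
    ids <- match(t, vocab)
    as.integer(ids[!is.na(ids)] - 1L)
  })
}

#' Fit a latent Dirichlet allocation topic model
#'
#' Collapsed Gibbs sampling with symmetric Dirichlet priors, run for a
#' fixed iteration budget; bit-reproducible for a fixed seed.  Defaults
#' follow common practice for short-text streams: priors `1/K`, 400
#' sweeps, vocabulary pruned of very rare and very common tokens.
#'
#' @param corpus list of token vectors (typically the `ngram_tokens` of a
#'   cleaned corpus).
#' @param n_topics number of topics `K` (>= 1).
#' @param seed integer seed for the Gibbs chain.
#' @param alpha,beta symmetric Dirichlet priors; default `1/K`.
#' @param n_iter Gibbs sweeps (default 400).
#' @param vocab optional fixed vocabulary; built with [build_vocab()]
#'   otherwise.
#' @param min_doc_count,max_doc_frac vocabulary pruning, see [build_vocab()].
#' @return a `vaem_topic_model`: list with `n_topics`, `phi` (K x V
#'   topic-word matrix, rows sum to 1), `theta` (D x K doc-topic matrix,
#'   rows sum to 1), `vocab`, `alpha`, `beta`, `n_iter`, `seed`.
#' @export
fit_topic_model <- function(corpus, n_topics, seed = 1,
                            alpha = 1 / n_topics, beta = 1 / n_topics,
                            n_iter = 400, vocab = NULL,
                            min_doc_count = 5, max_doc_frac = 0.5) {
  stopifnot(is.list(corpus), length(corpus) > 0, n_topics >= 1)
  if (is.null(vocab)) {
    vocab <- build_vocab(corpus, min_doc_count, max_doc_frac)
  }
  if (length(vocab) == 0) stop("vocabulary is empty after pruning")
  docs <- docs_to_ids(corpus, vocab)
  fit <- cpp_lda_fit(docs, length(vocab), as.integer(n_topics),
                     alpha, beta, as.integer(n_iter), as.integer(seed))
  nwk <- fit$topic_word_counts
  ndk <- fit$doc_topic_counts
  phi <- (nwk + beta) / (rowSums(nwk) + length(vocab) * beta)
  theta <- (ndk + alpha) / (rowSums(ndk) + n_topics * alpha)
  colnames(phi) <- vocab
  structure(list(n_topics = as.integer(n_topics), phi = phi, theta = theta,
                 vocab = vocab, alpha = alpha, beta = beta,
                 n_iter = as.integer(n_iter), seed = as.integer(seed)),
            class = "vaem_topic_model")
}

#' @export
print.vaem_topic_model <- function(x, ...) {
  cat(sprintf("LDA topic model: K=%d, V=%d, %d docs, %d sweeps, seed %d\n",
              x$n_topics, length(x$vocab), nrow(x$theta), x$n_iter, x$seed))
  invisible(x)
}

#' Infer doc-topic proportions for unseen documents
#'
#' Fold-in Gibbs sampling against the frozen topic-word distribution of a
#' trained model: no refitting, as required when applying trained models to
#' an incoming stream.
#'
#' @param model a `vaem_topic_model`.
#' @param corpus list of token vectors.
#' @param n_iter fold-in sweeps per document (default 30).
#' @param seed integer seed.
#' @return matrix (documents x topics) of topic proportions; documents with
#'   no in-vocabulary tokens get a uniform row.
#' @export
infer_topics <- function(model, corpus, n_iter = 30, seed = 1) {
  stopifnot(inherits(model, "vaem_topic_model"))
  docs <- docs_to_ids(corpus, model$vocab)
  cpp_lda_infer(docs, model$phi, model$alpha, as.integer(n_iter),
                as.integer(seed))
}

#' Dominant topic of each document
#'
#' Hard assignment: the argmax of each document's topic distribution, ties
#' broken toward the lowest topic index.
#'
#' @param x a `vaem_topic_model` (its training documents are used) or a
#'   documents-by-topics proportion matrix.
#' @return integer vector of 1-based topic indices.
#' @export
dominant_topic <- function(x) {
  theta <- if (inherits(x, "vaem_topic_model")) x$theta else as.matrix(x)
  max.col(theta, ties.method = "first")
}
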