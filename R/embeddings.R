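#' Train skip-gram word embeddings
#'
#' Word2vec-style skip-gram with negative sampling, trained single-threaded
#' so a fixed seed yields identical vectors.  Intended for the full cleaned
#' corpus (not only the filtered stream), as dense inputs for optional
#' neural classifiers.
#'
#' @param corpus list of token vectors (>= 100 documents).
#' @param dim embedding dimension (default 50).
#' @param window maximum context window (default 5).
#' @param seed integer seed.
#' @param min_count minimum corpus frequency for a token to get a vector
#'   (default 2).
#' @param negative negative samples per positive (default 5).
#' @param epochs passes over the corpus (default 5).
#' @param lr initial learning rate (default 0.025).
#' @return a `vaem_embeddings`: list with `vectors` (vocab x dim matrix,
#'   rownames = vocabulary), `dim`, `window`, `seed`.
#' @export
train_embeddings <- function(corpus, dim = 50, window = 5, seed = 1,
                             min_count = 2, negative = 5, epochs = 5,
                             lr = 0.025) {
  stopifnot(is.list(corpus), length(corpus) >= 100, dim >= 2, window >= 1)
  flat <- unlist(corpus, use.names = FALSE)
  cnt <- table(flat)
  vocab <- sort(names(cnt)[cnt >= min_count])
  if (length(vocab) < 2) stop("vocabulary too small for embeddings")
  docs <- docs_to_ids(corpus, vocab)
  docs <- docs[lengths(docs) > 1]
  m <- cpp_sgns_train(docs, as.integer(cnt[vocab]), as.integer(dim),
                      as.integer(window), as.integer(negative),
                      as.integer(epochs), lr, as.integer(seed))
  rownames(m) <- vocab
  structure(list(vectors = m, dim = as.integer(dim),
                 window = as.integer(window), seed = as.integer(seed)),
            class = "vaem_embeddings")
}

#' Look up embedding vectors
#'
#' @param emb a `vaem_embeddings`.
#' @param tokens character vector of tokens.
#' @return tokens x dim matrix; out-of-vocabulary tokens map to the zero
#'   vector.
#' @export
embedding_lookup <- function(emb, tokens) {
  stopifnot(inherits(emb, "vaem_embeddings"))
  idx <- match(tokens, rownames(emb$vectors))
  out <- matrix(0, nrow = length(tokens), ncol = emb$dim,
                dimnames = list(tokens, NULL))
  hit <- !is.na(idx)
  out[hit, ] <- emb$vectors[idx[hit], , drop = FALSE]
  out
}
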