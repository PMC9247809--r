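#' Merge frequent collocations into phrase tokens
#'
#' Iterated bigram merging in the style used for topic-model preprocessing:
#' a contiguous token pair (a, b) is merged into `a_b` when its pointwise
#' collocation score
#' \deqn{score(a,b) = \frac{(count(a,b) - min\_count) \cdot N}{count(a)\,count(b)}}
#' exceeds `threshold`, where `N` is the number of tokens in the corpus.
#' One pass produces bigrams; each further pass (up to `max_n - 1` passes)
#' can chain merged tokens into longer phrases.  Within a document merging
#' is greedy left-to-right, so every phrase token maps back to a contiguous
#' token run.  Deterministic for fixed input.
#'
#' @param corpus list of character token vectors.
#' @param max_n longest phrase length (in original tokens); default 3.
#' @param min_count minimum pair count before a pair can score; default 5.
#' @param threshold score above which a pair is merged; `Inf` disables
#'   merging; default 10.
#' @return list of token vectors with merged phrase tokens.
#' @export
build_phrases <- function(corpus, max_n = 3, min_count = 5, threshold = 10) {
  stopifnot(is.list(corpus), length(corpus) > 0, max_n >= 1)
  if (max_n == 1 || is.infinite(threshold)) return(corpus)
  for (pass in seq_len(max_n - 1)) {
    corpus <- phrase_pass(corpus, min_count, threshold)
  }
  corpus
}

phrase_pass <- function(corpus, min_count, threshold) {
  flat <- unlist(corpus, use.names = FALSE)
  if (length(flat) == 0) return(corpus)
  n_tok <- length(flat)
  uni <- table(flat)
  # adjacent pairs per document
  lens <- lengths(corpus)
  pair_docs <- lens >= 2
  if (!any(pair_docs)) return(corpus)
  pairs <- unlist(lapply(corpus[pair_docs], function(t) {
    paste(t[-length(t)], t[-1], sep = "\r")
  }), use.names = FALSE)
  pc <- table(pairs)
  pc <- pc[pc > min_count]
  if (length(pc) == 0) return(corpus)
  parts <- stringi::stri_split_fixed(names(pc), "\r", simplify = TRUE)
  score <- (as.numeric(pc) - min_count) * n_tok /
    (as.numeric(uni[parts[, 1]]) * as.numeric(uni[parts[, 2]]))
  good <- names(pc)[score > threshold]
  if (length(good) == 0) return(corpus)
  # only revisit documents that actually contain a mergeable pair
  hit_flat <- pairs %in% good
  which_docs <- which(pair_docs)
  doc_idx <- rep.int(seq_along(which_docs), lens[pair_docs] - 1L)
  hits_by_doc <- split(hit_flat, factor(doc_idx, levels = seq_along(which_docs)))
  j_hit <- which(vapply(hits_by_doc, any, logical(1)))
  corpus[which_docs[j_hit]] <- mapply(merge_pairs, corpus[which_docs[j_hit]],
                                      hits_by_doc[j_hit], SIMPLIFY = FALSE)
  corpus
}

merge_pairs <- function(tokens, hits) {
  n <- length(tokens)
  out <- character(n)
  k <- 0L
  i <- 1L
  while (i <= n) {
    if (i < n && hits[i]) {
      k <- k + 1L
      out[k] <- paste(tokens[i], tokens[i + 1L], sep = "_")
      i <- i + 2L  # greedy: the consumed token cannot start another merge
    } else {
      k <- k + 1L
      out[k] <- tokens[i]
      i <- i + 1L
    }
  }
  out[seq_len(k)]
}
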