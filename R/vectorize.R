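# Compact English stopword list (function words only; domain words are
# never stopworded).
.stopwords <- c(
  "a", "about", "after", "again", "all", "am", "an", "and", "any", "are",
  "as", "at", "be", "because", "been", "before", "being", "between", "both",
  "but", "by", "can", "did", "do", "does", "doing", "down", "during", "each",
  "few", "for", "from", "further", "had", "has", "have", "having", "he",
  "her", "here", "hers", "him", "his", "how", "i", "if", "in", "into", "is",
  "it", "its", "just", "me", "more", "most", "my", "no", "nor", "not", "now",
  "of", "off", "on", "once", "only", "or", "other", "our", "out", "over",
  "own", "same", "she", "so", "some", "such", "than", "that", "the", "their",
  "them", "then", "there", "these", "they", "this", "those", "through", "to",
  "too", "under", "until", "up", "very", "was", "we", "were", "what", "when",
  "where", "which", "while", "who", "whom", "why", "will", "with", "you",
  "your")

#' Bag-of-words vectorizer configuration
#'
#' @param weighting `"counts"` or `"tfidf"` (smoothed idf, l2-normalized
#'   rows).
#' @param ngram_range integer pair `(lo, hi)`, `1 <= lo <= hi <= 3`; word
#'   n-grams in that range become features.
#' @param remove_stopwords drop common English function words.
#' @param remove_numbers drop tokens containing digits.
#' @param lowercase fold tokens to lower case.
#' @param min_df drop features occurring in fewer documents (default 2).
#' @return a `vaem_vectorizer_config` list.
#' @export
vectorizer_config <- function(weighting = c("counts", "tfidf"),
                              ngram_range = c(1, 1),
                              remove_stopwords = FALSE,
                              remove_numbers = TRUE,
                              lowercase = TRUE,
                              min_df = 2) {
  weighting <- match.arg(weighting)
  stopifnot(length(ngram_range) == 2, ngram_range[1] >= 1,
            ngram_range[1] <= ngram_range[2], ngram_range[2] <= 3)
  structure(list(weighting = weighting,
                 ngram_range = as.integer(ngram_range),
                 remove_stopwords = isTRUE(remove_stopwords),
                 remove_numbers = isTRUE(remove_numbers),
                 lowercase = isTRUE(lowercase),
                 min_df = as.integer(min_df)),
            class = "vaem_vectorizer_config")
}

doc_features <- function(tokens, cfg) {
  lapply(tokens, function(t) {
    if (cfg$lowercase) t <- tolower(t)
    if (cfg$remove_numbers) t <- t[!grepl("[0-9]", t)]
    if (cfg$remove_stopwords) t <- t[!(t %in% .stopwords)]
    n <- length(t)
    feats <- character(0)
    for (g in seq(cfg$ngram_range[1], cfg$ngram_range[2])) {
      if (n >= g) {
        if (g == 1) {
          feats <- c(feats, t)
        } else {
          idx <- seq_len(n - g + 1)
          gram <- t[idx]
          for (o in seq_len(g - 1)) gram <- paste(gram, t[idx + o])
          feats <- c(feats, gram)
        }
      }
    }
    feats
  })
}

features_to_dtm <- function(feats, vocab) {
  ii <- jj <- integer(0)
  xx <- numeric(0)
  hit <- lapply(feats, function(f) {
    m <- match(f, vocab)
    m[!is.na(m)]
  })
  lens <- lengths(hit)
  ii <- rep.int(seq_along(feats), lens)
  jj <- unlist(hit, use.names = FALSE)
  Matrix::sparseMatrix(i = ii, j = jj, x = rep(1, length(ii)),
                       dims = c(length(feats), length(vocab)),
                       dimnames = list(NULL, vocab))
}

#' Fit a bag-of-words vectorizer
#'
#' Learns the feature vocabulary (and idf weights in tf-idf mode) from a
#' tokenized corpus.  Apply with [vectorize()].
#'
#' @param corpus list of token vectors.
#' @param cfg a [vectorizer_config()].
#' @return a `vaem_vectorizer` holding `vocab`, `idf` (or `NULL`) and `cfg`.
#' @export
fit_vectorizer <- function(corpus, cfg = vectorizer_config()) {
  stopifnot(is.list(corpus), length(corpus) > 0)
  feats <- doc_features(corpus, cfg)
  df <- table(unlist(lapply(feats, unique), use.names = FALSE))
  vocab <- sort(names(df)[df >= cfg$min_df])
  if (length(vocab) == 0) stop("empty vocabulary under this configuration")
  idf <- NULL
  if (cfg$weighting == "tfidf") {
    n <- length(corpus)
    dfv <- as.numeric(df[vocab])
    idf <- log((1 + n) / (1 + dfv)) + 1
    names(idf) <- vocab
  }
  structure(list(vocab = vocab, idf = idf, cfg = cfg),
            class = "vaem_vectorizer")
}

#' Vectorize a tokenized corpus into a sparse document-term matrix
#'
#' @param vec a fitted `vaem_vectorizer`.
#' @param corpus list of token vectors.
#' @return a `dgCMatrix`, rows aligned with documents, columns with the
#'   fitted vocabulary; tf-idf weighted and l2 row-normalized when the
#'   vectorizer was configured so.
#' @export
vectorize <- function(vec, corpus) {
  stopifnot(inherits(vec, "vaem_vectorizer"))
  feats <- doc_features(corpus, vec$cfg)
  # counts: accumulate duplicate (i,j) entries
  X <- features_to_dtm(feats, vec$vocab)
  if (!is.null(vec$idf)) {
    X <- X %*% Matrix::Diagonal(x = vec$idf)
    colnames(X) <- vec$vocab
    rn <- sqrt(Matrix::rowSums(X^2))
    rn[rn == 0] <- 1
    X <- Matrix::Diagonal(x = 1 / rn) %*% X
    colnames(X) <- vec$vocab
  }
  methods::as(X, "CsparseMatrix")
}
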