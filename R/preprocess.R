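#' Text normalization for short social-media posts
#'
#' Applies the cleaning rules used throughout the pipeline, in a fixed
#' order chosen so that each rule still sees the markup it needs:
#' URL removal, then \verb{@}-mention removal, lowercasing, `#` stripping
#' (the tag word itself is kept -- search keywords frequently occur only in
#' hashtag form), punctuation removal, digit removal, and whitespace
#' collapse.  Text is NFKC-folded first; emoji and other non-Latin symbols
#' fall to the punctuation rule.  The result matches `[a-z ]*`.
#'
#' @param text character vector of raw post text.
#' @param keep_hashtag_words keep the word after a `#` (default) or drop the
#'   whole tag token.
#' @return character vector of normalized text (possibly empty strings;
#'   callers filter those).
#' @export
#' @examples
#' normalize_text("Aw wtf my poor arm is dead af from my flu shot.")
normalize_text <- function(text, keep_hashtag_words = TRUE) {
  if (!is.character(text)) stop("`text` must be a character vector")
  x <- stringi::stri_trans_nfkc(text)
  x <- stringi::stri_replace_all_regex(x, "(https?://\\S+|www\\.\\S+)", " ")
  x <- stringi::stri_replace_all_regex(x, "@\\w+", " ")
  x <- stringi::stri_trans_tolower(x)
  if (keep_hashtag_words) {
    x <- stringi::stri_replace_all_fixed(x, "#", " ")
  } else {
    x <- stringi::stri_replace_all_regex(x, "#\\w+", " ")
  }
  x <- stringi::stri_replace_all_regex(x, "[^a-z0-9 ]", " ")
  x <- stringi::stri_replace_all_regex(x, "[0-9]", "")
  x <- stringi::stri_replace_all_regex(x, " +", " ")
  stringi::stri_trim_both(x)
}

#' Whitespace tokenizer
#'
#' @param norm_text character vector of normalized text.
#' @return list of character token vectors (length-0 for empty strings).
#' @export
tokenize <- function(norm_text) {
  out <- stringi::stri_split_regex(norm_text, " +", omit_empty = TRUE)
  lapply(out, function(t) if (length(t) == 1 && !nzchar(t)) character(0) else t)
}

#' Remove duplicate posts by id or text
#'
#' First occurrence wins, in input order.  A post is a duplicate if its id
#' *or* its exact text has occurred earlier in the input.
#'
#' @param posts data.frame with `id` and `text` columns.
#' @return the de-duplicated data.frame, original order preserved.
#' @export
deduplicate <- function(posts) {
  stopifnot(is.data.frame(posts), all(c("id", "text") %in% names(posts)))
  keep <- !duplicated(posts$id) & !duplicated(posts$text)
  posts[keep, , drop = FALSE]
}

#' Drop posts with too few tokens
#'
#' @param posts data.frame carrying a `tokens` list-column.
#' @param min_words minimum token count to retain (strictly shorter posts
#'   are removed); default 5.
#' @return filtered data.frame, order preserved.
#' @export
filter_short <- function(posts, min_words = 5) {
  stopifnot(min_words >= 1, "tokens" %in% names(posts))
  n <- lengths(posts$tokens)
  posts[n >= min_words, , drop = FALSE]
}

#' Clean a corpus of raw posts
#'
#' Full preprocessing: normalize, deduplicate (on raw id/text), tokenize,
#' drop short posts, and optionally merge collocations into n-gram tokens.
#'
#' @param posts data.frame of raw posts (see [read_posts()]).
#' @param min_words minimum tokens to retain a post.
#' @param keep_hashtag_words see [normalize_text()].
#' @param phrases logical; build n-gram tokens with [build_phrases()].
#' @param phrase_min_count,phrase_threshold,phrase_max_n collocation
#'   parameters passed to [build_phrases()].
#' @return data.frame of cleaned posts: `id`, `norm_text`, `tokens`
#'   (list-column), `ngram_tokens` (list-column), `label`.
#' @export
clean_posts <- function(posts, min_words = 5, keep_hashtag_words = TRUE,
                        phrases = TRUE, phrase_min_count = 5,
                        phrase_threshold = 10, phrase_max_n = 3) {
  posts <- deduplicate(posts)
  norm <- normalize_text(posts$text, keep_hashtag_words = keep_hashtag_words)
  toks <- tokenize(norm)
  out <- data.frame(id = posts$id, norm_text = norm, stringsAsFactors = FALSE)
  out$tokens <- toks
  out$label <- posts$label %||% rep("UNLABELED", nrow(posts))
  if ("subject_id" %in% names(posts)) out$subject_id <- posts$subject_id
  out <- filter_short(out, min_words = min_words)
  out$ngram_tokens <- if (phrases && nrow(out) > 0) {
    build_phrases(out$tokens, max_n = phrase_max_n,
                  min_count = phrase_min_count, threshold = phrase_threshold)
  } else {
    out$tokens
  }
  rownames(out) <- NULL
  out
}
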