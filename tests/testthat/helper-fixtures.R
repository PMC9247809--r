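# Small corpora built in code, shared across test files.

toy_posts <- function() {
  data.frame(
    id = as.character(1:6),
    text = c(
      "Aw wtf my poor arm is dead af from my flu shot.",
      "Got my #flushot from @clinic123 http://t.co/x — ouch 2x!",
      "Urgent vaccination plea after measles outbreak in West Yorkshire.",
      "flu shot flu shot flu shot again and again",
      "short one",
      "Researchers are developing a personalized vaccine for ovarian cancer."
    ),
    stringsAsFactors = FALSE
  )
}

# a tiny three-subject corpus with disjoint vocabularies, for topic tests
three_subject_tokens <- function(n_per = 40, len = 12, seed = 42) {
  vocabs <- list(paste0("alpha", 1:15), paste0("beta", 1:15),
                 paste0("gamma", 1:15))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  subj <- rep(1:3, each = n_per)
  docs <- lapply(subj, function(s) sample(vocabs[[s]], len, replace = TRUE))
  list(docs = docs, subject = subj)
}

# cached mid-size synthetic corpus for filter/classify tests
small_corpus_env <- new.env()
small_synthetic <- function() {
  if (is.null(small_corpus_env$cl)) {
    co <- generate_corpus(generator_config(n_posts = 8000, seed = 11))
    small_corpus_env$raw <- co
    small_corpus_env$cl <- clean_posts(co)
  }
  list(raw = small_corpus_env$raw, cl = small_corpus_env$cl)
}

# brute-force confusion-matrix scorer, independent of the package's path
oracle_prf <- function(pred, truth) {
  tp <- sum(pred & truth); fp <- sum(pred & !truth); fn <- sum(!pred & truth)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  list(precision = p, recall = r, f1 = f)
}
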