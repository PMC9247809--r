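test_that("normalize_text applies each removal rule in order", {
  expect_identical(
    normalize_text("Aw wtf my poor arm is dead af from my flu shot."),
    "aw wtf my poor arm is dead af from my flu shot")
  expect_identical(
    normalize_text("Got my #flushot from @clinic123 http://t.co/x — ouch 2x!"),
    "got my flushot from ouch x")
  expect_identical(normalize_text(""), "")
  # hashtag word kept by default, whole tag dropped on request
  expect_identical(normalize_text("#flushot hurts"), "flushot hurts")
  expect_identical(normalize_text("#flushot hurts", keep_hashtag_words = FALSE),
                   "hurts")
  expect_error(normalize_text(42), "character")
})

test_that("normalization is idempotent and closed over [a-z ]", {
  samples <- c(
    "MiXeD CaSe with 123 numbers!", "@a @b #c http://x.co/y z",
    "emoji \U0001F489 and symébols éüß",
    "  spaced   out\ttabs\nnewlines  ",
    "full-width ａｂｃ digits １２")
  for (s in samples) {
    once <- normalize_text(s)
    expect_identical(normalize_text(once), once)
    expect_match(once, "^[a-z ]*$")
  }
})

test_that("deduplicate drops id or text repeats, first occurrence wins", {
  posts <- data.frame(id = c("1", "1", "2", "3"),
                      text = c("a", "b", "a", "c"),
                      stringsAsFactors = FALSE)
  out <- deduplicate(posts)
  expect_identical(out$id, c("1", "3"))
  expect_identical(out$text, c("a", "c"))
  expect_identical(nrow(deduplicate(posts[0, ])), 0L)
  distinct <- data.frame(id = as.character(1:5), text = letters[1:5],
                         stringsAsFactors = FALSE)
  expect_identical(deduplicate(distinct), distinct)
})

test_that("deduplicate matches a brute-force pairwise oracle on random input", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(2:30, 1)
    posts <- data.frame(id = as.character(sample(1:12, n, replace = TRUE)),
                        text = sample(letters[1:8], n, replace = TRUE),
                        stringsAsFactors = FALSE)
    keep <- vapply(seq_len(n), function(i) {
      if (i == 1) return(TRUE)
      !(posts$id[i] %in% posts$id[1:(i - 1)] ||
          posts$text[i] %in% posts$text[1:(i - 1)])
    }, logical(1))
    out <- deduplicate(posts)
    expect_identical(out, posts[keep, , drop = FALSE])
    expect_false(any(duplicated(out$id)))
    expect_false(any(duplicated(out$text)))
  }
})

test_that("filter_short is a strict <min_words cutoff, idempotent, monotone", {
  df <- data.frame(id = as.character(1:3), stringsAsFactors = FALSE)
  df$tokens <- list(c("flu", "shot", "hurt"),
                    c("a", "b", "c", "d", "e"),
                    c("a", "b", "c", "d", "e", "f"))
  out <- filter_short(df, min_words = 5)
  expect_identical(out$id, c("2", "3"))  # exactly 5 tokens is retained
  expect_identical(filter_short(out, 5), out)
  expect_identical(filter_short(df, 1), df)
  # monotone: larger min_words yields a subset
  for (m in 1:7) {
    a <- filter_short(df, m)$id
    b <- filter_short(df, m + 1)$id
    expect_true(all(b %in% a))
  }
})

test_that("clean_posts retains structure and drops short/duplicate posts", {
  cl <- clean_posts(toy_posts(), phrases = FALSE)
  expect_true(all(c("id", "norm_text", "tokens", "ngram_tokens", "label")
                  %in% names(cl)))
  expect_false("5" %in% cl$id)  # "short one" has <5 words
  expect_true(all(lengths(cl$tokens) >= 5))
  expect_true(all(grepl("^[a-z ]*$", cl$norm_text)))
})

test_that("build_phrases merges frequent collocations and respects edges", {
  # "flu shot" recurs in every document; all other pairs are singletons
  docs <- list(c("got", "flu", "shot", "today"),
               c("my", "flu", "shot", "arm"),
               c("flu", "shot", "was", "fine"),
               c("that", "flu", "shot", "again"),
               c("ouch", "flu", "shot", "sore"))
  out <- build_phrases(docs, max_n = 2, min_count = 2, threshold = 1)
  expect_true(all(vapply(out, function(t) "flu_shot" %in% t, logical(1))))
  expect_false(any(vapply(out, function(t) "flu" %in% t, logical(1))))
  # +Inf threshold and single-token docs are identity transforms
  expect_identical(build_phrases(docs, threshold = Inf), docs)
  singles <- list("a", "b", "a")
  expect_identical(build_phrases(singles, min_count = 0, threshold = 0.1),
                   singles)
  # phrase tokens map back to contiguous runs: unsplitting restores input
  restored <- lapply(out, function(t) unlist(strsplit(t, "_", fixed = TRUE)))
  expect_identical(restored, docs)
})

test_that("jsonl and csv round-trips preserve posts", {
  posts <- toy_posts()
  posts$label <- c("VAEM", "VAEM", "NON_VAEM", "UNLABELED", "UNLABELED",
                   "NON_VAEM")
  tmp <- tempfile(fileext = ".jsonl")
  write_jsonl(posts, tmp)
  back <- read_posts(tmp)
  expect_identical(back$id, posts$id)
  expect_identical(back$text, posts$text)
  expect_identical(back$label, posts$label)
  tmpc <- tempfile(fileext = ".csv")
  utils::write.csv(posts[, c("id", "text", "label")], tmpc, row.names = FALSE)
  backc <- read_posts(tmpc)
  expect_identical(backc$text, posts$text)
})
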