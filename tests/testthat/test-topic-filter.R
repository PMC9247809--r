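test_that("concentration score is exact on hand-built assignments", {
  # perfect separation: all positives in topic 3, nothing else there
  dom <- c(rep(3, 10), rep(c(1, 2, 4), 10))
  y <- c(rep(TRUE, 10), rep(FALSE, 30))
  s <- concentration_score(dom, y)
  expect_identical(s$best_topic_set, 3L)
  expect_equal(s$f1, 1)
  # TP=8 FP=2 FN=2 in topic 1
  dom2 <- c(rep(1, 10), rep(2, 10))
  y2 <- c(rep(TRUE, 8), FALSE, FALSE, TRUE, TRUE, rep(FALSE, 8))
  s2 <- concentration_score(dom2, y2, max_topics = 1)
  expect_equal(s2$precision, 0.8)
  expect_equal(s2$recall, 0.8)
  expect_equal(s2$f1, 0.8)
  expect_error(concentration_score(dom, rep(FALSE, 40)), "positive")
  expect_error(concentration_score(dom, rep(TRUE, 40)), "negative")
})

test_that("greedy topic-set search never loses to the best single topic and
           tracks the exhaustive-subset oracle closely", {
  set.seed(123)
  gaps <- numeric(0)
  for (rep in 1:30) {
    K <- sample(3:6, 1)
    n <- 60
    dom <- sample.int(K, n, replace = TRUE)
    y <- stats::runif(n) < 0.3
    if (!any(y) || all(y)) next
    s <- concentration_score(dom, y, max_topics = K)
    # oracle: enumerate all non-empty subsets
    best <- 0
    for (mask in 1:(2^K - 1)) {
      set <- which(bitwAnd(mask, 2^(seq_len(K) - 1)) > 0)
      o <- oracle_prf(dom %in% set, y)
      best <- max(best, o$f1)
    }
    singles <- max(vapply(1:K, function(t) oracle_prf(dom == t, y)$f1,
                          numeric(1)))
    expect_gte(s$f1 + 1e-12, singles)
    # greedy matches the independent oracle for its own chosen set
    o_set <- oracle_prf(dom %in% s$best_topic_set, y)
    expect_equal(s$f1, o_set$f1)
    gaps <- c(gaps, best - s$f1)
  }
  # greedy is near-exhaustive on these small problems
  expect_lt(mean(gaps), 0.02)
})

test_that("model selection prefers the model that separates the labels", {
  ts <- three_subject_tokens(n_per = 50)
  y <- ts$subject == 1  # treat subject 1 as the positive label
  sel <- select_best_model(ts$docs, y,
                           grid = data.frame(n_topics = c(2, 3), seed = 1),
                           n_iter = 150, min_doc_count = 2)
  expect_identical(nrow(sel$log), 2L)
  expect_equal(sel$score$f1, max(sel$log$f1))
  expect_gte(sel$score$f1, 0.9)
  # single-point grid returns that model; selection is deterministic
  sel1 <- select_best_model(ts$docs, y,
                            grid = data.frame(n_topics = 3, seed = 1),
                            n_iter = 150, min_doc_count = 2)
  expect_identical(sel1$model$n_topics, 3L)
  sel2 <- select_best_model(ts$docs, y,
                            grid = data.frame(n_topics = c(2, 3), seed = 1),
                            n_iter = 150, min_doc_count = 2)
  expect_identical(sel$score$best_topic_set, sel2$score$best_topic_set)
  expect_identical(sel$log, sel2$log)
})

test_that("apply_filter partitions input and is monotone in the topic set", {
  ts <- three_subject_tokens(n_per = 40)
  m <- fit_topic_model(ts$docs, 3, seed = 4, n_iter = 150, min_doc_count = 2)
  ids <- paste0("d", seq_along(ts$docs))
  r1 <- apply_filter(m, 1L, ids = ids)
  expect_setequal(c(r1$retained, r1$discarded), ids)
  expect_length(intersect(r1$retained, r1$discarded), 0)
  # enlarging the set never shrinks the retained set
  prev <- character(0)
  for (k in 1:3) {
    rk <- apply_filter(m, seq_len(k), ids = ids)
    expect_true(all(prev %in% rk$retained))
    prev <- rk$retained
  }
  expect_setequal(apply_filter(m, 1:3, ids = ids)$retained, ids)
})

test_that("stage-2 refinement purifies at some recall cost on synthetic data", {
  sc <- small_synthetic()
  cl <- sc$cl
  lab_idx <- seq_len(2000)
  sel <- select_best_model(cl$ngram_tokens, cl$label[lab_idx],
                           labeled_docs = lab_idx,
                           grid = data.frame(n_topics = 13, seed = 1),
                           n_iter = 200)
  r1 <- apply_filter(sel$model, sel$score, ids = seq_len(nrow(cl)))
  v_all <- sum(cl$label == "VAEM")
  v1 <- sum(cl$label[r1$retained] == "VAEM")
  expect_gte(v1 / v_all, 0.9)                       # filtering keeps the VAEM
  expect_lte(length(r1$retained) / nrow(cl), 0.25)  # and discards the bulk
  r2 <- stage2_refine(cl$ngram_tokens[r1$retained], cl$label[r1$retained],
                      n_topics = 10, seed = 2, top_k = 3, ids = r1$retained,
                      n_iter = 150, min_doc_count = 3)
  expect_true(all(r2$retained %in% r1$retained))
  expect_length(unique(r2$topic_set), 3)
  v2 <- sum(cl$label[r2$retained] == "VAEM")
  purity1 <- v1 / length(r1$retained)
  purity2 <- v2 / length(r2$retained)
  expect_gt(purity2, purity1)   # purer...
  expect_lt(v2 / v_all, 1)      # ...at the expense of some VAEM
  # threshold mode at 0 is the identity on the stage-1 stream
  r0 <- stage2_refine(cl$ngram_tokens[r1$retained], cl$label[r1$retained],
                      n_topics = 5, seed = 2, top_k = NULL,
                      ratio_threshold = 0, ids = r1$retained,
                      n_iter = 50, min_doc_count = 3)
  expect_setequal(r0$retained, r1$retained)
})

test_that("concentration F1 equals the induced hard predictor's F1 on a
           fully labeled corpus", {
  set.seed(55)
  for (rep in 1:10) {
    K <- sample(4:8, 1)
    dom <- sample.int(K, 200, replace = TRUE)
    y <- stats::runif(200) < 0.2
    if (!any(y) || all(y)) next
    s <- concentration_score(dom, y, max_topics = 3)
    o <- oracle_prf(dom %in% s$best_topic_set, y)
    expect_equal(s$precision, o$precision)
    expect_equal(s$recall, o$recall)
    expect_equal(s$f1, o$f1)
  }
})
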