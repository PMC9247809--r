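test_that("count vectorization matches hand counts", {
  docs <- list(c("flu", "shot"), c("flu", "shot", "sore"))
  vec <- fit_vectorizer(docs, vectorizer_config(min_df = 1))
  X <- vectorize(vec, docs)
  expect_identical(colnames(X), c("flu", "shot", "sore"))
  expect_equal(as.matrix(X), matrix(c(1, 1, 1, 1, 0, 1), 2,
                                    dimnames = list(NULL, colnames(X))))
  # repeated tokens accumulate
  X2 <- vectorize(vec, list(c("flu", "flu", "flu")))
  expect_equal(as.numeric(X2[1, ]), c(3, 0, 0))
})

test_that("vectorizer config switches behave", {
  docs <- list(c("x", "2", "3", "x"), c("x", "y", "2"))
  vec <- fit_vectorizer(docs, vectorizer_config(min_df = 1))
  expect_false(any(grepl("[0-9]", colnames(vectorize(vec, docs)))))
  vec2 <- fit_vectorizer(docs, vectorizer_config(min_df = 1,
                                                 remove_numbers = FALSE))
  expect_true("2" %in% vec2$vocab)
  # stopwords
  docs3 <- list(c("the", "shot", "was", "fine"), c("the", "shot", "sore"))
  vec3 <- fit_vectorizer(docs3, vectorizer_config(min_df = 1,
                                                  remove_stopwords = TRUE))
  expect_false(any(c("the", "was") %in% vec3$vocab))
  # bigram features
  vec4 <- fit_vectorizer(docs3, vectorizer_config(min_df = 2,
                                                  ngram_range = c(1, 2)))
  expect_true("the shot" %in% vec4$vocab)
  # tf-idf rows are unit-norm for non-empty docs
  vec5 <- fit_vectorizer(docs3, vectorizer_config(weighting = "tfidf",
                                                  min_df = 1))
  X5 <- vectorize(vec5, docs3)
  expect_equal(unname(sqrt(Matrix::rowSums(X5^2))), c(1, 1), tolerance = 1e-12)
  expect_error(fit_vectorizer(list(c("9", "8")), vectorizer_config()),
               "empty vocabulary")
  expect_error(vectorizer_config(ngram_range = c(2, 1)))
})

test_that("NBSVM log-count ratio matches the closed form on a toy corpus", {
  # vocab {flu, shot, sore}; doc1 (pos): flu shot sore; doc2 (neg): flu shot
  X <- Matrix::sparseMatrix(i = c(1, 1, 1, 2, 2), j = c(1, 2, 3, 1, 2),
                            x = 1, dims = c(2, 3))
  y <- c(TRUE, FALSE)
  r <- nbsvm_log_count_ratio(X, y, alpha = 1)
  p <- c(1, 1, 1) + 1; q <- c(1, 1, 0) + 1
  expect_equal(r, log((p / sum(p)) / (q / sum(q))), tolerance = 1e-12)
})

test_that("linear models separate a separable toy problem perfectly", {
  set.seed(8)
  pos <- lapply(1:40, function(i) c("my", "arm", "sore",
                                    sample(letters, 3)))
  neg <- lapply(1:40, function(i) c("news", "study", "launch",
                                    sample(letters, 3)))
  docs <- c(pos, neg)
  y <- rep(c("VAEM", "NON_VAEM"), each = 40)
  vec <- fit_vectorizer(docs, vectorizer_config(min_df = 1))
  X <- vectorize(vec, docs)
  for (sp in c("logreg_cv", "sgd", "linear_svc", "nbsvm",
               "multinomial_nb")) {
    clf <- train_classifier(sp, X, y, seed = 3)
    expect_identical(unname(predict(clf, X)), y)
  }
})

test_that("tree ensembles and boosting are seed-deterministic", {
  sc <- small_synthetic()
  cl <- sc$cl
  pool <- cl[cl$subject_id == 1 & cl$label %in% c("VAEM", "NON_VAEM"), ]
  vec <- fit_vectorizer(pool$tokens, vectorizer_config())
  X <- vectorize(vec, pool$tokens)
  for (sp in c("random_forest", "extra_trees", "xgboost")) {
    a <- train_classifier(sp, X, pool$label, seed = 4)
    b <- train_classifier(sp, X, pool$label, seed = 4)
    expect_identical(predict(a, X), predict(b, X))
  }
  expect_error(train_classifier("nope", X, pool$label), "unknown")
  expect_error(train_classifier("sgd", X, rep("VAEM", nrow(X))), "both classes")
})

test_that("ensemble voting equals brute-force majority on all 2^5 patterns", {
  patterns <- as.matrix(expand.grid(rep(list(0:1), 5)))
  out <- ensemble_vote(patterns)
  brute <- apply(patterns, 1, function(v) as.integer(sum(v) >= 3))
  expect_identical(out, unname(brute))
  # label coding and basic cases
  expect_identical(ensemble_vote(matrix(c(1, 1, 0, 0, 1), 1)), 1L)
  expect_identical(ensemble_vote(matrix(c(0, 0, 0, 0, 1), 1)), 0L)
  labs <- matrix(rep(c("VAEM", "NON_VAEM", "VAEM"), each = 2), nrow = 2)
  expect_identical(ensemble_vote(labs), c("VAEM", "VAEM"))
  expect_error(ensemble_vote(patterns[, 1:4]), "odd")
})

test_that("evaluation identities hold for arbitrary confusion counts", {
  expect_equal(eval_report(90, 0, 0)$f1, 1)
  expect_equal(eval_report(8, 2, 2)$f1, 0.8)
  r0 <- evaluate(rep("NON_VAEM", 10),
                 rep(c("VAEM", "NON_VAEM"), 5))
  expect_identical(r0$f1, 0)  # degenerate all-negative predictor, not NaN
  set.seed(20)
  for (i in 1:100) {
    tp <- sample(0:50, 1); fp <- sample(0:50, 1)
    fn <- sample(0:50, 1); tn <- sample(0:50, 1)
    r <- eval_report(tp, fp, fn, tn)
    if (tp + fp > 0) expect_equal(r$precision, tp / (tp + fp))
    if (tp + fn > 0) expect_equal(r$recall, tp / (tp + fn))
    if (r$precision + r$recall > 0) {
      expect_equal(r$f1, 2 * r$precision * r$recall /
                     (r$precision + r$recall))
    } else {
      expect_identical(r$f1, 0)
    }
  }
})

test_that("balanced dataset construction balances and reproduces", {
  pool <- data.frame(id = as.character(1:1000),
                     label = rep(c("VAEM", "NON_VAEM"), c(100, 900)),
                     stringsAsFactors = FALSE)
  sp <- make_balanced_set(pool, seed = 6, holdout_frac = 0)
  tv <- rbind(sp$train, sp$validation)
  expect_identical(sum(tv$label == "VAEM"), 100L)
  expect_identical(sum(tv$label == "NON_VAEM"), 100L)
  expect_identical(nrow(sp$train), 150L)  # 75:25 of the balanced pool
  expect_identical(nrow(sp$validation), 50L)
  # holdout is carved before balancing and keeps the pool imbalance
  sp2 <- make_balanced_set(pool, seed = 6, holdout_frac = 0.2)
  expect_identical(nrow(sp2$test), 200L)
  expect_equal(mean(sp2$test$label == "VAEM"), 0.1, tolerance = 0.01)
  expect_length(intersect(sp2$test$id, c(sp2$train$id, sp2$validation$id)), 0)
  sp3 <- make_balanced_set(pool, seed = 6, holdout_frac = 0.2)
  expect_identical(sp2$train$id, sp3$train$id)
  expect_error(make_balanced_set(pool[1:100, ], seed = 1), "both classes")
})

test_that("grid search ranks consistently and is re-evaluable", {
  sc <- small_synthetic()
  cl <- sc$cl
  pool <- cl[cl$subject_id == 1 & cl$label %in% c("VAEM", "NON_VAEM"), ]
  sp <- make_balanced_set(pool, seed = 2, holdout_frac = 0)
  grid <- list(vectorizer_config(),
               vectorizer_config(weighting = "tfidf", ngram_range = c(1, 2)))
  log <- grid_search(sp$train$tokens, sp$train$label,
                     sp$validation$tokens, sp$validation$label,
                     vec_grid = grid, specs = c("nbsvm", "multinomial_nb"),
                     seed = 5)
  expect_identical(nrow(log), 4L)
  expect_identical(log$rank, 1:4)
  expect_true(all(diff(log$f1) <= 0))
  # recompute the top row independently
  top <- log[1, ]
  vec <- fit_vectorizer(sp$train$tokens, grid[[top$vec_cfg]])
  clf <- train_classifier(top$spec, vectorize(vec, sp$train$tokens),
                          sp$train$label, seed = 5)
  rep <- evaluate(predict(clf, vectorize(vec, sp$validation$tokens)),
                  sp$validation$label)
  expect_equal(rep$f1, top$f1)
  # singleton grid gives one row; ranking deterministic across calls
  one <- grid_search(sp$train$tokens, sp$train$label,
                     sp$validation$tokens, sp$validation$label,
                     vec_grid = grid[1], specs = "multinomial_nb", seed = 5)
  expect_identical(nrow(one), 1L)
  log2 <- grid_search(sp$train$tokens, sp$train$label,
                      sp$validation$tokens, sp$validation$label,
                      vec_grid = grid, specs = c("nbsvm", "multinomial_nb"),
                      seed = 5)
  expect_identical(log, log2)
})

test_that("more training data does not hurt the linear models", {
  sc <- small_synthetic()
  cl <- sc$cl
  pool <- cl[cl$subject_id == 1 & cl$label %in% c("VAEM", "NON_VAEM"), ]
  sp <- make_balanced_set(pool, seed = 9, holdout_frac = 0.25)
  vec <- fit_vectorizer(sp$train$tokens, vectorizer_config())
  xtr <- vectorize(vec, sp$train$tokens)
  xte <- vectorize(vec, sp$test$tokens)
  sub <- with(sp, seq_len(max(20, floor(nrow(train) * 0.2))))
  for (spn in c("logreg_cv", "nbsvm")) {
    f_full <- evaluate(predict(train_classifier(spn, xtr, sp$train$label,
                                                seed = 3), xte),
                       sp$test$label)$f1
    f_sub <- evaluate(predict(train_classifier(spn, xtr[sub, ],
                                               sp$train$label[sub],
                                               seed = 3), xte),
                      sp$test$label)$f1
    expect_gte(f_full + 0.02, f_sub)  # allow sampling jitter at this scale
  }
})
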