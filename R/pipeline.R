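#' Configuration for a full two-phase pipeline run
#'
#' A single config drives the whole workflow: generate (or ingest) posts,
#' clean, fit/score/select topic models on a training subsample, filter the
#' full stream, refine with a second topic-model stage, build balanced
#' classification datasets, train and evaluate classifiers, and account for
#' the funnel.  Every random step draws its own seed from `seed`, so two
#' runs with the same config are bit-identical.
#'
#' @param generator a [generator_config()] used when `posts` is `NULL`.
#' @param posts optional data.frame of raw posts (see [read_posts()]).
#' @param min_words cleaning threshold, see [clean_posts()].
#' @param topic_grid data.frame (`n_topics`, `seed`) of stage-1 candidates.
#' @param lda_iter Gibbs sweeps per candidate model (default 400).
#' @param fit_subsample documents used to fit candidate models; the frozen
#'   winner is then applied to the whole stream (default 12000).
#' @param n_labeled labeled posts used for concentration scoring
#'   (default 2000).
#' @param max_topics stage-1 topic-set size cap (default 3).
#' @param stage2 run the second topic-model stage (default `TRUE`).
#' @param stage2_n_topics stage-2 refit size (default 6).
#' @param stage2_top_k keep the k highest VAEM-ratio topics; `NULL`
#'   (default) uses the ratio threshold instead, which refines mildly no
#'   matter how many topics the positives occupy.
#' @param stage2_ratio_threshold retain stage-2 topics whose labeled VAEM
#'   ratio reaches this value (default 0.3).
#' @param classifiers classifier specs to train (see [train_classifier()]).
#' @param vectorizer a [vectorizer_config()] for classification.
#' @param holdout_frac imbalanced holdout test fraction (default 0.1).
#' @param mode `"train"` or `"apply"` (apply requires `artifacts`).
#' @param artifacts a `$artifacts` element from a previous train-mode
#'   report.
#' @param seed master seed.
#' @return a `vaem_pipeline_config` list.
#' @export
pipeline_config <- function(generator = generator_config(), posts = NULL,
                            min_words = 5,
                            topic_grid = expand.grid(
                              n_topics = c(8, 10, 13, 16, 20), seed = 1:3),
                            lda_iter = 400, fit_subsample = 12000,
                            n_labeled = 2000, max_topics = 3,
                            stage2 = TRUE, stage2_n_topics = 6,
                            stage2_top_k = NULL,
                            stage2_ratio_threshold = 0.3,
                            classifiers = c("nbsvm", "logreg_cv", "sgd",
                                            "linear_svc", "random_forest",
                                            "multinomial_nb", "xgboost"),
                            vectorizer = vectorizer_config(
                              weighting = "tfidf", ngram_range = c(1, 2)),
                            holdout_frac = 0.1,
                            mode = c("train", "apply"), artifacts = NULL,
                            seed = 7) {
  mode <- match.arg(mode)
  if (mode == "apply" && is.null(artifacts)) {
    stop("apply mode requires trained artifacts")
  }
  structure(list(generator = generator, posts = posts, min_words = min_words,
                 topic_grid = topic_grid, lda_iter = lda_iter,
                 fit_subsample = fit_subsample, n_labeled = n_labeled,
                 max_topics = max_topics, stage2 = isTRUE(stage2),
                 stage2_n_topics = stage2_n_topics,
                 stage2_top_k = stage2_top_k,
                 stage2_ratio_threshold = stage2_ratio_threshold,
                 classifiers = classifiers,
                 vectorizer = vectorizer, holdout_frac = holdout_frac,
                 mode = mode, artifacts = artifacts,
                 seed = as.integer(seed)),
            class = "vaem_pipeline_config")
}

#' Run the two-phase VAEM-mining pipeline
#'
#' Executes the configured stage sequence and returns a run report with
#' per-stage counts (a funnel ledger of its own run), topic-model scores,
#' classifier evaluations, an end-to-end effectiveness estimate, the
#' trained artifacts, and a provenance record (config hash, seed, package
#' version).  Stage failures propagate with the stage name prefixed.
#'
#' @param cfg a [pipeline_config()].
#' @return a `vaem_run_report` list; see Details in the package vignette.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "vaem_pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  report <- list(provenance = list(
    config_hash = config_hash(cfg[setdiff(names(cfg), c("posts", "artifacts"))]),
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("vaemmine")),
    mode = cfg$mode))

  posts <- stage("generate", {
    if (!is.null(cfg$posts)) as_posts(cfg$posts) else generate_corpus(cfg$generator)
  })
  n0 <- nrow(posts)

  cleaned <- stage("clean", clean_posts(posts, min_words = cfg$min_words))
  n1 <- nrow(cleaned)

  if (cfg$mode == "apply") {
    art <- cfg$artifacts
    res1 <- if (n1 > 0) {
      stage("filter", apply_filter(art$stage1_model, art$stage1_topic_set,
                                   corpus = cleaned$ngram_tokens,
                                   ids = seq_len(n1),
                                   infer_seed = derive_seed(cfg$seed, "infer")))
    } else {
      structure(list(retained = integer(0), discarded = integer(0),
                     stage = 1L, topic_set = art$stage1_topic_set,
                     dominant = integer(0)), class = "vaem_filter_result")
    }
    keep <- res1$retained
    pred <- if (length(keep) > 0) {
      x <- vectorize(art$vectorizer, cleaned$tokens[keep])
      predict(art$classifier, x)
    } else {
      character(0)
    }
    report$funnel <- build_funnel(max(n0, 1),
                                  c(cleaning = n1 - n0,
                                    stage1 = length(keep) - n1))
    report$retained_ids <- cleaned$id[keep]
    report$predictions <- data.frame(id = cleaned$id[keep], label = pred,
                                     stringsAsFactors = FALSE)
    class(report) <- "vaem_run_report"
    return(report)
  }

  # ---- stage 1: fit candidate topic models on a subsample, score by label
  # concentration over a small labeled sample, freeze the winner ----
  sel <- stage("topics", {
    sub <- with_seed(derive_seed(cfg$seed, "subsample"),
                     sort(sample.int(n1, min(cfg$fit_subsample, n1))))
    lab <- with_seed(derive_seed(cfg$seed, "labelset"),
                     sort(sample(seq_along(sub), min(cfg$n_labeled,
                                                     length(sub)))))
    labels <- cleaned$label[sub][lab]
    if (!any(labels == "VAEM")) {
      stop("labeled sample contains no VAEM; increase n_labeled")
    }
    s <- select_best_model(cleaned$ngram_tokens[sub], labels,
                           labeled_docs = lab, grid = cfg$topic_grid,
                           max_topics = cfg$max_topics, n_iter = cfg$lda_iter)
    s$fit_docs <- sub
    s
  })

  res1 <- stage("filter", {
    apply_filter(sel$model, sel$score, corpus = cleaned$ngram_tokens,
                 ids = seq_len(n1),
                 infer_seed = derive_seed(cfg$seed, "infer"))
  })
  keep1 <- res1$retained

  # ---- stage 2: refit on the retained stream, keep top-k VAEM-ratio
  # topics (the retained stream is labeled at this point) ----
  res2 <- NULL
  keep2 <- keep1
  if (cfg$stage2 && length(keep1) > 0) {
    res2 <- stage("stage2", {
      stage2_refine(cleaned$ngram_tokens[keep1], cleaned$label[keep1],
                    n_topics = cfg$stage2_n_topics,
                    seed = derive_seed(cfg$seed, "stage2"),
                    top_k = cfg$stage2_top_k,
                    ratio_threshold = cfg$stage2_ratio_threshold,
                    ids = keep1,
                    n_iter = min(cfg$lda_iter, 200), min_doc_count = 3)
    })
    keep2 <- res2$retained
  }

  # ---- classification datasets and training ----
  pool <- cleaned[keep2, , drop = FALSE]
  pool <- pool[pool$label %in% c("VAEM", "NON_VAEM"), , drop = FALSE]
  split <- stage("datasets", {
    make_balanced_set(pool, seed = derive_seed(cfg$seed, "datasets"),
                      holdout_frac = cfg$holdout_frac, name = "stage2-pool")
  })

  clf_log <- stage("train", {
    vec <- fit_vectorizer(split$train$tokens, cfg$vectorizer)
    xtr <- vectorize(vec, split$train$tokens)
    xva <- vectorize(vec, split$validation$tokens)
    xte <- vectorize(vec, split$test$tokens)
    rows <- list()
    fits <- list()
    for (sp in cfg$classifiers) {
      clf <- train_classifier(sp, xtr, split$train$label,
                              seed = derive_seed(cfg$seed, paste0("clf-", sp)))
      fits[[sp]] <- clf
      va <- evaluate(predict(clf, xva), split$validation$label,
                     classifier_id = sp, test_set = "validation")
      te <- evaluate(predict(clf, xte), split$test$label,
                     classifier_id = sp, test_set = "holdout")
      rows[[sp]] <- data.frame(spec = sp, valid_f1 = va$f1,
                               test_f1 = te$f1, test_precision = te$precision,
                               test_recall = te$recall,
                               stringsAsFactors = FALSE)
    }
    list(log = do.call(rbind, rows), fits = fits, vectorizer = vec,
         xte = xte)
  })
  log <- clf_log$log[order(-clf_log$log$valid_f1, clf_log$log$spec), ]
  rownames(log) <- NULL
  best_spec <- log$spec[1]
  best <- clf_log$fits[[best_spec]]
  best_report <- evaluate(predict(best, clf_log$xte), split$test$label,
                          classifier_id = best_spec, test_set = "holdout")

  # ---- accounting ----
  funnel <- build_funnel(n0, c(cleaning = n1 - n0,
                               stage1 = length(keep1) - n1,
                               stage2 = length(keep2) - length(keep1)))
  has_truth <- any(posts$label == "VAEM")
  metrics <- list(
    stage1_retention_pct = ratio_pct(length(keep1), n1),
    stage2_retention_pct = ratio_pct(length(keep2), n1))
  effectiveness <- NULL
  if (has_truth) {
    v_raw <- sum(posts$label == "VAEM")
    v_clean <- sum(cleaned$label == "VAEM")
    v1 <- sum(cleaned$label[keep1] == "VAEM")
    v2 <- sum(cleaned$label[keep2] == "VAEM")
    metrics$stage1_vaem_recall_pct <- ratio_pct(v1, v_clean)
    metrics$stage1_vaem_purity_pct <- ratio_pct(v1, max(length(keep1), 1))
    metrics$stage2_vaem_purity_pct <- ratio_pct(v2, max(length(keep2), 1))
    metrics$clean_vaem_prevalence_pct <- ratio_pct(v_clean, n1)
    effectiveness <- estimate_effectiveness(
      V = v2, N = length(keep2) - v2,
      r = max(best_report$recall, 1e-12),
      p = max(best_report$precision, 1e-12),
      c = max(v2 / v_raw, 1e-12), initial = n0)
  }

  report$funnel <- funnel
  report$topic_selection <- sel$log
  report$topic_score <- sel$score
  report$stage1 <- res1
  report$stage2 <- res2
  report$datasets <- split
  report$classifier_log <- log
  report$best_classifier <- best_spec
  report$best_report <- best_report
  report$metrics <- metrics
  report$effectiveness <- effectiveness
  report$artifacts <- list(stage1_model = sel$model,
                           stage1_topic_set = sel$score$best_topic_set,
                           stage2_model = res2$model,
                           stage2_topic_set = res2$topic_set,
                           vectorizer = clf_log$vectorizer,
                           classifier = best)
  class(report) <- "vaem_run_report"
  report
}

#' @export
print.vaem_run_report <- function(x, ...) {
  cat("two-phase VAEM-mining run (seed ", x$provenance$seed, ", config ",
      substr(x$provenance$config_hash, 1, 8), ")\n\n", sep = "")
  print(x$funnel)
  if (!is.null(x$topic_score)) { cat("\n"); print(x$topic_score) }
  if (!is.null(x$best_report)) {
    cat("\nbest classifier: ", x$best_classifier, "\n", sep = "")
    print(x$best_report)
  }
  if (!is.null(x$metrics)) {
    m <- x$metrics
    cat("\n")
    for (k in names(m)) cat(sprintf("  %s: %.2f\n", k, m[[k]]))
  }
  if (!is.null(x$effectiveness)) { cat("\n"); print(x$effectiveness) }
  invisible(x)
}

#' Persist / restore a topic model as a plain-text directory
#'
#' The topic-word matrix is written as dense tab-separated text and the
#' metadata (priors, seed, vocabulary) as JSON, so bundles survive any
#' text-only artifact store.  Training doc-topic proportions are not
#' persisted; unseen documents are inferred against the frozen model.
#'
#' @param model a `vaem_topic_model`.
#' @param dir directory to create/overwrite.
#' @return `dir` (for `save_topic_model`); a `vaem_topic_model` (for
#'   `load_topic_model`).
#' @export
save_topic_model <- function(model, dir) {
  stopifnot(inherits(model, "vaem_topic_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(model$phi, file.path(dir, "topic_word.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  meta <- list(n_topics = model$n_topics, vocab = model$vocab,
               alpha = model$alpha, beta = model$beta,
               n_iter = model$n_iter, seed = model$seed)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             file.path(dir, "metadata.json"))
  invisible(dir)
}

#' @rdname save_topic_model
#' @export
load_topic_model <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "metadata.json"))
  phi <- as.matrix(utils::read.table(file.path(dir, "topic_word.tsv"),
                                     sep = "\t"))
  dimnames(phi) <- list(NULL, meta$vocab)
  structure(list(n_topics = meta$n_topics, phi = phi,
                 theta = matrix(numeric(0), 0, meta$n_topics),
                 vocab = meta$vocab, alpha = meta$alpha, beta = meta$beta,
                 n_iter = meta$n_iter, seed = meta$seed),
            class = "vaem_topic_model")
}
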