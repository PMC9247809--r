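set_f1 <- function(dom, y, set) {
  pred <- dom %in% set
  tp <- sum(pred & y); fp <- sum(pred & !y); fn <- sum(!pred & y)
  positive_f1(tp, fp, fn)
}

#' Label-concentration score of a topic model
#'
#' Measures how strongly a topic model concentrates the positive (VAEM)
#' label into few topics: the predictor "document's dominant topic lies in
#' a topic set" is scored by positive-class precision/recall/F1 against a
#' small labeled sample.  The topic set is grown greedily -- best single
#' topic by F1, then add topics only while F1 strictly improves, up to
#' `max_topics` -- so a model scores well exactly when the positives sit in
#' one or very few topics.
#'
#' @param model a `vaem_topic_model`, or an integer vector of dominant
#'   topic assignments for the labeled documents.
#' @param labels character (`"VAEM"`/`"NON_VAEM"`) or logical labels.
#' @param docs when `model` is a fitted model: indices of the labeled
#'   documents among its training documents (default: all of them).
#' @param max_topics maximum size of the topic set (default 3).
#' @return a `vaem_concentration`: list with `best_topic_set` (integer,
#'   1-based), `precision`, `recall`, `f1`, `n_topics`, and the greedy
#'   `trace` (F1 after each accepted topic).
#' @export
concentration_score <- function(model, labels, docs = NULL, max_topics = 3) {
  if (inherits(model, "vaem_topic_model")) {
    dom_all <- dominant_topic(model)
    if (is.null(docs)) docs <- seq_along(dom_all)
    dom <- dom_all[docs]
    K <- model$n_topics
  } else {
    dom <- as.integer(model)
    K <- max(dom)
  }
  y <- if (is.logical(labels)) labels else labels == "VAEM"
  stopifnot(length(dom) == length(y))
  if (!any(y)) stop("no positive (VAEM) labels to score against")
  if (all(y)) stop("no negative labels to score against")

  best_t <- NA_integer_
  best <- c(precision = 0, recall = 0, f1 = -1)
  for (t in seq_len(K)) {
    s <- set_f1(dom, y, t)
    if (s["f1"] > best["f1"]) { best <- s; best_t <- t }
  }
  set <- best_t
  trace <- best["f1"]
  while (length(set) < max_topics) {
    cand_t <- NA_integer_
    cand <- best
    for (t in setdiff(seq_len(K), set)) {
      s <- set_f1(dom, y, c(set, t))
      if (s["f1"] > cand["f1"]) { cand <- s; cand_t <- t }
    }
    if (is.na(cand_t) || cand["f1"] <= best["f1"]) break
    set <- sort(c(set, cand_t))
    best <- cand
    trace <- c(trace, best["f1"])
  }
  structure(list(best_topic_set = sort(set),
                 precision = unname(best["precision"]),
                 recall = unname(best["recall"]),
                 f1 = unname(best["f1"]),
                 n_topics = K, trace = unname(trace)),
            class = "vaem_concentration")
}

#' @export
print.vaem_concentration <- function(x, ...) {
  cat(sprintf(
    "label-concentration score: topics {%s} of %d | P=%.3f R=%.3f F1=%.3f\n",
    paste(x$best_topic_set, collapse = ","), x$n_topics,
    x$precision, x$recall, x$f1))
  invisible(x)
}

#' Fit a grid of topic models and keep the best by label concentration
#'
#' Fits one model per `(n_topics, seed)` grid point and returns the model
#' with the highest label-concentration F1.  Ties break toward fewer topics
#' in the winning set, then smaller `n_topics`, then lower seed, so the
#' selection is deterministic for a fixed grid.
#'
#' @param corpus list of token vectors to fit on.
#' @param labels labels for the labeled subset.
#' @param labeled_docs indices of the labeled documents in `corpus`.
#' @param grid data.frame with columns `n_topics` and `seed`.
#' @param max_topics passed to [concentration_score()].
#' @param ... passed to [fit_topic_model()] (e.g. `n_iter`, `vocab`).
#' @return list with `model`, `score`, and a data.frame `log` of every grid
#'   point's F1.
#' @export
select_best_model <- function(corpus, labels, labeled_docs = NULL,
                              grid = expand.grid(n_topics = c(8, 10, 13, 16, 20),
                                                 seed = 1:3),
                              max_topics = 3, ...) {
  stopifnot(nrow(grid) > 0, all(c("n_topics", "seed") %in% names(grid)))
  fits <- vector("list", nrow(grid))
  scores <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    m <- fit_topic_model(corpus, n_topics = grid$n_topics[i],
                         seed = grid$seed[i], ...)
    fits[[i]] <- m
    scores[[i]] <- concentration_score(m, labels, docs = labeled_docs,
                                       max_topics = max_topics)
  }
  log <- data.frame(
    n_topics = grid$n_topics, seed = grid$seed,
    f1 = vapply(scores, `[[`, numeric(1), "f1"),
    precision = vapply(scores, `[[`, numeric(1), "precision"),
    recall = vapply(scores, `[[`, numeric(1), "recall"),
    set_size = vapply(scores, function(s) length(s$best_topic_set), integer(1))
  )
  ord <- order(-log$f1, log$set_size, log$n_topics, log$seed)
  best <- ord[1]
  list(model = fits[[best]], score = scores[[best]], log = log)
}

#' Apply a topic filter to a corpus
#'
#' Retains the documents whose dominant topic lies in the selected topic
#' set.  Documents the model was trained on use their training assignment;
#' an unseen corpus is inferred against the frozen model ([infer_topics()]).
#'
#' @param model a `vaem_topic_model`.
#' @param topic_set a `vaem_concentration` or an integer vector of 1-based
#'   topic indices.
#' @param corpus optional list of token vectors to filter; if `NULL` the
#'   model's training documents are filtered.
#' @param ids optional ids aligned with the documents; indices are used
#'   otherwise.
#' @param stage stage tag for the result (1 or 2).
#' @param infer_iter,infer_seed fold-in settings for unseen corpora.
#' @return a `vaem_filter_result`: list with `retained`, `discarded`
#'   (ids or indices, disjoint, jointly exhaustive), `stage`, `topic_set`,
#'   and the `dominant` assignment vector.
#' @export
apply_filter <- function(model, topic_set, corpus = NULL, ids = NULL,
                         stage = 1, infer_iter = 30, infer_seed = 1) {
  if (inherits(topic_set, "vaem_concentration")) {
    topic_set <- topic_set$best_topic_set
  }
  dom <- if (is.null(corpus)) {
    dominant_topic(model)
  } else {
    dominant_topic(infer_topics(model, corpus, n_iter = infer_iter,
                                seed = infer_seed))
  }
  if (is.null(ids)) ids <- seq_along(dom)
  keep <- dom %in% topic_set
  structure(list(retained = ids[keep], discarded = ids[!keep],
                 stage = as.integer(stage),
                 topic_set = sort(as.integer(topic_set)), dominant = dom),
            class = "vaem_filter_result")
}

#' @export
print.vaem_filter_result <- function(x, ...) {
  n <- length(x$retained) + length(x$discarded)
  cat(sprintf("stage-%d topic filter: retained %d/%d (%.2f%%), topics {%s}\n",
              x$stage, length(x$retained), n,
              100 * length(x$retained) / max(n, 1),
              paste(x$topic_set, collapse = ",")))
  invisible(x)
}

#' Second-stage refinement of a filtered stream
#'
#' Refits a topic model on the stage-1 retained documents and keeps the
#' topics richest in VAEM: either the `top_k` topics by labeled-VAEM ratio
#' (default 3, ties broken by VAEM count, then topic index) or, in
#' threshold mode, every topic with ratio >= `ratio_threshold`.  This
#' trades away a little VAEM recall for a purer stream.
#'
#' @param corpus list of token vectors (the stage-1 retained documents).
#' @param labels labels aligned with `corpus`; `"UNLABELED"` entries are
#'   ignored when computing ratios.
#' @param n_topics topics for the refit (default 10).
#' @param seed Gibbs seed for the refit.
#' @param top_k retain the k highest-ratio topics (default 3); set to
#'   `NULL` to use `ratio_threshold` instead.
#' @param ratio_threshold retain topics with VAEM ratio >= this value
#'   (0 retains everything).
#' @param ids optional ids aligned with `corpus`.
#' @param ... passed to [fit_topic_model()].
#' @return a `vaem_filter_result` (stage 2) with extra fields `model` and
#'   `topic_ratios`.
#' @export
stage2_refine <- function(corpus, labels, n_topics = 10, seed = 1,
                          top_k = 3, ratio_threshold = NULL, ids = NULL, ...) {
  stopifnot(length(corpus) > 0, length(labels) == length(corpus))
  model <- fit_topic_model(corpus, n_topics = n_topics, seed = seed, ...)
  dom <- dominant_topic(model)
  lab_known <- labels %in% c("VAEM", "NON_VAEM")
  ratios <- vapply(seq_len(n_topics), function(t) {
    in_t <- lab_known & dom == t
    if (!any(in_t)) return(0)
    mean(labels[in_t] == "VAEM")
  }, numeric(1))
  vcount <- vapply(seq_len(n_topics), function(t) {
    sum(labels == "VAEM" & dom == t)
  }, numeric(1))
  keep_topics <- if (!is.null(top_k)) {
    head(order(-ratios, -vcount, seq_len(n_topics)), top_k)
  } else {
    which(ratios >= ratio_threshold)
  }
  res <- apply_filter(model, sort(keep_topics), ids = ids, stage = 2)
  res$model <- model
  res$topic_ratios <- ratios
  res
}
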