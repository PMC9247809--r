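#' Smoothed naive-Bayes log-count ratio
#'
#' The NBSVM feature weight
#' \deqn{r = \log\frac{(p+\alpha)/\|p+\alpha\|_1}{(q+\alpha)/\|q+\alpha\|_1}}
#' where `p` and `q` are the per-feature count sums over positive and
#' negative documents.
#'
#' @param x document-term matrix (binarized internally).
#' @param y logical or label vector; `TRUE`/`"VAEM"` is the positive class.
#' @param alpha smoothing (default 1).
#' @return numeric vector of per-feature log-count ratios.
#' @export
nbsvm_log_count_ratio <- function(x, y, alpha = 1) {
  yb <- if (is.logical(y)) y else y == "VAEM"
  xb <- x
  xb@x <- rep(1, length(xb@x))
  p <- Matrix::colSums(xb[yb, , drop = FALSE]) + alpha
  q <- Matrix::colSums(xb[!yb, , drop = FALSE]) + alpha
  as.numeric(log((p / sum(p)) / (q / sum(q))))
}

#' Train a binary VAEM classifier
#'
#' One entry point over the classical model zoo.  Supported `spec` values:
#' `"logreg_cv"` (ridge logistic regression with internal cross-validated
#' regularization, via glmnet), `"sgd"` (hinge-loss linear model trained by
#' stochastic gradient descent), `"linear_svc"` (linear support-vector
#' classifier, via e1071), `"random_forest"` and `"extra_trees"` (ranger),
#' `"multinomial_nb"` (multinomial naive Bayes), `"nbsvm"` (log-count-ratio
#' scaled linear model, interpolation `beta`), and `"xgboost"`
#' (gradient-boosted trees).  All are seeded; decision threshold is 0.5 on
#' probabilistic outputs and the margin sign otherwise.
#'
#' @param spec classifier name (see above).
#' @param x sparse document-term matrix from [vectorize()].
#' @param y labels (`"VAEM"`/`"NON_VAEM"`) or logical.
#' @param seed integer seed.
#' @param params optional named list of model-specific overrides
#'   (`nbsvm`: `alpha`, `beta`, `lambda`; `sgd`: `epochs`, `lambda`;
#'   `random_forest`/`extra_trees`: `num_trees`; `xgboost`: `nrounds`,
#'   `max_depth`, `eta`).
#' @return a `vaem_classifier`; use [predict.vaem_classifier()].
#' @export
train_classifier <- function(spec, x, y, seed = 1, params = list()) {
  yb <- if (is.logical(y)) y else y == "VAEM"
  if (!any(yb) || all(yb)) stop("training data must contain both classes")
  yf <- factor(ifelse(yb, "VAEM", "NON_VAEM"), levels = c("NON_VAEM", "VAEM"))
  fit <- switch(
    spec,
    logreg_cv = with_seed(seed, {
      glmnet::cv.glmnet(x, yb, family = "binomial", alpha = 0, nfolds = 5)
    }),
    sgd = {
      xr <- methods::as(x, "RsparseMatrix")
      cpp_sgd_hinge(xr@p, xr@j, xr@x, ifelse(yb, 1, -1), ncol(x),
                    as.integer(params$epochs %||% 10),
                    params$lambda %||% 1e-4, as.integer(seed))
    },
    linear_svc = with_seed(seed, {
      e1071::svm(x, yf, kernel = "linear", cost = params$cost %||% 1,
                 scale = FALSE)
    }),
    random_forest = ranger::ranger(
      x = as.matrix(x), y = yf, num.trees = params$num_trees %||% 200,
      seed = seed, num.threads = 1, probability = TRUE),
    extra_trees = ranger::ranger(
      x = as.matrix(x), y = yf, num.trees = params$num_trees %||% 200,
      splitrule = "extratrees", num.random.splits = 1,
      seed = seed, num.threads = 1, probability = TRUE),
    multinomial_nb = {
      alpha <- params$alpha %||% 1
      pos <- Matrix::colSums(x[yb, , drop = FALSE]) + alpha
      neg <- Matrix::colSums(x[!yb, , drop = FALSE]) + alpha
      list(log_pos = log(pos / sum(pos)), log_neg = log(neg / sum(neg)),
           log_prior = log(mean(yb) / (1 - mean(yb))))
    },
    nbsvm = {
      alpha <- params$alpha %||% 1
      beta <- params$beta %||% 0.25
      r <- nbsvm_log_count_ratio(x, yb, alpha = alpha)
      xb <- x
      xb@x <- rep(1, length(xb@x))
      xs <- xb %*% Matrix::Diagonal(x = r)
      g <- with_seed(seed, {
        glmnet::glmnet(xs, yb, family = "binomial", alpha = 0,
                       lambda = params$lambda %||% 1e-3)
      })
      w <- as.numeric(g$beta[, 1])
      wbar <- mean(abs(w))
      list(r = r, w = (1 - beta) * wbar + beta * w,
           b = as.numeric(g$a0[1]), beta = beta)
    },
    xgboost = {
      dtr <- xgboost::xgb.DMatrix(data = x, label = as.numeric(yb))
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", nthread = 1,
                      max_depth = params$max_depth %||% 6,
                      eta = params$eta %||% 0.3, seed = seed),
        data = dtr, nrounds = params$nrounds %||% 80, verbose = 0)
    },
    stop("unknown classifier spec: ", spec)
  )
  structure(list(spec = spec, fit = fit, seed = as.integer(seed),
                 n_features = ncol(x)),
            class = "vaem_classifier")
}

#' Predict VAEM labels
#'
#' @param object a `vaem_classifier`.
#' @param x document-term matrix from the *same* vectorizer the classifier
#'   was trained on.
#' @param type `"label"` (default) or `"score"` (probability or margin).
#' @param ... unused.
#' @return character labels, or numeric scores when `type = "score"`.
#' @export
predict.vaem_classifier <- function(object, x, type = c("label", "score"),
                                    ...) {
  type <- match.arg(type)
  score <- switch(
    object$spec,
    logreg_cv = as.numeric(stats::predict(object$fit, newx = x,
                                          s = "lambda.min",
                                          type = "response")),
    sgd = as.numeric(x %*% object$fit$w + object$fit$b),
    linear_svc = {
      pr <- stats::predict(object$fit, x, decision.values = TRUE)
      dv <- as.numeric(attr(pr, "decision.values"))
      # e1071 orients the decision value by first-seen class; re-sign so
      # positive margin means VAEM
      if (colnames(attr(pr, "decision.values"))[1] == "NON_VAEM/VAEM") -dv else dv
    },
    random_forest = ,
    extra_trees = {
      pr <- stats::predict(object$fit, data = as.matrix(x),
                           num.threads = 1, seed = object$seed)
      pr$predictions[, "VAEM"]
    },
    multinomial_nb = as.numeric(
      x %*% (object$fit$log_pos - object$fit$log_neg) + object$fit$log_prior),
    nbsvm = {
      xb <- x
      xb@x <- rep(1, length(xb@x))
      as.numeric((xb %*% Matrix::Diagonal(x = object$fit$r)) %*%
                   object$fit$w + object$fit$b)
    },
    xgboost = as.numeric(stats::predict(object$fit,
                                        xgboost::xgb.DMatrix(data = x))),
    stop("unknown classifier spec: ", object$spec)
  )
  if (type == "score") return(score)
  thr <- if (object$spec %in% c("logreg_cv", "random_forest", "extra_trees",
                                "xgboost")) 0.5 else 0
  ifelse(score > thr, "VAEM", "NON_VAEM")
}

#' The five-member majority-voting ensemble
#'
#' Trains the NBSVM, logistic-regression-CV, SGD, linear-SVC and
#' random-forest members on the same matrix; predictions are combined by
#' [ensemble_vote()].
#'
#' @param x,y,seed as in [train_classifier()].
#' @return a `vaem_ensemble` (list of five `vaem_classifier`s).
#' @export
train_ensemble <- function(x, y, seed = 1) {
  members <- c("nbsvm", "logreg_cv", "sgd", "linear_svc", "random_forest")
  fits <- lapply(seq_along(members), function(i) {
    train_classifier(members[i], x, y, seed = seed + i)
  })
  names(fits) <- members
  structure(list(members = fits), class = "vaem_ensemble")
}

#' @rdname train_ensemble
#' @param object a `vaem_ensemble`.
#' @param ... unused.
#' @export
predict.vaem_ensemble <- function(object, x, ...) {
  votes <- vapply(object$members, function(m) predict(m, x),
                  character(nrow(x)))
  ensemble_vote(votes)
}

#' Majority vote over an odd number of binary predictions
#'
#' @param votes a documents-by-voters matrix (or list of equal-length
#'   vectors) of `"VAEM"`/`"NON_VAEM"` labels or 0/1 values.  The voter
#'   count must be odd: a tie is undefined.
#' @return per-document majority label (same coding as the input).
#' @export
ensemble_vote <- function(votes) {
  if (is.list(votes)) votes <- do.call(cbind, votes)
  votes <- as.matrix(votes)
  if (ncol(votes) %% 2 == 0) stop("voter count must be odd")
  num <- if (is.character(votes)) votes == "VAEM" else votes > 0
  maj <- rowSums(num) > ncol(votes) / 2
  if (is.character(votes)) ifelse(maj, "VAEM", "NON_VAEM") else as.integer(maj)
}
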