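#' Build a balanced training split with an imbalanced holdout test set
#'
#' Mirrors the dataset construction used downstream of topic filtering: a
#' stratified holdout test set is carved out *first* (keeping the filtered
#' stream's natural class ratio), then the remaining pool is balanced by
#' randomly undersampling negatives to the positive count, and finally the
#' balanced pool is split into stratified train/validation sets.
#'
#' @param pool data.frame of labeled posts (`label` in
#'   `"VAEM"`/`"NON_VAEM"`).
#' @param seed integer seed.
#' @param holdout_frac fraction of the pool carved out as the imbalanced
#'   test set before balancing (default 0.1).
#' @param train_frac train share of the balanced pool (default 0.75, i.e. a
#'   75:25 train:validation ratio).
#' @param name split name carried in the result.
#' @return a `vaem_dataset_split`: list with `train`, `validation`, `test`
#'   data.frames, `balance = "balanced"` and `name`.
#' @export
make_balanced_set <- function(pool, seed = 1, holdout_frac = 0.1,
                              train_frac = 0.75, name = "dataset") {
  stopifnot("label" %in% names(pool))
  n_pos <- sum(pool$label == "VAEM")
  n_neg <- sum(pool$label == "NON_VAEM")
  if (n_pos == 0 || n_neg == 0) {
    stop("pool must contain both classes to balance")
  }
  hold <- split_fixture(pool, c(1 - holdout_frac, 0, holdout_frac),
                        seed = derive_seed(seed, "holdout"))
  rest <- hold$train
  pos <- which(rest$label == "VAEM")
  neg <- which(rest$label == "NON_VAEM")
  with_seed(derive_seed(seed, "balance"), {
    if (length(neg) > length(pos)) {
      neg <- sort(sample(neg, length(pos)))
    } else if (length(pos) > length(neg)) {
      pos <- sort(sample(pos, length(neg)))
    }
  })
  balanced <- rest[sort(c(pos, neg)), , drop = FALSE]
  tv <- split_fixture(balanced, c(train_frac, 1 - train_frac, 0),
                      seed = derive_seed(seed, "trainvalid"))
  structure(list(train = tv$train, validation = tv$validation,
                 test = hold$test, balance = "balanced", name = name),
            class = "vaem_dataset_split")
}

#' @export
print.vaem_dataset_split <- function(x, ...) {
  f <- function(d) sprintf("%d (%d VAEM)", nrow(d), sum(d$label == "VAEM"))
  cat(sprintf("dataset '%s' (%s): train %s | validation %s | test %s\n",
              x$name, x$balance, f(x$train), f(x$validation), f(x$test)))
  invisible(x)
}
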