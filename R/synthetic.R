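# Word pools shared by every synthetic post.  All lowercase-letter words so
# that generated text survives normalization unchanged (decorations below
# add the markup that cleaning removes).
.vaccine_words <- c("vaccine", "vaccines", "vaccination", "vax", "flushot",
                    "jab", "flu", "shot", "immunization", "dose", "booster")
.symptom_words <- c("sore", "fever", "ache", "headache", "dizzy", "nausea",
                    "rash", "swollen", "fatigue", "chills", "pain", "numb",
                    "tired", "cramp", "itchy", "weak")
.body_words <- c("arm", "shoulder", "head", "leg", "stomach", "muscle",
                 "neck", "back", "hand", "skin")
.first_person <- c("my", "i", "im", "me", "got", "just", "today",
                   "yesterday", "feel", "feeling", "after", "since", "cant",
                   "really", "so", "still", "hurts", "bad", "whole", "woke")
.news_frame <- c("news", "breaking", "report", "officials", "urges",
                 "campaign", "outbreak", "study", "researchers", "health",
                 "department", "announces", "program", "launch", "public",
                 "experts", "warns", "plea", "update", "rollout")
.third_person <- c("people", "father", "patients", "children", "residents",
                   "staff", "community", "doctors")
.filler_words <- c("the", "a", "to", "and", "of", "in", "for", "on", "with",
                   "at", "this", "that", "it", "is", "was", "are", "be")

#' Configuration for the synthetic vaccine-conversation corpus
#'
#' The generator emulates the statistical structure the two-phase method
#' assumes: a stream of short vaccine-related posts drawn from `n_subjects`
#' latent subjects, exactly one of which is "personal health mention"-like;
#' a rare positive (VAEM) class concentrated almost entirely inside that
#' subject; and lexically similar hard negatives (posts using the same
#' vaccine/symptom vocabulary in non-personal news-style frames), both
#' inside the VAEM subject and, at `hard_negative_rate`, sprinkled through
#' the other subjects.
#'
#' @param n_posts number of posts to generate.
#' @param n_subjects number of latent subjects (default 13).
#' @param vaem_subject_index 1-based index of the personal-health-mention
#'   subject (default 1).
#' @param global_vaem_prevalence fraction of all posts labeled VAEM
#'   (default 0.0145).
#' @param within_subject_vaem_ratio VAEM fraction *inside* the VAEM subject;
#'   the rest of that subject are hard negatives (default 0.5).
#' @param vocab_size_per_subject distinct pseudo-words per subject
#'   (default 40).
#' @param hard_negative_rate fraction of other-subject posts that also use
#'   vaccine + symptom vocabulary (default 0.05).
#' @param stray_rate fraction of VAEM posts generated outside the VAEM
#'   subject -- the small positive tail any topic filter loses
#'   (default 0.01).
#' @param mean_length mean post length in tokens, Poisson, truncated to
#'   `[5, 50]` so posts survive the short-post filter (default 18).
#' @param exact_counts if `TRUE`, the VAEM count is exactly
#'   `round(prevalence * n_posts)` instead of Binomial.
#' @param seed integer seed; a fixed seed yields a bit-identical corpus.
#' @return a `vaem_generator_config` list.
#' @export
generator_config <- function(n_posts = 100000, n_subjects = 13,
                             vaem_subject_index = 1,
                             global_vaem_prevalence = 0.0145,
                             within_subject_vaem_ratio = 0.5,
                             vocab_size_per_subject = 40,
                             hard_negative_rate = 0.05,
                             stray_rate = 0.01,
                             mean_length = 18,
                             exact_counts = FALSE,
                             seed = 7) {
  cfg <- list(n_posts = as.integer(n_posts), n_subjects = as.integer(n_subjects),
              vaem_subject_index = as.integer(vaem_subject_index),
              global_vaem_prevalence = global_vaem_prevalence,
              within_subject_vaem_ratio = within_subject_vaem_ratio,
              vocab_size_per_subject = as.integer(vocab_size_per_subject),
              hard_negative_rate = hard_negative_rate,
              stray_rate = stray_rate, mean_length = mean_length,
              exact_counts = isTRUE(exact_counts), seed = as.integer(seed))
  stopifnot(cfg$n_posts >= 1, cfg$n_subjects >= 2,
            cfg$vaem_subject_index >= 1,
            cfg$vaem_subject_index <= cfg$n_subjects,
            cfg$global_vaem_prevalence > 0, cfg$global_vaem_prevalence < 1,
            cfg$within_subject_vaem_ratio > 0,
            cfg$within_subject_vaem_ratio <= 1,
            cfg$hard_negative_rate >= 0, cfg$stray_rate >= 0,
            cfg$stray_rate < 1)
  if (cfg$exact_counts &&
      round(cfg$global_vaem_prevalence * cfg$n_posts) < 1) {
    stop("infeasible config: exact_counts with prevalence * n_posts < 1")
  }
  class(cfg) <- "vaem_generator_config"
  cfg
}

# run `expr` under a private, seeded RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

# deterministic pseudo-word vocabularies, disjoint across subjects and from
# the shared English pools
subject_vocabularies <- function(n_subjects, size, seed) {
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t",
            "v", "z", "ch", "st", "tr", "pl", "br", "gr")
  vow <- c("a", "e", "i", "o", "u")
  syll <- as.vector(outer(cons, vow, paste0))
  with_seed(seed + 104729L, {
    words <- character(0)
    need <- n_subjects * size
    while (length(words) < need) {
      batch <- vapply(seq_len(need * 2), function(i) {
        paste(sample(syll, sample(2:3, 1), replace = TRUE), collapse = "")
      }, character(1))
      words <- unique(c(words, batch))
      words <- setdiff(words, c(.vaccine_words, .symptom_words, .body_words,
                                .first_person, .news_frame, .third_person,
                                .filler_words))
    }
    split(words[seq_len(need)], rep(seq_len(n_subjects), each = size))
  })
}

# draw `total` tokens from a named pool-mixture, vectorized
draw_mixture <- function(total, pools, probs) {
  if (total == 0) return(character(0))
  which_pool <- sample.int(length(pools), total, replace = TRUE, prob = probs)
  out <- character(total)
  for (j in seq_along(pools)) {
    idx <- which(which_pool == j)
    if (length(idx)) out[idx] <- sample(pools[[j]], length(idx), replace = TRUE)
  }
  out
}

#' Generate a synthetic labeled corpus of vaccine-related posts
#'
#' See [generator_config()] for the corpus structure.  VAEM posts follow a
#' first-person template (`i got <vaccine> <body> <symptom> ...`); hard
#' negatives open with a news-style frame over the same vaccine/symptom
#' vocabulary.  Raw text carries realistic markup (hashtags, mentions,
#' URLs, capitalization, trailing punctuation) so that cleaning is
#' exercised end to end.
#'
#' @param cfg a [generator_config()].
#' @return data.frame of posts: `id`, `text`, `created_at`, `label`
#'   (`"VAEM"`/`"NON_VAEM"`), `subject_id` (ground-truth subject).
#' @export
generate_corpus <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "vaem_generator_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_posts
    vocabs <- subject_vocabularies(cfg$n_subjects, cfg$vocab_size_per_subject,
                                   cfg$seed)
    m <- if (cfg$exact_counts) {
      as.integer(round(cfg$global_vaem_prevalence * n))
    } else {
      stats::rbinom(1, n, cfg$global_vaem_prevalence)
    }
    label <- rep("NON_VAEM", n)
    is_vaem <- if (m > 0) sample.int(n, m) else integer(0)
    label[is_vaem] <- "VAEM"

    # subjects: VAEM posts sit in the VAEM subject except a stray tail;
    # the VAEM subject also holds hard negatives at the configured ratio
    subject <- integer(n)
    others <- setdiff(seq_len(cfg$n_subjects), cfg$vaem_subject_index)
    n_stray <- round(cfg$stray_rate * m)
    stray <- if (n_stray > 0) sample(is_vaem, n_stray) else integer(0)
    subject[is_vaem] <- cfg$vaem_subject_index
    if (length(stray)) subject[stray] <- sample(others, length(stray),
                                                replace = TRUE)
    n_core_vaem <- m - length(stray)
    n_hardneg <- round(n_core_vaem *
                         (1 - cfg$within_subject_vaem_ratio) /
                         cfg$within_subject_vaem_ratio)
    neg_idx <- which(label == "NON_VAEM")
    n_hardneg <- min(n_hardneg, length(neg_idx))
    hardneg <- if (n_hardneg > 0) sample(neg_idx, n_hardneg) else integer(0)
    subject[hardneg] <- cfg$vaem_subject_index
    rest <- setdiff(neg_idx, hardneg)
    subject[rest] <- sample(others, length(rest), replace = TRUE)
    # news-style vaccine/symptom mentions sprinkled through other subjects
    newsy <- if (length(rest)) rest[stats::runif(length(rest)) <
                                      cfg$hard_negative_rate] else integer(0)

    len <- pmin(pmax(stats::rpois(n, cfg$mean_length), 5L), 50L)
    tokens <- vector("list", n)

    fill_group <- function(idx, pools, probs, head_fn) {
      if (!length(idx)) return()
      tot <- sum(len[idx])
      body <- draw_mixture(tot, pools, probs)
      parts <- split(body, rep(seq_along(idx), len[idx]))
      heads <- head_fn(length(idx))
      for (k in seq_along(idx)) {
        t <- parts[[k]]
        h <- heads[[k]]
        nh <- min(length(h), length(t))
        t[seq_len(nh)] <- h[seq_len(nh)]
        tokens[[idx[k]]] <<- t
      }
    }

    vaem_heads <- function(k) {
      opener <- sample(c("i", "my", "im"), k, replace = TRUE)
      verb <- sample(c("got", "had", "just"), k, replace = TRUE)
      vac <- sample(.vaccine_words, k, replace = TRUE)
      bod <- sample(.body_words, k, replace = TRUE)
      sym <- sample(.symptom_words, k, replace = TRUE)
      lapply(seq_len(k), function(j) c(opener[j], verb[j], vac[j], bod[j], sym[j]))
    }
    news_heads <- function(k) {
      op1 <- sample(.news_frame, k, replace = TRUE)
      op2 <- sample(.news_frame, k, replace = TRUE)
      vac <- sample(.vaccine_words, k, replace = TRUE)
      sym <- sample(.symptom_words, k, replace = TRUE)
      who <- sample(.third_person, k, replace = TRUE)
      lapply(seq_len(k), function(j) c(op1[j], op2[j], vac[j], who[j], sym[j]))
    }
    plain_heads <- function(k) {
      vac <- sample(.vaccine_words, k, replace = TRUE)
      lapply(seq_len(k), function(j) vac[j])
    }

    sv <- vocabs[[cfg$vaem_subject_index]]
    # genuine personal mentions in the VAEM subject
    fill_group(setdiff(is_vaem, stray),
               list(.first_person, .symptom_words, .body_words,
                    .vaccine_words, sv, .filler_words, .news_frame),
               c(.32, .13, .08, .10, .20, .09, .08), vaem_heads)
    # hard negatives in the VAEM subject: same lexical field, news frame
    fill_group(hardneg,
               list(.news_frame, .symptom_words, .vaccine_words, sv,
                    .filler_words, .third_person, .body_words, .first_person),
               c(.24, .12, .10, .20, .09, .08, .05, .12), news_heads)
    # stray VAEM: personal template over another subject's vocabulary
    for (s in unique(subject[stray])) {
      idx <- stray[subject[stray] == s]
      fill_group(idx,
                 list(.first_person, .symptom_words, .body_words,
                      .vaccine_words, vocabs[[s]], .filler_words),
                 c(.30, .12, .08, .08, .34, .08), vaem_heads)
    }
    # ordinary posts of the other subjects
    for (s in others) {
      idx <- rest[subject[rest] == s]
      hn <- intersect(idx, newsy)
      pl <- setdiff(idx, hn)
      fill_group(pl,
                 list(vocabs[[s]], .filler_words, .vaccine_words,
                      .news_frame, .third_person),
                 c(.55, .22, .10, .08, .05), plain_heads)
      fill_group(hn,
                 list(vocabs[[s]], .filler_words, .vaccine_words,
                      .symptom_words, .news_frame, .third_person),
                 c(.45, .15, .12, .12, .10, .06), news_heads)
    }

    text <- vapply(tokens, paste, character(1), collapse = " ")
    # markup the cleaner must strip
    u <- stats::runif(n)
    deco_hash <- u < 0.10
    text[deco_hash] <- paste0(text[deco_hash], " #",
                              sample(.vaccine_words, sum(deco_hash),
                                     replace = TRUE))
    deco_at <- u >= 0.10 & u < 0.18
    text[deco_at] <- paste0("@user", sample.int(9999, sum(deco_at),
                                                replace = TRUE), " ",
                            text[deco_at])
    deco_url <- u >= 0.18 & u < 0.25
    text[deco_url] <- paste0(text[deco_url], " https://t.co/",
                             sample.int(99999, sum(deco_url), replace = TRUE))
    cap <- stats::runif(n) < 0.5
    text[cap] <- paste0(toupper(substr(text[cap], 1, 1)),
                        substr(text[cap], 2, nchar(text[cap])))
    dot <- stats::runif(n) < 0.5
    text[dot] <- paste0(text[dot], ".")

    data.frame(
      id = sprintf("p%07d", seq_len(n)),
      text = text,
      created_at = format(as.POSIXct("2018-02-07", tz = "UTC") +
                            seq_len(n) * 30, "%Y-%m-%dT%H:%M:%SZ"),
      label = label,
      subject_id = subject,
      stringsAsFactors = FALSE
    )
  })
}

#' Stratified train/validation/test partition
#'
#' Partitions a corpus into disjoint, exhaustive splits whose class ratios
#' match the global ratio to within one post per class (largest-remainder
#' allocation inside each label stratum).
#'
#' @param corpus data.frame with a `label` column.
#' @param fractions numeric length-3 vector `(train, validation, test)`
#'   summing to 1.
#' @param seed integer seed for the within-stratum shuffle.
#' @return named list of data.frames `train`, `validation`, `test`.
#' @export
split_fixture <- function(corpus, fractions = c(0.75, 0.25, 0), seed = 1) {
  stopifnot(length(fractions) == 3, all(fractions >= 0),
            abs(sum(fractions) - 1) < 1e-8, "label" %in% names(corpus))
  assign_split <- integer(nrow(corpus))
  with_seed(seed, {
    for (lab in unique(corpus$label)) {
      idx <- which(corpus$label == lab)
      idx <- sample(idx)
      n <- length(idx)
      base <- floor(fractions * n)
      rem <- fractions * n - base
      short <- n - sum(base)
      if (short > 0) {
        add <- order(rem, decreasing = TRUE)[seq_len(short)]
        base[add] <- base[add] + 1
      }
      grp <- rep(1:3, times = base)
      assign_split[idx] <- grp
    }
  })
  list(train = corpus[assign_split == 1, , drop = FALSE],
       validation = corpus[assign_split == 2, , drop = FALSE],
       test = corpus[assign_split == 3, , drop = FALSE])
}
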