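#' Read a corpus of posts from JSONL or CSV
#'
#' One record per post with columns/keys `id`, `text`, and optionally
#' `created_at` and `label`.  `label` values other than `"VAEM"` /
#' `"NON_VAEM"` (including absence) are mapped to `"UNLABELED"`.
#'
#' @param path path to a UTF-8 `.jsonl`/`.ndjson` or `.csv` file.
#' @param format `"auto"` (by extension), `"jsonl"` or `"csv"`.
#' @return a `data.frame` with columns `id` (character), `text` (character),
#'   `created_at` (character or `NA`), `label` (character).
#' @export
read_posts <- function(path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  df <- if (format == "csv") {
    utils::read.csv(path, colClasses = "character", encoding = "UTF-8")
  } else {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(lines)]
    recs <- lapply(lines, jsonlite::fromJSON)
    as.data.frame(do.call(rbind, lapply(recs, function(r) {
      c(id = as.character(r$id %||% NA_character_),
        text = as.character(r$text %||% NA_character_),
        created_at = as.character(r$created_at %||% NA_character_),
        label = as.character(r$label %||% NA_character_))
    })), stringsAsFactors = FALSE)
  }
  as_posts(df)
}

#' Coerce a data frame to the canonical post layout
#'
#' @param df data.frame with at least `id` and `text` columns.
#' @return data.frame with columns `id`, `text`, `created_at`, `label`.
#' @export
as_posts <- function(df) {
  stopifnot(is.data.frame(df), all(c("id", "text") %in% names(df)))
  id <- as.character(df$id)
  text <- as.character(df$text)
  if (any(!nzchar(id)) || anyNA(id)) stop("post ids must be non-empty")
  if (anyNA(text)) stop("post text must be present")
  lab <- if ("label" %in% names(df)) as.character(df$label) else NA_character_
  lab[is.na(lab) | !(lab %in% c("VAEM", "NON_VAEM"))] <- "UNLABELED"
  out <- data.frame(
    id = id, text = text,
    created_at = if ("created_at" %in% names(df))
      as.character(df$created_at) else NA_character_,
    label = rep_len(lab, length(id)),
    stringsAsFactors = FALSE
  )
  if ("subject_id" %in% names(df)) out$subject_id <- as.integer(df$subject_id)
  out
}

#' Write posts or cleaned posts to JSONL
#'
#' @param df data.frame of posts (list-columns such as `tokens` are written
#'   as JSON arrays).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_jsonl <- function(df, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(df))) {
    rec <- lapply(df[i, , drop = FALSE], function(col) {
      v <- if (is.list(col)) col[[1]] else col
      if (length(v) == 1 && is.na(v)) NULL else v
    })
    rec <- rec[!vapply(rec, is.null, logical(1))]
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
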