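#' @keywords internal
"_PACKAGE"

#' @importFrom Rcpp sourceCpp
#' @useDynLib vaemmine, .registration = TRUE
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Commercial rounding used for all displayed percentages and estimated
#' counts: ties go away from zero (`round_half_up(0.125, 2) == 0.13`),
#' unlike base [round()], which rounds half to even.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places to keep.
#' @return numeric vector rounded to `digits` places.
#' @export
#' @examples
#' round_half_up(c(2.5, -2.5, 0.125), 0)
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x), is.numeric(digits))
  m <- 10^digits
  # nudge by an ulp-scale epsilon so values like 76.305 stored as
  # 76.30499999... still round up at the printed precision
  z <- abs(x) * m
  z <- floor(z + 0.5 + sqrt(.Machine$double.eps) * z)
  sign(x) * z / m
}

# deterministic content hash used in provenance records
config_hash <- function(x) {
  digest::digest(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                  force = TRUE, null = "null"))
}

# derive a reproducible child seed (< 2^31) from a base seed and a stage tag
derive_seed <- function(seed, tag) {
  h <- digest::digest(paste0(seed, "/", tag), algo = "xxhash32")
  as.integer(strtoi(substr(h, 1, 7), base = 16L))
}

positive_f1 <- function(tp, fp, fn) {
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f1)
}
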