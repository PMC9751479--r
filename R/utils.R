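#' @useDynLib ervkit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data abort %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

DNA_BASES <- c("A", "C", "G", "T")

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

chars_seq <- function(x) paste(x, collapse = "")

revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(x, function(s) {
    chars_seq(rev(seq_chars(s)))
  }, character(1), USE.NAMES = FALSE))
}

gc_content <- function(x) {
  ch <- seq_chars(x)
  ch <- ch[ch %in% DNA_BASES]
  if (length(ch) == 0) return(NA_real_)
  mean(ch %in% c("G", "C"))
}

#' Derive a reproducible sub-seed from a run seed and a stage name
#'
#' All randomness in the package flows from one explicit seed; independent
#' stages draw from named substreams so results are stable under stage
#' reordering. The derived seed is always a valid 32-bit integer.
#'
#' @param seed Integer run seed.
#' @param name Character stage name.
#' @return An integer seed.
#' @export
seed_stream <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(name))
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% 2147483587
  as.integer((abs(seed) %% 2147483587 * 48271 + h) %% 2147483587 + 1)
}

with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Coordinate conventions -------------------------------------------------
# All internal coordinates are 0-based half-open ([start, end)); published
# provirus annotations are 1-based inclusive and converted on load.

#' Convert between 1-based inclusive and 0-based half-open intervals
#'
#' `iv_from_1based()` converts published 1-based inclusive coordinates to the
#' package's 0-based half-open convention; `iv_to_1based()` is its inverse.
#' The two compose to the identity.
#'
#' @param start,end Interval coordinates.
#' @return A list with `start` and `end`.
#' @export
iv_from_1based <- function(start, end) {
  stopifnot(all(start >= 1), all(end >= start))
  list(start = start - 1L, end = end)
}

#' @rdname iv_from_1based
#' @export
iv_to_1based <- function(start, end) {
  stopifnot(all(start >= 0), all(end > start))
  list(start = start + 1L, end = end)
}

extract_iv <- function(seq, start, end) {
  # 0-based half-open extraction
  substr(seq, start + 1, end)
}

validate_dna <- function(seq, id = "sequence", allow_n = TRUE) {
  alphabet <- if (allow_n) "ACGTN" else "ACGT"
  bad <- gsub(sprintf("[%s]", alphabet), "", seq)
  if (nchar(bad) > 0) {
    abort(sprintf("record '%s' contains invalid character(s): %s",
                  id, paste(unique(seq_chars(bad)), collapse = ", ")))
  }
  invisible(seq)
}
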