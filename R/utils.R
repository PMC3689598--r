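#' @importFrom Biostrings DNAString DNAStringSet reverseComplement matchPattern
#'   vmatchPattern writeXStringSet readDNAStringSet pairwiseAlignment nmatch
#'   PDict matchPDict
#' @importFrom IRanges IRanges start end width findOverlaps reduce
#' @importFrom S4Vectors queryHits subjectHits mcols mcols<-
#' @importFrom stats setNames rbinom runif
#' @importFrom utils read.table write.table combn head
NULL

# Internal coordinate convention: 0-based, half-open [start, end) everywhere.
# 1-based conversions happen only inside readers/writers.

.valid_marks <- c("none", "5mC", "5hmC")

.mark_code <- function(mark) match(mark, c("5mC", "5hmC"), nomatch = 0L)

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

.is_palindromic <- function(recognition) {
  identical(toupper(recognition), .revcomp(recognition))
}

#' Derive a stage-salted child seed from a run seed
#'
#' A single run seed fans out to per-stage seeds so that any pipeline stage can
#' be re-run in isolation with the same stream of random numbers. The salt is a
#' simple polynomial hash of the label, folded into the 31-bit signed range.
#'
#' @param seed integer run seed.
#' @param label character scalar naming the consumer (e.g. "reads:ME_RDA:D7").
#' @return an integer usable with [set.seed()].
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% 2147483647
  as.integer((abs(seed) + h) %% 2147483647)
}

# vectorized hamming distance between equal-width strings
.hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  mapply(function(x, y) {
    sum(charToRaw(x) != charToRaw(y))
  }, a, b, USE.NAMES = FALSE)
}

.stop_if_missing_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s is missing column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

# empty data.frame with given column names/types (types from prototypes)
.empty_df <- function(proto) proto[0L, , drop = FALSE]
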