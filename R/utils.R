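#' @importFrom stats runif setNames
#' @importFrom utils read.delim write.table count.fields combn
NULL

DNA_BASES <- c("A", "C", "G", "T")

# Deterministic 31-bit seed derived from a master seed and a stream name, so
# each virome/genome gets its own reproducible random stream.
derive_seed <- function(seed, name) {
  h <- 0
  for (v in utf8ToInt(as.character(name))) h <- (h * 131 + v) %% 2147483647L
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Express a count as a percentage of a total
#'
#' Rounds to three significant digits, the precision used in the package's
#' summary reports (e.g. 4 of 67 genomes -> 5.97).
#'
#' @param n Count (numeric).
#' @param total Total (positive numeric).
#' @return Numeric percentage.
#' @export
#' @examples
#' percent_of(4, 67)
percent_of <- function(n, total) {
  stopifnot(is.numeric(n), is.numeric(total), total > 0)
  signif(100 * n / total, 3)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

log_msg <- function(...) message("[crassrecruit] ", ...)
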