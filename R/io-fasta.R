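#' Read genome sequences from a FASTA file
#'
#' Ids are the first whitespace-delimited token of each header; sequences are
#' case-folded to uppercase and validated against the {A,C,G,T,N} alphabet.
#'
#' @param path Path to a FASTA file.
#' @return data.frame with columns `id`, `sequence`, `length`.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0) stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1])
  }
  seqs <- toupper(as.character(set))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("record ", ids[bad][1], ": sequence contains characters outside ACGTN")
  }
  data.frame(id = ids, sequence = unname(seqs), length = nchar(seqs),
             stringsAsFactors = FALSE)
}

#' Write sequences to FASTA
#'
#' @param sequences Named character vector, or a [genome_set()].
#' @param path Output path.
#' @param width Line-wrap width (default 80).
#' @export
write_fasta <- function(sequences, path, width = 80) {
  if (inherits(sequences, "genome_set")) sequences <- sequences$seq
  set <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read reads from a FASTQ file
#'
#' @param path Path to a FASTQ file.
#' @return Named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  stopifnot(file.exists(path))
  set <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(set), names(set))
}

#' Write reads to FASTQ with dummy qualities
#'
#' @param reads Named character vector of read sequences.
#' @param path Output path.
#' @export
write_fastq <- function(reads, path) {
  set <- Biostrings::DNAStringSet(reads)
  qual <- Biostrings::BStringSet(vapply(nchar(reads), function(n) {
    strrep("I", n)
  }, character(1)))
  Biostrings::writeXStringSet(set, path, format = "fastq", qualities = qual)
  invisible(path)
}
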