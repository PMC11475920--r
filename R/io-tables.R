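ALN_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
              "qstart", "qend", "sstart", "send", "evalue", "bitscore")

#' Read a 12/13-column tabular alignment file
#'
#' Parses the standard tab-separated alignment dialect (qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore), optionally
#' extended with a 13th query-length column. The query-coverage filter needs
#' the query length, which the 12-column dialect does not carry, so a
#' `qlen_source` must be given: `"column13"`, `"fastq:<path>"` (look lengths up
#' in a FASTQ/FASTA of the reads), or `"constant:<N>"`.
#'
#' Minus-strand rows (`sstart > send`) are preserved as-is; coordinates are
#' 1-based inclusive throughout.
#'
#' @param path Path to the alignment table (no header).
#' @param qlen_source How to resolve query lengths (see Details).
#' @return data.frame of alignment records with a resolved `qlen` column.
#' @export
read_tabular_alignments <- function(path, qlen_source) {
  stopifnot(file.exists(path), is.character(qlen_source))
  nf <- count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (is.null(nf) || length(nf) == 0) {
    return(empty_alignments())
  }
  bad <- which(!nf %in% c(12L, 13L))
  if (length(bad)) {
    stop("row ", bad[1], ": expected 12 or 13 tab-separated columns, found ", nf[bad[1]])
  }
  has13 <- all(nf == 13L)
  df <- read.delim(path, header = FALSE, sep = "\t", quote = "",
                   comment.char = "", stringsAsFactors = FALSE)
  names(df)[1:12] <- ALN_COLS
  if (ncol(df) == 13) names(df)[13] <- "qlen"

  if (qlen_source == "column13") {
    if (!has13) stop("qlen_source 'column13' but table has only 12 columns")
  } else if (startsWith(qlen_source, "constant:")) {
    n <- as.numeric(sub("^constant:", "", qlen_source))
    if (!is.finite(n) || n < 1) stop("invalid constant qlen: ", qlen_source)
    df$qlen <- as.integer(n)
  } else if (startsWith(qlen_source, "fastq:") || startsWith(qlen_source, "fasta:")) {
    p <- sub("^fast[qa]:", "", qlen_source)
    reads <- if (startsWith(qlen_source, "fastq:")) read_fastq(p) else {
      fa <- read_fasta(p); setNames(fa$sequence, fa$id)
    }
    qlen <- nchar(reads)[df$qseqid]
    if (anyNA(qlen)) {
      stop("missing qlen for query ", df$qseqid[which(is.na(qlen))[1]])
    }
    df$qlen <- unname(qlen)
  } else {
    stop("qlen_source must be 'column13', 'fastq:<path>' or 'constant:<N>'")
  }
  validate_alignments(df)
  df
}

validate_alignments <- function(df) {
  stopifnot(all(df$qstart >= 1), all(df$qend >= df$qstart),
            all(df$pident >= 0 & df$pident <= 100),
            all(df$evalue >= 0))
  if (any(df$qend > df$qlen)) {
    stop("qend exceeds qlen for query ",
         df$qseqid[which(df$qend > df$qlen)[1]])
  }
  invisible(df)
}

#' Write a tabular alignment file (12 or 13 columns, no header)
#'
#' @param aln Alignment data.frame.
#' @param path Output path.
#' @param qlen Whether to emit the 13th qlen column (default TRUE when present).
#' @export
write_tabular_alignments <- function(aln, path, qlen = "qlen" %in% names(aln)) {
  cols <- if (qlen) c(ALN_COLS, "qlen") else ALN_COLS
  write.table(aln[, cols, drop = FALSE], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a virome metadata table
#'
#' TSV with header; required columns `virome_name`, `pool`, `dataset_bp`;
#' typical optional columns `country` and `sample_kind` (VLP or bulk). Unknown
#' columns are preserved.
#'
#' @param path Path to the metadata TSV.
#' @return data.frame of virome metadata.
#' @export
read_metadata <- function(path) {
  md <- read_table(path)
  for (col in c("virome_name", "pool", "dataset_bp")) {
    if (!col %in% names(md)) stop("metadata is missing required column: ", col)
  }
  md$dataset_bp <- as.numeric(md$dataset_bp)
  if (any(is.na(md$dataset_bp)) || any(md$dataset_bp <= 0)) {
    stop("dataset_bp must be a positive number for every virome")
  }
  if (any(md$pool == "")) stop("pool must be non-empty for every virome")
  md
}

#' Read / write headered TSV tables
#'
#' `write_table` and `read_table` round-trip data.frames losslessly through
#' tab-separated text. `write_table` can prepend `#`-prefixed comment lines
#' (used to echo run configuration into result files); `read_table` skips them.
#'
#' @param path File path.
#' @param rows data.frame to write.
#' @param comments Optional character vector of comment lines (without the
#'   leading `#`).
#' @return `read_table` returns a data.frame; `write_table` returns `path`.
#' @export
read_table <- function(path) {
  stopifnot(file.exists(path))
  read.delim(path, sep = "\t", quote = "", comment.char = "#",
             check.names = FALSE, stringsAsFactors = FALSE)
}

#' @rdname read_table
#' @export
write_table <- function(rows, path, comments = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comments)) writeLines(paste0("# ", comments), con)
  write.table(rows, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
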