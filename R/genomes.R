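#' Construct a genome set
#'
#' A `genome_set` bundles DNA sequences with their topology (circular or
#' linear). crAss-like phages carry circular dsDNA genomes of roughly 100 kb,
#' and circularity matters downstream: reads may span the origin and duplicate
#' detection must be rotation-aware.
#'
#' @param sequences Named character vector of uppercase DNA sequences.
#' @param circular Logical vector (recycled) flagging circular genomes.
#' @return An object of class `genome_set`.
#' @export
genome_set <- function(sequences, circular = TRUE) {
  stopifnot(is.character(sequences), length(sequences) >= 1)
  ids <- names(sequences)
  if (is.null(ids) || anyNA(ids) || any(ids == "")) {
    stop("sequences must be named by genome id")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate genome id: ", ids[duplicated(ids)][1])
  }
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad)) {
    stop("genome ", ids[bad][1], " contains non-ACGTN characters")
  }
  structure(
    list(seq = sequences,
         circular = setNames(rep_len(as.logical(circular), length(sequences)), ids)),
    class = "genome_set"
  )
}

#' @export
print.genome_set <- function(x, ...) {
  cat("genome_set with", length(x$seq), "genomes\n")
  n <- min(length(x$seq), 10L)
  for (i in seq_len(n)) {
    cat(sprintf("  %-20s %8d bp  %s\n", names(x$seq)[i], nchar(x$seq[i]),
                if (x$circular[i]) "circular" else "linear"))
  }
  if (length(x$seq) > n) cat("  ...\n")
  invisible(x)
}

#' @export
length.genome_set <- function(x) length(x$seq)

#' Genome lengths of a genome set
#'
#' @param genomes A `genome_set` or a named character vector of sequences.
#' @return Named integer vector of lengths in bases.
#' @export
genome_lengths <- function(genomes) {
  if (inherits(genomes, "genome_set")) {
    return(setNames(nchar(genomes$seq), names(genomes$seq)))
  }
  setNames(nchar(genomes), names(genomes))
}

#' Generate random reference genomes
#'
#' Draws i.i.d. bases with the requested GC content. Intended to stand in for
#' complete phage reference genomes so the whole pipeline can be exercised with
#' known ground truth.
#'
#' @param specs data.frame with columns `id`, `length`, and optionally `gc`
#'   (default 0.5) and `circular` (default TRUE).
#' @param seed Integer master seed; each genome uses a stream derived from its
#'   id, so adding genomes does not perturb existing ones.
#' @return A [genome_set()].
#' @export
#' @examples
#' gs <- generate_genomes(data.frame(id = c("gA", "gB"), length = 2000), seed = 1)
#' genome_lengths(gs)
generate_genomes <- function(specs, seed) {
  stopifnot(is.data.frame(specs), nrow(specs) >= 1,
            all(c("id", "length") %in% names(specs)))
  if (anyDuplicated(specs$id)) {
    stop("duplicate genome id: ", specs$id[duplicated(specs$id)][1])
  }
  if (any(specs$length < 1000)) stop("genome length must be >= 1000")
  gc <- if ("gc" %in% names(specs)) specs$gc else rep(0.5, nrow(specs))
  stopifnot(all(gc >= 0 & gc <= 1))
  circular <- if ("circular" %in% names(specs)) specs$circular else rep(TRUE, nrow(specs))
  seqs <- vapply(seq_len(nrow(specs)), function(i) {
    withr::with_seed(derive_seed(seed, paste0("genome:", specs$id[i])), {
      p <- c((1 - gc[i]) / 2, gc[i] / 2, gc[i] / 2, (1 - gc[i]) / 2)
      paste(sample(DNA_BASES, specs$length[i], replace = TRUE, prob = p),
            collapse = "")
    })
  }, character(1))
  genome_set(setNames(seqs, specs$id), circular = circular)
}

#' Mutate a genome by random substitutions
#'
#' Each position is substituted, independently with probability `divergence`,
#' by one of the three other bases. Substitution-only divergence keeps genome
#' length fixed, so full-length alignments between relatives have identity
#' close to `100 * (1 - divergence)` -- the regime in which the 95% species and
#' 70% genus demarcations operate.
#'
#' @param sequence DNA string.
#' @param divergence Per-base substitution probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return Mutated DNA string of the same length.
#' @export
mutate_genome <- function(sequence, divergence, seed) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  if (!is.numeric(divergence) || divergence < 0 || divergence > 1) {
    stop("divergence must be in [0, 1]")
  }
  if (divergence == 0) return(sequence)
  withr::with_seed(derive_seed(seed, "mutate"), {
    chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
    hit <- which(runif(length(chars)) < divergence)
    if (length(hit)) {
      chars[hit] <- vapply(chars[hit], function(b) {
        sample(setdiff(DNA_BASES, b), 1)
      }, character(1), USE.NAMES = FALSE)
    }
    paste(chars, collapse = "")
  })
}
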