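#' Specify a synthetic virome
#'
#' Describes one virome as a mixture of reads drawn from reference genomes at
#' controlled relative abundances and per-read identities, plus unrelated
#' background reads. Mirrors the structure of pooled gut/wastewater viromes
#' used in recruitment studies.
#'
#' @param name Virome (pool) name; also names the random stream.
#' @param abundances Named non-negative weights (genome id -> weight); weights
#'   are normalized internally.
#' @param n_reads Number of reads to draw.
#' @param read_length Read length in bases (fixed-length reads).
#' @param identity Length-2 numeric, per-read percent identity range; reads are
#'   drawn uniformly on this range (default `c(95, 100)`, the identity window
#'   of interest in recruitment plots).
#' @param background_fraction Expected fraction of reads that are random
#'   background sequence instead of genome-derived.
#' @param seed Integer seed for this virome's stream.
#' @return A list of class `virome_spec`.
#' @export
virome_spec <- function(name, abundances, n_reads, read_length = 100,
                        identity = c(95, 100), background_fraction = 0,
                        seed = 1) {
  stopifnot(is.character(name), nchar(name) > 0,
            n_reads >= 1, read_length >= 1,
            length(identity) == 2, identity[1] <= identity[2],
            identity[1] >= 0, identity[2] <= 100,
            background_fraction >= 0, background_fraction <= 1)
  if (background_fraction < 1) {
    if (is.null(names(abundances)) || !any(abundances > 0)) {
      stop("at least one positive abundance required unless background_fraction is 1")
    }
    if (any(abundances < 0)) stop("abundances must be non-negative")
  }
  structure(list(name = name, abundances = abundances, n_reads = as.integer(n_reads),
                 read_length = as.integer(read_length), identity = as.numeric(identity),
                 background_fraction = background_fraction, seed = as.integer(seed)),
            class = "virome_spec")
}

#' Simulate a virome with recorded ground truth
#'
#' Draws `n_reads` reads: each read is background (i.i.d. uniform bases) with
#' probability `background_fraction`, otherwise its source genome is drawn
#' proportionally to the normalized abundances. Genome reads are copied from a
#' uniformly random placement (circular genomes may span the origin; such
#' placements are unwrapped, i.e. `end` may exceed the genome length, and
#' flagged), on a uniformly random strand, and mutated by substitutions to a
#' per-read target identity drawn uniformly on the identity range. The implied
#' mismatch count is rounded to the nearest integer and the realized identity
#' recomputed from the actual count, so truth records are exact.
#'
#' @param genomes A [genome_set()].
#' @param spec A [virome_spec()].
#' @return List with elements `reads` (named character vector), `truth`
#'   (data.frame: read_id, source, start, end, strand, identity, n_mismatch,
#'   mm_first, spans_origin), and `dataset_bp` (total read bases).
#' @export
simulate_virome <- function(genomes, spec) {
  stopifnot(inherits(genomes, "genome_set"), inherits(spec, "virome_spec"))
  ab <- spec$abundances
  unknown <- setdiff(names(ab)[ab > 0], names(genomes$seq))
  if (length(unknown)) stop("unknown genome id in abundances: ", unknown[1])
  lens <- genome_lengths(genomes)
  rl <- spec$read_length
  for (g in names(ab)[ab > 0]) {
    if (rl > lens[[g]]) stop("read_length exceeds length of genome ", g)
  }
  n <- spec$n_reads

  withr::with_seed(derive_seed(spec$seed, paste0("virome:", spec$name)), {
    if (spec$background_fraction >= 1) {
      src <- rep("background", n)
    } else {
      pool <- names(ab)[ab > 0]
      w <- ab[pool] / sum(ab[pool])
      probs <- c(spec$background_fraction, (1 - spec$background_fraction) * w)
      src <- sample(c("background", pool), n, replace = TRUE, prob = probs)
    }

    start <- integer(n); end <- integer(n)
    strand <- rep("+", n)
    identity <- rep(NA_real_, n); nmm <- rep(NA_integer_, n)
    mm_first <- rep(NA_integer_, n); spans <- rep(FALSE, n)
    frag <- character(n)

    is_bg <- src == "background"
    if (any(is_bg)) {
      k <- sum(is_bg)
      m <- matrix(sample(DNA_BASES, k * rl, replace = TRUE), nrow = rl)
      frag[is_bg] <- do.call(paste0, lapply(seq_len(rl), function(r) m[r, , drop = TRUE]))
    }

    gi <- which(!is_bg)
    if (length(gi)) {
      strand[gi] <- sample(c("+", "-"), length(gi), replace = TRUE)
      id_target <- runif(length(gi), spec$identity[1], spec$identity[2])
      nmm[gi] <- as.integer(round(rl * (1 - id_target / 100)))
      identity[gi] <- 100 * (1 - nmm[gi] / rl)
      for (g in unique(src[gi])) {
        idx <- gi[src[gi] == g]
        L <- lens[[g]]
        if (genomes$circular[[g]]) {
          st <- sample.int(L, length(idx), replace = TRUE)
          doubled <- paste0(genomes$seq[[g]], genomes$seq[[g]])
          frag[idx] <- substring(doubled, st, st + rl - 1)
        } else {
          st <- sample.int(L - rl + 1, length(idx), replace = TRUE)
          frag[idx] <- substring(genomes$seq[[g]], st, st + rl - 1)
        }
        start[idx] <- st
        end[idx] <- st + rl - 1L
        spans[idx] <- end[idx] > L
      }
      # substitutions applied in subject orientation, then strand flip
      M <- matrix(unlist(strsplit(frag[gi], "", fixed = TRUE)), nrow = rl)
      pos_list <- lapply(nmm[gi], function(m) if (m > 0) sample.int(rl, m) else integer(0))
      cols <- rep(seq_along(gi), lengths(pos_list))
      pos <- unlist(pos_list)
      if (length(pos)) {
        idx <- (cols - 1L) * rl + pos
        alt <- matrix(c("C", "G", "T", "A", "G", "T", "A", "C", "T", "A", "C", "G"),
                      nrow = 4, byrow = TRUE)   # row b: the three bases != b
        cur <- match(M[idx], DNA_BASES)
        M[idx] <- alt[cbind(cur, sample.int(3, length(idx), replace = TRUE))]
      }
      sp_idx <- which(spans[gi])
      for (s in sp_idx) {
        i <- gi[s]
        L <- lens[[src[i]]]
        mm_first[i] <- sum(start[i] + pos_list[[s]] - 1L <= L)
      }
      minus <- which(strand[gi] == "-")
      if (length(minus)) M[, minus] <- M[rl:1, minus, drop = FALSE]
      strings <- do.call(paste0, lapply(seq_len(rl), function(r) M[r, , drop = TRUE]))
      if (length(minus)) strings[minus] <- chartr("ACGT", "TGCA", strings[minus])
      frag[gi] <- strings
    }

    read_id <- sprintf("%s_r%06d", spec$name, seq_len(n))
    truth <- data.frame(
      read_id = read_id, source = src, start = start, end = end,
      strand = strand, identity = identity, n_mismatch = nmm,
      mm_first = mm_first, spans_origin = spans,
      stringsAsFactors = FALSE
    )
    truth$start[is_bg] <- NA_integer_
    truth$end[is_bg] <- NA_integer_
    truth$strand[is_bg] <- NA_character_

    list(reads = setNames(frag, read_id), truth = truth,
         dataset_bp = as.numeric(n) * rl)
  })
}

#' Convert ground-truth placements to tabular alignment records
#'
#' Emits one full-length 13-column alignment record per non-background read
#' (background reads, being random sequence, yield no hit). Origin-spanning
#' reads on circular genomes are split into two records at the origin,
#' mirroring how a real aligner reports hits against a linearized reference.
#' The bitscore is a monotone function of (matches - mismatches).
#'
#' @param truth Truth data.frame from [simulate_virome()].
#' @param genomes The [genome_set()] used for simulation.
#' @param read_length Read length used in the simulation.
#' @return data.frame of alignment records (qseqid, sseqid, pident, length,
#'   mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore, qlen).
#' @export
truth_to_alignments <- function(truth, genomes, read_length) {
  stopifnot(is.data.frame(truth), inherits(genomes, "genome_set"))
  lens <- genome_lengths(genomes)
  tr <- truth[truth$source != "background", , drop = FALSE]
  rl <- as.integer(read_length)
  plain <- tr[!tr$spans_origin, , drop = FALSE]
  out <- list()
  if (nrow(plain)) {
    minus <- plain$strand == "-"
    out[[1]] <- data.frame(
      qseqid = plain$read_id, sseqid = plain$source,
      pident = round(plain$identity, 2), length = rl,
      mismatch = plain$n_mismatch, gapopen = 0L,
      qstart = 1L, qend = rl,
      sstart = ifelse(minus, plain$end, plain$start),
      send = ifelse(minus, plain$start, plain$end),
      evalue = 0, bitscore = 2 * (rl - 2 * plain$n_mismatch),
      qlen = rl, stringsAsFactors = FALSE)
  }
  span <- tr[tr$spans_origin, , drop = FALSE]
  for (i in seq_len(nrow(span))) {
    r <- span[i, ]
    L <- lens[[r$source]]
    {
      l1 <- L - r$start + 1L              # bases before the origin
      l2 <- rl - l1
      mm1 <- r$mm_first
      mm2 <- r$n_mismatch - mm1
      p1 <- 100 * (1 - mm1 / l1)
      p2 <- 100 * (1 - mm2 / l2)
      if (r$strand == "+") {
        a <- aln_row(r$read_id, r$source, p1, l1, mm1, 1L, l1, r$start, L, "+", rl)
        b <- aln_row(r$read_id, r$source, p2, l2, mm2, l1 + 1L, rl, 1L, l2, "+", rl)
      } else {
        # read runs from subject end back to start
        a <- aln_row(r$read_id, r$source, p2, l2, mm2, 1L, l2, 1L, l2, "-", rl)
        b <- aln_row(r$read_id, r$source, p1, l1, mm1, l2 + 1L, rl, r$start, L, "-", rl)
      }
      out[[length(out) + 1]] <- rbind(a, b)
    }
  }
  if (!length(out)) return(empty_alignments())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

aln_row <- function(qid, sid, pident, len, mm, qs, qe, ss, se, strand, qlen) {
  if (strand == "-") { tmp <- ss; ss <- se; se <- tmp }
  data.frame(qseqid = qid, sseqid = sid, pident = round(pident, 2),
             length = len, mismatch = mm, gapopen = 0L,
             qstart = qs, qend = qe, sstart = ss, send = se,
             evalue = 0, bitscore = 2 * (len - 2 * mm),
             qlen = qlen, stringsAsFactors = FALSE)
}

empty_alignments <- function() {
  data.frame(qseqid = character(), sseqid = character(), pident = numeric(),
             length = integer(), mismatch = integer(), gapopen = integer(),
             qstart = integer(), qend = integer(), sstart = integer(),
             send = integer(), evalue = numeric(), bitscore = numeric(),
             qlen = integer(), stringsAsFactors = FALSE)
}
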