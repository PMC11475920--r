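#' Collapse identical (possibly circularly permuted) genomes
#'
#' Two genomes are duplicates when they have equal length and one sequence (or
#' its reverse complement) is a substring of the other's doubled sequence --
#' the rotation-aware identity test that plain 100%-identity clustering
#' misses for circularly permuted assemblies of the same phage. One
#' representative (the lexicographically smallest id) is kept per duplicate
#' set.
#'
#' @param genomes A [genome_set()] or named character vector of sequences.
#' @return List with `representatives` (named character vector) and
#'   `duplicate_of` (named character vector mapping each removed id to its
#'   representative).
#' @export
dedupe_identical <- function(genomes) {
  seqs <- if (inherits(genomes, "genome_set")) genomes$seq else genomes
  ids <- names(seqs)
  parent <- setNames(ids, ids)
  find <- function(i) { while (parent[[i]] != i) i <- parent[[i]]; i }
  n <- length(seqs)
  lens <- nchar(seqs)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (lens[i] != lens[j]) next
      if (find(ids[i]) == find(ids[j])) next
      doubled <- strrep(seqs[[i]], 2)
      if (grepl(seqs[[j]], doubled, fixed = TRUE) ||
          grepl(reverse_complement(seqs[[j]]), doubled, fixed = TRUE)) {
        a <- find(ids[i]); b <- find(ids[j])
        # representative: lexicographically smallest id in the set
        if (a < b) parent[[b]] <- a else parent[[a]] <- b
      }
    }
  }
  rep_of <- vapply(ids, find, character(1))
  reps <- sort(unique(rep_of))
  list(representatives = seqs[reps],
       duplicate_of = rep_of[rep_of != ids])
}

#' Anchor-based ungapped pairwise alignment fragments
#'
#' A light-weight exact k-mer anchor aligner: shared k-mers between the two
#' sequences (both orientations) are grouped by diagonal, and each diagonal
#' supported by at least `min_anchors` anchors yields one ungapped fragment
#' spanning its anchors, with identical bases counted by direct comparison.
#' Sufficient for substitution-divergent genomes (including circularly
#' permuted ones, which split across two diagonals); fragments from an
#' external aligner's tabular output can be used instead wherever a fragment
#' table is accepted.
#'
#' @param a,b DNA strings.
#' @param k Anchor k-mer size (default 12).
#' @param min_anchors Minimum anchors per diagonal (default 2; screens out
#'   chance k-mer matches).
#' @return data.frame of fragments: `qstart`, `qend`, `sstart`, `send`
#'   (sstart > send on the minus strand), `length`, `ident` (identical
#'   bases), `score`.
#' @export
align_fragments <- function(a, b, k = 12, min_anchors = 2) {
  fw <- anchor_fragments(a, b, k, min_anchors)
  rc <- anchor_fragments(a, reverse_complement(b), k, min_anchors)
  if (nrow(rc)) {
    nb <- nchar(b)
    tmp <- nb - rc$sstart + 1
    rc$sstart <- nb - rc$send + 1
    rc$send <- tmp
    # store as minus strand: sstart > send
    sw <- rc$sstart < rc$send
    if (any(sw)) {
      t2 <- rc$sstart[sw]; rc$sstart[sw] <- rc$send[sw]; rc$send[sw] <- t2
    }
  }
  out <- rbind(fw, rc)
  out[order(-out$score), , drop = FALSE]
}

anchor_fragments <- function(a, b, k, min_anchors) {
  na <- nchar(a); nb <- nchar(b)
  empty <- data.frame(qstart = integer(), qend = integer(), sstart = integer(),
                      send = integer(), length = integer(), ident = integer(),
                      score = numeric())
  if (na < k || nb < k) return(empty)
  ka <- substring(a, 1:(na - k + 1), k:na)
  kb <- substring(b, 1:(nb - k + 1), k:nb)
  m <- match(kb, ka)
  hit <- which(!is.na(m))
  if (!length(hit)) return(empty)
  off <- m[hit] - hit                     # posA = posB + off
  rows <- lapply(split(hit, off), function(pb) {
    if (length(pb) < min_anchors) return(NULL)
    o <- m[pb][1] - pb[1]
    ss <- min(pb); se <- max(pb) + k - 1
    qs <- ss + o; qe <- se + o
    fa <- strsplit(substring(a, qs, qe), "", fixed = TRUE)[[1]]
    fb <- strsplit(substring(b, ss, se), "", fixed = TRUE)[[1]]
    ident <- sum(fa == fb)
    len <- qe - qs + 1
    data.frame(qstart = qs, qend = qe, sstart = ss, send = se,
               length = len, ident = ident,
               score = 2 * ident - 3 * (len - ident))
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) return(empty)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Trim fragments so no base is counted twice
#'
#' Fragments are admitted greedily by descending score; each later fragment is
#' trimmed to the positions not yet covered on either genome, with its
#' identical-base count rescaled proportionally to the retained length. This
#' makes the intergenomic-similarity formula well defined on any raw fragment
#' set.
#'
#' @param frags Fragment data.frame (see [align_fragments()]).
#' @return Non-overlapping fragment data.frame.
#' @export
resolve_overlaps <- function(frags) {
  if (nrow(frags) <= 1) return(frags)
  frags <- frags[order(-frags$score), , drop = FALSE]
  covA <- IRanges::IRanges(); covB <- IRanges::IRanges()
  out <- list()
  for (i in seq_len(nrow(frags))) {
    f <- frags[i, ]
    minus <- f$sstart > f$send
    blo <- min(f$sstart, f$send); bhi <- max(f$sstart, f$send)
    freeA <- IRanges::setdiff(IRanges::IRanges(f$qstart, f$qend), covA)
    freeB <- IRanges::setdiff(IRanges::IRanges(blo, bhi), covB)
    if (length(freeB)) {
      # map B-free ranges into A coordinates (ungapped, fixed offset)
      bs <- IRanges::start(freeB); be <- IRanges::end(freeB)
      if (!minus) {
        mapped <- IRanges::IRanges(f$qstart + (bs - blo), f$qstart + (be - blo))
      } else {
        mapped <- IRanges::IRanges(f$qstart + (bhi - be), f$qstart + (bhi - bs))
      }
    } else mapped <- IRanges::IRanges()
    allowed <- IRanges::intersect(freeA, mapped)
    if (!length(allowed)) next
    as_ <- IRanges::start(allowed); ae <- IRanges::end(allowed)
    for (j in seq_along(allowed)) {
      newlen <- ae[j] - as_[j] + 1
      if (!minus) {
        ss <- blo + (as_[j] - f$qstart); se <- blo + (ae[j] - f$qstart)
      } else {
        ss <- f$sstart - (as_[j] - f$qstart); se <- f$sstart - (ae[j] - f$qstart)
      }
      scale <- newlen / f$length
      out[[length(out) + 1]] <- data.frame(
        qstart = as_[j], qend = ae[j], sstart = ss, send = se,
        length = newlen, ident = f$ident * scale, score = f$score * scale)
      covB <- IRanges::union(covB, IRanges::IRanges(min(ss, se), max(ss, se)))
    }
    covA <- IRanges::union(covA, allowed)
  }
  if (!length(out)) return(frags[0, , drop = FALSE])
  do.call(rbind, out)
}

#' Intergenomic similarity from non-overlapping fragments
#'
#' The VIRIDIC-style statistic: `100 * 2 * (sum of identical bases) /
#' (lenA + lenB)`, together with the aligned fraction of each genome.
#'
#' @param frags Non-overlapping fragment data.frame.
#' @param lenA,lenB Genome lengths.
#' @return List with `similarity` (percent) and `aligned_fraction_A`,
#'   `aligned_fraction_B`.
#' @export
pairwise_similarity <- function(frags, lenA, lenB) {
  if (nrow(frags)) {
    blo <- pmin(frags$sstart, frags$send); bhi <- pmax(frags$sstart, frags$send)
    if (any(frags$qstart < 1) || any(frags$qend > lenA) ||
        any(blo < 1) || any(bhi > lenB)) {
      stop("fragment coordinates outside genome bounds")
    }
    sim <- 100 * 2 * sum(frags$ident) / (lenA + lenB)
    afa <- sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(frags$qstart, frags$qend)))) / lenA
    afb <- sum(IRanges::width(IRanges::reduce(IRanges::IRanges(blo, bhi)))) / lenB
  } else {
    sim <- 0; afa <- 0; afb <- 0
  }
  list(similarity = min(sim, 100), aligned_fraction_A = afa,
       aligned_fraction_B = afb)
}

#' All-vs-all intergenomic similarity matrix
#'
#' Runs the built-in anchor aligner on every genome pair, trims overlaps, and
#' assembles the symmetric similarity matrix (diagonal 100) plus the
#' aligned-fraction matrix (`aligned_fraction[i, j]` = fraction of genome i
#' aligned in its comparison with genome j).
#'
#' @param genomes A [genome_set()] or named character vector.
#' @param k,min_anchors Passed to [align_fragments()].
#' @return Object of class `intergenomic_similarity`: list with `similarity`
#'   and `aligned_fraction` matrices.
#' @export
intergenomic_similarity <- function(genomes, k = 12, min_anchors = 2) {
  seqs <- if (inherits(genomes, "genome_set")) genomes$seq else genomes
  ids <- names(seqs)
  n <- length(seqs)
  sim <- matrix(0, n, n, dimnames = list(ids, ids))
  af <- matrix(0, n, n, dimnames = list(ids, ids))
  diag(sim) <- 100; diag(af) <- 1
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        fr <- resolve_overlaps(align_fragments(seqs[[i]], seqs[[j]], k, min_anchors))
        ps <- pairwise_similarity(fr, nchar(seqs[[i]]), nchar(seqs[[j]]))
        sim[i, j] <- sim[j, i] <- ps$similarity
        af[i, j] <- ps$aligned_fraction_A
        af[j, i] <- ps$aligned_fraction_B
      }
    }
  }
  structure(list(similarity = sim, aligned_fraction = af),
            class = "intergenomic_similarity")
}

#' @export
print.intergenomic_similarity <- function(x, ...) {
  cat("intergenomic similarity over", nrow(x$similarity), "genomes\n")
  print(round(x$similarity, 1))
  invisible(x)
}

#' Threshold clustering of a similarity matrix
#'
#' Single-linkage clusters: connected components of the graph whose edges join
#' genome pairs with similarity at or above the threshold. With the 95%
#' species and 70% genus demarcations this reproduces the standard viral
#' taxonomy binning; note that chaining can merge borderline species.
#'
#' @param sim An `intergenomic_similarity` object or a symmetric similarity
#'   matrix in percent.
#' @param threshold Similarity threshold in percent (edges at `>=` threshold).
#' @param rank Optional label for the clustering rank (e.g. "species",
#'   "genus").
#' @return List of class `taxon_clusters` with `threshold`, `rank`,
#'   `clusters` (list of id sets) and `membership` (named integer vector).
#' @export
threshold_clusters <- function(sim, threshold, rank = NULL) {
  m <- if (inherits(sim, "intergenomic_similarity")) sim$similarity else sim
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  adj <- (m >= threshold) * 1
  diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  membership <- comp$membership
  clusters <- unname(split(names(membership), membership))
  clusters <- clusters[order(vapply(clusters, min, character(1)))]
  membership <- setNames(rep(seq_along(clusters), lengths(clusters)),
                         unlist(clusters))[rownames(m)]
  structure(list(threshold = threshold, rank = rank, clusters = clusters,
                 membership = membership),
            class = "taxon_clusters")
}

#' @export
print.taxon_clusters <- function(x, ...) {
  cat(length(x$clusters), if (is.null(x$rank)) "clusters" else paste0(x$rank, " clusters"),
      "at threshold", x$threshold, "%\n")
  for (cl in x$clusters) cat("  {", paste(cl, collapse = ", "), "}\n")
  invisible(x)
}
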