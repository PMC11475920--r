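#' Recruitment filter configuration
#'
#' Holds the alignment-filtering and detection constants of the recruitment
#' analysis: reads must align over at least 70% of their length with an
#' e-value of at most 0.1, each read keeps only its best hit, recruitment
#' plots show the 95-100% identity window, and a genome counts as detected in
#' a virome when its normalized abundance reaches 1e-5 SD/Gbp/Kbp.
#'
#' @param min_query_coverage Minimum aligned fraction of the read (default 0.70,
#'   boundary inclusive).
#' @param max_evalue Maximum e-value (default 0.1, boundary inclusive).
#' @param plot_identity_window Percent-identity window of the recruitment plot
#'   (default `c(95, 100)`).
#' @param detection_threshold Normalized-abundance detection limit in
#'   SD/Gbp/Kbp (default 1e-5).
#' @param anir_weighting `"length"` (identity weighted by aligned length, the
#'   standard ANIr definition) or `"uniform"` (plain mean over reads).
#' @return List of class `filter_config`.
#' @export
filter_config <- function(min_query_coverage = 0.70, max_evalue = 0.1,
                          plot_identity_window = c(95, 100),
                          detection_threshold = 1e-5,
                          anir_weighting = c("length", "uniform")) {
  stopifnot(min_query_coverage > 0, min_query_coverage <= 1,
            max_evalue >= 0, length(plot_identity_window) == 2,
            plot_identity_window[1] <= plot_identity_window[2],
            detection_threshold >= 0)
  structure(list(min_query_coverage = min_query_coverage,
                 max_evalue = max_evalue,
                 plot_identity_window = as.numeric(plot_identity_window),
                 detection_threshold = detection_threshold,
                 anir_weighting = match.arg(anir_weighting)),
            class = "filter_config")
}

#' Query coverage of alignment records
#'
#' Fraction of the read covered by the alignment, `(qend - qstart + 1) / qlen`,
#' clamped to at most 1.
#'
#' @param aln Alignment data.frame with resolved `qlen`.
#' @return Numeric vector of coverages in `(0, 1]`.
#' @export
query_coverage <- function(aln) {
  if (is.null(aln$qlen) || anyNA(aln$qlen)) stop("qlen not resolved")
  pmin((aln$qend - aln$qstart + 1) / aln$qlen, 1)
}

#' Keep each read's best hit
#'
#' For each query keeps the single hit with maximal bitscore; ties are broken
#' by higher percent identity, then lexicographically smaller subject id, then
#' subject coordinates, so the result is independent of input order.
#'
#' @param aln Alignment data.frame.
#' @return Alignment data.frame with one row per `qseqid`.
#' @export
best_hit <- function(aln) {
  if (nrow(aln) == 0) return(aln)
  o <- order(aln$qseqid, -aln$bitscore, -aln$pident, aln$sseqid,
             aln$sstart, aln$send, method = "radix")
  aln <- aln[o, , drop = FALSE]
  aln[!duplicated(aln$qseqid), , drop = FALSE]
}

#' Filter hits on query coverage and e-value
#'
#' Keeps records with query coverage at least `min_query_coverage` and e-value
#' at most `max_evalue` (both boundaries inclusive); input order is preserved.
#'
#' @param aln Alignment data.frame with resolved `qlen`.
#' @param cfg A [filter_config()].
#' @return Filtered alignment data.frame.
#' @export
filter_hits <- function(aln, cfg = filter_config()) {
  if (nrow(aln) == 0) return(aln)
  keep <- query_coverage(aln) >= cfg$min_query_coverage & aln$evalue <= cfg$max_evalue
  aln[keep, , drop = FALSE]
}

#' Apply the full hit-filtering chain
#'
#' Coverage/e-value filter first, then best-hit resolution among the surviving
#' hits.
#'
#' @inheritParams filter_hits
#' @return Filtered, best-hit-resolved alignment data.frame.
#' @export
apply_filters <- function(aln, cfg = filter_config()) {
  best_hit(filter_hits(aln, cfg))
}

subject_spans <- function(aln) {
  lo <- pmin(aln$sstart, aln$send)
  hi <- pmax(aln$sstart, aln$send)
  list(lo = lo, hi = hi, width = hi - lo + 1)
}

#' Sequencing depth (SD) of a genome
#'
#' Mean per-base depth: the summed aligned subject span of all hits divided by
#' the genome length. Spans are measured on the subject as
#' `|send - sstart| + 1` regardless of strand.
#'
#' @param aln Hits targeting one genome.
#' @param genome_length Genome length in bases.
#' @return Numeric depth (x coverage).
#' @export
sequencing_depth <- function(aln, genome_length) {
  if (genome_length <= 0) stop("genome_length must be positive")
  if (nrow(aln) == 0) return(0)
  sum(subject_spans(aln)$width) / genome_length
}

#' Normalize sequencing depth by dataset size and genome length
#'
#' The comparative abundance unit of the analysis: SD divided by the dataset
#' size in Gbp and by the genome length in Kbp (SD/Gbp/Kbp). Note SD already
#' divides once by genome length; the extra Kbp division is applied exactly as
#' the unit is defined. Set `per_kbp = FALSE` for plain SD/Gbp.
#'
#' @param depth_SD Sequencing depth from [sequencing_depth()].
#' @param dataset_bp Total bases in the virome dataset.
#' @param genome_length Genome length in bases.
#' @param per_kbp Also divide by genome length in Kbp (default TRUE).
#' @return Normalized abundance.
#' @export
normalize_abundance <- function(depth_SD, dataset_bp, genome_length,
                                per_kbp = TRUE) {
  if (any(dataset_bp <= 0)) stop("dataset_bp must be positive")
  out <- depth_SD / (dataset_bp / 1e9)
  if (per_kbp) out <- out / (genome_length / 1e3)
  out
}

#' Average nucleotide identity of mapped reads (ANIr)
#'
#' Identity of the recruited (already filtered) reads, either weighted by
#' aligned length (the standard ANIr definition, default) or as a plain mean
#' over reads. `NA` when there are no hits.
#'
#' @param aln Filtered hits targeting one genome.
#' @param weighting `"length"` or `"uniform"`.
#' @return Percent identity, or `NA_real_` with no hits.
#' @export
anir <- function(aln, weighting = c("length", "uniform")) {
  weighting <- match.arg(weighting)
  if (nrow(aln) == 0) return(NA_real_)
  if (weighting == "length") {
    sum(aln$pident * aln$length) / sum(aln$length)
  } else {
    mean(aln$pident)
  }
}

#' Horizontal genome coverage (breadth)
#'
#' Percentage of genome positions covered by at least one hit; overlapping
#' hits are counted once (interval union).
#'
#' @param aln Hits targeting one genome.
#' @param genome_length Genome length in bases.
#' @return Percent of positions covered, in `[0, 100]`.
#' @export
horizontal_coverage <- function(aln, genome_length) {
  if (genome_length <= 0) stop("genome_length must be positive")
  if (nrow(aln) == 0) return(0)
  sp <- subject_spans(aln)
  if (any(sp$hi > genome_length)) {
    stop("subject interval exceeds genome length (unwrap circular hits upstream)")
  }
  ir <- IRanges::reduce(IRanges::IRanges(start = sp$lo, end = sp$hi))
  100 * sum(IRanges::width(ir)) / genome_length
}

#' Recruitment-plot profile
#'
#' One row per hit inside the identity window: subject midpoint position vs
#' percent identity, the classic fragment-recruitment plot. Hits outside the
#' window are excluded from the plot table only, never from metrics.
#'
#' @param aln Filtered hits.
#' @param window Length-2 identity window in percent (default `c(95, 100)`,
#'   boundaries inclusive).
#' @return data.frame with columns `sseqid`, `position`, `pident`.
#' @export
recruitment_profile <- function(aln, window = c(95, 100)) {
  keep <- aln$pident >= window[1] & aln$pident <= window[2]
  aln <- aln[keep, , drop = FALSE]
  sp <- subject_spans(aln)
  out <- data.frame(sseqid = aln$sseqid, position = (sp$lo + sp$hi) / 2,
                    pident = aln$pident, stringsAsFactors = FALSE)
  if (!is.null(aln$virome)) out$virome <- aln$virome
  out
}

#' Detection call from normalized abundance
#'
#' A genome is detected when its normalized abundance reaches the detection
#' threshold (boundary inclusive).
#'
#' @param norm_abundance Normalized abundance(s), SD/Gbp/Kbp.
#' @param cfg A [filter_config()].
#' @return Logical vector.
#' @export
detection_call <- function(norm_abundance, cfg = filter_config()) {
  norm_abundance >= cfg$detection_threshold
}

#' Per-genome recruitment metrics for one hit set
#'
#' Applies the filter chain and computes, for every genome in
#' `genome_lengths`, the read count, sequencing depth, normalized abundance,
#' ANIr, horizontal coverage and detection call.
#'
#' @param aln Raw alignment records (qlen resolved).
#' @param genome_lengths Named vector of genome lengths.
#' @param dataset_bp Total dataset size in bases.
#' @param cfg A [filter_config()].
#' @param prefiltered Set TRUE if `aln` already went through [apply_filters()].
#' @return data.frame, one row per genome: `genome_id`, `n_reads`, `depth_SD`,
#'   `norm_abundance`, `anir`, `horizontal_coverage`, `detected`.
#' @export
recruitment_metrics <- function(aln, genome_lengths, dataset_bp,
                                cfg = filter_config(), prefiltered = FALSE) {
  if (!prefiltered) aln <- apply_filters(aln, cfg)
  out <- lapply(names(genome_lengths), function(g) {
    h <- aln[aln$sseqid == g, , drop = FALSE]
    L <- genome_lengths[[g]]
    sd_ <- sequencing_depth(h, L)
    na_ <- normalize_abundance(sd_, dataset_bp, L)
    data.frame(genome_id = g,
               n_reads = length(unique(h$qseqid)),
               depth_SD = sd_,
               norm_abundance = na_,
               anir = anir(h, cfg$anir_weighting),
               horizontal_coverage = horizontal_coverage(h, L),
               detected = detection_call(na_, cfg),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Recruit viromes against a genome set
#'
#' Computes per-(genome, virome) recruitment metrics and, in addition,
#' per-(genome, pool) metrics obtained by recomputing over the concatenated
#' hits of each pool with the pool's summed dataset size (pooling by origin,
#' not averaging of per-virome values).
#'
#' @param aln Alignment records carrying a `virome` column naming the source
#'   virome of each hit.
#' @param metadata Virome metadata (see [read_metadata()]).
#' @param genome_lengths Named vector of genome lengths (or a [genome_set()]).
#' @param cfg A [filter_config()].
#' @return data.frame of metrics with columns `level` ("virome" or "pool"),
#'   `unit` (the virome or pool name) and the [recruitment_metrics()] columns.
#' @export
recruit <- function(aln, metadata, genome_lengths, cfg = filter_config()) {
  if (inherits(genome_lengths, "genome_set")) {
    genome_lengths <- genome_lengths(genome_lengths)
  }
  if (nrow(aln) > 0 && is.null(aln$virome)) {
    stop("alignment table must carry a 'virome' column")
  }
  flt <- apply_filters(aln, cfg)
  per_unit <- function(level, unit, hits, bp) {
    cbind(data.frame(level = level, unit = unit, stringsAsFactors = FALSE),
          recruitment_metrics(hits, genome_lengths, bp, cfg, prefiltered = TRUE))
  }
  rows <- lapply(seq_len(nrow(metadata)), function(i) {
    v <- metadata$virome_name[i]
    per_unit("virome", v, flt[flt$virome == v, , drop = FALSE],
             metadata$dataset_bp[i])
  })
  for (p in unique(metadata$pool)) {
    vs <- metadata$virome_name[metadata$pool == p]
    rows[[length(rows) + 1]] <-
      per_unit("pool", p, flt[flt$virome %in% vs, , drop = FALSE],
               sum(metadata$dataset_bp[metadata$pool == p]))
  }
  do.call(rbind, rows)
}

#' Pivot pool-level metrics into a phage x pool coverage matrix
#'
#' @param metrics Output of [recruit()].
#' @param value Metric column to pivot (default `"horizontal_coverage"`).
#' @param level Which rows to use (default `"pool"`).
#' @return Numeric matrix, genomes x units.
#' @export
coverage_matrix <- function(metrics, value = "horizontal_coverage",
                            level = "pool") {
  m <- metrics[metrics$level == level, , drop = FALSE]
  units <- sort(unique(m$unit))
  ids <- sort(unique(m$genome_id))
  out <- matrix(NA_real_, nrow = length(ids), ncol = length(units),
                dimnames = list(ids, units))
  out[cbind(match(m$genome_id, ids), match(m$unit, units))] <- m[[value]]
  out
}
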