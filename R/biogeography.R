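#' Pool recruitment by country
#'
#' Aggregates per-virome hits into per-country abundance profiles by
#' recomputing sequencing depth over each country cohort's concatenated hits
#' with the cohort's summed dataset size (pooling by origin, never averaging
#' per-virome values). Cohorts are keyed by the metadata `pool` field, so a
#' country with several cohorts keeps them distinct (e.g. "USA 1" / "USA 2").
#' Within a cohort, each detected phage's share is its percentage of the
#' summed abundance of all detected phages; phages below the detection
#' threshold contribute zero.
#'
#' @param aln Alignment records with a `virome` column.
#' @param metadata Virome metadata with a `country` column.
#' @param genome_lengths Named vector of genome lengths (or a [genome_set()]).
#' @param cfg A [filter_config()].
#' @return data.frame with one row per (cohort, phage): `pool`, `country`,
#'   `genome_id`, `norm_abundance`, `share`, `detected`, `n_metagenomes`,
#'   `n_metagenomes_with_detection`.
#' @export
pool_by_country <- function(aln, metadata, genome_lengths,
                            cfg = filter_config()) {
  if (inherits(genome_lengths, "genome_set")) {
    genome_lengths <- genome_lengths(genome_lengths)
  }
  if (!"country" %in% names(metadata)) stop("metadata lacks a 'country' column")
  miss <- is.na(metadata$country) | metadata$country == ""
  if (any(miss)) {
    warning("excluding ", sum(miss), " virome(s) with missing country: ",
            paste(metadata$virome_name[miss], collapse = ", "))
    metadata <- metadata[!miss, , drop = FALSE]
  }
  flt <- apply_filters(aln, cfg)
  out <- lapply(unique(metadata$pool), function(p) {
    md <- metadata[metadata$pool == p, , drop = FALSE]
    hits <- flt[flt$virome %in% md$virome_name, , drop = FALSE]
    m <- recruitment_metrics(hits, genome_lengths, sum(md$dataset_bp), cfg,
                             prefiltered = TRUE)
    det_sum <- sum(m$norm_abundance[m$detected])
    share <- ifelse(m$detected & det_sum > 0,
                    100 * m$norm_abundance / det_sum, 0)
    per_v <- vapply(md$virome_name, function(v) {
      mv <- recruitment_metrics(flt[flt$virome == v, , drop = FALSE],
                                genome_lengths,
                                md$dataset_bp[md$virome_name == v], cfg,
                                prefiltered = TRUE)
      any(mv$detected)
    }, logical(1))
    data.frame(pool = p, country = md$country[1], genome_id = m$genome_id,
               norm_abundance = m$norm_abundance, share = share,
               detected = m$detected,
               n_metagenomes = nrow(md),
               n_metagenomes_with_detection = sum(per_v),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Prevalence of detection across metagenomes
#'
#' Fraction of metagenomes in which at least one phage is detected, with the
#' complement reported as below the detection limits.
#'
#' @param aln Alignment records with a `virome` column.
#' @param metadata Virome metadata.
#' @param genome_lengths Named genome lengths (or a [genome_set()]).
#' @param cfg A [filter_config()].
#' @return List with `n_total`, `n_detected`, `prevalence_pct`,
#'   `below_detection_pct`.
#' @export
prevalence <- function(aln, metadata, genome_lengths, cfg = filter_config()) {
  if (inherits(genome_lengths, "genome_set")) {
    genome_lengths <- genome_lengths(genome_lengths)
  }
  flt <- apply_filters(aln, cfg)
  det <- vapply(seq_len(nrow(metadata)), function(i) {
    m <- recruitment_metrics(
      flt[flt$virome == metadata$virome_name[i], , drop = FALSE],
      genome_lengths, metadata$dataset_bp[i], cfg, prefiltered = TRUE)
    any(m$detected)
  }, logical(1))
  n <- nrow(metadata)
  list(n_total = n, n_detected = sum(det),
       prevalence_pct = percent_of(sum(det), n),
       below_detection_pct = percent_of(n - sum(det), n))
}

#' Rank phages by pooled abundance
#'
#' Global ranking by total pooled abundance across cohorts (ties broken by
#' phage id), plus the top phage within each cohort.
#'
#' @param profiles Output of [pool_by_country()].
#' @return List with `global` (data.frame genome_id, total_abundance, rank)
#'   and `top_by_pool` (named character vector, cohort -> top phage).
#' @export
rank_phages <- function(profiles) {
  stopifnot(nrow(profiles) >= 1)
  tot <- tapply(profiles$norm_abundance, profiles$genome_id, sum)
  ids <- names(tot)
  o <- order(-unname(tot), ids)
  global <- data.frame(genome_id = ids[o], total_abundance = unname(tot)[o],
                       rank = seq_along(o), stringsAsFactors = FALSE)
  top_by_pool <- vapply(split(profiles, profiles$pool), function(d) {
    d$genome_id[order(-d$norm_abundance, d$genome_id)][1]
  }, character(1))
  list(global = global, top_by_pool = top_by_pool)
}
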