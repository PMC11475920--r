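#' Read, validate and write run configuration
#'
#' A single hierarchical YAML file is the source of truth for every numeric
#' constant of a run: the simulation layout (`genomes`, `viromes`), the
#' recruitment filter block, the specificity thresholds and pool roles, and
#' the species/genus similarity thresholds. Missing optional blocks are filled
#' with package defaults; missing required keys raise an error naming the key.
#'
#' @param path Path to a YAML config file.
#' @param config Config list (for `write_run_config`).
#' @return `read_run_config` returns a validated config list.
#' @export
read_run_config <- function(path) {
  stopifnot(file.exists(path))
  validate_run_config(yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname read_run_config
#' @export
validate_run_config <- function(config) {
  for (key in c("seed", "genomes", "viromes")) {
    if (is.null(config[[key]])) stop("config is missing required key: ", key)
  }
  for (v in config$viromes) {
    for (key in c("name", "pool", "n_reads")) {
      if (is.null(v[[key]])) stop("virome config is missing required key: ", key)
    }
  }
  f <- config$filter %||% list()
  config$filter_config <- filter_config(
    min_query_coverage = f$min_query_coverage %||% 0.70,
    max_evalue = f$max_evalue %||% 0.1,
    plot_identity_window = unlist(f$plot_identity_window %||% c(95, 100)),
    detection_threshold = f$detection_threshold %||% 1e-5,
    anir_weighting = f$anir_weighting %||% "length")
  s <- config$specificity %||% list()
  config$specificity <- list(threshold = s$threshold %||% 40,
                             human_pools = unlist(s$human_pools),
                             animal_pools = unlist(s$animal_pools))
  sim <- config$similarity %||% list()
  config$similarity <- list(species_threshold = sim$species_threshold %||% 95,
                            genus_threshold = sim$genus_threshold %||% 70)
  config
}

config_comments <- function(config, keys) {
  vapply(keys, function(k) paste0(k, " = ", paste(unlist(config[[k]]), collapse = ",")),
         character(1))
}

update_manifest <- function(dir, files) {
  path <- file.path(dir, "manifest.json")
  manifest <- if (file.exists(path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    list(package = "crassrecruit",
         version = as.character(utils::packageVersion("crassrecruit")),
         files = list())
  }
  sums <- tools::md5sum(file.path(dir, files))
  manifest$files <- utils::modifyList(as.list(manifest$files),
                                      as.list(setNames(unname(sums), files)))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Simulate a study: genomes, viromes, truth, alignments
#'
#' Generates (or loads) the reference genomes, simulates every virome in the
#' config, and writes the full set of study files to `dir`: `genomes.fasta`,
#' per-virome FASTQ reads, truth TSVs and 13-column alignment tables,
#' `metadata.tsv`, and a JSON manifest with MD5 checksums of every emitted
#' file. Reruns with the same config and seed are byte-identical.
#'
#' @param config Run config (list from [read_run_config()] or built in code).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
run_simulate <- function(config, dir) {
  config <- validate_run_config(config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  g <- config$genomes
  genomes <- if (!is.null(g$fasta)) {
    fa <- read_fasta(g$fasta)
    genome_set(setNames(fa$sequence, fa$id), circular = g$circular %||% TRUE)
  } else {
    specs <- data.frame(id = g$ids %||% sprintf("phage%02d", seq_len(g$n)),
                        length = g$length %||% 100000,
                        gc = g$gc %||% 0.45,
                        circular = g$circular %||% TRUE)
    generate_genomes(specs, seed = config$seed)
  }
  write_fasta(genomes, file.path(dir, "genomes.fasta"))
  files <- "genomes.fasta"
  md <- list()
  for (v in config$viromes) {
    spec <- virome_spec(name = v$name,
                        abundances = unlist(v$abundances) %||% numeric(),
                        n_reads = v$n_reads,
                        read_length = v$read_length %||% 100,
                        identity = unlist(v$identity %||% c(95, 100)),
                        background_fraction = v$background_fraction %||% 0,
                        seed = config$seed)
    sim <- simulate_virome(genomes, spec)
    aln <- truth_to_alignments(sim$truth, genomes, spec$read_length)
    write_fastq(sim$reads, file.path(dir, paste0("reads_", v$name, ".fastq")))
    write_table(sim$truth, file.path(dir, paste0("truth_", v$name, ".tsv")))
    write_tabular_alignments(aln, file.path(dir, paste0("alignments_", v$name, ".tsv")))
    files <- c(files, paste0(c("reads_", "truth_", "alignments_"), v$name,
                             c(".fastq", ".tsv", ".tsv")))
    md[[length(md) + 1]] <- data.frame(
      virome_name = v$name, pool = v$pool, country = v$country %||% "",
      dataset_bp = sim$dataset_bp, sample_kind = v$sample_kind %||% "VLP",
      stringsAsFactors = FALSE)
    log_msg("simulated virome ", v$name, ": ", spec$n_reads, " reads, ",
            nrow(aln), " alignment records")
  }
  write_table(do.call(rbind, md), file.path(dir, "metadata.tsv"))
  files <- c(files, "metadata.tsv")
  invisible(update_manifest(dir, files))
}

load_alignments_dir <- function(dir, metadata) {
  rows <- lapply(metadata$virome_name, function(v) {
    p <- file.path(dir, paste0("alignments_", v, ".tsv"))
    aln <- read_tabular_alignments(p, "column13")
    if (nrow(aln)) aln$virome <- v else aln$virome <- character(0)
    aln
  })
  do.call(rbind, rows)
}

#' Compute recruitment metrics and plot profiles for a simulated study
#'
#' Reads the alignments and metadata written by [run_simulate()] (or by an
#' external aligner following the same layout), computes per-virome and
#' per-pool recruitment metrics, and writes `metrics.tsv` and the plot-ready
#' `profile.tsv` restricted to the configured identity window.
#'
#' @param config Run config.
#' @param dir Study directory.
#' @return Invisibly, the metrics data.frame.
#' @export
run_recruit <- function(config, dir) {
  config <- validate_run_config(config)
  cfg <- config$filter_config
  metadata <- read_metadata(file.path(dir, "metadata.tsv"))
  fa <- read_fasta(file.path(dir, "genomes.fasta"))
  lens <- setNames(fa$length, fa$id)
  aln <- load_alignments_dir(dir, metadata)
  log_msg("loaded ", nrow(aln), " alignment records from ",
          nrow(metadata), " viromes")
  flt <- apply_filters(aln, cfg)
  log_msg(nrow(flt), " hits survive coverage >= ", cfg$min_query_coverage,
          ", evalue <= ", cfg$max_evalue, ", best-hit")
  metrics <- recruit(aln, metadata, lens, cfg)
  prof <- recruitment_profile(flt, cfg$plot_identity_window)
  echo <- config_comments(config, "seed")
  write_table(metrics, file.path(dir, "metrics.tsv"),
              comments = c(echo, paste0("min_query_coverage = ", cfg$min_query_coverage),
                           paste0("detection_threshold = ", cfg$detection_threshold)))
  write_table(prof, file.path(dir, "profile.tsv"))
  update_manifest(dir, c("metrics.tsv", "profile.tsv"))
  invisible(metrics)
}

#' Classify phages by human specificity from pooled coverages
#'
#' Builds the phage x pool horizontal-coverage matrix from `metrics.tsv` and
#' applies the specificity decision rule with the configured human/animal
#' pool roles and threshold. Writes `specificity_calls.tsv` with the class and
#' a per-pool pass flag (coverage strictly above threshold) for every phage.
#'
#' @param config Run config (must name `specificity$human_pools` and
#'   `specificity$animal_pools`).
#' @param dir Study directory.
#' @return Invisibly, the calls data.frame.
#' @export
run_classify <- function(config, dir) {
  config <- validate_run_config(config)
  sp <- config$specificity
  if (is.null(sp$human_pools) || is.null(sp$animal_pools)) {
    stop("config is missing required key: specificity$human_pools/animal_pools")
  }
  metrics <- read_table(file.path(dir, "metrics.tsv"))
  mat <- coverage_matrix(metrics)
  calls <- classify_specificity(mat, sp$human_pools, sp$animal_pools,
                                sp$threshold)
  for (p in c(sp$human_pools, sp$animal_pools)) {
    calls[[paste0("pass_", p)]] <- mat[calls$phage, p] > sp$threshold
  }
  log_msg("classified ", nrow(calls), " phages at threshold ", sp$threshold,
          "%: ", sum(calls$class == "HIGH"), " HIGH, ",
          sum(calls$class == "QUITE"), " QUITE")
  write_table(calls, file.path(dir, "specificity_calls.tsv"),
              comments = paste0("threshold = ", sp$threshold))
  update_manifest(dir, "specificity_calls.tsv")
  invisible(calls)
}

#' Compute intergenomic similarity and species/genus clusters
#'
#' Deduplicates identical (possibly circularly permuted) genomes, computes the
#' all-vs-all similarity matrix with the built-in anchor aligner, clusters at
#' the species and genus thresholds, and writes `similarity.tsv` and
#' `clusters.tsv`.
#'
#' @param config Run config.
#' @param dir Study directory containing `genomes.fasta`.
#' @return Invisibly, a list with the similarity object and both clusterings.
#' @export
run_similarity <- function(config, dir) {
  config <- validate_run_config(config)
  fa <- read_fasta(file.path(dir, "genomes.fasta"))
  seqs <- setNames(fa$sequence, fa$id)
  dd <- dedupe_identical(seqs)
  if (length(dd$duplicate_of)) {
    log_msg("collapsed ", length(dd$duplicate_of), " duplicate genome(s)")
  }
  sim <- intergenomic_similarity(dd$representatives)
  species <- threshold_clusters(sim, config$similarity$species_threshold, "species")
  genus <- threshold_clusters(sim, config$similarity$genus_threshold, "genus")
  simdf <- data.frame(genome_id = rownames(sim$similarity),
                      as.data.frame(sim$similarity, check.names = FALSE))
  write_table(simdf, file.path(dir, "similarity.tsv"))
  cl <- data.frame(genome_id = rownames(sim$similarity),
                   species_cluster = unname(species$membership),
                   genus_cluster = unname(genus$membership),
                   stringsAsFactors = FALSE)
  write_table(cl, file.path(dir, "clusters.tsv"),
              comments = c(paste0("species_threshold = ",
                                  config$similarity$species_threshold),
                           paste0("genus_threshold = ",
                                  config$similarity$genus_threshold)))
  log_msg(length(species$clusters), " species and ", length(genus$clusters),
          " genus clusters among ", nrow(sim$similarity), " genomes")
  update_manifest(dir, c("similarity.tsv", "clusters.tsv"))
  invisible(list(similarity = sim, species = species, genus = genus))
}

#' Aggregate recruitment by country
#'
#' Pools per-virome hits into country-cohort abundance profiles and writes
#' `country_profiles.tsv` (long format: cohort, country, phage, abundance,
#' share, detected) plus a prevalence line in the log.
#'
#' @param config Run config.
#' @param dir Study directory.
#' @return Invisibly, the profiles data.frame.
#' @export
run_biogeo <- function(config, dir) {
  config <- validate_run_config(config)
  cfg <- config$filter_config
  metadata <- read_metadata(file.path(dir, "metadata.tsv"))
  fa <- read_fasta(file.path(dir, "genomes.fasta"))
  lens <- setNames(fa$length, fa$id)
  aln <- load_alignments_dir(dir, metadata)
  profiles <- pool_by_country(aln, metadata, lens, cfg)
  prev <- prevalence(aln, metadata, lens, cfg)
  log_msg(prev$n_detected, " of ", prev$n_total, " metagenomes (",
          prev$prevalence_pct, "%) detected at least one phage")
  write_table(profiles, file.path(dir, "country_profiles.tsv"))
  update_manifest(dir, "country_profiles.tsv")
  invisible(profiles)
}
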