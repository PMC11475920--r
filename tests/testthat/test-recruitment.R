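test_that("query coverage and the coverage/e-value filter use inclusive boundaries", {
  aln <- make_aln(qseqid = c("a", "b", "c"), qstart = c(1, 1, 31),
                  qend = c(70, 100, 100), qlen = 100)
  expect_equal(query_coverage(aln), c(0.70, 1.0, 0.70))

  cfg <- filter_config()
  kept <- filter_hits(make_aln(qseqid = c("a", "b", "c"),
                               qstart = 1, qend = c(69, 70, 70),
                               evalue = c(1e-5, 0.1, 0.11)), cfg)
  expect_equal(kept$qseqid, "b")  # 0.69 coverage dropped; 0.70 & evalue 0.1 kept
  expect_equal(nrow(filter_hits(make_aln()[0, ], cfg)), 0)
  expect_error(query_coverage(transform(make_aln(), qlen = NA)), "qlen")
})

test_that("best hit keeps the top bitscore with deterministic tie-breaking", {
  two <- make_aln(qseqid = "r1", sseqid = c("g1", "g2"), bitscore = c(50, 60))
  expect_equal(best_hit(two)$sseqid, "g2")
  expect_equal(best_hit(make_aln()), make_aln())

  tie <- make_aln(qseqid = "r1", sseqid = c("gB", "gA", "gC"),
                  bitscore = 60, pident = c(97, 97, 99))
  expect_equal(best_hit(tie)$sseqid, "gC")  # higher pident wins the tie
  tie2 <- make_aln(qseqid = "r1", sseqid = c("gB", "gA"), bitscore = 60, pident = 97)
  expect_equal(best_hit(tie2)$sseqid, "gA") # then lexicographic sseqid

  # stability: result identical over every permutation of the input rows
  rows <- make_aln(qseqid = rep(c("r1", "r2"), each = 3),
                   sseqid = c("gB", "gA", "gC", "gA", "gC", "gB"),
                   bitscore = c(60, 60, 55, 70, 70, 70),
                   pident = c(97, 97, 99, 98, 98, 96))
  perms <- list(1:6, 6:1, c(3, 1, 2, 6, 4, 5), sample(6), sample(6))
  base <- best_hit(rows)
  for (p in perms) {
    got <- best_hit(rows[p, ])
    rownames(got) <- rownames(base) <- NULL
    expect_identical(got, base)
  }
})

test_that("sequencing depth sums aligned subject spans over the genome length", {
  h <- make_aln(qseqid = c("a", "b"), sstart = c(1, 200), send = c(100, 101))
  expect_equal(sequencing_depth(h, 1000), 0.2)  # one hit per strand direction
  expect_equal(sequencing_depth(make_aln()[0, ], 1000), 0)
  expect_error(sequencing_depth(h, 0), "genome_length")

  withr::with_seed(21, {
    h50 <- random_hits(50, 10000, span = 200)
    expect_equal(sequencing_depth(h50, 10000), 1.0)
    expect_equal(sequencing_depth(h50, 10000), oracle_depth(h50, 10000))
  })
})

test_that("abundance normalization divides by Gbp and Kbp exactly as defined", {
  expect_equal(normalize_abundance(0.2, 1e6, 1000), 200)
  expect_equal(normalize_abundance(0, 1e9, 1000), 0)
  expect_equal(normalize_abundance(0.2, 2e6, 1000),
               normalize_abundance(0.2, 1e6, 1000) / 2)
  expect_equal(normalize_abundance(0.2, 1e6, 1000, per_kbp = FALSE), 200)
  expect_equal(normalize_abundance(0.2, 1e6, 2000, per_kbp = FALSE),
               normalize_abundance(0.2, 1e6, 1000, per_kbp = FALSE))
  expect_error(normalize_abundance(0.2, 0, 1000), "dataset_bp")
})

test_that("ANIr matches both weightings and is NA with no hits", {
  eq <- make_aln(qseqid = c("a", "b", "c"), pident = c(96, 98, 100), length = 100)
  expect_equal(anir(eq, "length"), 98)
  expect_equal(anir(eq, "uniform"), 98)
  expect_equal(anir(make_aln(pident = 97.3)), 97.3)
  w <- make_aln(qseqid = c("a", "b"), pident = c(90, 100), length = c(100, 300))
  expect_equal(anir(w, "length"), 97.5)
  expect_equal(anir(w, "uniform"), 95)
  expect_true(is.na(anir(make_aln()[0, ])))
})

test_that("horizontal coverage is the union of subject intervals", {
  h <- make_aln(qseqid = c("a", "b"), sstart = c(1, 21), send = c(30, 50))
  expect_equal(horizontal_coverage(h, 100), 50)
  tile <- make_aln(qseqid = c("a", "b"), sstart = c(1, 51), send = c(50, 100))
  expect_equal(horizontal_coverage(tile, 100), 100)
  withr::with_seed(31, {
    h200 <- random_hits(200, 10000, span = 100)
    expect_equal(horizontal_coverage(h200, 10000), oracle_breadth(h200, 10000))
  })
  expect_error(horizontal_coverage(make_aln(sstart = 90, send = 189), 100),
               "exceeds genome length")
})

test_that("recruitment profile windows hits without touching metrics", {
  h <- make_aln(qseqid = c("a", "b", "c"), pident = c(94.9, 95.0, 99.5),
                sstart = c(1, 101, 201), send = c(100, 200, 300))
  prof <- recruitment_profile(h, c(95, 100))
  expect_equal(prof$pident, c(95.0, 99.5))  # 94.9 excluded, boundary inclusive
  expect_equal(prof$position, c(150.5, 250.5))
  before <- sequencing_depth(h, 1000)
  invisible(recruitment_profile(h, c(95, 100)))
  expect_equal(sequencing_depth(h, 1000), before)
})

test_that("detection threshold is boundary inclusive", {
  cfg <- filter_config()
  expect_equal(detection_call(c(0.000009, 0.00001, 3.7), cfg),
               c(FALSE, TRUE, TRUE))
})

test_that("depth, breadth and ANIr agree exactly with per-position oracles", {
  withr::with_seed(77, {
    for (rep in 1:5) {
      n <- sample(20:200, 1)
      h <- random_hits(n, 8000, span = sample(c(50, 100, 150), 1))
      expect_equal(sequencing_depth(h, 8000), oracle_depth(h, 8000))
      expect_equal(horizontal_coverage(h, 8000), oracle_breadth(h, 8000))
      expect_equal(anir(h, "length"), oracle_anir_length(h))
    }
  })
})

test_that("raising the query-coverage cutoff never increases any metric", {
  gs <- small_genomes(1, length = 5000)
  sim <- simulate_virome(gs, virome_spec("v", c(g01 = 1), n_reads = 1500, seed = 8))
  aln <- truth_to_alignments(sim$truth, gs, 100)
  # origin-split records give a spread of query coverages
  prev <- NULL
  for (qc in c(0.5, 0.7, 0.9, 1.0)) {
    cfg <- filter_config(min_query_coverage = qc)
    m <- recruitment_metrics(aln, genome_lengths(gs), sim$dataset_bp, cfg)
    if (!is.null(prev)) {
      expect_lte(m$n_reads, prev$n_reads)
      expect_lte(m$depth_SD, prev$depth_SD)
      expect_lte(m$horizontal_coverage, prev$horizontal_coverage)
    }
    prev <- m
  }
})

test_that("pool metrics equal recomputation over concatenated hits", {
  gs <- small_genomes(2, length = 5000)
  md <- data.frame(virome_name = c("v1", "v2"), pool = "human_gut",
                   dataset_bp = c(2e5, 3e5))
  alns <- lapply(c(v1 = 11, v2 = 12), function(s) {
    sim <- simulate_virome(gs, virome_spec(paste0("v", s), c(g01 = 2, g02 = 1),
                                           n_reads = 2000, seed = s))
    truth_to_alignments(sim$truth, gs, 100)
  })
  alns$v1$virome <- "v1"; alns$v2$virome <- "v2"
  combined <- rbind(alns$v1, alns$v2)
  metrics <- recruit(combined, md, gs)
  pool <- metrics[metrics$level == "pool", ]
  direct <- recruitment_metrics(combined, genome_lengths(gs), sum(md$dataset_bp))
  expect_equal(pool$depth_SD, direct$depth_SD)
  expect_equal(pool$norm_abundance, direct$norm_abundance)
  expect_equal(pool$anir, direct$anir)
  # virome-level rows also present: |genomes| x (|viromes| + |pools|) rows
  expect_equal(nrow(metrics), 2 * (2 + 1))
})
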