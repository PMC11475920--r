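test_that("generated genomes have forced length, requested GC, and are deterministic", {
  specs <- data.frame(id = "g1", length = 10000, gc = 0.5)
  gs <- generate_genomes(specs, seed = 7)
  expect_equal(unname(genome_lengths(gs)), 10000)
  expect_identical(gs$seq, generate_genomes(specs, seed = 7)$seq)

  big <- generate_genomes(data.frame(id = "g1", length = 100000, gc = 0.5), seed = 7)
  gc_obs <- mean(strsplit(big$seq[[1]], "")[[1]] %in% c("G", "C"))
  # binomial 99.99% interval for n = 1e5, p = 0.5
  expect_gt(gc_obs, 0.49)
  expect_lt(gc_obs, 0.51)

  expect_error(generate_genomes(data.frame(id = c("a", "a"), length = 2000), 1),
               "duplicate.*a")
  expect_error(generate_genomes(data.frame(id = "a", length = 10), 1), "1000")
})

test_that("mutate_genome realizes the requested substitution divergence", {
  g <- small_genomes(1, length = 2000)$seq[[1]]
  expect_identical(mutate_genome(g, 0, seed = 3), g)

  m1 <- mutate_genome(g, 1, seed = 3)
  expect_equal(nchar(m1), nchar(g))
  expect_false(any(strsplit(m1, "")[[1]] == strsplit(g, "")[[1]]))

  big <- generate_genomes(data.frame(id = "x", length = 100000), seed = 11)$seq[[1]]
  m <- mutate_genome(big, 0.04, seed = 5)
  d <- mean(strsplit(m, "")[[1]] != strsplit(big, "")[[1]])
  expect_gt(d, 0.037)  # binomial 99.9% interval around 0.04
  expect_lt(d, 0.043)

  expect_error(mutate_genome(g, 1.2, seed = 1), "divergence")
})

test_that("simulated viromes hit the planted mixture and conserve read counts", {
  gs <- small_genomes(2, length = 5000)
  one <- simulate_virome(gs, virome_spec("v", c(g01 = 1), n_reads = 100, seed = 1))
  expect_true(all(one$truth$source == "g01"))
  expect_equal(length(one$reads), 100)
  expect_equal(one$dataset_bp, 100 * 100)

  mix <- simulate_virome(gs, virome_spec("v", c(g01 = 3, g02 = 1),
                                         n_reads = 4000, seed = 1))
  nA <- sum(mix$truth$source == "g01")
  expect_gt(nA, 2850)  # binomial 99.9% interval, p = 0.75
  expect_lt(nA, 3150)
  expect_equal(nrow(mix$truth), 4000)

  bg <- simulate_virome(gs, virome_spec("v", c(g01 = 1), n_reads = 200,
                                        background_fraction = 1, seed = 1))
  expect_true(all(bg$truth$source == "background"))

  expect_error(simulate_virome(gs, virome_spec("v", c(nope = 1), 10, seed = 1)),
               "unknown genome")
  expect_error(
    simulate_virome(gs, virome_spec("v", c(g01 = 1), 10, read_length = 9999, seed = 1)),
    "read_length")
})

test_that("realized identities track the planted uniform range", {
  gs <- small_genomes(1, length = 5000)
  sim <- simulate_virome(gs, virome_spec("v", c(g01 = 1), n_reads = 2000,
                                         identity = c(95, 100), seed = 4))
  expect_true(all(sim$truth$identity >= 94.9 & sim$truth$identity <= 100))
  expect_lt(abs(mean(sim$truth$identity) - 97.5), 0.5)
  # realized identity is recomputed from the actual mismatch count
  expect_equal(sim$truth$identity,
               100 * (1 - sim$truth$n_mismatch / 100))
})

test_that("simulation is deterministic for a fixed spec and seed", {
  gs <- small_genomes(2)
  spec <- virome_spec("v", c(g01 = 2, g02 = 1), n_reads = 500,
                      background_fraction = 0.2, seed = 123)
  a <- simulate_virome(gs, spec)
  b <- simulate_virome(gs, spec)
  expect_identical(a, b)
  expect_identical(truth_to_alignments(a$truth, gs, 100),
                   truth_to_alignments(b$truth, gs, 100))
})

test_that("truth records convert to pass-through alignment records", {
  gs <- small_genomes(1, length = 5000, circular = FALSE)
  sim <- simulate_virome(gs, virome_spec("v", c(g01 = 1), n_reads = 10,
                                         background_fraction = 0.5, seed = 9))
  aln <- truth_to_alignments(sim$truth, gs, 100)
  n_src <- sum(sim$truth$source != "background")
  expect_equal(nrow(aln), n_src)  # background reads yield no record
  tr <- sim$truth[sim$truth$source != "background", ]
  expect_equal(aln$pident, round(tr$identity, 2))
  expect_equal(aln$qstart, rep(1L, n_src))
  expect_equal(aln$qend, rep(100L, n_src))
  plus <- tr$strand == "+"
  expect_equal(aln$sstart[plus], tr$start[plus])
  expect_equal(aln$send[plus], tr$end[plus])
  expect_equal(aln$sstart[!plus], tr$end[!plus])
  expect_equal(aln$send[!plus], tr$start[!plus])
  # bitscore is monotone in matches - mismatches
  expect_equal(order(aln$bitscore), order(-aln$mismatch))
})

test_that("origin-spanning reads on circular genomes split into two records", {
  gs <- small_genomes(1, length = 1000, circular = TRUE)
  sim <- simulate_virome(gs, virome_spec("v", c(g01 = 1), n_reads = 600,
                                         read_length = 100, seed = 2))
  sp <- sim$truth[sim$truth$spans_origin, ]
  expect_gt(nrow(sp), 0)  # ~10% of placements on a 1 kb circle span the origin
  aln <- truth_to_alignments(sim$truth, gs, 100)
  for (id in sp$read_id) {
    parts <- aln[aln$qseqid == id, ]
    expect_equal(nrow(parts), 2)
    expect_equal(sum(parts$length), 100)
    expect_equal(sum(parts$mismatch), sp$n_mismatch[sp$read_id == id])
    # the two parts tile the read exactly
    expect_setequal(parts$qstart, c(1, parts$length[parts$qstart == 1] + 1))
    # subject coordinates stay within the linearized genome
    expect_true(all(pmax(parts$sstart, parts$send) <= 1000))
  }
  # non-spanning reads keep one full-length record each
  expect_equal(nrow(aln), nrow(sim$truth) + nrow(sp))
})
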