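# Fixture builders and independent brute-force oracles used across the suite.

make_aln <- function(qseqid = "r1", sseqid = "g1", pident = 97, length = 100,
                     mismatch = 3, gapopen = 0, qstart = 1, qend = 100,
                     sstart = 1, send = 100, evalue = 1e-30, bitscore = 180,
                     qlen = 100) {
  data.frame(qseqid = qseqid, sseqid = sseqid, pident = pident, length = length,
             mismatch = mismatch, gapopen = gapopen, qstart = qstart,
             qend = qend, sstart = sstart, send = send, evalue = evalue,
             bitscore = bitscore, qlen = qlen, stringsAsFactors = FALSE)
}

# random hit set against a single genome, all passing default filters
random_hits <- function(n, genome_length, span = 100, genome = "g1") {
  lo <- sample.int(genome_length - span + 1, n, replace = TRUE)
  hi <- lo + span - 1
  minus <- sample(c(TRUE, FALSE), n, replace = TRUE)
  make_aln(qseqid = sprintf("r%04d", seq_len(n)), sseqid = genome,
           pident = round(runif(n, 95, 100), 2), length = span,
           mismatch = 0, qstart = 1, qend = span,
           sstart = ifelse(minus, hi, lo), send = ifelse(minus, lo, hi),
           bitscore = round(runif(n, 100, 200), 1), qlen = span)
}

# --- per-position / per-read brute-force oracles -----------------------------

oracle_depth <- function(aln, genome_length) {
  cov <- integer(genome_length)
  for (i in seq_len(nrow(aln))) {
    lo <- min(aln$sstart[i], aln$send[i]); hi <- max(aln$sstart[i], aln$send[i])
    cov[lo:hi] <- cov[lo:hi] + 1L
  }
  sum(cov) / genome_length
}

oracle_breadth <- function(aln, genome_length) {
  mask <- logical(genome_length)
  for (i in seq_len(nrow(aln))) {
    lo <- min(aln$sstart[i], aln$send[i]); hi <- max(aln$sstart[i], aln$send[i])
    mask[lo:hi] <- TRUE
  }
  100 * sum(mask) / genome_length
}

oracle_anir_length <- function(aln) {
  if (nrow(aln) == 0) return(NA_real_)
  tot <- 0; w <- 0
  for (i in seq_len(nrow(aln))) {
    tot <- tot + aln$pident[i] * aln$length[i]
    w <- w + aln$length[i]
  }
  tot / w
}

# exhaustive-enumeration Mann-Whitney oracle, written independently:
# statistic counted pair by pair, tail enumerated over explicit labelings
oracle_mwu <- function(x, y) {
  count_u <- function(a, b) {
    u <- 0
    for (ai in a) for (bj in b) u <- u + (ai > bj) + 0.5 * (ai == bj)
    u
  }
  ux <- count_u(x, y); uy <- count_u(y, x)
  u_obs <- max(ux, uy)
  pooled <- c(x, y)
  idx <- utils::combn(length(pooled), length(x))
  tail <- 0
  for (j in seq_len(ncol(idx))) {
    xs <- pooled[idx[, j]]; ys <- pooled[-idx[, j]]
    if (count_u(xs, ys) >= u_obs - 1e-9) tail <- tail + 1
  }
  list(U = u_obs, p = min(1, 2 * tail / ncol(idx)))
}

table2_matrix <- function() {
  path <- system.file("extdata", "human_phage_coverage.tsv",
                      package = "crassrecruit")
  df <- read.delim(path)
  m <- as.matrix(df[, c("human_gut", "urban_ww", "poultry_spain", "poultry_china")])
  rownames(m) <- df$phage
  attr(m, "reported") <- setNames(df$reported_specificity, df$phage)
  m
}

small_genomes <- function(n = 3, length = 5000, seed = 99, circular = TRUE) {
  generate_genomes(data.frame(id = sprintf("g%02d", seq_len(n)),
                              length = length, gc = 0.45, circular = circular),
                   seed = seed)
}
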