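---
title: "Methods: fragment recruitment, specificity calling and genome clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fragment recruitment, specificity calling and genome clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crassrecruit)
```

## The model

Fragment recruitment asks whether a reference genome is present in a
metagenome by mapping the metagenome's reads onto it and inspecting how much
of the genome they tile and at what identity. `crassrecruit` implements this
for phage genomes in viromes, with the human-specificity screen of crAss-like
phages as the motivating application. The pipeline has five stages, each an
exported function family:

1. **Alignment filtering** (`filter_hits()`, `best_hit()`): hits must cover at
   least 70% of the read (`(qend − qstart + 1)/qlen`, boundary inclusive) and
   have e-value at most 0.1; each read then keeps its single highest-bitscore
   hit, preventing one read from counting toward several genomes. Filtering
   precedes best-hit resolution, so the chosen hit is always a valid one.
2. **Recruitment statistics** (`recruitment_metrics()`, `recruit()`):
   sequencing depth, normalized abundance, ANIr and horizontal coverage per
   (genome, virome) pair, and per pool by *recomputing over concatenated
   hits with summed dataset sizes* — never by averaging per-virome values,
   which would introduce Simpson-type artifacts.
3. **Specificity calling** (`classify_specificity()`): the 40%
   horizontal-coverage decision rule on a phage × pool matrix.
4. **Genome taxonomy** (`intergenomic_similarity()`, `threshold_clusters()`):
   VIRIDIC-style pairwise similarity with species (95%) and genus (70%)
   single-linkage clustering, after rotation-aware deduplication
   (`dedupe_identical()`).
5. **Biogeography** (`pool_by_country()`, `prevalence()`, `rank_phages()`):
   country-cohort abundance profiles, within-cohort shares, and detection
   prevalence.

## Parameters that matter

| parameter | default | unit | rationale |
|---|---|---|---|
| `min_query_coverage` | 0.70 | fraction of read | discards partial, potentially spurious local hits |
| `max_evalue` | 0.1 | — | permissive cap; best-hit and coverage do the real work |
| `plot_identity_window` | 95–100 | % identity | the window in which population-level presence is judged on recruitment plots |
| `detection_threshold` | 1e-5 | SD/Gbp/Kbp | below this the genome is treated as undetected |
| specificity `threshold` | 40 | % horizontal coverage | a single shared gene on a ~100 kb genome is ~10%; 40% cannot be explained by one conserved region |
| species / genus thresholds | 95 / 70 | % intergenomic similarity | the standard demarcations for bacterial and archaeal viruses |

Notes on two deliberate choices:

* **e-value direction.** The filter keeps hits with e-value *at most* the
  cutoff. A filter keeping only hits with large e-values would retain only
  poor alignments, which is not a meaningful analysis, so the permissive
  direction is used and the threshold is configurable.
* **Double length normalization.** SD already divides by genome length; the
  SD/Gbp/Kbp unit divides by genome length (Kbp) again. The unit is
  implemented exactly as defined because it is the unit in which all
  comparative results are expressed; `normalize_abundance(per_kbp = FALSE)`
  exposes plain SD/Gbp for users who prefer a singly-normalized quantity.
* **ANIr weighting.** Whether the average identity of mapped reads should be
  read-weighted or length-weighted is ambiguous in common usage; the package
  defaults to length-weighting (the standard ANIr definition, and identical
  to read-weighting when reads align full length) and exposes
  `anir_weighting = "uniform"` for the plain mean.

## The specificity decision rule

All comparisons are strict: a phage is a candidate when its horizontal
coverage exceeds the threshold in *every* designated human pool (when both a
gut and a urine pool are designated, both must pass; exactly 40.0 counts as
absent). Candidates are classed by the number of animal pools in which they
also exceed the threshold: none → `HIGH`, all → `EXCLUDED`, some → `QUITE`.
The `QUITE` class exists because presence in only one of several animal
cohorts cannot be distinguished from human faecal contamination of that
cohort's samples. Pools with anecdotal sub-threshold recruitment need no
special handling — the strict rule already ignores them. The rule is monotone
(raising an animal-pool entry can only move a phage toward `EXCLUDED`;
raising a human entry can only keep or create candidacy) and invariant to row
and column order; both properties are tested.

## Exact Mann–Whitney U

For two small groups the package computes `U_x = #(x_i > y_j) + 0.5·#ties`
(via midranks), reports `U = max(U_x, U_y)`, and obtains the exact two-sided
p-value as `min(1, 2·Pr(U_x ≥ U))`, with the null distribution of `U_x`
enumerated over all `choose(n_x + n_y, n_x)` relabelings of the pooled
values. For a 4-vs-5 comparison with complete separation this gives
`U = 20`, `p = 2/126 ≈ 0.0159`. Enumeration is limited to group sizes ≤ 12;
ties are handled by midrank counting rather than excluded.

## Intergenomic similarity

Pairwise similarity is `100 · 2 · (identical aligned bases) / (lenA + lenB)`
over non-overlapping alignment fragments, together with each genome's aligned
fraction. Fragments may come from an external aligner's tabular output or
from the built-in anchor aligner: exact shared k-mers (k = 12, both
orientations) are grouped by diagonal, and each diagonal with at least two
anchors yields one ungapped fragment whose identical bases are counted by
direct comparison. This is sufficient for substitution-divergent genomes —
including circularly permuted ones, which simply split across two diagonals —
and makes the package fully testable offline; it is not a replacement for a
full seed-and-extend aligner on genomes with large indels or rearrangements.
`resolve_overlaps()` admits fragments greedily by score and trims later
fragments so no base on either genome is counted twice (identical-base counts
rescaled proportionally on trim), which makes the similarity formula well
defined on any raw fragment set.

On full-length substitution-only relatives the similarity is ≈ `100·(1 − d)`
for divergence `d`, so the 95% species threshold groups genomes within ~5%
divergence and the 70% genus threshold within ~30%; the planted-divergence
tests exercise exactly this regime. Clustering is single-linkage (connected
components at the threshold), mirroring standard practice; chaining can in
principle merge borderline species, which is the known cost of
single-linkage. The one-number threshold is the default demarcation mode; the
two-part criterion (95% identity over 85% of the genome) can be applied by
additionally requiring `aligned_fraction ≥ 0.85` from the returned matrix.

Before clustering, genomes identical up to rotation and/or reverse
complement are collapsed (`dedupe_identical()`): two equal-length genomes are
duplicates when one (or its reverse complement) is a substring of the other's
doubled sequence — the test that plain 100%-identity clustering fails for
circularly permuted assemblies.

## The synthetic-data generator

`generate_genomes()`, `mutate_genome()`, `simulate_virome()` and
`truth_to_alignments()` emulate the inputs of a recruitment study: reference
genomes (i.i.d. bases at a chosen GC), divergent relatives (independent
per-base substitutions), and viromes as mixtures of reads drawn from the
references at controlled weights and identities plus random background reads.
Design choices:

* **Substitutions only, fixed read length.** No indels, chimeras, duplicated
  reads, quality-error models or paired ends. Truth alignments therefore have
  exactly 100% query coverage and per-base oracles stay exact. Real viromes
  have none of these simplifications, so passing tests demonstrate the
  *correctness of the statistics*, not aligner robustness on real reads.
  Public virome read lengths vary by platform; a configurable fixed length
  (default 100 bp) is used instead of a length distribution.
* **Per-read identity** is drawn uniformly on the configured range (default
  95–100%), the implied mismatch count rounded to the nearest integer, and
  the realized identity recomputed from the actual count — so the recorded
  truth is exact, and the mean realized identity over many reads sits at the
  range midpoint (97.5 for the default range), which the ANIr-recovery tests
  use.
* **Circular genomes** are sampled via an internally doubled sequence; reads
  spanning the origin are recorded with unwrapped coordinates plus a flag,
  and `truth_to_alignments()` splits them into two records at the origin,
  mirroring real aligner behaviour on a linearized reference.
* **Background reads** are i.i.d. uniform bases: with overwhelming
  probability no background read produces a full-length high-identity hit,
  so "background ⇒ no alignment record" is exact rather than approximate.
* **Seeding.** One master seed drives a derived, named stream per genome and
  per virome (`withr::with_seed`), so regenerating one virome never perturbs
  another and every pipeline output is byte-reproducible (tested by checksum).

## Numerical and degenerate-input choices

* All thresholds on the filtering side are *inclusive* (coverage 0.70,
  e-value 0.1, detection 1e-5, plot window endpoints); the specificity rule
  is *strict* (> 40). Both follow from how each rule is stated in use.
* Best-hit ties break by higher identity, then lexicographic subject id, then
  subject coordinates — the result is a pure function of the hit set,
  independent of input order (tested over permutations).
* ANIr of an empty hit set is `NA`, never 0; depth and coverage of an empty
  set are 0; an empty alignment file yields all-zero metrics without error.
* Subject spans use `|send − sstart| + 1` regardless of strand; gap columns
  are ignored in span computation (spans are measured on the subject).
* Genomes may contain `N`; it never matches and is counted as a mismatch by
  the fragment aligner's direct comparison — conservative for similarity.

## Problem sizes

The test suite validates the statistical properties at sizes chosen to make
sampling error negligible relative to the asserted tolerances: genomes of
5–15 kb, viromes of 2 000–20 000 reads for distributional checks, and a
100 000-read virome for the 100× dynamic-range abundance-recovery check
(rank correlation ≥ 0.95, pairwise ratio error ≤ 15%). These are the
package's own fixture sizes; the statistics themselves are size-agnostic and
run comfortably on full-size (~100 kb genome, multi-Gbp virome) inputs.

## Known limitations

* The built-in fragment aligner handles substitution divergence and circular
  permutation, not large indels or rearrangements; for real genome sets,
  import fragments from a dedicated aligner and feed them through
  `resolve_overlaps()` / `pairwise_similarity()`.
* Best-hit resolution keeps a single record per read, so the second record of
  an origin-spanning read is discarded; the effect on depth and coverage is
  bounded by read length / genome length and is negligible at realistic
  sizes.
* Exact Mann–Whitney enumeration is exponential in group size and capped at
  12 per group; beyond that a normal approximation (deliberately out of
  scope) is the standard tool.
* Coverage-evenness statistics, per-base consensus/variant calling, and
  proteome-level trees are out of scope.
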