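---
title: "SSR discovery and length-polymorphism calling: models and design"
author: "micropoly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SSR discovery and length-polymorphism calling: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micropoly)
```

# The problem

Simple sequence repeats (SSRs, microsatellites) are tandem repetitions of
2–6 bp DNA motifs. Their repeat counts mutate fast, which makes them
informative molecular markers for breed discrimination, diversity studies
and marker-assisted selection — provided the polymorphic ones can be found.
One efficient route is an *SSR-enriched library*: genomic DNA is sheared to
~400 bp inserts, hybridization-captured with biotinylated repeat-motif
probes (here the panel AG, AC, AAC, ACG, AAG, AGG, ACAT, ATCT), and
sequenced as 2×250 bp pairs, so that most fragments carry a repeat tract
with usable flanking sequence on both sides.

`micropoly` implements the full computational side of that protocol:

1. **readprep** — sliding-window quality trimming, short-pair filtering,
   and merging of overlapping pairs into insert-length sequences;
2. **ssrscan** — detection of maximal perfect SSRs with MISA-style
   minimum-repeat thresholds and canonicalization of repeat motifs;
3. **sslp** — masking of repeat tracts, greedy flank-similarity clustering,
   and the SSR length polymorphism (SSLP) statistic per cluster;
4. **genomemap** — anchoring of clusters to a reference genome through
   their flanks, cross-population overlap, and gene-region annotation;
5. **simulate** — a generator of synthetic references, allele pools and
   enrichment-library reads with ground truth, so every stage is testable
   without downloads;
6. a pipeline driver (`run_pipeline()`) and a thin command-line wrapper
   (`exec/micropoly`) over the same functions.

# Read preparation

Each read is scanned 5'→3' with a 5 bp window advanced 1 bp at a time and
truncated immediately before the first window whose mean phred quality is
below 20 or whose final base quality is below 2. The published description
of this step is ambiguous about what exactly is kept around the offending
window; we adopt prefix truncation (keep everything before the first
failing window) because windowed trimmers conventionally clip 3' tails.
Reads shorter than one window pass unchanged — the pair-length filter
catches them. `N` bases count as quality 0 in window means. Pairs are
dropped when either trimmed mate is shorter than 50 bp (strict
"less than").

Merging considers every innie overlap length $L$ from the shorter read
length down to 100 bp between read 1 and the reverse complement of read 2.
Each candidate is scored by mismatch density $d = m/L$, with `N` always a
mismatch; the lowest density wins, ties going to the larger $L$, and the
merge is accepted iff $d \le 0.1$ (the boundary is inclusive: 10
mismatches in a 100 bp overlap merge, 11 do not). At mismatched positions
the base with the higher quality wins (ties to read 1) and the winning
quality is kept — mismatch qualities are not capped. Outie (read-through)
overlaps are not considered. The per-candidate mismatch counting is the
one hot loop of this stage and is implemented in C++ (`src/overlap.cpp`).

# SSR scanning and motif classes

A tract is reported when a primitive unit of size $k \in [2,6]$ repeats at
least $\{6,5,5,5,5\}$ times for $k = 2..6$. "Primitive" excludes units
that are themselves repetitions (ATAT); mononucleotide runs are out of
scope. Detection works on single-base periodicity: positions where
$s[i] = s[i+k]$ form runs; a maximal run of length $r$ is a periodic
region of $r + k$ bases holding $c = \lfloor (r+k)/k \rfloor$ complete
units anchored at the region's left edge. Tract coordinates cover complete
units only (size = unit × count, the MISA convention), so a region with a
partial trailing unit anchors its tract at the left; this is why the
reverse-complement scan mirrors tracts only up to $k - 1$ bp while the
(class, unit, count) multiset is exactly mirrored. Runs of `N` split a
sequence into independently scanned segments. Internally coordinates are
0-based half-open; exported TSVs are 1-based inclusive.

A motif's class label is `"X/Y"` with `X` the lexicographically smallest
string among all cyclic rotations of the motif and of its reverse
complement, and `Y` the smallest rotation of `revcomp(X)` — so all $2k$
variants of a unit collapse to one label (GT, TG, CA, AC → `AC/GT`).
Exhaustive enumeration over all primitive motifs yields 4, 10, 33, 102 and
350 classes for unit sizes 2–6, which the test suite asserts.

Tracts separated by at most 100 bp are annotated as compound SSRs; census
tables count individual tracts.

# Masking, clustering, and the SSLP statistic

Every tract in a merged sequence is replaced by a single `R`; one record is
emitted per tract with that tract *focal*. A single mask character (rather
than one per base) keeps the flanks adjacent and makes the allele length
invisible to clustering, which is the point: sequences from the same locus
but different alleles must cluster together on flank similarity alone.
Records whose focal flank on either side is shorter than 20 bp are
dropped (the flank is what clustering and mapping run on; we require both
sides). Overlapping tracts of different unit sizes are merged into one
masked segment and yield no focal record — neither flanks nor a single
allele length are well defined there. Sequences with more than 5 masked
segments are discarded as likely artifacts (configurable).

Clustering is greedy and CD-HIT-like: records sorted by masked length
(longest first, ties broken by record id in C-locale order for
determinism); each record joins the first existing cluster whose
representative aligns at ≥ 90% identity and ≥ 70% coverage, else founds a
new cluster. Identity is identical aligned positions over the *shorter*
sequence's length; coverage is the aligned fraction of the shorter
sequence; the alignment is ends-free global (Gotoh) with match +1,
mismatch 0, gap open 1, gap extension 0, and `R` aligning only to `R`. The
aligner is implemented in C++ (`src/align.cpp`) and is cross-checked
against `Biostrings::pairwiseAlignment` in the tests. A conservative
shared 8-mer prefilter skips representative comparisons that provably
cannot reach the identity threshold (each non-matching position of the
shorter sequence destroys at most $k$ of its $n_s - k + 1$ k-mers, so
identity $\ge I$ forces at least $(n_s - k + 1) - (1 - I)\,n_s k$ shared
words). With heavily gapped alignments the bound can in principle be
evaded, so `prefilter = FALSE` disables it; the test suite checks that
both settings give identical partitions on random data.

The SSLP of a cluster is the number of distinct focal tract lengths among
its members: 1 when all members agree, 2 for two lengths, and so on.
Polymorphic SSRs are clusters with SSLP ≥ 2 (strict).

**Allele support.** Substitution errors inside a repeat tract shorten or
split it, planting a wrong tract length in an otherwise correct cluster;
at depth $D$ and per-base error rate $e$ a given false length can collect
up to ~$2eD$ supporting reads. `compute_sslp()` therefore applies a
relative support rule: a length counts as an allele only when its read
support reaches `min_allele_frac` of the best-supported length's. The
default is 0.20 — the conventional minor-peak threshold in STR genotyping.
The rule leaves equal-support inputs untouched (a set of synthesized
variant sequences, one per allele, keeps every length at any
`min_allele_frac` ≤ 1), and `min_allele_frac = 0` restores the strict
count-every-observed-length definition.

# Genome anchoring, locus aggregation, overlap, annotation

For each cluster the exported flanks are per-position majority-vote
consensus sequences over its members (anchored at the tract boundary, up
to 60 bp): isolated sequencing errors that any single representative
would carry are voted out. Both flanks must place uniquely on the
reference (exact or k-mismatch search on toy references; a SAM import
path with MAPQ ≥ 30, primary-only filtering covers real genomes and
external aligners), on the same sequence and strand, in order, at most
1 kb apart; the tract interval is the gap between the flank hits.

One physical locus can split across several clusters when reads sample
different fragment windows; after anchoring, clusters of the same motif
class with overlapping tract intervals are aggregated into one genome
locus, their read support pooled, and the allele set and SSLP recomputed
on the pooled counts — support thresholds are meaningful at locus level,
where all reads of a locus sit in one pool. For the same reason *all*
clusters (monomorphic included) are mapped, and polymorphy is judged on
the aggregated locus.

Across populations, two loci are the same SSR iff their tract intervals
overlap by ≥ 1 bp on the same chromosome and share a motif class — exact
coordinates are not required because allele-length differences shift
tract ends between populations. Merged loci carry the union of
populations and alleles; exclusive-intersection (UpSet) counts are
reported for every population combination and always sum to the size of
the locus union. Region annotation assigns each locus one class with
precedence CDS > 5' UTR > 3' UTR > intron > intergenic (any overlap
triggers the class; intron means inside a gene span with no exon
overlap); class counts always sum to the locus count. The gene list
behind exonic loci is exported for downstream enrichment tools;
enrichment itself is out of scope.

# The synthetic-data generator

`sim_config()` defaults describe the emulated study: 400 bp inserts,
2×250 bp reads, four populations, planted motif classes weighted towards
the enrichment-probe panel, repeat counts 8–20, allele-pool sizes
distributed 0.30/0.25/0.20/0.15/0.07/0.03 over 1–6 alleles, each
population carrying each locus independently with probability 0.6,
30 fragments per (population, locus, allele), base error rate 0.001, 10%
background fragments, and 2% of reads given a low-quality 3' tail to
exercise the trimmer. Where the emulated protocol states a value (insert
size, read length, probe panel, coverage, error regime) the default *is*
that value; the remaining defaults are one-time choices of what a
realistic enrichment experiment looks like at desk scale (500 kb over two
toy chromosomes, 200 loci) and are not tuned.

The generator plants tracts with several hundred bases of unique random
flank, fixes the bases adjacent to each tract so planted coordinates are
exactly maximal, lays toy gene models so each locus's region class is
known (10% CDS, 5% each UTR, 20% intron, 60% intergenic), and centres
fragments on the locus with ±10 bp jitter — enrichment capture yields
tract-containing fragments, and the small jitter keeps same-locus flank
windows within the 90% identity radius while still exercising the
aggregation path. Everything derives from one seed; rebuilding with the
same seed is byte-identical.

What the generator does *not* model: platform-specific quality profiles,
PCR duplicates and stutter (indel slippage), probe thermodynamics, and
real flank repetitiveness (flanks are uniform random DNA, so mapping
ambiguity is rarer than on a real genome). Passing the end-to-end tests
therefore demonstrates the pipeline's internal correctness and its
robustness to substitution noise at the stated depth, not performance on
real libraries.

# Numerical and scale choices

* Desk-scale problem sizes: the full recovery analysis uses 200 loci ×
  4 populations at 30× per allele (~40k read pairs); unit tests use
  12–25 loci. The scanner's oracle equivalence is asserted exhaustively
  over the binary alphabet up to length 14 (32,766 strings), on 2,000
  random length-60 binary strings, and on 10⁴ random 200-bp sequences.
* Tie-breaks are fixed everywhere: merge candidates prefer the larger
  overlap at equal density; equal-quality overlap mismatches keep read 1's
  base; greedy clustering breaks length ties by record id (radix order)
  and joins the first qualifying representative; the aligner prefers the
  diagonal at equal score.
* Degenerate inputs are defined, not errors: empty read sets, sequences
  without hits, all-monomorphic clusters and empty FASTQ libraries flow
  through with empty tables (plus a warning for empty libraries).
* `--threads` in the CLI is accepted for interface compatibility; the
  implementation is single-threaded, so results are trivially independent
  of the requested thread count.

# Known limitations

* SSLP is a count of distinct tract lengths, not a genotype: no allele
  frequencies, no stutter-aware collapsing, no statistical model of
  capillary-style artifacts.
* Exact flank search is meant for toy references; real genomes should go
  through an external aligner and `import_sam()` (flank repeats in real
  genomes will produce `ambiguous` rejections that random toy flanks
  almost never trigger).
* MISA parity is targeted at the semantic level (complete-unit maximal
  tracts, thresholds, compound distance); corner-case parity with any
  specific MISA build (e.g. overlapping different-unit tracts) is not
  guaranteed.
* The paper-scale per-breed numbers (millions of reads, hundreds of
  thousands of clusters) are out of desk-scale reach; the package's
  claims at that scale are structural (identities, determinism), not
  numeric.
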