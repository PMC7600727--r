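# micropoly

Microsatellite discovery and length-polymorphism calling from
SSR-enriched sequencing libraries, in R.

Simple sequence repeats (SSRs, microsatellites) — tandem repetitions of
2–6 bp motifs — mutate in repeat count fast enough to serve as molecular
markers for breed discrimination, diversity studies and marker-assisted
selection. A cost-effective way to find the *polymorphic* ones in a
population is an SSR-enriched library: pooled genomic DNA is sheared to
~400 bp inserts, hybridization-captured with biotinylated repeat-motif
probes, and sequenced as 2×250 bp pairs. `micropoly` is the computational
pipeline for such libraries, aimed at researchers developing SSR marker
panels for non-model populations (the built-in synthetic-data generator
emulates a four-breed miniature-pig experiment, but nothing is
species-specific):

* **merge** — sliding-window quality trimming (5 bp window, Q20 mean /
  Q2 last base), 50 bp pair filter, and FLASH-style merging of
  overlapping pairs (min overlap 100, max mismatch density 0.1) into
  insert-length sequences;
* **scan** — maximal perfect SSR detection with MISA-style minimum
  repeats (6/5/5/5/5 for di- to hexanucleotides) and motif
  canonicalization into strand/rotation classes labelled like `AC/GT`;
* **sslp** — each tract is masked with a single `R`, records with < 20 bp
  of flank on either side are removed, masked sequences are clustered
  greedily on flank similarity (identity ≥ 0.90 over the shorter
  sequence, coverage ≥ 0.70, gap open 1 / extension 0), and each cluster
  gets its **SSLP**: the number of distinct tract lengths among its
  members. SSLP = 1 means monomorphic; SSLP ≥ 2 defines a polymorphic
  SSR;
* **map / overlap / annotate** — consensus flanks anchor each cluster to
  a reference genome, same-class overlapping clusters are aggregated into
  genome loci with pooled read support, loci are intersected across
  populations (UpSet-style exclusive counts), and classified by gene
  region (CDS > 5' UTR > 3' UTR > intron > intergenic) from GFF3 models;
* **simulate** — synthetic references with planted SSR loci, per-breed
  allele pools, gene models and paired reads, all byte-reproducible from
  one seed, so the whole pipeline is testable offline.

The vignette (`vignettes/micropoly-methods.Rmd`) documents the models,
parameter choices and limitations in detail.

## A worked example

Five synthetic inserts share 60 bp flanks and carry (AC)₁₂, (AC)₁₄,
(AC)₁₅, (AC)₁₆ and (AC)₁₇ — five alleles of one locus:

```r
library(micropoly)
set.seed(7)
flank <- function(n) paste(sample(c("A","C","G","T"), n, TRUE), collapse = "")
L <- flank(60); R <- flank(60)
seqs <- vapply(c(12, 14, 15, 16, 17),
               function(n) paste0(L, strrep("AC", n), R), character(1))
names(seqs) <- paste0("insert", 1:5)

(hits <- scan_ssrs(seqs))
#>    seq_id start end motif unit_size repeat_count canonical_class
#> 1 insert1    60  84    AC         2           12           AC/GT
#> 2 insert2    60  88    AC         2           14           AC/GT
#> 3 insert3    60  90    AC         2           15           AC/GT
#> 4 insert4    60  92    AC         2           16           AC/GT
#> 5 insert5    60  94    AC         2           17           AC/GT

clusters <- greedy_cluster(mask_and_filter(seqs, hits))
clusters$loci[, c("locus_id", "n_members", "focal_class",
                  "allele_lengths", "sslp")]
#>         locus_id n_members focal_class allele_lengths sslp
#> 1 C00001.0.AC/GT         5       AC/GT 24,28,30,32,34    5
```

The scanner reports each tract with 0-based half-open coordinates, its
observed motif and canonical class; masking makes the allele length
invisible to clustering, so all five inserts fall into one cluster, whose
allele lengths are the five tract lengths (24–34 bp) and whose SSLP is 5
— a polymorphic SSR with five alleles.

The full pipeline over simulated multi-breed libraries is one call:

```r
cfg <- sim_config(seed = 1)          # 200 loci, 4 breeds, 30x per allele
ref <- make_reference(cfg)
sim <- simulate_reads(ref)
libs <- lapply(setNames(cfg$breed_names, cfg$breed_names),
               function(b) sim[[b]])
res <- run_pipeline(libs, reference = ref$reference, gene_models = ref$gff,
                    out_dir = "out")
res$log                              # per-stage counts for every library
```

or, from a shell, `exec/micropoly` with subcommands `simulate`, `merge`,
`scan`, `sslp`, `map` and `run`.

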