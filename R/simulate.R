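# Synthetic data: toy reference genomes with planted SSR loci, per-breed
# allele pools, gene models, and enrichment-library paired reads with a
# ground-truth table, so every pipeline stage is testable without
# downloads.

#' Simulation configuration
#'
#' Defaults emulate an SSR-enriched MiSeq library of pooled DNA from
#' several small pig populations: 400-bp inserts, 2x250 bp reads, probe
#' motifs biased towards the enrichment panel (AG, AC, AAC, ACG, AAG, AGG,
#' ACAT, ATCT), and per-breed allele pools over a shared reference.
#'
#' @param seed integer; fixes all randomness (reference, alleles, reads).
#' @param genome_len total reference length in bp, split over `n_chrom`
#'   sequences.
#' @param n_chrom number of reference sequences.
#' @param gc GC fraction of the random background.
#' @param n_loci number of planted SSR loci.
#' @param motif_class_weights named probabilities of planted motif classes
#'   (names are representative motifs; each planted tract uses a random
#'   rotation/strand variant).
#' @param repeat_count_range inclusive range of planted repeat counts.
#' @param n_breeds,breed_names number and labels of populations.
#' @param alleles_per_locus_dist named probabilities over allele-pool sizes
#'   (`"1"`, `"2"`, ...).
#' @param breed_sharing_design `"random"` (each breed carries each locus
#'   independently with `breed_carry_prob`, at least one carrier) or
#'   `"all"`.
#' @param breed_carry_prob carrier probability under the random design.
#' @param insert_len,read_len fragment and read lengths in bp
#'   (`2 * read_len >= insert_len` guarantees an overlap).
#' @param per_allele_coverage fragments generated per (breed, locus,
#'   allele).
#' @param base_error_rate per-base substitution error probability.
#' @param enrichment_bias optional named relative capture weights per
#'   planted motif; `NULL` means equal.
#' @param background_fraction background (non-locus) fragments as a
#'   fraction of locus fragments.
#' @param low_tail_rate fraction of reads given a low-quality 3' tail (the
#'   trimming path's workload).
#' @param gene_region_design named probabilities of the region class
#'   planted around each locus.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, genome_len = 500000L, n_chrom = 2L,
                       gc = 0.42, n_loci = 200L,
                       motif_class_weights = c(
                         AC = 0.30, AG = 0.22, AAC = 0.10, AAG = 0.08,
                         AGG = 0.05, ACG = 0.03, ACAT = 0.12, ATCT = 0.10),
                       repeat_count_range = c(8L, 20L),
                       n_breeds = 4L,
                       breed_names = c("WZS", "BM", "LC", "ZX"),
                       alleles_per_locus_dist = c(
                         "1" = 0.30, "2" = 0.25, "3" = 0.20, "4" = 0.15,
                         "5" = 0.07, "6" = 0.03),
                       breed_sharing_design = c("random", "all"),
                       breed_carry_prob = 0.6,
                       insert_len = 400L, read_len = 250L,
                       per_allele_coverage = 30L,
                       base_error_rate = 0.001,
                       enrichment_bias = NULL,
                       background_fraction = 0.1,
                       low_tail_rate = 0.02,
                       gene_region_design = c(
                         CDS = 0.10, five_prime_utr = 0.05,
                         three_prime_utr = 0.05, intron = 0.20,
                         intergenic = 0.60)) {
  breed_sharing_design <- match.arg(breed_sharing_design)
  stopifnot(abs(sum(motif_class_weights) - 1) < 1e-8,
            abs(sum(alleles_per_locus_dist) - 1) < 1e-8,
            abs(sum(gene_region_design) - 1) < 1e-8,
            2L * read_len >= insert_len,
            max(as.integer(names(alleles_per_locus_dist))) <=
              diff(repeat_count_range) + 1L,
            n_breeds <= length(breed_names))
  structure(list(
    seed = as.integer(seed), genome_len = as.integer(genome_len),
    n_chrom = as.integer(n_chrom), gc = gc, n_loci = as.integer(n_loci),
    motif_class_weights = motif_class_weights,
    repeat_count_range = as.integer(repeat_count_range),
    n_breeds = as.integer(n_breeds),
    breed_names = breed_names[seq_len(n_breeds)],
    alleles_per_locus_dist = alleles_per_locus_dist,
    breed_sharing_design = breed_sharing_design,
    breed_carry_prob = breed_carry_prob,
    insert_len = as.integer(insert_len), read_len = as.integer(read_len),
    per_allele_coverage = as.integer(per_allele_coverage),
    base_error_rate = base_error_rate,
    enrichment_bias = enrichment_bias,
    background_fraction = background_fraction,
    low_tail_rate = low_tail_rate,
    gene_region_design = gene_region_design), class = "sim_config")
}

random_genome <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

#' Build a synthetic reference with planted SSR loci and gene models
#'
#' Plants `n_loci` non-overlapping perfect tracts into a random genome
#' (each with several hundred bp of unique random flank), fixes the bases
#' adjacent to each tract so planted coordinates are exactly maximal, and
#' lays down toy gene models so each locus's region class is known.
#'
#' @param config a [sim_config] object.
#' @return list with `reference` ([Biostrings::DNAStringSet]), `truth`
#'   (per-locus data.frame: coordinates are 1-based inclusive), `gff`
#'   ([GenomicRanges::GRanges] of gene models) and `config`.
#' @export
make_reference <- function(config = sim_config()) {
  set.seed(config$seed)
  margin <- 300L
  chrom_len <- rep(config$genome_len %/% config$n_chrom, config$n_chrom)
  chrom_names <- paste0("chr", seq_len(config$n_chrom))
  per_chrom <- diff(round(seq(0, config$n_loci,
                              length.out = config$n_chrom + 1L)))
  if (config$n_loci > 0 &&
      any(chrom_len < 2L * margin + per_chrom * 150L))
    stop("genome too small for the requested number of loci")
  chroms <- lapply(chrom_len, random_genome, gc = config$gc)
  names(chroms) <- chrom_names
  truth <- list()
  gff <- list()
  li <- 0L
  for (ci in seq_len(config$n_chrom)) {
    nl <- per_chrom[ci]
    if (nl == 0L) next
    W <- (chrom_len[ci] - 2L * margin) %/% nl
    for (j in seq_len(nl)) {
      li <- li + 1L
      motif0 <- sample(names(config$motif_class_weights), 1L,
                       prob = config$motif_class_weights)
      variant <- sample(c(rotations(motif0), rotations(revcomp(motif0))),
                        1L)
      k <- nchar(variant)
      cnt <- sample(seq.int(config$repeat_count_range[1],
                            config$repeat_count_range[2]), 1L)
      tlen <- k * cnt
      start <- margin + (j - 1L) * W +
        sample.int(max(W - tlen - 100L, 1L), 1L)   # 1-based tract start
      end <- start + tlen - 1L
      tract <- strsplit(strrep(variant, cnt), "", fixed = TRUE)[[1]]
      chroms[[ci]][start:end] <- tract
      # fix neighbours so the planted tract is exactly maximal
      vchars <- strsplit(variant, "", fixed = TRUE)[[1]]
      chroms[[ci]][start - 1L] <-
        sample(setdiff(c("A", "C", "G", "T"), vchars[k]), 1L)
      chroms[[ci]][end + 1L] <-
        sample(setdiff(c("A", "C", "G", "T"), vchars[1L]), 1L)
      n_all <- as.integer(sample(names(config$alleles_per_locus_dist), 1L,
                                 prob = config$alleles_per_locus_dist))
      counts <- sort(sample(seq.int(config$repeat_count_range[1],
                                    config$repeat_count_range[2]), n_all))
      carriers <- if (config$breed_sharing_design == "all") {
        config$breed_names
      } else {
        repeat {
          cs <- config$breed_names[stats::runif(config$n_breeds) <
                                     config$breed_carry_prob]
          if (length(cs) > 0L) break
        }
        cs
      }
      region <- sample(names(config$gene_region_design), 1L,
                       prob = config$gene_region_design)
      truth[[li]] <- data.frame(
        locus_id = sprintf("L%04d", li), chrom = chrom_names[ci],
        start = start, end = end, motif = variant,
        motif_class = canonical_class(variant), unit_size = k,
        ref_repeat_count = cnt,
        allele_counts = paste(counts, collapse = ","),
        allele_lengths = paste(counts * k, collapse = ","),
        breeds = paste(sort(carriers), collapse = "+"),
        region = region)
      if (region != "intergenic") {
        gff[[length(gff) + 1L]] <-
          locus_gene_model(chrom_names[ci], start, end, region,
                           sprintf("gene%04d", li), chrom_len[ci])
      }
    }
  }
  reference <- Biostrings::DNAStringSet(
    vapply(chroms, paste, character(1), collapse = ""))
  names(reference) <- chrom_names
  truth <- if (li > 0L) do.call(rbind, truth) else data.frame()
  gff <- if (length(gff)) suppressWarnings(do.call(c, gff)) else
    GenomicRanges::GRanges()
  list(reference = reference, truth = truth, gff = gff, config = config)
}

# Toy gene model placing one locus in a known region class.
locus_gene_model <- function(chrom, tstart, tend, region, gene_id,
                             chrom_len) {
  gs <- max(1L, tstart - 250L)
  ge <- min(chrom_len, tend + 250L)
  feat <- function(type, s, e, id = NULL) {
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(s, e),
                                 strand = "+")
    gr$type <- type
    gr$ID <- id %||% paste0(gene_id, ".", type, ".", s)
    gr
  }
  g <- feat("gene", gs, ge, gene_id)
  parts <- switch(
    region,
    CDS = c(feat("exon", tstart - 30L, tend + 30L),
            feat("CDS", tstart - 30L, tend + 30L)),
    five_prime_utr = c(feat("exon", tstart - 30L, tend + 30L),
                       feat("five_prime_UTR", tstart - 10L, tend + 10L)),
    three_prime_utr = c(feat("exon", tstart - 30L, tend + 30L),
                        feat("three_prime_UTR", tstart - 10L, tend + 10L)),
    intron = c(feat("exon", gs, gs + 40L), feat("exon", ge - 40L, ge)))
  c(g, parts)
}

#' Simulate enrichment-library paired reads per breed
#'
#' For each carrying breed and allele, draws `per_allele_coverage`
#' insert-length fragments centred (with jitter) on the locus tract, swaps
#' in the allele's tract, adds background fragments, and emits 2x
#' `read_len` paired reads with substitution errors at `base_error_rate`
#' and a two-state (high / low-tail) quality model.
#'
#' @param ref result of [make_reference].
#' @return list with one element per breed (`list(r1=, r2=)` [qreads]
#'   pairs) plus `truth` (the reference truth table) and `config`.
#' @export
simulate_reads <- function(ref) {
  config <- ref$config
  set.seed(config$seed + 1L)
  chrom_str <- as.character(ref$reference)
  bias <- config$enrichment_bias
  rel_bias <- function(motif) {
    if (is.null(bias)) return(1)
    b <- bias[[motif]] %||% min(bias)
    b / mean(unlist(bias))
  }
  out <- list()
  for (breed in config$breed_names) {
    frags <- character(0)
    ids <- character(0)
    n_locus_frag <- 0L
    fr <- list(); fi <- 0L
    for (i in seq_len(nrow(ref$truth))) {
      tr <- ref$truth[i, ]
      carriers <- strsplit(tr$breeds, "+", fixed = TRUE)[[1]]
      if (!(breed %in% carriers)) next
      counts <- as.integer(strsplit(tr$allele_counts, ",")[[1]])
      k <- tr$unit_size
      n_frag <- max(1L, round(config$per_allele_coverage *
                                rel_bias(tr$motif)))
      for (a in counts) {
        tract <- strrep(tr$motif, a)
        tlen <- nchar(tract)
        for (f in seq_len(n_frag)) {
          fi <- fi + 1L
          left_len <- (config$insert_len - tlen) %/% 2L +
            sample.int(21L, 1L) - 11L
          right_len <- config$insert_len - tlen - left_len
          s <- chrom_str[[tr$chrom]]
          frag <- paste0(
            substr(s, tr$start - left_len, tr$start - 1L), tract,
            substr(s, tr$end + 1L, tr$end + right_len))
          if (stats::runif(1) < 0.5) frag <- revcomp(frag)
          fr[[fi]] <- c(sprintf("%s:%s:a%d:%d", breed, tr$locus_id, a, f),
                        frag)
        }
      }
      n_locus_frag <- n_locus_frag + n_frag * length(counts)
    }
    n_bg <- round(config$background_fraction * n_locus_frag)
    for (b in seq_len(n_bg)) {
      ci <- sample.int(config$n_chrom, 1L)
      s <- chrom_str[[ci]]
      pos <- sample.int(nchar(s) - config$insert_len, 1L)
      fi <- fi + 1L
      fr[[fi]] <- c(sprintf("%s:bg:%d", breed, b),
                    substr(s, pos, pos + config$insert_len - 1L))
    }
    ids <- vapply(fr, `[`, character(1), 1L)
    frags <- vapply(fr, `[`, character(1), 2L)
    out[[breed]] <- fragments_to_pairs(ids, frags, config)
  }
  out$truth <- ref$truth
  out$config <- config
  out
}

# Turn fragments into error-bearing read pairs with phred qualities.
fragments_to_pairs <- function(ids, frags, config) {
  rl <- config$read_len
  r1 <- substr(frags, 1L, rl)
  r2 <- revcomp(substr(frags, nchar(frags) - rl + 1L, nchar(frags)))
  mk <- function(seqs, mate) {
    n <- length(seqs)
    qual <- vector("list", n)
    for (i in seq_len(n)) {
      s <- seqs[i]
      ne <- stats::rbinom(1L, rl, config$base_error_rate)
      if (ne > 0L) {
        pos <- sample.int(rl, ne)
        ch <- strsplit(s, "", fixed = TRUE)[[1]]
        for (p in pos)
          ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
        s <- paste(ch, collapse = "")
        seqs[i] <- s
      }
      q <- sample(33:41, rl, replace = TRUE)
      if (stats::runif(1) < config$low_tail_rate) {
        tl <- sample(10:40, 1L)
        q[seq.int(rl - tl + 1L, rl)] <- sample(2:15, tl, replace = TRUE)
      }
      qual[[i]] <- q
    }
    qreads(paste0(ids, "/", mate), seqs, qual)
  }
  list(r1 = mk(r1, 1L), r2 = mk(r2, 2L))
}

#' Write a simulated run to disk
#'
#' Emits the reference FASTA, GFF3 gene models, truth TSV and per-breed
#' gzip FASTQ pairs into a directory.
#'
#' @param sim result of [simulate_reads].
#' @param ref result of [make_reference].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, ref, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(ref$reference,
                              file.path(dir, "reference.fa"))
  if (length(ref$gff))
    suppressWarnings(rtracklayer::export(ref$gff,
                                         file.path(dir, "genes.gff3"),
                                         format = "gff3"))
  utils::write.table(ref$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (breed in ref$config$breed_names) {
    write_fastq(sim[[breed]]$r1,
                file.path(dir, paste0(breed, "_R1.fastq.gz")))
    write_fastq(sim[[breed]]$r2,
                file.path(dir, paste0(breed, "_R2.fastq.gz")))
  }
  invisible(dir)
}
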