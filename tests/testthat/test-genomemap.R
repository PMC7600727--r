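# Flank anchoring, SAM import, breed overlap and region annotation.

toy_reference <- function(seed = 51, len = 8000) {
  withr::with_seed(seed, {
    ref <- Biostrings::DNAStringSet(c(chr1 = random_dna(len),
                                      chr2 = random_dna(len)))
  })
  ref
}

test_that("flanks copied from the reference map back to the planted interval", {
  ref <- toy_reference()
  s <- as.character(ref[["chr1"]])
  left <- substr(s, 1001, 1060)
  right <- substr(s, 1101, 1160)
  m <- map_flanks_exact(left, right, ref)
  expect_identical(m$status, "mapped")
  expect_identical(m$chrom, "chr1")
  expect_identical(m$start, 1061L)
  expect_identical(m$end, 1100L)
  expect_identical(m$strand, "+")
  # the same cluster seen on the opposite strand maps to the same interval
  m2 <- map_flanks_exact(revcomp(right), revcomp(left), ref)
  expect_identical(m2$status, "mapped")
  expect_identical(m2$strand, "-")
  expect_identical(c(m2$start, m2$end), c(1061L, 1100L))
})

test_that("ambiguous, absent and discordant flanks are rejected with reasons", {
  ref <- toy_reference()
  s1 <- as.character(ref[["chr1"]])
  s2 <- as.character(ref[["chr2"]])
  dup <- Biostrings::DNAStringSet(c(
    chr1 = paste0(s1, substr(s1, 1001, 1060))))   # left flank twice
  expect_identical(
    map_flanks_exact(substr(s1, 1001, 1060), substr(s1, 1101, 1160),
                     dup)$status, "ambiguous")
  expect_identical(
    map_flanks_exact(strrep("ACGT", 15), substr(s1, 1101, 1160),
                     ref)$status, "no_hit")
  expect_identical(
    map_flanks_exact(substr(s1, 1001, 1060), substr(s2, 1101, 1160),
                     ref)$status, "discordant")
  # flanks in the wrong order or too far apart
  expect_identical(
    map_flanks_exact(substr(s1, 1101, 1160), substr(s1, 1001, 1060),
                     ref)$status, "discordant")
  expect_identical(
    map_flanks_exact(substr(s1, 1001, 1060), substr(s1, 3001, 3060),
                     ref)$status, "discordant")
})

write_sam <- function(path, ref, rows) {
  hdr <- c("@HD\tVN:1.6",
           paste0("@SQ\tSN:", names(ref), "\tLN:", Biostrings::width(ref)))
  body <- vapply(rows, function(r) {
    paste(r$qname, r$flag, r$rname, r$pos, r$mapq,
          paste0(r$len, "M"), "*", 0, 0, strrep("A", r$len), "*",
          sep = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  path
}

test_that("SAM import applies MAPQ, primary and concordance rules", {
  ref <- toy_reference()
  poly <- data.frame(locus_id = c("C1.0", "C2.0", "C3.0"),
                     focal_class = "AC/GT", allele_lengths = "24,28",
                     sslp = 2L, source = "toy",
                     left_flank = strrep("A", 60),
                     right_flank = strrep("A", 60))
  sam <- tempfile(fileext = ".sam")
  write_sam(sam, ref, list(
    list(qname = "C1.0/L", flag = 0L, rname = "chr1", pos = 1001L,
         mapq = 60L, len = 60L),
    list(qname = "C1.0/R", flag = 0L, rname = "chr1", pos = 1101L,
         mapq = 60L, len = 60L),
    list(qname = "C2.0/L", flag = 0L, rname = "chr1", pos = 2001L,
         mapq = 0L, len = 60L),                      # low MAPQ
    list(qname = "C2.0/R", flag = 0L, rname = "chr1", pos = 2101L,
         mapq = 60L, len = 60L),
    list(qname = "C3.0/L", flag = 4L, rname = "*", pos = 0L,
         mapq = 0L, len = 60L),                      # unmapped
    list(qname = "C3.0/R", flag = 0L, rname = "chr2", pos = 501L,
         mapq = 60L, len = 60L)))
  got <- import_sam(poly, sam)
  expect_identical(nrow(got$loci), 1L)
  expect_identical(got$loci$locus_id, "C1.0")
  expect_identical(c(got$loci$start, got$loci$end), c(1061L, 1100L))
  expect_setequal(got$unmapped$reason, c("low_mapq", "no_hit"))
  unlink(sam)
})

test_that("exact search and SAM import agree on a synthetic fixture", {
  ref <- toy_reference(seed = 52)
  s <- as.character(ref[["chr1"]])
  # three planted loci; flanks lifted straight from the reference
  at <- c(1000L, 3000L, 5500L)
  poly <- do.call(rbind, lapply(seq_along(at), function(i) {
    p <- at[i]
    data.frame(locus_id = sprintf("C%d.0", i), focal_class = "AC/GT",
               allele_lengths = "24,26", sslp = 2L, source = "toy",
               left_flank = substr(s, p - 59, p),
               right_flank = substr(s, p + 31, p + 90))
  }))
  direct <- map_clusters(poly, ref)
  # SAM route: alignments at the positions the flanks were lifted from
  sam <- tempfile(fileext = ".sam")
  write_sam(sam, ref, unlist(lapply(seq_along(at), function(i) {
    p <- at[i]
    list(list(qname = sprintf("C%d.0/L", i), flag = 0L, rname = "chr1",
              pos = p - 59L, mapq = 60L, len = 60L),
         list(qname = sprintf("C%d.0/R", i), flag = 0L, rname = "chr1",
              pos = p + 31L, mapq = 60L, len = 60L))
  }), recursive = FALSE))
  viasam <- import_sam(poly, sam)
  expect_identical(direct$loci[c("locus_id", "chrom", "start", "end",
                                 "strand")],
                   viasam$loci[c("locus_id", "chrom", "start", "end",
                                 "strand")])
  unlink(sam)
})

breed_locus <- function(chrom, start, end, cls = "AC/GT",
                        alleles = "24,28") {
  data.frame(locus_id = sprintf("%s:%d-%d", chrom, start, end),
             chrom = chrom, start = start, end = end, strand = "+",
             motif_class = cls, allele_lengths = alleles,
             sslp = lengths(strsplit(alleles, ",")), source = "x")
}

test_that("breed overlap counts exclusive intersections that sum to the union", {
  shared <- breed_locus("chr1", 100L, 130L)
  per <- list(A = shared, B = shared, C = shared, D = shared)
  ov <- overlap_breeds(per)
  expect_identical(nrow(ov$loci), 1L)
  expect_identical(ov$loci$breeds, "A+B+C+D")
  expect_identical(ov$counts$n[ov$counts$combo == "A+B+C+D"], 1L)
  expect_identical(sum(ov$counts$n), nrow(ov$loci))
  # disjoint loci: every breed keeps its own
  per2 <- list(A = breed_locus("chr1", 100L, 130L),
               B = breed_locus("chr1", 500L, 530L),
               C = breed_locus("chr2", 100L, 130L),
               D = breed_locus("chr2", 500L, 530L))
  ov2 <- overlap_breeds(per2)
  expect_identical(nrow(ov2$loci), 4L)
  expect_identical(ov2$counts$n[ov2$counts$degree == 1], rep(1L, 4))
  expect_identical(sum(ov2$counts$n), 4L)
  # same interval, different motif class: not the same locus
  per3 <- list(A = breed_locus("chr1", 100L, 130L, "AC/GT"),
               B = breed_locus("chr1", 100L, 130L, "AG/CT"))
  expect_identical(nrow(overlap_breeds(per3)$loci), 2L)
  # overlap by >= 1 bp with shifted tract ends merges, alleles unioned
  per4 <- list(A = breed_locus("chr1", 100L, 130L, alleles = "24,28"),
               B = breed_locus("chr1", 128L, 160L, alleles = "28,30"))
  ov4 <- overlap_breeds(per4)
  expect_identical(nrow(ov4$loci), 1L)
  expect_identical(ov4$loci$allele_lengths, "24,28,30")
  expect_identical(ov4$loci$sslp, 3L)
})

test_that("breed overlap is symmetric in breed order", {
  withr::with_seed(53, {
    mk <- function() breed_locus("chr1", s <- sample(1e5, 1), s + 30L)
    sets <- list(A = do.call(rbind, replicate(5, mk(), simplify = FALSE)),
                 B = do.call(rbind, replicate(3, mk(), simplify = FALSE)),
                 C = mk())
    ov1 <- overlap_breeds(sets)
    ov2 <- overlap_breeds(rev(sets))
    expect_identical(ov1$counts, ov2$counts)
  })
})

toy_gff <- function() {
  feat <- function(chrom, s, e, type, id) {
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(s, e),
                                 strand = "+")
    gr$type <- type
    gr$ID <- id
    gr
  }
  suppressWarnings(c(
    feat("chr1", 1000, 3000, "gene", "geneA"),
    feat("chr1", 1000, 1500, "exon", "geneA.e1"),
    feat("chr1", 1100, 1400, "CDS", "geneA.c1"),
    feat("chr1", 1000, 1099, "five_prime_UTR", "geneA.u5"),
    feat("chr1", 2500, 3000, "exon", "geneA.e2"),
    feat("chr1", 2600, 3000, "three_prime_UTR", "geneA.u3")))
}

test_that("region annotation follows the CDS > UTR > intron > intergenic precedence", {
  gm <- toy_gff()
  loci <- data.frame(chrom = "chr1",
                     start = c(1200L, 1010L, 2700L, 1700L, 5000L),
                     end = c(1230L, 1040L, 2730L, 1730L, 5030L))
  ann <- annotate_regions(loci, gm)
  expect_identical(ann$annotations$region,
                   c("CDS", "five_prime_utr", "three_prime_utr", "intron",
                     "intergenic"))
  expect_identical(ann$annotations$gene_id,
                   c("geneA", "geneA", "geneA", "geneA", NA))
  expect_identical(sum(ann$summary$n), nrow(loci))
  expect_equal(sum(ann$summary$proportion), 1)
})

test_that("region annotation round-trips through a GFF3 file and warns on missing chromosomes", {
  gm <- toy_gff()
  f <- tempfile(fileext = ".gff3")
  suppressWarnings(rtracklayer::export(gm, f, format = "gff3"))
  loci <- data.frame(chrom = c("chr1", "chrZ"), start = c(1200L, 10L),
                     end = c(1230L, 40L))
  expect_warning(ann <- annotate_regions(loci, f), "absent")
  expect_identical(ann$annotations$region, c("CDS", "intergenic"))
  unlink(f)
})

test_that("aggregation pools split clusters into one genome locus", {
  # two clusters of one physical locus: same class, overlapping intervals
  mapped <- data.frame(
    locus_id = c("C00001.0.AC/GT", "C00002.0.AC/GT"),
    chrom = "chr1", start = c(100L, 102L), end = c(130L, 132L),
    strand = "+", motif_class = "AC/GT",
    allele_lengths = c("24,28", "24"), sslp = c(2L, 1L), source = "toy")
  members <- data.frame(
    record_id = sprintf("r%02d", 1:12),
    locus_id = rep(c("C00001.0.AC/GT", "C00002.0.AC/GT"), c(9, 3)),
    focal_tract_len = c(rep(24L, 5), rep(28L, 4), rep(24L, 2), 30L))
  clusters <- structure(list(members = members), class = "ssr_clusters")
  gl <- aggregate_mapped_loci(mapped, clusters,
                              cluster_params(min_allele_frac = 0.2))
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$n_clusters, 2L)
  expect_identical(gl$n_reads, 12L)
  # pooled support: 24 x7, 28 x4, 30 x1 -> 30 falls below 0.2 * 7
  expect_identical(gl$allele_lengths, "24,28")
  expect_identical(gl$sslp, 2L)
})
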