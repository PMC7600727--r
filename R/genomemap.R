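# Anchoring polymorphic SSR clusters to a reference genome through their
# flanks, cross-population locus overlap (UpSet-style exclusive counts) and
# gene-region annotation from GFF3 models.

#' Map one cluster's flanks onto a reference by exact/k-mismatch search
#'
#' Both flanks must place uniquely in the reference (each exactly one hit
#' over both strands), on the same sequence and strand, in order, separated
#' by at least 1 and at most `max_gap` bp; the tract interval is the gap
#' between the two flank hits. Intended for toy-scale references; use
#' [import_sam] with an external aligner for real genomes.
#'
#' @param left_flank,right_flank flank sequences as they appear on the
#'   merged sequence (left flank 5' of the tract).
#' @param reference a [Biostrings::DNAStringSet].
#' @param max_gap maximum distance between flank hits, in bp.
#' @param max_mismatch number of mismatches tolerated in each flank hit.
#' @return `list(status=, chrom=, start=, end=, strand=)`; `status` is
#'   `"mapped"` or a reason code (`"no_hit"`, `"ambiguous"`,
#'   `"discordant"`), coordinates are 1-based inclusive for the tract
#'   interval and `NA` unless mapped.
#' @export
map_flanks_exact <- function(left_flank, right_flank, reference,
                             max_gap = 1000L, max_mismatch = 0L) {
  hit1 <- flank_hits(left_flank, reference, max_mismatch)
  hit2 <- flank_hits(right_flank, reference, max_mismatch)
  if (nrow(hit1) == 0L || nrow(hit2) == 0L)
    return(unmapped_locus("no_hit"))
  if (nrow(hit1) > 1L || nrow(hit2) > 1L)
    return(unmapped_locus("ambiguous"))
  if (hit1$chrom != hit2$chrom || hit1$strand != hit2$strand)
    return(unmapped_locus("discordant"))
  if (hit1$strand == "+") {
    tstart <- hit1$end + 1L
    tend <- hit2$start - 1L
  } else {
    tstart <- hit2$end + 1L
    tend <- hit1$start - 1L
  }
  gap <- tend - tstart + 1L
  if (gap < 1L || gap > max_gap) return(unmapped_locus("discordant"))
  list(status = "mapped", chrom = hit1$chrom, start = tstart, end = tend,
       strand = hit1$strand)
}

unmapped_locus <- function(reason) {
  list(status = reason, chrom = NA_character_, start = NA_integer_,
       end = NA_integer_, strand = NA_character_)
}

flank_hits <- function(flank, reference, max_mismatch) {
  fwd <- Biostrings::vmatchPattern(flank, reference,
                                   max.mismatch = max_mismatch)
  rev <- Biostrings::vmatchPattern(revcomp(flank), reference,
                                   max.mismatch = max_mismatch)
  rows <- list()
  for (i in seq_along(reference)) {
    f <- fwd[[i]]; r <- rev[[i]]
    if (length(f))
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = names(reference)[i], start = IRanges::start(f),
        end = IRanges::end(f), strand = "+")
    if (length(r))
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = names(reference)[i], start = IRanges::start(r),
        end = IRanges::end(r), strand = "-")
  }
  if (length(rows) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0)))
  do.call(rbind, rows)
}

#' Map a table of polymorphic loci onto a reference
#'
#' Runs [map_flanks_exact] for every row of a [polymorphic_records] table.
#'
#' @param poly data.frame from [polymorphic_records].
#' @param reference a [Biostrings::DNAStringSet].
#' @param max_gap,max_mismatch see [map_flanks_exact].
#' @return list with `loci` (data.frame of mapped loci: `locus_id`,
#'   `chrom`, `start`, `end`, `strand`, `motif_class`, `allele_lengths`,
#'   `sslp`, `source`) and `unmapped` (data.frame `locus_id`, `reason`).
#' @export
map_clusters <- function(poly, reference, max_gap = 1000L,
                         max_mismatch = 0L) {
  loci <- vector("list", nrow(poly))
  un <- vector("list", nrow(poly))
  for (i in seq_len(nrow(poly))) {
    m <- map_flanks_exact(poly$left_flank[i], poly$right_flank[i],
                          reference, max_gap, max_mismatch)
    if (m$status == "mapped") {
      loci[[i]] <- data.frame(
        locus_id = poly$locus_id[i], chrom = m$chrom, start = m$start,
        end = m$end, strand = m$strand,
        motif_class = poly$focal_class[i],
        allele_lengths = poly$allele_lengths[i], sslp = poly$sslp[i],
        source = poly$source[i])
    } else {
      un[[i]] <- data.frame(locus_id = poly$locus_id[i], reason = m$status)
    }
  }
  list(loci = rbind_or_empty(loci, mapped_locus_proto()),
       unmapped = rbind_or_empty(un, data.frame(locus_id = character(0),
                                                reason = character(0))))
}

mapped_locus_proto <- function() {
  data.frame(locus_id = character(0), chrom = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             motif_class = character(0), allele_lengths = character(0),
             sslp = integer(0), source = character(0))
}

rbind_or_empty <- function(lst, proto) {
  lst <- lst[!vapply(lst, is.null, logical(1))]
  if (length(lst) == 0L) return(proto)
  out <- do.call(rbind, lst)
  rownames(out) <- NULL
  out
}

#' Export flank pairs as FASTA for an external aligner
#'
#' Writes each locus representative's flanks as `<locus_id>/L` and
#' `<locus_id>/R` records, the input expected by [import_sam].
#'
#' @param poly data.frame from [polymorphic_records].
#' @param path output FASTA path.
#' @export
write_flank_fasta <- function(poly, path) {
  seqs <- Biostrings::DNAStringSet(c(poly$left_flank, poly$right_flank))
  names(seqs) <- c(paste0(poly$locus_id, "/L"), paste0(poly$locus_id, "/R"))
  ord <- order(names(seqs))
  Biostrings::writeXStringSet(seqs[ord], path)
  invisible(path)
}

#' Import flank alignments from SAM and derive loci
#'
#' Reads a SAM file of flank alignments (query names `<locus_id>/L` and
#' `<locus_id>/R`, as written by [write_flank_fasta]) produced by an
#' external mapper, keeps primary mapped alignments with MAPQ at or above
#' `mapq_min`, and applies the same concordance rules as
#' [map_flanks_exact].
#'
#' @param poly data.frame from [polymorphic_records] (supplies motif class,
#'   alleles and SSLP per locus id).
#' @param sam_path path to the SAM file.
#' @param mapq_min minimum mapping quality.
#' @param max_gap maximum distance between flank hits, in bp.
#' @return same shape as [map_clusters]: list of `loci` and `unmapped`
#'   (reasons include `"low_mapq"`, `"no_hit"`, `"ambiguous"`,
#'   `"discordant"`).
#' @export
import_sam <- function(poly, sam_path, mapq_min = 30L, max_gap = 1000L) {
  bam <- Rsamtools::asBam(sam_path,
                          destination = tempfile(fileext = ""),
                          overwrite = TRUE, indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  b <- Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "mapq", "cigar")))[[1]]
  aln <- data.frame(qname = b$qname, flag = b$flag,
                    rname = as.character(b$rname), pos = b$pos,
                    mapq = b$mapq, cigar = b$cigar)
  aln <- aln[!bitwAnd(aln$flag, 4L) & !bitwAnd(aln$flag, 256L) &
               !bitwAnd(aln$flag, 2048L), , drop = FALSE]
  aln$strand <- ifelse(bitwAnd(aln$flag, 16L) > 0L, "-", "+")
  aln$end <- aln$pos + cigar_ref_width(aln$cigar) - 1L
  loci <- vector("list", nrow(poly))
  un <- vector("list", nrow(poly))
  for (i in seq_len(nrow(poly))) {
    id <- poly$locus_id[i]
    aL <- aln[aln$qname == paste0(id, "/L"), , drop = FALSE]
    aR <- aln[aln$qname == paste0(id, "/R"), , drop = FALSE]
    status <- NULL
    if (nrow(aL) == 0L || nrow(aR) == 0L) {
      status <- "no_hit"
    } else if (nrow(aL) > 1L || nrow(aR) > 1L) {
      status <- "ambiguous"
    } else if (aL$mapq < mapq_min || aR$mapq < mapq_min) {
      status <- "low_mapq"
    } else if (aL$rname != aR$rname || aL$strand != aR$strand) {
      status <- "discordant"
    } else {
      if (aL$strand == "+") {
        tstart <- aL$end + 1L; tend <- aR$pos - 1L
      } else {
        tstart <- aR$end + 1L; tend <- aL$pos - 1L
      }
      if (tend - tstart + 1L < 1L || tend - tstart + 1L > max_gap) {
        status <- "discordant"
      } else {
        loci[[i]] <- data.frame(
          locus_id = id, chrom = aL$rname, start = tstart, end = tend,
          strand = aL$strand, motif_class = poly$focal_class[i],
          allele_lengths = poly$allele_lengths[i], sslp = poly$sslp[i],
          source = poly$source[i])
      }
    }
    if (!is.null(status))
      un[[i]] <- data.frame(locus_id = id, reason = status)
  }
  list(loci = rbind_or_empty(loci, mapped_locus_proto()),
       unmapped = rbind_or_empty(un, data.frame(locus_id = character(0),
                                                reason = character(0))))
}

# Reference-space width of CIGAR strings (M/D/N/=/X consume reference).
cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    ops <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    n <- as.integer(sub("[MIDNSHP=X]", "", ops))
    op <- sub("\\d+", "", ops)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Aggregate mapped clusters into genome loci within one library
#'
#' Flank clustering can split one physical SSR locus into several clusters
#' (reads sample different fragment windows); once clusters are anchored to
#' the reference, clusters of the same motif class whose tract intervals
#' overlap are one locus. This step merges them, pools the read support
#' behind every tract length, and recomputes the allele set and SSLP with
#' the relative-support rule on the pooled counts (see [compute_sslp]) —
#' support thresholds are meaningful at locus level, where all reads of a
#' locus are in one pool.
#'
#' @param mapping result of [map_clusters] or [import_sam] (or its `loci`
#'   data.frame).
#' @param clusters the `ssr_clusters` object the mapping came from.
#' @param params a [cluster_params] object (supplies `min_allele_frac`).
#' @return data.frame of genome loci: `locus_id` (`chrom:start-end`),
#'   `chrom`, `start`, `end`, `motif_class`, `allele_lengths`, `sslp`,
#'   `n_clusters`, `n_reads`, `source`.
#' @export
aggregate_mapped_loci <- function(mapping, clusters,
                                  params = cluster_params()) {
  loci <- if (is.data.frame(mapping)) mapping else mapping$loci
  proto <- data.frame(locus_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      motif_class = character(0),
                      allele_lengths = character(0), sslp = integer(0),
                      n_clusters = integer(0), n_reads = integer(0),
                      source = character(0))
  if (nrow(loci) == 0L) return(proto)
  lens_by_locus <- split(clusters$members$focal_tract_len,
                         clusters$members$locus_id)
  out <- list()
  for (cls in unique(loci$motif_class)) {
    x <- loci[loci$motif_class == cls, , drop = FALSE]
    gr <- GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start, x$end))
    mrg <- GenomicRanges::reduce(gr)
    hit <- GenomicRanges::findOverlaps(gr, mrg)
    grp <- S4Vectors::subjectHits(hit)[order(S4Vectors::queryHits(hit))]
    for (g in seq_along(mrg)) {
      ids <- x$locus_id[grp == g]
      pooled <- unlist(lens_by_locus[ids], use.names = FALSE)
      kept <- supported_lengths(pooled, params$min_allele_frac)
      out[[length(out) + 1L]] <- data.frame(
        locus_id = sprintf("%s:%d-%d",
                           as.character(GenomicRanges::seqnames(mrg)[g]),
                           GenomicRanges::start(mrg)[g],
                           GenomicRanges::end(mrg)[g]),
        chrom = as.character(GenomicRanges::seqnames(mrg)[g]),
        start = GenomicRanges::start(mrg)[g],
        end = GenomicRanges::end(mrg)[g],
        motif_class = cls,
        allele_lengths = paste(kept, collapse = ","),
        sslp = length(kept),
        n_clusters = length(ids),
        n_reads = length(pooled),
        source = x$source[grp == g][1L])
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cross-population overlap of mapped loci
#'
#' Two loci are the same SSR iff their tract intervals overlap by at least
#' 1 bp on the same chromosome and share a motif class (allele-length
#' differences shift tract ends between populations, so exact coordinates
#' are not required). Merged loci carry the union of populations and allele
#' lengths. Exclusive-intersection counts (UpSet semantics) are reported
#' for every population combination and always sum to the size of the
#' locus union.
#'
#' @param per_breed_loci named list of mapped-locus data.frames (the `loci`
#'   element of [map_clusters] / [import_sam]), one per population.
#' @return list with `loci` (merged loci: `chrom`, `start`, `end`,
#'   `motif_class`, `breeds` (comma-joined, sorted), `n_breeds`,
#'   `allele_lengths` (union), `sslp` (distinct union lengths)) and
#'   `counts` (data.frame `combo`, `degree`, `n`, exclusive counts).
#' @export
overlap_breeds <- function(per_breed_loci) {
  stopifnot(length(names(per_breed_loci)) == length(per_breed_loci))
  breeds <- sort(names(per_breed_loci))
  all <- do.call(rbind, lapply(breeds, function(b) {
    x <- per_breed_loci[[b]]
    if (nrow(x) == 0L) return(NULL)
    x$breed <- b
    x
  }))
  combos <- unlist(lapply(seq_along(breeds), function(d) {
    apply(utils::combn(breeds, d), 2, paste, collapse = "+")
  }))
  empty_counts <- data.frame(
    combo = combos,
    degree = lengths(strsplit(combos, "+", fixed = TRUE)),
    n = 0L)
  if (is.null(all) || nrow(all) == 0L) {
    return(list(loci = data.frame(chrom = character(0), start = integer(0),
                                  end = integer(0),
                                  motif_class = character(0),
                                  breeds = character(0),
                                  n_breeds = integer(0),
                                  allele_lengths = character(0),
                                  sslp = integer(0)),
                counts = empty_counts))
  }
  out <- list()
  for (cls in unique(all$motif_class)) {
    x <- all[all$motif_class == cls, , drop = FALSE]
    gr <- GenomicRanges::GRanges(x$chrom,
                                 IRanges::IRanges(x$start, x$end))
    mrg <- GenomicRanges::reduce(gr)
    hit <- GenomicRanges::findOverlaps(gr, mrg)
    grp <- S4Vectors::subjectHits(hit)[order(S4Vectors::queryHits(hit))]
    for (g in seq_along(mrg)) {
      rows <- x[grp == g, , drop = FALSE]
      lens <- sort(unique(as.integer(unlist(
        strsplit(rows$allele_lengths, ",")))))
      out[[length(out) + 1L]] <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(mrg)[g]),
        start = GenomicRanges::start(mrg)[g],
        end = GenomicRanges::end(mrg)[g],
        motif_class = cls,
        breeds = paste(sort(unique(rows$breed)), collapse = "+"),
        n_breeds = length(unique(rows$breed)),
        allele_lengths = paste(lens, collapse = ","),
        sslp = length(lens))
    }
  }
  loci <- do.call(rbind, out)
  rownames(loci) <- NULL
  counts <- empty_counts
  tb <- table(loci$breeds)
  counts$n <- as.integer(tb[counts$combo])
  counts$n[is.na(counts$n)] <- 0L
  list(loci = loci, counts = counts)
}

#' Annotate loci by gene region
#'
#' Assigns each locus one region class with precedence CDS > 5' UTR >
#' 3' UTR > intron > intergenic (any overlap triggers the class; intron
#' means inside a gene span without exon overlap). Loci on chromosomes
#' absent from the annotation are intergenic, with a warning.
#'
#' @param loci data.frame of loci (`chrom`, `start`, `end`, 1-based
#'   inclusive).
#' @param gene_models a GFF3 path or a [GenomicRanges::GRanges] as returned
#'   by [rtracklayer::import] with `gene`, `exon`, `CDS`,
#'   `five_prime_UTR`, `three_prime_UTR` features.
#' @return list with `annotations` (the loci plus `region` and `gene_id`)
#'   and `summary` (data.frame `region`, `n`, `proportion`; counts sum to
#'   the locus count).
#' @export
annotate_regions <- function(loci, gene_models) {
  if (is.character(gene_models))
    gene_models <- rtracklayer::import(gene_models, format = "gff3")
  gm <- gene_models
  type <- as.character(gm$type)
  gr <- GenomicRanges::GRanges(loci$chrom,
                               IRanges::IRanges(loci$start, loci$end))
  missing_chrom <- !(loci$chrom %in%
                       as.character(GenomicRanges::seqnames(gm)))
  if (any(missing_chrom))
    warning(sum(missing_chrom),
            " locus/loci on chromosomes absent from the annotation;",
            " classified intergenic")
  overlaps_any <- function(sub) {
    if (length(sub) == 0L) return(logical(length(gr)))
    IRanges::overlapsAny(gr, sub, ignore.strand = TRUE)
  }
  in_cds <- overlaps_any(gm[type == "CDS"])
  in_utr5 <- overlaps_any(gm[type == "five_prime_UTR"])
  in_utr3 <- overlaps_any(gm[type == "three_prime_UTR"])
  in_exon <- overlaps_any(gm[type == "exon"])
  genes <- gm[type == "gene"]
  in_gene <- overlaps_any(genes)
  region <- rep("intergenic", length(gr))
  region[in_gene & !in_exon] <- "intron"
  region[in_utr3] <- "three_prime_utr"
  region[in_utr5] <- "five_prime_utr"
  region[in_cds] <- "CDS"
  gene_id <- rep(NA_character_, length(gr))
  if (length(genes)) {
    hit <- GenomicRanges::findOverlaps(gr, genes, ignore.strand = TRUE)
    ids <- genes$ID %||% genes$gene_id %||%
      as.character(seq_along(genes))
    first <- !duplicated(S4Vectors::queryHits(hit))
    gene_id[S4Vectors::queryHits(hit)[first]] <-
      ids[S4Vectors::subjectHits(hit)[first]]
  }
  gene_id[region == "intergenic"] <- NA_character_
  ann <- loci
  ann$region <- region
  ann$gene_id <- gene_id
  lev <- c("CDS", "five_prime_utr", "three_prime_utr", "intron",
           "intergenic")
  n <- as.integer(table(factor(region, levels = lev)))
  summary <- data.frame(region = lev, n = n,
                        proportion = if (length(gr)) n / length(gr) else
                          rep(NA_real_, 5L))
  list(annotations = ann, summary = summary)
}

#' Write loci as BED (0-based half-open) and TSV (1-based inclusive)
#'
#' @param loci mapped-locus data.frame.
#' @param bed_path,tsv_path output paths (`NULL` skips either).
#' @export
write_loci <- function(loci, bed_path = NULL, tsv_path = NULL) {
  if (!is.null(bed_path)) {
    bed <- data.frame(loci$chrom, loci$start - 1L, loci$end,
                      loci$locus_id %||% loci$motif_class,
                      loci$sslp, loci$strand %||% ".")
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(tsv_path))
    utils::write.table(loci, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(NULL)
}
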