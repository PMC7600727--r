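# Pipeline orchestration: merge -> scan -> sslp -> (map -> overlap ->
# annotate) with per-stage counts and table-shaped reports.

#' Pipeline configuration
#'
#' Bundles the per-stage parameter objects. Defaults are the protocol's
#' settings throughout (window 5 / Q20 / Q2 / 50 bp; overlap 100 / density
#' 0.1; min repeats 6/5/5/5/5; flank 20 bp; identity 0.90 / coverage
#' 0.70).
#'
#' @param trim a [trim_params] object.
#' @param merge a [merge_params] object.
#' @param scan a [scan_params] object.
#' @param cluster a [cluster_params] object.
#' @param max_gap,max_mismatch,mapq_min genome-mapping settings (see
#'   [map_clusters], [import_sam]).
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(trim = trim_params(), merge = merge_params(),
                            scan = scan_params(),
                            cluster = cluster_params(),
                            max_gap = 1000L, max_mismatch = 0L,
                            mapq_min = 30L) {
  stopifnot(inherits(trim, "trim_params"),
            inherits(merge, "merge_params"),
            inherits(scan, "scan_params"),
            inherits(cluster, "cluster_params"),
            max_gap >= 1, max_mismatch >= 0, mapq_min >= 0)
  structure(list(trim = trim, merge = merge, scan = scan,
                 cluster = cluster, max_gap = as.integer(max_gap),
                 max_mismatch = as.integer(max_mismatch),
                 mapq_min = as.integer(mapq_min)),
            class = "pipeline_config")
}

empty_clusters <- function(params) {
  structure(list(
    members = data.frame(record_id = character(0),
                         focal_tract_len = integer(0)),
    loci = data.frame(locus_id = character(0), cluster_id = character(0),
                      representative = character(0), n_members = integer(0),
                      focal_class = character(0),
                      focal_unit_size = integer(0),
                      allele_lengths = character(0),
                      allele_repeat_counts = character(0),
                      sslp = integer(0)),
    params = params), class = "ssr_clusters")
}

#' Run the full SSR discovery pipeline
#'
#' Executes merge -> scan -> mask/cluster/SSLP per library, then (when a
#' reference is given) flank mapping, cross-library overlap and gene-region
#' annotation. Every filter's in/out counts are logged.
#'
#' @param libraries named list, one element per library/breed, each either
#'   `list(r1=, r2=)` of [qreads] objects or of FASTQ paths.
#' @param reference optional [Biostrings::DNAStringSet] (or FASTA path)
#'   for flank mapping.
#' @param gene_models optional GFF3 path or GRanges for region annotation.
#' @param config a [pipeline_config] object.
#' @param out_dir optional directory for per-stage TSV outputs.
#' @return list with `per_breed` (for each library: `merged`, `hits`,
#'   `records`, `clusters`, `histogram`, `polymorphic`, `mapping`),
#'   `overlap`, `annotation`, `library_stats` (combined-sequence counts per
#'   library), `sslp_table` (per-library SSLP histogram matrix) and `log`
#'   (per-stage counts).
#' @export
run_pipeline <- function(libraries, reference = NULL, gene_models = NULL,
                         config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"),
            length(names(libraries)) == length(libraries))
  if (is.character(reference))
    reference <- Biostrings::readDNAStringSet(reference)
  per_breed <- list()
  log <- list()
  for (breed in names(libraries)) {
    lib <- libraries[[breed]]
    r1 <- if (is.character(lib$r1)) read_fastq(lib$r1) else lib$r1
    r2 <- if (is.character(lib$r2)) read_fastq(lib$r2) else lib$r2
    if (length(r1) == 0L) {
      warning("library ", breed, " has no reads; reports will be empty")
      ml <- list(merged = qreads(character(0), character(0), list()),
                 stats = data.frame(source = breed, raw_reads = 0L,
                                    high_quality_reads = 0L,
                                    high_quality_bases = 0L,
                                    combined_sequences = 0L,
                                    combined_bases = 0L),
                 kept = logical(0), merged_ok = logical(0))
    } else {
      ml <- merge_library(r1, r2, config$trim, config$merge, source = breed)
    }
    hits <- scan_ssrs(stats::setNames(ml$merged$seq, ml$merged$id),
                      config$scan)
    records <- mask_and_filter(ml$merged, hits, config$cluster,
                               source = breed)
    clusters <- if (nrow(records) > 0L) {
      greedy_cluster(records, config$cluster)
    } else {
      empty_clusters(config$cluster)
    }
    hist <- sslp_histogram(clusters)
    poly <- polymorphic_records(clusters)
    mapping <- NULL
    genome_loci <- NULL
    if (!is.null(reference) && nrow(clusters$loci) > 0L) {
      # map every cluster (monomorphic too): pooled read support at the
      # genome-locus level is what polymorphy is judged on
      mapping <- map_clusters(cluster_flank_table(clusters), reference,
                              config$max_gap, config$max_mismatch)
      genome_loci <- aggregate_mapped_loci(mapping, clusters,
                                           config$cluster)
    }
    log[[breed]] <- data.frame(
      breed = breed,
      pairs_in = length(r1),
      pairs_kept = sum(ml$kept),
      pairs_dropped_short = length(r1) - sum(ml$kept),
      pairs_merged = length(ml$merged),
      pairs_unmerged = sum(ml$kept) - length(ml$merged),
      ssr_hits = nrow(hits),
      masked_records = nrow(records),
      clusters = length(unique(clusters$members$cluster_id)),
      ssr_loci = nrow(clusters$loci),
      polymorphic = nrow(poly),
      mapped = if (is.null(mapping)) NA_integer_ else nrow(mapping$loci),
      unmapped = if (is.null(mapping)) NA_integer_ else
        nrow(mapping$unmapped))
    per_breed[[breed]] <- list(merged = ml$merged, stats = ml$stats,
                               hits = hits, records = records,
                               clusters = clusters, histogram = hist,
                               polymorphic = poly, mapping = mapping,
                               genome_loci = genome_loci)
  }
  overlap <- NULL
  mapped_sets <- lapply(per_breed, function(x)
    if (is.null(x$genome_loci)) NULL else
      x$genome_loci[x$genome_loci$sslp >= 2L, , drop = FALSE])
  mapped_sets <- mapped_sets[!vapply(mapped_sets, is.null, logical(1))]
  if (length(mapped_sets) >= 2L)
    overlap <- overlap_breeds(mapped_sets)
  annotation <- NULL
  if (!is.null(gene_models) && !is.null(overlap) &&
      nrow(overlap$loci) > 0L)
    annotation <- annotate_regions(overlap$loci, gene_models)
  library_stats <- do.call(rbind, lapply(per_breed, `[[`, "stats"))
  sslp_table <- do.call(cbind, lapply(per_breed, function(x)
    stats::setNames(x$histogram$counts$n, x$histogram$counts$sslp_bin)))
  log <- do.call(rbind, log)
  rownames(log) <- NULL
  res <- list(per_breed = per_breed, overlap = overlap,
              annotation = annotation, library_stats = library_stats,
              sslp_table = sslp_table, log = log, config = config)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, name) {
    utils::write.table(x, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  tsv(res$library_stats, "library_stats.tsv")
  tsv(res$log, "pipeline_log.tsv")
  tsv(cbind(sslp_bin = rownames(res$sslp_table), res$sslp_table),
      "sslp_histograms.tsv")
  for (breed in names(res$per_breed)) {
    x <- res$per_breed[[breed]]
    write_misa_tsv(x$hits, file.path(out_dir, paste0(breed, "_ssrs.tsv")))
    tsv(x$clusters$loci, paste0(breed, "_loci.tsv"))
    if (!is.null(x$mapping))
      tsv(x$mapping$loci, paste0(breed, "_mapped.tsv"))
  }
  if (!is.null(res$overlap)) {
    tsv(res$overlap$loci, "overlap_loci.tsv")
    tsv(res$overlap$counts, "overlap_counts.tsv")
  }
  if (!is.null(res$annotation)) {
    tsv(res$annotation$annotations, "region_annotations.tsv")
    tsv(res$annotation$summary, "region_summary.tsv")
    genes <- unique(stats::na.omit(res$annotation$annotations$gene_id))
    writeLines(genes, file.path(out_dir, "gene_list.txt"))
  }
  invisible(out_dir)
}
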