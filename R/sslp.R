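# SSR length polymorphism: mask tracts with 'R', filter by flank length,
# cluster masked sequences by flank similarity (greedy, CD-HIT style) and
# count distinct focal tract lengths per cluster (the SSLP statistic).

#' Clustering parameters
#'
#' Greedy flank-similarity clustering settings. Identity is the fraction of
#' identical aligned positions over the length of the shorter sequence;
#' coverage is the aligned fraction of the shorter sequence. The alignment
#' is global with free end gaps, match +1, mismatch 0, gap open `gap_open`,
#' gap extension `gap_ext`; the mask character `R` aligns only to `R`.
#'
#' @param identity minimum identity fraction.
#' @param coverage minimum aligned coverage of the shorter sequence.
#' @param gap_open,gap_ext gap penalties.
#' @param min_flank minimum flank length in bp on each side of the focal
#'   tract for a record to survive masking.
#' @param max_tracts sequences with more masked tract segments than this are
#'   dropped as likely artifacts.
#' @param min_allele_frac a tract length counts as an allele only when its
#'   read support is at least this fraction of the best-supported length's;
#'   `0` counts every observed length.
#' @param kmer,prefilter word size and switch for the conservative shared
#'   k-mer prefilter that skips alignments which provably cannot reach
#'   `identity`.
#' @return a list of class `cluster_params`.
#' @export
cluster_params <- function(identity = 0.90, coverage = 0.70, gap_open = 1,
                           gap_ext = 0, min_flank = 20L, max_tracts = 5L,
                           min_allele_frac = 0.20, kmer = 8L,
                           prefilter = TRUE) {
  stopifnot(identity > 0, identity <= 1, coverage > 0, coverage <= 1,
            min_allele_frac >= 0, min_allele_frac <= 1, kmer >= 4)
  structure(list(identity = identity, coverage = coverage,
                 gap_open = gap_open, gap_ext = gap_ext,
                 min_flank = as.integer(min_flank),
                 max_tracts = as.integer(max_tracts),
                 min_allele_frac = min_allele_frac, kmer = as.integer(kmer),
                 prefilter = isTRUE(prefilter)),
            class = "cluster_params")
}

# Substitution matrix for masked-sequence alignment: +1 on identical
# A/C/G/T and R-R; 0 for base-base mismatches and anything involving N;
# R never aligns to a base.
masked_submat <- function() {
  letters <- c("A", "C", "G", "T", "N", "R")
  m <- matrix(0, 6, 6, dimnames = list(letters, letters))
  diag(m) <- 1
  m["N", "N"] <- 0
  m["R", c("A", "C", "G", "T", "N")] <- -1000
  m[c("A", "C", "G", "T", "N"), "R"] <- -1000
  m
}

#' Identity and coverage of two masked sequences
#'
#' Aligns two masked sequences (ends-free global alignment, Gotoh affine
#' gaps with the parameters in `params`) and reports the identity fraction
#' (identical aligned positions / shorter length) and the aligned coverage
#' of the shorter sequence.
#'
#' @param a,b masked sequence strings over `{A,C,G,T,N,R}`.
#' @param params a [cluster_params] object.
#' @return `list(identity=, coverage=)`.
#' @export
flank_identity <- function(a, b, params = cluster_params()) {
  al <- masked_align(a, b, params$gap_open, params$gap_ext)
  ns <- min(nchar(a), nchar(b))
  span <- if (nchar(a) <= nchar(b)) {
    al$a_end - al$a_start + 1L
  } else {
    al$b_end - al$b_start + 1L
  }
  list(identity = al$matches / ns, coverage = max(span, 0L) / ns)
}

#' Mask SSR tracts and emit per-tract focal records
#'
#' Replaces every tract with a single `R` (so allele length is invisible to
#' flank clustering) and emits one record per tract with that tract focal.
#' Records whose focal flank on either side (sequence between the tract and
#' the sequence end or the adjacent tract) is shorter than
#' `params$min_flank` are dropped, as are sequences with more than
#' `params$max_tracts` masked segments. Overlapping tracts (different unit
#' sizes sharing bases) are merged into one masked segment and produce no
#' focal record, since neither flanks nor a single allele length are well
#' defined for them.
#'
#' @param seqs named character vector (or [qreads] / DNAStringSet) of
#'   merged sequences.
#' @param hits hit table from [scan_ssrs] on those sequences.
#' @param params a [cluster_params] object.
#' @param source optional library/breed label copied onto records.
#' @return data.frame of masked records: `record_id`, `source_seq_id`,
#'   `masked`, `focal_index` (0-based ordinal of the focal `R`),
#'   `focal_tract_len`, `focal_motif`, `focal_class`, `focal_unit_size`,
#'   `focal_repeat_count`, `left_flank_len`, `right_flank_len`,
#'   `left_flank`, `right_flank` (unmasked flank sequences), `source`.
#' @export
mask_and_filter <- function(seqs, hits, params = cluster_params(),
                            source = NA_character_) {
  if (inherits(seqs, "qreads")) {
    seqs <- stats::setNames(seqs$seq, seqs$id)
  } else if (methods::is(seqs, "XStringSet")) {
    seqs <- stats::setNames(as.character(seqs), names(seqs))
  }
  cols <- c("record_id", "source_seq_id", "masked", "focal_index",
            "focal_tract_len", "focal_motif", "focal_class",
            "focal_unit_size", "focal_repeat_count", "left_flank_len",
            "right_flank_len", "left_flank", "right_flank", "source")
  empty <- as.data.frame(stats::setNames(
    list(character(0), character(0), character(0), integer(0), integer(0),
         character(0), character(0), integer(0), integer(0), integer(0),
         integer(0), character(0), character(0), character(0)), cols))
  if (nrow(hits) == 0L) return(empty)
  nmax <- nrow(hits)
  acc <- list(record_id = character(nmax), source_seq_id = character(nmax),
              masked = character(nmax), focal_index = integer(nmax),
              focal_tract_len = integer(nmax), focal_motif = character(nmax),
              focal_class = character(nmax), focal_unit_size = integer(nmax),
              focal_repeat_count = integer(nmax),
              left_flank_len = integer(nmax), right_flank_len = integer(nmax),
              left_flank = character(nmax), right_flank = character(nmax))
  oi <- 0L
  for (h in split(hits, factor(hits$seq_id, levels = unique(hits$seq_id)))) {
    sid <- h$seq_id[1L]
    s <- seqs[[sid]]
    n <- nchar(s)
    # merge overlapping tract intervals into masked segments
    ir <- IRanges::reduce(IRanges::IRanges(h$start + 1L, h$end))
    if (length(ir) > params$max_tracts) next
    seg_start <- IRanges::start(ir) - 1L       # 0-based
    seg_end <- IRanges::end(ir)
    # masked string: inter-segment pieces joined by 'R'
    piece_from <- c(1L, seg_end + 1L)
    piece_to <- c(seg_start, n)
    masked <- paste(substring(s, piece_from, piece_to), collapse = "R")
    # which segment each hit falls in, and how many hits per segment
    seg_of <- findInterval(h$start, seg_start)
    multi <- tabulate(seg_of, nbins = length(ir)) > 1L
    for (j in which(!multi[seg_of])) {
      sg <- seg_of[j]
      lf <- seg_start[sg] - if (sg > 1L) seg_end[sg - 1L] else 0L
      rf <- (if (sg < length(ir)) seg_start[sg + 1L] else n) - seg_end[sg]
      if (lf < params$min_flank || rf < params$min_flank) next
      oi <- oi + 1L
      acc$record_id[oi] <- paste0(sid, ".", j)
      acc$source_seq_id[oi] <- sid
      acc$masked[oi] <- masked
      acc$focal_index[oi] <- sg - 1L
      acc$focal_tract_len[oi] <- h$end[j] - h$start[j]
      acc$focal_motif[oi] <- h$motif[j]
      acc$focal_class[oi] <- h$canonical_class[j]
      acc$focal_unit_size[oi] <- h$unit_size[j]
      acc$focal_repeat_count[oi] <- h$repeat_count[j]
      acc$left_flank_len[oi] <- lf
      acc$right_flank_len[oi] <- rf
      acc$left_flank[oi] <- substr(s, seg_start[sg] - lf + 1L, seg_start[sg])
      acc$right_flank[oi] <- substr(s, seg_end[sg] + 1L, seg_end[sg] + rf)
    }
  }
  if (oi == 0L) return(empty)
  res <- as.data.frame(lapply(acc, `[`, seq_len(oi)))
  res$source <- source
  res
}

# Shared-kmer prefilter index: environment kmer -> integer vector of rep ids.
kmers_of <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  unique(substring(s, seq_len(n - k + 1L), seq.int(k, n)))
}

#' Greedy flank-similarity clustering of masked records
#'
#' CD-HIT-style greedy incremental clustering: records are sorted by masked
#' length (longest first, ties by `record_id`); each record joins the first
#' existing cluster whose representative aligns with at least the required
#' identity and coverage, otherwise it founds a new cluster. Identical
#' masked strings are grouped up front. A conservative shared k-mer count
#' bound skips representative alignments that cannot reach the identity
#' threshold (`prefilter = FALSE` disables it).
#'
#' After clustering, members are partitioned into SSR loci by (cluster,
#' focal tract ordinal, motif class), and each locus gets its SSLP: the
#' number of distinct focal tract lengths among supporting records (subject
#' to `min_allele_frac`, see [compute_sslp]).
#'
#' @param records data.frame from [mask_and_filter].
#' @param params a [cluster_params] object.
#' @return an object of class `ssr_clusters`: list with `members` (the
#'   input records plus `cluster_id` and `locus_id`) and `loci` (one row
#'   per SSR locus: `locus_id`, `cluster_id`, `representative`,
#'   `n_members`, `focal_class`, `focal_unit_size`, `allele_lengths`,
#'   `allele_repeat_counts` (comma-joined), `sslp`).
#' @export
greedy_cluster <- function(records, params = cluster_params()) {
  stopifnot(nrow(records) > 0L)
  len <- nchar(records$masked)
  ord <- order(-len, records$record_id, method = "radix")
  records <- records[ord, , drop = FALSE]
  len <- len[ord]
  # collapse identical masked strings (first occurrence keeps sort rank)
  grp <- match(records$masked, unique(records$masked))
  ustr <- unique(records$masked)
  ulen <- nchar(ustr)
  n_u <- length(ustr)
  rep_of <- integer(n_u)            # cluster id per unique string
  rep_str <- character(0)
  rep_len <- integer(0)
  idx <- new.env(parent = emptyenv(), size = 4L * n_u)
  k <- params$kmer
  for (u in seq_len(n_u)) {
    s <- ustr[u]
    cand <- seq_along(rep_str)
    if (params$prefilter && length(cand)) {
      ks <- kmers_of(s, k)
      shared <- integer(length(rep_str))
      if (length(ks)) {
        hit <- unlist(mget(ks, envir = idx, ifnotfound = list(integer(0))),
                      use.names = FALSE)
        if (length(hit)) {
          tb <- tabulate(hit, nbins = length(rep_str))
          shared <- tb
        }
      }
      ns <- pmin(ulen[u], rep_len)
      need <- (ns - k + 1) - (1 - params$identity) * ns * k
      cand <- which(shared >= need)
    }
    assigned <- 0L
    for (ci in cand) {
      # exact duplicates were collapsed, but cheap exact check first
      if (ustr[ci] == s) { assigned <- ci; break }
      fi <- flank_identity(s, rep_str[ci], params)
      if (fi$identity >= params$identity && fi$coverage >= params$coverage) {
        assigned <- ci
        break
      }
    }
    if (assigned == 0L) {
      rep_str <- c(rep_str, s)
      rep_len <- c(rep_len, ulen[u])
      assigned <- length(rep_str)
      for (km in kmers_of(s, k)) {
        idx[[km]] <- c(idx[[km]], assigned)
      }
    }
    rep_of[u] <- assigned
  }
  records$cluster_id <- sprintf("C%05d", rep_of[grp])
  records$locus_id <- paste0(records$cluster_id, ".", records$focal_index,
                             ".", records$focal_class)
  loci <- lapply(split(seq_len(nrow(records)), records$locus_id),
                 function(i) {
                   m <- records[i, , drop = FALSE]
                   best <- order(-nchar(m$masked), m$record_id,
                                 method = "radix")[1L]
                   kept <- supported_lengths(m$focal_tract_len,
                                             params$min_allele_frac)
                   data.frame(
                     locus_id = m$locus_id[1L],
                     cluster_id = m$cluster_id[1L],
                     representative = m$record_id[best],
                     n_members = nrow(m),
                     focal_class = m$focal_class[1L],
                     focal_unit_size = m$focal_unit_size[1L],
                     allele_lengths = paste(kept, collapse = ","),
                     allele_repeat_counts = paste(
                       sort(unique(m$focal_repeat_count[
                         m$focal_tract_len %in% kept])), collapse = ","),
                     sslp = length(kept))
                 })
  loci <- do.call(rbind, loci)
  rownames(loci) <- NULL
  structure(list(members = records, loci = loci,
                 params = params), class = "ssr_clusters")
}

# Distinct tract lengths passing the relative read-support rule.
supported_lengths <- function(lens, min_allele_frac) {
  tb <- table(lens)
  keep <- tb >= min_allele_frac * max(tb)
  sort(as.integer(names(tb)[keep]))
}

#' SSLP of one cluster
#'
#' The SSR length polymorphism statistic: the number of distinct focal
#' tract lengths in a cluster (1 when all members share one length). With
#' `min_allele_frac > 0`, a length counts only when its read support is at
#' least that fraction of the best-supported length's — an error-robustness
#' rule that leaves equal-support inputs untouched; `min_allele_frac = 0`
#' is the strict every-observed-length definition.
#'
#' @param tract_lengths integer vector of focal tract lengths (bp) of the
#'   cluster's members.
#' @param min_allele_frac relative support threshold in `[0, 1]`.
#' @return integer SSLP value.
#' @export
compute_sslp <- function(tract_lengths, min_allele_frac = 0.20) {
  stopifnot(length(tract_lengths) > 0L)
  length(supported_lengths(tract_lengths, min_allele_frac))
}

#' SSLP histogram (bins 1-9 and >=10)
#'
#' @param clusters an `ssr_clusters` object, or a data.frame with an `sslp`
#'   column.
#' @return list with `counts` (data.frame `sslp_bin`, `n`) and
#'   `total_clusters`; the bin counts always sum to the total.
#' @export
sslp_histogram <- function(clusters) {
  loci <- if (inherits(clusters, "ssr_clusters")) clusters$loci else clusters
  bins <- c(as.character(1:9), ">=10")
  v <- loci$sslp %||% integer(0)
  lab <- ifelse(v >= 10, ">=10", as.character(v))
  n <- as.integer(table(factor(lab, levels = bins)))
  list(counts = data.frame(sslp_bin = bins, n = n),
       total_clusters = length(v))
}

#' Polymorphic clusters (SSLP >= 2)
#'
#' Filters loci with more than one allele length and attaches flank
#' sequences for genome mapping and primer design: a per-position
#' majority-vote consensus over the members' flanks (anchored at the tract
#' boundary, up to `flank_len` bp), which suppresses isolated sequencing
#' errors that a single representative would carry.
#'
#' @param clusters an `ssr_clusters` object.
#' @param flank_len maximum exported flank length in bp.
#' @return data.frame of polymorphic loci with `left_flank` and
#'   `right_flank` consensus columns.
#' @export
polymorphic_records <- function(clusters, flank_len = 60L) {
  tab <- cluster_flank_table(clusters, flank_len)
  tab <- tab[tab$sslp >= 2L, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Flank table for every cluster locus
#'
#' Like [polymorphic_records] but without the SSLP filter: consensus
#' flanks for every cluster locus, so that monomorphic clusters can also
#' be anchored to the genome (their read support still counts when
#' clusters are pooled into genome loci by [aggregate_mapped_loci]).
#'
#' @inheritParams polymorphic_records
#' @return data.frame of all cluster loci with consensus flank columns.
#' @export
cluster_flank_table <- function(clusters, flank_len = 60L) {
  stopifnot(inherits(clusters, "ssr_clusters"))
  loci <- clusters$loci
  i <- match(loci$representative, clusters$members$record_id)
  mem <- split(clusters$members,
               factor(clusters$members$locus_id, levels = loci$locus_id))
  loci$left_flank <- vapply(mem, function(m)
    consensus_flank(m$left_flank, "left", flank_len), character(1))
  loci$right_flank <- vapply(mem, function(m)
    consensus_flank(m$right_flank, "right", flank_len), character(1))
  loci$focal_motif <- clusters$members$focal_motif[i]
  loci$source <- clusters$members$source[i]
  rownames(loci) <- NULL
  loci
}

# Majority-vote consensus of flank sequences anchored at the tract
# boundary: left flanks are right-aligned (they end at the tract), right
# flanks left-aligned. Positions are called from the members covering them.
consensus_flank <- function(flanks, side = c("left", "right"),
                            max_len = 60L) {
  side <- match.arg(side)
  if (length(flanks) == 1L) {
    return(if (side == "left")
      substr(flanks, max(1L, nchar(flanks) - max_len + 1L), nchar(flanks))
      else substr(flanks, 1L, max_len))
  }
  L <- min(max(nchar(flanks)), max_len)
  cons <- character(L)
  chs <- strsplit(flanks, "", fixed = TRUE)
  for (off in seq_len(L)) {
    b <- vapply(chs, function(ch) {
      n <- length(ch)
      if (n < off) NA_character_
      else if (side == "left") ch[n - off + 1L] else ch[off]
    }, character(1))
    b <- b[!is.na(b)]
    if (length(b) == 0L) { L <- off - 1L; break }
    tb <- sort(table(b), decreasing = TRUE)
    cons[off] <- names(tb)[1L]
  }
  cons <- cons[seq_len(L)]
  if (side == "left") paste(rev(cons), collapse = "")
  else paste(cons, collapse = "")
}
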