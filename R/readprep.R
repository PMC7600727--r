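# Read preparation: sliding-window quality trimming, short-pair filtering,
# and FLASH-style merging of overlapping innie pairs.

#' Trimming parameters
#'
#' Sliding-window quality trimming settings. A read is scanned 5'->3' with a
#' window of `window` bp advanced by `step` bp; it is truncated immediately
#' before the first window whose mean quality falls below `mean_q_min` or
#' whose final base quality falls below `last_q_min`. Pairs in which either
#' mate ends up shorter than `pair_min_len` are discarded.
#'
#' @param window window size in bp.
#' @param step window step in bp.
#' @param mean_q_min minimum mean phred quality per window.
#' @param last_q_min minimum phred quality of the window's last base.
#' @param pair_min_len minimum post-trim length of each mate, in bp.
#' @return a list of class `trim_params`.
#' @export
trim_params <- function(window = 5L, step = 1L, mean_q_min = 20,
                        last_q_min = 2, pair_min_len = 50L) {
  stopifnot(window >= 1, step >= 1, pair_min_len >= 0)
  structure(list(window = as.integer(window), step = as.integer(step),
                 mean_q_min = mean_q_min, last_q_min = last_q_min,
                 pair_min_len = as.integer(pair_min_len)),
            class = "trim_params")
}

#' Merge parameters
#'
#' Settings for overlap-merging a read pair into one fragment-length
#' sequence. Every innie overlap length from `min_overlap` up to the shorter
#' read length is scored by mismatch density (mismatches / overlap length,
#' `N` always counting as a mismatch); the lowest-density candidate wins,
#' ties broken towards the longer overlap, and the merge is accepted iff
#' that density is at most `max_mismatch_density`. Outie (read-through)
#' overlaps are not considered.
#'
#' @param min_overlap minimum overlap length in bp.
#' @param max_mismatch_density maximum accepted mismatch fraction in the
#'   overlap.
#' @param allow_outies must be `FALSE`; accepted for interface completeness.
#' @return a list of class `merge_params`.
#' @export
merge_params <- function(min_overlap = 100L, max_mismatch_density = 0.1,
                         allow_outies = FALSE) {
  stopifnot(min_overlap >= 1,
            max_mismatch_density >= 0, max_mismatch_density <= 1)
  if (isTRUE(allow_outies))
    stop("outie merging is not implemented (disabled in this protocol)")
  structure(list(min_overlap = as.integer(min_overlap),
                 max_mismatch_density = max_mismatch_density,
                 allow_outies = FALSE),
            class = "merge_params")
}

#' Construct a set of quality-scored reads
#'
#' The package's light-weight in-memory read container: parallel vectors of
#' ids and sequences plus a list of integer phred quality vectors.
#'
#' @param id character vector of read ids.
#' @param seq character vector of sequences over `{A,C,G,T,N}`.
#' @param qual list of integer phred quality vectors, one per read, each the
#'   same length as its sequence.
#' @return a list of class `qreads`.
#' @export
qreads <- function(id, seq, qual) {
  stopifnot(length(id) == length(seq), length(seq) == length(qual))
  lens_ok <- nchar(seq) == lengths(qual)
  if (!all(lens_ok))
    stop("sequence and quality lengths differ for read(s): ",
         paste(utils::head(id[!lens_ok], 3), collapse = ", "))
  rng <- range(c(0L, unlist(qual, use.names = FALSE)))
  if (rng[1] < 0 || rng[2] > 93) stop("phred qualities must be in [0, 93]")
  structure(list(id = unname(as.character(id)),
                 seq = unname(toupper(seq)),
                 qual = unname(lapply(qual, unname))),
            class = "qreads")
}

#' @export
length.qreads <- function(x) length(x$id)

#' @export
`[.qreads` <- function(x, i) qreads(x$id[i], x$seq[i], x$qual[i])

#' Read a FASTQ file (phred+33, plain or gzip)
#'
#' @param path FASTQ path; `.gz` is handled transparently.
#' @return a [qreads] object.
#' @export
read_fastq <- function(path) {
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  qual <- as.list(methods::as(Biostrings::quality(x), "IntegerList"))
  qreads(names(x), as.character(x), qual)
}

#' Write reads as FASTQ (phred+33)
#'
#' @param reads a [qreads] object.
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @export
write_fastq <- function(reads, path) {
  qchar <- vapply(reads$qual,
                  function(q) rawToChar(as.raw(q + 33L)), character(1))
  # Biostrings warns about dropping (empty) metadata columns here
  suppressWarnings({
    x <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(reads$seq),
      Biostrings::PhredQuality(qchar))
    names(x) <- reads$id
    Biostrings::writeQualityScaledXStringSet(
      x, path, compress = grepl("\\.gz$", path))
  })
  invisible(path)
}

# Kept prefix length of one read under the windowed rule. `q` is the quality
# vector with N bases already forced to 0.
trimmed_length <- function(q, params) {
  n <- length(q)
  w <- params$window
  if (n < w) return(n)                      # no full window fits: unchanged
  starts <- seq.int(1L, n - w + 1L, by = params$step)
  cs <- cumsum(c(0, q))
  means <- (cs[starts + w] - cs[starts]) / w
  bad <- means < params$mean_q_min | q[starts + w - 1L] < params$last_q_min
  i <- which(bad)[1L]
  if (is.na(i)) n else starts[i] - 1L
}

#' Quality-trim a single read
#'
#' Scans 5'->3' with the configured sliding window and keeps the prefix
#' before the first failing window (possibly empty). `N` bases count as
#' quality 0 in window means. Reads shorter than one window are returned
#' unchanged; the pair-length filter handles them downstream.
#'
#' @param bases sequence string.
#' @param quals integer phred qualities, one per base.
#' @param params a [trim_params] object.
#' @return `list(bases=, quals=)` with the kept prefix.
#' @export
trim_read <- function(bases, quals, params = trim_params()) {
  stopifnot(nchar(bases) == length(quals))
  q <- quals
  if (grepl("N", bases, fixed = TRUE)) {
    q[strsplit(bases, "", fixed = TRUE)[[1]] == "N"] <- 0L
  }
  keep <- trimmed_length(q, params)
  list(bases = substr(bases, 1L, keep), quals = quals[seq_len(keep)])
}

#' Quality-trim a read set
#'
#' Vectorized [trim_read] over a [qreads] object.
#'
#' @param reads a [qreads] object.
#' @param params a [trim_params] object.
#' @return a trimmed [qreads] object.
#' @export
trim_reads <- function(reads, params = trim_params()) {
  keep <- integer(length(reads))
  for (i in seq_along(keep)) {
    q <- reads$qual[[i]]
    s <- reads$seq[i]
    if (grepl("N", s, fixed = TRUE))
      q[strsplit(s, "", fixed = TRUE)[[1]] == "N"] <- 0L
    keep[i] <- trimmed_length(q, params)
  }
  qreads(reads$id, substr(reads$seq, 1L, keep),
         mapply(function(q, k) q[seq_len(k)], reads$qual, keep,
                SIMPLIFY = FALSE))
}

#' Short-pair filter
#'
#' A pair is kept iff both trimmed mates are at least `pair_min_len` bp
#' ("less than" is strict: a 50-bp mate passes the default 50-bp rule).
#'
#' @param len1,len2 integer vectors of mate lengths.
#' @param params a [trim_params] object.
#' @return logical vector, `TRUE` for kept pairs.
#' @export
filter_pair <- function(len1, len2, params = trim_params()) {
  len1 >= params$pair_min_len & len2 >= params$pair_min_len
}

#' Merge one read pair by its best innie overlap
#'
#' Considers every overlap length L from the shorter read length down to
#' `min_overlap` between read 1 and the reverse complement of read 2; picks
#' the candidate with the lowest mismatch density (ties to the larger L) and
#' merges iff that density is at most `max_mismatch_density`. At mismatched
#' positions the base with the higher quality wins (ties to read 1) and the
#' winning quality is kept; at matches the higher of the two qualities is
#' kept (mismatch qualities are not capped).
#'
#' @param r1,r2 sequence strings (r2 as sequenced, i.e. reverse-strand mate).
#' @param q1,q2 integer quality vectors.
#' @param params a [merge_params] object.
#' @return `list(bases=, quals=, overlap_len=)` or `NULL` when no candidate
#'   overlap qualifies.
#' @export
merge_pair <- function(r1, q1, r2, q2, params = merge_params()) {
  rc2 <- revcomp(r2)
  q2r <- rev(q2)
  a <- encode_bases(r1)
  b <- encode_bases(rc2)
  mm <- overlap_mismatch_counts(a, b, params$min_overlap)
  if (length(mm) == 0L) return(NULL)
  Ls <- seq.int(params$min_overlap, length.out = length(mm))
  dens <- mm / Ls
  best <- order(dens, -Ls)[1L]
  if (dens[best] > params$max_mismatch_density) return(NULL)
  L <- Ls[best]
  n1 <- length(a); n2 <- length(b)
  ia <- seq.int(n1 - L + 1L, n1)
  ib <- seq_len(L)
  ca <- strsplit(substr(r1, n1 - L + 1L, n1), "", fixed = TRUE)[[1]]
  cb <- strsplit(substr(rc2, 1L, L), "", fixed = TRUE)[[1]]
  qa <- q1[ia]; qb <- q2r[ib]
  take_b <- ca != cb & qb > qa
  cons <- ca
  cons[take_b] <- cb[take_b]
  bases <- paste0(substr(r1, 1L, n1 - L), paste(cons, collapse = ""),
                  substr(rc2, L + 1L, n2))
  quals <- c(q1[seq_len(n1 - L)], pmax(qa, qb), q2r[seq.int(L + 1L, length.out = n2 - L)])
  list(bases = bases, quals = quals, overlap_len = L)
}

#' Trim, filter and merge a full library of read pairs
#'
#' Runs [trim_reads] on both mates, drops short pairs, merges the rest, and
#' reports per-library counts (raw reads, high-quality reads, total bases,
#' combined sequences, combined bases).
#'
#' @param r1,r2 [qreads] objects of mates 1 and 2, in matching order.
#' @param trim a [trim_params] object.
#' @param merge a [merge_params] object.
#' @param source optional library/breed label stored on the merged set.
#' @return a list with `merged` (a [qreads] of combined sequences),
#'   `overlap_len` (integer vector), `stats` (one-row data.frame), and
#'   `kept` / `merged_ok` logical vectors tracing each input pair.
#' @export
merge_library <- function(r1, r2, trim = trim_params(),
                          merge = merge_params(), source = "library") {
  stopifnot(length(r1) == length(r2))
  n_raw <- 2L * length(r1)
  t1 <- trim_reads(r1, trim)
  t2 <- trim_reads(r2, trim)
  kept <- filter_pair(nchar(t1$seq), nchar(t2$seq), trim)
  idx <- which(kept)
  seqs <- character(length(idx))
  quals <- vector("list", length(idx))
  ovl <- integer(length(idx))
  ok <- logical(length(idx))
  for (j in seq_along(idx)) {
    i <- idx[j]
    m <- merge_pair(t1$seq[i], t1$qual[[i]], t2$seq[i], t2$qual[[i]], merge)
    if (!is.null(m)) {
      ok[j] <- TRUE
      seqs[j] <- m$bases
      quals[[j]] <- m$quals
      ovl[j] <- m$overlap_len
    }
  }
  merged_ok <- logical(length(r1))
  merged_ok[idx[ok]] <- TRUE
  merged <- qreads(sub("/[12]$", "", t1$id[idx[ok]]), seqs[ok], quals[ok])
  ovl <- ovl[ok]
  stats <- data.frame(
    source = source,
    raw_reads = n_raw,
    high_quality_reads = 2L * sum(kept),
    high_quality_bases = sum(nchar(t1$seq[kept])) + sum(nchar(t2$seq[kept])),
    combined_sequences = length(merged),
    combined_bases = sum(nchar(seqs)))
  list(merged = merged, overlap_len = ovl, stats = stats,
       kept = kept, merged_ok = merged_ok, source = source)
}
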