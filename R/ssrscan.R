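# Maximal perfect SSR detection (unit sizes 2-6), MISA-style thresholds,
# motif canonicalization into strand/rotation classes, and census summaries.

#' Scan parameters
#'
#' @param min_repeats named integer vector mapping unit size (`"2"`..`"6"`)
#'   to the minimum repeat count for a tract to be reported.
#' @param max_interruption maximum gap in bp between consecutive tracts for
#'   them to be grouped as one compound SSR.
#' @return a list of class `scan_params`.
#' @export
scan_params <- function(min_repeats = c("2" = 6L, "3" = 5L, "4" = 5L,
                                        "5" = 5L, "6" = 5L),
                        max_interruption = 100L) {
  stopifnot(identical(sort(names(min_repeats)), c("2", "3", "4", "5", "6")),
            all(min_repeats >= 2))
  structure(list(min_repeats = min_repeats[c("2", "3", "4", "5", "6")],
                 max_interruption = as.integer(max_interruption)),
            class = "scan_params")
}

#' Is a motif primitive?
#'
#' A motif is primitive when it is not a whole-number repetition of a
#' shorter unit (`"ATAT"` is `(AT)x2`, hence not primitive).
#'
#' @param motif character vector of motifs.
#' @return logical vector.
#' @export
is_primitive_motif <- function(motif) {
  vapply(motif, function(m) {
    k <- nchar(m)
    for (d in seq_len(k - 1)) {
      if (k %% d == 0L &&
          m == strrep(substr(m, 1L, d), k %/% d)) return(FALSE)
    }
    TRUE
  }, logical(1), USE.NAMES = FALSE)
}

rotations <- function(m) {
  k <- nchar(m)
  vapply(seq_len(k), function(i) {
    paste0(substr(m, i, k), substr(m, 1L, i - 1L))
  }, character(1))
}

#' Canonical strand/rotation class of a repeat motif
#'
#' Maps a motif to its class label `"X/Y"` where `X` is the
#' lexicographically smallest string among all cyclic rotations of the motif
#' and of its reverse complement, and `Y` is the smallest rotation of
#' `revcomp(X)`. All `2k` rotation/strand variants of a motif share one
#' label (e.g. `"GT"`, `"TG"`, `"CA"`, `"AC"` are all `"AC/GT"`).
#'
#' @param motif character vector of primitive motifs over `{A,C,G,T}`,
#'   lengths 2-6.
#' @return character vector of class labels.
#' @export
canonical_class <- function(motif) {
  if (length(motif) == 0L) return(character(0))
  if (!all(grepl("^[ACGT]+$", motif)))
    stop("motif must be over the alphabet {A,C,G,T}")
  if (!all(nchar(motif) %in% 2:6))
    stop("motif length must be in [2, 6]")
  if (!all(is_primitive_motif(motif)))
    stop("motif must be primitive (not a repetition of a shorter unit): ",
         paste(unique(motif[!is_primitive_motif(motif)]), collapse = ", "))
  u <- unique(motif)
  lab <- vapply(u, function(m) {
    x <- min(c(rotations(m), rotations(revcomp(m))))
    paste0(x, "/", min(rotations(revcomp(x))))
  }, character(1))
  unname(lab[match(motif, u)])
}

#' Scan sequences for maximal perfect SSRs
#'
#' Finds every maximal perfect tandem tract with a primitive repeat unit of
#' 2-6 bp and repeat count at or above the per-unit-size threshold. Tract
#' boundaries cover complete units only (MISA convention: size = unit x
#' count); a periodic region yields one tract, anchored at the region's
#' leftmost position. Runs of `N` split a sequence into independently
#' scanned segments. Coordinates are 0-based half-open.
#'
#' @param seqs character vector of sequences over `{A,C,G,T,N}` (a
#'   [Biostrings::DNAStringSet] is accepted and converted).
#' @param params a [scan_params] object.
#' @param seq_ids sequence identifiers; defaults to `names(seqs)` or an
#'   index.
#' @return data.frame with columns `seq_id`, `start`, `end`, `motif`,
#'   `unit_size`, `repeat_count`, `canonical_class`, sorted by sequence and
#'   ascending start.
#' @export
scan_ssrs <- function(seqs, params = scan_params(), seq_ids = NULL) {
  if (methods::is(seqs, "XStringSet")) seqs <- as.character(seqs)
  if (is.null(seq_ids))
    seq_ids <- names(seqs) %||% as.character(seq_along(seqs))
  empty <- data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), motif = character(0),
                      unit_size = integer(0), repeat_count = integer(0),
                      canonical_class = character(0))
  if (length(seqs) == 0L || all(nchar(seqs) == 0L)) return(empty)
  seqs <- toupper(seqs)
  # One pass over the concatenation, sequences separated by an N sentinel.
  big <- strsplit(paste(seqs, collapse = "N"), "", fixed = TRUE)[[1]]
  offs <- cumsum(c(1L, nchar(seqs) + 1L))[seq_along(seqs)]  # 1-based starts
  n <- length(big)
  notN <- big != "N"
  out <- vector("list", 5L)
  for (k in 2:6) {
    if (n <= k) next
    b <- big[seq_len(n - k)] == big[seq.int(k + 1L, n)] &
      notN[seq_len(n - k)] & notN[seq.int(k + 1L, n)]
    r <- rle(b)
    ends <- cumsum(r$lengths)
    sel <- r$values & r$lengths + k >= k * params$min_repeats[[as.character(k)]]
    if (!any(sel)) next
    run_start <- ends[sel] - r$lengths[sel] + 1L
    cnt <- (r$lengths[sel] + k) %/% k
    motif <- vapply(run_start,
                    function(i) paste(big[seq.int(i, i + k - 1L)],
                                      collapse = ""), character(1))
    prim <- is_primitive_motif(motif)
    if (!any(prim)) next
    run_start <- run_start[prim]; cnt <- cnt[prim]; motif <- motif[prim]
    si <- findInterval(run_start, offs)
    start0 <- run_start - offs[si]           # 0-based within the sequence
    out[[k - 1L]] <- data.frame(
      seq_id = seq_ids[si], start = start0, end = start0 + k * cnt,
      motif = motif, unit_size = k, repeat_count = cnt,
      canonical_class = canonical_class(motif))
  }
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0L) return(empty)
  out <- out[order(match(out$seq_id, seq_ids), out$start, out$unit_size), ]
  rownames(out) <- NULL
  out
}

#' Group nearby tracts into compound SSRs
#'
#' Consecutive tracts on one sequence whose gap is at most
#' `max_interruption` bp form one compound group (MISA-compatible
#' annotation; census tables still count individual tracts).
#'
#' @param hits a hit table from [scan_ssrs], sorted by sequence and start.
#' @param params a [scan_params] object.
#' @return the hit table with an added `compound_id` column
#'   (`<seq_id>.c<index>`); singleton groups allowed.
#' @export
group_compound <- function(hits, params = scan_params()) {
  if (nrow(hits) == 0L) {
    hits$compound_id <- character(0)
    return(hits)
  }
  new_seq <- c(TRUE, hits$seq_id[-1] != hits$seq_id[-nrow(hits)])
  gap <- c(0L, hits$start[-1] - hits$end[-nrow(hits)])
  brk <- new_seq | gap > params$max_interruption
  grp <- cumsum(brk)
  idx <- stats::ave(grp, hits$seq_id, FUN = function(g) match(g, unique(g)))
  hits$compound_id <- paste0(hits$seq_id, ".c", idx)
  hits
}

#' Census of repeat-unit classes
#'
#' @param hits a hit table from [scan_ssrs].
#' @param seq_lengths integer vector of scanned sequence lengths (for the
#'   genome-fraction figure); optional.
#' @return a list with `table` (counts by unit size, class and repeat
#'   count), `by_unit` (counts and proportions per unit size),
#'   `class_by_unit` (per-class proportions within each unit size) and
#'   `genome_fraction` (total tract bp / total sequence bp, `0` when
#'   `seq_lengths` is missing or empty).
#' @export
summarize_classes <- function(hits, seq_lengths = NULL) {
  if (nrow(hits) == 0L) {
    return(list(table = data.frame(unit_size = integer(0),
                                   canonical_class = character(0),
                                   repeat_count = integer(0), n = integer(0)),
                by_unit = data.frame(unit_size = integer(0), n = integer(0),
                                     proportion = numeric(0)),
                class_by_unit = data.frame(unit_size = integer(0),
                                           canonical_class = character(0),
                                           n = integer(0),
                                           proportion = numeric(0)),
                genome_fraction = 0))
  }
  tab <- stats::aggregate(
    list(n = rep(1L, nrow(hits))),
    by = hits[c("unit_size", "canonical_class", "repeat_count")], FUN = sum)
  tab <- tab[order(tab$unit_size, tab$canonical_class, tab$repeat_count), ]
  by_unit <- stats::aggregate(list(n = rep(1L, nrow(hits))),
                              by = hits["unit_size"], FUN = sum)
  by_unit$proportion <- by_unit$n / sum(by_unit$n)
  cbu <- stats::aggregate(list(n = rep(1L, nrow(hits))),
                          by = hits[c("unit_size", "canonical_class")],
                          FUN = sum)
  cbu$proportion <- cbu$n / by_unit$n[match(cbu$unit_size, by_unit$unit_size)]
  cbu <- cbu[order(cbu$unit_size, -cbu$n), ]
  gf <- if (is.null(seq_lengths) || sum(seq_lengths) == 0) 0 else
    sum(hits$end - hits$start) / sum(seq_lengths)
  rownames(tab) <- rownames(by_unit) <- rownames(cbu) <- NULL
  list(table = tab, by_unit = by_unit, class_by_unit = cbu,
       genome_fraction = gf)
}

#' Positional frequency of tract starts
#'
#' Histograms of tract start positions, absolute (bp bins) and normalized
#' by sequence length (equal-width bins on `[0, 1]`).
#'
#' @param hits a hit table from [scan_ssrs].
#' @param seq_lengths named integer vector of sequence lengths, names
#'   matching `seq_id`.
#' @param bins number of bins.
#' @return list with data.frames `absolute` (`bin_start`, `bin_end`, `n`)
#'   and `normalized` (`bin_lo`, `bin_hi`, `n`); both empty for empty input.
#' @export
positional_frequency <- function(hits, seq_lengths, bins = 10L) {
  if (nrow(hits) == 0L) {
    return(list(absolute = data.frame(bin_start = numeric(0),
                                      bin_end = numeric(0), n = integer(0)),
                normalized = data.frame(bin_lo = numeric(0),
                                        bin_hi = numeric(0), n = integer(0))))
  }
  maxlen <- max(seq_lengths)
  abr <- seq(0, maxlen, length.out = bins + 1L)
  acut <- cut(hits$start, breaks = abr, include.lowest = TRUE, right = FALSE)
  absolute <- data.frame(bin_start = abr[-length(abr)], bin_end = abr[-1],
                         n = as.integer(table(acut)))
  rel <- hits$start / seq_lengths[hits$seq_id]
  nbr <- seq(0, 1, length.out = bins + 1L)
  ncut <- cut(rel, breaks = nbr, include.lowest = TRUE, right = FALSE)
  normalized <- data.frame(bin_lo = nbr[-length(nbr)], bin_hi = nbr[-1],
                           n = as.integer(table(ncut)))
  list(absolute = absolute, normalized = normalized)
}

#' Export hits as a MISA-style TSV (1-based inclusive coordinates)
#'
#' @param hits a hit table from [scan_ssrs] (optionally with `compound_id`
#'   from [group_compound]).
#' @param path output TSV path.
#' @export
write_misa_tsv <- function(hits, path) {
  hits <- group_compound(hits)
  nr <- stats::ave(seq_len(nrow(hits)), hits$seq_id,
                   FUN = seq_along)
  out <- data.frame(
    ID = hits$seq_id,
    `SSR nr.` = if (nrow(hits)) nr else integer(0),
    `SSR type` = paste0("p", hits$unit_size),
    SSR = paste0("(", hits$motif, ")", hits$repeat_count),
    size = hits$end - hits$start,
    start = hits$start + 1L,
    end = hits$end,
    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
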