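# Independent brute-force oracles and small fixture builders.

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Brute-force maximal perfect SSR enumerator: per-position left/right
# extension of single-base periodicity, complete-unit tract boundaries.
# Independent of the package's vectorized run-length implementation.
brute_scan <- function(s, min_rep = c("2" = 6L, "3" = 5L, "4" = 5L,
                                      "5" = 5L, "6" = 5L)) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(ch)
  out <- list()
  for (k in 2:6) {
    bij <- function(j) {
      j >= 1 && j + k <= n && ch[j] != "N" && ch[j + k] != "N" &&
        ch[j] == ch[j + k]
    }
    i <- 1L
    while (i + k <= n) {
      if (bij(i) && !bij(i - 1L)) {
        m <- k
        j <- i
        while (bij(j)) {
          m <- m + 1L
          j <- j + 1L
        }
        cnt <- m %/% k
        motif <- paste(ch[i:(i + k - 1L)], collapse = "")
        if (cnt >= min_rep[[as.character(k)]] &&
            !grepl("N", motif, fixed = TRUE) &&
            is_primitive_motif(motif)) {
          out[[length(out) + 1L]] <- data.frame(
            start = i - 1L, end = i - 1L + k * cnt, motif = motif,
            unit_size = k, repeat_count = cnt)
        }
        i <- j + 1L
      } else {
        i <- i + 1L
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      motif = character(0), unit_size = integer(0),
                      repeat_count = integer(0)))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$unit_size), ]
  rownames(res) <- NULL
  res
}

# Brute-force sliding-window trimmer: literal loop over every window.
brute_trim_length <- function(q, window = 5L, step = 1L, mean_q_min = 20,
                              last_q_min = 2) {
  n <- length(q)
  if (n < window) return(n)
  i <- 1L
  while (i + window - 1L <= n) {
    w <- q[i:(i + window - 1L)]
    if (mean(w) < mean_q_min || w[window] < last_q_min) return(i - 1L)
    i <- i + step
  }
  n
}

# A fixed flank pair guaranteed to carry no SSR and not to extend an
# adjacent tract of the given motif (checked, deterministic under seed).
ssr_free_flanks <- function(len = 60L, motif = "AC", seed = 42L) {
  withr::with_seed(seed, {
    repeat {
      fl <- random_dna(len)
      fr <- random_dna(len)
      probe <- paste0(fl, strrep(motif, 12L), fr)
      h <- scan_ssrs(probe)
      if (nrow(h) == 1L && h$end - h$start == 24L &&
          nrow(scan_ssrs(fl)) == 0L && nrow(scan_ssrs(fr)) == 0L) {
        return(list(left = fl, right = fr))
      }
    }
  })
}

# Shared small simulated dataset for pipeline-level tests (built once per
# test run; ~12 loci, 2 breeds, low coverage).
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 7L, genome_len = 80000L, n_chrom = 2L,
                        n_loci = 12L, n_breeds = 2L,
                        per_allele_coverage = 8L,
                        breed_sharing_design = "all",
                        base_error_rate = 0, low_tail_rate = 0)
      ref <- make_reference(cfg)
      sim <- simulate_reads(ref)
      cache <<- list(ref = ref, sim = sim)
    }
    cache
  }
})
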