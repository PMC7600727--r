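# Masking, flank clustering and the SSLP statistic.

tract_seq <- function(left, motif, n, right) paste0(left, strrep(motif, n),
                                                    right)

test_that("masking replaces tracts with one R and enforces the 20-bp flank rule", {
  fl <- ssr_free_flanks(20, "AC", seed = 101)
  s <- c(m1 = tract_seq(fl$left, "AC", 12, fl$right))
  rec <- mask_and_filter(s, scan_ssrs(s))
  expect_identical(nrow(rec), 1L)
  expect_identical(nchar(rec$masked), 41L)
  expect_identical(rec$focal_tract_len, 24L)
  expect_identical(rec$left_flank_len, 20L)
  expect_identical(lengths(regmatches(rec$masked,
                                      gregexpr("R", rec$masked))), 1L)
  # 19-bp left flank: dropped
  s19 <- c(m2 = tract_seq(substr(fl$left, 2, 20), "AC", 12,
                          paste0(fl$right, fl$left)))
  expect_identical(nrow(mask_and_filter(s19, scan_ssrs(s19))), 0L)
})

test_that("two tracts 30 bp apart yield two records with both flanks counted to the neighbour", {
  fl <- ssr_free_flanks(25, "AC", seed = 102)
  mid <- ssr_free_flanks(30, "AC", seed = 103)$left
  s <- c(d1 = paste0(fl$left, strrep("AC", 12), mid, strrep("AT", 8),
                     fl$right))
  h <- scan_ssrs(s)
  expect_identical(nrow(h), 2L)
  rec <- mask_and_filter(s, h)
  expect_identical(nrow(rec), 2L)
  expect_identical(rec$focal_index, c(0L, 1L))
  expect_identical(rec$left_flank_len, c(25L, 30L))
  expect_identical(rec$right_flank_len, c(30L, 25L))
  expect_identical(rec$masked[1], rec$masked[2])
  # both records keep the unmasked flank sequence next to their tract
  expect_identical(rec$right_flank[1], mid)
  expect_identical(rec$left_flank[2], mid)
})

test_that("overlapping tracts of different unit sizes produce no focal record", {
  fl <- ssr_free_flanks(40, "AC", seed = 104)
  s <- c(ov = paste0(fl$left, "ACACACACACACGACGACGACGACG", fl$right))
  h <- scan_ssrs(s)
  expect_identical(nrow(h), 2L)      # AC x6 and ACG x5, sharing bases
  expect_identical(nrow(mask_and_filter(s, h)), 0L)
})

test_that("alignment identity/coverage agree with Biostrings on score and on designed cases", {
  p <- cluster_params()
  submat <- micropoly:::masked_submat()
  withr::with_seed(41, {
    for (i in 1:20) {
      n <- sample(60:150, 1)
      a <- random_dna(n)
      sh <- sample(0:12, 1)
      b <- paste0(substr(a, sh + 1, n),
                  paste(sample(c("A", "C", "G", "T"), sh, TRUE),
                        collapse = ""))
      al <- micropoly:::masked_align(a, b, p$gap_open, p$gap_ext)
      bs <- Biostrings::pairwiseAlignment(
        Biostrings::BString(a), Biostrings::BString(b), type = "overlap",
        substitutionMatrix = submat, gapOpening = p$gap_open,
        gapExtension = p$gap_ext)
      expect_equal(al$score, Biostrings::score(bs))
    }
  })
  # substitution-only pair: identity is exactly (n - subs)/n
  withr::with_seed(42, {
    a <- random_dna(100)
    ch <- strsplit(a, "")[[1]]
    pos <- sample(5:95, 15)
    for (q in pos) ch[q] <- setdiff(c("A", "C", "G", "T"), ch[q])[1]
    b <- paste(ch, collapse = "")
    fi <- flank_identity(a, b, p)
    expect_equal(fi$identity, 0.85)
    expect_equal(fi$coverage, 1)
  })
  # R aligns only to R
  fi <- flank_identity("AAAARAAAA", "AAAARAAAA", p)
  expect_equal(fi$identity, 1)
  fi2 <- flank_identity("AAAARAAAA", "AAAACAAAA", p)
  expect_lt(fi2$identity, 1)
})

test_that("identical records form one cluster and allele length is invisible to clustering", {
  fl <- ssr_free_flanks(40, "AC", seed = 105)
  seqs <- stats::setNames(rep(tract_seq(fl$left, "AC", 12, fl$right), 10),
                          sprintf("r%02d", 1:10))
  cl <- greedy_cluster(mask_and_filter(seqs, scan_ssrs(seqs)))
  expect_identical(length(unique(cl$members$cluster_id)), 1L)
  expect_identical(cl$loci$n_members, 10L)
  expect_identical(cl$loci$sslp, 1L)
  # same flanks, tract lengths 24 vs 34: masking collapses the alleles
  s2 <- c(a = tract_seq(fl$left, "AC", 12, fl$right),
          b = tract_seq(fl$left, "AC", 17, fl$right))
  cl2 <- greedy_cluster(mask_and_filter(s2, scan_ssrs(s2)))
  expect_identical(length(unique(cl2$members$cluster_id)), 1L)
  expect_identical(cl2$loci$sslp, 2L)
  expect_identical(cl2$loci$allele_lengths, "24,34")
})

test_that("sub-threshold flank identity founds a new cluster", {
  withr::with_seed(43, {
    fl <- ssr_free_flanks(40, "AC", seed = 106)
    a <- tract_seq(fl$left, "AC", 12, fl$right)
    # 15 scattered substitutions in 104 bp of flank: identity ~0.85 < 0.90
    ch <- strsplit(a, "")[[1]]
    flank_pos <- c(3:38, 68:100)
    for (q in sample(flank_pos, 15))
      ch[q] <- setdiff(c("A", "C", "G", "T"), ch[q])[1]
    b <- paste(ch, collapse = "")
    s <- c(a = a, b = b)
    h <- scan_ssrs(s)
    expect_identical(nrow(h), 2L)
    cl <- greedy_cluster(mask_and_filter(s, h))
    expect_identical(length(unique(cl$members$cluster_id)), 2L)
  })
})

test_that("clustering is a deterministic partition, invariant to input order", {
  withr::with_seed(44, {
    fls <- lapply(1:6, function(i) ssr_free_flanks(40, "AC",
                                                   seed = 200 + i))
    seqs <- unlist(lapply(seq_along(fls), function(i) {
      vapply(sample(10:16, 4), function(n)
        tract_seq(fls[[i]]$left, "AC", n, fls[[i]]$right), character(1))
    }))
    names(seqs) <- sprintf("x%02d", seq_along(seqs))
    rec <- mask_and_filter(seqs, scan_ssrs(seqs))
    cl <- greedy_cluster(rec)
    # partition: every record in exactly one cluster
    expect_setequal(cl$members$record_id, rec$record_id)
    expect_identical(anyDuplicated(cl$members$record_id), 0L)
    # permuting input rows changes nothing
    cl2 <- greedy_cluster(rec[sample(nrow(rec)), ])
    m1 <- cl$members[order(cl$members$record_id), ]
    m2 <- cl2$members[order(cl2$members$record_id), ]
    expect_identical(m1$cluster_id, m2$cluster_id)
    expect_identical(cl$loci$sslp[order(cl$loci$locus_id)],
                     cl2$loci$sslp[order(cl2$loci$locus_id)])
    # prefilter is an optimization only
    cl3 <- greedy_cluster(rec, cluster_params(prefilter = FALSE))
    m3 <- cl3$members[order(cl3$members$record_id), ]
    expect_identical(m1$cluster_id, m3$cluster_id)
  })
})

test_that("adding repeat units to the focal tract never moves a record across clusters", {
  fl <- ssr_free_flanks(40, "AC", seed = 107)
  base <- tract_seq(fl$left, "AC", 12, fl$right)
  grown <- vapply(c(0, 2, 5, 9), function(k)
    tract_seq(fl$left, "AC", 12 + k, fl$right), character(1))
  names(grown) <- sprintf("g%d", seq_along(grown))
  rec <- mask_and_filter(grown, scan_ssrs(grown))
  expect_identical(length(unique(rec$masked)), 1L)   # single-R masking
  cl <- greedy_cluster(rec)
  expect_identical(length(unique(cl$members$cluster_id)), 1L)
  expect_identical(cl$loci$sslp, 4L)
})

test_that("compute_sslp counts distinct supported tract lengths", {
  expect_identical(compute_sslp(c(24L, 28L, 30L, 32L, 34L)), 5L)
  expect_identical(compute_sslp(30L), 1L)
  expect_identical(compute_sslp(rep(30L, 10)), 1L)
  # relative support rule: 2 reads against 30 falls below a 0.2 floor
  lens <- c(rep(30L, 30), rep(32L, 2))
  expect_identical(compute_sslp(lens, min_allele_frac = 0.2), 1L)
  expect_identical(compute_sslp(lens, min_allele_frac = 0), 2L)
})

test_that("SSLP histogram bins 1-9 and >=10 and preserves totals", {
  h <- sslp_histogram(data.frame(sslp = c(1L, 1L, 2L, 3L, 12L)))
  expect_identical(h$total_clusters, 5L)
  expect_identical(h$counts$n[h$counts$sslp_bin == "1"], 2L)
  expect_identical(h$counts$n[h$counts$sslp_bin == "2"], 1L)
  expect_identical(h$counts$n[h$counts$sslp_bin == "3"], 1L)
  expect_identical(h$counts$n[h$counts$sslp_bin == ">=10"], 1L)
  expect_identical(sum(h$counts$n), h$total_clusters)
  h0 <- sslp_histogram(data.frame(sslp = integer(0)))
  expect_identical(h0$total_clusters, 0L)
  expect_identical(sum(h0$counts$n), 0L)
})

test_that("polymorphic export keeps only SSLP >= 2 with usable flanks", {
  fls <- lapply(1:4, function(i) ssr_free_flanks(40, "AC",
                                                 seed = 300 + i))
  counts <- list(c(12L), c(12L, 14L), c(12L, 15L), c(10L, 12L, 13L, 15L,
                                                     16L))
  seqs <- unlist(lapply(seq_along(fls), function(i)
    vapply(counts[[i]], function(n)
      tract_seq(fls[[i]]$left, "AC", n, fls[[i]]$right), character(1))))
  names(seqs) <- sprintf("p%02d", seq_along(seqs))
  cl <- greedy_cluster(mask_and_filter(seqs, scan_ssrs(seqs)))
  poly <- polymorphic_records(cl)
  expect_identical(nrow(poly), 3L)
  expect_setequal(poly$sslp, c(2L, 2L, 5L))
  expect_true(all(nchar(poly$left_flank) >= 20))
  expect_true(all(nchar(poly$right_flank) >= 20))
  # all-monomorphic input exports nothing
  mono <- seqs[1]
  clm <- greedy_cluster(mask_and_filter(mono, scan_ssrs(mono)))
  expect_identical(nrow(polymorphic_records(clm)), 0L)
})

test_that("consensus flanks vote out isolated errors", {
  fl <- ssr_free_flanks(40, "AC", seed = 108)
  good <- tract_seq(fl$left, "AC", 12, fl$right)
  ch <- strsplit(good, "")[[1]]
  ch[10] <- setdiff(c("A", "C", "G", "T"), ch[10])[1]
  seqs <- c(a = good, b = good, c = paste(ch, collapse = ""))
  cl <- greedy_cluster(mask_and_filter(seqs, scan_ssrs(seqs)))
  poly <- cluster_flank_table(cl, flank_len = 40L)
  expect_identical(poly$left_flank, fl$left)
  expect_identical(poly$right_flank, fl$right)
})
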