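mk_intron <- function(seq, id = "g|1", first = TRUE) {
  data.frame(intron_id = id, gene_id = sub("\\|.*", "", id),
             transcript_id = paste0(sub("\\|.*", "", id), ".1"), chrom = "c1",
             start = 0L, end = nchar(seq), strand = "+", rank = 1L,
             is_first = first, in_utr5 = FALSE, sequence = seq,
             dist_tss = 0L, dist_cds = 0L, stringsAsFactors = FALSE)
}

test_that("canonical form is the lexicographic minimum with its reverse complement", {
  expect_equal(canonical_kmer("AAATCG"), "AAATCG")
  expect_equal(canonical_kmer("CGATTT"), "AAATCG")
  expect_equal(canonical_kmer("GAATTC"), "GAATTC")  # palindromic
  expect_true(is.na(canonical_kmer("AANTCG")))
})

test_that("window counting trims ends and skips masked or N windows", {
  # 12 bp, trim 3, k 6: exactly one window
  tab <- count_kmers(mk_intron("AAAAAAAAAAAA"))
  expect_equal(tab$count_first[tab$kmer == "AAAAAA"], 1)
  # a SNP at offset 5 covers the single window: masked count 0
  snps <- toy_snps("c1", pos = 5)
  si <- snps_in_intervals(snps, mk_intron("AAAAAAAAAAAA"), trim = 3)
  tabm <- count_kmers(mk_intron("AAAAAAAAAAAA"), snps = si)
  expect_equal(tabm$masked_first[tabm$kmer == "AAAAAA"], 0)
  # trim 0 on 8 bp: three windows, canonically collapsed
  tab0 <- count_kmers(mk_intron("ACGTACGT"), trim = 0)
  expect_equal(sum(tab0$count_first), 3)
  expect_setequal(tab0$kmer, canonical_kmer(c("ACGTAC", "CGTACG", "GTACGT")))
  # too-short intron contributes zero windows
  expect_equal(nrow(count_kmers(mk_intron("ACGTACGTAC"))), 0)
})

test_that("window totals match a brute-force recount on a toy corpus", {
  set.seed(3)
  seqs <- vapply(1:12, function(i)
    paste(sample(c("A", "C", "G", "T", "N"), sample(10:40, 1), TRUE,
                 prob = c(.3, .2, .2, .29, .01)), collapse = ""), character(1))
  introns <- do.call(rbind, lapply(seq_along(seqs), function(i)
    mk_intron(seqs[i], id = paste0("g", i, "|1"), first = i %% 2 == 0)))
  tab <- count_kmers(introns, k = 6, trim = 3)
  brute_f <- 0; brute_o <- 0
  for (i in seq_along(seqs)) {
    s <- seqs[i]; L <- nchar(s)
    if (L < 12) next
    for (p in 4:(L - 8)) {
      w <- substr(s, p, p + 5)
      if (grepl("N", w, fixed = TRUE)) next
      if (i %% 2 == 0) brute_f <- brute_f + 1 else brute_o <- brute_o + 1
    }
  }
  expect_equal(sum(tab$count_first), brute_f)
  expect_equal(sum(tab$count_other), brute_o)
})

test_that("relative frequency follows the normalized count ratio and its symmetries", {
  tab <- count_kmers(rbind(mk_intron("AAAAACAAAAAA", "a|1", TRUE),
                           mk_intron("AAAAACAAAAAA", "b|1", FALSE)))
  expect_true(all(relative_frequency(tab) == 1))
  # direct arithmetic: 2/10 vs 1/10
  tab2 <- data.frame(kmer = c("AAAAAA", "AAAAAC"),
                     count_first = c(2L, 8L), count_other = c(1L, 9L),
                     masked_first = c(2L, 8L), masked_other = c(1L, 9L))
  F <- relative_frequency(tab2)
  expect_equal(unname(F["AAAAAA"]), 2)
  # doubling one set leaves F unchanged
  tab3 <- tab2
  tab3$count_first <- tab3$count_first * 2L
  expect_equal(relative_frequency(tab3), F)
  # exchanging set labels inverts F
  tab4 <- tab2
  names(tab4)[2:3] <- c("count_other", "count_first")
  expect_equal(relative_frequency(tab4), 1 / F)
})

test_that("positional entropy matches hand-computed values", {
  expect_equal(positional_entropy(rep(0.05, 7))$entropy, 0)
  expect_equal(positional_entropy(seq(0.05, 0.95, by = 0.1))$entropy,
               log(10))
  # counts (3, 1) over 2 bins
  e <- positional_entropy(c(0.1, 0.2, 0.3, 0.8), bins = 2)
  expect_equal(e$entropy, -(0.75 * log(0.75) + 0.25 * log(0.25)),
               tolerance = 1e-12)
  expect_equal(e$counts, c(3L, 1L))
})

test_that("entropy empirical p-value behaves as an add-one exceedance probability", {
  p_max <- entropy_empirical_pvalue(log(10), 100, n_sim = 2000, seed = 1)
  expect_gt(p_max, 0.99)
  p_min <- entropy_empirical_pvalue(0, 1000, n_sim = 2000, seed = 1)
  expect_equal(p_min, 1 / 2001)
  # monotone in the observed entropy at fixed seed
  ps <- vapply(c(1.2, 1.8, 2.1, 2.25, log(10)), function(s)
    entropy_empirical_pvalue(s, 200, n_sim = 1000, seed = 7), numeric(1))
  expect_true(all(diff(ps) >= 0))
})

test_that("entropy p-values are approximately uniform under a uniform null", {
  set.seed(11)
  ps <- replicate(200, {
    pos <- runif(60)
    s <- positional_entropy(pos)$entropy
    entropy_empirical_pvalue(s, 60, n_sim = 1000, seed = sample.int(1e6, 1))
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("positional contrast test agrees with the exact test and detects disjoint support", {
  expect_gt(positional_contrast_test(c(5, 5, 5), c(5, 5, 5),
                                     n_sim = 5000, seed = 1), 0.9)
  expect_lt(positional_contrast_test(c(100, rep(0, 9)), c(rep(0, 9), 100),
                                     n_sim = 5000, seed = 1), 1e-3)
  # 2x2 collapse, exact: p = 2/252
  expect_equal(positional_contrast_test(c(5, 0), c(0, 5), method = "exact"),
               2 / 252, tolerance = 1e-9)
  # Monte-Carlo matches the exact network algorithm on a small 2x4 table
  bf <- c(8, 2, 5, 1); bo <- c(2, 6, 3, 7)
  p_ex <- positional_contrast_test(bf, bo, method = "exact")
  p_mc <- positional_contrast_test(bf, bo, n_sim = 2e4, seed = 3)
  expect_equal(p_mc, p_ex, tolerance = 0.03)
  expect_true(is.na(positional_contrast_test(rep(0, 10), rep(0, 10))))
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(0.04, 5)), rep(0.04, 5))
  expect_error(bh_fdr(c(0.5, 1.7)), "\\[0, 1\\]")
  # explicit step-up on an unordered vector
  p <- c(0.03, 0.002, 0.04, 0.01)
  m <- length(p)
  o <- order(p)
  manual <- numeric(m)
  manual[o] <- rev(cummin(rev(p[o] * m / seq_len(m))))
  expect_equal(bh_fdr(p), pmin(manual, 1))
})

test_that("candidate selection is the strict four-way conjunction", {
  rows <- data.frame(kmer = c("a", "b", "c", "d"),
                     F = c(2, 0.9, 2, 1),
                     cons_first = c(0.95, 0.95, 0.95, 0.95),
                     cons_other = c(0.90, 0.90, 0.90, 0.95),
                     q_entropy = c(0.01, 0.01, 0.2, 0.01),
                     q_contrast = c(0.01, 0.01, 0.01, 0.01))
  out <- select_candidates(rows, alpha = 0.05)
  expect_equal(out$candidate, c(TRUE, FALSE, FALSE, FALSE))
  out0 <- select_candidates(rows, alpha = 0)
  expect_false(any(out0$candidate))
})
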