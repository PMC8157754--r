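test_that("upper-quartile normalisation equalises sample quartiles and is scale-invariant", {
  set.seed(2)
  counts <- matrix(rpois(400, 20), 100, 4,
                   dimnames = list(paste0("g", 1:100), paste0("s", 1:4)))
  counts[, 2] <- counts[, 1] * 2          # sample 2 is a scaled copy of 1
  norm <- upper_quartile_normalize(counts)
  expect_equal(norm[, 1], norm[, 2], ignore_attr = TRUE)
  q75 <- apply(norm, 2, function(x) quantile(exp(x) - 1, 0.75))
  expect_equal(max(q75) - min(q75), 0, tolerance = 1e-8)
  bad <- counts; bad[, 3] <- 0
  expect_error(upper_quartile_normalize(bad), "s3")
})

test_that("Cohen's d uses the pooled-SD formula with antisymmetry", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3))$cohens_d, 0)
  d <- cohens_d(c(2, 4), c(1, 3))
  expect_equal(d$cohens_d, 1 / sqrt(2))
  expect_equal(cohens_d(c(1, 3), c(2, 4))$cohens_d, -d$cohens_d)
  expect_true(is.na(cohens_d(c(1, 1), c(1, 1))$cohens_d))
})

test_that("pairwise correlations cover all unordered pairs with degenerate cases", {
  expr <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(4, 3, 2, 1),
                d = c(1, 3, 2, 4))
  r <- pairwise_correlations(expr, c("a", "b", "c", "d"))
  expect_length(r, 6)
  expect_equal(pairwise_correlations(expr, c("a", "b")), 1)
  expect_equal(pairwise_correlations(expr, c("a", "c")), -1)
  expr2 <- rbind(expr, e = c(5, 5, 5, 5))
  expect_warning(r2 <- pairwise_correlations(expr2, c("a", "b", "e")),
                 "zero-variance")
  expect_length(r2, 1)
  # subsampling returns exactly max_pairs seeded draws
  set.seed(1)
  big <- matrix(rnorm(200), 20, 10, dimnames = list(paste0("g", 1:20), NULL))
  r3 <- pairwise_correlations(big, rownames(big), max_pairs = 50, seed = 3)
  expect_length(r3, 50)
  expect_equal(r3, pairwise_correlations(big, rownames(big), max_pairs = 50,
                                         seed = 3))
})

test_that("occurrence-matched controls use inclusive relative bounds", {
  tab <- data.frame(kmer = c("AAAAAA", "AAAAAC", "AAAAAG", "AAAAAT", "AAAACA"),
                    count_first = c(100L, 90L, 110L, 89L, 111L),
                    count_other = 1L, masked_first = 0L, masked_other = 0L)
  ctrl <- matched_control_hexamers("AAAAAA", tab, tol = 0.10)
  expect_setequal(ctrl, c("AAAAAC", "AAAAAG"))
  expect_equal(matched_control_hexamers("AAAAAA", tab, tol = 0),
               character(0))
  expect_false("AAAAAA" %in% matched_control_hexamers("AAAAAA", tab, tol = 1))
})

test_that("expression-level effect recovers planted shifts and nulls", {
  set.seed(8)
  expr <- matrix(rnorm(1000 * 10), 1000, 10,
                 dimnames = list(paste0("g", 1:1000), paste0("s", 1:10)))
  all_genes <- rownames(expr)
  # a random subset of the background is a null
  d0 <- expression_level_effect(sample(all_genes, 400), expr, all_genes)
  expect_lt(abs(d0$cohens_d), 0.1)
  # set equal to background
  expect_equal(expression_level_effect(all_genes, expr, all_genes)$cohens_d, 0)
  # planted +1 shift with unit variance against a disjoint background
  vals <- c(rnorm(500, 1), rnorm(1000, 0))
  expr1 <- matrix(rep(vals, 3), ncol = 3,
                  dimnames = list(paste0("h", seq_along(vals)), NULL))
  d1 <- expression_level_effect(paste0("h", 1:500), expr1,
                                paste0("h", 501:1500))
  expect_equal(d1$cohens_d, 1, tolerance = 0.15)
})

test_that("pentamer log-odds weights have the expected symmetries and signs", {
  mk <- function(seqs, first = TRUE) do.call(rbind, lapply(seq_along(seqs),
    function(i) data.frame(intron_id = paste0("s", i, "|1"),
                           gene_id = paste0("s", i), transcript_id = "t",
                           chrom = "c1", start = 0L, end = nchar(seqs[i]),
                           strand = "+", rank = 1L, is_first = first,
                           in_utr5 = FALSE, sequence = seqs[i], dist_tss = 0L,
                           dist_cds = 0L, stringsAsFactors = FALSE)))
  seqs <- c("ACGTACGTACGTACGTAA", "TTTTCCCCGGGGAAAATT")
  w_same <- train_pentamer_logodds(mk(seqs), mk(seqs, FALSE))
  expect_true(all(w_same$weights == 0))
  # a pentamer present only in the proximal corpus gets positive weight
  w <- train_pentamer_logodds(mk("AAAAATCGATAAAAA"), mk("CCCCCCCCCCCCCCC", FALSE))
  expect_gt(w$weights[canonical_kmer("ATCGA")], 0)
  # doubling both corpora leaves weights unchanged
  w2 <- train_pentamer_logodds(mk(rep("AAAAATCGATAAAAA", 2)),
                               mk(rep("CCCCCCCCCCCCCCC", 2), FALSE))
  expect_equal(w$weights, w2$weights)
})

test_that("the pentamer score is a sum over windows", {
  words <- sort(unique(imescan:::canonical_map(5L)))
  w <- list(weights = setNames(rep(0, length(words)), words),
            pseudocount = 1, n_proximal = 1, n_distal = 1)
  class(w) <- "pentamer_logodds"
  expect_equal(imeter_like_score("ACGTACGTAC", w), 0)
  w$weights[] <- seq_along(words) / length(words)
  wmax <- names(which.max(w$weights))
  s <- paste(rep(substr(wmax, 1, 1), 20), collapse = "")
  # homogeneous sequence of one repeated base scores (L-4) * weight
  hom <- paste(rep("A", 12), collapse = "")
  expect_equal(imeter_like_score(hom, w),
               (12 - 4) * unname(w$weights["AAAAA"]))
  # additive over concatenation up to the 4 boundary windows
  a <- "ACGTACGTAC"; b <- "GGGTTTAAACCC"
  boundary <- sum(vapply(1:4, function(i) {
    win <- substr(paste0(a, b), nchar(a) - 4 + i, nchar(a) + i)
    unname(w$weights[canonical_kmer(win)])
  }, numeric(1)))
  expect_equal(imeter_like_score(paste0(a, b), w),
               imeter_like_score(a, w) + imeter_like_score(b, w) + boundary)
  expect_warning(s0 <- imeter_like_score("ACG", w), "shorter")
  expect_equal(s0, 0)
})

test_that("co-expression effect recovers a planted latent factor", {
  sim <- shared_corpus()
  ann <- read_annotation(sim$paths$gff)
  introns <- fetch_sequences(flag_utr5_introns(extract_introns(ann), ann),
                             sim$paths$genome)
  expr <- read_expression_tsv(sim$paths$expr_conditions)
  genes <- filter_expressed_genes(expr, introns, mode = "condition")
  tab <- count_kmers(introns)
  pk <- canonical_kmer(sim$corpus$truth$motif)
  ce <- coexpression_effect(pk, expr, introns, tab, genes = genes, seed = 4)
  expect_gt(ce$n_controls, 0)
  expect_gt(ce$mean_d, 0)
  # mean over a single control equals that control's d
  one <- ce$controls[1, ]
  ce1 <- coexpression_effect(pk, expr, introns, tab, genes = genes,
                             tol = 0, max_controls = 1, seed = 4)
  if (ce1$n_controls == 1)
    expect_equal(ce1$mean_d, ce1$controls$cohens_d[1])
})
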