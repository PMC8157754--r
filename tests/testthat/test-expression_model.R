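test_that("the feature table has 25 columns with correct composition features", {
  seqs <- c(paste0("GT", strrep("A", 30), "AG"),
            paste0("GT", strrep("ACGT", 8), "AG"))
  introns <- do.call(rbind, lapply(1:2, function(i) data.frame(
    intron_id = paste0("g", i, "|1"), gene_id = paste0("g", i),
    transcript_id = paste0("g", i, ".1"), chrom = "c1", start = 0L,
    end = nchar(seqs[i]), strand = "+", rank = 1L, is_first = TRUE,
    in_utr5 = FALSE, sequence = seqs[i], dist_tss = 10L, dist_cds = -5L,
    stringsAsFactors = FALSE)))
  ft <- build_feature_table(introns)
  expect_equal(ncol(ft), 25)
  expect_equal(nrow(ft), 2)
  # 10 canonical dimers: (16 + 4) / 2
  expect_length(imescan:::canonical_dimers(), 10)
  # trimmed core of gene 1 is all A
  expect_equal(ft["g1", "A"], 1)
  expect_equal(ft["g1", "C"] + ft["g1", "G"] + ft["g1", "T"], 0)
  expect_equal(rowSums(ft[, c("A", "C", "G", "T")]), c(g1 = 1, g2 = 1))
  expect_equal(ft["g1", "distance_TSS"], 10)
})

test_that("intron retention flags overlap with alternative-transcript exons", {
  ann <- toy_annotation(list(
    list(id = "g1", tx_id = "g1.1", chrom = "c1", strand = "+",
         exons = list(c(1, 100), c(201, 300)))))
  ann2 <- toy_annotation(list(
    list(id = "g1", tx_id = "g1.2", chrom = "c1", strand = "+",
         exons = list(c(1, 300)))))
  ann$transcripts <- rbind(ann$transcripts, ann2$transcripts)
  ann$exons <- rbind(ann$exons, ann2$exons)
  introns <- extract_introns(ann)
  introns$sequence <- strrep("A", introns$end - introns$start)
  ft <- build_feature_table(introns, annotation = ann)
  expect_equal(ft["g1", "IR"], 1)
  # without the retaining isoform the flag is 0
  ann_solo <- toy_annotation(list(
    list(id = "g1", tx_id = "g1.1", chrom = "c1", strand = "+",
         exons = list(c(1, 100), c(201, 300)))))
  introns2 <- extract_introns(ann_solo)
  introns2$sequence <- strrep("A", introns2$end - introns2$start)
  ft2 <- build_feature_table(introns2, annotation = ann_solo)
  expect_equal(ft2["g1", "IR"], 0)
})

test_that("expression class labels follow median and quartile rules", {
  expr <- matrix(rep(1:100, 3), 100, 3,
                 dimnames = list(paste0("g", 1:100), NULL))
  lab_m <- label_expression_classes(expr, "median")
  expect_true(all(!is.na(lab_m)))
  expect_lte(abs(sum(lab_m == 1) - sum(lab_m == 0)), 1)
  lab_q <- label_expression_classes(expr, "quartile")
  expect_equal(sum(!is.na(lab_q)), 50)
  expect_equal(sum(lab_q == 1, na.rm = TRUE), 25)
  # a gene exactly at the median goes to the low class
  expr_tie <- matrix(rep(c(1, 1, 2, 3), 3), 4, 3,
                     dimnames = list(paste0("t", 1:4), NULL))
  expect_error(label_expression_classes(expr_tie, "median"), "at least 8")
  expr_tie8 <- matrix(rep(c(1, 2, 3, 4, 4, 5, 6, 7), 3), 8, 3,
                      dimnames = list(paste0("t", 1:8), NULL))
  lab_tie <- label_expression_classes(expr_tie8, "median")
  expect_equal(unname(lab_tie[c("t4", "t5")]), c(0L, 0L))
})

test_that("a deterministic label-copy feature yields near-perfect AUC and dominates importances", {
  set.seed(10)
  n <- 300
  X <- matrix(rnorm(n * 10), n, 10,
              dimnames = list(paste0("g", 1:n), paste0("f", 1:10)))
  y <- setNames(rbinom(n, 1, 0.5), rownames(X))
  X <- cbind(X, copy = y, const = 1)
  rep <- train_and_evaluate(X, y, seed = 2, n_trees = 300)
  expect_gt(rep$cv_auc, 0.95)
  expect_gt(rep$heldout_accuracy, 0.9)
  mda <- permutation_importance(rep, seed = 3)
  expect_equal(names(which.max(mda)), "copy")
  expect_gt(mda["copy"], 0.3)
  expect_lt(abs(mda["const"]), 1e-9)
  sh <- shapley_attribution(rep, rep$features)
  ranking <- sort(colMeans(abs(sh$attributions)), decreasing = TRUE)
  expect_equal(names(ranking)[1], "copy")
  expect_lt(max(abs(sh$attributions[, "const"])), 1e-6)
  # additivity: attributions + base value reproduce the prediction
  pr <- imescan:::rf_predict(rep$model, rep$features)
  expect_lt(max(abs(rowSums(sh$attributions) + sh$base_value - pr)), 1e-4)
})

test_that("tree-exact attributions are additive to single precision on a small forest", {
  set.seed(3)
  X <- matrix(rnorm(1500), 100, 15, dimnames = list(NULL, paste0("f", 1:15)))
  y <- as.integer(X[, 1] > 0)
  m <- imescan:::fit_rf(X, y, n_trees = 100, max_depth = 6, min_leaf = 2,
                        subsample = 0.632, seed = 1)
  sh <- shapley_attribution(m, X)
  pr <- imescan:::rf_predict(m, X)
  expect_lt(max(abs(rowSums(sh$attributions) + sh$base_value - pr)), 1e-6)
})

test_that("training rejects degenerate label sets", {
  X <- matrix(rnorm(600), 150, 4)
  expect_error(train_and_evaluate(X, rep(1L, 150), seed = 1), "single class")
  expect_error(train_and_evaluate(X[1:50, ], rep(c(0L, 1L), 25), seed = 1),
               "100 labeled")
})

test_that("AUC is invariant to feature column order", {
  set.seed(12)
  X <- matrix(rnorm(2000), 200, 10, dimnames = list(NULL, paste0("f", 1:10)))
  y <- as.integer(X[, 3] + rnorm(200, 0, 0.5) > 0)
  r1 <- train_and_evaluate(X, y, seed = 4, n_trees = 200)
  r2 <- train_and_evaluate(X[, 10:1], y, seed = 4, n_trees = 200)
  expect_equal(r1$cv_auc, r2$cv_auc, tolerance = 0.06)
})

test_that("G-content and the pentamer score rank highly when both drive the class", {
  sim <- simulate_ime_corpus(seed = 61, n_genes = 250, n_conditions = 50)
  ann <- read_annotation(sim$paths$gff)
  introns <- fetch_sequences(flag_utr5_introns(extract_introns(ann), ann),
                             sim$paths$genome)
  ft <- build_feature_table(introns)
  # high class driven by G content plus the planted motif, which the model
  # can only see through the pentamer score and composition
  motif <- as.numeric(rownames(ft) %in% sim$corpus$truth$genes)
  set.seed(61)
  z <- scale(ft$G) + 1.2 * scale(motif) + rnorm(nrow(ft), 0, 0.6)
  lab <- setNames(as.integer(z > median(z)), rownames(ft))
  rep <- train_and_evaluate(ft, lab, seed = 61, n_trees = 1500)
  mda <- permutation_importance(rep, seed = 61)
  sh <- shapley_attribution(rep, rep$features)
  shap_rank <- names(sort(colMeans(abs(sh$attributions)), decreasing = TRUE))
  mda_rank <- names(sort(mda, decreasing = TRUE))
  expect_true("G" %in% shap_rank[1:5])
  expect_true("imeter" %in% shap_rank[1:5])
  expect_true("G" %in% mda_rank[1:5])
  expect_true("imeter" %in% mda_rank[1:5])
})

test_that("augmenting intron features with first-exon features raises CV AUC when both carry signal", {
  sim <- simulate_ime_corpus(seed = 72, n_genes = 250, n_conditions = 50)
  ann <- read_annotation(sim$paths$gff)
  introns <- fetch_sequences(flag_utr5_introns(extract_introns(ann), ann),
                             sim$paths$genome)
  Xi <- build_feature_table(introns)
  exons <- first_exon_records(ann, sim$paths$genome)
  w <- train_pentamer_logodds(introns[introns$is_first, ],
                              introns[!introns$is_first, ])
  Xe <- build_feature_table(exons, imeter_weights = w)
  colnames(Xe) <- paste0("exon_", colnames(Xe))
  common <- intersect(rownames(Xi), rownames(Xe))
  Xi <- Xi[common, ]; Xe <- Xe[common, ]
  # label built from independent intron and exon signals
  set.seed(72)
  z <- scale(Xi$imeter) + scale(Xe$exon_G) + rnorm(length(common), 0, 0.7)
  y <- setNames(as.integer(z > 0), common)
  r_intron <- train_and_evaluate(Xi, y, seed = 72, n_trees = 1000)
  r_both <- train_and_evaluate(cbind(Xi, Xe), y, seed = 72, n_trees = 1000)
  expect_gt(r_both$cv_auc, r_intron$cv_auc)
})
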