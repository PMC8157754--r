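#' Read a BED file of intervals
#' @param path BED3+ file (0-based half-open).
#' @return data frame with chrom, start, end.
#' @export
read_bed <- function(path) {
  bed <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  names(bed)[1:3] <- c("chrom", "start", "end")
  bed
}

# bp of overlap between one interval and a BED interval set, plus the number
# of overlapping intervals
interval_overlap <- function(chrom, start, end, bed) {
  if (is.null(bed) || !nrow(bed)) return(c(bp = 0L, n = 0L))
  b <- bed[bed$chrom == chrom & bed$start < end & bed$end > start, , drop = FALSE]
  if (!nrow(b)) return(c(bp = 0L, n = 0L))
  bp <- sum(pmin(b$end, end) - pmax(b$start, start))
  c(bp = bp, n = nrow(b))
}

canonical_dimers <- function() sort(unique(canonical_map(2L)))

#' Build the per-gene first-intron feature table
#'
#' Assembles the 25 features used by the expression classifier: intron
#' length, distance to CDS start and to the TSS, the pentamer log-odds
#' (IMEter-style) score, SNP rate per bp, differentially methylated positions
#' in C and CG context, transposable-element count normalised by length,
#' intron retention (1 iff the intron interval overlaps an exon of an
#' alternative transcript of the same gene), conserved non-coding positions
#' normalised by length, minimum folding energy (consumed from a per-intron
#' table and divided by intron length + 40 for the 20 bp exon overhangs),
#' base composition (A/T/C/G, splice-site-trimmed, over non-N positions) and
#' the 10 reverse-complement-collapsed dimer frequencies normalised by intron
#' length. Missing auxiliary inputs yield zero features.
#'
#' @param introns intron data frame with sequences (first introns are used).
#' @param snps optional `snp_table` intersected with the introns.
#' @param dmr_c,dmr_cg optional BED data frames of differentially methylated
#'   regions (all-context and CG context).
#' @param cns_bed optional BED data frame of conserved non-coding sequence.
#' @param te_bed optional BED data frame of transposable elements.
#' @param fold_energy optional data frame (intron_id, energy).
#' @param annotation optional `genome_annotation` (needed for the IR feature).
#' @param imeter_weights optional `pentamer_logodds`; when NULL a scorer is
#'   trained on the supplied introns (first = proximal vs other = distal).
#' @param dmr_mode `"positions"` (bp inside DMRs, default) or `"regions"`
#'   (count of DMR intervals).
#' @param trim bp trimmed at each end for composition features (default 3).
#' @return data frame with rownames = gene ids and 25 feature columns in
#'   fixed order.
#' @export
build_feature_table <- function(introns, snps = NULL, dmr_c = NULL,
                                dmr_cg = NULL, cns_bed = NULL, te_bed = NULL,
                                fold_energy = NULL, annotation = NULL,
                                imeter_weights = NULL,
                                dmr_mode = c("positions", "regions"),
                                trim = 3L) {
  dmr_mode <- match.arg(dmr_mode)
  fi <- introns[introns$is_first, , drop = FALSE]
  if (!nrow(fi)) stop("no first introns supplied")
  if (is.null(imeter_weights)) {
    oth <- introns[!introns$is_first, , drop = FALSE]
    if (!nrow(oth)) oth <- fi
    imeter_weights <- train_pentamer_logodds(fi, oth)
  }
  snp_per_intron <- if (!is.null(snps) && !is.null(snps$map))
    table(snps$map$intron_id) else NULL
  fe <- if (!is.null(fold_energy))
    setNames(fold_energy[[2]], fold_energy[[1]]) else NULL

  # exons of alternative transcripts, for the retention feature
  alt_exons <- NULL
  if (!is.null(annotation)) {
    tx2gene <- setNames(annotation$transcripts$gene_id,
                        annotation$transcripts$transcript_id)
    alt_exons <- annotation$exons
    alt_exons$gene_id <- unname(tx2gene[alt_exons$transcript_id])
  }

  dimers <- canonical_dimers()
  rows <- vector("list", nrow(fi))
  for (i in seq_len(nrow(fi))) {
    len <- fi$end[i] - fi$start[i]
    s <- fi$sequence[i]
    core <- substr(s, trim + 1L, nchar(s) - trim)
    bases <- chars(core)
    bases <- bases[bases %in% c("A", "C", "G", "T")]
    nb <- max(1L, length(bases))
    comp <- c(A = sum(bases == "A"), T = sum(bases == "T"),
              C = sum(bases == "C"), G = sum(bases == "G")) / nb
    # canonical dimer counts within the trimmed core, over intron length
    dvec <- setNames(numeric(length(dimers)), dimers)
    if (nchar(core) >= 2L) {
      dw <- substring(core, 1:(nchar(core) - 1L), 2:nchar(core))
      dc <- canonical_kmer(dw)
      tt <- table(dc[!is.na(dc)])
      dvec[names(tt)] <- as.integer(tt) / len
    }
    n_snp <- 0L
    if (!is.null(snp_per_intron)) {
      v <- snp_per_intron[fi$intron_id[i]]
      if (length(v) == 1L && !is.na(v)) n_snp <- as.integer(v)
    }
    ov_dmr_c <- interval_overlap(fi$chrom[i], fi$start[i], fi$end[i], dmr_c)
    ov_dmr_cg <- interval_overlap(fi$chrom[i], fi$start[i], fi$end[i], dmr_cg)
    ov_cns <- interval_overlap(fi$chrom[i], fi$start[i], fi$end[i], cns_bed)
    ov_te <- interval_overlap(fi$chrom[i], fi$start[i], fi$end[i], te_bed)
    dmr_key <- if (dmr_mode == "positions") "bp" else "n"
    ir <- 0L
    if (!is.null(alt_exons)) {
      ae <- alt_exons[alt_exons$gene_id == fi$gene_id[i] &
                        alt_exons$transcript_id != fi$transcript_id[i], ,
                      drop = FALSE]
      ir <- as.integer(nrow(ae) > 0 &&
                         any(ae$start < fi$end[i] & ae$end > fi$start[i]))
    }
    mfe <- 0
    if (!is.null(fe)) {
      v <- fe[fi$intron_id[i]]
      if (length(v) == 1L && !is.na(v)) mfe <- unname(v) / (len + 40)
    }
    rows[[i]] <- c(
      length = len,
      distance_CDS = fi$dist_cds[i],
      distance_TSS = fi$dist_tss[i],
      imeter = imeter_like_score(s, imeter_weights),
      SNP_per_bp = n_snp / len,
      DMR_C = unname(ov_dmr_c[dmr_key]),
      DMR_CG = unname(ov_dmr_cg[dmr_key]),
      n_transposons = unname(ov_te["n"]) / len,
      IR = ir,
      CNS = unname(ov_cns["bp"]) / len,
      min_fold_energy = mfe,
      comp,
      dvec)
  }
  out <- as.data.frame(do.call(rbind, rows))
  rownames(out) <- fi$gene_id
  out$distance_CDS[is.na(out$distance_CDS)] <- 0
  stopifnot(ncol(out) == 25L)
  out
}

#' First-exon records in the intron-record layout
#'
#' Builds one record per gene for its 5'-most exon (transcript orientation),
#' shaped like the intron table so [build_feature_table()] can compute the
#' same 25 features on first exons — the augmentation hook for
#' exon-plus-intron classifier studies.
#'
#' @param annotation a `genome_annotation`.
#' @param genome a [Biostrings::DNAStringSet] or FASTA path.
#' @return data frame in the intron-record layout (`is_first` TRUE, rank 1,
#'   `intron_id` of the form `gene|E1`).
#' @export
first_exon_records <- function(annotation, genome) {
  tx <- annotation$transcripts
  ex <- annotation$exons
  rows <- list()
  for (i in seq_len(nrow(tx))) {
    t <- tx[i, ]
    e <- ex[ex$transcript_id == t$transcript_id, , drop = FALSE]
    if (!nrow(e)) next
    pick <- if (t$strand == "+") which.min(e$start) else which.max(e$end)
    e1 <- e[pick, ]
    rows[[t$gene_id]] <- data.frame(
      intron_id = paste0(t$gene_id, "|E1"), gene_id = t$gene_id,
      transcript_id = t$transcript_id, chrom = t$chrom, start = e1$start,
      end = e1$end, strand = t$strand, rank = 1L, is_first = TRUE,
      in_utr5 = NA, sequence = NA_character_, dist_tss = 0L,
      dist_cds = NA_integer_, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  fetch_sequences(out, genome)
}

#' Label genes into expression classes
#'
#' Median mode splits all genes at the median of per-gene median expression
#' (ties assigned to the low class); quartile mode labels only the top and
#' bottom quartiles, leaving the middle half unlabeled (`NA`, excluded from
#' training) to sharpen class contrast.
#'
#' @param expr expression matrix (genes x samples).
#' @param mode `"median"` or `"quartile"`.
#' @return named integer vector (1 = high, 0 = low, NA = unlabeled).
#' @export
label_expression_classes <- function(expr, mode = c("median", "quartile")) {
  mode <- match.arg(mode)
  if (nrow(expr) < 8) stop("need at least 8 genes to label")
  med <- apply(expr, 1, median, na.rm = TRUE)
  if (mode == "median") {
    lab <- as.integer(med > median(med))
  } else {
    q <- quantile(med, c(0.25, 0.75), names = FALSE)
    lab <- rep(NA_integer_, length(med))
    lab[med <= q[1]] <- 0L
    lab[med >= q[2]] <- 1L
  }
  setNames(lab, rownames(expr))
}

rf_params <- function(n_features, n_trees, max_depth, min_leaf, subsample, seed) {
  list(objective = "reg:squarederror", eta = 1, max_depth = max_depth,
       min_child_weight = min_leaf, subsample = subsample,
       colsample_bynode = max(1, floor(sqrt(n_features))) / n_features,
       num_parallel_tree = n_trees, nthread = 1, seed = seed)
}

fit_rf <- function(X, y, n_trees, max_depth, min_leaf, subsample, seed) {
  dtr <- xgboost::xgb.DMatrix(as.matrix(X), label = y)
  xgboost::xgb.train(rf_params(ncol(X), n_trees, max_depth, min_leaf,
                               subsample, seed),
                     dtr, nrounds = 1, verbose = 0)
}

rf_predict <- function(model, X) {
  p <- predict(model, xgboost::xgb.DMatrix(as.matrix(X)))
  pmin(pmax(p, 0), 1)
}

auc_of <- function(labels, scores) {
  as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                 direction = "<", levels = c(0, 1))))
}

#' Train and evaluate the expression random forest
#'
#' Fits a random forest (bagged trees with per-node feature subsampling,
#' trained in xgboost's parallel-tree mode) with the default hyperparameters
#' of 6000 trees, maximum depth 10, minimum 2 samples per leaf and
#' sqrt(n_features) candidate features per split, on an 80/20 train/test
#' split; reports held-out accuracy and AUC plus 10-fold cross-validated
#' ROC/AUC on the whole labeled set. A single master seed fans out to the
#' split, bagging and fold sub-seeds.
#'
#' @param features feature data frame/matrix (genes x features).
#' @param labels integer vector (1/0, NA allowed; NA rows are dropped),
#'   aligned with `features` rows by name or position.
#' @param seed master integer seed.
#' @param n_trees,max_depth,min_leaf forest hyperparameters.
#' @param subsample per-tree bagging fraction (default 0.632, matching the
#'   expected unique fraction of a bootstrap sample).
#' @param train_frac training fraction of the 80/20 split.
#' @param cv_folds folds for the cross-validated ROC (default 10).
#' @return object of class `rf_report`: list with `model`, `train_idx`,
#'   `test_idx`, `heldout_accuracy`, `heldout_auc`, `cv_auc` (mean),
#'   `cv_auc_folds`, `roc` (pooled CV curve: fpr, tpr), `features`, `labels`,
#'   `seed`.
#' @export
train_and_evaluate <- function(features, labels, seed = 1L, n_trees = 6000L,
                               max_depth = 10L, min_leaf = 2L,
                               subsample = 0.632, train_frac = 0.8,
                               cv_folds = 10L) {
  X <- as.matrix(features)
  if (!is.null(names(labels)) && !is.null(rownames(X)))
    labels <- labels[rownames(X)]
  keep <- !is.na(labels)
  X <- X[keep, , drop = FALSE]
  y <- as.integer(labels[keep])
  if (length(unique(y)) < 2) stop("labels contain a single class")
  if (length(y) < 100) stop("need at least 100 labeled genes")
  n <- length(y)
  set.seed(derive_seed(seed, 1L))
  train_idx <- sort(sample.int(n, round(train_frac * n)))
  test_idx <- setdiff(seq_len(n), train_idx)
  model <- fit_rf(X[train_idx, ], y[train_idx], n_trees, max_depth, min_leaf,
                  subsample, derive_seed(seed, 2L))
  p_test <- rf_predict(model, X[test_idx, ])
  heldout_accuracy <- mean((p_test > 0.5) == (y[test_idx] == 1L))
  heldout_auc <- auc_of(y[test_idx], p_test)

  set.seed(derive_seed(seed, 3L))
  fold <- sample(rep_len(seq_len(cv_folds), n))
  cv_scores <- numeric(n)
  cv_auc_folds <- numeric(cv_folds)
  for (f in seq_len(cv_folds)) {
    tr <- fold != f
    m <- fit_rf(X[tr, ], y[tr], n_trees, max_depth, min_leaf, subsample,
                derive_seed(seed, 10L + f))
    cv_scores[!tr] <- rf_predict(m, X[!tr, , drop = FALSE])
    cv_auc_folds[f] <- if (length(unique(y[!tr])) == 2)
      auc_of(y[!tr], cv_scores[!tr]) else NA_real_
  }
  r <- pROC::roc(y, cv_scores, quiet = TRUE, direction = "<", levels = c(0, 1))
  roc_df <- data.frame(fpr = 1 - r$specificities, tpr = r$sensitivities)
  out <- list(model = model, train_idx = train_idx, test_idx = test_idx,
              heldout_accuracy = heldout_accuracy, heldout_auc = heldout_auc,
              cv_auc = mean(cv_auc_folds, na.rm = TRUE),
              cv_auc_folds = cv_auc_folds, roc = roc_df,
              features = X, labels = y, seed = seed)
  class(out) <- "rf_report"
  out
}

#' @export
print.rf_report <- function(x, ...) {
  cat(sprintf("rf_report: heldout accuracy %.3f, heldout AUC %.3f, CV AUC %.3f\n",
              x$heldout_accuracy, x$heldout_auc, x$cv_auc))
  invisible(x)
}

#' Permutation feature importance (mean decrease in accuracy)
#'
#' For each feature, the held-out classification accuracy drop is averaged
#' over `repeats` seeded random permutations of that feature column.
#'
#' @param report an `rf_report` (its model and held-out split are used), or a
#'   model when `X_test`/`y_test` are given.
#' @param X_test,y_test optional explicit held-out data.
#' @param repeats permutations per feature (default 5).
#' @param seed integer seed.
#' @return named numeric vector of MDA values (one per feature).
#' @export
permutation_importance <- function(report, X_test = NULL, y_test = NULL,
                                   repeats = 5L, seed = 1L) {
  if (inherits(report, "rf_report")) {
    model <- report$model
    X_test <- X_test %||% report$features[report$test_idx, , drop = FALSE]
    y_test <- y_test %||% report$labels[report$test_idx]
  } else model <- report
  X_test <- as.matrix(X_test)
  base_acc <- mean((rf_predict(model, X_test) > 0.5) == (y_test == 1L))
  mda <- setNames(numeric(ncol(X_test)), colnames(X_test))
  for (j in seq_len(ncol(X_test))) {
    drops <- numeric(repeats)
    for (r in seq_len(repeats)) {
      set.seed(derive_seed(seed, j * 100L + r))
      Xp <- X_test
      Xp[, j] <- Xp[sample.int(nrow(Xp)), j]
      acc <- mean((rf_predict(model, Xp) > 0.5) == (y_test == 1L))
      drops[r] <- base_acc - acc
    }
    mda[j] <- mean(drops)
  }
  mda
}

#' Tree-exact Shapley attributions
#'
#' Per-sample, per-feature additive attributions of the forest's prediction,
#' computed exactly from the tree structure (path-dependent feature
#' perturbation). For every sample, the attributions plus the base value sum
#' to the model output.
#'
#' @param model a fitted forest (from an `rf_report` or [train_and_evaluate()]'s
#'   `model` element).
#' @param features feature matrix to attribute.
#' @return list with `attributions` (samples x features matrix) and
#'   `base_value`.
#' @export
shapley_attribution <- function(model, features) {
  if (inherits(model, "rf_report")) model <- model$model
  X <- as.matrix(features)
  ctr <- predict(model, xgboost::xgb.DMatrix(X), predcontrib = TRUE)
  p <- ncol(X)
  attributions <- ctr[, seq_len(p), drop = FALSE]
  colnames(attributions) <- colnames(X)
  list(attributions = attributions, base_value = unname(ctr[1, p + 1L]))
}
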