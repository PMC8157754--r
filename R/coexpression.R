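#' Upper-quartile normalise and log-transform a count matrix
#'
#' Each sample is scaled so that its 75th percentile over expressed genes
#' (value > 0) equals the mean 75th percentile across samples, then
#' `ln(x + 1)` is applied.
#'
#' @param counts non-negative gene x sample matrix.
#' @return normalised log-expression matrix of the same shape.
#' @export
upper_quartile_normalize <- function(counts) {
  stopifnot(all(counts >= 0))
  q75 <- apply(counts, 2, function(x) {
    x <- x[x > 0]
    if (!length(x)) NA_real_ else quantile(x, 0.75, names = FALSE)
  })
  if (any(is.na(q75)))
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[is.na(q75)], collapse = ", "))
  scaled <- sweep(counts, 2, mean(q75) / q75, "*")
  log(scaled + 1)
}

#' Select genes eligible for expression analysis
#'
#' Condition mode keeps genes with a first intron, an annotated 5'UTR
#' (`in_utr5` information available via the intron table's gene set; the
#' caller supplies the gene list with UTRs) and median log expression above
#' 0.1. Accession mode keeps genes with a first intron and median expression
#' above 1 (normalisation of very low expressed genes is unreliable).
#'
#' @param expr expression matrix (genes x samples) on the scale the mode
#'   expects (log for condition mode).
#' @param introns intron data frame (used for the first-intron requirement).
#' @param mode `"condition"` or `"accession"`.
#' @param utr5_genes optional character vector of genes with a 5'UTR of
#'   positive length (condition mode only; default: no UTR restriction).
#' @return character vector of gene ids.
#' @export
filter_expressed_genes <- function(expr, introns, mode = c("condition", "accession"),
                                   utr5_genes = NULL) {
  mode <- match.arg(mode)
  med <- apply(expr, 1, median, na.rm = TRUE)
  first_genes <- unique(introns$gene_id[introns$is_first])
  keep <- if (mode == "condition") med > 0.1 else med > 1
  genes <- rownames(expr)[keep]
  genes <- intersect(genes, first_genes)
  if (mode == "condition" && !is.null(utr5_genes))
    genes <- intersect(genes, utr5_genes)
  if (!length(genes)) warning("no genes pass the expression filter")
  genes
}

#' Pairwise Pearson correlations within a gene set
#'
#' Pearson r across samples for every unordered pair of genes in the set, or
#' a seeded uniform subsample of `max_pairs` pairs when the full pair count
#' exceeds it. Genes with zero expression variance are dropped with a
#' warning (their correlations are undefined).
#'
#' @param expr expression matrix (genes x samples).
#' @param gene_set character vector of gene ids (>= 2).
#' @param max_pairs cap on the number of pairs (default 200000).
#' @param seed integer seed for the subsample.
#' @return numeric vector of correlation coefficients.
#' @export
pairwise_correlations <- function(expr, gene_set, max_pairs = 2e5, seed = 1L) {
  gene_set <- intersect(gene_set, rownames(expr))
  stopifnot(length(gene_set) >= 2)
  m <- expr[gene_set, , drop = FALSE]
  v <- apply(m, 1, var)
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance gene(s) skipped")
    m <- m[v > 0, , drop = FALSE]
    if (nrow(m) < 2) return(numeric())
  }
  n <- nrow(m)
  n_pairs <- n * (n - 1) / 2
  if (n_pairs <= max_pairs) {
    cm <- cor(t(m))
    return(cm[upper.tri(cm)])
  }
  set.seed(seed)
  idx <- sample.int(n_pairs, max_pairs)
  # map linear upper-triangle index (column-major) to (i, j)
  j <- ceiling((1 + sqrt(1 + 8 * idx)) / 2)
  i <- idx - (j - 1) * (j - 2) / 2
  vapply(seq_along(idx), function(s) cor(m[i[s], ], m[j[s], ]), numeric(1))
}

#' Cohen's d effect size for two samples
#'
#' Pooled-standard-deviation form (Hedges-uncorrected):
#' `d = (mean(x) - mean(y)) / s_pooled` with
#' `s_pooled = sqrt(((n1-1)s1^2 + (n2-1)s2^2) / (n1+n2-2))`. Positive d means
#' the first group is larger. The reported p-value is from a Welch two-sample
#' t-test.
#'
#' @param x,y numeric vectors (length >= 2 each).
#' @return list with `cohens_d`, `n1`, `n2`, `p`.
#' @export
cohens_d <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  stopifnot(n1 >= 2, n2 >= 2)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  d <- if (sp2 > 0) (mean(x) - mean(y)) / sqrt(sp2) else NA_real_
  p <- if (sp2 > 0) t.test(x, y)$p.value else NA_real_
  list(cohens_d = d, n1 = n1, n2 = n2, p = p)
}

#' Occurrence-matched control hexamers
#'
#' All other canonical k-mers whose first-intron count lies within +/- `tol`
#' (relative) of the target's count, inclusive bounds
#' `[ceiling((1-tol) c), floor((1+tol) c)]`. The target itself is never
#' returned; an empty result is returned as-is (the caller decides).
#'
#' @param target canonical k-mer present in `table`.
#' @param table a `kmer_count_table`.
#' @param tol relative occurrence tolerance (default 0.10).
#' @return character vector of control k-mers.
#' @export
matched_control_hexamers <- function(target, table, tol = 0.10) {
  i <- match(target, table$kmer)
  if (is.na(i)) stop("target k-mer not in count table: ", target)
  cc <- table$count_first[i]
  lo <- ceiling((1 - tol) * cc)
  hi <- floor((1 + tol) * cc)
  hit <- table$count_first >= lo & table$count_first <= hi
  setdiff(table$kmer[hit], target)
}

# genes whose first intron contains the k-mer (or its reverse complement)
genes_with_motif <- function(motif, introns) {
  fi <- introns[introns$is_first, , drop = FALSE]
  rc <- revcomp(motif)
  hit <- grepl(motif, fi$sequence, fixed = TRUE) |
    grepl(rc, fi$sequence, fixed = TRUE)
  unique(fi$gene_id[hit])
}

#' Mean co-expression effect size of a motif against matched controls
#'
#' The gene set harbouring the motif in its first intron is compared, through
#' its vector of pairwise expression correlations, to the gene set of every
#' occurrence-matched control hexamer; Cohen's d is computed per control and
#' the mean over controls is reported. Positive values mean the motif's genes
#' are more co-expressed than genes sharing an arbitrary equally frequent
#' hexamer.
#'
#' @param motif canonical hexamer.
#' @param expr log expression matrix (genes x samples).
#' @param introns intron data frame with sequences.
#' @param table a `kmer_count_table` (for occurrence matching).
#' @param genes optional restriction of the analysis gene universe.
#' @param tol occurrence-matching tolerance (default 0.10).
#' @param max_controls cap on the number of control hexamers (seeded
#'   subsample; default 30).
#' @param max_pairs cap on correlation pairs per set (default 200000).
#' @param seed integer seed.
#' @return list with `mean_d`, `n_controls`, `n_genes` and per-control data
#'   frame `controls` (kmer, cohens_d, n1, n2, p); NULL elements when no
#'   controls or too few motif genes.
#' @export
coexpression_effect <- function(motif, expr, introns, table, genes = NULL,
                                tol = 0.10, max_controls = 30L,
                                max_pairs = 2e5, seed = 1L) {
  universe <- genes %||% rownames(expr)
  mgenes <- intersect(genes_with_motif(motif, introns), universe)
  if (length(mgenes) < 2)
    return(list(mean_d = NA_real_, n_controls = 0L, n_genes = length(mgenes),
                controls = NULL))
  ctrl <- matched_control_hexamers(motif, table, tol = tol)
  if (!length(ctrl))
    return(list(mean_d = NA_real_, n_controls = 0L, n_genes = length(mgenes),
                controls = NULL))
  if (length(ctrl) > max_controls) {
    set.seed(derive_seed(seed, 7L))
    ctrl <- sort(sample(ctrl, max_controls))
  }
  r_motif <- pairwise_correlations(expr, mgenes, max_pairs = max_pairs,
                                   seed = derive_seed(seed, 1L))
  res <- lapply(seq_along(ctrl), function(ci) {
    cgenes <- intersect(genes_with_motif(ctrl[ci], introns), universe)
    if (length(cgenes) < 2) return(NULL)
    r_ctrl <- pairwise_correlations(expr, cgenes, max_pairs = max_pairs,
                                    seed = derive_seed(seed, 100L + ci))
    if (length(r_ctrl) < 2 || length(r_motif) < 2) return(NULL)
    d <- cohens_d(r_motif, r_ctrl)
    data.frame(kmer = ctrl[ci], cohens_d = d$cohens_d, n1 = d$n1, n2 = d$n2,
               p = d$p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res) || !nrow(res))
    return(list(mean_d = NA_real_, n_controls = 0L, n_genes = length(mgenes),
                controls = NULL))
  list(mean_d = mean(res$cohens_d, na.rm = TRUE), n_controls = nrow(res),
       n_genes = length(mgenes), controls = res)
}

#' Expression-level effect size of a gene set against a background
#'
#' Compares per-gene median expression of the set against the background
#' (default: all genes in the matrix) with Cohen's d and a Welch t-test.
#'
#' @param gene_set character vector of gene ids.
#' @param expr log expression matrix.
#' @param background background gene ids (default all rows of `expr`).
#' @return list as returned by [cohens_d()]; NA `cohens_d` when the set has
#'   fewer than 2 usable genes.
#' @export
expression_level_effect <- function(gene_set, expr, background = NULL) {
  background <- background %||% rownames(expr)
  gene_set <- intersect(gene_set, rownames(expr))
  background <- intersect(background, rownames(expr))
  if (length(gene_set) < 2)
    return(list(cohens_d = NA_real_, n1 = length(gene_set),
                n2 = length(background), p = NA_real_))
  med <- apply(expr, 1, median, na.rm = TRUE)
  cohens_d(med[gene_set], med[background])
}

#' Train a pentamer log-odds scorer from proximal vs distal introns
#'
#' A reimplementation of the IMEter idea on the corpus at hand: canonical
#' pentamer relative frequencies in TSS-proximal introns are contrasted with
#' those in distal introns as log2 odds. Smoothing adds
#' `pseudocount / 4^5` to both relative frequencies, which keeps weights
#' finite for unseen pentamers while leaving them invariant to corpus
#' duplication. Positive weights mark pentamers enriched near the TSS.
#'
#' @param proximal intron data frame (typically first introns) with sequences.
#' @param distal intron data frame (other introns) with sequences.
#' @param pseudocount additive count pseudocount (default 1).
#' @param trim bp excluded at each intron end (default 3).
#' @return object of class `pentamer_logodds`: list with `weights` (named
#'   numeric over canonical pentamers), `pseudocount`, `n_proximal`,
#'   `n_distal`.
#' @export
train_pentamer_logodds <- function(proximal, distal, pseudocount = 1,
                                   trim = 3L) {
  stopifnot(nrow(proximal) > 0, nrow(distal) > 0)
  words <- sort(unique(canonical_map(5L)))
  cnt <- function(introns, set_flag) {
    introns$is_first <- set_flag
    tab <- count_kmers(introns, k = 5L, trim = trim)
    v <- setNames(rep(0L, length(words)), words)
    col <- if (set_flag) "count_first" else "count_other"
    v[tab$kmer] <- tab[[col]]
    v
  }
  cp <- cnt(proximal, TRUE)
  cd <- cnt(distal, FALSE)
  a <- pseudocount / 4^5
  rf <- function(x) if (sum(x) > 0) x / sum(x) else x
  w <- log2((rf(cp) + a) / (rf(cd) + a))
  out <- list(weights = w, pseudocount = pseudocount,
              n_proximal = nrow(proximal), n_distal = nrow(distal))
  class(out) <- "pentamer_logodds"
  out
}

#' Score a sequence with pentamer log-odds weights
#'
#' Sum of the trained weights over all step-1 pentamer windows (canonical
#' collapse consistent with training). Sequences shorter than 5 bp score 0
#' with a warning; windows containing `N` contribute 0.
#'
#' @param sequence DNA string.
#' @param weights a `pentamer_logodds` object.
#' @return numeric score.
#' @export
imeter_like_score <- function(sequence, weights) {
  stopifnot(inherits(weights, "pentamer_logodds"))
  L <- nchar(sequence)
  if (L < 5L) {
    warning("sequence shorter than 5 bp scores 0")
    return(0)
  }
  w <- substring(sequence, 1:(L - 4L), 5:L)
  canon <- canonical_kmer(w)
  canon <- canon[!is.na(canon)]
  if (!length(canon)) return(0)
  sum(weights$weights[canon])
}
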