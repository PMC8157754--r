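#' Locate motif occurrences in first introns
#'
#' Finds all occurrences of an IUPAC motif (or its reverse complement) on the
#' transcript-oriented intron sequences, recording transcript-relative offsets
#' and mapping them back to genomic coordinates (0-based half-open).
#'
#' @param introns intron data frame with sequences (typically first introns).
#' @param motif IUPAC motif text, length >= 4.
#' @return data frame of motif loci: motif, gene_id, intron_id, chrom, offset
#'   (0-based on the transcript-oriented sequence), genomic_start,
#'   genomic_end, strand_hit ("fwd"/"rev" relative to the intron sequence).
#' @export
locate_motif <- function(introns, motif) {
  stopifnot(nchar(motif) >= 4)
  motif <- toupper(motif)
  stopifnot(all(chars(motif) %in% names(IUPAC_SETS)))
  len <- nchar(motif)
  seqs <- Biostrings::DNAStringSet(introns$sequence)
  hits <- list()
  for (orient in c("fwd", "rev")) {
    pat <- if (orient == "fwd") motif else iupac_revcomp(motif)
    mm <- Biostrings::vmatchPattern(pat, seqs, fixed = FALSE)
    for (i in seq_along(mm)) {
      st <- Biostrings::startIndex(mm)[[i]]
      if (is.null(st) || !length(st)) next
      off <- st - 1L                       # 0-based transcript-oriented
      gs <- if (introns$strand[i] == "+") introns$start[i] + off else
        introns$end[i] - off - len
      hits[[length(hits) + 1L]] <- data.frame(
        motif = motif, gene_id = introns$gene_id[i],
        intron_id = introns$intron_id[i], chrom = introns$chrom[i],
        offset = off, genomic_start = gs, genomic_end = gs + len,
        strand_hit = orient, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(motif = character(), gene_id = character(),
               intron_id = character(), chrom = character(), offset = integer(),
               genomic_start = integer(), genomic_end = integer(),
               strand_hit = character(), stringsAsFactors = FALSE)
  out <- unique(out)
  rownames(out) <- NULL
  out
}

#' Split accessions into canonical and variant allele sets at a motif locus
#'
#' An accession is a variant iff it carries at least one alternate allele at
#' any genomic position covered by any occurrence of the motif in the gene;
#' it is canonical iff it carries no alternate allele and has at least one
#' called genotype over the covered positions. Accessions missing at all
#' covered positions are dropped. When no SNP overlaps the locus the variant
#' set is empty (the gene is then untestable, which is a signal, not an
#' error).
#'
#' @param locus data frame of motif occurrences for one gene (rows of
#'   [locate_motif()] output).
#' @param snps a `snp_table` with a genotype matrix.
#' @return list with `canonical`, `variant` (accession id vectors) and
#'   `n_sites` (number of SNP positions inside the locus).
#' @export
split_allele_sets <- function(locus, snps) {
  stopifnot(!is.null(snps$gt))
  stopifnot(length(unique(locus$gene_id)) == 1L)
  covered <- unique(unlist(mapply(seq, locus$genomic_start,
                                  locus$genomic_end - 1L, SIMPLIFY = FALSE)))
  sel <- which(snps$sites$chrom == locus$chrom[1] & snps$sites$pos %in% covered)
  if (!length(sel))
    return(list(canonical = character(), variant = character(), n_sites = 0L))
  g <- snps$gt[sel, , drop = FALSE]
  any_alt <- apply(g, 2, function(x) any(x > 0, na.rm = TRUE))
  any_called <- apply(g, 2, function(x) any(!is.na(x)))
  acc <- colnames(g)
  list(canonical = acc[any_called & !any_alt],
       variant = acc[any_called & any_alt],
       n_sites = length(sel))
}

#' Allele-specific expression effect for one gene
#'
#' Cohen's d (canonical minus variant: positive means the unmutated motif
#' allele is expressed higher) with a Welch two-sample t-test p-value, over
#' per-accession expression of the gene.
#'
#' @param gene gene id (must be a row of `accession_expr`).
#' @param sets list from [split_allele_sets()].
#' @param accession_expr expression matrix (genes x accessions).
#' @param min_group minimum accessions per side (default 2).
#' @return list with `cohens_d`, `n1` (canonical), `n2` (variant), `p`;
#'   NULL when either group is too small.
#' @export
allele_effect <- function(gene, sets, accession_expr, min_group = 2L) {
  if (!gene %in% rownames(accession_expr)) return(NULL)
  x <- accession_expr[gene, intersect(sets$canonical, colnames(accession_expr))]
  y <- accession_expr[gene, intersect(sets$variant, colnames(accession_expr))]
  if (length(x) < min_group || length(y) < min_group) return(NULL)
  cohens_d(as.numeric(x), as.numeric(y))
}

#' Per-gene allele effects for one motif
#'
#' Locates the motif in first introns, splits accessions per gene, applies
#' the accession-mode expression filter, and computes the per-gene allele
#' effect sizes.
#'
#' @param motif IUPAC motif.
#' @param introns intron data frame with sequences (first introns used).
#' @param snps `snp_table` with genotypes.
#' @param accession_expr expression matrix (genes x accessions).
#' @param genes optional pre-filtered analysis gene universe.
#' @param min_group minimum accessions per allele set (default 2).
#' @return data frame: motif, gene_id, n_canonical, n_variant, cohens_d, p.
#' @export
motif_allele_effects <- function(motif, introns, snps, accession_expr,
                                 genes = NULL, min_group = 2L) {
  fi <- introns[introns$is_first, , drop = FALSE]
  loci <- locate_motif(fi, motif)
  universe <- genes %||% rownames(accession_expr)
  res <- list()
  for (g in intersect(unique(loci$gene_id), universe)) {
    sets <- split_allele_sets(loci[loci$gene_id == g, , drop = FALSE], snps)
    eff <- allele_effect(g, sets, accession_expr, min_group = min_group)
    if (is.null(eff) || is.na(eff$cohens_d)) next
    res[[length(res) + 1L]] <- data.frame(
      motif = motif, gene_id = g, n_canonical = eff$n1, n_variant = eff$n2,
      cohens_d = eff$cohens_d, p = eff$p, stringsAsFactors = FALSE)
  }
  if (!length(res))
    return(data.frame(motif = character(), gene_id = character(),
                      n_canonical = integer(), n_variant = integer(),
                      cohens_d = numeric(), p = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Summarise per-gene allele effects for one motif
#'
#' Produces the summary row used for cross-motif reporting: overall mean and
#' median Cohen's d, a one-sample t-test of the d values against zero, the
#' same summaries over the subset of genes with a significant (uncorrected
#' two-sample t, p < `sig_alpha`) allelic expression difference, the count of
#' positive-d significant genes, and a Wilcoxon signed-rank test on the
#' significant subset. FDR correction across motifs is applied by the caller
#' within each test family.
#'
#' @param per_gene data frame from [motif_allele_effects()].
#' @param sig_alpha per-gene significance filter (default 0.05, uncorrected).
#' @return one-row data frame: motif, mean_d, median_d, t_p, mean_d_sig,
#'   median_d_sig, n_genes, n_sig, n_sig_positive, wilcox_p_sig.
#' @export
summarize_motif <- function(per_gene, sig_alpha = 0.05) {
  stopifnot(nrow(per_gene) >= 1)
  d <- per_gene$cohens_d
  t_p <- if (length(d) >= 2 && sd(d) > 0) t.test(d, mu = 0)$p.value else NA_real_
  sig <- per_gene[per_gene$p < sig_alpha, , drop = FALSE]
  wil <- if (nrow(sig) >= 1 && any(sig$cohens_d != 0))
    suppressWarnings(wilcox.test(sig$cohens_d, mu = 0)$p.value) else NA_real_
  data.frame(
    motif = per_gene$motif[1],
    mean_d = mean(d), median_d = median(d), t_p = t_p,
    mean_d_sig = if (nrow(sig)) mean(sig$cohens_d) else NA_real_,
    median_d_sig = if (nrow(sig)) median(sig$cohens_d) else NA_real_,
    n_genes = nrow(per_gene), n_sig = nrow(sig),
    n_sig_positive = sum(sig$cohens_d > 0),
    wilcox_p_sig = wil,
    stringsAsFactors = FALSE)
}

#' Cross-motif enrichment of positive allele effects
#'
#' Tests whether candidate motifs are enriched for positive median allele
#' effects relative to control motifs: a one-sided (greater) Fisher exact
#' test on the 2 x 2 table `[candidates +/-; controls +/-]`, and a two-sided
#' exact binomial test of the candidate positive count against p0 = 0.5.
#'
#' @param candidate_positive logical vector: one entry per candidate motif,
#'   TRUE when its median Cohen's d is positive.
#' @param control_positive logical vector over control motifs (may be empty;
#'   the Fisher test is then NA and only the binomial test is computed).
#' @return list with `fisher_p`, `binomial_p` and the 2 x 2 `table`.
#' @export
cross_motif_enrichment <- function(candidate_positive, control_positive = logical()) {
  k <- sum(candidate_positive)
  n <- length(candidate_positive)
  binomial_p <- binom.test(k, n, p = 0.5, alternative = "two.sided")$p.value
  tab <- matrix(c(k, n - k, sum(control_positive),
                  length(control_positive) - sum(control_positive)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("candidate", "control"),
                                c("positive", "negative")))
  fisher_p <- if (length(control_positive))
    fisher.test(tab, alternative = "greater")$p.value else NA_real_
  list(fisher_p = fisher_p, binomial_p = binomial_p, table = tab)
}

#' Allelic-effect summary table across motifs
#'
#' Runs [motif_allele_effects()] and [summarize_motif()] for each motif and
#' applies BH-FDR across motifs within each test family.
#'
#' @param motifs character vector of IUPAC motifs.
#' @param introns intron data frame with sequences.
#' @param snps `snp_table` with genotypes.
#' @param accession_expr expression matrix (genes x accessions).
#' @param genes optional analysis gene universe.
#' @param sig_alpha per-gene significance filter (default 0.05).
#' @return list with `summary` (one row per motif incl. `t_p_fdr`,
#'   `wilcox_p_fdr`) and `per_gene` (long format).
#' @export
allelic_scan <- function(motifs, introns, snps, accession_expr, genes = NULL,
                         sig_alpha = 0.05) {
  per_gene <- list()
  rows <- list()
  for (m in motifs) {
    pg <- motif_allele_effects(m, introns, snps, accession_expr, genes = genes)
    if (!nrow(pg)) next
    per_gene[[m]] <- pg
    rows[[m]] <- summarize_motif(pg, sig_alpha = sig_alpha)
  }
  if (!length(rows)) return(list(summary = NULL, per_gene = NULL))
  summary <- do.call(rbind, rows)
  summary$t_p_fdr <- bh_fdr(summary$t_p)
  summary$wilcox_p_fdr <- bh_fdr(summary$wilcox_p_sig)
  rownames(summary) <- NULL
  list(summary = summary, per_gene = do.call(rbind, per_gene))
}
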