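#' Run the full candidate-motif discovery pipeline on a corpus directory
#'
#' Reads a corpus written in the pipeline's input formats (genome FASTA, GFF3
#' annotation, VCF variants, condition-wise expression TSV), derives introns
#' with sequences and UTR flags, filters and intersects the SNPs, runs the
#' four-criterion hexamer scan, and refines the candidates by the mean
#' co-expression effect size against occurrence-matched control hexamers.
#'
#' @param dir corpus directory (file names as written by
#'   [simulate_ime_corpus()]), or a named list of paths (`genome`, `gff`,
#'   `vcf`, `expr_conditions`).
#' @param min_minor_count,min_called SNP filter thresholds. The defaults here
#'   (50 and 150) keep the minor-allele rule of the hexamer screen but scale
#'   the called-allele requirement to a 200-accession panel.
#' @param k,trim,bins,alpha scan parameters (see [kmer_scan()]).
#' @param n_sim_entropy,n_sim_contrast simulation sizes (see [kmer_scan()]).
#' @param d_threshold co-expression refinement threshold on the mean Cohen's
#'   d (default +0.05).
#' @param tol occurrence-matching tolerance for control hexamers (0.10).
#' @param max_controls control hexamers per candidate (default 30).
#' @param seed master integer seed.
#' @return list with `introns`, `snps`, `stats` (per-k-mer table),
#'   `candidates`, `coexpression` (per-candidate mean d), `refined`
#'   (candidates passing `d_threshold`), `conservation` (per-set density
#'   summaries).
#' @export
ime_candidate_scan <- function(dir, min_minor_count = 50L, min_called = 150L,
                               k = 6L, trim = 3L, bins = 10L, alpha = 0.05,
                               n_sim_entropy = 1e5, n_sim_contrast = 1e5,
                               d_threshold = 0.05, tol = 0.10,
                               max_controls = 30L, seed = 1L) {
  paths <- if (is.character(dir)) {
    list(genome = file.path(dir, "genome.fa"),
         gff = file.path(dir, "annotation.gff3"),
         vcf = file.path(dir, "variants.vcf"),
         expr_conditions = file.path(dir, "expr_conditions.tsv"))
  } else dir
  ann <- read_annotation(paths$gff)
  introns <- extract_introns(ann)
  introns <- flag_utr5_introns(introns, ann)
  introns <- fetch_sequences(introns, paths$genome)
  snps <- filter_snps(read_snps(paths$vcf),
                      min_minor_count = min_minor_count,
                      min_called = min_called)
  snps_in <- snps_in_intervals(snps, introns, trim = trim)
  stats <- kmer_scan(introns, snps = snps_in, k = k, trim = trim, bins = bins,
                     n_sim_entropy = n_sim_entropy,
                     n_sim_contrast = n_sim_contrast, alpha = alpha,
                     seed = seed)
  candidates <- stats$kmer[which(stats$candidate)]

  expr <- read_expression_tsv(paths$expr_conditions)
  genes <- filter_expressed_genes(expr, introns, mode = "condition")
  tab <- count_kmers(introns, k = k, trim = trim)
  coex <- lapply(candidates, function(m)
    coexpression_effect(m, expr, introns, tab, genes = genes, tol = tol,
                        max_controls = max_controls, seed = seed))
  mean_d <- vapply(coex, function(x) x$mean_d %||% NA_real_, numeric(1))
  coexpression <- data.frame(kmer = candidates, mean_d = mean_d,
                             n_controls = vapply(coex, function(x)
                               x$n_controls, integer(1)),
                             n_genes = vapply(coex, function(x)
                               as.integer(x$n_genes), integer(1)),
                             stringsAsFactors = FALSE)
  refined <- candidates[!is.na(mean_d) & mean_d > d_threshold]

  first <- introns[introns$is_first, , drop = FALSE]
  other <- introns[!introns$is_first, , drop = FALSE]
  conservation <- list(first = conservation_summary(first, snps, k = k, trim = trim),
                       other = conservation_summary(other, snps, k = k, trim = trim))
  list(introns = introns, snps = snps_in, stats = stats,
       candidates = candidates, coexpression = coexpression,
       refined = refined, conservation = conservation)
}
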