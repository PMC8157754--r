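# Synthetic corpus generator: genome + annotation + variants + expression
# with known planted truth, emulating the statistical structure of a plant
# genome screened for first-intron IME motifs (AT-rich composition, ~260 bp
# first / ~160 bp other introns, SNP density ~0.016/bp with suppressed
# density inside planted motifs, positionally biased planted occurrences, a
# shared expression factor plus an expression-level shift for motif genes,
# and an allele-specific decrement when the motif is mutated).

random_dna <- function(n, gc = 0.32) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

#' Generate a synthetic genome and annotation
#'
#' Genes are placed sequentially on `n_chroms` chromosomes, on both strands,
#' each with 2-6 exons, GT..AG introns whose lengths follow lognormal
#' distributions (first introns longer on average than other introns, as
#' observed in plant genomes), annotated 5'UTRs and CDS. A configurable
#' fraction of genes has its first intron inside the 5'UTR. Base composition
#' defaults to AT-rich (GC = 0.32, typical of plant introns).
#'
#' @param n_genes number of genes (default 500).
#' @param n_chroms chromosomes (default 2).
#' @param exon_range range of exon counts per gene (default 2:6).
#' @param first_intron_meanlog,other_intron_meanlog,intron_sdlog lognormal
#'   parameters of intron lengths (defaults target means of ~260 and ~160 bp).
#' @param gc GC fraction of generated sequence (default 0.32).
#' @param utr_intron_frac fraction of genes whose first intron lies in the
#'   5'UTR (default 0.3).
#' @param seed integer seed; a fixed seed yields byte-identical output.
#' @return an `ime_corpus` object (gene structures plus placement); pass to
#'   [plant_motifs()], [corpus_genome()], [corpus_annotation()].
#' @export
generate_genome <- function(n_genes = 500L, n_chroms = 2L, exon_range = 2:6,
                            first_intron_meanlog = log(260),
                            other_intron_meanlog = log(160),
                            intron_sdlog = 0.45, gc = 0.32,
                            utr_intron_frac = 0.3, seed = 1L) {
  set.seed(derive_seed(seed, 1L))
  structs <- vector("list", n_genes)
  pos <- integer(n_chroms)          # current end per chromosome (0-based)
  gap_len0 <- sample(200:500, n_chroms, replace = TRUE)
  lead_gaps <- vapply(gap_len0, random_dna, character(1), gc = gc)
  pos <- gap_len0
  for (g in seq_len(n_genes)) {
    chrom <- ((g - 1L) %% n_chroms) + 1L
    strand <- sample(c("+", "-"), 1L)
    n_ex <- sample(exon_range, 1L)
    exon_lens <- c(sample(120:260, 1L), sample(80:250, n_ex - 1L, replace = TRUE))
    intron_lens <- integer(n_ex - 1L)
    intron_lens[1] <- max(60L, round(exp(rnorm(1, first_intron_meanlog, intron_sdlog))))
    if (n_ex > 2L)
      intron_lens[2:(n_ex - 1L)] <-
        pmax(30L, round(exp(rnorm(n_ex - 2L, other_intron_meanlog, intron_sdlog))))
    exon_seqs <- vapply(exon_lens, random_dna, character(1), gc = gc)
    intron_seqs <- vapply(intron_lens, function(L)
      paste0("GT", random_dna(L - 4L, gc = gc), "AG"), character(1))
    utr_in_intron <- runif(1) < utr_intron_frac
    if (utr_in_intron) {
      w <- sample(20:60, 1L)
      utr5 <- list(mode = "spans_intron1", exon1_full = TRUE, exon2_part = w)
      cds_start_pre <- exon_lens[1] + intron_lens[1] + w
    } else {
      u <- sample(30:80, 1L)
      utr5 <- list(mode = "within_exon1", exon1_part = u)
      cds_start_pre <- u
    }
    gap <- sample(200:500, 1L)
    gap_seq <- random_dna(gap, gc = gc)
    gene_len <- sum(exon_lens) + sum(intron_lens)
    structs[[g]] <- list(
      gene_id = sprintf("g%04d", g), chrom = paste0("chr", chrom),
      strand = strand, exon_lens = exon_lens, intron_lens = intron_lens,
      exon_seqs = exon_seqs, intron_seqs = intron_seqs, utr5 = utr5,
      cds_start_pre = cds_start_pre, start = pos[chrom],
      end = pos[chrom] + gene_len, gap_after = gap_seq)
    pos[chrom] <- pos[chrom] + gene_len + gap
  }
  out <- list(structs = structs, n_chroms = n_chroms, lead_gaps = lead_gaps,
              gc = gc, seed = seed,
              truth = list(motif = NULL, genes = character(),
                           occurrences = list(), seed = seed))
  class(out) <- "ime_corpus"
  out
}

#' @export
print.ime_corpus <- function(x, ...) {
  cat("ime_corpus:", length(x$structs), "genes on", x$n_chroms,
      "chromosomes; planted motif:", x$truth$motif %||% "none", "\n")
  invisible(x)
}

# pre-mRNA (transcript-oriented, unspliced) sequence of one gene
gene_pre_mrna <- function(st) {
  n_ex <- length(st$exon_lens)
  parts <- character(2L * n_ex - 1L)
  parts[seq(1, 2 * n_ex - 1, by = 2)] <- st$exon_seqs
  if (n_ex > 1) parts[seq(2, 2 * n_ex - 2, by = 2)] <- st$intron_seqs
  paste(parts, collapse = "")
}

# pre-mRNA interval [a, b) -> genomic interval [start, end), honouring strand
pre_to_genomic <- function(st, a, b) {
  L <- sum(st$exon_lens) + sum(st$intron_lens)
  if (st$strand == "+") c(st$start + a, st$start + b)
  else c(st$start + L - b, st$start + L - a)
}

# per-gene feature intervals in pre-mRNA coordinates
gene_layout <- function(st) {
  n_ex <- length(st$exon_lens)
  ex_start <- integer(n_ex)
  in_start <- integer(max(0L, n_ex - 1L))
  p <- 0L
  for (k in seq_len(n_ex)) {
    ex_start[k] <- p
    p <- p + st$exon_lens[k]
    if (k < n_ex) {
      in_start[k] <- p
      p <- p + st$intron_lens[k]
    }
  }
  list(ex_start = ex_start, in_start = in_start, total = p)
}

#' Plant motif occurrences into first introns
#'
#' Writes copies of `motif` into the first introns of a seeded random subset
#' of genes, at relative positions drawn from a Beta distribution (the
#' two-parameter family spans uniform placement (1,1) to strongly 5'-biased
#' shapes). Overwritten bases and all planted offsets are recorded in the
#' corpus truth. Introns too short for the requested copies are skipped with
#' a message.
#'
#' @param corpus an `ime_corpus`.
#' @param motif DNA text to plant (default "TTTCGA").
#' @param gene_fraction fraction of genes receiving the motif (default 0.33;
#'   together with two copies per intron this places the planted hexamer's
#'   total first-intron count inside the densest stratum of background
#'   hexamer counts, so occurrence-matched controls exist).
#' @param occurrences_per_intron copies per first intron (default 2).
#' @param position_beta Beta parameters of the relative placement
#'   (default c(2, 5), 5'-biased).
#' @param margin bp kept free at each intron end (default 4, protects splice
#'   sites and the trim zone).
#' @param seed integer seed.
#' @return the updated `ime_corpus` with `truth` filled.
#' @export
plant_motifs <- function(corpus, motif = "TTTCGA", gene_fraction = 0.33,
                         occurrences_per_intron = 2L,
                         position_beta = c(2, 5), margin = 4L, seed = 1L) {
  set.seed(derive_seed(seed, 2L))
  k <- nchar(motif)
  n_genes <- length(corpus$structs)
  n_pick <- round(gene_fraction * n_genes)
  if (n_pick == 0) return(corpus)
  picked <- sort(sample.int(n_genes, n_pick))
  truth_genes <- character()
  truth_occ <- list()
  overwritten <- list()
  for (g in picked) {
    st <- corpus$structs[[g]]
    len <- st$intron_lens[1]
    lo <- margin
    hi <- len - k - margin
    if (hi - lo + 1L < occurrences_per_intron * (k + 1L)) {
      message("intron too short for planting in ", st$gene_id, "; skipped")
      next
    }
    seq_ch <- chars(st$intron_seqs[1])
    offs <- integer(0)
    tries <- 0L
    while (length(offs) < occurrences_per_intron && tries < 200L) {
      tries <- tries + 1L
      o <- lo + round(rbeta(1, position_beta[1], position_beta[2]) * (hi - lo))
      if (!length(offs) || all(abs(offs - o) >= k)) offs <- c(offs, o)
    }
    if (length(offs) < occurrences_per_intron) next
    offs <- sort(offs)
    old <- vapply(offs, function(o)
      paste(seq_ch[(o + 1L):(o + k)], collapse = ""), character(1))
    for (o in offs) seq_ch[(o + 1L):(o + k)] <- chars(motif)
    corpus$structs[[g]]$intron_seqs[1] <- paste(seq_ch, collapse = "")
    truth_genes <- c(truth_genes, st$gene_id)
    truth_occ[[st$gene_id]] <- offs
    overwritten[[st$gene_id]] <- old
  }
  corpus$truth$motif <- motif
  corpus$truth$genes <- truth_genes
  corpus$truth$occurrences <- truth_occ
  corpus$truth$overwritten <- overwritten
  corpus$truth$position_beta <- position_beta
  corpus
}

#' Assemble the genome sequence of a corpus
#' @param corpus an `ime_corpus`.
#' @return a [Biostrings::DNAStringSet], one entry per chromosome.
#' @export
corpus_genome <- function(corpus) {
  chroms <- paste0("chr", seq_len(corpus$n_chroms))
  seqs <- setNames(vector("list", length(chroms)), chroms)
  for (ch in chroms) seqs[[ch]] <- list(corpus$lead_gaps[match(ch, chroms)])
  for (st in corpus$structs) {
    body <- gene_pre_mrna(st)
    if (st$strand == "-")
      body <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(body)))
    seqs[[st$chrom]] <- c(seqs[[st$chrom]], list(body, st$gap_after))
  }
  Biostrings::DNAStringSet(vapply(seqs, function(p)
    paste(unlist(p), collapse = ""), character(1)))
}

# genomic footprint (0-based half-open intervals) of planted motif copies
planted_motif_loci <- function(corpus) {
  k <- nchar(corpus$truth$motif %||% "")
  if (!k) return(NULL)
  rows <- list()
  for (st in corpus$structs) {
    offs <- corpus$truth$occurrences[[st$gene_id]]
    if (is.null(offs)) next
    lay <- gene_layout(st)
    for (o in offs) {
      gi <- pre_to_genomic(st, lay$in_start[1] + o, lay$in_start[1] + o + k)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = st$gene_id, chrom = st$chrom, start = gi[1], end = gi[2],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

#' Build the `genome_annotation` object of a corpus
#' @param corpus an `ime_corpus`.
#' @return a `genome_annotation` as produced by [read_annotation()].
#' @export
corpus_annotation <- function(corpus) {
  genes <- list(); tx <- list(); exons <- list(); utr5 <- list(); cds <- list()
  for (st in corpus$structs) {
    lay <- gene_layout(st)
    gid <- st$gene_id
    tid <- paste0(gid, ".1")
    genes[[gid]] <- data.frame(gene_id = gid, chrom = st$chrom,
                               start = st$start, end = st$end,
                               strand = st$strand, stringsAsFactors = FALSE)
    tx[[gid]] <- data.frame(transcript_id = tid, gene_id = gid,
                            chrom = st$chrom, start = st$start, end = st$end,
                            strand = st$strand, stringsAsFactors = FALSE)
    add <- function(lst, a, b) {
      gi <- pre_to_genomic(st, a, b)
      c(lst, list(data.frame(transcript_id = tid, chrom = st$chrom,
                             start = gi[1], end = gi[2], strand = st$strand,
                             stringsAsFactors = FALSE)))
    }
    n_ex <- length(st$exon_lens)
    for (kx in seq_len(n_ex))
      exons <- add(exons, lay$ex_start[kx], lay$ex_start[kx] + st$exon_lens[kx])
    if (st$utr5$mode == "within_exon1") {
      utr5 <- add(utr5, 0L, st$utr5$exon1_part)
    } else {
      utr5 <- add(utr5, 0L, st$exon_lens[1])
      utr5 <- add(utr5, lay$ex_start[2], lay$ex_start[2] + st$utr5$exon2_part)
    }
    # CDS: exon portions from cds_start_pre to transcript end
    for (kx in seq_len(n_ex)) {
      a <- max(lay$ex_start[kx], st$cds_start_pre)
      b <- lay$ex_start[kx] + st$exon_lens[kx]
      if (a < b) cds <- add(cds, a, b)
    }
  }
  ann <- list(genes = do.call(rbind, genes),
              transcripts = do.call(rbind, tx),
              exons = do.call(rbind, exons),
              utr5 = do.call(rbind, utr5),
              cds = do.call(rbind, cds))
  ann <- lapply(ann, function(df) { rownames(df) <- NULL; df })
  class(ann) <- "genome_annotation"
  ann
}

#' Write a corpus annotation as GFF3
#' @param corpus an `ime_corpus`.
#' @param path output GFF3 path.
#' @export
write_corpus_gff3 <- function(corpus, path) {
  ann <- corpus_annotation(corpus)
  lines <- c("##gff-version 3")
  fmt <- function(chrom, type, start, end, strand, attrs)
    sprintf("%s\tsynthetic\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, type, start + 1L, end, strand, attrs)
  for (i in seq_len(nrow(ann$genes))) {
    g <- ann$genes[i, ]
    tid <- paste0(g$gene_id, ".1")
    lines <- c(lines,
               fmt(g$chrom, "gene", g$start, g$end, g$strand,
                   paste0("ID=", g$gene_id)),
               fmt(g$chrom, "mRNA", g$start, g$end, g$strand,
                   paste0("ID=", tid, ";Parent=", g$gene_id)))
    for (what in c("exons", "utr5", "cds")) {
      typ <- c(exons = "exon", utr5 = "five_prime_UTR", cds = "CDS")[[what]]
      sub <- ann[[what]]
      sub <- sub[sub$transcript_id == tid, , drop = FALSE]
      for (j in seq_len(nrow(sub)))
        lines <- c(lines, fmt(sub$chrom[j], typ, sub$start[j], sub$end[j],
                              sub$strand[j], paste0("Parent=", tid)))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Generate population variants for a corpus
#'
#' Places SNPs by per-site Bernoulli draws at `base_rate` per bp over the
#' whole genome, multiplied by `motif_suppression` inside planted motif
#' footprints (conserved functional sequence). Per-accession haploid
#' genotypes are drawn from a two-point allele-frequency mixture (a `common`
#' class whose minor-allele counts pass the >= 50 filter and a rare class
#' that fails it) with a small missing-call rate. The truth gains, per
#' planted gene, the motif-covering SNP positions and the accessions carrying
#' a variant motif allele.
#'
#' @param corpus an `ime_corpus` (after [plant_motifs()]).
#' @param n_accessions accessions (default 200).
#' @param base_rate SNP density per bp (default 0.016).
#' @param motif_suppression rate multiplier inside planted motifs
#'   (default 0.2).
#' @param common_frac fraction of sites in the common-allele class
#'   (default 0.7).
#' @param common_range,rare_range minor-allele count ranges of the two
#'   classes (defaults 55..100 and 2..40).
#' @param missing_rate per-call missing probability (default 0.02).
#' @param seed integer seed.
#' @return list with `snps` (a `snp_table` with genotypes), and the updated
#'   `corpus` (truth extended with `motif_snps` and `variant_accessions`).
#' @export
generate_variants <- function(corpus, n_accessions = 200L, base_rate = 0.016,
                              motif_suppression = 0.2, common_frac = 0.7,
                              common_range = c(55L, 100L),
                              rare_range = c(2L, 40L),
                              missing_rate = 0.02, seed = 1L) {
  stopifnot(base_rate >= 0, base_rate <= 1,
            motif_suppression >= 0, motif_suppression <= 1)
  set.seed(derive_seed(seed, 3L))
  genome <- corpus_genome(corpus)
  loci <- planted_motif_loci(corpus)
  acc <- sprintf("acc%03d", seq_len(n_accessions))
  sites <- list()
  gts <- list()
  for (ch in names(genome)) {
    L <- length(genome[[ch]])
    rate <- rep(base_rate, L)
    if (!is.null(loci)) {
      lc <- loci[loci$chrom == ch, , drop = FALSE]
      for (j in seq_len(nrow(lc)))
        rate[(lc$start[j] + 1L):lc$end[j]] <- base_rate * motif_suppression
    }
    hit <- which(runif(L) < rate)
    if (!length(hit)) next
    refs <- chars(as.character(genome[[ch]]))[hit]
    ok <- refs %in% c("A", "C", "G", "T")
    hit <- hit[ok]; refs <- refs[ok]
    alts <- vapply(refs, function(r)
      sample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1))
    n_site <- length(hit)
    gt <- matrix(0L, nrow = n_site, ncol = n_accessions,
                 dimnames = list(NULL, acc))
    common <- runif(n_site) < common_frac
    m <- integer(n_site)
    m[common] <- sample(common_range[1]:common_range[2], sum(common), TRUE)
    m[!common] <- sample(rare_range[1]:rare_range[2], sum(!common), TRUE)
    m <- pmin(m, n_accessions %/% 2L)  # minor allele stays minor
    for (s in seq_len(n_site)) {
      gt[s, sample.int(n_accessions, m[s])] <- 1L
      miss <- runif(n_accessions) < missing_rate
      gt[s, miss] <- NA_integer_
    }
    sites[[ch]] <- data.frame(chrom = ch, pos = hit - 1L, ref = refs,
                              alt = unname(alts), stringsAsFactors = FALSE)
    gts[[ch]] <- gt
  }
  sites <- do.call(rbind, sites)
  gt <- do.call(rbind, gts)
  rownames(sites) <- NULL
  called <- rowSums(!is.na(gt))
  alt_count <- rowSums(gt, na.rm = TRUE)
  sites$alt_count <- as.integer(alt_count)
  sites$called <- as.integer(called)
  sites$minor_count <- pmin(sites$alt_count, sites$called - sites$alt_count)
  snps <- list(sites = sites, gt = gt)
  class(snps) <- "snp_table"

  # truth: motif SNPs and variant accessions per planted gene
  if (!is.null(loci)) {
    motif_snps <- list(); variant_acc <- list()
    for (g in unique(loci$gene_id)) {
      lg <- loci[loci$gene_id == g, , drop = FALSE]
      sel <- integer(0)
      for (j in seq_len(nrow(lg)))
        sel <- union(sel, which(sites$chrom == lg$chrom[j] &
                                  sites$pos >= lg$start[j] &
                                  sites$pos < lg$end[j]))
      motif_snps[[g]] <- sites$pos[sel]
      variant_acc[[g]] <- if (length(sel))
        colnames(gt)[apply(gt[sel, , drop = FALSE], 2,
                           function(x) any(x > 0, na.rm = TRUE))]
      else character()
    }
    corpus$truth$motif_snps <- motif_snps
    corpus$truth$variant_accessions <- variant_acc
  }
  corpus$truth$n_accessions <- n_accessions
  corpus$truth$base_rate <- base_rate
  corpus$truth$motif_suppression <- motif_suppression
  list(snps = snps, corpus = corpus)
}

#' Write a `snp_table` with genotypes as a haploid VCF
#' @param snps `snp_table` with genotype matrix.
#' @param path output VCF path.
#' @export
write_vcf <- function(snps, path) {
  acc <- colnames(snps$gt)
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", acc), collapse = "\t"))
  s <- snps$sites
  gt_chr <- matrix(as.character(snps$gt), nrow = nrow(s))
  gt_chr[is.na(gt_chr)] <- "."
  body <- paste(s$chrom, s$pos + 1L, ".", s$ref, s$alt, ".", "PASS",
                paste0("AC=", s$alt_count, ";AN=", s$called), "GT",
                apply(gt_chr, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Generate condition- and accession-wise expression matrices
#'
#' Condition matrix: `value = baseline_g + level_shift * motif_g +
#' latent_loading * motif_g * f_c + N(0, noise_sd)` with `f_c` a shared
#' standard-normal factor per condition, so planted-motif genes are both
#' shifted upward and mutually correlated. Accession matrix:
#' `value = baseline_g + level_shift * motif_g - allele_delta * mutated_{g,a}
#' + N(0, noise_sd)` where `mutated` marks accessions carrying an alternate
#' allele in the gene's planted motif (from the variant truth), so the
#' theoretical per-gene allele effect is `d = allele_delta / noise_sd`.
#'
#' @param corpus an `ime_corpus` whose truth has variant accessions (run
#'   [generate_variants()] first, or supply `variant_accessions`).
#' @param n_conditions columns of the condition matrix (default 300).
#' @param latent_loading loading of motif genes on the shared factor
#'   (default 0.6).
#' @param level_shift expression-level shift of motif genes (default 0.4).
#' @param allele_delta decrement of mutated-motif accessions (default 0.5).
#' @param noise_sd residual standard deviation (default 1.0).
#' @param baseline_mean,baseline_sd per-gene baseline distribution
#'   (defaults 3 and 1, log scale).
#' @param g_loading optional coupling of the baseline to the standardised
#'   G content of the gene's first intron (default 0: expression depends on
#'   the planted motif only; nonzero values make base composition a true
#'   expression determinant, for classifier studies).
#' @param seed integer seed.
#' @return list with `conditions` (genes x conditions matrix) and
#'   `accessions` (genes x accessions matrix).
#' @export
generate_expression <- function(corpus, n_conditions = 300L,
                                latent_loading = 0.6, level_shift = 0.4,
                                allele_delta = 0.5, noise_sd = 1.0,
                                baseline_mean = 3, baseline_sd = 1,
                                g_loading = 0, seed = 1L) {
  set.seed(derive_seed(seed, 4L))
  gene_ids <- vapply(corpus$structs, function(s) s$gene_id, character(1))
  n_genes <- length(gene_ids)
  motif <- as.numeric(gene_ids %in% corpus$truth$genes)
  baseline <- rnorm(n_genes, baseline_mean, baseline_sd)
  if (g_loading != 0) {
    gfrac <- vapply(corpus$structs, function(s) {
      ch <- chars(s$intron_seqs[1])
      mean(ch == "G")
    }, numeric(1))
    baseline <- baseline + g_loading * as.numeric(scale(gfrac))
  }
  f_c <- rnorm(n_conditions)
  cond <- matrix(rnorm(n_genes * n_conditions, sd = noise_sd),
                 n_genes, n_conditions,
                 dimnames = list(gene_ids,
                                 sprintf("cond%03d", seq_len(n_conditions))))
  cond <- cond + baseline + level_shift * motif +
    latent_loading * outer(motif, f_c)

  n_acc <- corpus$truth$n_accessions %||% 200L
  acc <- sprintf("acc%03d", seq_len(n_acc))
  accm <- matrix(rnorm(n_genes * n_acc, sd = noise_sd), n_genes, n_acc,
                 dimnames = list(gene_ids, acc))
  mut <- matrix(0, n_genes, n_acc, dimnames = list(gene_ids, acc))
  va <- corpus$truth$variant_accessions
  if (!is.null(va)) {
    for (g in names(va)) if (length(va[[g]])) mut[g, va[[g]]] <- 1
  }
  accm <- accm + baseline + level_shift * motif - allele_delta * mut
  list(conditions = cond, accessions = accm)
}

#' Write an expression matrix as TSV
#' @param mat genes x samples matrix.
#' @param path output TSV (header row of sample ids, first column gene_id).
#' @export
write_expression_tsv <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix written by [write_expression_tsv()]
#' @param path TSV path.
#' @return genes x samples numeric matrix.
#' @export
read_expression_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

random_bed <- function(genome, n, width_range = c(50L, 200L)) {
  rows <- list()
  for (i in seq_len(n)) {
    ch <- sample(names(genome), 1L)
    w <- sample(width_range[1]:width_range[2], 1L)
    L <- length(genome[[ch]])
    s <- sample.int(max(1L, L - w), 1L) - 1L
    rows[[i]] <- data.frame(chrom = ch, start = s, end = s + w,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out[order(out$chrom, out$start), ]
}

#' Generate a complete synthetic corpus and write it to disk
#'
#' Orchestrates [generate_genome()], [plant_motifs()], [generate_variants()]
#' and [generate_expression()], fabricates the auxiliary interval annotations
#' (DMRs, CNS, transposons) and a plausibly scaled per-intron folding-energy
#' table, and writes everything in the pipeline's input formats: genome.fa,
#' annotation.gff3, variants.vcf, expr_conditions.tsv, expr_accessions.tsv,
#' dmr_c.bed, dmr_cg.bed, cns.bed, te.bed, fold_energy.tsv, truth.json.
#'
#' @param out_dir output directory (default a fresh tempdir subdirectory).
#' @param seed master integer seed; every downstream number is determined by
#'   it.
#' @param ... overrides passed to the generator stages (matched by name:
#'   `n_genes`, `motif`, `gene_fraction`, `occurrences_per_intron`,
#'   `position_beta`, `n_accessions`, `base_rate`, `motif_suppression`,
#'   `n_conditions`, `latent_loading`, `level_shift`, `allele_delta`,
#'   `noise_sd`, `g_loading`, ...).
#' @return list with `dir`, file `paths`, the `corpus` (including truth), the
#'   `snps` table and the expression matrices.
#' @export
simulate_ime_corpus <- function(out_dir = NULL, seed = 1L, ...) {
  dots <- list(...)
  pick <- function(fn, extra) {
    ok <- intersect(names(dots), setdiff(names(formals(fn)), "seed"))
    c(extra, dots[ok], list(seed = seed))
  }
  corpus <- do.call(generate_genome, pick(generate_genome, list()))
  corpus <- do.call(plant_motifs, pick(plant_motifs, list(corpus = corpus)))
  gv <- do.call(generate_variants, pick(generate_variants, list(corpus = corpus)))
  corpus <- gv$corpus
  snps <- gv$snps
  expr <- do.call(generate_expression, pick(generate_expression,
                                            list(corpus = corpus)))
  genome <- corpus_genome(corpus)

  set.seed(derive_seed(seed, 5L))
  dmr_c <- random_bed(genome, 200L)
  dmr_cg <- random_bed(genome, 150L)
  cns <- random_bed(genome, 300L)
  te <- random_bed(genome, 100L, width_range = c(80L, 400L))
  # plausibly scaled folding energies for first introns (kcal/mol-like)
  fe_rows <- lapply(corpus$structs, function(st) {
    data.frame(intron_id = paste0(st$gene_id, "|1"),
               energy = -0.3 * st$intron_lens[1] + rnorm(1, 0, 5),
               stringsAsFactors = FALSE)
  })
  fold_energy <- do.call(rbind, fe_rows)

  out_dir <- out_dir %||% file.path(tempdir(),
                                    paste0("ime_corpus_", seed, "_",
                                           as.integer(stats::runif(1, 1, 1e6))))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    genome = file.path(out_dir, "genome.fa"),
    gff = file.path(out_dir, "annotation.gff3"),
    vcf = file.path(out_dir, "variants.vcf"),
    expr_conditions = file.path(out_dir, "expr_conditions.tsv"),
    expr_accessions = file.path(out_dir, "expr_accessions.tsv"),
    dmr_c = file.path(out_dir, "dmr_c.bed"),
    dmr_cg = file.path(out_dir, "dmr_cg.bed"),
    cns = file.path(out_dir, "cns.bed"),
    te = file.path(out_dir, "te.bed"),
    fold_energy = file.path(out_dir, "fold_energy.tsv"),
    truth = file.path(out_dir, "truth.json"))
  Biostrings::writeXStringSet(genome, paths$genome)
  write_corpus_gff3(corpus, paths$gff)
  write_vcf(snps, paths$vcf)
  write_expression_tsv(expr$conditions, paths$expr_conditions)
  write_expression_tsv(expr$accessions, paths$expr_accessions)
  for (nm in c("dmr_c", "dmr_cg", "cns", "te"))
    write.table(get(nm), paths[[nm]], sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  write.table(fold_energy, paths$fold_energy, sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(corpus$truth, paths$truth, auto_unbox = TRUE,
                       digits = NA)
  list(dir = out_dir, paths = paths, corpus = corpus, snps = snps,
       expr = expr, aux = list(dmr_c = dmr_c, dmr_cg = dmr_cg, cns = cns,
                               te = te, fold_energy = fold_energy))
}
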