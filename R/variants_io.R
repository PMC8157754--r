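#' Read population SNPs from a VCF file
#'
#' Reads a (plain or bgzipped) VCF and returns a `snp_table`: per-site
#' chromosome, 0-based position, ref/alt alleles, haploid counts, plus the
#' per-accession genotype matrix when GT fields are present. Only
#' single-nucleotide records are retained; multi-allelic records are treated
#' as one polymorphic position (any alternate allele counts). Allele counts
#' are haploid: each called allele of each accession contributes one; missing
#' ('.') alleles are excluded from the called count.
#'
#' @param vcf path to a VCF file.
#' @return object of class `snp_table`: list with `sites` (data frame: chrom,
#'   pos, ref, alt, alt_count, minor_count, called) and `gt` (sites x
#'   accessions integer matrix of alternate-allele carrier status, or NULL
#'   when the VCF has no GT field).
#' @export
read_snps <- function(vcf) {
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  snv <- nchar(fix$REF) == 1L &
    vapply(strsplit(fix$ALT, ",", fixed = TRUE),
           function(a) all(nchar(a) == 1L) && all(a %in% c("A", "C", "G", "T")),
           logical(1))
  gt <- NULL
  has_gt <- ncol(v@gt) > 1L && any(grepl("GT", v@gt[, 1]))
  if (has_gt) {
    g <- vcfR::extract.gt(v, element = "GT")
    g <- g[snv, , drop = FALSE]
    # haploid or diploid calls; count alt and called alleles per cell
    alt_n <- function(x) {
      x[is.na(x)] <- "."
      al <- strsplit(x, "[/|]")
      list(alt = vapply(al, function(a) sum(a != "." & a != "0"), integer(1)),
           called = vapply(al, function(a) sum(a != "."), integer(1)))
    }
    altm <- matrix(0L, nrow(g), ncol(g), dimnames = dimnames(g))
    callm <- altm
    for (j in seq_len(ncol(g))) {
      cell <- alt_n(g[, j])
      altm[, j] <- cell$alt
      callm[, j] <- cell$called
    }
    alt_count <- rowSums(altm)
    called <- rowSums(callm)
    gt <- altm
    gt[callm == 0L] <- NA_integer_
  } else {
    info <- fix$INFO[snv]
    ac <- suppressWarnings(as.integer(sub(".*AC=([0-9]+).*", "\\1", info)))
    an <- suppressWarnings(as.integer(sub(".*AN=([0-9]+).*", "\\1", info)))
    if (all(is.na(ac)) || all(is.na(an)))
      stop("VCF has neither GT fields nor AC/AN INFO")
    alt_count <- ac
    called <- an
  }
  sites <- data.frame(
    chrom = fix$CHROM[snv],
    pos = as.integer(fix$POS[snv]) - 1L,
    ref = fix$REF[snv],
    alt = fix$ALT[snv],
    alt_count = as.integer(alt_count),
    called = as.integer(called),
    stringsAsFactors = FALSE
  )
  sites$minor_count <- pmin(sites$alt_count, sites$called - sites$alt_count)
  out <- list(sites = sites, gt = gt)
  class(out) <- "snp_table"
  out
}

#' @export
print.snp_table <- function(x, ...) {
  cat("snp_table:", nrow(x$sites), "sites",
      if (!is.null(x$gt)) paste0("x ", ncol(x$gt), " accessions"), "\n")
  invisible(x)
}

#' Filter SNPs on minor-allele and called-allele counts
#'
#' Retains positions whose haploid minor-allele count is at least
#' `min_minor_count` and whose number of called (non-missing) haploid alleles
#' is at least `min_called`. Raising either threshold can only remove sites.
#'
#' @param snps a `snp_table` (or path to a VCF, which is read first).
#' @param min_minor_count minimum haploid minor-allele count (default 50).
#' @param min_called minimum called haploid alleles (default 500).
#' @return the filtered `snp_table`.
#' @export
filter_snps <- function(snps, min_minor_count = 50L, min_called = 500L) {
  if (is.character(snps)) snps <- read_snps(snps)
  keep <- !is.na(snps$sites$minor_count) &
    snps$sites$minor_count >= min_minor_count &
    snps$sites$called >= min_called
  subset_snps(snps, keep)
}

subset_snps <- function(snps, keep) {
  snps$sites <- snps$sites[keep, , drop = FALSE]
  rownames(snps$sites) <- NULL
  if (!is.null(snps$gt)) snps$gt <- snps$gt[keep, , drop = FALSE]
  if (!is.null(snps$map)) snps$map <- NULL
  snps
}

#' Intersect SNPs with intron intervals
#'
#' Returns the SNPs falling inside the given introns after excluding `trim`
#' bp at each intron end (splice-site positions are over-conserved and would
#' bias k-mer conservation). Adds a `map` data frame with one row per
#' (SNP, intron) hit carrying the transcript-oriented intron offset (0-based),
#' so masking can be applied directly to intron sequences.
#'
#' @param snps a `snp_table`.
#' @param introns intron data frame.
#' @param trim bp excluded at each intron end (default 3).
#' @return the intersected `snp_table` with a `map` element (chrom, pos,
#'   intron_id, intron_offset).
#' @export
snps_in_intervals <- function(snps, introns, trim = 3L) {
  sites <- snps$sites
  hits_list <- vector("list", length(unique(introns$chrom)))
  maps <- list()
  keep <- rep(FALSE, nrow(sites))
  for (ch in unique(introns$chrom)) {
    ii <- introns[introns$chrom == ch, , drop = FALSE]
    si <- which(sites$chrom == ch)
    if (!nrow(ii) || !length(si)) next
    ir_int <- IRanges::IRanges(start = ii$start + trim + 1L,
                               end = pmax(ii$end - trim, ii$start + trim))
    ir_snp <- IRanges::IRanges(start = sites$pos[si] + 1L, width = 1L)
    ov <- IRanges::findOverlaps(ir_snp, ir_int)
    if (!length(ov)) next
    qi <- si[S4Vectors::queryHits(ov)]
    sj <- S4Vectors::subjectHits(ov)
    keep[qi] <- TRUE
    off <- ifelse(ii$strand[sj] == "+",
                  sites$pos[qi] - ii$start[sj],
                  ii$end[sj] - 1L - sites$pos[qi])
    maps[[length(maps) + 1L]] <- data.frame(
      chrom = ch, pos = sites$pos[qi], intron_id = ii$intron_id[sj],
      intron_offset = as.integer(off), stringsAsFactors = FALSE)
  }
  out <- subset_snps(snps, keep)
  map <- if (length(maps)) do.call(rbind, maps) else
    data.frame(chrom = character(), pos = integer(), intron_id = character(),
               intron_offset = integer(), stringsAsFactors = FALSE)
  rownames(map) <- NULL
  out$map <- map
  out
}

#' Mask SNP positions in a sequence
#'
#' Replaces the given 0-based offsets with a symbol outside the nucleic-acid
#' alphabet so that k-mer windows covering a polymorphic position are not
#' counted. Duplicate offsets mask one position; length is preserved.
#'
#' @param sequence DNA string.
#' @param snp_offsets integer vector of 0-based positions within the sequence.
#' @param mask masking character (default `*`).
#' @return the masked sequence.
#' @export
mask_sequence <- function(sequence, snp_offsets, mask = "*") {
  if (!length(snp_offsets)) return(sequence)
  snp_offsets <- unique(as.integer(snp_offsets))
  n <- nchar(sequence)
  if (any(snp_offsets < 0L | snp_offsets >= n))
    stop("SNP offset out of range for sequence of length ", n)
  ch <- chars(sequence)
  ch[snp_offsets + 1L] <- mask
  paste(ch, collapse = "")
}

#' Per-position relative SNP frequency around intron 5' ends
#'
#' For each aligned position (the first `flank` bp of the intron in transcript
#' orientation, and the `flank` bp of the immediately preceding exon), the
#' relative SNP frequency is the number of introns carrying a SNP at that
#' position divided by the number of introns covering it. Exon positions are
#' labelled -flank..-1, intron positions 1..flank.
#'
#' @param introns intron data frame.
#' @param snps a `snp_table` (genome-wide; not pre-intersected).
#' @param flank positions on each side (default 20).
#' @return data frame with `position`, `n_snps`, `n_covering`, `frequency`
#'   (NA when no intron covers a position).
#' @export
snp_density_profile <- function(introns, snps, flank = 20L) {
  sites <- snps$sites
  snp_key <- paste(sites$chrom, sites$pos)
  positions <- c(-(flank:1), 1:flank)
  n_snp <- setNames(integer(length(positions)), positions)
  n_cov <- n_snp
  for (i in seq_len(nrow(introns))) {
    len <- introns$end[i] - introns$start[i]
    for (p in positions) {
      if (p > 0 && p > len) next
      gpos <- if (introns$strand[i] == "+") {
        if (p > 0) introns$start[i] + p - 1L else introns$start[i] + p
      } else {
        if (p > 0) introns$end[i] - p else introns$end[i] - 1L - p
      }
      lab <- as.character(p)
      n_cov[lab] <- n_cov[lab] + 1L
      if (paste(introns$chrom[i], gpos) %in% snp_key)
        n_snp[lab] <- n_snp[lab] + 1L
    }
  }
  data.frame(position = positions, n_snps = unname(n_snp),
             n_covering = unname(n_cov),
             frequency = ifelse(n_cov > 0, n_snp / n_cov, NA_real_))
}

#' Randomly expected k-mer conservation
#'
#' Probability that a k-mer window contains no SNP under uniformly random SNP
#' placement at the given density: `(1 - density)^k`.
#'
#' @param density SNP density (SNPs per bp), in `[0, 1]`.
#' @param k k-mer size.
#' @return expected conservation rate.
#' @export
expected_conservation <- function(density, k) {
  if (any(density < 0 | density > 1)) stop("density must be in [0, 1]")
  stopifnot(k >= 1)
  (1 - density)^k
}

#' Summarise SNP density and expected conservation over an intron set
#'
#' @param introns intron data frame (one set, e.g. first introns).
#' @param snps a `snp_table` already filtered to the analysis thresholds.
#' @param k k-mer size for the expected conservation (default 6).
#' @param trim bp excluded at each intron end (default 3).
#' @return list with `n_snp`, `n_bp`, `density` and `c_r`.
#' @export
conservation_summary <- function(introns, snps, k = 6L, trim = 3L) {
  inside <- snps_in_intervals(snps, introns, trim = trim)
  n_snp <- nrow(inside$map)
  n_bp <- sum(pmax(0L, introns$end - introns$start - 2L * trim))
  density <- if (n_bp > 0) n_snp / n_bp else NA_real_
  list(n_snp = n_snp, n_bp = n_bp, density = density,
       c_r = expected_conservation(density, k))
}
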