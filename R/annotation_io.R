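#' Read a GFF3 gene annotation into the internal representation
#'
#' Parses `gene`, `mRNA`, `exon`, `five_prime_UTR` and `CDS` features from a
#' GFF3 file. All coordinates are converted to 0-based half-open intervals,
#' which is the convention used throughout the package (GFF3 input is 1-based
#' inclusive; BED output is 0-based half-open).
#'
#' @param gff path to a GFF3 file.
#' @return an object of class `genome_annotation`: a list with data frames
#'   `genes` (gene_id, chrom, start, end, strand), `transcripts`
#'   (transcript_id, gene_id, chrom, strand, start, end), `exons`, `utr5` and
#'   `cds` (each transcript_id, start, end).
#' @export
read_annotation <- function(gff) {
  gr <- rtracklayer::import(gff)
  typ <- as.character(gr$type)
  first_parent <- function(p) vapply(p, function(x) if (length(x)) x[[1]] else NA_character_, character(1))
  take <- function(sel, id_col = NULL, parent = FALSE) {
    g <- gr[sel]
    df <- data.frame(
      chrom  = as.character(GenomicRanges::seqnames(g)),
      start  = GenomicRanges::start(g) - 1L,
      end    = GenomicRanges::end(g),
      strand = as.character(GenomicRanges::strand(g)),
      stringsAsFactors = FALSE
    )
    if (!is.null(id_col)) df$id <- as.character(S4Vectors::mcols(g)[[id_col]])
    if (parent) df$parent <- first_parent(S4Vectors::mcols(g)$Parent)
    df
  }
  genes <- take(typ == "gene", id_col = "ID")
  names(genes)[names(genes) == "id"] <- "gene_id"
  tx <- take(typ %in% c("mRNA", "transcript"), id_col = "ID", parent = TRUE)
  names(tx)[names(tx) == "id"] <- "transcript_id"
  names(tx)[names(tx) == "parent"] <- "gene_id"
  sub <- function(what) {
    df <- take(typ == what, parent = TRUE)
    names(df)[names(df) == "parent"] <- "transcript_id"
    df[, c("transcript_id", "chrom", "start", "end", "strand")]
  }
  ann <- list(
    genes = genes[, c("gene_id", "chrom", "start", "end", "strand")],
    transcripts = tx[, c("transcript_id", "gene_id", "chrom", "start", "end", "strand")],
    exons = sub("exon"),
    utr5 = sub("five_prime_UTR"),
    cds = sub("CDS")
  )
  class(ann) <- "genome_annotation"
  ann
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", nrow(x$genes), "genes,", nrow(x$transcripts),
      "transcripts,", nrow(x$exons), "exons\n")
  invisible(x)
}

#' Derive introns from exon positions
#'
#' Introns are the gaps between consecutive exons of a transcript. Ranks are
#' numbered in transcript (5'->3') orientation, so for minus-strand genes rank
#' 1 is the genomically 3'-most gap. Introns shorter than `min_length` are
#' dropped. Duplicate intron intervals arising from multiple transcripts of
#' one gene are collapsed to unique (gene, interval) records keeping the
#' minimum rank; per gene, at most one intron carries `is_first = TRUE`,
#' resolved as the rank-1 intron whose 5' end lies closest to the gene's TSS
#' (ties broken by longest transcript, then transcript id).
#'
#' @param annotation a `genome_annotation`.
#' @param min_length minimum intron length in bp (default 10; shorter gaps are
#'   discarded as likely annotation artefacts).
#' @return data frame of intron records: intron_id, gene_id, transcript_id,
#'   chrom, start, end (0-based half-open), strand, rank, is_first, in_utr5
#'   (NA until flagged), sequence (NA until fetched), dist_tss, dist_cds.
#' @export
extract_introns <- function(annotation, min_length = 10L) {
  stopifnot(inherits(annotation, "genome_annotation"))
  tx <- annotation$transcripts
  ex <- annotation$exons
  cds <- annotation$cds
  ex_by_tx <- split(ex, ex$transcript_id)
  cds_by_tx <- split(cds, cds$transcript_id)
  recs <- vector("list", nrow(tx))
  for (i in seq_len(nrow(tx))) {
    t <- tx[i, ]
    e <- ex_by_tx[[t$transcript_id]]
    if (is.null(e) || nrow(e) < 2L) next
    e <- e[order(e$start), ]
    if (any(e$start[-1] < e$end[-nrow(e)])) {
      warning("overlapping exons in transcript ", t$transcript_id,
              "; transcript rejected", call. = FALSE)
      next
    }
    gstart <- e$end[-nrow(e)]
    gend <- e$start[-1]
    n <- length(gstart)
    rank <- if (t$strand == "+") seq_len(n) else rev(seq_len(n))
    # translation start in genomic coords (5'-most CDS base in tx orientation)
    cc <- cds_by_tx[[t$transcript_id]]
    cds_start <- if (is.null(cc) || !nrow(cc)) NA_integer_ else
      if (t$strand == "+") min(cc$start) else max(cc$end)
    if (t$strand == "+") {
      dist_tss <- gstart - t$start
      dist_cds <- if (is.na(cds_start)) NA_integer_ else gstart - cds_start
    } else {
      dist_tss <- t$end - gend
      dist_cds <- if (is.na(cds_start)) NA_integer_ else cds_start - gend
    }
    recs[[i]] <- data.frame(
      gene_id = t$gene_id, transcript_id = t$transcript_id, chrom = t$chrom,
      start = gstart, end = gend, strand = t$strand, rank = rank,
      dist_tss = dist_tss, dist_cds = dist_cds, tx_len = t$end - t$start,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, recs)
  if (is.null(out) || !nrow(out)) return(empty_introns())
  out <- out[out$end - out$start >= min_length, , drop = FALSE]
  if (!nrow(out)) return(empty_introns())

  # collapse duplicates per (gene, interval): min rank; carrier transcript by
  # min rank, then longest transcript, then transcript id
  key <- paste(out$gene_id, out$chrom, out$start, out$end, sep = "\r")
  out <- out[order(key, out$rank, -out$tx_len, out$transcript_id), ]
  out <- out[!duplicated(paste(out$gene_id, out$chrom, out$start, out$end, sep = "\r")), ]

  # per-gene first intron among rank-1 records: 5' end closest to gene TSS
  genes <- annotation$genes
  gtss <- ifelse(genes$strand == "+", genes$start, genes$end)
  names(gtss) <- genes$gene_id
  p5 <- ifelse(out$strand == "+", out$start, out$end)
  out$is_first <- FALSE
  for (g in unique(out$gene_id[out$rank == 1L])) {
    idx <- which(out$gene_id == g & out$rank == 1L)
    d <- abs(p5[idx] - gtss[[g]])
    pick <- idx[order(d, -out$tx_len[idx], out$transcript_id[idx])][1]
    out$is_first[pick] <- TRUE
  }
  out$tx_len <- NULL
  out$in_utr5 <- NA
  out$sequence <- NA_character_
  out$intron_id <- paste0(out$gene_id, "|", out$rank)
  rownames(out) <- NULL
  out[, intron_cols()]
}

intron_cols <- function() {
  c("intron_id", "gene_id", "transcript_id", "chrom", "start", "end", "strand",
    "rank", "is_first", "in_utr5", "sequence", "dist_tss", "dist_cds")
}

empty_introns <- function() {
  df <- data.frame(intron_id = character(), gene_id = character(),
                   transcript_id = character(), chrom = character(),
                   start = integer(), end = integer(), strand = character(),
                   rank = integer(), is_first = logical(), in_utr5 = logical(),
                   sequence = character(), dist_tss = integer(),
                   dist_cds = integer(), stringsAsFactors = FALSE)
  df
}

#' Flag introns located in the 5' UTR
#'
#' An intron is flagged `in_utr5` when its interval, artificially extended by
#' `extension` bp at either end, overlaps any annotated 5'UTR interval of the
#' same gene by at least one bp. Genes without annotated 5'UTR yield `FALSE`.
#'
#' @param introns intron data frame from [extract_introns()].
#' @param annotation the `genome_annotation` the introns came from.
#' @param extension bp added at both ends before the overlap test (default 5).
#' @return the intron data frame with `in_utr5` filled.
#' @export
flag_utr5_introns <- function(introns, annotation, extension = 5L) {
  utr <- annotation$utr5
  tx2gene <- setNames(annotation$transcripts$gene_id, annotation$transcripts$transcript_id)
  utr$gene_id <- unname(tx2gene[utr$transcript_id])
  introns$in_utr5 <- FALSE
  if (!nrow(utr) || !nrow(introns)) return(introns)
  utr_by_gene <- split(utr, utr$gene_id)
  for (i in seq_len(nrow(introns))) {
    u <- utr_by_gene[[introns$gene_id[i]]]
    if (is.null(u)) next
    s <- introns$start[i] - extension
    e <- introns$end[i] + extension
    introns$in_utr5[i] <- any(u$chrom == introns$chrom[i] & u$start < e & u$end > s)
  }
  introns
}

#' Fill intron sequences from the genome
#'
#' Sequences are returned in transcript orientation: minus-strand intervals
#' are reverse-complemented. Output is upper case; length always equals
#' `end - start`.
#'
#' @param introns intron data frame.
#' @param genome a [Biostrings::DNAStringSet] or path to a FASTA file.
#' @return the intron data frame with `sequence` filled.
#' @export
fetch_sequences <- function(introns, genome) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (!nrow(introns)) return(introns)
  bad <- !(introns$chrom %in% names(genome))
  if (any(bad)) stop("chromosome(s) not in genome: ",
                     paste(unique(introns$chrom[bad]), collapse = ", "))
  lens <- Biostrings::width(genome)[match(introns$chrom, names(genome))]
  oob <- introns$start < 0L | introns$end > lens
  if (any(oob)) stop("interval out of bounds for intron ",
                     introns$intron_id[which(oob)[1]])
  seqs <- character(nrow(introns))
  for (ch in unique(introns$chrom)) {
    idx <- which(introns$chrom == ch)
    v <- Biostrings::Views(genome[[ch]], start = introns$start[idx] + 1L,
                           end = introns$end[idx])
    s <- toupper(as.character(v))
    neg <- introns$strand[idx] == "-"
    if (any(neg)) s[neg] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(s[neg])))
    seqs[idx] <- s
  }
  introns$sequence <- unname(seqs)
  introns
}

#' Write introns as BED6
#'
#' name is `gene_id|rank`, score is intron length, coordinates are 0-based
#' half-open as BED requires.
#'
#' @param introns intron data frame.
#' @param path output file.
#' @export
write_intron_bed <- function(introns, path) {
  bed <- data.frame(introns$chrom, introns$start, introns$end,
                    introns$intron_id, introns$end - introns$start,
                    introns$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 file of introns written by [write_intron_bed()]
#' @param path BED file.
#' @return data frame with chrom, start, end, intron_id, length, strand.
#' @export
read_intron_bed <- function(path) {
  bed <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  names(bed) <- c("chrom", "start", "end", "intron_id", "length", "strand")
  bed
}

#' Write intron sequences as FASTA
#' @param introns intron data frame with sequences.
#' @param path output file.
#' @export
write_intron_fasta <- function(introns, path) {
  ss <- Biostrings::DNAStringSet(introns$sequence)
  names(ss) <- introns$intron_id
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
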