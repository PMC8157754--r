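# toy fixtures built in code

# build a genome_annotation directly from per-transcript exon intervals
# (1-based inclusive, as a human would write them; converted internally)
toy_annotation <- function(genes) {
  g <- list(); tx <- list(); ex <- list(); utr <- list(); cds <- list()
  for (gn in genes) {
    exons0 <- lapply(gn$exons, function(e)
      c(as.integer(e[1]) - 1L, as.integer(e[2])))  # to 0-based
    gstart <- min(vapply(exons0, `[`, integer(1), 1))
    gend <- max(vapply(exons0, `[`, integer(1), 2))
    g[[gn$id]] <- data.frame(gene_id = gn$id, chrom = gn$chrom,
                             start = gstart, end = gend, strand = gn$strand,
                             stringsAsFactors = FALSE)
    tid <- gn$tx_id %||% paste0(gn$id, ".1")
    tx[[gn$id]] <- data.frame(transcript_id = tid, gene_id = gn$id,
                              chrom = gn$chrom, start = gstart, end = gend,
                              strand = gn$strand, stringsAsFactors = FALSE)
    for (e in exons0)
      ex[[length(ex) + 1L]] <- data.frame(transcript_id = tid,
                                          chrom = gn$chrom, start = e[1],
                                          end = e[2], strand = gn$strand,
                                          stringsAsFactors = FALSE)
    for (u in gn$utr5 %||% list())
      utr[[length(utr) + 1L]] <- data.frame(transcript_id = tid,
                                            chrom = gn$chrom,
                                            start = u[1] - 1L, end = u[2],
                                            strand = gn$strand,
                                            stringsAsFactors = FALSE)
    for (cc in gn$cds %||% list())
      cds[[length(cds) + 1L]] <- data.frame(transcript_id = tid,
                                            chrom = gn$chrom,
                                            start = cc[1] - 1L, end = cc[2],
                                            strand = gn$strand,
                                            stringsAsFactors = FALSE)
  }
  empty <- data.frame(transcript_id = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      stringsAsFactors = FALSE)
  ann <- list(genes = do.call(rbind, g), transcripts = do.call(rbind, tx),
              exons = do.call(rbind, ex),
              utr5 = if (length(utr)) do.call(rbind, utr) else empty,
              cds = if (length(cds)) do.call(rbind, cds) else empty)
  ann <- lapply(ann, function(df) { rownames(df) <- NULL; df })
  class(ann) <- "genome_annotation"
  ann
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a snp_table built from explicit fields (gt optional: accessions x sites
# supplied as a sites x accessions matrix of 0/1/NA)
toy_snps <- function(chrom, pos, minor_count = NULL, called = NULL, gt = NULL) {
  n <- length(pos)
  alt_count <- minor_count %||% rep(1L, n)
  called <- called %||% rep(100L, n)
  sites <- data.frame(chrom = rep_len(chrom, n), pos = as.integer(pos),
                      ref = rep("A", n), alt = rep("T", n),
                      alt_count = as.integer(alt_count),
                      called = as.integer(called),
                      stringsAsFactors = FALSE)
  sites$minor_count <- pmin(sites$alt_count, sites$called - sites$alt_count)
  out <- list(sites = sites, gt = gt)
  class(out) <- "snp_table"
  out
}

# does a sequence match an IUPAC motif at some offset (either strand)?
iupac_matches <- function(seq, motif) {
  pat <- Biostrings::DNAString(motif)
  s <- Biostrings::DNAString(seq)
  n_f <- length(Biostrings::matchPattern(pat, s, fixed = FALSE))
  n_r <- length(Biostrings::matchPattern(
    Biostrings::reverseComplement(pat), s, fixed = FALSE))
  n_f + n_r > 0
}

# small cached synthetic corpus shared across test files
shared_corpus <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_ime_corpus(seed = 42, n_genes = 80,
                                    n_accessions = 60, n_conditions = 80)
    }
    cache
  }
})
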