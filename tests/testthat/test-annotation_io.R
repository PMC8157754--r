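test_that("introns are the gaps between exons, ranked in transcript orientation", {
  ann <- toy_annotation(list(
    list(id = "gp", chrom = "c1", strand = "+",
         exons = list(c(1, 100), c(201, 300), c(401, 500))),
    list(id = "gm", chrom = "c2", strand = "-",
         exons = list(c(1, 100), c(201, 300), c(401, 500)))))
  introns <- extract_introns(ann)
  ip <- introns[introns$gene_id == "gp", ]
  expect_equal(ip$start, c(100, 300))
  expect_equal(ip$end, c(200, 400))
  expect_equal(ip$rank, c(1, 2))
  expect_equal(ip$end - ip$start, c(100, 100))
  # minus strand: rank 1 is the genomically 3'-most gap
  im <- introns[introns$gene_id == "gm", ]
  expect_equal(im$rank[im$start == 300], 1)
  expect_equal(im$rank[im$start == 100], 2)
  expect_true(im$is_first[im$start == 300])
})

test_that("short gaps are excluded and single-exon transcripts yield nothing", {
  ann <- toy_annotation(list(
    list(id = "g1", chrom = "c1", strand = "+",
         exons = list(c(1, 100), c(106, 200))),
    list(id = "g2", chrom = "c1", strand = "+", exons = list(c(300, 500)))))
  introns <- extract_introns(ann)
  expect_equal(nrow(introns), 0)
})

test_that("overlapping exons reject the transcript with a warning", {
  ann <- toy_annotation(list(
    list(id = "g1", chrom = "c1", strand = "+",
         exons = list(c(1, 100), c(50, 200)))))
  expect_warning(introns <- extract_introns(ann), "overlapping")
  expect_equal(nrow(introns), 0)
})

test_that("duplicate intervals from multiple transcripts collapse to min rank, one is_first per gene", {
  ann <- toy_annotation(list(
    list(id = "g1", tx_id = "g1.1", chrom = "c1", strand = "+",
         exons = list(c(1, 100), c(201, 300), c(401, 500)))))
  ann2 <- toy_annotation(list(
    list(id = "g1", tx_id = "g1.2", chrom = "c1", strand = "+",
         exons = list(c(201, 300), c(401, 500)))))
  ann$transcripts <- rbind(ann$transcripts, ann2$transcripts)
  ann$exons <- rbind(ann$exons, ann2$exons)
  introns <- extract_introns(ann)
  # interval (300,400] appears in both transcripts: rank 2 in g1.1, rank 1 in g1.2
  expect_equal(nrow(introns), 2)
  expect_equal(introns$rank[introns$start == 300], 1)
  expect_equal(sum(introns$is_first[introns$gene_id == "g1"]), 1)
})

test_that("intron count matches a brute-force rescan over random toy annotations", {
  set.seed(5)
  for (rep in 1:5) {
    genes <- lapply(1:8, function(i) {
      n_ex <- sample(1:5, 1)
      starts <- cumsum(c(1, sample(5:120, max(0, n_ex * 2 - 1), TRUE)))
      exons <- lapply(seq_len(n_ex), function(k)
        c(starts[2 * k - 1], starts[2 * k] - 1))
      list(id = paste0("g", i), chrom = "c1",
           strand = sample(c("+", "-"), 1), exons = exons)
    })
    ann <- toy_annotation(genes)
    introns <- extract_introns(ann, min_length = 10)
    expected <- 0
    for (gn in genes) {
      if (length(gn$exons) < 2) next
      for (k in seq_len(length(gn$exons) - 1))
        if (gn$exons[[k + 1]][1] - gn$exons[[k]][2] - 1 >= 10)
          expected <- expected + 1
    }
    expect_equal(nrow(introns), expected)
    first_per_gene <- tapply(introns$is_first, introns$gene_id, sum)
    expect_true(all(first_per_gene == 1))
  }
})

test_that("5'UTR flagging uses the extended-overlap rule", {
  base <- list(id = "g1", chrom = "c1", strand = "+",
               exons = list(c(1, 101), c(202, 300)))
  # intron is (101,201] 0-based; UTR (95,101] 0-based = 96..101 1-based
  ann <- toy_annotation(list(c(base, list(utr5 = list(c(96, 101))))))
  introns <- flag_utr5_introns(extract_introns(ann), ann, extension = 5)
  expect_true(introns$in_utr5[1])
  ann2 <- toy_annotation(list(c(base, list(utr5 = list(c(91, 94))))))
  introns2 <- flag_utr5_introns(extract_introns(ann2), ann2, extension = 5)
  expect_false(introns2$in_utr5[1])
  # extension 0: half-open intervals sharing an endpoint do not overlap
  introns3 <- flag_utr5_introns(extract_introns(ann), ann, extension = 0)
  expect_false(introns3$in_utr5[1])
  # no annotated UTR: FALSE, no error
  ann4 <- toy_annotation(list(base))
  introns4 <- flag_utr5_introns(extract_introns(ann4), ann4)
  expect_false(introns4$in_utr5[1])
})

test_that("sequences are fetched in transcript orientation, upper case", {
  genome <- Biostrings::DNAStringSet(c(c1 = "NNacgtNNNNAAACNN"))
  mk <- function(strand, start, end) {
    data.frame(intron_id = "x|1", gene_id = "x", transcript_id = "x.1",
               chrom = "c1", start = start, end = end, strand = strand,
               rank = 1L, is_first = TRUE, in_utr5 = FALSE,
               sequence = NA_character_, dist_tss = 0L, dist_cds = 0L,
               stringsAsFactors = FALSE)
  }
  expect_equal(fetch_sequences(mk("+", 2, 6), genome)$sequence, "ACGT")
  expect_equal(fetch_sequences(mk("-", 2, 6), genome)$sequence, "ACGT")
  expect_equal(fetch_sequences(mk("-", 10, 14), genome)$sequence, "GTTT")
  expect_error(fetch_sequences(mk("+", 10, 99), genome), "out of bounds")
})

test_that("BED round-trip reproduces intervals", {
  ann <- toy_annotation(list(
    list(id = "g1", chrom = "c1", strand = "+",
         exons = list(c(1, 100), c(201, 300), c(401, 500)))))
  introns <- extract_introns(ann)
  path <- withr::local_tempfile(fileext = ".bed")
  write_intron_bed(introns, path)
  back <- read_intron_bed(path)
  expect_equal(back$start, introns$start)
  expect_equal(back$end, introns$end)
  expect_equal(back$intron_id, introns$intron_id)
})

test_that("GFF3 reading matches the in-memory annotation of the generator", {
  sim <- shared_corpus()
  ann_file <- read_annotation(sim$paths$gff)
  ann_mem <- corpus_annotation(sim$corpus)
  a <- extract_introns(ann_file)
  b <- extract_introns(ann_mem)
  o <- order(a$intron_id)
  p <- order(b$intron_id)
  expect_equal(a$start[o], b$start[p])
  expect_equal(a$end[o], b$end[p])
  expect_equal(a$rank[o], b$rank[p])
  expect_equal(a$dist_tss[o], b$dist_tss[p])
})
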