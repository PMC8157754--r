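# best gapless alignment of b (or its reverse complement) against a over
# offsets -max_offset..+max_offset; returns orientation, offset and distance
best_kmer_alignment <- function(a, b, max_offset = 2L, gap_penalty = 0.25) {
  ka <- nchar(a)
  kb <- nchar(b)
  ach <- chars(a)
  best <- list(dist = Inf, orient = "fwd", offset = 0L)
  for (orient in c("fwd", "rev")) {
    bb <- if (orient == "fwd") b else revcomp(b)
    bch <- chars(bb)
    for (o in -max_offset:max_offset) {
      # b index i aligns a index i + o
      lo <- max(1L, 1L + o)
      hi <- min(ka, kb + o)
      if (lo > hi) next
      ia <- lo:hi
      ib <- ia - o
      mism <- sum(ach[ia] != bch[ib])
      overhang <- (ka - length(ia)) + (kb - length(ib))
      d <- (mism + gap_penalty * overhang) / max(ka, kb)
      if (d < best$dist) best <- list(dist = min(d, 1), orient = orient, offset = o)
    }
  }
  best
}

#' Alignment distance between two k-mers
#'
#' Minimum over relative orientations (the second k-mer and its reverse
#' complement) and offsets `-max_offset..max_offset` of the mismatch count in
#' the overlap plus a per-base overhang penalty, normalised by k into
#' `[0, 1]`. Identical k-mers, and a k-mer against its own reverse
#' complement, have distance 0.
#'
#' @param a,b DNA k-mers.
#' @param max_offset maximum shift considered (default 2).
#' @param gap_penalty penalty per overhanging base (default 0.25).
#' @return distance in `[0, 1]`.
#' @export
kmer_alignment_distance <- function(a, b, max_offset = 2L, gap_penalty = 0.25) {
  best_kmer_alignment(a, b, max_offset, gap_penalty)$dist
}

#' Pairwise alignment distance matrix for a set of k-mers
#' @param kmers character vector.
#' @inheritParams kmer_alignment_distance
#' @return symmetric numeric matrix.
#' @export
kmer_distance_matrix <- function(kmers, max_offset = 2L, gap_penalty = 0.25) {
  n <- length(kmers)
  D <- matrix(0, n, n, dimnames = list(kmers, kmers))
  if (n < 2) return(D)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    D[i, j] <- D[j, i] <- kmer_alignment_distance(kmers[i], kmers[j],
                                                  max_offset, gap_penalty)
  }
  D
}

#' Cluster k-mers by alignment distance
#'
#' Average-linkage hierarchical clustering of the alignment distance matrix,
#' cut at `threshold`. Deterministic given input order. The default threshold
#' groups k-mers that differ by roughly one substitution or a one-base shift
#' while keeping unrelated k-mers apart.
#'
#' @param distances symmetric distance matrix from [kmer_distance_matrix()].
#' @param threshold linkage-height cut (default 0.22).
#' @return list with `clusters` (list of k-mer character vectors, ordered by
#'   decreasing size), `membership` (named integer vector) and the `hclust`
#'   object (`tree`) with its linkage heights.
#' @export
cluster_kmers <- function(distances, threshold = 0.22) {
  kmers <- rownames(distances)
  if (length(kmers) == 1L) {
    return(list(clusters = list(kmers),
                membership = setNames(1L, kmers), tree = NULL))
  }
  hc <- hclust(as.dist(distances), method = "average")
  memb <- cutree(hc, h = threshold)
  cl <- split(names(memb), memb)
  cl <- cl[order(-vapply(cl, length, integer(1)),
                 vapply(cl, function(x) x[1], character(1)))]
  names(cl) <- NULL
  list(clusters = cl, membership = memb, tree = hc)
}

#' Build an IUPAC consensus motif from a k-mer cluster
#'
#' Members are oriented and offset against the cluster medoid (the member
#' minimising total alignment distance) using their best pairwise alignments.
#' Each alignment column emits the IUPAC code covering every base observed in
#' it; columns supported by fewer than `min_support` member bases are trimmed
#' from both ends.
#'
#' @param members character vector of k-mers (one cluster).
#' @param min_support minimum member bases per kept consensus column
#'   (default 2; single-member clusters return the k-mer itself).
#' @param max_offset,gap_penalty alignment parameters (see
#'   [kmer_alignment_distance()]).
#' @return object of class `consensus_motif`: list with `consensus` (IUPAC
#'   text), `members`, `support` (per kept column), `counts` (base x column
#'   support matrix) and `aligned` (oriented, offset member strings).
#' @export
build_consensus <- function(members, min_support = 2L, max_offset = 2L,
                            gap_penalty = 0.25) {
  stopifnot(length(members) >= 1)
  if (length(members) == 1L) {
    out <- list(consensus = members, members = members,
                support = rep(1L, nchar(members)), counts = NULL,
                aligned = members)
    class(out) <- "consensus_motif"
    return(out)
  }
  D <- kmer_distance_matrix(members, max_offset, gap_penalty)
  medoid <- members[which.min(rowSums(D))]
  k <- nchar(medoid)
  ali <- lapply(members, function(m) {
    if (m == medoid) list(dist = 0, orient = "fwd", offset = 0L)
    else best_kmer_alignment(medoid, m, max_offset, gap_penalty)
  })
  offs <- vapply(ali, function(a) a$offset, integer(1))
  lens <- nchar(members)
  # member base i sits at medoid-frame column i + offset
  col_lo <- min(1L + offs)
  col_hi <- max(lens + offs)
  ncol_all <- col_hi - col_lo + 1L
  counts <- matrix(0L, nrow = 4, ncol = ncol_all,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  aligned <- character(length(members))
  for (mi in seq_along(members)) {
    s <- if (ali[[mi]]$orient == "fwd") members[mi] else revcomp(members[mi])
    aligned[mi] <- s
    bch <- chars(s)
    for (i in seq_along(bch)) {
      col <- i + offs[mi] - col_lo + 1L
      counts[bch[i], col] <- counts[bch[i], col] + 1L
    }
  }
  support <- colSums(counts)
  keep <- which(support >= min_support)
  if (!length(keep)) {
    # no consistently aligned columns: fall back to the medoid, flagged
    out <- list(consensus = medoid, members = members,
                support = support, counts = counts, aligned = aligned,
                fallback = TRUE)
    class(out) <- "consensus_motif"
    return(out)
  }
  keep <- min(keep):max(keep)  # trim from the ends only
  code <- vapply(keep, function(col) {
    iupac_code(rownames(counts)[counts[, col] > 0])
  }, character(1))
  out <- list(consensus = paste(code, collapse = ""), members = members,
              support = support[keep], counts = counts[, keep, drop = FALSE],
              aligned = aligned)
  class(out) <- "consensus_motif"
  out
}

#' @export
print.consensus_motif <- function(x, ...) {
  cat("consensus:", x$consensus, " members:",
      paste(x$members, collapse = ", "), "\n")
  invisible(x)
}

#' Collapse candidate hexamers into consensus motifs
#'
#' Clusters the k-mers by alignment distance and builds one IUPAC consensus
#' per cluster.
#'
#' @param kmers character vector of candidate k-mers.
#' @param threshold clustering cut height (default 0.22).
#' @param min_support minimum member bases per consensus column (default 2).
#' @param max_offset,gap_penalty alignment parameters.
#' @return list of `consensus_motif` objects, largest clusters first.
#' @export
consensus_motifs <- function(kmers, threshold = 0.22, min_support = 2L,
                             max_offset = 2L, gap_penalty = 0.25) {
  D <- kmer_distance_matrix(kmers, max_offset, gap_penalty)
  cl <- cluster_kmers(D, threshold = threshold)
  lapply(cl$clusters, build_consensus, min_support = min_support,
         max_offset = max_offset, gap_penalty = gap_penalty)
}

#' Write consensus motifs as a minimal MEME-like text block
#'
#' @param motifs list of `consensus_motif` objects.
#' @param path output file.
#' @export
write_consensus_motifs <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME-like consensus motifs", "ALPHABET= ACGT", ""), con)
  for (m in motifs) {
    writeLines(sprintf("MOTIF %s", m$consensus), con)
    writeLines(sprintf("members: %s", paste(m$members, collapse = " ")), con)
    if (!is.null(m$counts)) {
      writeLines("letter-count matrix (rows A C G T):", con)
      for (b in rownames(m$counts))
        writeLines(paste(c(b, m$counts[b, ]), collapse = " "), con)
    }
    writeLines("", con)
  }
  invisible(path)
}
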