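#' Canonical form of a k-mer
#'
#' Double-stranded motifs are counted once by collapsing each k-mer with its
#' reverse complement and keeping the lexicographically smaller of the two.
#' K-mers containing `N` (or any non-ACGT character) are uncountable and
#' return `NA`.
#'
#' @param seq character vector of k-mers.
#' @return character vector of canonical k-mers (`NA` where uncountable).
#' @export
canonical_kmer <- function(seq) {
  ok <- !is.na(seq) & grepl("^[ACGT]+$", seq)
  out <- rep(NA_character_, length(seq))
  if (any(ok)) {
    rc <- revcomp(seq[ok])
    out[ok] <- ifelse(seq[ok] <= rc, seq[ok], rc)
  }
  out
}

#' Number of canonical k-mer classes
#'
#' For even k this is `(4^k + 4^(k/2)) / 2` (palindromes are their own
#' reverse complement); for odd k no palindromes exist and it is `4^k / 2`.
#'
#' @param k k-mer size.
#' @return integer count (2080 for k = 6).
#' @export
n_canonical_kmers <- function(k) {
  if (k %% 2 == 0) as.integer((4^k + 4^(k / 2)) / 2) else as.integer(4^k / 2)
}

# full lookup table word -> canonical word for small k
canonical_map <- function(k) {
  words <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
  setNames(canonical_kmer(words), words)
}

# Internal single-pass scanner: one row per countable k-mer window.
# Returns data.table(kmer, set, relpos, conserved) where `conserved` is FALSE
# for windows covering a masked (SNP) position. `trim` bp at each intron end
# are excluded from window starts.
scan_kmer_windows <- function(introns, k = 6L, trim = 3L, snps = NULL) {
  stopifnot(all(!is.na(introns$sequence)))
  cmap <- if (k <= 8L) canonical_map(k) else NULL
  off_by_intron <- if (!is.null(snps) && !is.null(snps$map) && nrow(snps$map)) {
    split(snps$map$intron_offset, snps$map$intron_id)
  } else list()
  res <- vector("list", nrow(introns))
  for (i in seq_len(nrow(introns))) {
    s <- introns$sequence[i]
    L <- nchar(s)
    nw <- L - 2L * trim - k + 1L
    if (nw < 1L) next
    starts <- (trim + 1L):(trim + nw)            # 1-based within intron
    w <- substring(s, starts, starts + k - 1L)
    canon <- if (!is.null(cmap)) unname(cmap[w]) else canonical_kmer(w)
    keep <- !is.na(canon)
    if (!any(keep)) next
    snp_off <- off_by_intron[[introns$intron_id[i]]]
    if (length(snp_off)) {
      flag <- integer(L)
      flag[snp_off + 1L] <- 1L
      cs <- c(0L, cumsum(flag))
      has_snp <- (cs[starts + k] - cs[starts]) > 0L
    } else has_snp <- rep(FALSE, nw)
    res[[i]] <- data.table::data.table(
      kmer = canon[keep],
      set = if (isTRUE(introns$is_first[i])) "first" else "other",
      relpos = starts[keep] / L,
      conserved = !has_snp[keep]
    )
  }
  out <- data.table::rbindlist(res)
  if (!nrow(out))
    out <- data.table::data.table(kmer = character(), set = character(),
                                  relpos = numeric(), conserved = logical())
  data.table::setattr(out, "k", k)
  out
}

#' Count canonical k-mers in first and other introns
#'
#' Slides a step-1 window over each intron sequence with `trim` bp excluded at
#' both ends (splice-site avoidance). Windows containing `N` are skipped;
#' when a `snp_table` intersected with the introns is supplied, windows
#' covering a SNP position additionally feed the masked counts (a masked
#' count is the number of windows free of SNPs, i.e. surviving masking).
#'
#' @param introns intron data frame with `sequence` and `is_first` filled.
#' @param k k-mer size (default 6).
#' @param trim bp excluded at each intron end (default 3).
#' @param snps optional `snp_table` from [snps_in_intervals()].
#' @return a `kmer_count_table` data frame: kmer, count_first, count_other,
#'   masked_first, masked_other, with totals in attributes `total_first` and
#'   `total_other`.
#' @export
count_kmers <- function(introns, k = 6L, trim = 3L, snps = NULL) {
  occ <- scan_kmer_windows(introns, k = k, trim = trim, snps = snps)
  count_kmers_from_windows(occ)
}

count_kmers_from_windows <- function(occ) {
  kmer <- set <- conserved <- NULL  # data.table NSE
  if (!nrow(occ)) {
    out <- data.frame(kmer = character(), count_first = integer(),
                      count_other = integer(), masked_first = integer(),
                      masked_other = integer(), stringsAsFactors = FALSE)
    attr(out, "total_first") <- 0L
    attr(out, "total_other") <- 0L
    class(out) <- c("kmer_count_table", "data.frame")
    return(out)
  }
  agg <- occ[, list(count = .N, masked = sum(conserved)), by = list(kmer, set)]
  wide <- data.table::dcast(agg, kmer ~ set, value.var = c("count", "masked"),
                            fill = 0L)
  for (col in c("count_first", "count_other", "masked_first", "masked_other"))
    if (!col %in% names(wide)) wide[[col]] <- 0L
  out <- as.data.frame(wide[, c("kmer", "count_first", "count_other",
                                "masked_first", "masked_other"), with = FALSE])
  out <- out[order(out$kmer), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "total_first") <- sum(out$count_first)
  attr(out, "total_other") <- sum(out$count_other)
  attr(out, "k") <- attr(occ, "k")
  class(out) <- c("kmer_count_table", "data.frame")
  out
}

#' Relative first-versus-other frequency of each k-mer
#'
#' `F = (C_f / sum C_f) / (C_o / sum C_o)`. K-mers absent from the other-intron
#' set get `F = Inf` (flagged by the caller).
#'
#' @param table a `kmer_count_table`.
#' @return named numeric vector of F values.
#' @export
relative_frequency <- function(table) {
  tf <- sum(table$count_first)
  to <- sum(table$count_other)
  if (tf == 0 || to == 0) stop("zero total k-mer count in one intron set")
  f <- (table$count_first / tf) / (table$count_other / to)
  setNames(f, table$kmer)
}

#' Per-k-mer conservation rate
#'
#' Ratio of the k-mer count with SNP positions masked to the unmasked count.
#' Values near 1 indicate high conservation. K-mers with zero count in the
#' requested set are `NA`.
#'
#' @param table a `kmer_count_table`.
#' @param set `"first"` or `"other"`.
#' @return named numeric vector of conservation rates.
#' @export
conservation_rate <- function(table, set = c("first", "other")) {
  set <- match.arg(set)
  cnt <- table[[paste0("count_", set)]]
  msk <- table[[paste0("masked_", set)]]
  setNames(ifelse(cnt > 0, msk / cnt, NA_real_), table$kmer)
}

#' Positional entropy of k-mer occurrences
#'
#' Relative start positions (first base of the occurrence divided by intron
#' length, hence in (0,1)) are binned into `bins` equal bins and the Shannon
#' entropy of the bin frequencies is returned (natural log, with 0 log 0 = 0).
#' Low entropy indicates positional preference; the maximum is `log(bins)`.
#'
#' @param positions numeric vector of relative positions in (0, 1).
#' @param bins number of bins (default 10).
#' @return list with `entropy` and integer `counts` (length `bins`).
#' @export
positional_entropy <- function(positions, bins = 10L) {
  if (!length(positions)) return(list(entropy = NA_real_, counts = integer(bins)))
  stopifnot(all(positions > 0 & positions < 1))
  b <- pmin(bins, floor(positions * bins) + 1L)
  counts <- tabulate(b, nbins = bins)
  p <- counts / sum(counts)
  nz <- p > 0
  list(entropy = -sum(p[nz] * log(p[nz])), counts = counts)
}

entropy_of_count_matrix <- function(m) {
  # m: bins x nsim integer matrix
  p <- m / rep(colSums(m), each = nrow(m))
  plogp <- p * log(p)
  plogp[!is.finite(plogp)] <- 0
  -colSums(plogp)
}

#' Empirical p-value for positional entropy under a uniform null
#'
#' Simulates `n_sim` multinomial draws of `n_occurrences` occurrences over
#' `bins` equally likely bins and reports the add-one empirical probability of
#' observing an entropy as low as `s_obs`:
#' `p = (1 + #\{S_sim <= S_obs\}) / (1 + n_sim)`. Deterministic under a fixed
#' seed.
#'
#' @param s_obs observed entropy.
#' @param n_occurrences number of occurrences behind `s_obs`.
#' @param bins number of bins (default 10).
#' @param n_sim number of simulated uniform distributions (default 10000).
#' @param seed optional integer seed.
#' @return empirical p-value.
#' @export
entropy_empirical_pvalue <- function(s_obs, n_occurrences, bins = 10L,
                                     n_sim = 10000L, seed = NULL) {
  stopifnot(n_occurrences >= 1)
  if (!is.null(seed)) set.seed(seed)
  sims <- rmultinom(n_sim, n_occurrences, rep(1 / bins, bins))
  s_sim <- entropy_of_count_matrix(sims)
  (1 + sum(s_sim <= s_obs + 1e-9)) / (1 + n_sim)
}

#' Exact-conditional test for positional contrast between intron sets
#'
#' Tests homogeneity of a 2 x B contingency table (binned positional counts
#' of one k-mer in first vs other introns). The default is a Monte-Carlo
#' exact conditional test: tables are drawn from the multivariate
#' hypergeometric null given the observed margins (vectorised sequential
#' `rhyper` sampling) and the add-one fraction of tables at most as probable
#' as the observed one is reported. `method = "exact"` delegates to
#' [stats::fisher.test()] (feasible for small tables only).
#'
#' @param binned_first integer vector of bin counts in first introns.
#' @param binned_other integer vector of bin counts in other introns.
#' @param method `"montecarlo"` (default) or `"exact"`.
#' @param n_sim Monte-Carlo sample size (default 1e5).
#' @param seed optional integer seed.
#' @return p-value (NA when both vectors are all zero).
#' @export
positional_contrast_test <- function(binned_first, binned_other,
                                     method = c("montecarlo", "exact"),
                                     n_sim = 1e5, seed = NULL) {
  method <- match.arg(method)
  stopifnot(length(binned_first) == length(binned_other))
  n1 <- sum(binned_first)
  n2 <- sum(binned_other)
  if (n1 + n2 == 0) return(NA_real_)
  if (method == "exact") {
    return(fisher.test(rbind(binned_first, binned_other),
                       workspace = 2e7)$p.value)
  }
  contrast_mc_p(binned_first, binned_other, n_sim = n_sim, seed = seed)
}

# Monte-Carlo exact conditional test for a 2 x B table: tables are drawn from
# the multivariate hypergeometric null given the margins (vectorised
# sequential rhyper over sims, log-probabilities accumulated bin by bin).
contrast_mc_p <- function(binned_first, binned_other, n_sim = 1e5,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cs <- binned_first + binned_other
  nz <- cs > 0                       # empty-margin bins carry no probability
  bf <- binned_first[nz]
  cs <- cs[nz]
  nb <- length(cs)
  if (nb < 2L) return(1)
  n1 <- sum(bf)
  n <- sum(cs)
  lf <- lgamma(seq_len(max(cs) + 1L))   # lf[x + 1] = lgamma(x + 1), lf[1] = 0
  lp_obs <- -sum(lf[bf + 1L] + lf[cs - bf + 1L])
  lp <- numeric(n_sim)
  rem_k <- rep.int(n1, n_sim)
  rem_tot <- n
  for (b in seq_len(nb - 1L)) {
    x <- rhyper(n_sim, m = cs[b], n = rem_tot - cs[b], k = rem_k)
    lp <- lp - lf[x + 1L] - lf[cs[b] - x + 1L]
    rem_k <- rem_k - x
    rem_tot <- rem_tot - cs[b]
  }
  lp <- lp - lf[rem_k + 1L] - lf[cs[nb] - rem_k + 1L]
  (1 + sum(lp <= lp_obs + 1e-7)) / (1 + n_sim)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Standard step-up adjustment with monotonicity enforcement; order-preserving
#' and tolerant of `NA` entries.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values.
#' @export
bh_fdr <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Apply the four-criterion candidate filter
#'
#' A k-mer is a candidate iff it is (1) more conserved in first than in other
#' introns, (2) relatively more frequent in first introns (F > 1), (3)
#' non-uniformly positioned within first introns (entropy FDR < alpha), and
#' (4) differently positioned in first vs other introns (contrast FDR <
#' alpha). Ties (equal conservation, F = 1) fail the strict inequalities.
#' Rows with a missing statistic are excluded with a warning.
#'
#' @param rows k-mer statistics data frame from [kmer_scan()].
#' @param alpha FDR threshold for criteria 3 and 4 (default 0.05).
#' @return the data frame with logical columns c1..c4 and `candidate` set.
#' @export
select_candidates <- function(rows, alpha = 0.05) {
  need <- c("cons_first", "cons_other", "F", "q_entropy", "q_contrast")
  miss <- !stats::complete.cases(rows[, need])
  if (any(miss))
    warning(sum(miss), " k-mer(s) with missing statistics excluded")
  rows$c1 <- rows$cons_first > rows$cons_other
  rows$c2 <- is.finite(rows$F) & rows$F > 1
  rows$c3 <- rows$q_entropy < alpha
  rows$c4 <- rows$q_contrast < alpha
  rows$candidate <- rows$c1 & rows$c2 & rows$c3 & rows$c4
  rows$candidate[miss] <- FALSE
  rows[miss, c("c1", "c2", "c3", "c4")] <- NA
  rows
}

#' Genome-wide candidate hexamer scan
#'
#' Runs the full k-mer statistics stage: canonical counting with SNP masking,
#' relative frequency, conservation rates, positional entropy with its
#' simulated uniform null, the first-vs-other positional contrast test, BH-FDR
#' over both p-value families, and the four-criterion candidate filter.
#'
#' The entropy null defaults to `n_sim_entropy = 1e5` simulations (not the
#' 1e4 used for a single k-mer test): the add-one empirical p-value has floor
#' `1/(n_sim+1)`, and BH control across ~2080 k-mers requires that floor to
#' sit below `alpha / n_kmers`.
#'
#' @param introns intron data frame with `sequence` and `is_first` filled
#'   (both first and other introns).
#' @param snps optional `snp_table` intersected with the introns (enables the
#'   conservation criterion; without it conservation rates are all 1).
#' @param k k-mer size (default 6).
#' @param trim bp excluded at each intron end (default 3).
#' @param bins positional bins (default 10).
#' @param n_sim_entropy simulations for the entropy null (default 1e5).
#' @param n_sim_contrast Monte-Carlo sample size for the contrast test
#'   (default 1e5).
#' @param alpha FDR threshold (default 0.05).
#' @param seed integer seed controlling both simulation families.
#' @return data frame with one row per observed canonical k-mer: counts,
#'   F, conservation rates, entropy, raw and FDR-adjusted p-values, c1..c4 and
#'   `candidate`.
#' @export
kmer_scan <- function(introns, snps = NULL, k = 6L, trim = 3L, bins = 10L,
                      n_sim_entropy = 1e5, n_sim_contrast = 1e5,
                      alpha = 0.05, seed = 1L) {
  kmer <- set <- relpos <- NULL
  occ <- scan_kmer_windows(introns, k = k, trim = trim, snps = snps)
  tab <- count_kmers_from_windows(occ)
  F_vec <- relative_frequency(tab)
  cons_f <- conservation_rate(tab, "first")
  cons_o <- conservation_rate(tab, "other")

  # binned positional profiles per k-mer and set
  occ_first <- occ[set == "first"]
  occ_other <- occ[set == "other"]
  bin_counts <- function(d) {
    b <- pmin(bins, floor(d$relpos * bins) + 1L)
    m <- table(factor(d$kmer, levels = tab$kmer), factor(b, levels = 1:bins))
    matrix(m, nrow = nrow(tab), dimnames = list(tab$kmer, NULL))
  }
  bf <- bin_counts(occ_first)
  bo <- bin_counts(occ_other)

  # Both p-value families use a two-stage Monte-Carlo scheme: a cheap first
  # pass over every k-mer, then full-resolution refinement only where the
  # coarse p could matter after BH (p1 <= refine_cut); large p-values keep
  # their (valid, add-one) coarse estimate. Entropy nulls are cached per
  # occurrence count, with a count-derived seed so results are independent of
  # k-mer order.
  refine_cut <- 0.1
  n_stage1 <- 2000L
  ent <- rep(NA_real_, nrow(tab))
  p_ent <- rep(NA_real_, nrow(tab))
  cache1 <- new.env(parent = emptyenv())
  cache2 <- new.env(parent = emptyenv())
  ent_null <- function(n_occ, n_sim, cache, seed_off) {
    key <- as.character(n_occ)
    if (is.null(cache[[key]])) {
      set.seed(derive_seed(seed, n_occ + seed_off))
      sims <- rmultinom(n_sim, n_occ, rep(1 / bins, bins))
      cache[[key]] <- sort(entropy_of_count_matrix(sims))
    }
    cache[[key]]
  }
  for (i in seq_len(nrow(tab))) {
    n_occ <- sum(bf[i, ])
    if (n_occ == 0) next
    p <- bf[i, ] / n_occ
    nz <- p > 0
    ent[i] <- -sum(p[nz] * log(p[nz]))
    s1 <- ent_null(n_occ, n_stage1, cache1, 0L)
    p1 <- (1 + findInterval(ent[i] + 1e-9, s1)) / (1 + n_stage1)
    if (p1 <= refine_cut && n_sim_entropy > n_stage1) {
      s2 <- ent_null(n_occ, n_sim_entropy, cache2, 500000L)
      p1 <- (1 + findInterval(ent[i] + 1e-9, s2)) / (1 + n_sim_entropy)
    }
    p_ent[i] <- p1
  }

  p_con <- rep(NA_real_, nrow(tab))
  for (i in seq_len(nrow(tab))) {
    if (sum(bf[i, ]) + sum(bo[i, ]) == 0) next
    p1 <- contrast_mc_p(bf[i, ], bo[i, ], n_sim = n_stage1,
                        seed = derive_seed(seed, i))
    if (p1 <= refine_cut && n_sim_contrast > n_stage1)
      p1 <- contrast_mc_p(bf[i, ], bo[i, ], n_sim = n_sim_contrast,
                          seed = derive_seed(seed, i + 700000L))
    p_con[i] <- p1
  }

  rows <- data.frame(
    kmer = tab$kmer,
    count_first = tab$count_first, count_other = tab$count_other,
    masked_first = tab$masked_first, masked_other = tab$masked_other,
    F = unname(F_vec[tab$kmer]),
    cons_first = unname(cons_f[tab$kmer]),
    cons_other = unname(cons_o[tab$kmer]),
    entropy = ent,
    p_entropy = p_ent,
    q_entropy = bh_fdr(p_ent),
    p_contrast = p_con,
    q_contrast = bh_fdr(p_con),
    stringsAsFactors = FALSE
  )
  select_candidates(rows, alpha = alpha)
}
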