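# data.table is used via :: calls; declare awareness for correct dispatch
.datatable.aware <- TRUE

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over plain character vectors. `N` maps to `N`.
#'
#' @param x character vector of DNA strings (A/C/G/T/N, upper case).
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  out <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(out, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# IUPAC code -> base set, used for consensus building and motif matching checks
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# base set (sorted, subset of ACGT) -> IUPAC code
iupac_code <- function(bases) {
  bases <- sort(unique(bases))
  key <- paste(bases, collapse = "")
  codes <- c(A = "A", C = "C", G = "G", T = "T",
             AG = "R", CT = "Y", CG = "S", AT = "W", GT = "K", AC = "M",
             CGT = "B", AGT = "D", ACT = "H", ACG = "V", ACGT = "N")
  unname(codes[key])
}

iupac_revcomp <- function(x) {
  out <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", x)
  vapply(strsplit(out, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# split a string into single characters
chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic sub-seed derivation: keeps derived seeds < 2^31
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 1013L * as.integer(offset)) %% 2147483647L
}
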