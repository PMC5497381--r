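#' @keywords internal
"_PACKAGE"

#' @importFrom stats pbinom pchisq sd runif rbinom setNames optimize
#' @importFrom utils head combn
NULL

# IUPAC nucleotide expansions used for degenerate primer matching.
IUPAC_EXPAND <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Reverse complement of nucleotide strings
#'
#' Vectorised reverse complement supporting IUPAC degenerate codes.
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Split sequences of equal length into a character matrix (rows = sequences).
seq_matrix <- function(x) {
  n <- unique(nchar(x))
  if (length(n) != 1L)
    stop("sequences must have equal length")
  matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
         nrow = length(x), ncol = n, byrow = TRUE)
}

#' Translate nucleotide sequences in frame 1
#'
#' Translates complete codons with the standard genetic code; a trailing
#' incomplete codon (the exon-3 amplicons carry one dangling base) is ignored.
#' Stop codons are rendered as `*`.
#'
#' @param x character vector of nucleotide sequences (ACGT).
#' @return character vector of amino-acid sequences.
#' @export
translate_nt <- function(x) {
  code <- Biostrings::GENETIC_CODE
  vapply(x, function(s) {
    nc <- 3L * (nchar(s) %/% 3L)
    if (nc == 0L) return("")
    cods <- substring(s, seq(1L, nc, 3L), seq(3L, nc, 3L))
    aa <- code[cods]
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Count mismatches between equal-length reads and an IUPAC primer,
# degenerate positions matching any of their expansions.
# reads: character vector (all nchar == nchar(primer)).
iupac_mismatches <- function(reads, primer) {
  p <- strsplit(primer, "")[[1]]
  mm <- integer(length(reads))
  for (i in seq_along(p)) {
    allowed <- IUPAC_EXPAND[[p[i]]]
    if (is.null(allowed)) stop("unknown IUPAC code in primer: ", p[i])
    b <- substr(reads, i, i)
    mm <- mm + !(b %in% allowed)
  }
  mm
}

#' Derive a stage-specific seed from a global seed
#'
#' Deterministic fan-out of one global seed into per-stage seeds so pipeline
#' stages can be rerun independently yet reproducibly. The derivation is a
#' fixed integer hash of the stage name folded into the seed, kept below
#' 2^31 - 1.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return integer seed.
#' @export
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483647)
}

# Sorted order used throughout variant tables: count descending, sequence
# lexicographic ascending on ties (a total order on unique sequences).
order_variants <- function(sequence, count) {
  order(-count, sequence, method = "radix")
}

LENGTH_CLASSES <- c("no_del", "del3", "del6", "other")

`%||%` <- function(a, b) if (is.null(a)) b else a
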