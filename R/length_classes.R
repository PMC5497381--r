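# Partition of alleles into no-deletion / 3 bp / 6 bp / other classes by
# codon-aware comparison against a no-deletion reference, with deletion
# placement in exon-local 0-based codon coordinates.
#
# Scoring: match +1, mismatch -1, gap open -4, gap extend -1 per base, and a
# +2 bonus for a gap that both starts on a codon boundary and has length
# divisible by 3. Because the admissible geometries here are deletion-only
# (one 3-base gap, one 6-base gap, or two single-codon gaps), the optimal
# alignment under this scoring is found by exhaustive gap placement; ties are
# broken leftmost.

GAP_OPEN <- 4; GAP_EXTEND <- 1; CODON_BONUS <- 2

# Mismatch counts helper: query aligned to ref with a gap of `g` ref bases
# starting after ref position `start` (0-based): mm = pre[start] +
# (shifted suffix mismatches). Precomputes cumulative mismatch vectors for
# shifts 0, 3 and 6.
shift_mismatch_cums <- function(q, r) {
  qc <- strsplit(q, "")[[1]]; rc <- strsplit(r, "")[[1]]
  lq <- length(qc)
  cums <- list()
  for (s in c(0L, 3L, 6L)) {
    if (lq + s > length(rc)) { cums[[as.character(s)]] <- NULL; next }
    v <- qc != rc[seq_len(lq) + s]
    cums[[as.character(s)]] <- c(0, cumsum(v))
  }
  cums
}

#' Classify one allele against the no-deletion reference
#'
#' Codon-aware comparison to the configured 241 bp class representative:
#' equal length with no gaps is `no_del`; exactly one in-frame 3-base gap is
#' `del3` with its codon index; one in-frame 6-base gap or two single-codon
#' gaps is `del6` with both codon indices; anything else (insertions,
#' frame-breaking gaps such as the known 11 bp deletion pseudogenes) is
#' `other`.
#'
#' @param sequence allele nucleotide sequence (ACGT only).
#' @param reference the no-deletion reference sequence.
#' @return list: `class`, `deleted_codons` (0-based reference codon indices),
#'   `aa_sequence`.
#' @export
classify_allele <- function(sequence, reference) {
  if (grepl("[^ACGT]", sequence)) stop("sequence contains non-ACGT characters")
  lq <- nchar(sequence); lr <- nchar(reference)
  d <- lr - lq
  res <- list(class = "other", deleted_codons = integer(0),
              aa_sequence = translate_nt(sequence))
  if (d == 0L) {
    res$class <- "no_del"
    return(res)
  }
  if (!d %in% c(3L, 6L)) return(res)
  cums <- shift_mismatch_cums(sequence, reference)
  c0 <- cums[["0"]]
  score_single <- function(gstarts, glen, cpost) {
    mm <- c0[gstarts + 1L] + (cpost[lq + 1L] - cpost[gstarts + 1L])
    bonus <- ifelse(gstarts %% 3L == 0L, CODON_BONUS, 0)
    (lq - mm) - mm - (GAP_OPEN + GAP_EXTEND * glen) + bonus
  }
  if (d == 3L) {
    g <- 0:(lr - 3L)
    sc <- score_single(g, 3L, cums[["3"]])
    best <- g[which.max(sc)]           # which.max -> leftmost on ties
    if (best %% 3L == 0L) {
      res$class <- "del3"
      res$deleted_codons <- best %/% 3L
    }
    return(res)
  }
  # d == 6: single 6-base gap at any start, or two single-codon gaps.
  g <- 0:(lr - 6L)
  sc6 <- score_single(g, 6L, cums[["6"]])
  best6 <- max(sc6); best6_start <- g[which.max(sc6)]
  ncod <- lr %/% 3L
  c3 <- cums[["3"]]; c6 <- cums[["6"]]
  # pairs of non-adjacent codon deletions i < j (adjacent equals the single
  # 6-gap case already scored, with one gap opening)
  best_pair <- -Inf; best_ij <- NULL
  for (i in 0:(ncod - 2L)) {
    js <- (i + 2L):(ncod - 1L)
    if (i + 2L > ncod - 1L) next
    p1 <- 3L * i; p2 <- 3L * js
    mm <- c0[p1 + 1L] + (c3[p2 - 3L + 1L] - c3[p1 + 1L]) +
      (c6[lq + 1L] - c6[p2 - 3L + 1L])
    scp <- (lq - mm) - mm - 2 * (GAP_OPEN + GAP_EXTEND * 3L) + 2 * CODON_BONUS
    k <- which.max(scp)
    if (scp[k] > best_pair) { best_pair <- scp[k]; best_ij <- c(i, js[k]) }
  }
  if (best6 >= best_pair) {
    if (best6_start %% 3L == 0L) {
      res$class <- "del6"
      res$deleted_codons <- best6_start %/% 3L + c(0L, 1L)
    }
  } else {
    res$class <- "del6"
    res$deleted_codons <- best_ij
  }
  res
}

#' Classify a set of alleles
#'
#' Vectorised, memoised wrapper around [classify_allele()]; classification is
#' deterministic and invariant to input order.
#'
#' @param sequences character vector of allele sequences.
#' @param reference no-deletion reference.
#' @return data.frame: sequence, class, deleted_codons (comma string),
#'   aa_sequence.
#' @export
classify_alleles <- function(sequences, reference) {
  uniq <- unique(sequences)
  cls <- lapply(uniq, classify_allele, reference = reference)
  df <- data.frame(
    sequence = uniq,
    class = vapply(cls, `[[`, character(1), "class"),
    deleted_codons = vapply(cls, function(x)
      paste(x$deleted_codons, collapse = ","), character(1)),
    aa_sequence = vapply(cls, `[[`, character(1), "aa_sequence"),
    stringsAsFactors = FALSE)
  df[match(sequences, df$sequence), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Gap-align alleles of all length classes to the reference
#'
#' Uses the codon-aware classification to place each allele's deleted codons
#' as gap columns, producing an equal-length (reference-length) alignment
#' across classes. Alleles classified `other` are returned as NA.
#'
#' @param sequences character vector of allele sequences.
#' @param reference no-deletion reference.
#' @return character vector of gapped sequences (NA for unalignable alleles).
#' @export
align_to_reference <- function(sequences, reference) {
  cls <- classify_alleles(sequences, reference)
  vapply(seq_along(sequences), function(i) {
    if (cls$class[i] == "other") return(NA_character_)
    if (cls$class[i] == "no_del") return(sequences[i])
    del <- as.integer(strsplit(cls$deleted_codons[i], ",")[[1]])
    s <- sequences[i]
    for (cd in sort(del)) {  # reinsert gaps left to right at ref coordinates
      pos <- 3L * cd
      s <- paste0(substr(s, 1L, pos), "---",
                  substr(s, pos + 1L, nchar(s)))
    }
    s
  }, character(1))
}

#' Per-individual and population length-class census
#'
#' @param genotypes data.frame with columns `individual_id` and `class`
#'   (one row per allele carried).
#' @return list: `per_individual` (individual x class counts), `carrier_fraction`
#'   (population fraction of individuals carrying each class), `spectra`
#'   (per-class table of per-individual allele counts).
#' @export
class_census <- function(genotypes) {
  stopifnot(all(c("individual_id", "class") %in% names(genotypes)))
  tab <- table(genotypes$individual_id, genotypes$class)
  counts <- as.data.frame.matrix(tab)
  counts$individual_id <- rownames(counts)
  rownames(counts) <- NULL
  carrier <- colMeans(tab > 0)
  spectra <- lapply(colnames(tab), function(cl) table(tab[, cl]))
  names(spectra) <- colnames(tab)
  list(per_individual = counts, carrier_fraction = carrier, spectra = spectra)
}
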