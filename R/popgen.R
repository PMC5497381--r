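# Diversity and divergence statistics: pairwise p-distances at nucleotide and
# amino-acid level, nucleotide diversity over unique alleles, per-individual
# summaries, the minimum-locus bound and genotyping repeatability.

#' Pairwise p-distance
#'
#' Mean, SD and full matrix of pairwise p-distances (proportion of differing
#' positions) over a set of equal-length sequences. Columns where either
#' member of a pair carries a gap (`-`) or ambiguity are excluded pairwise.
#'
#' @param sequences character vector (>= 2 unique sequences).
#' @param level `"nt"` to compare as given, `"aa"` to translate first.
#' @return list: `mean`, `sd` (over unordered pairs), `matrix` (symmetric,
#'   zero diagonal).
#' @export
p_distance <- function(sequences, level = c("nt", "aa")) {
  level <- match.arg(level)
  if (level == "aa") sequences <- translate_nt(sequences)
  n <- length(sequences)
  if (length(unique(sequences)) < 2L)
    stop("p_distance needs at least 2 unique sequences")
  M <- seq_matrix(sequences)
  valid <- if (level == "nt") M %in% c("A", "C", "G", "T") else
    !(M %in% c("-", "X"))
  valid <- matrix(valid, nrow = n)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    ok <- valid[i, ] & valid[j, ]
    if (!any(ok)) stop("no comparable sites for pair ", i, ",", j)
    D[i, j] <- D[j, i] <- sum(M[i, ok] != M[j, ok]) / sum(ok)
  }
  vals <- D[upper.tri(D)]
  list(mean = mean(vals), sd = if (length(vals) > 1L) sd(vals) else 0,
       matrix = D)
}

#' Nucleotide diversity over unique alleles
#'
#' The unweighted mean pairwise nucleotide p-distance over the set of unique
#' alleles; an optional frequency-weighted variant uses every input sequence
#' (weighting alleles by their multiplicity).
#'
#' @param sequences character vector of allele sequences.
#' @param weighted if TRUE, duplicates are kept and contribute frequency
#'   weight; default FALSE (allele-set diversity).
#' @return numeric pi.
#' @export
nucleotide_diversity <- function(sequences, weighted = FALSE) {
  if (!weighted) sequences <- unique(sequences)
  p_distance(sequences, "nt")$mean
}

#' Minimum number of loci implied by a maximum per-individual allele count
#'
#' Assuming heterozygosity, `k` distinct alleles in one individual require at
#' least `ceiling(k / 2)` loci.
#'
#' @param max_alleles_per_individual positive count.
#' @return integer lower bound on locus number.
#' @export
min_locus_bound <- function(max_alleles_per_individual) {
  if (max_alleles_per_individual < 1) stop("allele count must be positive")
  as.integer(ceiling(max_alleles_per_individual / 2))
}

#' Ratio of amino-acid to nucleotide allele counts
#'
#' @param n_aa,n_nt unique amino-acid and nucleotide allele counts.
#' @param digits display rounding (default 2, matching reported precision).
#' @return numeric ratio.
#' @export
aa_nt_ratio <- function(n_aa, n_nt, digits = 2) {
  round(n_aa / n_nt, digits)
}

#' Per-class diversity and divergence report
#'
#' For each length class: number of unique nucleotide alleles, nucleotide
#' diversity pi, number of unique amino-acid sequences, mean and SD of
#' amino-acid p-distance, and the aa/nt allele-count ratio.
#'
#' @param sequences character vector of allele sequences.
#' @param class character vector of length-class labels, parallel to
#'   `sequences`.
#' @return data.frame, one row per class plus an `all` row for counts and
#'   ratio.
#' @export
diversity_report <- function(sequences, class) {
  stopifnot(length(sequences) == length(class))
  one <- function(seqs) {
    seqs <- unique(seqs)
    aa <- unique(translate_nt(seqs))
    pi <- if (length(seqs) >= 2L) nucleotide_diversity(seqs) else NA_real_
    aad <- if (length(aa) >= 2L) p_distance(seqs, "aa") else
      list(mean = NA_real_, sd = NA_real_)
    data.frame(n_nt_alleles = length(seqs), pi = pi,
               n_aa_alleles = length(aa), mean_aa_pdist = aad$mean,
               sd_aa_pdist = aad$sd,
               aa_per_nt_ratio = aa_nt_ratio(length(aa), length(seqs)))
  }
  classes <- sort(unique(class))
  out <- do.call(rbind, lapply(classes, function(cl)
    cbind(data.frame(class = cl), one(sequences[class == cl]))))
  all_seqs <- unique(sequences)
  all_aa <- unique(translate_nt(all_seqs))
  out <- rbind(out, data.frame(
    class = "all", n_nt_alleles = length(all_seqs), pi = NA_real_,
    n_aa_alleles = length(all_aa), mean_aa_pdist = NA_real_,
    sd_aa_pdist = NA_real_,
    aa_per_nt_ratio = aa_nt_ratio(length(all_aa), length(all_seqs))))
  rownames(out) <- NULL
  out
}

#' Per-individual and aggregate genotype summaries
#'
#' @param genotypes data.frame with `individual_id` and `class`, one row per
#'   allele carried.
#' @return list: `per_individual` (totals and per-class counts),
#'   `aggregate` (mean, sample SD, range of totals and per-class counts over
#'   carriers).
#' @export
summarize_population <- function(genotypes) {
  if (nrow(genotypes) == 0L) stop("empty population")
  cen <- class_census(genotypes)
  per <- cen$per_individual
  cls <- setdiff(names(per), "individual_id")
  per$total <- rowSums(per[, cls, drop = FALSE])
  agg <- function(x) {
    x <- x[x > 0]
    data.frame(mean = mean(x), sd = if (length(x) > 1L) sd(x) else 0,
               min = min(x), max = max(x))
  }
  aggregate <- do.call(rbind, c(
    list(total = agg(per$total)),
    setNames(lapply(cls, function(cl) agg(per[[cl]])), cls)))
  list(per_individual = per, aggregate = aggregate)
}

#' Genotyping repeatability between two allele sets of one individual
#'
#' @param setA,setB character vectors of allele sequences or ids.
#' @param mode `"jaccard"` (|A n B| / |A u B|) or `"recall_vs_A"`
#'   (|A n B| / |A|).
#' @return numeric fraction in [0, 1].
#' @export
repeatability <- function(setA, setB, mode = c("jaccard", "recall_vs_A")) {
  mode <- match.arg(mode)
  setA <- unique(setA); setB <- unique(setB)
  if (length(setA) + length(setB) == 0L)
    stop("repeatability undefined for two empty sets")
  inter <- length(intersect(setA, setB))
  if (mode == "jaccard") inter / length(union(setA, setB))
  else inter / length(setA)
}
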