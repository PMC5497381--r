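# Shared fixture builders: everything is generated in code at test time.

BASES <- c("A", "C", "G", "T")

rand_seq <- function(L) paste(sample(BASES, L, replace = TRUE), collapse = "")

rand_seqs <- function(n, L) vapply(seq_len(n), function(i) rand_seq(L), "")

# independent brute-force oracle for mean pairwise p-distance
brute_pdist_mean <- function(seqs) {
  n <- length(seqs)
  tot <- 0; cnt <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- strsplit(seqs[i], "")[[1]]
    b <- strsplit(seqs[j], "")[[1]]
    tot <- tot + sum(a != b) / length(a)
    cnt <- cnt + 1
  }
  tot / cnt
}

# small simulation config for fast end-to-end tests
tiny_sim_config <- function(seed = 7, ...) {
  sim_config(seed = seed, n_individuals = 3, coverage = 600,
             class_pool_sizes = c(no_del = 20, del3 = 8, del6 = 10),
             error_rate = 0, chimera_rate = 0, stop_codon_fraction = 0, ...)
}

# variant table from explicit sequences/counts
vt <- function(sequence, count) {
  tab <- data.frame(sequence = sequence, count = as.integer(count),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$count, tab$sequence), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("mhc_variant_table", "data.frame")
  attr(tab, "total_reads_used") <- sum(tab$count)
  tab
}

# mutate single positions of a sequence
mutate_at <- function(seq, pos, base = NULL) {
  ch <- strsplit(seq, "")[[1]]
  for (p in pos) {
    ch[p] <- if (is.null(base)) setdiff(BASES, ch[p])[1] else base
  }
  paste(ch, collapse = "")
}

# truth-vs-called precision/recall over all individuals
genotyping_scores <- function(truth, calls) {
  g <- calls$calls[calls$calls$expression != "cdna_only", , drop = FALSE]
  tp <- fp <- fn <- 0
  for (ind in unique(truth$genotypes$individual_id)) {
    ids <- truth$genotypes$allele_id[truth$genotypes$individual_id == ind]
    tru <- truth$pool$sequence[match(ids, truth$pool$allele_id)]
    got <- unique(g$sequence[g$individual_id == ind])
    tp <- tp + length(intersect(tru, got))
    fp <- fp + length(setdiff(got, tru))
    fn <- fn + length(setdiff(tru, got))
  }
  c(precision = tp / (tp + fp), recall = tp / (tp + fn))
}

run_genotyping <- function(cfg) {
  truth <- assign_genotypes(generate_allele_pool(cfg))
  sheet <- make_tag_sheet(cfg)
  sim <- simulate_reads(truth, cfg, sheet)
  dm <- demultiplex(sim$reads, sheet, cfg$fwd_primer, cfg$rev_primer)
  calls <- call_genotypes(variant_tables(dm), sheet)
  list(truth = truth, sim = sim, calls = calls,
       scores = genotyping_scores(truth, calls))
}
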