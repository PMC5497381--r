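# Synthetic amplicon-read generator. Emulates the statistical structure the
# downstream analysis assumes: an exon-3 allele pool in three in-frame
# deletion length classes (241 / 238 / 235 bp), per-individual copy-number
# variation, dual-tagged replicate PCRs with negative controls, per-read
# substitution errors and two-parent PCR chimeras, all with full provenance.

#' Simulation configuration
#'
#' Builds and validates the configuration that drives the synthetic amplicon
#' generator. Defaults describe a desk-scale population in the same regime as
#' a wild passerine MHC class I study: three exon-3 length classes with
#' per-class diversity targets, positively selected codon sites with elevated
#' nonsynonymous rates, tens-of-alleles-scale copy-number variation, dual 6 bp
#' barcodes, two PCR replicates per individual and template, and negative
#' controls.
#'
#' @param seed integer; global seed, fanned out per stage via [derive_seed()].
#' @param n_individuals number of genotyped individuals.
#' @param reference_length_bp length of the no-deletion reference (241 bp:
#'   80 complete codons plus one dangling base of a split codon).
#' @param del3_codon 0-based reference codon index removed in the 3 bp class.
#' @param del6_codons pair of 0-based reference codon indices removed in the
#'   6 bp class (adjacent by default).
#' @param class_pool_sizes named counts of pool alleles per class.
#' @param class_target_pi named per-class target mean pairwise nucleotide
#'   p-distance of the pool.
#' @param pss_sites named list of 0-based reference codon indices per class
#'   with elevated nonsynonymous rate, or a single vector applied to all.
#' @param omega_background,omega_pss nonsynonymous:synonymous rate odds at
#'   background and selected sites.
#' @param class_stem_subs named per-class count of shared stem substitutions
#'   applied to the class founder before alleles are drawn; gives a deletion
#'   lineage its own divergent branch, as in the observed split networks.
#' @param copy_number_range named list of c(min, max) alleles per individual
#'   per class.
#' @param carrier_prob named per-class probability that an individual carries
#'   any allele of the class.
#' @param coverage reads per amplicon.
#' @param error_rate per-base substitution error probability (whole read,
#'   tags and primers included).
#' @param chimera_rate per-read probability of a two-parent chimera.
#' @param stop_codon_fraction fraction of pool alleles given an in-frame stop.
#' @param transcription_prob named per-class probability an allele is
#'   transcribed (appears in cDNA).
#' @param tag_length barcode length (6).
#' @param n_negative_controls template-free amplicons added to the tag sheet.
#' @param fwd_primer,rev_primer amplification primers, IUPAC degenerate codes
#'   allowed; the bundled defaults are synthetic oligos.
#' @param revcomp_fraction fraction of reads emitted on the reverse strand.
#' @param reference_seq optional explicit reference sequence; random when NULL.
#' @return object of class `mhc_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_individuals = 20L,
                       reference_length_bp = 241L,
                       del3_codon = 42L,
                       del6_codons = c(48L, 49L),
                       class_pool_sizes = c(no_del = 100L, del3 = 47L, del6 = 60L),
                       class_target_pi = c(no_del = 0.128, del3 = 0.016, del6 = 0.111),
                       pss_sites = list(
                         no_del = c(2L, 5L, 9L, 13L, 16L, 21L, 24L, 28L, 33L, 37L,
                                    45L, 52L, 56L, 60L, 63L, 68L, 72L, 76L),
                         del3 = integer(0),
                         del6 = c(9L, 16L, 24L, 37L, 56L, 68L, 30L, 66L)),
                       omega_background = 1,
                       omega_pss = 5,
                       class_stem_subs = c(no_del = 0L, del3 = 25L, del6 = 8L),
                       copy_number_range = list(no_del = c(5L, 10L),
                                                del3 = c(1L, 2L),
                                                del6 = c(1L, 4L)),
                       carrier_prob = c(no_del = 1, del3 = 0.99, del6 = 0.93),
                       coverage = 1000L,
                       error_rate = 0.005,
                       chimera_rate = 0.02,
                       stop_codon_fraction = 0.03,
                       transcription_prob = c(no_del = 0.60, del3 = 0.80, del6 = 0.73),
                       tag_length = 6L,
                       n_negative_controls = 6L,
                       fwd_primer = "GCTACGTGGYTCTGCACGAM",
                       rev_primer = "CAGTSGTTCAGGTCAWGCTC",
                       revcomp_fraction = 0.5,
                       min_pool_edit = 3L,
                       reference_seq = NULL) {
  cfg <- list(seed = as.integer(seed), n_individuals = as.integer(n_individuals),
              reference_length_bp = as.integer(reference_length_bp),
              del3_codon = as.integer(del3_codon),
              del6_codons = as.integer(del6_codons),
              class_pool_sizes = class_pool_sizes,
              class_target_pi = class_target_pi,
              pss_sites = pss_sites,
              omega_background = omega_background, omega_pss = omega_pss,
              class_stem_subs = class_stem_subs,
              copy_number_range = copy_number_range,
              carrier_prob = carrier_prob,
              coverage = as.integer(coverage), error_rate = error_rate,
              chimera_rate = chimera_rate,
              stop_codon_fraction = stop_codon_fraction,
              transcription_prob = transcription_prob,
              tag_length = as.integer(tag_length),
              n_negative_controls = as.integer(n_negative_controls),
              fwd_primer = fwd_primer, rev_primer = rev_primer,
              revcomp_fraction = revcomp_fraction,
              min_pool_edit = as.integer(min_pool_edit),
              reference_seq = reference_seq)
  class(cfg) <- "mhc_sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$reference_length_bp %% 3L != 1L || cfg$reference_length_bp < 31L)
    stop("reference_length_bp must leave one dangling base (length = 3k + 1)")
  ncod <- cfg$reference_length_bp %/% 3L
  if (cfg$del3_codon < 0L || cfg$del3_codon >= ncod)
    stop("del3_codon outside the reference sequence")
  if (length(cfg$del6_codons) != 2L || anyDuplicated(cfg$del6_codons) ||
      any(cfg$del6_codons < 0L) || any(cfg$del6_codons >= ncod))
    stop("del6_codons must be two distinct codon indices inside the reference")
  probs <- c(cfg$error_rate, cfg$chimera_rate, cfg$stop_codon_fraction,
             cfg$revcomp_fraction, cfg$carrier_prob, cfg$transcription_prob)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  if (any(unlist(cfg$copy_number_range) < 1))
    stop("copy_number_range entries must be positive")
  for (cl in names(cfg$copy_number_range)) {
    r <- cfg$copy_number_range[[cl]]
    if (length(r) != 2L || r[1] > r[2]) stop("bad copy_number_range for ", cl)
  }
  if (any(cfg$class_pool_sizes < 0)) stop("class_pool_sizes must be non-negative")
  if (is.list(cfg$pss_sites)) {
    if (any(unlist(cfg$pss_sites) >= ncod) || any(unlist(cfg$pss_sites) < 0))
      stop("pss_sites outside the reference codon range")
  }
  invisible(cfg)
}

# Per-class pss set as reference codon indices.
class_pss <- function(cfg, cl) {
  if (is.list(cfg$pss_sites)) cfg$pss_sites[[cl]] %||% integer(0)
  else cfg$pss_sites
}

# Reference codon indices deleted in a class.
class_deleted <- function(cfg, cl) {
  switch(cl, no_del = integer(0), del3 = cfg$del3_codon,
         del6 = sort(cfg$del6_codons), integer(0))
}

# Per-codon substitution probability solving the pairwise-difference
# expectation (2 m - 0.444 m^2) / 3 = pi for independently derived alleles.
calibrate_codon_rate <- function(target_pi) {
  if (target_pi <= 0) return(0)
  disc <- 4 - 4 * 0.444 * 3 * target_pi
  if (disc < 0) return(0.9)
  min(0.9, (2 - sqrt(disc)) / (2 * 0.444))
}

random_reference <- function(ncod) {
  tab <- codon_tables()
  codons <- sample(tab$sense, ncod, replace = TRUE)
  paste0(paste(codons, collapse = ""), sample(c("A", "C", "G", "T"), 1))
}

# Draw one allele from a class base sequence: per codon, mutate with a
# probability scaled by the mean neighbour weight (omega on nonsynonymous
# changes), then pick a weighted single-nucleotide neighbour.
mutate_allele <- function(base_codons, tail_base, m, omega_map) {
  tab <- codon_tables()
  out <- base_codons
  for (j in seq_along(out)) {
    nb <- tab$neighbours[[out[j]]]
    if (is.null(nb) || nrow(nb) == 0L) next
    w <- ifelse(nb$syn, 1, omega_map[j])
    mj <- min(0.95, m * sum(w) / nrow(nb))
    if (runif(1) < mj)
      out[j] <- nb$codon[sample.int(nrow(nb), 1L, prob = w)]
  }
  paste0(paste(out, collapse = ""), tail_base)
}

#' Generate the synthetic allele pool
#'
#' Draws, per length class, a set of unique exon-3 alleles derived from a
#' common reference by codon-level single-nucleotide substitutions whose
#' nonsynonymous:synonymous odds are governed by omega at each site. The
#' realized pool diversity targets `class_target_pi`; a configured fraction of
#' alleles receives an in-frame stop codon and each allele carries a
#' class-specific transcription flag.
#'
#' @param config `mhc_sim_config`.
#' @return object of class `mhc_truth` holding the reference, the pool table
#'   (allele_id, class, sequence, transcribed, has_stop, deleted_ref_codons)
#'   and the class-local positively-selected-site maps.
#' @export
generate_allele_pool <- function(config) {
  stopifnot(inherits(config, "mhc_sim_config"))
  set.seed(derive_seed(config$seed, "pool"))
  ncod <- config$reference_length_bp %/% 3L
  reference <- config$reference_seq %||% random_reference(ncod)
  if (nchar(reference) != config$reference_length_bp)
    stop("reference_seq length does not match reference_length_bp")
  ref_codons <- split_codons(reference)
  tail_base <- substr(reference, nchar(reference), nchar(reference))

  prefix <- c(no_del = "ND", del3 = "D3", del6 = "D6")
  pool <- list()
  pss_local <- list()
  for (cl in names(config$class_pool_sizes)) {
    npool <- config$class_pool_sizes[[cl]]
    if (npool <= 0) next
    deleted <- class_deleted(config, cl)
    keep <- setdiff(seq_len(ncod) - 1L, deleted)
    base_codons <- ref_codons[keep + 1L]
    nstem <- (config$class_stem_subs %||% c())[cl]
    if (!is.na(nstem) && nstem > 0) {
      tab <- codon_tables()
      for (k in seq_len(nstem)) {
        j <- sample.int(length(base_codons), 1L)
        nb <- tab$neighbours[[base_codons[j]]]
        if (is.null(nb) || nrow(nb) == 0L) next
        base_codons[j] <- nb$codon[sample.int(nrow(nb), 1L)]
      }
    }
    pss_ref <- setdiff(class_pss(config, cl), deleted)
    local_idx <- match(pss_ref, keep) - 1L          # 0-based class-local
    pss_local[[cl]] <- sort(local_idx[!is.na(local_idx)])
    omega_map <- rep(config$omega_background, length(keep))
    omega_map[pss_local[[cl]] + 1L] <- config$omega_pss
    m <- calibrate_codon_rate(config$class_target_pi[[cl]])

    # correct the per-codon rate for the omega-driven inflation applied in
    # mutate_allele so realized diversity tracks the class target
    tabn <- codon_tables()
    infl <- vapply(seq_along(base_codons), function(j) {
      nb <- tabn$neighbours[[base_codons[j]]]
      if (is.null(nb) || nrow(nb) == 0L) return(1)
      sum(ifelse(nb$syn, 1, omega_map[j])) / nrow(nb)
    }, numeric(1))
    m <- m / mean(infl)

    seqs <- character(npool)
    for (i in seq_len(npool)) {
      s <- mutate_allele(base_codons, tail_base, m, omega_map)
      if (m > 0 && i > 1L) {
        tries <- 0L
        while (s %in% seqs[seq_len(i - 1L)] && tries < 200L) {
          s <- mutate_allele(base_codons, tail_base, m, omega_map)
          tries <- tries + 1L
        }
        while (s %in% seqs[seq_len(i - 1L)]) {  # force uniqueness
          cods <- split_codons(s)
          j <- sample.int(length(cods), 1L)
          nb <- tabn$neighbours[[cods[j]]]
          cods[j] <- nb$codon[sample.int(nrow(nb), 1L)]
          s <- paste0(paste(cods, collapse = ""), tail_base)
        }
      }
      seqs[i] <- s
    }

    has_stop <- rep(FALSE, npool)
    n_stop <- round(config$stop_codon_fraction * npool)
    if (n_stop > 0) {
      tab <- codon_tables()
      for (i in sample.int(npool, n_stop)) {
        repeat {
          cods <- split_codons(seqs[i])
          j <- sample.int(length(cods), 1L)
          cods[j] <- sample(tab$stops, 1L)
          s <- paste0(paste(cods, collapse = ""), tail_base)
          if (!s %in% seqs[-i]) { seqs[i] <- s; has_stop[i] <- TRUE; break }
        }
      }
    }

    pool[[cl]] <- data.frame(
      allele_id = sprintf("%s-%03d", prefix[[cl]], seq_len(npool)),
      class = cl, sequence = seqs,
      transcribed = runif(npool) < config$transcription_prob[[cl]],
      has_stop = has_stop,
      deleted_ref_codons = paste(deleted, collapse = ","),
      stringsAsFactors = FALSE)
  }
  truth <- list(config = config, reference = reference,
                pool = do.call(rbind, pool), pss_local = pss_local,
                genotypes = NULL)
  rownames(truth$pool) <- NULL
  class(truth) <- "mhc_truth"
  truth
}

#' Assign genotypes to simulated individuals
#'
#' Per individual and class, draws carrier status and a copy number uniform in
#' the configured range, then samples that many distinct alleles from the
#' class pool. Alleles closer than `min_pool_edit` edits (default 3) are
#' never co-assigned to one individual: such pairs are indistinguishable
#' from PCR-error variants under the 1-2 bp collapse rule, so a genotype a
#' replicate-verified pipeline can recover keeps its alleles at least that
#' far apart (the constraint is skipped when the class diversity target is
#' zero).
#'
#' @param truth `mhc_truth` from [generate_allele_pool()].
#' @param config `mhc_sim_config` (defaults to the one inside `truth`).
#' @return `truth` with a `genotypes` data.frame (individual_id, allele_id).
#' @export
assign_genotypes <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "mhc_truth"))
  set.seed(derive_seed(config$seed, "genotypes"))
  min_edit <- config$min_pool_edit %||% 3L
  pool_seq <- setNames(truth$pool$sequence, truth$pool$allele_id)
  rows <- list()
  for (i in seq_len(config$n_individuals)) {
    ind <- sprintf("ind%02d", i)
    for (cl in unique(truth$pool$class)) {
      if (runif(1) >= (config$carrier_prob[[cl]] %||% 1)) next
      rng <- config$copy_number_range[[cl]]
      ids <- truth$pool$allele_id[truth$pool$class == cl]
      k <- min(sample(seq.int(rng[1], rng[2]), 1L), length(ids))
      enforce <- (config$class_target_pi[[cl]] %||% 1) > 0
      chosen <- character(0)
      cand <- sample(ids)
      for (id in cand) {
        if (length(chosen) >= k) break
        if (enforce && length(chosen) &&
            min(utils::adist(pool_seq[id], pool_seq[chosen])) < min_edit)
          next
        chosen <- c(chosen, id)
      }
      if (!length(chosen)) next
      rows[[length(rows) + 1L]] <- data.frame(
        individual_id = ind, allele_id = chosen,
        stringsAsFactors = FALSE)
    }
  }
  truth$genotypes <- do.call(rbind, rows)
  rownames(truth$genotypes) <- NULL
  truth
}

#' Build a dual-barcode tag sheet
#'
#' One amplicon per individual x template (gDNA, cDNA) x PCR replicate (1, 2),
#' plus template-free negative controls, each with a unique combination of a
#' forward and a reverse 6 bp tag (grid assignment, as on a barcoded plate).
#'
#' @param config `mhc_sim_config`.
#' @return data.frame with columns amplicon_id, individual_id, template,
#'   replicate, fwd_tag, rev_tag, is_negative_control.
#' @export
make_tag_sheet <- function(config) {
  set.seed(derive_seed(config$seed, "tags"))
  inds <- sprintf("ind%02d", seq_len(config$n_individuals))
  grid <- expand.grid(replicate = 1:2, template = c("gDNA", "cDNA"),
                      individual_id = inds, stringsAsFactors = FALSE)
  grid <- grid[, c("individual_id", "template", "replicate")]
  if (config$n_negative_controls > 0) {
    nc <- data.frame(individual_id = NA_character_, template = "gDNA",
                     replicate = 1L, stringsAsFactors = FALSE)
    nc <- nc[rep(1L, config$n_negative_controls), , drop = FALSE]
    grid <- rbind(grid, nc)
  }
  n <- nrow(grid)
  n_rev <- 8L
  n_fwd <- ceiling(n / n_rev)
  tags <- character(0)
  while (length(tags) < n_fwd + n_rev) {
    cand <- paste(sample(c("A", "C", "G", "T"), config$tag_length, replace = TRUE),
                  collapse = "")
    if (!cand %in% tags) tags <- c(tags, cand)
  }
  fwd <- tags[seq_len(n_fwd)]
  rev <- tags[n_fwd + seq_len(n_rev)]
  idx <- seq_len(n) - 1L
  grid$fwd_tag <- fwd[idx %/% n_rev + 1L]
  grid$rev_tag <- rev[idx %% n_rev + 1L]
  grid$is_negative_control <- is.na(grid$individual_id)
  grid$amplicon_id <- ifelse(grid$is_negative_control,
                             sprintf("NC%02d", cumsum(grid$is_negative_control)),
                             paste0(grid$individual_id, "_", grid$template,
                                    "_r", grid$replicate))
  rownames(grid) <- NULL
  grid[, c("amplicon_id", "individual_id", "template", "replicate",
           "fwd_tag", "rev_tag", "is_negative_control")]
}

# One concrete realization per read of an IUPAC primer: each degenerate
# position is drawn uniformly from its expansion (a degenerate oligo is a
# mixture of concrete oligos).
concretize_primer <- function(primer, n) {
  p <- strsplit(primer, "")[[1]]
  out <- matrix(rep(p, each = n), nrow = n)
  for (i in seq_along(p)) {
    allowed <- IUPAC_EXPAND[[p[i]]]
    if (length(allowed) > 1L)
      out[, i] <- sample(allowed, n, replace = TRUE)
  }
  do.call(paste0, asplit(out, 2))
}

# Apply i.i.d. substitution errors to a set of equal-length reads; returns the
# mutated reads plus per-read total and flank (tag/primer region) error counts.
apply_read_errors <- function(reads, error_rate, flank5, flank3) {
  n <- length(reads); L <- nchar(reads[1])
  if (n == 0L || error_rate <= 0)
    return(list(reads = reads, n_err = integer(n), n_flank = integer(n)))
  M <- seq_matrix(reads)
  hit <- matrix(runif(n * L) < error_rate, n, L)
  idx <- which(hit)
  if (length(idx)) {
    bases <- c("A", "C", "G", "T")
    cur <- match(M[idx], bases)
    M[idx] <- bases[(cur - 1L + sample.int(3L, length(idx), replace = TRUE)) %% 4L + 1L]
  }
  flank_cols <- c(seq_len(flank5), seq.int(L - flank3 + 1L, L))
  list(reads = do.call(paste0, asplit(M, 2)),
       n_err = as.integer(rowSums(hit)),
       n_flank = as.integer(rowSums(hit[, flank_cols, drop = FALSE])))
}

#' Simulate tagged amplicon reads
#'
#' Emits, per amplicon in the tag sheet, `coverage` reads of the form
#' fwd_tag + fwd_primer + insert + revcomp(rev_primer) + revcomp(rev_tag),
#' where the insert is a uniformly chosen genotype template or, with
#' probability `chimera_rate`, a two-parent join at a uniform internal
#' breakpoint. Substitution errors are i.i.d. over the whole read; a
#' configured fraction of reads is emitted on the reverse strand. Negative
#' controls receive zero reads. Every read is logged with its template,
#' chimera parents and error counts.
#'
#' @param truth `mhc_truth` with genotypes (assigned on the fly if absent).
#' @param config `mhc_sim_config`.
#' @param tag_sheet tag sheet from [make_tag_sheet()].
#' @return object of class `mhc_readsim`: named read vector, provenance log,
#'   the tag sheet and the config.
#' @export
simulate_reads <- function(truth, config = truth$config,
                           tag_sheet = make_tag_sheet(config)) {
  stopifnot(inherits(truth, "mhc_truth"))
  if (anyDuplicated(paste(tag_sheet$fwd_tag, tag_sheet$rev_tag)))
    stop("duplicate (fwd_tag, rev_tag) pair in tag sheet")
  if (is.null(truth$genotypes)) truth <- assign_genotypes(truth, config)
  set.seed(derive_seed(config$seed, "reads"))

  pool_seq <- setNames(truth$pool$sequence, truth$pool$allele_id)
  transcribed <- setNames(truth$pool$transcribed, truth$pool$allele_id)
  rp_rc <- revcomp(config$rev_primer)
  flank5 <- config$tag_length + nchar(config$fwd_primer)
  flank3 <- config$tag_length + nchar(config$rev_primer)

  all_reads <- list(); all_logs <- list()
  for (r in seq_len(nrow(tag_sheet))) {
    row <- tag_sheet[r, ]
    if (isTRUE(row$is_negative_control)) next
    ids <- truth$genotypes$allele_id[truth$genotypes$individual_id == row$individual_id]
    if (row$template == "cDNA") ids <- ids[transcribed[ids]]
    if (length(ids) == 0L) next
    nreads <- config$coverage
    tmpl <- sample(ids, nreads, replace = TRUE)
    chim <- runif(nreads) < config$chimera_rate & length(ids) >= 2L
    parent2 <- rep(NA_character_, nreads)
    brk <- rep(NA_integer_, nreads)
    inserts <- unname(pool_seq[tmpl])
    for (i in which(chim)) {
      p2 <- sample(setdiff(ids, tmpl[i]), 1L)
      lmin <- min(nchar(pool_seq[tmpl[i]]), nchar(pool_seq[p2]))
      k <- sample.int(lmin - 1L, 1L)
      inserts[i] <- paste0(substr(pool_seq[tmpl[i]], 1L, k),
                           substr(pool_seq[p2], k + 1L, nchar(pool_seq[p2])))
      parent2[i] <- p2; brk[i] <- k
    }
    reads <- paste0(row$fwd_tag, concretize_primer(config$fwd_primer, nreads),
                    inserts, concretize_primer(rp_rc, nreads),
                    revcomp(row$rev_tag))
    n_err <- integer(nreads); n_flank <- integer(nreads)
    for (L in unique(nchar(reads))) {
      sel <- which(nchar(reads) == L)
      mut <- apply_read_errors(reads[sel], config$error_rate, flank5, flank3)
      reads[sel] <- mut$reads; n_err[sel] <- mut$n_err; n_flank[sel] <- mut$n_flank
    }
    flip <- runif(nreads) < config$revcomp_fraction
    if (any(flip)) reads[flip] <- revcomp(reads[flip])
    rid <- sprintf("%s_%05d", row$amplicon_id, seq_len(nreads))
    all_reads[[row$amplicon_id]] <- setNames(reads, rid)
    all_logs[[row$amplicon_id]] <- data.frame(
      read_id = rid, amplicon_id = row$amplicon_id, template_id = tmpl,
      chimera = chim & !is.na(parent2), parent2 = parent2, breakpoint = brk,
      n_errors = n_err, n_flank_errors = n_flank, revcomped = flip,
      stringsAsFactors = FALSE)
  }
  out <- list(reads = unlist(unname(all_reads)),
              log = do.call(rbind, c(all_logs, list(make.row.names = FALSE))),
              tag_sheet = tag_sheet, config = config)
  class(out) <- "mhc_readsim"
  out
}

#' Write simulated reads as FASTQ
#'
#' Placeholder Sanger qualities (`I` throughout); byte-identical output for
#' identical simulations.
#'
#' @param sim `mhc_readsim`.
#' @param path output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(sim, path) {
  reads <- if (inherits(sim, "mhc_readsim")) sim$reads else sim
  lines <- character(4L * length(reads))
  lines[seq(1, by = 4, length.out = length(reads))] <- paste0("@", names(reads))
  lines[seq(2, by = 4, length.out = length(reads))] <- unname(reads)
  lines[seq(3, by = 4, length.out = length(reads))] <- "+"
  lines[seq(4, by = 4, length.out = length(reads))] <- strrep("I", nchar(reads))
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTQ or FASTA file into a named character vector
#' @param path input file; format inferred from the first character.
#' @return named character vector of sequences.
#' @export
read_sequences <- function(path) {
  first <- substr(readLines(path, n = 1L), 1, 1)
  fmt <- if (first == "@") "fastq" else "fasta"
  x <- Biostrings::readDNAStringSet(path, format = fmt)
  setNames(as.character(x), names(x))
}

#' Write sequences as FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Write truth tables and the tag sheet as TSV
#' @param truth `mhc_truth`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(truth$pool, file.path(dir, "pool.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(truth$genotypes))
    utils::write.table(truth$genotypes, file.path(dir, "genotypes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
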