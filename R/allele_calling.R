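# Artifact filters (low-copy, PCR chimera, 1-2 bp error variants),
# replicate verification and expression classification. The filters are
# contractive and applied in a fixed order: copy threshold, then chimera
# flagging, then error collapse; every removal is logged.

as_variant_table <- function(tab, amplicon_id = attr(tab, "amplicon_id")) {
  attr(tab, "amplicon_id") <- amplicon_id
  attr(tab, "total_reads_used") <- sum(tab$count)
  if (!inherits(tab, "mhc_variant_table"))
    class(tab) <- c("mhc_variant_table", "data.frame")
  tab
}

#' Remove low-copy variants
#'
#' Retains exactly the variants with `count >= min_copies` (default 10, the
#' fixed per-amplicon copy threshold).
#'
#' @param table variant table.
#' @param min_copies minimum read count retained.
#' @return filtered variant table.
#' @export
filter_low_copy <- function(table, min_copies = 10L) {
  if (min_copies < 1L) stop("min_copies must be >= 1")
  out <- table[table$count >= min_copies, , drop = FALSE]
  rownames(out) <- NULL
  as_variant_table(out, attr(table, "amplicon_id"))
}

# Exhaustive single-breakpoint test: does V agree with A at every A/B-differing
# site up to some breakpoint and with B beyond it (or vice versa), with at
# least one differing site on each side?
single_breakpoint <- function(v, a, b) {
  va <- strsplit(v, "")[[1]]; aa <- strsplit(a, "")[[1]]; bb <- strsplit(b, "")[[1]]
  d <- which(aa != bb)
  if (length(d) < 2L) return(NULL)
  matches_a <- va[d] == aa[d]
  matches_b <- va[d] == bb[d]
  if (!all(matches_a | matches_b)) return(NULL)
  k <- length(d)
  # A-then-B: first i sites match A, rest match B, 1 <= i < k
  for (i in seq_len(k - 1L)) {
    if (all(matches_a[seq_len(i)]) && all(matches_b[seq.int(i + 1L, k)]))
      return(list(first = "A", breakpoint = d[i]))
  }
  for (i in seq_len(k - 1L)) {
    if (all(matches_b[seq_len(i)]) && all(matches_a[seq.int(i + 1L, k)]))
      return(list(first = "B", breakpoint = d[i]))
  }
  NULL
}

#' Flag PCR-chimera variants
#'
#' A variant is flagged as a chimera when two strictly more abundant,
#' equal-length parents exist in the table such that the variant agrees with
#' one parent at every parent-differing site up to a single breakpoint and
#' with the other parent beyond it, with at least one differing site on each
#' side. Flagged variants are removed from the retained set and reported.
#'
#' @param table variant table sorted by abundance.
#' @return list with `retained` (variant table) and `flagged` (data.frame of
#'   sequence, count, parent_a, parent_b, breakpoint).
#' @export
flag_chimeras <- function(table) {
  n <- nrow(table)
  flagged <- list()
  is_chim <- logical(n)
  if (n >= 3L) {
    for (v in seq_len(n)) {
      cand <- which(table$count > table$count[v] &
                    nchar(table$sequence) == nchar(table$sequence[v]))
      cand <- setdiff(cand, v)
      if (length(cand) < 2L) next
      pairs <- combn(cand, 2L)
      for (p in seq_len(ncol(pairs))) {
        a <- pairs[1, p]; b <- pairs[2, p]
        hit <- single_breakpoint(table$sequence[v], table$sequence[a],
                                 table$sequence[b])
        if (!is.null(hit)) {
          is_chim[v] <- TRUE
          flagged[[length(flagged) + 1L]] <- data.frame(
            sequence = table$sequence[v], count = table$count[v],
            parent_a = table$sequence[if (hit$first == "A") a else b],
            parent_b = table$sequence[if (hit$first == "A") b else a],
            breakpoint = hit$breakpoint, stringsAsFactors = FALSE)
          break
        }
      }
    }
  }
  retained <- table[!is_chim, , drop = FALSE]
  rownames(retained) <- NULL
  list(retained = as_variant_table(retained, attr(table, "amplicon_id")),
       flagged = if (length(flagged)) do.call(rbind, flagged) else
         data.frame(sequence = character(0), count = integer(0),
                    parent_a = character(0), parent_b = character(0),
                    breakpoint = integer(0)))
}

#' Collapse 1-2 bp error variants into more abundant variants
#'
#' Processing variants in descending abundance, a variant is removed when its
#' edit distance (Levenshtein, so rare 1-base indel artifacts are also
#' caught) to an already-retained, strictly more abundant variant is at most
#' `max_edit`. Removals are logged with their parent.
#'
#' @param table variant table sorted by abundance.
#' @param max_edit maximum edit distance collapsed (default 2).
#' @return list with `retained` (variant table) and `removed` (data.frame of
#'   sequence, count, parent).
#' @export
collapse_errors <- function(table, max_edit = 2L) {
  n <- nrow(table)
  keep <- logical(n); removed <- list()
  for (i in seq_len(n)) {
    parents <- which(keep & table$count > table$count[i])
    drop <- FALSE
    if (length(parents)) {
      d <- utils::adist(table$sequence[i], table$sequence[parents])
      j <- which(d <= max_edit)[1]
      if (!is.na(j)) {
        drop <- TRUE
        removed[[length(removed) + 1L]] <- data.frame(
          sequence = table$sequence[i], count = table$count[i],
          parent = table$sequence[parents[j]], stringsAsFactors = FALSE)
      }
    }
    keep[i] <- !drop
  }
  retained <- table[keep, , drop = FALSE]
  rownames(retained) <- NULL
  list(retained = as_variant_table(retained, attr(table, "amplicon_id")),
       removed = if (length(removed)) do.call(rbind, removed) else
         data.frame(sequence = character(0), count = integer(0),
                    parent = character(0)))
}

#' Apply the full artifact-filter chain to one variant table
#'
#' Fixed composition: low-copy threshold, then chimera flagging, then
#' 1-2 bp error collapse. The composed filter is contractive and idempotent.
#'
#' @param table variant table.
#' @param min_copies,max_edit filter parameters.
#' @return list with `retained` and a `log` of removals by stage.
#' @export
apply_artifact_filters <- function(table, min_copies = 10L, max_edit = 2L) {
  t1 <- filter_low_copy(table, min_copies)
  ch <- flag_chimeras(t1)
  co <- collapse_errors(ch$retained, max_edit)
  list(retained = co$retained,
       log = list(low_copy = table$sequence[table$count < min_copies],
                  chimeras = ch$flagged, collapsed = co$removed))
}

#' Replicate-verify alleles for one individual and template
#'
#' Only alleles found in (at least) `min_replicates` of the replicate PCRs of
#' the same individual and template are treated as true alleles.
#'
#' @param tables named list of retained variant tables, one per replicate.
#' @param min_replicates replicates an allele must appear in (default: all).
#' @return list with `status` ("scored" or "unscored"), `verified`
#'   (character vector of sequences) and `support` (per-replicate counts).
#' @export
verify_replicates <- function(tables, min_replicates = length(tables)) {
  if (length(tables) < min_replicates || length(tables) == 0L ||
      any(vapply(tables, is.null, logical(1))))
    return(list(status = "unscored", verified = character(0), support = NULL))
  seqs <- sort(unique(unlist(lapply(tables, `[[`, "sequence"))))
  support <- vapply(tables, function(t)
    t$count[match(seqs, t$sequence)], numeric(length(seqs)))
  support <- matrix(support, nrow = length(seqs),
                    dimnames = list(seqs, names(tables)))
  hits <- rowSums(!is.na(support))
  list(status = "scored", verified = seqs[hits >= min_replicates],
       support = support)
}

#' Classify expression from verified gDNA and cDNA allele sets
#'
#' Alleles verified in both templates of an individual are transcribed;
#' gDNA-only alleles are putatively non-expressed; cDNA-only alleles are
#' reported but never added to genotypes (gDNA is the genotype source). ORF
#' status is computed in the configured frame: frameshift when the length is
#' incompatible with an in-frame interpretation, stop_codon when the
#' translation contains a stop, else orf.
#'
#' @param gdna,cdna character vectors of verified sequences for one
#'   individual.
#' @param frame_mod expected sequence length modulo 3 for an in-frame exon
#'   fragment (1 for these 241/238/235 bp amplicons).
#' @return data.frame: sequence, expression, orf_status.
#' @export
classify_expression <- function(gdna, cdna = character(0), frame_mod = 1L) {
  seqs <- sort(union(gdna, cdna))
  expression <- ifelse(seqs %in% gdna & seqs %in% cdna, "transcribed",
                       ifelse(seqs %in% gdna, "gdna_only", "cdna_only"))
  orf <- vapply(seqs, function(s) {
    if (nchar(s) %% 3L != frame_mod) return("frameshift")
    if (grepl("*", translate_nt(s), fixed = TRUE)) return("stop_codon")
    "orf"
  }, character(1), USE.NAMES = FALSE)
  data.frame(sequence = seqs, expression = expression, orf_status = orf,
             stringsAsFactors = FALSE)
}

#' Mean transcribed fraction over individuals
#'
#' Given per-individual counts of gDNA-verified alleles in open reading frame
#' and of transcribed alleles (present in both templates), returns the mean
#' per-individual transcribed fraction, in percent.
#'
#' @param n_gdna,n_transcribed integer vectors, one entry per individual.
#' @param digits rounding for display (0 = whole percent).
#' @return numeric percentage.
#' @export
mean_transcribed_fraction <- function(n_gdna, n_transcribed, digits = 0) {
  stopifnot(length(n_gdna) == length(n_transcribed), all(n_gdna > 0))
  round(mean(n_transcribed / n_gdna) * 100, digits)
}

#' Call replicate-verified genotypes from variant tables
#'
#' Full allele-calling driver: per amplicon, applies the artifact-filter
#' chain; per individual and template, replicate-verifies alleles; classifies
#' expression against the cDNA template where present. Allele identifiers are
#' assigned to unique sequences in order of discovery.
#'
#' @param tables named list of variant tables (names = amplicon ids).
#' @param tag_sheet tag sheet mapping amplicons to individual/template/
#'   replicate.
#' @param min_copies,max_edit,min_replicates filter and verification
#'   parameters.
#' @return object of class `mhc_calls`: `$calls` data.frame (individual_id,
#'   allele_id, sequence, expression, orf_status, per-replicate counts),
#'   `$unscored` (individual x template combinations lacking replicates),
#'   `$filter_log`.
#' @export
call_genotypes <- function(tables, tag_sheet, min_copies = 10L,
                           max_edit = 2L, min_replicates = 2L) {
  sheet <- tag_sheet[!tag_sheet$is_negative_control, , drop = FALSE]
  filtered <- list(); logs <- list()
  for (a in names(tables)) {
    f <- apply_artifact_filters(tables[[a]], min_copies, max_edit)
    filtered[[a]] <- f$retained; logs[[a]] <- f$log
  }
  calls <- list(); unscored <- list()
  for (ind in unique(sheet$individual_id)) {
    per_template <- list()
    for (tmpl in unique(sheet$template[sheet$individual_id == ind])) {
      amps <- sheet$amplicon_id[sheet$individual_id == ind &
                                sheet$template == tmpl]
      reps <- filtered[amps]
      have <- !vapply(reps, is.null, logical(1))
      vr <- verify_replicates(reps[have], min_replicates)
      if (vr$status == "unscored") {
        unscored[[length(unscored) + 1L]] <- data.frame(
          individual_id = ind, template = tmpl, stringsAsFactors = FALSE)
        next
      }
      per_template[[tmpl]] <- vr
    }
    gdna <- per_template[["gDNA"]]$verified %||% character(0)
    cdna <- per_template[["cDNA"]]$verified %||% character(0)
    if (length(gdna) + length(cdna) == 0L) next
    cls <- classify_expression(gdna, cdna)
    cls$individual_id <- ind
    sup <- per_template[["gDNA"]]$support
    if (!is.null(sup)) {
      idx <- match(cls$sequence, rownames(sup))
      for (j in seq_len(ncol(sup)))
        cls[[paste0("gdna_rep", j)]] <- sup[idx, j]
    }
    calls[[length(calls) + 1L]] <- cls
  }
  calls <- if (length(calls)) do.call(rbind, c(calls, list(make.row.names = FALSE))) else NULL
  if (is.null(calls))
    calls <- data.frame(sequence = character(0), expression = character(0),
                        orf_status = character(0),
                        individual_id = character(0))
  uniq <- unique(calls$sequence)
  calls$allele_id <- sprintf("A%04d", match(calls$sequence, uniq))
  out <- list(calls = calls,
              unscored = do.call(rbind, unscored) %||%
                data.frame(individual_id = character(0),
                           template = character(0)),
              filter_log = logs)
  class(out) <- "mhc_calls"
  out
}

#' Write genotype calls as TSV
#' @param calls `mhc_calls`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path) {
  utils::write.table(calls$calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
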