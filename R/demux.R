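# Demultiplexing by dual tags and primers, and per-amplicon variant tables
# (sequence -> read count), the unit all downstream artifact filters act on.

#' Assign reads to amplicons by dual tags and primers
#'
#' A read is assigned if and only if both 6 bp tags match exactly and both
#' primers match with at most `max_primer_mismatches` mismatches (IUPAC
#' degenerate primer positions match any of their expansions). Both strand
#' orientations are tried. Tags and primers are trimmed from the retained
#' insert; unassigned reads are counted with a reason.
#'
#' @param reads named character vector of reads, or a FASTQ/FASTA path.
#' @param tag_sheet tag sheet (see [make_tag_sheet()]); tag pairs must be
#'   unique.
#' @param fwd_primer,rev_primer amplification primers (IUPAC codes allowed).
#' @param max_primer_mismatches maximum mismatches tolerated per primer.
#' @return object of class `mhc_demux`: `$inserts` (read_id, amplicon_id,
#'   insert), `$unassigned` (reason counts), `$n_input`.
#' @export
demultiplex <- function(reads, tag_sheet, fwd_primer, rev_primer,
                        max_primer_mismatches = 0L) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    reads <- read_sequences(reads)
  if (nrow(tag_sheet) == 0L) stop("empty tag sheet")
  key <- paste(tag_sheet$fwd_tag, tag_sheet$rev_tag)
  if (anyDuplicated(key)) stop("duplicate tag pairs in tag sheet")
  tl <- nchar(tag_sheet$fwd_tag[1])
  fl <- nchar(fwd_primer); rl <- nchar(rev_primer)
  n <- length(reads)
  if (is.null(names(reads))) names(reads) <- sprintf("read%06d", seq_len(n))

  assigned_amp <- rep(NA_character_, n)
  insert <- rep(NA_character_, n)
  reason <- rep("tag_mismatch", n)
  todo <- seq_len(n)
  for (orient in 1:2) {
    if (length(todo) == 0L) break
    rr <- if (orient == 1L) reads[todo] else revcomp(reads[todo])
    L <- nchar(rr)
    long_enough <- L >= (2L * tl + fl + rl + 1L)
    ft <- substr(rr, 1L, tl)
    rt <- revcomp(substr(rr, L - tl + 1L, L))
    m <- match(paste(ft, rt), key)
    hit <- which(!is.na(m) & long_enough)
    if (length(hit)) {
      fp_region <- substr(rr[hit], tl + 1L, tl + fl)
      rp_region <- revcomp(substr(rr[hit], L[hit] - tl - rl + 1L, L[hit] - tl))
      mm_f <- iupac_mismatches(fp_region, fwd_primer)
      mm_r <- iupac_mismatches(rp_region, rev_primer)
      good <- mm_f <= max_primer_mismatches & mm_r <= max_primer_mismatches
      gi <- hit[good]
      assigned_amp[todo[gi]] <- tag_sheet$amplicon_id[m[gi]]
      insert[todo[gi]] <- substr(rr[gi], tl + fl + 1L, L[gi] - tl - rl)
      reason[todo[hit[!good]]] <- "primer_mismatch"
    }
    todo <- todo[is.na(assigned_amp[todo])]
  }
  ok <- !is.na(assigned_amp)
  out <- list(
    inserts = data.frame(read_id = names(reads)[ok],
                         amplicon_id = assigned_amp[ok],
                         insert = insert[ok], stringsAsFactors = FALSE),
    unassigned = table(reason[!ok]),
    n_input = n)
  class(out) <- "mhc_demux"
  out
}

#' Build a per-amplicon variant table
#'
#' Drops reads containing non-ACGT characters, applies a seeded uniform
#' subsample when the amplicon exceeds `read_cap`, and collapses identical
#' inserts into (sequence, count) rows ordered by descending count with
#' lexicographic tie-break.
#'
#' @param inserts character vector of tag/primer-trimmed inserts.
#' @param read_cap maximum reads used per amplicon (default 20000).
#' @param seed seed for the subsample.
#' @param amplicon_id optional label stored on the table.
#' @return data.frame of class `mhc_variant_table` with columns `sequence`,
#'   `count`; attributes `amplicon_id` and `total_reads_used`.
#' @export
build_variant_table <- function(inserts, read_cap = 20000L, seed = 1L,
                                amplicon_id = NA_character_) {
  inserts <- inserts[!grepl("[^ACGT]", inserts)]
  if (length(inserts) > read_cap) {
    set.seed(seed)
    inserts <- inserts[sample.int(length(inserts), read_cap)]
  }
  if (length(inserts) == 0L) {
    tab <- data.frame(sequence = character(0), count = integer(0),
                      stringsAsFactors = FALSE)
  } else {
    cnt <- table(inserts)
    tab <- data.frame(sequence = names(cnt), count = as.integer(cnt),
                      stringsAsFactors = FALSE)
    tab <- tab[order_variants(tab$sequence, tab$count), , drop = FALSE]
    rownames(tab) <- NULL
  }
  attr(tab, "amplicon_id") <- amplicon_id
  attr(tab, "total_reads_used") <- sum(tab$count)
  class(tab) <- c("mhc_variant_table", "data.frame")
  tab
}

#' Build variant tables for every amplicon of a demultiplexing result
#'
#' @param demux `mhc_demux` from [demultiplex()].
#' @param read_cap,seed passed to [build_variant_table()]; the seed is fanned
#'   out per amplicon with [derive_seed()].
#' @param amplicon_ids amplicons to build (default: all in the result).
#' @return named list of `mhc_variant_table`.
#' @export
variant_tables <- function(demux, read_cap = 20000L, seed = 1L,
                           amplicon_ids = NULL) {
  ids <- amplicon_ids %||% sort(unique(demux$inserts$amplicon_id))
  sets <- split(demux$inserts$insert, demux$inserts$amplicon_id)
  out <- lapply(ids, function(a)
    build_variant_table(sets[[a]] %||% character(0), read_cap = read_cap,
                        seed = derive_seed(seed, a), amplicon_id = a))
  setNames(out, ids)
}

#' Write variant tables as TSV
#' @param tables named list of variant tables.
#' @param path output TSV (amplicon_id, rank, sequence, count).
#' @return `path`, invisibly.
#' @export
write_variant_tables <- function(tables, path) {
  rows <- lapply(names(tables), function(a) {
    t <- tables[[a]]
    if (nrow(t) == 0L) return(NULL)
    data.frame(amplicon_id = a, rank = seq_len(nrow(t)),
               sequence = t$sequence, count = t$count,
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
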