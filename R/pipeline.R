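# End-to-end orchestration: simulate -> demux -> call -> classify -> stats ->
# select -> recomb -> network, with one structured config, per-stage seeds
# derived from a single global seed, content-hashed stage outputs and a
# machine-readable summary.

pipeline_defaults <- function() {
  list(
    seed = 1L,
    paths = list(reads = NULL, tags = NULL, reference = NULL),
    simulate = list(enabled = TRUE),
    demux = list(max_primer_mismatches = 0L),
    call = list(min_copies = 10L, max_edit = 2L, read_cap = 20000L,
                min_replicates = 2L),
    selection = list(enabled = TRUE, alpha = 0.05, k = 2L,
                     subset_size = 47L, n_reps = 100L, subsample = FALSE),
    recombination = list(enabled = FALSE, top = 50L, n_permutations = 200L,
                         k = 2L, alpha = 0.05),
    network = list(enabled = TRUE, gamma_shape = 0.29, threshold = 1e-6,
                   bootstrap = 1000L, support_display_min = 70, max_taxa = 30L))
}

merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    if (!key %in% names(defaults))
      stop("unknown pipeline config key: ", paste0(path, key))
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]])))
      defaults[[key]] <- merge_config(defaults[[key]], as.list(user[[key]]),
                                      paste0(path, key, "."))
    else defaults[[key]] <- user[[key]]
  }
  defaults
}

#' Build and validate a pipeline configuration
#'
#' Stage parameter blocks mirror each module's defaults (min_copies 10,
#' max_edit 2, read_cap 20000, subset_size 47, n_reps 100, gamma shape 0.29,
#' split threshold 1e-6, bootstrap 1000, display support 70); unknown keys
#' are rejected. `sim` holds the simulation config when the simulate stage
#' is enabled.
#'
#' @param ... overrides of the default blocks (named lists), or a single
#'   named list (e.g. parsed from YAML).
#' @param sim optional [sim_config()] (built from the pipeline seed when
#'   absent).
#' @return object of class `mhc_pipeline_config`.
#' @export
pipeline_config <- function(..., sim = NULL) {
  user <- list(...)
  if (length(user) == 1L && is.null(names(user)) && is.list(user[[1]]))
    user <- user[[1]]
  cfg <- merge_config(pipeline_defaults(), user)
  cfg$sim <- sim
  class(cfg) <- "mhc_pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file with pipeline blocks.
#' @return `mhc_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  pipeline_config(yaml::read_yaml(path))
}

#' Run the full pipeline
#'
#' Stages run in fixed order; each stage's outputs are written under
#' `out_dir` and content-hashed in `log.tsv`; `summary.json` holds
#' per-class allele counts, diversity, consensus PSS counts, recombination
#' consensus events and network file paths. Stage seeds are derived from the
#' global seed with [derive_seed()], so reruns with the same config are
#' identical.
#'
#' @param config `mhc_pipeline_config`.
#' @param out_dir run directory (created).
#' @return the summary, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "mhc_pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  summary <- list(seed = config$seed)
  stage <- "simulate"
  res <- tryCatch({
    if (isTRUE(config$simulate$enabled)) {
      simc <- config$sim %||% sim_config(seed = config$seed)
      truth <- assign_genotypes(generate_allele_pool(simc))
      sheet <- make_tag_sheet(simc)
      sim <- simulate_reads(truth, simc, sheet)
      fq <- file.path(out_dir, "reads.fastq")
      write_fastq(sim, fq)
      utils::write.table(sheet, file.path(out_dir, "tag_sheet.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      write_truth(truth, file.path(out_dir, "truth"))
      files <- c(files, fq, file.path(out_dir, "tag_sheet.tsv"))
      reads <- sim$reads
      reference <- truth$reference
      fwd <- simc$fwd_primer; rev <- simc$rev_primer
    } else {
      if (is.null(config$paths$reads) || is.null(config$paths$tags))
        stop("reads and tags paths required when simulation is disabled")
      reads <- read_sequences(config$paths$reads)
      sheet <- utils::read.delim(config$paths$tags, stringsAsFactors = FALSE)
      reference <- config$paths$reference
      fwd <- config$demux$fwd_primer; rev <- config$demux$rev_primer
      truth <- NULL
    }

    stage <- "demux"
    dm <- demultiplex(reads, sheet, fwd, rev,
                      config$demux$max_primer_mismatches)
    tabs <- variant_tables(dm, read_cap = config$call$read_cap,
                           seed = derive_seed(config$seed, "cap"))
    vt_path <- file.path(out_dir, "variant_tables.tsv")
    write_variant_tables(tabs, vt_path)
    files <- c(files, vt_path)
    summary$demux <- list(n_input = dm$n_input,
                          n_assigned = nrow(dm$inserts),
                          unassigned = as.list(dm$unassigned))

    stage <- "call"
    calls <- call_genotypes(tabs, sheet,
                            min_copies = config$call$min_copies,
                            max_edit = config$call$max_edit,
                            min_replicates = config$call$min_replicates)
    calls_path <- file.path(out_dir, "calls.tsv")
    write_calls(calls, calls_path)
    files <- c(files, calls_path)

    stage <- "classify"
    geno <- calls$calls[calls$calls$expression != "cdna_only", , drop = FALSE]
    if (is.null(reference))
      reference <- names(sort(-table(
        geno$sequence[nchar(geno$sequence) == max(nchar(geno$sequence))])))[1]
    cls <- classify_alleles(geno$sequence, reference)
    geno$class <- cls$class
    summary$classes <- as.list(table(
      cls$class[!duplicated(geno$sequence)]))

    stage <- "stats"
    uniq <- !duplicated(geno$sequence)
    rep_tab <- diversity_report(geno$sequence[uniq], geno$class[uniq])
    utils::write.table(rep_tab, file.path(out_dir, "diversity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, file.path(out_dir, "diversity.tsv"))
    summary$diversity <- rep_tab
    summary$population <- summarize_population(geno)$aggregate

    if (isTRUE(config$selection$enabled)) {
      stage <- "selection"
      pss <- list()
      for (cl in setdiff(unique(geno$class), "other")) {
        seqs <- unique(geno$sequence[geno$class == cl])
        names(seqs) <- sprintf("%s_%03d", cl, seq_along(seqs))
        stop_free <- !grepl("*", translate_nt(seqs), fixed = TRUE)
        if (sum(stop_free) < 4L) next
        sel <- site_selection(seqs[stop_free], k = config$selection$k,
                              alpha = config$selection$alpha)
        pss[[cl]] <- list(n_alleles = length(seqs),
                          consensus_pss = length(sel$consensus_sites),
                          sites = sel$consensus_sites)
      }
      summary$selection <- pss
    }

    if (isTRUE(config$recombination$enabled)) {
      stage <- "recombination"
      per_class <- list()
      for (cl in setdiff(unique(geno$class), "other")) {
        seqs <- unique(geno$sequence[geno$class == cl])
        if (length(seqs) < 4L) next
        names(seqs) <- sprintf("%s_%03d", cl, seq_along(seqs))
        cnt <- as.integer(table(geno$sequence)[seqs])
        sc <- scan_recombination(seqs, counts = cnt,
                                 top = config$recombination$top,
                                 n_permutations = config$recombination$n_permutations,
                                 seed = derive_seed(config$seed, "recomb"),
                                 k = config$recombination$k,
                                 alpha = config$recombination$alpha)
        per_class[[cl]] <- list(n_consensus = sum(sc$events$consensus),
                                phi_p = sc$phi$p)
      }
      summary$recombination <- per_class
    }

    if (isTRUE(config$network$enabled)) {
      stage <- "network"
      seqs <- geno$sequence[uniq]
      ord <- order(-table(geno$sequence)[seqs])
      seqs <- seqs[ord][seq_len(min(config$network$max_taxa, length(seqs)))]
      keep_len <- nchar(seqs) == max(nchar(seqs))
      seqs <- seqs[keep_len]
      if (length(seqs) >= 4L) {
        names(seqs) <- sprintf("a%03d", seq_along(seqs))
        net <- bootstrap_supports(
          seqs, n_replicates = config$network$bootstrap,
          support_display_min = config$network$support_display_min,
          seed = derive_seed(config$seed, "boot"),
          gamma_shape = config$network$gamma_shape,
          threshold = config$network$threshold)
        nx <- file.path(out_dir, "network.nex")
        write_nexus_splits(net, nx)
        files <- c(files, nx)
        summary$network <- list(path = nx, n_splits = length(net$splits),
                                max_support = max(net$supports))
      }
    }
    summary
  }, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))

  log <- data.frame(file = basename(files),
                    md5 = unname(tools::md5sum(files)))
  utils::write.table(log, file.path(out_dir, "log.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(res, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(res)
}
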