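# Codon-level machinery shared by the simulator and the selection tests:
# single-nucleotide codon neighbourhoods, Nei-Gojobori potential-site
# fractions, and pathway-averaged synonymous/nonsynonymous counts for
# observed codon changes.

.codon_env <- new.env(parent = emptyenv())

codon_tables <- function() {
  if (!is.null(.codon_env$tab)) return(.codon_env$tab)
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  codons <- sort(codons)
  code <- Biostrings::GENETIC_CODE[codons]
  stops <- codons[code == "*"]
  sense <- setdiff(codons, stops)

  # neighbours[[codon]]: data.frame(codon, pos, syn) for all 9 single-nt
  # changes landing on a sense codon.
  neighbours <- lapply(codons, function(cd) {
    ch <- strsplit(cd, "")[[1]]
    out <- list()
    for (pos in 1:3) for (b in setdiff(bases, ch[pos])) {
      ch2 <- ch; ch2[pos] <- b
      cd2 <- paste(ch2, collapse = "")
      if (code[cd2] == "*") next
      out[[length(out) + 1L]] <- data.frame(
        codon = cd2, pos = pos,
        syn = unname(code[cd2] == code[cd]),
        stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
  names(neighbours) <- codons

  # Nei-Gojobori potential nonsynonymous fraction per codon, stop-excluded.
  ng_frac <- vapply(codons, function(cd) {
    nb <- neighbours[[cd]]
    if (is.null(nb) || nrow(nb) == 0L) return(NA_real_)
    mean(!nb$syn)
  }, numeric(1))

  .codon_env$tab <- list(codons = codons, code = code, stops = stops,
                         sense = sense, neighbours = neighbours,
                         ng_frac = ng_frac)
  .codon_env$tab
}

is_stop_codon <- function(codon) {
  codon %in% codon_tables()$stops
}

# Pathway-averaged (n, s) counts for an observed codon change a -> b.
# Averages over all orderings of the differing positions; pathways passing
# through a stop codon are excluded unless every pathway does.
codon_path_counts <- function(a, b) {
  key <- paste0(a, b)
  memo <- .codon_env$paths
  if (is.null(memo)) { memo <- new.env(parent = emptyenv()); .codon_env$paths <- memo }
  hit <- memo[[key]]
  if (!is.null(hit)) return(hit)

  tab <- codon_tables()
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  diffpos <- which(ca != cb)
  res <- c(n = 0, s = 0)
  if (length(diffpos) > 0L) {
    perms <- if (length(diffpos) == 1L) list(diffpos) else {
      pl <- list()
      pm <- if (length(diffpos) == 2L) list(1:2, 2:1) else
        list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
      for (p in pm) pl[[length(pl) + 1L]] <- diffpos[p]
      pl
    }
    score_path <- function(ord) {
      cur <- ca; n <- 0; s <- 0; ok <- TRUE
      for (pos in ord) {
        nxt <- cur; nxt[pos] <- cb[pos]
        c1 <- paste(cur, collapse = ""); c2 <- paste(nxt, collapse = "")
        if (tab$code[c2] == "*") ok <- FALSE
        if (tab$code[c1] == tab$code[c2]) s <- s + 1 else n <- n + 1
        cur <- nxt
      }
      list(n = n, s = s, ok = ok)
    }
    scored <- lapply(perms, score_path)
    keep <- vapply(scored, `[[`, logical(1), "ok")
    if (!any(keep)) keep <- rep(TRUE, length(scored))
    ns <- vapply(scored[keep], `[[`, numeric(1), "n")
    ss <- vapply(scored[keep], `[[`, numeric(1), "s")
    res <- c(n = mean(ns), s = mean(ss))
  }
  memo[[key]] <- res
  res
}

# Split a nucleotide string into its complete codons (trailing base dropped).
split_codons <- function(seq) {
  nc <- 3L * (nchar(seq) %/% 3L)
  if (nc == 0L) return(character(0))
  substring(seq, seq(1L, nc, 3L), seq(3L, nc, 3L))
}
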