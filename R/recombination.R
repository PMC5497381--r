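# Recombination detection: MaxChi-style pairwise scans, Chimaera-style
# triplet scans and a pairwise-homoplasy (PHI) test, all with permutation
# p-values, plus the k-of-m consensus over tests.

# Maximum 2x2 chi-square over candidate breakpoints of a binary indicator
# vector x (1 = difference / match-to-A, depending on the caller). Returns
# the maximising breakpoint index (last position of the left segment) and
# the statistic.
max_breakpoint_chi2 <- function(x) {
  L <- length(x)
  cs <- cumsum(x)
  k <- seq_len(L - 1L)
  a <- cs[k]                     # left hits
  b <- k - a                     # left non-hits
  cc <- cs[L] - a                # right hits
  d <- (L - k) - cc              # right non-hits
  num <- L * (a * d - b * cc)^2
  den <- (a + b) * (cc + d) * (a + cc) * (b + d)
  chi <- ifelse(den > 0, num / den, 0)
  i <- which.max(chi)
  list(breakpoint = i, chi2 = chi[i])
}

# Permutation null of the max chi-square for a binary vector with `hits` ones
# among `L` positions; cached by (L, hits) so scans over many pairs reuse it.
.null_env <- new.env(parent = emptyenv())
null_max_chi2 <- function(L, hits, n_permutations, seed) {
  key <- paste(L, hits, n_permutations, seed, sep = "_")
  hit <- .null_env[[key]]
  if (!is.null(hit)) return(hit)
  set.seed(seed)
  stat <- numeric(n_permutations)
  base <- c(rep(1L, hits), rep(0L, L - hits))
  for (i in seq_len(n_permutations))
    stat[i] <- max_breakpoint_chi2(sample(base))$chi2
  .null_env[[key]] <- stat
  stat
}

perm_p <- function(observed, null_stats) {
  (1 + sum(null_stats >= observed)) / (length(null_stats) + 1)
}

#' MaxChi recombination scan for a sequence pair
#'
#' Scores every candidate breakpoint along the aligned pair by the 2x2
#' chi-square of the left/right split of the site-difference indicator, and
#' reports the maximising breakpoint with a permutation p-value obtained by
#' shuffling site order.
#'
#' @param seqA,seqB equal-length aligned sequences with >= 4 differing sites.
#' @param n_permutations permutations of site order (default 1000).
#' @param seed integer seed.
#' @return list: `status` ("ok"/"untestable"), `best_breakpoint` (alignment
#'   column ending the left segment), `chi2_max`, `p`.
#' @export
maxchi_scan <- function(seqA, seqB, n_permutations = 1000L, seed = 1L) {
  if (nchar(seqA) != nchar(seqB)) stop("sequences must be aligned to equal length")
  a <- strsplit(seqA, "")[[1]]; b <- strsplit(seqB, "")[[1]]
  use <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  x <- as.integer(a[use] != b[use])
  cols <- which(use)
  if (sum(x) < 4L)
    return(list(status = "untestable", best_breakpoint = NA_integer_,
                chi2_max = NA_real_, p = NA_real_))
  obs <- max_breakpoint_chi2(x)
  null <- null_max_chi2(length(x), sum(x), n_permutations, seed)
  # report the midpoint of the inter-variable-site gap containing the
  # maximising column: the data only localise the breakpoint to that gap
  vs <- cols[x == 1L]
  kcol <- cols[obs$breakpoint]
  left <- suppressWarnings(max(vs[vs <= kcol]))
  right <- suppressWarnings(min(vs[vs > kcol]))
  bp <- if (is.finite(left) && is.finite(right)) (left + right) %/% 2L
        else kcol
  list(status = "ok", best_breakpoint = bp,
       chi2_max = obs$chi2, p = perm_p(obs$chi2, null))
}

#' Chimaera recombination scan for a recombinant/parent triplet
#'
#' Restricts to parent-informative sites (where the two putative parents
#' differ), encodes the recombinant as a binary match-to-parent-A vector,
#' maximises the 2x2 chi-square over breakpoints and assigns a permutation
#' p-value by shuffling the binary vector.
#'
#' @param recombinant,parentA,parentB equal-length aligned sequences; parents
#'   must differ at >= 4 sites.
#' @param n_permutations,seed permutation settings.
#' @return list: `status`, `breakpoint_col` (alignment column of the last
#'   informative site in the left segment), `breakpoint_idx` (its index among
#'   informative sites), `stat`, `p`.
#' @export
chimaera_scan <- function(recombinant, parentA, parentB,
                          n_permutations = 1000L, seed = 1L) {
  if (length(unique(nchar(c(recombinant, parentA, parentB)))) != 1L)
    stop("triplet must be aligned to equal length")
  r <- strsplit(recombinant, "")[[1]]
  a <- strsplit(parentA, "")[[1]]
  b <- strsplit(parentB, "")[[1]]
  acgt <- c("A", "C", "G", "T")
  inf <- which(a != b & a %in% acgt & b %in% acgt & r %in% acgt)
  inf <- inf[r[inf] == a[inf] | r[inf] == b[inf]]
  if (length(inf) < 4L || sum(r[inf] == a[inf]) < 1L || sum(r[inf] == b[inf]) < 1L)
    return(list(status = "untestable", breakpoint_col = NA_integer_,
                breakpoint_idx = NA_integer_, stat = NA_real_, p = NA_real_))
  x <- as.integer(r[inf] == a[inf])
  obs <- max_breakpoint_chi2(x)
  null <- null_max_chi2(length(x), sum(x), n_permutations, seed)
  list(status = "ok", breakpoint_col = inf[obs$breakpoint],
       breakpoint_idx = obs$breakpoint, stat = obs$chi2,
       p = perm_p(obs$chi2, null))
}

# Refined incompatibility score of a site pair: minimum number of extra
# homoplasies implied jointly, computed from the bipartite graph of observed
# joint states (k joint states, a and b marginal states, c connected
# components): score = max(0, k - a - b + c).
pair_incompatibility <- function(si, sj) {
  ok <- si %in% c("A", "C", "G", "T") & sj %in% c("A", "C", "G", "T")
  si <- si[ok]; sj <- sj[ok]
  if (!length(si)) return(0)
  joint <- unique(paste(si, sj))
  a <- length(unique(si)); b <- length(unique(sj)); k <- length(joint)
  # connected components of the bipartite state graph
  left <- sub(" .*", "", joint); right <- sub(".* ", "", joint)
  comp <- seq_along(joint)
  repeat {
    changed <- FALSE
    for (i in seq_along(joint)) {
      link <- which(left == left[i] | right == right[i])
      m <- min(comp[link])
      if (any(comp[link] != m)) { comp[link] <- m; changed <- TRUE }
    }
    if (!changed) break
  }
  cc <- length(unique(comp))
  max(0, k - a - b + cc)
}

#' Pairwise homoplasy (PHI) test for recombination
#'
#' Mean refined incompatibility over pairs of nearby parsimony-informative
#' sites; the permutation null shuffles site order, destroying the
#' distance structure that recombination induces (nearby sites more
#' compatible than distant ones). One-sided: small observed statistic is
#' evidence for recombination.
#'
#' @param sequences character vector (>= 4, equal length).
#' @param window maximum distance in alignment columns between paired sites
#'   (default 100).
#' @param n_permutations,seed permutation settings.
#' @return list: `status`, `statistic`, `p`.
#' @export
phi_test <- function(sequences, window = 100L, n_permutations = 1000L,
                     seed = 1L) {
  if (length(sequences) < 4L) stop("need at least 4 sequences")
  M <- seq_matrix(sequences)
  informative <- which(apply(M, 2, function(col) {
    col <- col[col %in% c("A", "C", "G", "T")]
    sum(table(col) >= 2L) >= 2L
  }))
  if (length(informative) < 2L)
    return(list(status = "untestable", statistic = NA_real_, p = NA_real_))
  cols <- lapply(informative, function(j) M[, j])
  ni <- length(informative)
  idx <- utils::combn(ni, 2L)
  pi_ <- idx[1, ]; pj_ <- idx[2, ]
  scorevec <- vapply(seq_len(ncol(idx)), function(q)
    pair_incompatibility(cols[[pi_[q]]], cols[[pj_[q]]]), numeric(1))
  mean_near <- function(pos) {
    sel <- abs(pos[pi_] - pos[pj_]) <= window
    if (!any(sel)) NA_real_ else mean(scorevec[sel])
  }
  obs <- mean_near(informative)
  if (is.na(obs))
    return(list(status = "untestable", statistic = NA_real_, p = NA_real_))
  set.seed(seed)
  null <- numeric(n_permutations)
  for (r in seq_len(n_permutations))
    null[r] <- mean_near(sample(informative))
  p <- (1 + sum(null <= obs, na.rm = TRUE)) / (n_permutations + 1)
  list(status = "ok", statistic = obs, p = p)
}

#' Consensus over recombination tests
#'
#' Partitions candidate events into consensus (significant in at least `k`
#' enabled tests) and sub-threshold (reported with their test tally).
#'
#' @param p_values data.frame or named list: one row/element per event, one
#'   p-value per test (NA = untestable).
#' @param k consensus threshold.
#' @param alpha significance level.
#' @return list: `consensus` (logical per event), `tally` (significant-test
#'   counts), `n_tests`.
#' @export
consensus_events <- function(p_values, k = 2L, alpha = 0.05) {
  P <- as.matrix(as.data.frame(p_values))
  if (k > ncol(P)) stop("consensus k cannot exceed the number of tests")
  sig <- !is.na(P) & P < alpha
  tally <- rowSums(sig)
  list(consensus = tally >= k, tally = tally, n_tests = ncol(P))
}

#' Scan an allele set for recombination events
#'
#' Runs Chimaera triplet scans for each candidate recombinant against parent
#' pairs drawn from the most frequent alleles, MaxChi on the implicated
#' pairs, and the alignment-wide PHI test, then applies the k-of-m consensus.
#' Scans are restricted to the `top` most frequent alleles by default.
#'
#' @param sequences named character vector of aligned alleles.
#' @param counts optional abundance used to rank alleles (default: input
#'   order).
#' @param top number of most frequent alleles scanned (default 50).
#' @param n_permutations,seed permutation settings.
#' @param k,alpha consensus parameters (default 2 of the 3 in-repo tests).
#' @return list: `events` data.frame (recombinant, parent_a, parent_b,
#'   breakpoint, p_chimaera, p_maxchi, p_phi, tally, consensus), `phi`
#'   (alignment-wide PHI result).
#' @export
scan_recombination <- function(sequences, counts = NULL, top = 50L,
                               n_permutations = 200L, seed = 1L,
                               k = 2L, alpha = 0.05) {
  if (is.null(names(sequences)))
    names(sequences) <- sprintf("t%03d", seq_along(sequences))
  ord <- if (is.null(counts)) seq_along(sequences) else order(-counts)
  sel <- sequences[ord[seq_len(min(top, length(sequences)))]]
  phi <- if (length(sel) >= 4L)
    phi_test(sel, n_permutations = n_permutations,
             seed = derive_seed(seed, "phi"))
  else list(status = "untestable", statistic = NA_real_, p = NA_real_)
  events <- list()
  nm <- names(sel)
  for (ri in seq_along(sel)) {
    others <- setdiff(seq_along(sel), ri)
    if (length(others) < 2L) next
    best <- NULL
    for (pp in utils::combn(others, 2L, simplify = FALSE)) {
      ch <- chimaera_scan(sel[ri], sel[pp[1]], sel[pp[2]],
                          n_permutations = n_permutations,
                          seed = derive_seed(seed, "chimaera"))
      if (ch$status != "ok") next
      if (is.null(best) || ch$p < best$ch$p)
        best <- list(ch = ch, pp = pp)
    }
    if (is.null(best)) next
    mc <- maxchi_scan(sel[best$pp[1]], sel[ri],
                      n_permutations = n_permutations,
                      seed = derive_seed(seed, "maxchi"))
    events[[length(events) + 1L]] <- data.frame(
      recombinant = nm[ri], parent_a = nm[best$pp[1]],
      parent_b = nm[best$pp[2]], breakpoint = best$ch$breakpoint_col,
      p_chimaera = best$ch$p, p_maxchi = mc$p, p_phi = phi$p,
      stringsAsFactors = FALSE)
  }
  events <- do.call(rbind, events) %||%
    data.frame(recombinant = character(0), parent_a = character(0),
               parent_b = character(0), breakpoint = integer(0),
               p_chimaera = numeric(0), p_maxchi = numeric(0),
               p_phi = numeric(0))
  if (nrow(events)) {
    cons <- consensus_events(events[, c("p_chimaera", "p_maxchi", "p_phi")],
                             k = k, alpha = alpha)
    events$tally <- cons$tally
    events$consensus <- cons$consensus
  } else {
    events$tally <- integer(0); events$consensus <- logical(0)
  }
  list(events = events, phi = phi)
}
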