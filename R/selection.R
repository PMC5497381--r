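# Site-wise positive-selection detection: neighbor-joining tree, parsimony
# ancestral codon states, Nei-Gojobori pathway counting of synonymous and
# nonsynonymous changes per codon site, a counting (binomial-tail) test and a
# likelihood-ratio test on the same sufficient counts, a configurable k-of-m
# consensus rule, and the subsampling randomization comparing allele classes.

#' Neighbor-joining tree from a sequence set
#'
#' Standard neighbor joining on p-distances or K2P distances; negative branch
#' lengths are clamped to zero.
#'
#' @param sequences named character vector (>= 3, equal length); names are
#'   taxa labels and must be unique.
#' @param model `"p"` (default) or `"k2p"`.
#' @return an [ape::phylo] tree.
#' @export
build_tree <- function(sequences, model = c("p", "k2p")) {
  model <- match.arg(model)
  if (length(sequences) < 3L) stop("need at least 3 sequences")
  if (is.null(names(sequences)))
    names(sequences) <- sprintf("t%03d", seq_along(sequences))
  if (anyDuplicated(names(sequences))) stop("duplicate taxa labels")
  d <- if (length(unique(sequences)) < 2L)
    matrix(0, length(sequences), length(sequences))
  else if (model == "p") p_distance(sequences, "nt")$matrix
  else k2p_gamma_distance(sequences, gamma_shape = Inf)
  dimnames(d) <- list(names(sequences), names(sequences))
  tr <- ape::nj(as.dist(d))
  tr$edge.length <- pmax(tr$edge.length, 0)
  tr
}

# Fitch parsimony ancestral codon states and pathway-averaged substitution
# counts per codon site. Returns data.frame(site, n, s, f): site is the
# 0-based codon index, n and s the inferred nonsynonymous and synonymous
# change counts over all edges, f the Nei-Gojobori potential nonsynonymous
# fraction of the observed codons at the site.
site_substitution_counts <- function(sequences, tree) {
  stopifnot(!is.null(names(sequences)))
  sequences <- sequences[tree$tip.label]
  if (anyNA(sequences)) stop("alignment is missing tree tips")
  L <- unique(nchar(sequences))
  if (length(L) != 1L) stop("sequences must be aligned to equal length")
  nsite <- L %/% 3L
  ntip <- length(sequences)
  tab <- codon_tables()

  po <- ape::reorder.phylo(tree, "postorder")$edge
  parents_in_order <- unique(po[, 1])
  children <- split(po[, 2], factor(po[, 1], levels = parents_in_order))
  root <- parents_in_order[length(parents_in_order)]
  nnode <- ntip + tree$Nnode

  codmat <- matrix("", ntip, nsite)
  for (i in seq_len(ntip)) codmat[i, ] <- split_codons(sequences[i])

  out <- data.frame(site = seq_len(nsite) - 1L, n = 0, s = 0, f = NA_real_)
  for (site in seq_len(nsite)) {
    tipcod <- codmat[, site]
    out$f[site] <- mean(tab$ng_frac[tipcod], na.rm = TRUE)
    if (length(unique(tipcod)) == 1L) next
    sets <- vector("list", nnode)
    for (i in seq_len(ntip)) sets[[i]] <- tipcod[i]
    for (pa in parents_in_order) {
      kid_sets <- sets[children[[as.character(pa)]]]
      inter <- Reduce(intersect, kid_sets)
      sets[[pa]] <- if (length(inter)) inter else
        sort(unique(unlist(kid_sets)))
    }
    state <- character(nnode)
    state[root] <- min(sets[[root]])
    for (e in rev(seq_len(nrow(po)))) {
      pa <- po[e, 1]; ch <- po[e, 2]
      state[ch] <- if (state[pa] %in% sets[[ch]]) state[pa] else min(sets[[ch]])
    }
    n <- 0; s <- 0
    for (e in seq_len(nrow(po))) {
      a <- state[po[e, 1]]; b <- state[po[e, 2]]
      if (a != b) {
        cnt <- codon_path_counts(a, b)
        n <- n + cnt[["n"]]; s <- s + cnt[["s"]]
      }
    }
    out$n[site] <- n; out$s[site] <- s
  }
  out
}

#' Counting site test for positive selection
#'
#' Parsimony-inferred nonsynonymous (n) and synonymous (s) change counts per
#' codon site are compared against the Nei-Gojobori expected nonsynonymous
#' fraction f of that site's codons: the p-value is the binomial tail
#' probability of the observed count in the observed direction, and a site is
#' called positively selected when n/(n+s) > f with p below `alpha`. Sites
#' with zero inferred changes get p = 1.
#'
#' @param sequences named codon alignment (no in-frame stops).
#' @param tree phylogeny from [build_tree()]; built on the fly when NULL.
#' @param alpha significance level.
#' @param counts optional precomputed [site_substitution_counts()] output.
#' @return data.frame: site (0-based codon), n, s, f, dn_minus_ds sign,
#'   p, positive.
#' @export
counting_site_test <- function(sequences, tree = NULL, alpha = 0.05,
                               counts = NULL) {
  if (is.null(counts)) {
    if (is.null(tree)) tree <- build_tree(sequences)
    counts <- site_substitution_counts(sequences, tree)
  }
  res <- counts
  c_tot <- res$n + res$s
  k <- pmin(round(res$n), round(c_tot))
  ci <- round(c_tot)
  p <- rep(1, nrow(res))
  up <- ci > 0 & res$n / pmax(c_tot, 1e-12) > res$f
  dn <- ci > 0 & !up
  p[up] <- pbinom(k[up] - 1L, ci[up], res$f[up], lower.tail = FALSE)
  p[dn] <- pbinom(k[dn], ci[dn], res$f[dn])
  res$dn_minus_ds <- sign(res$n / pmax(c_tot, 1e-12) - res$f)
  res$dn_minus_ds[ci == 0] <- 0
  res$p <- pmin(1, p)
  res$positive <- ci > 0 & res$dn_minus_ds > 0 & res$p < alpha
  res$test <- "counting"
  res
}

#' Likelihood-ratio site test for positive selection
#'
#' Per site, a two-rate model (synonymous rate alpha_s, nonsynonymous rate
#' beta_s) is fitted by maximum likelihood to the parsimony-inferred
#' substitution counts with Nei-Gojobori mutational-opportunity exposures,
#' and the constrained model beta_s = alpha_s is compared by a likelihood
#' ratio test against chi-squared with one degree of freedom. A site is
#' called positively selected when beta_s > alpha_s with p below `alpha`.
#' Invariant sites have statistic 0 and p = 1.
#'
#' @inheritParams counting_site_test
#' @return data.frame: site, n, s, f, dn_minus_ds, lrt, p, positive.
#' @export
likelihood_site_test <- function(sequences, tree = NULL, alpha = 0.05,
                                 counts = NULL) {
  if (is.null(counts)) {
    if (is.null(tree)) tree <- build_tree(sequences)
    counts <- site_substitution_counts(sequences, tree)
  }
  res <- counts
  c_tot <- res$n + res$s
  xlogx <- function(x, e) ifelse(x > 0, x * log(x / e), 0)
  lrt <- 2 * (xlogx(res$n, c_tot * res$f) +
                xlogx(res$s, c_tot * (1 - res$f)))
  lrt[c_tot == 0] <- 0
  lrt <- pmax(lrt, 0)
  res$dn_minus_ds <- sign(res$n / pmax(c_tot, 1e-12) - res$f)
  res$dn_minus_ds[c_tot == 0] <- 0
  res$lrt <- lrt
  res$p <- ifelse(c_tot == 0, 1, pchisq(lrt, df = 1, lower.tail = FALSE))
  res$positive <- c_tot > 0 & res$dn_minus_ds > 0 & res$p < alpha
  res$test <- "likelihood"
  res
}

#' k-of-m consensus of site-wise selection tests
#'
#' A site is a consensus positively selected site (PSS) when it is called
#' positive in at least `k` of the `m` enabled tests.
#'
#' @param results list of per-test data.frames (each with `site` and
#'   `positive`).
#' @param k consensus threshold; defaults to all enabled tests.
#' @return integer vector of consensus PSS sites (0-based codon indices).
#' @export
consensus_pss <- function(results, k = length(results)) {
  m <- length(results)
  if (m < 1L) stop("at least one test must be enabled")
  if (k > m) stop("consensus k cannot exceed the number of enabled tests")
  sites <- results[[1]]$site
  votes <- Reduce(`+`, lapply(results, function(r)
    as.integer(r$positive[match(sites, r$site)])))
  sort(sites[votes >= k])
}

#' Run the site-selection consensus analysis on one allele set
#'
#' Excludes stop-containing alleles, builds the NJ tree, runs the enabled
#' tests on shared substitution counts and applies the k-of-m consensus.
#'
#' @param sequences named character vector of alleles (equal length).
#' @param tests subset of `c("counting", "likelihood")`.
#' @param k consensus threshold (default: all enabled).
#' @param alpha significance level.
#' @param tree optional prebuilt tree.
#' @return list: `results` (per test), `consensus_sites`, `counts`,
#'   `n_sequences_used`.
#' @export
site_selection <- function(sequences, tests = c("counting", "likelihood"),
                           k = length(tests), alpha = 0.05, tree = NULL) {
  tests <- match.arg(tests, several.ok = TRUE)
  has_stop <- grepl("*", translate_nt(sequences), fixed = TRUE)
  if (any(has_stop)) {
    warning(sum(has_stop), " stop-containing sequences excluded from selection input")
    sequences <- sequences[!has_stop]
  }
  if (length(sequences) < 3L) stop("need at least 3 stop-free sequences")
  if (is.null(names(sequences)))
    names(sequences) <- sprintf("t%03d", seq_along(sequences))
  if (is.null(tree)) tree <- build_tree(sequences)
  counts <- site_substitution_counts(sequences, tree)
  results <- list()
  if ("counting" %in% tests)
    results$counting <- counting_site_test(sequences, tree, alpha, counts)
  if ("likelihood" %in% tests)
    results$likelihood <- likelihood_site_test(sequences, tree, alpha, counts)
  list(results = results, consensus_sites = consensus_pss(results, k),
       counts = counts, n_sequences_used = length(sequences))
}

#' Subsampling randomization of a single site test
#'
#' Repeatedly subsamples `subset_size` alleles without replacement, runs the
#' designated single test on each subsample and records the number of
#' positive sites, yielding the distribution used to compare allele classes
#' at matched sample size.
#'
#' @param sequences named character vector of alleles.
#' @param subset_size alleles per draw (default 47).
#' @param n_reps number of randomized draws (default 100).
#' @param test `"counting"` (default) or `"likelihood"`.
#' @param seed integer seed.
#' @param alpha significance level.
#' @return object of class `mhc_subsample`: `pss_counts` (length `n_reps`),
#'   `subset_size`, `n_reps`, `test`, `seed`.
#' @export
subsample_selection <- function(sequences, subset_size = 47L, n_reps = 100L,
                                test = c("counting", "likelihood"),
                                seed = 1L, alpha = 0.05) {
  test <- match.arg(test)
  if (subset_size > length(sequences))
    stop("subset_size exceeds the number of sequences")
  if (is.null(names(sequences)))
    names(sequences) <- sprintf("t%03d", seq_along(sequences))
  set.seed(seed)
  testfun <- if (test == "counting") counting_site_test else likelihood_site_test
  pss <- integer(n_reps)
  for (r in seq_len(n_reps)) {
    sub <- sequences[sample.int(length(sequences), subset_size)]
    if (length(unique(sub)) < 3L) { pss[r] <- 0L; next }
    res <- testfun(sub, tree = build_tree(sub), alpha = alpha)
    pss[r] <- sum(res$positive)
  }
  structure(list(pss_counts = pss, subset_size = subset_size,
                 n_reps = n_reps, test = test, seed = seed),
            class = "mhc_subsample")
}
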