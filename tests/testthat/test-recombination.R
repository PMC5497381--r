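# Parents with evenly spaced differences give scans a known mosaic geometry.
make_parents <- function(L = 241, spacing = 3, seed = 5) {
  set.seed(seed)
  A <- rand_seq(L)
  dpos <- seq(3, L - 3, by = spacing)
  B <- mutate_at(A, dpos)
  list(A = A, B = B, dpos = dpos)
}

test_that("maxchi flags a clean mosaic with an accurate breakpoint", {
  p <- make_parents()
  k <- 120
  rec <- paste0(substr(p$A, 1, k), substr(p$B, k + 1, nchar(p$B)))
  res <- maxchi_scan(p$A, rec, n_permutations = 500, seed = 2)
  expect_equal(res$status, "ok")
  expect_lt(res$p, 0.01)
  expect_lte(abs(res$best_breakpoint - k), 2)
})

test_that("maxchi is untestable on (near-)identical pairs", {
  s <- rand_seq(100)
  expect_equal(maxchi_scan(s, s)$status, "untestable")
  expect_equal(maxchi_scan(s, mutate_at(s, c(5, 50, 90)))$status,
               "untestable")  # < 4 variable sites
})

test_that("maxchi permutation p-values are uniform under the null", {
  p <- make_parents()
  achars <- strsplit(p$A, "")[[1]]
  bchars <- strsplit(p$B, "")[[1]]
  ps <- vapply(1:60, function(i) {
    set.seed(1000 + i)
    pos <- sample(241, 20)
    r <- achars
    r[pos] <- vapply(achars[pos], function(x) setdiff(BASES, x)[1], "")
    maxchi_scan(p$A, paste(r, collapse = ""), n_permutations = 200,
                seed = 2000 + i)$p
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("chimaera localises simulated chimeras from the provenance log", {
  cfg <- sim_config(seed = 61, n_individuals = 4, coverage = 300,
                    chimera_rate = 0.05, error_rate = 0,
                    class_pool_sizes = c(no_del = 40, del3 = 0, del6 = 0),
                    stop_codon_fraction = 0)
  truth <- assign_genotypes(generate_allele_pool(cfg))
  sim <- simulate_reads(truth, cfg)
  pool_seq <- setNames(truth$pool$sequence, truth$pool$allele_id)
  log <- sim$log[sim$log$chimera, ]
  tested <- 0L
  for (i in seq_len(nrow(log))) {
    if (tested >= 15L) break
    pa <- pool_seq[[log$template_id[i]]]
    pb <- pool_seq[[log$parent2[i]]]
    k <- log$breakpoint[i]
    inf <- which(strsplit(pa, "")[[1]] != strsplit(pb, "")[[1]])
    if (sum(inf <= k) < 3L || sum(inf > k) < 3L) next
    rec <- paste0(substr(pa, 1, k), substr(pb, k + 1, nchar(pb)))
    res <- chimaera_scan(rec, pa, pb, n_permutations = 500,
                         seed = 70 + i)
    expect_equal(res$status, "ok")
    expect_lt(res$p, 0.01)
    true_idx <- sum(inf <= k)
    expect_lte(abs(res$breakpoint_idx - true_idx), 2)
    tested <- tested + 1L
  }
  expect_gte(tested, 5L)
})

test_that("chimaera null constructions keep type-I error in check", {
  cfg <- sim_config(seed = 67, class_pool_sizes = c(no_del = 30, del3 = 0,
                                                    del6 = 0),
                    stop_codon_fraction = 0)
  pool <- generate_allele_pool(cfg)$pool$sequence
  fp <- 0L; n <- 100L
  for (i in seq_len(n)) {
    set.seed(500 + i)
    pair <- sample(30, 2)
    pa <- pool[pair[1]]; pb <- pool[pair[2]]
    d <- which(strsplit(pa, "")[[1]] != strsplit(pb, "")[[1]])
    r <- strsplit(pa, "")[[1]]
    pick <- d[runif(length(d)) < 0.5]
    r[pick] <- strsplit(pb, "")[[1]][pick]
    res <- chimaera_scan(paste(r, collapse = ""), pa, pb,
                         n_permutations = 200, seed = 600 + i)
    if (!is.na(res$p) && res$p < 0.05) fp <- fp + 1L
  }
  expect_lte(fp / n, 1.5 * 0.05)
})

test_that("a recombinant identical to one parent is untestable, not flagged", {
  p <- make_parents()
  res <- chimaera_scan(p$A, p$A, p$B)
  expect_equal(res$status, "untestable")
})

test_that("phi separates clonal from mosaic alignments with bounded p", {
  cfg <- sim_config(seed = 71, class_pool_sizes = c(no_del = 30, del3 = 0,
                                                    del6 = 0),
                    stop_codon_fraction = 0)
  pool <- generate_allele_pool(cfg)$pool$sequence
  clonal <- setNames(pool[1:10], paste0("c", 1:10))
  res_c <- phi_test(clonal, n_permutations = 200, seed = 3)
  expect_gte(res_c$p, 1 / 201)             # bounded below, never zero
  set.seed(73)
  mosa <- vapply(1:14, function(i) {
    k <- sample(60:180, 1)
    paste0(substr(pool[sample(30, 1)], 1, k),
           substr(pool[sample(30, 1)], k + 1, 241))
  }, "")
  res_m <- phi_test(setNames(mosa, paste0("m", 1:14)),
                    n_permutations = 400, seed = 3)
  expect_lt(res_m$p, 0.01)
  expect_gte(res_m$p, 1 / 401)
  expect_error(phi_test(pool[1:3]), "at least 4")
})

test_that("consensus events are partitioned by the k-of-m rule", {
  P <- data.frame(maxchi = c(0.01, 0.01, 0.2),
                  chimaera = c(0.02, 0.03, 0.3),
                  phi = c(0.9, 0.01, 0.4))
  res <- consensus_events(P, k = 3)
  expect_equal(res$consensus, c(FALSE, TRUE, FALSE))
  expect_equal(res$tally, c(2, 3, 0))
  res2 <- consensus_events(P, k = 2)
  expect_equal(res2$consensus, c(TRUE, TRUE, FALSE))
  expect_error(consensus_events(P, k = 4), "cannot exceed")
})

test_that("the scan driver reports chimeras among frequent alleles", {
  cfg <- sim_config(seed = 79, class_pool_sizes = c(no_del = 8, del3 = 0,
                                                    del6 = 0),
                    stop_codon_fraction = 0)
  pool <- generate_allele_pool(cfg)$pool$sequence
  k <- 120
  rec <- paste0(substr(pool[1], 1, k), substr(pool[2], k + 1, 241))
  seqs <- setNames(c(pool, rec), c(paste0("a", 1:8), "rec"))
  counts <- c(rep(100, 8), 20)
  sc <- scan_recombination(seqs, counts = counts, top = 9,
                           n_permutations = 200, seed = 5, k = 2)
  hit <- sc$events[sc$events$recombinant == "rec", ]
  expect_equal(nrow(hit), 1L)
  expect_true(hit$consensus)
  expect_setequal(c(hit$parent_a, hit$parent_b), c("a1", "a2"))
})
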