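test_that("neighbor joining recovers quartets from additive signals", {
  set.seed(41)
  for (rep in 1:10) {
    L <- 120
    base <- rand_seq(L)
    # quartet (t1,t2 | t3,t4): shared internal-edge differences plus
    # private terminal differences, all at disjoint sites (no homoplasy)
    sites <- sample(L, 50)
    grp <- split(sites, rep(1:5, each = 10))
    t1 <- mutate_at(base, grp[[2]])
    t2 <- mutate_at(base, grp[[3]])
    t3 <- mutate_at(mutate_at(base, grp[[1]]), grp[[4]])
    t4 <- mutate_at(mutate_at(base, grp[[1]]), grp[[5]])
    tr <- build_tree(c(t1 = t1, t2 = t2, t3 = t3, t4 = t4))
    parts <- ape::prop.part(ape::unroot(tr))
    labs <- lapply(parts, function(p) sort(attr(parts, "labels")[p]))
    has <- function(x) any(vapply(labs, identical, logical(1), x))
    expect_true(has(c("t1", "t2")) || has(c("t3", "t4")))
  }
})

test_that("tree construction handles edge cases", {
  s <- rand_seqs(3, 30)
  expect_s3_class(build_tree(setNames(s, c("a", "b", "c"))), "phylo")
  expect_error(build_tree(setNames(s, c("a", "a", "b"))), "duplicate")
  expect_error(build_tree(s[1:2]), "at least 3")
  ident <- build_tree(setNames(rep(rand_seq(30), 4), letters[1:4]))
  expect_true(all(ident$edge.length == 0))
})

test_that("counting test follows the binomial tail on supplied counts", {
  # invariant site: no changes, p = 1, never positive
  inv <- counting_site_test(counts = data.frame(site = 0, n = 0, s = 0,
                                                f = 0.7))
  expect_equal(inv$p, 1)
  expect_false(inv$positive)
  # 10 nonsynonymous changes out of 10 at f = 0.7: tail 0.7^10 = 0.028
  hot <- counting_site_test(counts = data.frame(site = 0, n = 10, s = 0,
                                                f = 0.7))
  expect_equal(hot$p, 0.7^10, tolerance = 1e-12)
  expect_true(hot$positive)
  expect_equal(hot$dn_minus_ds, 1)
  # deficit direction is never a positive call
  cold <- counting_site_test(counts = data.frame(site = 0, n = 0, s = 10,
                                                 f = 0.7))
  expect_false(cold$positive)
  expect_equal(cold$dn_minus_ds, -1)
})

test_that("likelihood-ratio test matches its closed form and direction rule", {
  inv <- likelihood_site_test(counts = data.frame(site = 0, n = 0, s = 0,
                                                  f = 0.7))
  expect_equal(inv$lrt, 0)
  expect_equal(inv$p, 1)
  n <- 12; s <- 2; f <- 0.7; ct <- n + s
  res <- likelihood_site_test(counts = data.frame(site = 0, n = n, s = s,
                                                  f = f))
  g_manual <- 2 * (n * log(n / (ct * f)) + s * log(s / (ct * (1 - f))))
  expect_equal(res$lrt, g_manual, tolerance = 1e-12)
  expect_equal(res$p, pchisq(g_manual, 1, lower.tail = FALSE))
})

test_that("consensus is k-of-m and monotone non-increasing in k", {
  r1 <- data.frame(site = 0:4, positive = c(TRUE, TRUE, FALSE, FALSE, TRUE))
  r2 <- data.frame(site = 0:4, positive = c(TRUE, FALSE, FALSE, TRUE, TRUE))
  expect_equal(consensus_pss(list(r1, r2), k = 2), c(0L, 4L))
  expect_equal(consensus_pss(list(r1, r2), k = 1), c(0L, 1L, 3L, 4L))
  expect_error(consensus_pss(list(r1, r2), k = 3), "cannot exceed")
  sets <- lapply(1:2, function(k) consensus_pss(list(r1, r2), k = k))
  expect_true(all(sets[[2]] %in% sets[[1]]))
})

test_that("site tests are calibrated under neutral simulation", {
  fp_c <- 0; fp_l <- 0; nsites <- 0
  for (s in 1:2) {
    cfg <- sim_config(seed = 300 + s,
                      class_pool_sizes = c(no_del = 50, del3 = 0, del6 = 0),
                      pss_sites = list(no_del = integer(0), del3 = integer(0),
                                       del6 = integer(0)),
                      stop_codon_fraction = 0)
    pool <- generate_allele_pool(cfg)$pool
    seqs <- setNames(pool$sequence, pool$allele_id)
    sel <- site_selection(seqs)
    fp_c <- fp_c + sum(sel$results$counting$positive)
    fp_l <- fp_l + sum(sel$results$likelihood$positive)
    nsites <- nsites + nrow(sel$counts)
  }
  expect_lte(fp_c / nsites, 1.6 * 0.05)
  expect_lte(fp_l / nsites, 1.6 * 0.05)
})

test_that("strongly selected sites are recovered and tests agree", {
  planted <- c(5L, 13L, 21L, 37L, 52L, 68L)
  cfg <- sim_config(seed = 44,
                    class_pool_sizes = c(no_del = 60, del3 = 0, del6 = 0),
                    pss_sites = list(no_del = planted, del3 = integer(0),
                                     del6 = integer(0)),
                    omega_background = 0.2, omega_pss = 5,
                    stop_codon_fraction = 0)
  pool <- generate_allele_pool(cfg)$pool
  seqs <- setNames(pool$sequence, pool$allele_id)
  sel <- site_selection(seqs)
  hits_c <- sel$results$counting$site[sel$results$counting$positive]
  hits_l <- sel$results$likelihood$site[sel$results$likelihood$positive]
  expect_gte(length(intersect(sel$consensus_sites, planted)), 3)
  # cross-test concordance on calls
  expect_gte(length(intersect(hits_c, hits_l)) /
               max(1, length(union(hits_c, hits_l))), 0.7)
})

test_that("stop-containing alleles are excluded from selection input", {
  cfg <- sim_config(seed = 50, class_pool_sizes = c(no_del = 20, del3 = 0,
                                                    del6 = 0),
                    stop_codon_fraction = 0.2)
  pool <- generate_allele_pool(cfg)$pool
  seqs <- setNames(pool$sequence, pool$allele_id)
  expect_warning(sel <- site_selection(seqs), "stop-containing")
  expect_equal(sel$n_sequences_used, sum(!pool$has_stop))
})

test_that("subsampling distributions are seeded and degenerate at full size", {
  cfg <- tiny_sim_config(seed = 53)
  pool <- generate_allele_pool(cfg)$pool
  seqs <- setNames(pool$sequence, pool$allele_id)[pool$class == "no_del"]
  full <- subsample_selection(seqs, subset_size = length(seqs), n_reps = 4,
                              seed = 1)
  expect_length(unique(full$pss_counts), 1L)   # all replicates identical
  s1 <- subsample_selection(seqs, subset_size = 10, n_reps = 6, seed = 9)
  s2 <- subsample_selection(seqs, subset_size = 10, n_reps = 6, seed = 9)
  expect_identical(s1$pss_counts, s2$pss_counts)
  expect_error(subsample_selection(seqs, subset_size = 100), "exceeds")
})
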