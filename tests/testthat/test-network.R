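test_that("K2P distances match the closed form and the ape oracle", {
  base <- strrep("ACGT", 10)
  # 4 transitions (A->G) out of 40 sites, no transversions
  ch <- strsplit(base, "")[[1]]
  ch[which(ch == "A")[1:4]] <- "G"
  pair <- c(a = base, b = paste(ch, collapse = ""))
  d <- k2p_gamma_distance(pair, gamma_shape = Inf)
  expect_equal(d["a", "b"], -0.5 * log(1 - 2 * 0.1), tolerance = 1e-9)

  set.seed(91)
  root <- rand_seq(200)
  seqs <- setNames(vapply(1:8, function(i)
    mutate_at(root, sample(200, 20)), ""), paste0("s", 1:8))
  mat <- t(vapply(seqs, function(s) strsplit(s, "")[[1]], character(200)))
  db <- ape::as.DNAbin(mat)
  for (g in c(Inf, 0.29)) {
    D1 <- k2p_gamma_distance(seqs, gamma_shape = g)
    D2 <- as.matrix(ape::dist.dna(db, model = "K80",
                                  gamma = if (is.finite(g)) g else FALSE))
    expect_equal(max(abs(D1 - D2[rownames(D1), colnames(D1)])), 0,
                 tolerance = 1e-9)
  }
})

test_that("gamma correction only increases distances; identical pairs are 0", {
  set.seed(92)
  seqs <- setNames(rand_seqs(5, 150), paste0("s", 1:5))
  plain <- k2p_gamma_distance(seqs, gamma_shape = Inf)
  gam <- k2p_gamma_distance(seqs, gamma_shape = 0.29)
  off <- upper.tri(plain)
  expect_true(all(gam[off] >= plain[off]))
  same <- k2p_gamma_distance(c(a = seqs[[1]], b = seqs[[1]]))
  expect_equal(same["a", "b"], 0)
})

test_that("saturated pairs are flagged and set to the ceiling", {
  a <- strrep("A", 60); g <- strrep("G", 60)
  D <- k2p_gamma_distance(c(x = a, y = g), saturation_ceiling = 7)
  expect_equal(D["x", "y"], 7)
  expect_equal(attr(D, "saturated")[[1]], c("x", "y"))
})

test_that("tree metrics are reproduced: splits, weights and induced distances", {
  set.seed(93)
  for (rep in 1:3) {
    tr <- ape::unroot(ape::rtree(7))
    tr$edge.length <- tr$edge.length + 0.05
    d <- ape::cophenetic.phylo(tr)
    ord <- neighbornet_ordering(d)
    net <- fit_split_weights(d, ord)
    ind <- induced_distances(net)
    t <- rownames(ind)
    expect_lt(max(abs(ind[t, t] - d[t, t])), 1e-4)
    expect_lt(net$rss, 1e-12)
    # every internal tree split appears with its branch length
    parts <- ape::prop.part(tr)
    labs <- attr(parts, "labels")
    keyfun <- function(s) paste(sort(s), collapse = "|")
    keys <- vapply(net$splits, keyfun, "")
    compl <- vapply(net$splits, function(s)
      paste(sort(setdiff(ord, s)), collapse = "|"), "")
    edge_of <- function(node) tr$edge.length[tr$edge[, 2] == node]
    for (k in seq_along(parts)[-1]) {
      key <- paste(sort(labs[parts[[k]]]), collapse = "|")
      idx <- which(keys == key | compl == key)
      expect_length(idx, 1L)
      expect_equal(net$weights[idx], edge_of(length(labs) + k),
                   tolerance = 1e-6)
    }
  }
})

test_that("the fitted split system is invariant to taxon input order", {
  set.seed(94)
  tr <- ape::unroot(ape::rtree(6))
  tr$edge.length <- tr$edge.length + 0.05
  d <- ape::cophenetic.phylo(tr)
  keyfun <- function(net) {
    keys <- vapply(seq_along(net$splits), function(k) {
      s <- net$splits[[k]]
      side <- if ("t1" %in% s) sort(setdiff(net$ordering, s)) else sort(s)
      paste(side, collapse = "|")
    }, "")
    setNames(round(net$weights, 9), keys)[order(keys)]
  }
  n1 <- fit_split_weights(d, neighbornet_ordering(d))
  perm <- sample(6)
  dp <- d[perm, perm]
  n2 <- fit_split_weights(dp, neighbornet_ordering(dp))
  expect_equal(keyfun(n1), keyfun(n2))
  expect_error(neighbornet_ordering(d[1:3, 1:3]), "at least 4")
  dbad <- d; dbad[1, 2] <- dbad[1, 2] + 1
  expect_error(neighbornet_ordering(dbad), "symmetric")
})

test_that("four equidistant taxa yield the canonical lexicographic ordering", {
  d <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(d) <- 0
  ord <- neighbornet_ordering(d)
  expect_equal(ord[1], "a")
  expect_true(ord[2] < ord[4])
})

test_that("star trees give only trivial splits; duplicates are merged", {
  n <- 5
  lens <- c(a = 0.3, b = 0.5, c = 0.2, d = 0.4, e = 0.6)
  d <- outer(lens, lens, `+`)
  diag(d) <- 0
  net <- fit_split_weights(d, neighbornet_ordering(d))
  sizes <- lengths(net$splits)
  nontrivial <- net$weights[sizes > 1 & sizes < n - 1]
  expect_true(all(nontrivial < 1e-6))
  for (tx in names(lens)) {
    idx <- which(vapply(net$splits, function(s)
      identical(s, tx) || identical(sort(setdiff(net$ordering, s)), tx),
      logical(1)))
    expect_equal(sum(net$weights[idx]), unname(lens[tx]), tolerance = 1e-6)
  }
  # duplicated taxon distances are merged and reported
  d2 <- rbind(cbind(d, f = d[, "a"]), f = c(d["a", ], 0))
  rownames(d2)[6] <- "f"
  net2 <- fit_split_weights(d2, c(neighbornet_ordering(d), "f"))
  expect_equal(net2$merged[[1]], c("a", "f"))
  expect_false("f" %in% net2$ordering)
})

test_that("a planted tight cluster attains high bootstrap support", {
  cfg <- sim_config(seed = 9, class_pool_sizes = c(no_del = 10, del3 = 5,
                                                   del6 = 0),
                    stop_codon_fraction = 0)
  truth <- generate_allele_pool(cfg)
  pool <- truth$pool
  aln <- align_to_reference(pool$sequence, truth$reference)
  names(aln) <- pool$allele_id
  net <- bootstrap_supports(aln, n_replicates = 60, seed = 4)
  expect_true(all(net$supports >= 0 & net$supports <= 100))
  d3 <- sort(pool$allele_id[pool$class == "del3"])
  idx <- which(vapply(seq_along(net$splits), function(k)
    identical(sort(net$splits[[k]]), d3) ||
      identical(sort(setdiff(net$ordering, net$splits[[k]])), d3),
    logical(1)))
  expect_length(idx, 1L)
  expect_gt(net$supports[idx], 90)
  # display filter is presentation-only
  expect_true(all(net$display >= 70))
})

test_that("bootstrap supports are reproducible under a fixed seed", {
  set.seed(95)
  seqs <- setNames(rand_seqs(6, 120), paste0("s", 1:6))
  n1 <- bootstrap_supports(seqs, n_replicates = 20, seed = 8)
  n2 <- bootstrap_supports(seqs, n_replicates = 20, seed = 8)
  expect_identical(n1$supports, n2$supports)
  expect_error(bootstrap_supports(seqs, n_replicates = 0), "n_replicates")
})

test_that("NEXUS output carries taxa, cycle and splits blocks", {
  set.seed(96)
  seqs <- setNames(rand_seqs(5, 100), paste0("s", 1:5))
  net <- neighbor_net(seqs)
  path <- tempfile(fileext = ".nex")
  write_nexus_splits(net, path, d = k2p_gamma_distance(seqs))
  txt <- readLines(path)
  expect_equal(txt[1], "#NEXUS")
  expect_true(any(grepl("BEGIN Taxa;", txt)))
  expect_true(any(grepl("BEGIN Distances;", txt)))
  expect_true(any(grepl("BEGIN Splits;", txt)))
  expect_true(any(grepl("CYCLE", txt)))
  unlink(path)
})
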