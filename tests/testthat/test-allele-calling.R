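test_that("low-copy filter retains exactly variants at or above threshold", {
  tab <- vt(c("AAAA", "CCCC"), c(100, 9))
  out <- filter_low_copy(tab)
  expect_equal(out$sequence, "AAAA")
  expect_equal(filter_low_copy(vt("AAAA", 10))$count, 10L)  # boundary kept
  expect_equal(nrow(filter_low_copy(vt(character(0), integer(0)))), 0L)
  expect_error(filter_low_copy(tab, min_copies = 0), "min_copies")
})

test_that("chimera flagging finds single-breakpoint mosaics only", {
  set.seed(21)
  A <- rand_seq(100)
  B <- mutate_at(A, c(10, 20, 60, 70))
  V <- mutate_at(A, c(60, 70))          # = A on {10,20}, = B on {60,70}
  res <- flag_chimeras(vt(c(A, B, V), c(500, 400, 50)))
  expect_equal(res$flagged$sequence, V)
  expect_true(res$flagged$breakpoint >= 20 && res$flagged$breakpoint < 60)
  expect_false(V %in% res$retained$sequence)

  # interleaved pattern: no single breakpoint exists
  W <- mutate_at(A, c(20, 70))          # = A on {10,60}, = B on {20,70}
  res2 <- flag_chimeras(vt(c(A, B, W), c(500, 400, 50)))
  expect_equal(nrow(res2$flagged), 0L)

  # a chimera at least as abundant as a parent is not flagged
  res3 <- flag_chimeras(vt(c(A, B, V), c(500, 50, 400)))
  expect_equal(nrow(res3$flagged), 0L)
})

test_that("error collapse removes 1-2 bp satellites of more abundant variants", {
  A <- rand_seq(80)
  A1 <- mutate_at(A, 5)
  out <- collapse_errors(vt(c(A, A1), c(1000, 30)))
  expect_equal(out$retained$sequence, A)
  expect_equal(out$removed$parent, A)

  B <- mutate_at(A, c(5, 20, 40))       # distance 3: both retained
  out2 <- collapse_errors(vt(c(A, B), c(1000, 900)))
  expect_equal(nrow(out2$retained), 2L)

  # equal counts: strictly-more-abundant requirement keeps both
  out3 <- collapse_errors(vt(c(A, A1), c(100, 100)))
  expect_equal(nrow(out3$retained), 2L)

  # 1-base indel artifacts are caught too (edit distance, not Hamming)
  Adel <- paste0(substr(A, 1, 39), substr(A, 41, 80))
  out4 <- collapse_errors(vt(c(A, Adel), c(1000, 20)))
  expect_equal(out4$retained$sequence, A)
})

test_that("the composed filter chain is contractive and idempotent", {
  set.seed(33)
  for (rep in 1:5) {
    seqs <- rand_seqs(8, 60)
    tab <- vt(seqs, sample(c(5:15, 100:150), 8))
    f1 <- apply_artifact_filters(tab)
    expect_true(all(f1$retained$sequence %in% tab$sequence))
    f2 <- apply_artifact_filters(f1$retained)
    expect_equal(f2$retained$sequence, f1$retained$sequence)
    expect_equal(f2$retained$count, f1$retained$count)
  }
})

test_that("replicate verification requires presence in all replicates", {
  A <- rand_seq(30); B <- rand_seq(30)
  t1 <- vt(c(A, B), c(12, 20)); t2 <- vt(A, 48)
  res <- verify_replicates(list(r1 = t1, r2 = t2))
  expect_equal(res$status, "scored")
  expect_equal(res$verified, A)
  expect_equal(unname(res$support[A, ]), c(12, 48))

  # missing replicate: unscored, never silently passed
  res2 <- verify_replicates(list(r1 = t1), min_replicates = 2)
  expect_equal(res2$status, "unscored")

  # configurable r-of-n
  res3 <- verify_replicates(list(r1 = t1, r2 = t2, r3 = vt(B, 15)),
                            min_replicates = 2)
  expect_setequal(res3$verified, c(A, B))
})

test_that("expression classification splits transcribed / gdna_only / cdna_only", {
  a <- "ATGAAACCC"; b <- "ATGCCCAAA"; cc <- "ATGGGGAAA"; d <- "ATGTTTAAA"
  res <- classify_expression(gdna = c(a, b, cc), cdna = c(a, b, d),
                             frame_mod = 0)
  expect_equal(res$expression[res$sequence == a], "transcribed")
  expect_equal(res$expression[res$sequence == cc], "gdna_only")
  expect_equal(res$expression[res$sequence == d], "cdna_only")
  # per-individual transcribed fraction 2/3 of gDNA alleles
  expect_equal(sum(res$expression == "transcribed") /
                 sum(res$expression != "cdna_only"), 2 / 3)
})

test_that("ORF status detects stop codons and frame-breaking lengths", {
  stopper <- paste0("ATGTAA", "CCC", "A")       # TAA in frame, length 3k+1
  res <- classify_expression(gdna = stopper, frame_mod = 1)
  expect_equal(res$orf_status, "stop_codon")
  shifted <- paste0("ATGAAA", "CC")              # length 8: no in-frame reading
  res2 <- classify_expression(gdna = shifted, frame_mod = 1)
  expect_equal(res2$orf_status, "frameshift")
  clean <- paste0("ATGAAACCC", "G")
  expect_equal(classify_expression(gdna = clean)$orf_status, "orf")
})

test_that("mean transcribed fraction reproduces per-individual averaging", {
  expect_equal(mean_transcribed_fraction(c(10, 20), c(5, 10)), 50)
  expect_error(mean_transcribed_fraction(c(10, 0), c(5, 0)))
})

test_that("zero-noise genotyping recovers the truth exactly end to end", {
  out <- run_genotyping(tiny_sim_config(seed = 7))
  expect_equal(unname(out$scores), c(1, 1))
  # replicate-verified set equals the truth genotype per individual
  g <- out$calls$calls[out$calls$calls$expression != "cdna_only", ]
  for (ind in unique(out$truth$genotypes$individual_id)) {
    ids <- out$truth$genotypes$allele_id[
      out$truth$genotypes$individual_id == ind]
    tru <- sort(out$truth$pool$sequence[match(ids, out$truth$pool$allele_id)])
    expect_equal(sort(unique(g$sequence[g$individual_id == ind])), tru)
  }
})

test_that("transcribed calls match the simulated transcription flags", {
  out <- run_genotyping(tiny_sim_config(seed = 19))
  g <- out$calls$calls
  truth <- out$truth
  tr_seq <- truth$pool$sequence[truth$pool$transcribed]
  called_tr <- unique(g$sequence[g$expression == "transcribed"])
  expect_true(all(called_tr %in% tr_seq))
})
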