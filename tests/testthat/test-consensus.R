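test_that("match score reproduces the forced default-weight cases", {
  expect_equal(match_score(c(1, 0, 0), c(1, 0, 0)), 1.5)
  expect_equal(match_score(c(0, 0, 1), c(0, 0, 1)), 1.3)
  expect_equal(match_score(c(0, 0, 0), c(0.2, 0.3, 0.5)), 0.5)
  # mixed statuses interpolate between offset and full credit
  expect_equal(match_score(c(0.5, 0, 0.5), c(0.5, 0, 0.5)),
               1 * 0.25 + 0.8 * 0.25 + 0.5)
})

test_that("alignment posteriors behave like posteriors", {
  po <- pairwise_posteriors("GGGAAACCC", "GGGAAACCC", beta = 0)
  expect_true(all(diag(po) == apply(po, 1, max)))
  set.seed(31)
  for (t in 1:5) {
    a <- random_rna(sample(15:30, 1)); b <- random_rna(sample(15:30, 1))
    p <- pairwise_posteriors(a, b, beta = 0)
    expect_true(all(p >= 0 & p <= 1))
    expect_lt(max(rowSums(p)), 1 + 1e-6)
    expect_lt(max(colSums(p)), 1 + 1e-6)
    expect_equal(p, t(pairwise_posteriors(b, a, beta = 0)),
                 tolerance = 1e-12)
  }
})

test_that("structural term in the emission shifts posteriors deterministically", {
  a <- "GGGAAACCCAA"; b <- "AAGGGAAACCC"
  pa <- partition_probabilities(a); pb <- partition_probabilities(b)
  p0 <- pairwise_posteriors(a, b, beta = 0)
  p1 <- pairwise_posteriors(a, b, pa, pb, beta = 1)
  p1b <- pairwise_posteriors(a, b, pa, pb, beta = 1)
  expect_identical(p1, p1b)
  expect_false(identical(p0, p1))
})

test_that("extrinsic information equals its direct triple-sum definition", {
  set.seed(41)
  seqs <- c("GGGAAACCCA", "GGGAAACCCA", "GGCAAAGCCA")
  probs <- lapply(seqs, partition_probabilities)
  posts <- list()
  for (m in 1:2) for (n in (m + 1):3)
    posts[[paste0(m, "|", n)]] <-
      pairwise_posteriors(seqs[m], seqs[n], beta = 0)
  E <- extrinsic_information(1, probs, posts)
  # independent oracle: explicit summation over k < l
  L <- 10
  Eref <- matrix(0, L, L)
  for (n in 2:3) {
    pi_tn <- rnadecoy:::get_post(posts, 1, n)
    P <- probs[[n]]$P
    for (i in 1:L) for (j in 1:L) {
      acc <- 0
      for (k in 1:(L - 1)) for (l in (k + 1):L)
        acc <- acc + pi_tn[i, k] * pi_tn[j, l] * P[k, l]
      Eref[i, j] <- Eref[i, j] + acc
    }
  }
  Eref <- Eref / 2
  expect_equal(E, Eref, tolerance = 1e-12)
  expect_true(all(E >= 0))
  expect_true(all(E <= 1 + 1e-9))
})

test_that("extrinsic information degenerates correctly", {
  probs <- lapply(c("AAAAAA", "AAAAAA"), partition_probabilities)
  posts <- list("1|2" = pairwise_posteriors("AAAAAA", "AAAAAA", beta = 0))
  expect_true(all(extrinsic_information(1, probs, posts) == 0))
  p1 <- list(partition_probabilities("GGGAAACCC"))
  expect_true(all(extrinsic_information(1, p1, list()) == 0))
})

test_that("the consensus loop passes single sequences through unchanged", {
  t1 <- run_turbo(rna_group("GGGAAAACCC", ids = "solo"))
  expect_identical(t1$final_probs[[1]]$P, t1$initial_probs[[1]]$P)
  expect_equal(t1$msa$rows, "GGGAAAACCC")
})

test_that("identical sequences align without gaps and runs are reproducible", {
  g <- rna_group(rep("GGGAAAACCC", 5), ids = paste0("s", 1:5))
  tr <- run_turbo(g)
  expect_false(any(grepl("-", tr$msa$rows, fixed = TRUE)))
  g2 <- make_decoy_group(seed = 5, n_homologs = 5, length = 50)
  a <- run_turbo(g2)
  b <- run_turbo(g2)
  expect_identical(a$final_probs, b$final_probs)
  expect_identical(a$msa$rows, b$msa$rows)
})

test_that("alignments strip back to their sequences after every run", {
  for (seed in c(2, 9)) {
    g <- make_decoy_group(seed = seed, n_homologs = 5, length = 60)
    tr <- run_turbo(g)
    stripped <- gsub("-", "", tr$msa$rows, fixed = TRUE)
    expect_identical(stripped, g$seqs)
    for (p in tr$final_probs)
      expect_lt(max(abs(p$p_paired5 + p$p_paired3 + p$p_unpaired - 1)),
                1e-9)
  }
})

test_that("features are invariant to the order of group members", {
  g <- make_decoy_group(seed = 3, n_homologs = 5, length = 60)
  f1 <- feature_table(run_turbo(g))
  perm <- c(4, 2, 6, 1, 5, 3)
  f2 <- feature_table(run_turbo(g[perm]))
  f2 <- f2[match(f1$id, f2$id), ]
  for (col in c("kl_score", "z_score", "seq_entropy", "ss_final"))
    expect_equal(f2[[col]], f1[[col]], tolerance = 1e-8)
})
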