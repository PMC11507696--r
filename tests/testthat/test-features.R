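test_that("pairing/unpairing scores reproduce the forced cases", {
  # two sequences, one certain pair (1,9): column 1 is fully 5'-paired
  probs <- list(single_pair_probs(9, 1, 9, 1), single_pair_probs(9, 1, 9, 1))
  msa <- rna_msa(c(a = "GGGAAACCC", b = "GGGAAACCC"))
  sc <- ps_us_scores(1, msa, probs)
  expect_equal(sc$ps[1], 1)
  expect_equal(sc$us[1], 0)
  expect_equal(sc$ps[9], 1)    # 3'-paired on both
  expect_equal(sc$us[5], 1)    # unpaired on both
  expect_equal(sc$ps[5], 0)
  expect_true(all(sc$ps + sc$us <= 1 + 1e-9))
})

test_that("a gapped target position scores zero in its column", {
  probs <- list(pair_probs(matrix(0, 8, 8)), pair_probs(matrix(0, 9, 9)))
  msa <- rna_msa(c(a = "GGGA-ACCC", b = "GGGAAACCC"))
  sc <- ps_us_scores(1, msa, probs)
  expect_equal(sc$ps[5], 0)
  expect_equal(sc$us[5], 0)
  expect_true(sc$gap[5])
  expect_error(ps_us_scores(1, rna_msa(c(a = "ACGU")), probs[1]),
               "at least 2")
})

test_that("unpaired agreement among three sequences gives US = 1", {
  probs <- replicate(3, pair_probs(matrix(0, 6, 6)), simplify = FALSE)
  msa <- rna_msa(c(a = "AAAAAA", b = "AAAAAA", c = "AAAAAA"))
  sc <- ps_us_scores(1, msa, probs)
  expect_true(all(sc$us == 1))
})

test_that("the PS-US histogram has 465 bins and clamps boundaries", {
  probs <- list(single_pair_probs(9, 1, 9, 1), single_pair_probs(9, 1, 9, 1))
  msa <- rna_msa(c(a = "GGGAAACCC", b = "GGGAAACCC"))
  h <- build_histogram(ps_us_scores(1, msa, probs))
  expect_length(h, 465L)
  expect_equal(sum(h), 1)
  # columns 1 and 9 have PS = 1 -> bin (29, 0); columns 2-8 US in {0,1}
  expect_equal(h[psus_bin_index(29, 0)], 2 / 9)
  expect_equal(h[psus_bin_index(0, 29)], 7 / 9)

  # a single all-zero column lands in bin (0, 0)
  zp <- list(pair_probs(matrix(0, 1, 1)), pair_probs(matrix(0, 1, 1)))
  mz <- rna_msa(c(a = "A", b = "C"))
  sc <- ps_us_scores(1, mz, zp)
  sc$us <- 0 * sc$us   # force (0,0): other sequence unpaired too -> us=1 else
  h0 <- build_histogram(sc)
  expect_equal(h0[psus_bin_index(0, 0)], 1)

  gap_sc <- structure(list(ps = 0, us = 0, gap = TRUE),
                      class = "psus_scores")
  expect_warning(hg <- build_histogram(gap_sc), "gap")
  expect_true(all(hg == 0))
})

test_that("KL score is a divergence with pseudocounts", {
  probs <- list(single_pair_probs(9, 1, 9, 1), single_pair_probs(9, 1, 9, 1))
  msa <- rna_msa(c(a = "GGGAAACCC", b = "GGGAAACCC"))
  h <- build_histogram(ps_us_scores(1, msa, probs))
  expect_lt(kl_score(h, list(h, h, h)), 1e-12)
  set.seed(17)
  for (t in 1:10) {
    a <- as.numeric(rmultinom(1, 50, runif(465))) / 50
    b <- as.numeric(rmultinom(1, 50, runif(465))) / 50
    class(a) <- class(b) <- "psus_histogram"
    expect_gte(kl_score(a, list(b)), 0)
  }
  expect_error(kl_score(h, list()), "at least one")
})

test_that("KL score matches hand arithmetic on a two-bin contrast", {
  q <- numeric(465); q[psus_bin_index(0, 0)] <- 1
  r <- numeric(465); r[psus_bin_index(29, 0)] <- 1
  class(q) <- class(r) <- "psus_histogram"
  # after pseudocounts both distributions are (mass + 1/465)/2 in their
  # loaded bin and (1/465)/2 elsewhere
  hi <- (1 + 1 / 465) / 2
  lo <- (1 / 465) / 2
  expected <- hi * log(hi / lo) + lo * log(lo / hi)   # remaining bins cancel
  expect_equal(kl_score(q, list(r)), expected, tolerance = 1e-12)
})

test_that("Z-score follows the population formula over the others", {
  expect_equal(z_score(-11, c(-10, -12)), 0)
  expect_equal(z_score(-13, c(-10, -12)), -2)
  set.seed(19)
  x <- rnorm(6)
  expect_equal(z_score(x[1] + 5, x[-1] + 5), z_score(x[1], x[-1]))
  expect_warning(z0 <- z_score(-3, c(-2, -2)), "spread")
  expect_equal(z0, 0)
  expect_error(z_score(0, -1), "at least 2")
})

test_that("sequence entropy is the printed per-column mean", {
  msa_same <- rna_msa(c(a = "GGAU", b = "GGAU", c = "GGAU"))
  expect_equal(sequence_entropy(1, msa_same), 0)
  msa2 <- rna_msa(c(a = "A", b = "C"))
  expect_equal(sequence_entropy(1, msa2), 0.5 * log10(0.5))
  set.seed(23)
  rows <- vapply(1:5, function(i)
    paste(sample(c("A", "C", "G", "U", "-"), 20, TRUE), collapse = ""), "")
  msa3 <- rna_msa(rows)
  for (m in 1:5) {
    v <- sequence_entropy(m, msa3)
    expect_lte(v, 0)
    expect_gte(v, -log10(5))
  }
})

test_that("structural entropy is zero for deterministic ensembles", {
  expect_equal(structural_entropy(single_pair_probs(9, 1, 9, 1)), 0)
  expect_equal(structural_entropy(pair_probs(matrix(0, 5, 5))), 0)
  expect_equal(structural_entropy(single_pair_probs(10, 1, 10, 0.5)),
               -(0.5 * log10(0.5)) / 10)
  set.seed(29)
  p <- partition_probabilities(random_rna(40))
  expect_gte(structural_entropy(p), 0)
})

test_that("feature vectors assemble deterministically and need 3 sequences", {
  g <- rna_group(rep("GGGAAAACCC", 4), ids = paste0("s", 1:4))
  tr <- run_turbo(g)
  # identical sequences have zero free-energy spread: Z-score warns and is 0
  expect_warning(fv <- feature_vector(1, tr), "spread")
  expect_named(fv, c("kl_score", "z_score", "seq_entropy", "ss_initial",
                     "ss_final", "ss_delta"))
  expect_lt(fv[["kl_score"]], 1e-12)   # identical sequences
  expect_equal(fv[["seq_entropy"]], 0)
  expect_equal(fv[["ss_delta"]], fv[["ss_initial"]] - fv[["ss_final"]])
  expect_identical(fv, suppressWarnings(feature_vector(1, tr)))
  small <- run_turbo(rna_group(rep("GGGAAAACCC", 2), ids = c("a", "b")))
  expect_error(feature_vector(1, small), "at least 3")
})

test_that("decoys carry higher KL scores than homologs on average", {
  set.seed(37)
  kl_d <- kl_h <- numeric(0)
  for (trial in 1:8) {
    g <- make_decoy_group(seed = 400 + trial, n_homologs = 6, length = 60)
    ft <- feature_table(run_turbo(g))
    kl_d <- c(kl_d, ft$kl_score[ft$label == "decoy"])
    kl_h <- c(kl_h, ft$kl_score[ft$label == "homolog"])
  }
  expect_gt(mean(kl_d), mean(kl_h))
})
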