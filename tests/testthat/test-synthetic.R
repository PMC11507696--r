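count_helices <- function(st, min_stack = 3L) {
  if (!nrow(st$pairs)) return(0L)
  p <- st$pairs[order(st$pairs[, 1]), , drop = FALSE]
  runs <- 0L; len <- 1L
  for (r in seq_len(nrow(p))[-1]) {
    stacked <- p[r, 1] == p[r - 1, 1] + 1 && p[r, 2] == p[r - 1, 2] - 1
    if (stacked) len <- len + 1L
    else { if (len >= min_stack) runs <- runs + 1L; len <- 1L }
  }
  if (len >= min_stack) runs <- runs + 1L
  runs
}

test_that("random consensus structures meet the generator contract", {
  for (L in c(40, 60, 90, 120)) {
    st <- random_consensus_structure(L, seed = L)
    expect_true(validate_structure(st$pairs, L))
    cov <- 2 * nrow(st$pairs) / L
    expect_gte(cov, 0.3); expect_lte(cov, 0.6)
    expect_gte(count_helices(st), 2L)
  }
  a <- random_consensus_structure(70, seed = 5)
  b <- random_consensus_structure(70, seed = 5)
  expect_identical(a$pairs, b$pairs)
})

test_that("simulated families hit the identity target and keep the structure", {
  fam <- generate_family(length = 70, n_members = 12,
                         target_identity = 1, seed = 2)
  expect_true(all(fam$seqs == fam$seqs[1]))

  for (target in c(0.55, 0.7, 0.8)) {
    fam <- generate_family(length = 80, n_members = 14,
                           target_identity = target, seed = 100 * target)
    expect_lt(abs(attr(fam, "mean_identity") - target), 0.08)
    cons <- attr(fam, "consensus")
    canon <- c("GC", "CG", "AU", "UA", "GU", "UG")
    frac_canon <- vapply(fam$seqs, function(s) {
      r <- strsplit(s, "")[[1]]
      mean(paste0(r[cons$pairs[, 1]], r[cons$pairs[, 2]]) %in% canon)
    }, 0)
    expect_true(all(frac_canon >= 0.9))
  }
})

test_that("family members share the consensus structure when folded", {
  overlaps <- vapply(1:5, function(k) {
    fam <- generate_family(length = 70, n_members = 6,
                           target_identity = 0.7, seed = 900 + k)
    cons <- attr(fam, "consensus")
    mean(vapply(fam$seqs, function(s)
      score_structure(mea_structure(partition_probabilities(s)),
                      cons)[["sensitivity"]], 0))
  }, 0)
  expect_gte(mean(overlaps), 0.6)
})

test_that("group assembly samples, labels and reproduces exactly", {
  fams <- list()
  for (k in 1:3)
    fams[[paste0("f", k)]] <- generate_family(length = 50, n_members = 10,
                                              target_identity = 0.7,
                                              family_id = paste0("f", k),
                                              seed = k)
  g0 <- build_group(fams, n_decoys = 0, n_homologs = 6, seed = 1)
  expect_length(g0, 6L)
  expect_true(all(g0$labels == "homolog"))

  g3 <- build_group(fams, n_homologs = 5, n_decoys = 3,
                    decoy_kind = "shuffled", seed = 2)
  expect_length(g3, 8L)
  expect_equal(sum(g3$labels == "decoy"), 3L)

  expect_identical(build_group(fams, n_homologs = 6, n_decoys = 2, seed = 4),
                   build_group(fams, n_homologs = 6, n_decoys = 2, seed = 4))
  expect_error(build_group(fams["f1"], n_decoys = 1,
                           decoy_kind = "cross_family", seed = 1),
               "at least 2 families")
})

test_that("corpus construction keeps train and test families disjoint", {
  corp <- build_corpus(n_train_families = 3, n_test_families = 2,
                       groups_per_condition = 4L,
                       test_groups_per_condition = 2L,
                       length_range = c(40L, 60L), seed = 11)
  expect_length(corp$train, 3L * 4L + 2L)
  expect_length(corp$test, 6L * 2L + 2L)
  expect_length(intersect(names(corp$train_families),
                          names(corp$test_families)), 0L)
  man <- corp$manifest
  expect_equal(nrow(man), length(corp$train) + length(corp$test))
  expect_true(all(man$family[man$partition == "train"] %in%
                  names(corp$train_families)))
  expect_true(all(man$family[man$partition == "test"] %in%
                  names(corp$test_families)))
  expect_true(all(man$n_total >= 5))
  # reproducible manifest
  corp2 <- build_corpus(n_train_families = 3, n_test_families = 2,
                        groups_per_condition = 4L,
                        test_groups_per_condition = 2L,
                        length_range = c(40L, 60L), seed = 11)
  expect_identical(corp2$manifest, man)
})
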