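# shared fixtures: all built in code at test time

random_rna <- function(L) paste(sample(c("A", "C", "G", "U"), L, TRUE),
                                collapse = "")

# small structured family + one shuffled decoy, used by several suites
make_decoy_group <- function(seed, n_homologs = 8L, length = 80L,
                             identity = 0.65) {
  fam <- generate_family(length = length, n_members = n_homologs + 4L,
                         target_identity = identity, family_id = "fix",
                         seed = seed)
  dec <- shuffle_decoy(fam$seqs[n_homologs + 1L],
                       keep_fraction = attr(fam, "mean_identity"),
                       id = fam$ids[n_homologs + 1L], seed = seed)
  grp <- rna_group(c(fam$seqs[seq_len(n_homologs)], dec$seqs),
                   ids = c(fam$ids[seq_len(n_homologs)], dec$ids),
                   labels = c(rep("homolog", n_homologs), "decoy"))
  attr(grp, "consensus") <- attr(fam, "consensus")
  grp
}

# MEA objective value of a structure, for exhaustive cross-checks
mea_objective <- function(pairs, P, q, gamma = 1) {
  v <- if (NROW(pairs)) sum(2 * gamma * P[pairs, drop = FALSE]) else 0
  unpaired <- setdiff(seq_len(nrow(P)), as.vector(pairs))
  v + sum(q[unpaired])
}

# pair_probs with a single hand-placed pair probability
single_pair_probs <- function(L, i, j, p) {
  P <- matrix(0, L, L)
  P[i, j] <- P[j, i] <- p
  pair_probs(P)
}
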