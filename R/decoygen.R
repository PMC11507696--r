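#' Mean pairwise sequence identity of an alignment
#'
#' Mean, over all unordered pairs of rows, of the fraction of matching
#' non-gap columns among columns where at least one of the two rows is
#' non-gap.
#'
#' @param msa an [rna_msa] with at least 2 rows.
#' @return identity fraction in \[0, 1\].
#' @export
mean_pairwise_identity <- function(msa) {
  stopifnot(inherits(msa, "rna_msa"))
  S <- length(msa$rows)
  if (S < 2L) stop("identity needs at least 2 sequences")
  mat <- do.call(rbind, strsplit(msa$rows, ""))
  ids <- numeric(0)
  for (m in seq_len(S - 1L)) for (n in (m + 1L):S) {
    a <- mat[m, ]; b <- mat[n, ]
    covered <- a != "-" | b != "-"
    match_ <- a == b & a != "-"
    ids <- c(ids, if (any(covered)) sum(match_) / sum(covered) else 0)
  }
  mean(ids)
}

#' Generate a shuffled decoy from a homolog
#'
#' Holds a fraction of positions fixed and applies a uniform random
#' permutation to the residues at the remaining
#' `round((1 - keep_fraction) * L)` positions (chosen uniformly without
#' replacement; rounding is half-up). The residue multiset and length are
#' preserved, and the decoy's identity to the original is at least
#' `keep_fraction`. Setting `keep_fraction` to the family's mean pairwise
#' identity yields decoys that still look like family members by identity
#' and length alone.
#'
#' @param seq the source sequence (string).
#' @param keep_fraction fraction of positions held fixed, in \[0, 1\].
#' @param id identifier of the source; the decoy gets `id` + `"_shuffled"`.
#' @param seed optional RNG seed for reproducibility.
#' @return single-sequence [rna_group] labeled `"decoy"`.
#' @export
shuffle_decoy <- function(seq, keep_fraction, id = "seq", seed = NULL) {
  stopifnot(keep_fraction >= 0, keep_fraction <= 1)
  res <- as_residues(seq)
  L <- length(res)
  n_shuffle <- floor((1 - keep_fraction) * L + 0.5)
  with_seed(seed, {
    if (n_shuffle > 0L) {
      at <- sample.int(L, n_shuffle)
      res[at] <- res[at][sample.int(n_shuffle)]
    }
  })
  rna_group(paste(res, collapse = ""), ids = paste0(id, "_shuffled"),
            labels = "decoy")
}

#' Draw a cross-family decoy
#'
#' Uniformly samples a donor family other than `exclude`, then one of its
#' members. The returned record is labeled `"decoy"` and carries the donor
#' family in attribute `"donor_family"`.
#'
#' @param donor_families named list of [rna_group] objects (names are
#'   family identifiers).
#' @param exclude family identifier that must not donate.
#' @param seed optional RNG seed.
#' @return single-sequence [rna_group].
#' @export
cross_family_decoy <- function(donor_families, exclude, seed = NULL) {
  pool <- setdiff(names(donor_families), exclude)
  if (!length(pool)) stop("no eligible donor family")
  with_seed(seed, {
    fam <- sample(pool, 1L)
    members <- donor_families[[fam]]
    m <- sample.int(length(members), 1L)
  })
  rec <- members[m]
  rec$labels <- "decoy"
  attr(rec, "donor_family") <- fam
  rec
}
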