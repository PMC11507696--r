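#' Per-column pairing and unpairing conservation scores
#'
#' For a target sequence in an aligned group, the pairing score of column
#' `i` averages, over the other sequences, the probability that both hold a
#' partner on the same side (`PS(i) = mean_n(P5m*P5n + P3m*P3n)`), and the
#' unpairing score the probability both are unpaired
#' (`US(i) = mean_n(Pom*Pon)`). A gapped position contributes the all-zero
#' marginal triple, so columns where the target is gapped score zero; the
#' scores satisfy `PS + US <= 1` columnwise.
#'
#' @param target index of the sequence of interest.
#' @param msa an [rna_msa] for the group.
#' @param probs_list list of [pair_probs] (sequence coordinates), one per
#'   group member, in alignment row order.
#' @return object of class `psus_scores`: list with per-column `ps`, `us`
#'   and the logical `gap` mask of the target.
#' @export
ps_us_scores <- function(target, msa, probs_list) {
  S <- length(msa$rows)
  if (S < 2L) stop("pairing/unpairing scores need at least 2 sequences")
  stopifnot(target >= 1L, target <= S, length(probs_list) == S)
  W <- msa$width
  # per-sequence column-mapped marginals (gap rows zero)
  trip <- function(m) {
    out <- matrix(0, W, 3L)
    pos <- msa$pos_of[[m]]
    ok <- !is.na(pos)
    p <- probs_list[[m]]
    out[ok, 1L] <- p$p_paired5[pos[ok]]
    out[ok, 2L] <- p$p_paired3[pos[ok]]
    out[ok, 3L] <- p$p_unpaired[pos[ok]]
    out
  }
  tm <- trip(target)
  s5 <- s3 <- so <- numeric(W)
  for (n in seq_len(S)) {
    if (n == target) next
    tn <- trip(n)
    s5 <- s5 + tn[, 1L]; s3 <- s3 + tn[, 2L]; so <- so + tn[, 3L]
  }
  ps <- (tm[, 1L] * s5 + tm[, 2L] * s3) / (S - 1)
  us <- (tm[, 3L] * so) / (S - 1)
  structure(list(ps = ps, us = us, gap = is.na(msa$pos_of[[target]])),
            class = "psus_scores")
}

# number of histogram bins on the triangular (PS, US) grid
N_PSUS_BINS <- 465L

#' Linear index of a (PS, US) histogram bin
#'
#' Bins live on the triangular grid `{(x, y): 0 <= x, y <= 29, x + y <= 29}`
#' with bin width 1/30 on each axis; there are exactly 465 of them.
#'
#' @param x,y integer bin coordinates (0-based).
#' @return 1-based linear index into the histogram vector.
#' @export
psus_bin_index <- function(x, y) {
  stopifnot(all(x >= 0), all(x <= 29), all(y >= 0), all(y + x <= 29))
  as.integer(x * 30 - x * (x - 1) / 2 + y + 1)
}

#' Triangular histogram of pairing/unpairing scores
#'
#' Each non-gap column increments the bin `(floor(PS * 30), floor(US * 30))`
#' (values of exactly 1 clamp into bin 29; the rare boundary columns whose
#' bin falls just outside the triangle are clamped onto its diagonal).
#' Counts are normalized by the total count.
#'
#' @param scores a [ps_us_scores()] result.
#' @return object of class `psus_histogram`: numeric vector of 465
#'   normalized bin values (all zero, with a warning, if every column is a
#'   gap).
#' @export
build_histogram <- function(scores) {
  stopifnot(inherits(scores, "psus_scores"))
  keep <- !scores$gap
  h <- numeric(N_PSUS_BINS)
  if (!any(keep)) {
    warning("all columns are gaps; returning an all-zero histogram")
    return(structure(h, class = "psus_histogram"))
  }
  x <- pmin(floor(scores$ps[keep] * 30), 29)
  y <- pmin(floor(scores$us[keep] * 30), 29)
  y <- pmin(y, 29 - x)   # clamp boundary columns onto the triangle
  idx <- psus_bin_index(x, y)
  tab <- tabulate(idx, nbins = N_PSUS_BINS)
  structure(tab / sum(tab), class = "psus_histogram")
}

#' Kullback-Leibler score of a sequence's histogram against the group
#'
#' Measures how far the target's (PS, US) histogram departs from the
#' bin-wise mean histogram of the other sequences. Both distributions
#' receive a pseudocount of 1/465 per bin and are renormalized before
#' `sum(q * log(q / r))` (natural log) is taken, so the score is finite,
#' nonnegative, and zero when the target matches the others exactly.
#'
#' @param target_hist a [build_histogram()] result for the target.
#' @param other_hists list of histograms for the remaining sequences.
#' @return nonnegative scalar.
#' @export
kl_score <- function(target_hist, other_hists) {
  if (!length(other_hists)) stop("need at least one other histogram")
  q <- as.numeric(target_hist)
  r <- Reduce(`+`, lapply(other_hists, as.numeric)) / length(other_hists)
  stopifnot(length(q) == N_PSUS_BINS, length(r) == N_PSUS_BINS)
  q <- q + 1 / N_PSUS_BINS; q <- q / sum(q)
  r <- r + 1 / N_PSUS_BINS; r <- r / sum(r)
  sum(q * log(q / r))
}

#' Z-score of the folding free energy
#'
#' `(dG(m) - mean(dG(others))) / sd(dG(others))` with the population
#' standard deviation over the others. If that deviation is zero the score
#' is defined as 0, with a warning.
#'
#' @param target_dg free energy of the target.
#' @param other_dgs free energies of the other group members (at least 2).
#' @return scalar Z-score.
#' @export
z_score <- function(target_dg, other_dgs) {
  if (length(other_dgs) < 2L) stop("Z-score needs at least 2 other values")
  mu <- mean(other_dgs)
  sigma <- sqrt(mean((other_dgs - mu)^2))
  if (sigma == 0) {
    warning("zero free-energy spread among the other sequences; Z-score 0")
    return(0)
  }
  (target_dg - mu) / sigma
}

#' Mean sequence Shannon entropy of one alignment row
#'
#' `(1/A) * sum_i P_t(i) * log10(P_t(i))` over the `A` alignment columns,
#' where `t` is the target's symbol at column `i` (A, C, G, U or gap) and
#' `P_t(i)` its frequency in that column. Computed exactly in this form
#' (no leading minus), so identical rows give 0 and the value lies in
#' `[-log10(5), 0]`.
#'
#' @param target row index of the sequence of interest.
#' @param msa an [rna_msa].
#' @return scalar, at most 0.
#' @export
sequence_entropy <- function(target, msa) {
  S <- length(msa$rows)
  stopifnot(target >= 1L, target <= S)
  mat <- do.call(rbind, strsplit(msa$rows, ""))
  tgt <- mat[target, ]
  pt <- vapply(seq_len(ncol(mat)),
               function(i) mean(mat[, i] == tgt[i]), 0)
  mean(pt * log10(pt))
}

#' Structural Shannon entropy of a base-pair probability matrix
#'
#' `-(1/N) * sum_{i<j} P(i,j) * log10(P(i,j))` with `0 * log 0 = 0`;
#' a measure of how well-defined a single structure is (0 when every pair
#' probability is 0 or 1).
#'
#' @param probs a [pair_probs].
#' @return nonnegative scalar.
#' @export
structural_entropy <- function(probs) {
  stopifnot(inherits(probs, "pair_probs"))
  p <- probs$P[upper.tri(probs$P)]
  p <- p[p > 0]
  if (!length(p)) return(0)
  -sum(p * log10(p)) / probs$length
}

#' Assemble the six classification features for one sequence
#'
#' KL score of the (PS, US) histogram (final iteration), free-energy
#' Z-score, mean sequence Shannon entropy on the final alignment, and the
#' structural Shannon entropy before and after consensus refinement plus
#' their difference (`ss_delta = ss_initial - ss_final`; contaminants are
#' expected to change more because the consensus forces their fold toward
#' the family structure).
#'
#' @param target sequence index within the group.
#' @param result a [run_turbo()] result on a group of at least 3.
#' @return named numeric vector of the six features.
#' @export
feature_vector <- function(target, result) {
  stopifnot(inherits(result, "turbo_result"))
  S <- length(result$group)
  if (S < 3L) stop("features need a group of at least 3 sequences")
  hists <- result$histograms %||% lapply(seq_len(S), function(m)
    build_histogram(ps_us_scores(m, result$msa, result$final_probs)))
  kl <- kl_score(hists[[target]], hists[-target])
  z <- z_score(result$free_energies[[target]],
               result$free_energies[-target])
  se <- sequence_entropy(target, result$msa)
  ss0 <- structural_entropy(result$initial_probs[[target]])
  ss1 <- structural_entropy(result$final_probs[[target]])
  c(kl_score = kl, z_score = z, seq_entropy = se,
    ss_initial = ss0, ss_final = ss1, ss_delta = ss0 - ss1)
}

#' Feature table for a whole group
#'
#' One row per sequence: identifier, the six features, and the truth label
#' when the group carries one. Suitable for [decoy_classifier()] or for
#' export to external machine-learning tooling.
#'
#' @param result a [run_turbo()] result.
#' @return data frame with columns `id`, `kl_score`, `z_score`,
#'   `seq_entropy`, `ss_initial`, `ss_final`, `ss_delta` and optionally
#'   `label`.
#' @export
feature_table <- function(result) {
  stopifnot(inherits(result, "turbo_result"))
  S <- length(result$group)
  result$histograms <- lapply(seq_len(S), function(m)
    build_histogram(ps_us_scores(m, result$msa, result$final_probs)))
  fv <- t(vapply(seq_len(S), feature_vector, numeric(6L), result = result))
  out <- data.frame(id = result$group$ids, fv, stringsAsFactors = FALSE)
  if (!is.null(result$group$labels)) out$label <- result$group$labels
  out
}

#' Full (PS, US) histogram matrix for a group
#'
#' The 465-dimensional normalized histograms of every sequence, as used by
#' the histogram-only classifier variant in ROC comparisons.
#'
#' @param result a [run_turbo()] result.
#' @return numeric matrix, one row per sequence, 465 columns.
#' @export
histogram_matrix <- function(result) {
  stopifnot(inherits(result, "turbo_result"))
  S <- length(result$group)
  h <- t(vapply(seq_len(S), function(m)
    as.numeric(build_histogram(ps_us_scores(m, result$msa,
                                            result$final_probs))),
    numeric(N_PSUS_BINS)))
  rownames(h) <- result$group$ids
  h
}
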