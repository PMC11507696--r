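#' Match-score weights
#'
#' Weights of the structural match score between two aligned positions:
#' `a1` rewards conserved pairing direction, `a2` conserved unpairedness,
#' and `a3` is a flat offset. The defaults are the values established for
#' iterative consensus folding (a1 = 1.0, a2 = 0.8, a3 = 0.5).
#'
#' @param a1,a2,a3 numeric weights.
#' @return an object of class `match_params`.
#' @export
match_params <- function(a1 = 1.0, a2 = 0.8, a3 = 0.5) {
  structure(list(a1 = a1, a2 = a2, a3 = a3), class = "match_params")
}

#' Pair-HMM alignment parameters
#'
#' @param gap_open probability of opening a gap (transition match -> insert).
#' @param gap_extend probability of extending an open gap.
#' @param match_prob joint probability of seeing the same base aligned
#'   (per identical base pair; background 1/16 per ordered pair).
#' @param mismatch_prob joint probability of a specific mismatched pair.
#' @return an object of class `hmm_params`.
#' @export
hmm_params <- function(gap_open = 0.05, gap_extend = 0.3,
                       match_prob = 0.16, mismatch_prob = 0.03) {
  stopifnot(gap_open > 0, gap_open < 0.5, gap_extend > 0, gap_extend < 1,
            abs(4 * match_prob + 12 * mismatch_prob - 1) < 1e-9)
  structure(list(gap_open = gap_open, gap_extend = gap_extend,
                 match_prob = match_prob, mismatch_prob = mismatch_prob),
            class = "hmm_params")
}

#' Structural match score of two aligned positions
#'
#' `a1 * (P5m*P5n + P3m*P3n) + a2 * (Pom*Pon) + a3`, where each argument is
#' the pairing-status triple (probability the partner is 5', the partner is
#' 3', unpaired) of one position. A gapped position contributes the
#' all-zero triple, so two gaps score exactly `a3`.
#'
#' @param m_marginals,n_marginals numeric length-3 vectors
#'   `(p_paired5, p_paired3, p_unpaired)`; all-zero encodes a gap.
#' @param params a [match_params].
#' @return the match score (scalar).
#' @examples
#' match_score(c(1, 0, 0), c(1, 0, 0))  # conserved 5'-pairing: 1.5
#' @export
match_score <- function(m_marginals, n_marginals, params = match_params()) {
  stopifnot(length(m_marginals) == 3L, length(n_marginals) == 3L)
  params$a1 * (m_marginals[1L] * n_marginals[1L] +
               m_marginals[2L] * n_marginals[2L]) +
    params$a2 * (m_marginals[3L] * n_marginals[3L]) + params$a3
}

# Lm x Ln matrix of match scores from two pair_probs objects
match_score_matrix <- function(probs_m, probs_n, params = match_params()) {
  params$a1 * (outer(probs_m$p_paired5, probs_n$p_paired5) +
               outer(probs_m$p_paired3, probs_n$p_paired3)) +
    params$a2 * outer(probs_m$p_unpaired, probs_n$p_unpaired) + params$a3
}

# base-substitution log-odds matrix for two residue vectors
substitution_logodds <- function(res_m, res_n, hmm) {
  lo_match <- log(hmm$match_prob / 0.0625)
  lo_mis <- log(hmm$mismatch_prob / 0.0625)
  ifelse(outer(res_m, res_n, "=="), lo_match, lo_mis)
}

#' Posterior alignment probabilities of two sequences
#'
#' Runs forward-backward on a three-state pair hidden Markov model (match,
#' insert in `m`, insert in `n`). The match emission log-score is a base
#' substitution log-odds term plus `beta * log(match_score)` when pair
#' probabilities are supplied, so positions with the same predicted pairing
#' status are more likely to align. Deterministic for fixed inputs.
#'
#' @param seq_m,seq_n RNA sequences (strings).
#' @param probs_m,probs_n optional [pair_probs] for the two sequences; when
#'   either is NULL (or `beta = 0`) the alignment is sequence-only.
#' @param params a [match_params].
#' @param beta weight of the structural term in the match emission.
#' @param hmm an [hmm_params].
#' @return matrix of posterior probabilities, rows = positions of `seq_m`.
#' @export
pairwise_posteriors <- function(seq_m, seq_n, probs_m = NULL, probs_n = NULL,
                                params = match_params(), beta = 1,
                                hmm = hmm_params()) {
  res_m <- as_residues(seq_m)
  res_n <- as_residues(seq_n)
  logEmit <- substitution_logodds(res_m, res_n, hmm)
  if (beta > 0 && !is.null(probs_m) && !is.null(probs_n)) {
    ms <- match_score_matrix(probs_m, probs_n, params)
    logEmit <- logEmit + beta * log(ms)
  }
  c_hmm_posterior(logEmit, hmm$gap_open, hmm$gap_extend)
}

# store pairwise posteriors for m < n; fetch either orientation
post_key <- function(m, n) paste0(min(m, n), "|", max(m, n))
get_post <- function(posts, m, n) {
  p <- posts[[post_key(m, n)]]
  if (m < n) p else t(p)
}

#' Extrinsic pairing information for one sequence
#'
#' Pair proclivities for the target inferred from the other sequences'
#' base-pair probabilities carried through the alignment posteriors:
#' `E(i, j) = mean over n != target of
#' sum_{k<l} pi(i, k) * pi(j, l) * P_n(k, l)`. Nonnegative and bounded by
#' one; a single-sequence group yields the all-zero matrix.
#'
#' @param target index of the target sequence in the group.
#' @param probs_list list of [pair_probs], one per group member.
#' @param posteriors list of pairwise posterior matrices keyed as produced
#'   by [run_turbo()] (`"m|n"` with `m < n`, rows = sequence `m`).
#' @return square nonnegative matrix over target positions (upper triangle
#'   is the meaningful orientation).
#' @export
extrinsic_information <- function(target, probs_list, posteriors) {
  S <- length(probs_list)
  L <- probs_list[[target]]$length
  E <- matrix(0, L, L)
  if (S < 2L) return(E)
  for (n in seq_len(S)) {
    if (n == target) next
    pi_tn <- get_post(posteriors, target, n)
    Pup <- probs_list[[n]]$P
    Pup[lower.tri(Pup, diag = TRUE)] <- 0
    E <- E + pi_tn %*% Pup %*% t(pi_tn)
  }
  E / (S - 1)
}

# one round of triplet consistency: pi'_mn = (pi_mn + mean_h pi_mh pi_hn)/2
consistency_transform <- function(posts, S) {
  if (S <= 2L) return(posts)
  out <- list()
  for (m in seq_len(S - 1L)) for (n in (m + 1L):S) {
    pmn <- get_post(posts, m, n)
    acc <- matrix(0, nrow(pmn), ncol(pmn))
    inter <- setdiff(seq_len(S), c(m, n))
    for (h in inter)
      acc <- acc + get_post(posts, m, h) %*% get_post(posts, h, n)
    out[[post_key(m, n)]] <- 0.5 * (pmn + acc / length(inter))
  }
  out
}

# posterior-expected identity between two sequences
posterior_identity <- function(res_m, res_n, pi_mn) {
  same <- outer(res_m, res_n, "==")
  sum(pi_mn * same) / min(length(res_m), length(res_n))
}

# Progressive profile alignment over a UPGMA guide tree built from
# posterior-expected identities. Returns an rna_msa in group order.
progressive_msa <- function(group, posts) {
  S <- length(group)
  reslist <- lapply(group$seqs, function(s) strsplit(s, "")[[1L]])
  if (S == 1L)
    return(rna_msa(group$seqs, ids = group$ids))
  D <- matrix(0, S, S)
  for (m in seq_len(S - 1L)) for (n in (m + 1L):S) {
    idmn <- posterior_identity(reslist[[m]], reslist[[n]],
                               get_post(posts, m, n))
    D[m, n] <- D[n, m] <- 1 - idmn
  }
  # profiles: list(members, pos = matrix columns x members (NA = gap))
  profiles <- lapply(seq_len(S), function(m)
    list(members = m,
         pos = matrix(seq_along(reslist[[m]]), ncol = 1L)))
  if (S == 2L) {
    order_merge <- matrix(c(-1L, -2L), 1L)
  } else {
    hc <- hclust(as.dist(D), method = "average")
    order_merge <- hc$merge
  }
  node <- vector("list", nrow(order_merge))
  for (step in seq_len(nrow(order_merge))) {
    pick <- function(ref) if (ref < 0) profiles[[-ref]] else node[[ref]]
    A <- pick(order_merge[step, 1L])
    B <- pick(order_merge[step, 2L])
    Smat <- matrix(0, nrow(A$pos), nrow(B$pos))
    for (ai in seq_along(A$members)) for (bi in seq_along(B$members)) {
      m <- A$members[ai]; n <- B$members[bi]
      pm <- A$pos[, ai]; pn <- B$pos[, bi]
      ok_m <- !is.na(pm); ok_n <- !is.na(pn)
      if (any(ok_m) && any(ok_n)) {
        pi_mn <- get_post(posts, m, n)
        Smat[ok_m, ok_n] <- Smat[ok_m, ok_n] +
          pi_mn[pm[ok_m], pn[ok_n], drop = FALSE]
      }
    }
    path <- c_nw(Smat)
    take <- function(pos, idx) {
      out <- matrix(NA_integer_, length(idx), ncol(pos))
      out[idx > 0, ] <- pos[idx[idx > 0], , drop = FALSE]
      out
    }
    node[[step]] <- list(members = c(A$members, B$members),
                         pos = cbind(take(A$pos, path$a),
                                     take(B$pos, path$b)))
  }
  final <- node[[nrow(order_merge)]]
  ordcol <- order(match(final$members, seq_len(S)))
  pos <- final$pos[, ordcol, drop = FALSE]
  rows <- vapply(seq_len(S), function(m) {
    ch <- rep("-", nrow(pos))
    ok <- !is.na(pos[, m])
    ch[ok] <- reslist[[m]][pos[ok, m]]
    paste(ch, collapse = "")
  }, "")
  rna_msa(rows, ids = group$ids)
}

#' Iterative consensus folding of a sequence group
#'
#' The core refinement loop. Iteration 0 folds every sequence on its own
#' (intrinsic information) and aligns every pair with the sequence-only
#' HMM. Each subsequent iteration computes extrinsic pairing information
#' for every sequence from the others' probabilities and the current
#' alignment posteriors, refolds with the extrinsic bonus, recomputes match
#' scores, and realigns. After `iterations` rounds a progressive multiple
#' alignment is built from consistency-transformed posteriors, and maximum
#' expected accuracy structures are predicted from the final probabilities.
#'
#' @param group an [rna_group] (2 or more sequences for the loop to have
#'   any effect; a single sequence passes through unchanged).
#' @param model an [energy_model].
#' @param iterations number of refinement iterations (default 3).
#' @param params a [match_params].
#' @param gamma weight of the extrinsic bonus in refolding.
#' @param beta weight of the match score in the alignment HMM.
#' @param hmm an [hmm_params].
#' @param gamma_mea pair weight for the final MEA predictions.
#' @return an object of class `turbo_result`: list with `group`,
#'   `initial_probs`, `final_probs` (per-sequence [pair_probs]),
#'   `posteriors` (final pairwise posterior matrices), `msa`
#'   (an [rna_msa]), `free_energies` (intrinsic ensemble free energies),
#'   `mea` (per-sequence [rna_structure]), and the parameters used.
#' @export
run_turbo <- function(group, model = energy_model(), iterations = 3L,
                      params = match_params(), gamma = 20, beta = 1,
                      hmm = hmm_params(), gamma_mea = 1) {
  stopifnot(inherits(group, "rna_group"), iterations >= 0L)
  S <- length(group)
  probs0 <- lapply(group$seqs, partition_probabilities, model = model)
  fe <- vapply(probs0, function(p) -attr(p, "logQ") / model$temperature_scale, 0)
  names(fe) <- group$ids
  probs <- probs0
  posts <- list()
  if (S >= 2L) {
    for (m in seq_len(S - 1L)) for (n in (m + 1L):S)
      posts[[post_key(m, n)]] <-
        pairwise_posteriors(group$seqs[m], group$seqs[n], beta = 0, hmm = hmm)
    for (it in seq_len(iterations)) {
      newprobs <- vector("list", S)
      for (m in seq_len(S)) {
        E <- extrinsic_information(m, probs, posts)
        newprobs[[m]] <- partition_probabilities(group$seqs[m], model,
                                                 extrinsic = E, gamma = gamma)
      }
      probs <- newprobs
      for (m in seq_len(S - 1L)) for (n in (m + 1L):S)
        posts[[post_key(m, n)]] <-
          pairwise_posteriors(group$seqs[m], group$seqs[n],
                              probs[[m]], probs[[n]],
                              params = params, beta = beta, hmm = hmm)
    }
  }
  cposts <- consistency_transform(posts, S)
  msa <- progressive_msa(group, cposts)
  mea <- lapply(probs, mea_structure, gamma_mea = gamma_mea,
                min_hairpin = model$min_hairpin)
  structure(list(group = group, initial_probs = probs0, final_probs = probs,
                 posteriors = posts, msa = msa, free_energies = fe,
                 mea = mea,
                 params = list(model = model, iterations = iterations,
                               match = params, gamma = gamma, beta = beta,
                               hmm = hmm, gamma_mea = gamma_mea)),
            class = "turbo_result")
}

#' @export
print.turbo_result <- function(x, ...) {
  cat("<turbo_result> ", length(x$group), " sequences, ",
      x$params$iterations, " iterations, alignment width ",
      x$msa$width, "\n", sep = "")
  invisible(x)
}
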