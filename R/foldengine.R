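#' Simplified RNA folding energy model
#'
#' A per-pair stability model: each canonical pair type contributes a
#' stability (in kcal/mol-equivalents, larger = more stable) and directly
#' stacked pairs earn an extra `stack_bonus`. This deliberately replaces a
#' full nearest-neighbor parameter set; the pipeline's features depend on
#' probabilities and free-energy differences *within* a group, which this
#' model supplies, and externally computed probability matrices can be
#' substituted wherever higher fidelity is needed.
#'
#' @param pair_scores named stabilities for the canonical pair classes
#'   `GC`, `AU`, `GU` (applied symmetrically, e.g. `GC` covers `CG`).
#' @param stack_bonus extra stability when a pair sits directly inside
#'   another (i+1 paired to j-1 inside pair i,j).
#' @param min_hairpin minimum unpaired residues enclosed by a hairpin
#'   (at least 3).
#' @param temperature_scale inverse-temperature factor beta converting
#'   stabilities to Boltzmann exponents (weight = exp(beta * stability)).
#' @return an object of class `energy_model`.
#' @examples
#' m <- energy_model()
#' partition_probabilities("GGGAAACCC", m)
#' @export
energy_model <- function(pair_scores = c(GC = 3, AU = 2, GU = 1),
                         stack_bonus = 1, min_hairpin = 3L,
                         temperature_scale = 1) {
  stopifnot(all(c("GC", "AU", "GU") %in% names(pair_scores)),
            min_hairpin >= 3L, temperature_scale > 0,
            is.finite(stack_bonus))
  structure(list(pair_scores = pair_scores[c("GC", "AU", "GU")],
                 stack_bonus = stack_bonus,
                 min_hairpin = as.integer(min_hairpin),
                 temperature_scale = temperature_scale),
            class = "energy_model")
}

#' @export
print.energy_model <- function(x, ...) {
  cat("<energy_model> pair stabilities GC=", x$pair_scores["GC"],
      " AU=", x$pair_scores["AU"], " GU=", x$pair_scores["GU"],
      ", stack bonus ", x$stack_bonus,
      ", min hairpin ", x$min_hairpin, "\n", sep = "")
  invisible(x)
}

# stability of the (a, b) residue pair under the model, 0 if non-canonical
pair_score_lookup <- function(model) {
  sc <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "U"),
                                        c("A", "C", "G", "U")))
  sc["G", "C"] <- sc["C", "G"] <- model$pair_scores["GC"]
  sc["A", "U"] <- sc["U", "A"] <- model$pair_scores["AU"]
  sc["G", "U"] <- sc["U", "G"] <- model$pair_scores["GU"]
  sc
}

as_residues <- function(seq) {
  if (inherits(seq, "rna_group")) {
    stopifnot(length(seq) == 1L)
    seq <- seq$seqs[1L]
  }
  stopifnot(is.character(seq), length(seq) == 1L)
  strsplit(normalize_rna(seq), "")[[1L]]
}

# Boltzmann pair-weight matrix, optionally boosted by extrinsic information:
# w(i,j) = exp(beta * stability(i,j)) * (1 + gamma * E(i,j)), 0 if the pair
# is inadmissible.
pair_weight_matrix <- function(res, model, extrinsic = NULL, gamma = 20) {
  L <- length(res)
  sc <- pair_score_lookup(model)[res, res, drop = FALSE]
  w <- matrix(0, L, L)
  ok <- sc > 0
  w[ok] <- exp(model$temperature_scale * sc[ok])
  # hairpin minimum: |i - j| must exceed min_hairpin
  d <- abs(row(w) - col(w))
  w[d <= model$min_hairpin] <- 0
  if (!is.null(extrinsic)) {
    stopifnot(is.matrix(extrinsic), all(dim(extrinsic) == L))
    if (any(extrinsic < -1e-12)) stop("extrinsic bonuses must be nonnegative")
    E <- extrinsic
    E[lower.tri(E)] <- t(E)[lower.tri(E)]   # use the i<j orientation
    w <- w * (1 + gamma * pmax(E, 0))
  }
  w
}

#' Base-pair probabilities by partition function
#'
#' Exact pair probabilities under the simplified energy model, computed by
#' inside/outside dynamic programming over all pseudoknot-free structures
#' obeying the hairpin minimum. When an extrinsic pair-bonus matrix is
#' supplied (see [extrinsic_information()]), each admissible pair's
#' Boltzmann weight is multiplied by `1 + gamma * E(i, j)`, tilting the
#' ensemble toward pairs favored by the rest of the group.
#'
#' @param seq an RNA sequence (string) or single-sequence [rna_group].
#' @param model an [energy_model].
#' @param extrinsic optional nonnegative square matrix of pair bonuses.
#' @param gamma weight of the extrinsic term.
#' @return a [pair_probs] with the log partition function in attribute
#'   `"logQ"`.
#' @export
partition_probabilities <- function(seq, model = energy_model(),
                                    extrinsic = NULL, gamma = 20) {
  res <- as_residues(seq)
  w <- pair_weight_matrix(res, model, extrinsic, gamma)
  out <- c_partition(w, exp(model$temperature_scale * model$stack_bonus),
                     model$min_hairpin)
  pair_probs(out$P, logQ = out$logQ)
}

#' Ensemble folding free energy
#'
#' Returns `-(1 / beta) * log(Q)` where `Q` is the partition function sum
#' over all structures including the open chain, so a sequence with no
#' admissible pairs has free energy zero. This structure-choice-free
#' quantity stands in for scoring one predicted structure and is the input
#' to the free-energy Z-score feature.
#'
#' @inheritParams partition_probabilities
#' @return free energy in kcal/mol-equivalents (never positive).
#' @export
ensemble_free_energy <- function(seq, model = energy_model()) {
  res <- as_residues(seq)
  w <- pair_weight_matrix(res, model)
  out <- c_partition(w, exp(model$temperature_scale * model$stack_bonus),
                     model$min_hairpin)
  -out$logQ / model$temperature_scale
}

#' Brute-force pair probabilities (testing oracle)
#'
#' Enumerates every pseudoknot-free structure obeying the hairpin minimum,
#' Boltzmann-weights each, and returns exact pair probabilities. Refuses
#' sequences longer than `max_len` (the enumeration is exponential).
#'
#' @inheritParams partition_probabilities
#' @param max_len hard length cap.
#' @return a [pair_probs] with attribute `"logQ"`.
#' @export
brute_force_probabilities <- function(seq, model = energy_model(),
                                      max_len = 16L) {
  res <- as_residues(seq)
  L <- length(res)
  if (L > max_len) stop("refusing to enumerate structures for length > ",
                        max_len)
  structs <- enumerate_structures(res, model$min_hairpin)
  sc <- pair_score_lookup(model)
  wts <- vapply(structs, function(prs) {
    if (!NROW(prs)) return(1)
    e <- sum(sc[cbind(res[prs[, 1L]], res[prs[, 2L]])])
    if (nrow(prs) > 1L) {
      key <- paste(prs[, 1L], prs[, 2L])
      stacked <- paste(prs[, 1L] + 1L, prs[, 2L] - 1L) %in% key
      e <- e + model$stack_bonus * sum(stacked)
    }
    exp(model$temperature_scale * e)
  }, 0)
  Q <- sum(wts)
  P <- matrix(0, L, L)
  for (s in seq_along(structs)) {
    prs <- structs[[s]]
    if (NROW(prs)) {
      P[prs] <- P[prs] + wts[s]
      P[prs[, 2:1, drop = FALSE]] <- P[prs[, 2:1, drop = FALSE]] + wts[s]
    }
  }
  pair_probs(P / Q, logQ = log(Q))
}

# all pseudoknot-free structures on res as lists of 2-col pair matrices
enumerate_structures <- function(res, min_hairpin = 3L) {
  sc <- pair_score_lookup(energy_model())   # canonical-pair test only
  canon <- sc > 0
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (j - i < min_hairpin + 1L)
      return(list(matrix(integer(), 0L, 2L)))
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- rec(i, j - 1L)                       # j unpaired
    for (k in i:(j - min_hairpin - 1L)) {
      if (!canon[res[k], res[j]]) next
      left <- rec(i, k - 1L)
      right <- rec(k + 1L, j - 1L)
      for (a in left) for (b in right)
        out <- c(out, list(rbind(a, b, c(k, j))))
    }
    memo[[key]] <- out
    out
  }
  rec(1L, length(res))
}

#' Maximum expected accuracy structure
#'
#' Finds the pseudoknot-free structure maximizing
#' `sum(2 * gamma_mea * P(i, j))` over its pairs plus the unpaired
#' probabilities of its single-stranded positions, by dynamic programming.
#' Ties are broken deterministically in favor of leaving positions
#' unpaired, then the smallest 5' index.
#'
#' @param probs a [pair_probs].
#' @param gamma_mea weight on pairs relative to unpaired positions.
#' @param min_hairpin hairpin minimum imposed on the prediction.
#' @return an [rna_structure].
#' @export
mea_structure <- function(probs, gamma_mea = 1, min_hairpin = 3L) {
  stopifnot(inherits(probs, "pair_probs"))
  pairs <- c_mea(probs$P, probs$p_unpaired, gamma_mea, min_hairpin)
  rna_structure(pairs, probs$length, min_hairpin = min_hairpin)
}

#' Score a predicted structure against an accepted one
#'
#' Sensitivity is the fraction of accepted pairs that are predicted; PPV
#' (positive predictive value) is the fraction of predicted pairs that are
#' accepted. Both are defined as 1 when their denominator is zero.
#'
#' @param predicted,accepted [rna_structure] objects on the same length.
#' @return named numeric vector `c(sensitivity = , ppv = )`.
#' @export
score_structure <- function(predicted, accepted) {
  stopifnot(inherits(predicted, "rna_structure"),
            inherits(accepted, "rna_structure"))
  if (predicted$length != accepted$length)
    stop("structures are on different sequence lengths")
  keyp <- paste(predicted$pairs[, 1L], predicted$pairs[, 2L])
  keya <- paste(accepted$pairs[, 1L], accepted$pairs[, 2L])
  hit <- length(intersect(keyp, keya))
  c(sensitivity = if (length(keya)) hit / length(keya) else 1,
    ppv = if (length(keyp)) hit / length(keyp) else 1)
}
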