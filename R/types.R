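#' Construct a group of RNA sequences
#'
#' The atomic container handled by the pipeline: an ordered set of RNA
#' sequences with unique identifiers and optional ground-truth labels.
#' Residues are normalized to uppercase RNA (`T` is mapped to `U`).
#'
#' @param seqs character vector of sequences over A/C/G/U (T accepted).
#' @param ids character vector of unique identifiers; defaults to names of
#'   `seqs` or `seq1`, `seq2`, ...
#' @param labels optional per-sequence truth tags, each one of `"homolog"`,
#'   `"decoy"` or `"unknown"`.
#' @return An object of class `rna_group`: a list with elements `ids`,
#'   `seqs` and (possibly NULL) `labels`.
#' @examples
#' g <- rna_group(c(a = "GGGAAACCC", b = "GGCAAAGCC"))
#' length(g)
#' @export
rna_group <- function(seqs, ids = NULL, labels = NULL) {
  stopifnot(is.character(seqs), length(seqs) >= 1L)
  if (is.null(ids)) ids <- names(seqs) %||% paste0("seq", seq_along(seqs))
  ids <- as.character(ids)
  if (anyNA(ids) || any(!nzchar(ids)))
    stop("all sequence ids must be non-empty")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate sequence id: ", dup[1L])
  seqs <- normalize_rna(seqs, ids)
  if (!is.null(labels)) {
    labels <- as.character(labels)
    stopifnot(length(labels) == length(seqs))
    bad <- setdiff(unique(labels), c("homolog", "decoy", "unknown"))
    if (length(bad)) stop("unknown label: ", bad[1L])
  }
  structure(list(ids = ids, seqs = unname(seqs), labels = labels),
            class = "rna_group")
}

normalize_rna <- function(seqs, ids = NULL) {
  seqs <- chartr("t", "u", chartr("T", "U", toupper(seqs)))
  bad <- grepl("[^ACGU]", seqs)
  if (any(bad)) {
    who <- if (is.null(ids)) which(bad)[1L] else ids[bad][1L]
    stop("non-nucleotide characters in record '", who, "'")
  }
  if (any(!nzchar(seqs))) stop("zero-length sequence")
  seqs
}

#' @export
length.rna_group <- function(x) length(x$seqs)

#' @export
`[.rna_group` <- function(x, i) {
  rna_group(x$seqs[i], ids = x$ids[i],
            labels = if (!is.null(x$labels)) x$labels[i])
}

#' @export
print.rna_group <- function(x, ...) {
  cat("<rna_group> ", length(x), " sequences, lengths ",
      min(nchar(x$seqs)), "-", max(nchar(x$seqs)), "\n", sep = "")
  if (!is.null(x$labels))
    cat("  labels:", paste(sprintf("%s=%d", names(table(x$labels)),
                                   table(x$labels)), collapse = ", "), "\n")
  invisible(x)
}

#' Base-pair probability container
#'
#' Wraps a symmetric matrix of pair probabilities P(i, j) together with the
#' derived per-position pairing-status marginals: the probability that the
#' partner lies 3' of the position (`p_paired3`), 5' of it (`p_paired5`),
#' or that the position is unpaired (`p_unpaired`). The three marginals sum
#' to one at every position.
#'
#' @param P symmetric numeric matrix with entries in \[0, 1\] and zero
#'   diagonal.
#' @param logQ optional log partition function to carry along.
#' @return An object of class `pair_probs` with elements `P`, `p_paired5`,
#'   `p_paired3`, `p_unpaired`, `length`.
#' @export
pair_probs <- function(P, logQ = NULL) {
  stopifnot(is.matrix(P), nrow(P) == ncol(P))
  L <- nrow(P)
  if (any(P < -1e-9) || any(P > 1 + 1e-9)) stop("pair probability outside [0, 1]")
  if (L > 1 && max(abs(P - t(P))) > 1e-9) stop("pair probability matrix not symmetric")
  P <- pmin(pmax(P, 0), 1)
  diag(P) <- 0
  p3 <- sapply(seq_len(L), function(i) if (i < L) sum(P[i, (i + 1):L]) else 0)
  p5 <- sapply(seq_len(L), function(i) if (i > 1) sum(P[i, 1:(i - 1)]) else 0)
  paired <- p3 + p5
  if (any(paired > 1 + 1e-6))
    stop("per-nucleotide pairing marginal exceeds 1 at position ",
         which(paired > 1 + 1e-6)[1L])
  obj <- list(P = P, p_paired5 = p5, p_paired3 = p3,
              p_unpaired = pmax(1 - paired, 0), length = L)
  if (!is.null(logQ)) attr(obj, "logQ") <- logQ
  structure(obj, class = "pair_probs")
}

#' @export
print.pair_probs <- function(x, ...) {
  np <- sum(x$P[upper.tri(x$P)] > 0.001)
  cat("<pair_probs> length ", x$length, ", ", np,
      " pairs with P > 0.001\n", sep = "")
  invisible(x)
}

#' Plot a base-pair probability dot plot
#'
#' @param x a [pair_probs] object.
#' @param ... passed to [graphics::image].
#' @exportS3Method base::plot
plot.pair_probs <- function(x, ...) {
  image(seq_len(x$length), seq_len(x$length), x$P,
        xlab = "position", ylab = "position",
        col = grey(seq(1, 0, length.out = 64)), ...)
  invisible(x)
}

#' @importFrom grDevices grey
NULL

#' Secondary structure as a set of base pairs
#'
#' @param pairs two-column integer matrix of pairs (5' index, 3' index),
#'   1-based, or a zero-row matrix for the open chain.
#' @param length sequence length the structure lives on.
#' @param min_hairpin minimum number of unpaired residues enclosed by a
#'   hairpin-closing pair (validation only).
#' @return An object of class `rna_structure`.
#' @export
rna_structure <- function(pairs, length, min_hairpin = 3L) {
  if (is.null(pairs) || NROW(pairs) == 0L) {
    pairs <- matrix(integer(), 0L, 2L)
  } else {
    pairs <- matrix(as.integer(pairs), ncol = 2L)
    flip <- pairs[, 1L] > pairs[, 2L]
    pairs[flip, ] <- pairs[flip, 2:1]
    pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  }
  validate_structure(pairs, length, min_hairpin)
  structure(list(pairs = pairs, length = as.integer(length)),
            class = "rna_structure")
}

#' Validate a set of base pairs as a secondary structure
#'
#' Checks the structural invariants: indices inside the sequence, each
#' position in at most one pair, no pseudoknots, hairpin loops of at least
#' `min_hairpin` unpaired residues. Errors describe the first violation.
#'
#' @param pairs two-column matrix of (5', 3') indices.
#' @param length sequence length.
#' @param min_hairpin hairpin minimum.
#' @return TRUE, invisibly, when the structure is valid.
#' @export
validate_structure <- function(pairs, length, min_hairpin = 3L) {
  if (NROW(pairs) == 0L) return(invisible(TRUE))
  if (min(pairs) < 1L || max(pairs) > length)
    stop("pair index outside the sequence")
  idx <- as.vector(pairs)
  if (anyDuplicated(idx)) stop("a position takes part in more than one pair")
  if (any(pairs[, 2L] - pairs[, 1L] - 1L < min_hairpin))
    stop("hairpin loop shorter than ", min_hairpin, " unpaired residues")
  n <- nrow(pairs)
  if (n > 1L) {
    for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
      i <- pairs[a, 1L]; j <- pairs[a, 2L]
      k <- pairs[b, 1L]; l <- pairs[b, 2L]
      if (i < k && k < j && j < l) stop("pseudoknotted pairs (",
                                        i, ",", j, ") and (", k, ",", l, ")")
    }
  }
  invisible(TRUE)
}

#' @export
print.rna_structure <- function(x, ...) {
  cat("<rna_structure> length ", x$length, ", ", nrow(x$pairs),
      " pairs\n", sep = "")
  if (x$length <= 120) cat(" ", structure_to_dotbracket(x), "\n")
  invisible(x)
}

#' Convert a structure to dot-bracket notation
#' @param structure an [rna_structure].
#' @return a single dot-bracket string.
#' @export
structure_to_dotbracket <- function(structure) {
  db <- rep(".", structure$length)
  if (nrow(structure$pairs)) {
    db[structure$pairs[, 1L]] <- "("
    db[structure$pairs[, 2L]] <- ")"
  }
  paste(db, collapse = "")
}

#' Parse dot-bracket notation into a structure
#' @param db dot-bracket string over `.`, `(` and `)`.
#' @return an [rna_structure].
#' @export
dotbracket_to_structure <- function(db) {
  ch <- strsplit(db, "")[[1L]]
  if (any(!ch %in% c(".", "(", ")"))) stop("invalid dot-bracket character")
  stack <- integer(); pairs <- NULL
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket string")
      pairs <- rbind(pairs, c(stack[length(stack)], i))
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket string")
  rna_structure(pairs, length(ch))
}

#' Multiple sequence alignment container
#'
#' Stores gapped rows plus the two column/position maps used throughout the
#' feature calculations: `pos_of[[m]][col]` gives the ungapped position of
#' sequence `m` at an alignment column (NA at gaps) and `col_of[[m]][pos]`
#' the column of each position.
#'
#' @param rows character vector of equal-length gapped sequences
#'   (gap character `-`).
#' @param ids identifiers, defaulting to names of `rows`.
#' @return An object of class `rna_msa`.
#' @export
rna_msa <- function(rows, ids = NULL) {
  stopifnot(is.character(rows), length(rows) >= 1L)
  if (is.null(ids)) ids <- names(rows) %||% paste0("seq", seq_along(rows))
  wid <- unique(nchar(rows))
  if (length(wid) != 1L) stop("alignment rows have unequal lengths")
  rowmat <- do.call(rbind, strsplit(unname(rows), ""))
  pos_of <- lapply(seq_along(rows), function(m) {
    nongap <- rowmat[m, ] != "-"
    p <- rep(NA_integer_, wid)
    p[nongap] <- seq_len(sum(nongap))
    p
  })
  col_of <- lapply(pos_of, function(p) which(!is.na(p)))
  structure(list(rows = unname(rows), ids = as.character(ids),
                 width = wid, pos_of = pos_of, col_of = col_of),
            class = "rna_msa")
}

#' @export
print.rna_msa <- function(x, ...) {
  cat("<rna_msa> ", length(x$rows), " sequences x ", x$width,
      " columns\n", sep = "")
  show <- head(seq_along(x$rows), 8L)
  for (m in show)
    cat(sprintf(" %-12s %s\n", substr(x$ids[m], 1, 12),
                if (x$width <= 70) x$rows[m] else
                  paste0(substr(x$rows[m], 1, 67), "...")))
  invisible(x)
}

# strip gaps from one alignment row
ungap <- function(row) gsub("-", "", row, fixed = TRUE)
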