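#' Read a FASTA file into an RNA group
#'
#' Sequences are normalized (uppercase, T mapped to U) and validated; the
#' first whitespace-separated token of each header is the identifier. A
#' `label=homolog|decoy|unknown` token in the header, as written by
#' [write_fasta()] for simulated corpora, is picked up as the truth label.
#'
#' @param path path to a FASTA file.
#' @return an [rna_group].
#' @examples
#' g <- read_fasta(system.file("extdata", "example_group.fasta",
#'                             package = "rnadecoy"))
#' g
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no sequences in ", path)
  headers <- names(set)
  ids <- vapply(strsplit(headers, "\\s+"), `[`, "", 1L)
  labels <- rep(NA_character_, length(set))
  hit <- regmatches(headers, regexpr("label=\\S+", headers))
  has <- grepl("label=", headers)
  labels[has] <- sub("label=", "", hit)
  labels <- if (all(is.na(labels))) NULL else ifelse(is.na(labels), "unknown", labels)
  rna_group(as.character(set), ids = ids, labels = labels)
}

#' Write an RNA group to FASTA
#'
#' @param group an [rna_group].
#' @param path output path.
#' @param width line width for wrapping residues.
#' @export
write_fasta <- function(group, path, width = 70L) {
  con <- file(path, "w"); on.exit(close(con))
  for (m in seq_along(group$ids)) {
    hdr <- group$ids[m]
    if (!is.null(group$labels)) hdr <- paste0(hdr, " label=", group$labels[m])
    writeLines(paste0(">", hdr), con)
    s <- group$seqs[m]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a base-pair probability matrix from "i j prob" text
#'
#' One whitespace-delimited line per pair, 1-based indices; unlisted pairs
#' are zero. The file is rejected if any probability falls outside \[0, 1\],
#' an index exceeds `length`, or a per-nucleotide pairing marginal exceeds
#' one beyond rounding.
#'
#' @param path path to the text file (comment lines starting `#` ignored).
#' @param length sequence length defining the matrix dimension.
#' @return a [pair_probs].
#' @export
read_pair_probs <- function(path, length) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  P <- matrix(0, length, length)
  if (length(lines)) {
    tab <- read.table(text = lines, col.names = c("i", "j", "p"))
    if (any(tab$p < 0 | tab$p > 1))
      stop("pair probability outside [0, 1] in ", path)
    if (any(tab$i < 1 | tab$i > length | tab$j < 1 | tab$j > length))
      stop("pair index out of range in ", path)
    if (any(tab$i == tab$j)) stop("self-pair in ", path)
    for (r in seq_len(nrow(tab))) {
      P[tab$i[r], tab$j[r]] <- tab$p[r]
      P[tab$j[r], tab$i[r]] <- tab$p[r]
    }
  }
  pair_probs(P)
}

#' Write a base-pair probability matrix as "i j prob" text
#'
#' @param probs a [pair_probs].
#' @param path output path.
#' @param digits decimal places written (values rounding to zero are
#'   omitted, so a write/read round trip agrees to `digits` places).
#' @export
write_pair_probs <- function(probs, path, digits = 6L) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# pair probabilities, length %d", probs$length), con)
  idx <- which(upper.tri(probs$P) & probs$P >= 0.5 * 10^(-digits), arr.ind = TRUE)
  if (nrow(idx)) {
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
    writeLines(sprintf(paste0("%d %d %.", digits, "f"),
                       idx[, 1L], idx[, 2L], probs$P[idx]), con)
  }
  invisible(path)
}

#' Read a structure file (dot-bracket or CT)
#'
#' Dot-bracket files carry an optional `>id` header, the sequence line and
#' the bracket line; CT is the standard 6-column connect table.
#'
#' @param path input path; format chosen by extension (`.ct` for CT,
#'   anything else parsed as dot-bracket) unless `format` is given.
#' @param format `"dotbracket"`, `"ct"`, or `NULL` to infer.
#' @return list with `id`, `seq` (possibly NA) and `structure`
#'   (an [rna_structure]).
#' @export
read_structure <- function(path, format = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  format <- format %||%
    (if (grepl("\\.ct$", path, ignore.case = TRUE)) "ct" else "dotbracket")
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (format == "ct") {
    hdr <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
    L <- as.integer(hdr[1L])
    body <- read.table(text = lines[-1L])
    if (nrow(body) != L) stop("CT body does not match header length")
    pairto <- as.integer(body[[5L]])
    keep <- pairto > seq_len(L)
    pairs <- cbind(which(keep), pairto[keep])
    list(id = paste(hdr[-1L], collapse = " "),
         seq = paste(body[[2L]], collapse = ""),
         structure = rna_structure(pairs, L))
  } else {
    id <- NA_character_
    if (startsWith(lines[1L], ">")) {
      id <- sub("^>\\s*", "", lines[1L]); lines <- lines[-1L]
    }
    seqline <- NA_character_
    if (length(lines) > 1L && grepl("^[ACGUTacgut]+$", lines[1L])) {
      seqline <- normalize_rna(lines[1L]); lines <- lines[-1L]
    }
    list(id = id, seq = seqline,
         structure = dotbracket_to_structure(trimws(lines[1L])))
  }
}

#' Write a structure to dot-bracket or CT
#'
#' @param structure an [rna_structure].
#' @param path output path.
#' @param seq the sequence (required for CT output).
#' @param id record identifier.
#' @param format `"dotbracket"` (canonical) or `"ct"`.
#' @export
write_structure <- function(structure, path, seq = NULL, id = "structure",
                            format = c("dotbracket", "ct")) {
  format <- match.arg(format)
  con <- file(path, "w"); on.exit(close(con))
  if (format == "dotbracket") {
    writeLines(paste0(">", id), con)
    if (!is.null(seq)) writeLines(seq, con)
    writeLines(structure_to_dotbracket(structure), con)
  } else {
    if (is.null(seq)) stop("CT output needs the sequence")
    L <- structure$length
    stopifnot(nchar(seq) == L)
    partner <- integer(L)
    if (nrow(structure$pairs)) {
      partner[structure$pairs[, 1L]] <- structure$pairs[, 2L]
      partner[structure$pairs[, 2L]] <- structure$pairs[, 1L]
    }
    writeLines(sprintf("%5d %s", L, id), con)
    ch <- strsplit(seq, "")[[1L]]
    writeLines(sprintf("%5d %s %7d %4d %4d %4d", seq_len(L), ch,
                       seq_len(L) - 1L, c(seq_len(L - 1L) + 1L, 0L),
                       partner, seq_len(L)), con)
  }
  invisible(path)
}

#' Write an alignment as aligned FASTA
#' @param msa an [rna_msa].
#' @param path output path.
#' @export
write_msa <- function(msa, path) {
  g <- list(ids = msa$ids, seqs = msa$rows, labels = NULL)
  con <- file(path, "w"); on.exit(close(con))
  for (m in seq_along(g$ids)) {
    writeLines(c(paste0(">", g$ids[m]), g$seqs[m]), con)
  }
  invisible(path)
}

#' Read an aligned FASTA file
#' @param path input path.
#' @return an [rna_msa].
#' @export
read_msa <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no sequences in ", path)
  rows <- chartr("t", "u", chartr("T", "U", toupper(as.character(set))))
  rows <- gsub("\\.", "-", rows)
  bad <- grepl("[^ACGU-]", rows)
  if (any(bad)) stop("non-nucleotide characters in alignment row ",
                     names(set)[bad][1L])
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1L)
  rna_msa(rows, ids = ids)
}

#' Write a per-sequence classification report
#'
#' Tab-separated table in input order: identifier, the six features, the
#' decoy probability and the verdict at the supplied threshold.
#'
#' @param results data frame as returned by [classify_group()] (columns
#'   `id`, the feature columns, `decoy_probability`).
#' @param path output path.
#' @param threshold decoy-call threshold on the probability.
#' @export
write_report <- function(results, path, threshold = 0.4971) {
  stopifnot(is.data.frame(results), "id" %in% names(results),
            "decoy_probability" %in% names(results))
  out <- results
  out$verdict <- ifelse(out$decoy_probability >= threshold, "decoy", "homolog")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# rnadecoy %s; decoy threshold %g",
                     as.character(packageVersion("rnadecoy")), threshold), con)
  write.table(format(out, digits = 6L, scientific = FALSE), con,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a flat key=value configuration file
#'
#' Lines are `key = value`; a value wrapped in braces is split on `;` into a
#' character vector (this accepts the `InSeq = {a.fa;b.fa;}` sequence-list
#' dialect of external folding engines). Unknown keys are kept verbatim;
#' lines that parse as neither are skipped with a warning.
#'
#' @param path path to the config file.
#' @return named list of character values.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*[#;]", lines)]
  cfg <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      warning("skipping unparseable config line: ", ln)
      next
    }
    key <- trimws(sub("=.*", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (grepl("^\\{.*\\}$", val)) {
      val <- strsplit(gsub("^\\{|\\}$", "", val), ";")[[1L]]
      val <- trimws(val[nzchar(trimws(val))])
    }
    cfg[[key]] <- val
  }
  cfg
}
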