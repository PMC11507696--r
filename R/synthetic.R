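#' Random nested consensus structure
#'
#' Draws a pseudoknot-free structure with at least two helices of three or
#' more stacked pairs, hairpin loops of at least three residues, and a
#' paired-residue coverage between 30 and 60 percent of the sequence;
#' longer structures may be wrapped in an additional closing helix. Used as
#' the conserved core of a simulated RNA family.
#'
#' @param length sequence length (at least 10; lengths of typical small
#'   structured RNAs, 40-120, are the intended range).
#' @param seed optional RNG seed.
#' @return an [rna_structure].
#' @export
random_consensus_structure <- function(length, seed = NULL) {
  stopifnot(length >= 10L)
  with_seed(seed, {
    for (attempt in 1:200) {
      st <- try(draw_structure_once(length), silent = TRUE)
      if (inherits(st, "try-error") || is.null(st)) next
      npair <- nrow(st$pairs)
      cov <- 2 * npair / length
      if (cov >= 0.3 && cov <= 0.6) return(st)
    }
    stop("failed to draw a consensus structure for length ", length)
  })
}

# one attempt: sequential hairpin modules, optionally wrapped by an outer
# helix; returns NULL when the pieces do not fit
draw_structure_once <- function(length) {
  target_cov <- runif(1, 0.35, 0.55)
  outer_helix <- length >= 60 && runif(1) < 0.5
  avail <- length
  outer_len <- 0L
  if (outer_helix) {
    outer_len <- sample(3:5, 1L)
    avail <- avail - 2L * outer_len
  }
  n_pairs_target <- max(6L, round(target_cov * length / 2) - outer_len)
  nh_max <- max(2L, min(3L, avail %/% 16L))
  nh <- if (nh_max <= 2L) 2L else sample(2:nh_max, 1L)
  base <- n_pairs_target %/% nh
  hel <- pmax(3L, base + sample(-1:1, nh, replace = TRUE))
  loops <- sample(3:6, nh, replace = TRUE)
  used <- sum(2L * hel + loops)
  if (used > avail) {
    # shrink helices (never below 3) until the modules fit
    while (used > avail && any(hel > 3L)) {
      k <- which.max(hel)
      hel[k] <- hel[k] - 1L
      used <- used - 2L
    }
    if (used > avail) return(NULL)
  }
  spare <- avail - used
  gaps <- tabulate(sample.int(nh + 1L, spare, replace = TRUE), nh + 1L)
  pairs <- NULL
  cursor <- if (outer_helix) outer_len else 0L
  cursor <- cursor + gaps[1L]
  for (k in seq_len(nh)) {
    h <- hel[k]; l <- loops[k]
    left <- cursor + seq_len(h)
    right <- cursor + 2L * h + l + 1L - seq_len(h)
    pairs <- rbind(pairs, cbind(left, right))
    cursor <- cursor + 2L * h + l + gaps[k + 1L]
  }
  if (outer_helix) {
    pairs <- rbind(pairs,
                   cbind(seq_len(outer_len), length + 1L - seq_len(outer_len)))
  }
  rna_structure(pairs, length)
}

# canonical pair classes and sampling weights used when seeding families
CANONICAL_PAIRS <- c("GC", "CG", "AU", "UA", "GU", "UG")
CANONICAL_WEIGHTS <- c(0.30, 0.30, 0.15, 0.15, 0.05, 0.05)

# per-position substitution rate giving an expected pairwise identity
# near `target` between two members mutated independently from one seed:
# P(same) = (1 - mu)^2 + mu^2 / 3
identity_to_rate <- function(target) {
  stopifnot(target > 0, target <= 1)
  if (target >= 1) return(0)
  f <- function(mu) (1 - mu)^2 + mu^2 / 3 - target
  uniroot(f, c(0, 0.75))$root
}

#' Simulate an RNA family with a conserved structure
#'
#' Seeds a random sequence compatible with the consensus structure
#' (canonical pairs at paired positions, GC-rich helices) and derives each
#' member by point mutations calibrated to the target mean pairwise
#' identity. Mutations hitting a paired position are compensatory with
#' probability `compensatory`: both partners switch to another canonical
#' pair, preserving the consensus structure.
#'
#' @param length sequence length; ignored when `structure` is supplied.
#' @param n_members number of family members.
#' @param target_identity desired mean pairwise identity (families in the
#'   0.5-0.8 range behave like typical curated seed alignments).
#' @param structure optional [rna_structure] to use as the consensus.
#' @param compensatory probability that a mutation at a paired position
#'   changes both partners to another canonical pair.
#' @param family_id identifier prefix for member names.
#' @param seed optional RNG seed.
#' @return an [rna_group] with attributes `"consensus"` (the structure),
#'   `"family_id"` and `"mean_identity"` (realized value).
#' @export
generate_family <- function(length = 80L, n_members = 10L,
                            target_identity = 0.65, structure = NULL,
                            compensatory = 0.9, family_id = "fam",
                            seed = NULL) {
  with_seed(seed, {
    if (is.null(structure)) structure <- random_consensus_structure(length)
    L <- structure$length
    pairs <- structure$pairs
    paired5 <- pairs[, 1L]; paired3 <- pairs[, 2L]
    partner <- integer(L)
    partner[paired5] <- paired3; partner[paired3] <- paired5
    seedres <- sample(c("A", "C", "G", "U"), L, replace = TRUE)
    ptype <- sample(CANONICAL_PAIRS, nrow(pairs), replace = TRUE,
                    prob = CANONICAL_WEIGHTS)
    seedres[paired5] <- substr(ptype, 1L, 1L)
    seedres[paired3] <- substr(ptype, 2L, 2L)
    mu <- identity_to_rate(target_identity)
    members <- vapply(seq_len(n_members), function(m) {
      res <- seedres
      # unpaired positions: independent substitutions
      un <- which(partner == 0L)
      hit <- un[runif(length(un)) < mu]
      for (i in hit) res[i] <- sample(setdiff(c("A", "C", "G", "U"), res[i]), 1L)
      # paired positions: mutate each pair with the same per-position rate
      hitp <- which(runif(nrow(pairs)) < mu)
      for (r in hitp) {
        i <- pairs[r, 1L]; j <- pairs[r, 2L]
        if (runif(1) < compensatory) {
          cur <- paste0(res[i], res[j])
          alt <- sample(setdiff(CANONICAL_PAIRS, cur), 1L)
          res[i] <- substr(alt, 1L, 1L); res[j] <- substr(alt, 2L, 2L)
        } else {
          side <- if (runif(1) < 0.5) i else j
          res[side] <- sample(setdiff(c("A", "C", "G", "U"), res[side]), 1L)
        }
      }
      paste(res, collapse = "")
    }, "")
    fam <- rna_group(members,
                     ids = sprintf("%s_m%02d", family_id, seq_len(n_members)),
                     labels = rep("homolog", n_members))
    attr(fam, "consensus") <- structure
    attr(fam, "family_id") <- family_id
    attr(fam, "mean_identity") <-
      mean_pairwise_identity(rna_msa(fam$seqs, ids = fam$ids))
    fam
  })
}

#' Assemble a labeled analysis group from simulated families
#'
#' Samples homologs from one family and adds decoys that are either
#' shuffled family members (`keep_fraction` = the family's mean pairwise
#' identity) or sequences drawn from other families; member order is
#' shuffled and ground-truth labels are attached.
#'
#' @param families named list of [generate_family()] outputs.
#' @param family_id which family supplies the homologs (default: sampled).
#' @param n_homologs number of homologs, 5-20 in the standard protocol.
#' @param n_decoys number of decoys, 0-3.
#' @param decoy_kind `"cross_family"`, `"shuffled"`, or `"mixed"` (each
#'   decoy drawn 50/50).
#' @param seed optional RNG seed.
#' @return an [rna_group] with truth labels and attribute `"family_id"`.
#' @export
build_group <- function(families, family_id = NULL, n_homologs = 8L,
                        n_decoys = 1L,
                        decoy_kind = c("mixed", "cross_family", "shuffled"),
                        seed = NULL) {
  decoy_kind <- match.arg(decoy_kind)
  stopifnot(n_homologs >= 2L, n_decoys >= 0L)
  if (decoy_kind %in% c("mixed", "cross_family") && n_decoys > 0L &&
      length(families) < 2L)
    stop("cross-family decoys need at least 2 families")
  with_seed(seed, {
    if (is.null(family_id)) family_id <- sample(names(families), 1L)
    fam <- families[[family_id]]
    if (length(fam) < n_homologs)
      stop("family ", family_id, " has fewer than ", n_homologs, " members")
    take <- sample.int(length(fam), n_homologs)
    group <- fam[take]
    keep <- attr(fam, "mean_identity")
    if (n_decoys > 0L) {
      for (d in seq_len(n_decoys)) {
        kind <- switch(decoy_kind,
                       mixed = sample(c("cross_family", "shuffled"), 1L),
                       decoy_kind)
        rec <- if (kind == "shuffled") {
          pool <- setdiff(seq_along(fam$ids), take)
          src <- if (length(pool)) pool[sample.int(length(pool), 1L)]
                 else take[sample.int(length(take), 1L)]
          shuffle_decoy(fam$seqs[src], keep_fraction = keep,
                        id = fam$ids[src])
        } else {
          cross_family_decoy(families, exclude = family_id)
        }
        # keep ids unique if the same donor is drawn twice
        while (rec$ids %in% group$ids) rec$ids <- paste0(rec$ids, "x")
        group <- rna_group(c(group$seqs, rec$seqs),
                           ids = c(group$ids, rec$ids),
                           labels = c(group$labels, rec$labels))
      }
    }
    ord <- sample.int(length(group))
    out <- group[ord]
    attr(out, "family_id") <- family_id
    out
  })
}

#' Build a train/test corpus of simulated groups
#'
#' Mirrors the standard protocol at a configurable scale: training groups
#' mix shuffled and cross-family decoys (plus no-decoy controls), test
#' groups separate the two decoy kinds, and the family sets used for
#' training and testing are disjoint. The default
#' `groups_per_condition = 60` with `test_groups_per_condition = 10` is a
#' 1/10-scale corpus: 3 x 60 decoy conditions + 30 controls = 210 training
#' groups and 6 x 10 + 10 = 70 test groups.
#'
#' @param n_train_families,n_test_families how many families to simulate
#'   for each partition.
#' @param groups_per_condition training groups per decoy count (1, 2, 3);
#'   half as many no-decoy controls are added.
#' @param test_groups_per_condition test groups per decoy kind and count,
#'   plus that many no-decoy controls.
#' @param length_range,identity_range per-family length and mean-identity
#'   ranges sampled uniformly.
#' @param members_per_family sequences simulated per family.
#' @param seed RNG seed for the whole corpus.
#' @return list with `train` and `test` (lists of labeled [rna_group]),
#'   `train_families`, `test_families`, and a `manifest` data frame
#'   (group id, partition, family, sizes, decoy kind).
#' @export
build_corpus <- function(n_train_families = 8L, n_test_families = 5L,
                         groups_per_condition = 60L,
                         test_groups_per_condition = 10L,
                         length_range = c(40L, 120L),
                         identity_range = c(0.5, 0.8),
                         members_per_family = 24L,
                         seed = 1L) {
  stopifnot(n_train_families >= 2L, n_test_families >= 2L)
  with_seed(seed, {
    make_families <- function(prefix, n) {
      fams <- lapply(seq_len(n), function(k)
        generate_family(length = sample(length_range[1L]:length_range[2L], 1L),
                        n_members = members_per_family,
                        target_identity = runif(1, identity_range[1L],
                                                identity_range[2L]),
                        family_id = sprintf("%s%02d", prefix, k)))
      names(fams) <- vapply(fams, attr, "", "family_id")
      fams
    }
    train_fams <- make_families("trn", n_train_families)
    test_fams <- make_families("tst", n_test_families)

    manifest <- NULL
    make_groups <- function(fams, spec_rows, prefix) {
      groups <- vector("list", nrow(spec_rows))
      for (g in seq_len(nrow(spec_rows))) {
        nh <- sample(5:20, 1L)
        grp <- build_group(fams, n_homologs = min(nh, members_per_family),
                           n_decoys = spec_rows$n_decoys[g],
                           decoy_kind = spec_rows$kind[g])
        gid <- sprintf("%s_g%03d", prefix, g)
        attr(grp, "group_id") <- gid
        groups[[g]] <- grp
        manifest <<- rbind(manifest, data.frame(
          group = gid, partition = prefix,
          family = attr(grp, "family_id"),
          n_total = length(grp),
          n_decoys = sum(grp$labels == "decoy"),
          kind = spec_rows$kind[g], stringsAsFactors = FALSE))
      }
      groups
    }
    train_spec <- rbind(
      data.frame(n_decoys = rep(1:3, each = groups_per_condition),
                 kind = "mixed", stringsAsFactors = FALSE),
      data.frame(n_decoys = rep(0L, max(1L, groups_per_condition %/% 2L)),
                 kind = "mixed", stringsAsFactors = FALSE))
    test_spec <- rbind(
      data.frame(n_decoys = rep(1:3, each = test_groups_per_condition),
                 kind = "cross_family", stringsAsFactors = FALSE),
      data.frame(n_decoys = rep(1:3, each = test_groups_per_condition),
                 kind = "shuffled", stringsAsFactors = FALSE),
      data.frame(n_decoys = rep(0L, test_groups_per_condition),
                 kind = "mixed", stringsAsFactors = FALSE))
    train <- make_groups(train_fams, train_spec, "train")
    test <- make_groups(test_fams, test_spec, "test")
    list(train = train, test = test,
         train_families = train_fams, test_families = test_fams,
         manifest = manifest)
  })
}
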