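# Divergence-based family clustering.
#
# Families follow the criterion: a group of sequences is a family when its
# highest intra-group divergence is lower than its divergence to any other
# group, with no overlap between the intra- and inter-group distance
# distributions. The partitioner is a single-linkage agglomerative sweep that
# re-tests the global criterion after every merge and returns the
# fewest-family state that satisfies it (all-singletons satisfies it
# vacuously, so a valid partition always exists).

#' Pairwise p-distances with pairwise deletion of gaps
#'
#' Proportion of differing sites per pair, excluding sites where either
#' member carries a gap (`-` or `.`).
#'
#' @param aligned_seqs Named character vector of equal-length aligned rows
#'   (nucleotide or amino acid).
#' @return Symmetric numeric matrix with zero diagonal, `deletion_mode`
#'   attribute `"pairwise"`.
#' @export
pairwise_p_distance <- function(aligned_seqs) {
  n <- length(aligned_seqs)
  if (n < 2L) abort("need at least 2 sequences")
  lens <- nchar(aligned_seqs)
  if (length(unique(lens)) != 1L) abort("aligned rows must have equal length")
  ids <- names(aligned_seqs) %||% sprintf("seq%d", seq_len(n))
  ids[!nzchar(ids)] <- sprintf("seq%d", which(!nzchar(ids)))
  mat <- do.call(rbind, lapply(aligned_seqs, function(s) seq_chars(toupper(s))))
  gap <- mat == "-" | mat == "."
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !gap[i, ] & !gap[j, ]
      nc <- sum(ok)
      if (nc == 0L) {
        abort(sprintf("no comparable sites between '%s' and '%s'", ids[i], ids[j]),
              class = "ltrtrace_undefined_distance")
      }
      d[i, j] <- d[j, i] <- sum(mat[i, ok] != mat[j, ok]) / nc
    }
  }
  attr(d, "deletion_mode") <- "pairwise"
  d
}

# max intra / min inter of a partition; NA when undefined
.partition_stats <- function(d, assignment) {
  ids <- rownames(d)
  fam <- assignment[ids]
  same <- outer(fam, fam, "==")
  ut <- upper.tri(d)
  intra <- d[ut & same]
  inter <- d[ut & !same]
  list(max_intra = if (length(intra)) max(intra) else NA_real_,
       min_inter = if (length(inter)) min(inter) else NA_real_)
}

# global non-overlap criterion: max intra strictly below min inter. The
# all-singletons partition satisfies it vacuously. A partition with a single
# family has no inter-group distances to compare against, so it is accepted
# only in the degenerate case of identical members (max intra 0) — a diverse
# group cannot be validated as one family without an outgroup.
.criterion_ok <- function(d, assignment) {
  st <- .partition_stats(d, assignment)
  if (is.na(st$max_intra)) return(TRUE)
  if (is.na(st$min_inter)) return(st$max_intra == 0)
  st$max_intra < st$min_inter
}

#' Partition sequences into families by the divergence-overlap criterion
#'
#' Single-linkage agglomerative sweep over pairs ordered by distance (ties
#' broken by lexicographic id pair); after each merge the global criterion —
#' max intra-family distance strictly below min inter-family distance, i.e.
#' disjoint intra/inter distributions — is re-tested, and the fewest-family
#' state that satisfied it is returned.
#'
#' @param d Distance matrix from [pairwise_p_distance()].
#' @return Object of class `family_partition`: `$assignment` (tibble `id`,
#'   `family`), `$max_intra` and `$min_inter` (per family / family pair),
#'   `$criterion_satisfied` (always `TRUE`), `$n_families`.
#' @export
partition_families <- function(d) {
  ids <- rownames(d)
  n <- length(ids)
  pairs <- tibble(
    i = rep(seq_len(n), times = n), j = rep(seq_len(n), each = n)) %>%
    filter(.data$i < .data$j) %>%
    mutate(dist = d[cbind(.data$i, .data$j)],
           a = pmin(ids[.data$i], ids[.data$j]),
           b = pmax(ids[.data$i], ids[.data$j])) %>%
    arrange(.data$dist, .data$a, .data$b)
  assignment <- setNames(ids, ids)
  best <- assignment
  for (r in seq_len(nrow(pairs))) {
    fa <- assignment[ids[pairs$i[r]]]
    fb <- assignment[ids[pairs$j[r]]]
    if (fa == fb) next
    assignment[assignment == fb] <- fa
    if (.criterion_ok(d, assignment)) best <- assignment
  }
  fam_ids <- unique(best)
  relabel <- setNames(sprintf("F%02d", seq_along(fam_ids)), fam_ids)
  assignment_tbl <- tibble(id = ids, family = unname(relabel[best[ids]]))
  fams <- split(assignment_tbl$id, assignment_tbl$family)
  max_intra <- tibble(
    family = names(fams),
    max_intra = map_dbl(fams, function(m) {
      if (length(m) < 2L) return(NA_real_)
      max(d[m, m][upper.tri(d[m, m])])
    }))
  pairs_f <- if (length(fams) > 1L) {
    cmb <- combn(names(fams), 2L)
    tibble(family_a = cmb[1, ], family_b = cmb[2, ],
           min_inter = vapply(seq_len(ncol(cmb)), function(k) {
             min(d[fams[[cmb[1, k]]], fams[[cmb[2, k]]], drop = FALSE])
           }, numeric(1)))
  } else {
    tibble(family_a = character(0), family_b = character(0),
           min_inter = numeric(0))
  }
  stopifnot(.criterion_ok(d, setNames(assignment_tbl$family, assignment_tbl$id)))
  structure(list(assignment = assignment_tbl, max_intra = max_intra,
                 min_inter = pairs_f, criterion_satisfied = TRUE,
                 n_families = length(fams), distances = d),
            class = "family_partition")
}

#' @export
print.family_partition <- function(x, ...) {
  cat(sprintf("<family_partition> %d sequences in %d families\n",
              nrow(x$assignment), x$n_families))
  invisible(x)
}

# global alignment identity between two unaligned sequences
.global_identity <- function(a, b) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = TRUE),
    gapOpening = 5, gapExtension = 2)
  Biostrings::pid(al, type = "PID1") / 100
}

#' Assign a query sequence to an existing family
#'
#' Computes global-alignment identity (match +1 / mismatch -1, gap open 5 /
#' extend 2) between the query and each family representative, and assigns
#' the family whose best representative identity is maximal and exceeds that
#' family's threshold.
#'
#' @param query DNA string.
#' @param representatives Tibble with columns `family`, `sequence` (one or
#'   more representatives per family).
#' @param min_identity_per_family Either a single threshold or a named
#'   numeric vector keyed by family.
#' @return One-row tibble: `family` (NA when unassigned), `identity`,
#'   `assigned`.
#' @export
assign_to_family <- function(query, representatives, min_identity_per_family = 0.9) {
  if (!nrow(representatives)) abort("representatives must be non-empty")
  per_fam <- representatives %>%
    group_by(.data$family) %>%
    summarise(identity = max(vapply(.data$sequence, .global_identity, numeric(1),
                                    a = query)), .groups = "drop") %>%
    arrange(desc(.data$identity))
  thr <- if (length(min_identity_per_family) == 1L && is.null(names(min_identity_per_family))) {
    setNames(rep(min_identity_per_family, nrow(per_fam)), per_fam$family)
  } else min_identity_per_family
  per_fam <- mutate(per_fam, threshold = unname(thr[.data$family]),
                    passes = .data$identity >= .data$threshold)
  top <- per_fam[per_fam$passes, , drop = FALSE]
  if (nrow(top)) {
    tibble(family = top$family[1], identity = top$identity[1], assigned = TRUE)
  } else {
    tibble(family = NA_character_, identity = per_fam$identity[1], assigned = FALSE)
  }
}
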