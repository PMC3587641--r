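# Overlap-validated assembly of walking fragments into chimeric consensus
# elements. Joins require a minimum suffix/prefix overlap and a minimum
# ungapped DNA identity over the overlap (gaps are not modelled: walking
# products are orientation-normalised, substitution-only copies). Overlaps
# are found by an exhaustive ungapped offset scan, which is exact at these
# input sizes.

#' Assembly thresholds
#'
#' @param min_overlap Minimum suffix/prefix overlap between two fragments (bp).
#' @param min_identity Minimum DNA identity over the overlap.
#' @return Object of class `assembly_params`.
#' @export
assembly_params <- function(min_overlap = 50L, min_identity = 0.95) {
  if (min_overlap < 1L) abort("min_overlap must be >= 1")
  if (min_identity <= 0 || min_identity > 1) abort("min_identity must be in (0, 1]")
  structure(list(min_overlap = as.integer(min_overlap),
                 min_identity = min_identity), class = "assembly_params")
}

# identity of the length-L suffix(a)/prefix(b) overlap for all L
.overlap_scan <- function(a, b) {
  na <- nchar(a); nb <- nchar(b)
  lmax <- min(na, nb)
  ac <- seq_chars(a); bc <- seq_chars(b)
  vapply(seq_len(lmax), function(L) {
    sum(ac[(na - L + 1L):na] == bc[seq_len(L)]) / L
  }, numeric(1))
}

#' Validate a candidate join between two fragments
#'
#' Scans all suffix(`a`)/prefix(`b`) overlap lengths and accepts the best
#' candidate meeting both thresholds (highest identity, then the shortest
#' sufficient overlap — walking products of LTR elements can share their
#' entire terminal repeat, so the longest equal-identity overlap may join
#' non-adjacent fragments); rejections name the threshold that failed.
#'
#' @param a,b Fragment DNA strings (a's suffix against b's prefix).
#' @param params [assembly_params()].
#' @return One-row tibble: `accepted`, `overlap_length`, `identity`,
#'   `offset` (start of `b` relative to `a`, 1-based), `reason` (`NA` when
#'   accepted, otherwise `"overlap_below_minimum"` or
#'   `"identity_below_minimum"`).
#' @export
validate_join <- function(a, b, params = assembly_params()) {
  if (!nchar(a) || !nchar(b)) abort("fragments must be non-empty")
  idents <- .overlap_scan(a, b)
  ls <- seq_along(idents)
  ok_id <- idents >= params$min_identity
  ok_len <- ls >= params$min_overlap
  pick <- function(cand) cand[order(-idents[cand], -ls[cand])][1]
  pick_short <- function(cand) cand[order(-idents[cand], ls[cand])][1]
  row <- function(L, accepted, reason) {
    tibble(accepted = accepted, overlap_length = L, identity = idents[L],
           offset = nchar(a) - L + 1L, reason = reason)
  }
  if (any(ok_id & ok_len)) {
    return(row(pick_short(which(ok_id & ok_len)), TRUE, NA_character_))
  }
  if (any(ok_id)) {
    return(row(pick(which(ok_id)), FALSE, "overlap_below_minimum"))
  }
  if (!any(ok_len)) {
    return(row(pick(ls), FALSE, "overlap_below_minimum"))
  }
  row(pick(which(ok_len)), FALSE, "identity_below_minimum")
}

# column-majority consensus of fragments placed at offsets (ties: the
# earliest-listed fragment)
.layout_consensus <- function(seqs, offsets, input_order) {
  span <- max(offsets + nchar(seqs) - 1L)
  votes <- vector("list", span)
  ord <- order(input_order)
  cons <- character(span)
  for (i in ord) {
    chars <- seq_chars(seqs[i])
    pos <- offsets[i] + seq_along(chars) - 1L
    for (k in seq_along(chars)) {
      votes[[pos[k]]] <- c(votes[[pos[k]]], chars[k])
    }
  }
  for (p in seq_len(span)) {
    v <- votes[[p]]
    tab <- table(v)
    winners <- names(tab)[tab == max(tab)]
    cons[p] <- if (length(winners) == 1L) winners else v[v %in% winners][1]
  }
  paste0(cons, collapse = "")
}

#' Assemble fragments into a chimeric consensus
#'
#' Greedy best-overlap layout: all directed fragment joins passing
#' [validate_join()] are computed, and contigs are merged best-join-first
#' (highest identity, then shortest sufficient overlap, then lexicographic
#' ids; see [validate_join()] for why short wins ties).
#' Disagreeing overlap columns are resolved by majority, ties by the
#' first-listed fragment. Fragments with no valid join are reported
#' unplaced.
#'
#' @param fragments Named character vector of fragment DNA.
#' @param params [assembly_params()].
#' @return Object of class `chimeric_consensus`: `$sequence`, `$layout`
#'   (tibble `id`, `offset`), `$joins` (tibble `left_id`, `right_id`,
#'   `overlap_length`, `identity`), `$unplaced` (character).
#' @export
assemble_chimeric_consensus <- function(fragments, params = assembly_params()) {
  if (!length(fragments)) abort("need at least one fragment")
  ids <- names(fragments) %||% sprintf("frag%02d", seq_along(fragments))
  ids[!nzchar(ids)] <- sprintf("frag%02d", which(!nzchar(ids)))
  names(fragments) <- ids
  input_order <- setNames(seq_along(ids), ids)

  # contigs: list of tibbles (id, offset); contig sequences rebuilt on merge
  contigs <- lapply(ids, function(id) tibble(id = id, offset = 1L))
  names(contigs) <- ids
  contig_seq <- as.list(fragments)
  joins <- tibble(left_id = character(0), right_id = character(0),
                  overlap_length = integer(0), identity = numeric(0))

  repeat {
    nms <- names(contigs)
    if (length(nms) < 2L) break
    best <- NULL
    for (x in nms) for (y in nms) {
      if (x == y) next
      vj <- validate_join(contig_seq[[x]], contig_seq[[y]], params)
      if (!vj$accepted) next
      cand <- mutate(vj, left = x, right = y)
      # highest identity first; ties broken by the *shortest* overlap (long
      # equal-identity overlaps are the signature of shared terminal
      # repeats), then lexicographic ids
      better <- is.null(best) || cand$identity > best$identity ||
        (cand$identity == best$identity && (cand$overlap_length < best$overlap_length ||
          (cand$overlap_length == best$overlap_length &&
             paste(cand$left, cand$right) < paste(best$left, best$right))))
      if (better) best <- cand
    }
    if (is.null(best)) break
    off <- nchar(contig_seq[[best$left]]) - best$overlap_length
    merged <- bind_rows(contigs[[best$left]],
                        mutate(contigs[[best$right]], offset = .data$offset + off))
    seqs <- fragments[merged$id]
    merged_seq <- .layout_consensus(seqs, merged$offset, input_order[merged$id])
    joins <- bind_rows(joins, tibble(left_id = best$left, right_id = best$right,
                                     overlap_length = best$overlap_length,
                                     identity = best$identity))
    contigs[[best$left]] <- merged
    contig_seq[[best$left]] <- merged_seq
    contigs[[best$right]] <- NULL
    contig_seq[[best$right]] <- NULL
  }

  # the main contig is the longest; others are unplaced
  lens <- vapply(contig_seq, nchar, integer(1))
  main <- names(contigs)[which.max(lens)]
  unplaced <- unlist(lapply(setdiff(names(contigs), main),
                            function(x) contigs[[x]]$id), use.names = FALSE)
  layout <- arrange(contigs[[main]], .data$offset)
  stopifnot(all(joins$overlap_length >= params$min_overlap),
            all(joins$identity >= params$min_identity))
  structure(list(sequence = contig_seq[[main]], layout = layout,
                 joins = joins, unplaced = unplaced %||% character(0),
                 params = params),
            class = "chimeric_consensus")
}

#' @export
print.chimeric_consensus <- function(x, ...) {
  cat(sprintf("<chimeric_consensus> %d bp from %d fragments (%d joins, %d unplaced)\n",
              nchar(x$sequence), nrow(x$layout), nrow(x$joins), length(x$unplaced)))
  invisible(x)
}
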