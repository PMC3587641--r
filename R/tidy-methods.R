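# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' Tidy an element annotation into a feature table
#'
#' One row per feature (LTRs, PBS, PPT, ORFs, defects, domain motifs), with
#' 1-based inclusive coordinates — ready for [write_gff3()].
#'
#' @param x An `element_annotation`.
#' @param ... Unused.
#' @return Tibble with `seqid`, `type`, `start`, `end`, `strand`, `label`.
#' @export
tidy.element_annotation <- function(x, ...) {
  rows <- list()
  add <- function(type, start, end, label) {
    rows[[length(rows) + 1L]] <<- tibble(
      seqid = "element", type = type, start = as.integer(start),
      end = as.integer(end), strand = "+", label = label)
  }
  if (!is.null(x$ltr)) {
    add("long_terminal_repeat", x$ltr$five_start, x$ltr$five_end, "five_prime_LTR")
    add("long_terminal_repeat", x$ltr$three_start, x$ltr$three_end, "three_prime_LTR")
  }
  if (!is.null(x$pbs)) {
    add("primer_binding_site", x$pbs$position,
        x$pbs$position + x$pbs$matched_length - 1L, x$pbs$trna_label)
  }
  if (!is.null(x$ppt)) {
    add("polypurine_tract", x$ppt$position, x$ppt$position + x$ppt$length - 1L,
        "PPT")
  }
  if (nrow(x$orfs)) {
    for (i in seq_len(nrow(x$orfs))) {
      add("open_reading_frame", x$orfs$start[i], x$orfs$end[i],
          sprintf("ORF%d", x$orfs$orf[i]))
      dfs <- x$orfs$defects[[i]]
      if (nrow(dfs)) {
        for (k in seq_len(nrow(dfs))) {
          add(if (dfs$kind[k] == "stop") "stop_codon" else "frameshift",
              dfs$position[k],
              dfs$position[k] + if (dfs$kind[k] == "stop") 2L else 0L,
              dfs$kind[k])
        }
      }
    }
  }
  if (nrow(x$domains)) {
    for (i in seq_len(nrow(x$domains))) {
      add("protein_motif", x$domains$nt_position[i], x$domains$nt_position[i] + 2L,
          x$domains$motif[i])
    }
  }
  if (!length(rows)) {
    return(tibble(seqid = character(0), type = character(0), start = integer(0),
                  end = integer(0), strand = character(0), label = character(0)))
  }
  bind_rows(rows) %>% arrange(.data$start, .data$type)
}

#' One-row summary of an element annotation
#'
#' @param x An `element_annotation`.
#' @param ... Unused.
#' @return One-row tibble: element length, LTR length/identity, PBS and PPT
#'   positions, ORF and defect counts, domain order, superfamily,
#'   completeness.
#' @export
glance.element_annotation <- function(x, ...) {
  n_defects <- if (nrow(x$orfs)) sum(vapply(x$orfs$defects, nrow, integer(1))) else 0L
  tibble(
    length = x$length,
    ltr_length = if (!is.null(x$ltr)) x$ltr$length else NA_integer_,
    ltr_identity = if (!is.null(x$ltr)) x$ltr$identity else NA_real_,
    termini = if (!is.null(x$ltr)) paste0(x$ltr$termini_start, "..", x$ltr$termini_end)
      else NA_character_,
    pbs_position = if (!is.null(x$pbs)) x$pbs$position else NA_integer_,
    pbs_trna = if (!is.null(x$pbs)) x$pbs$trna_label else NA_character_,
    ppt_position = if (!is.null(x$ppt)) x$ppt$position else NA_integer_,
    n_orfs = nrow(x$orfs), n_defects = n_defects,
    domain_order = x$domain_order, superfamily = x$superfamily,
    completeness = x$completeness)
}

#' Tidy a family partition
#'
#' @param x A `family_partition`.
#' @param ... Unused.
#' @return The assignment tibble (`id`, `family`).
#' @export
tidy.family_partition <- function(x, ...) x$assignment

#' One-row summary of a family partition
#'
#' @param x A `family_partition`.
#' @param ... Unused.
#' @return One-row tibble: sequence and family counts, global max intra- and
#'   min inter-family distances, criterion flag.
#' @export
glance.family_partition <- function(x, ...) {
  tibble(n_sequences = nrow(x$assignment), n_families = x$n_families,
         max_intra = if (all(is.na(x$max_intra$max_intra))) NA_real_
           else max(x$max_intra$max_intra, na.rm = TRUE),
         min_inter = if (nrow(x$min_inter)) min(x$min_inter$min_inter) else NA_real_,
         criterion_satisfied = x$criterion_satisfied)
}

#' Tidy a supported tree into an edge table
#'
#' @param x A `supported_tree`.
#' @param ... Unused.
#' @return Tibble of edges with branch lengths and (for internal child
#'   nodes) bootstrap supports.
#' @export
tidy.supported_tree <- function(x, ...) {
  tr <- x$tree
  n_tip <- length(tr$tip.label)
  child <- tr$edge[, 2]
  label <- rep(NA_character_, length(child))
  label[child <= n_tip] <- tr$tip.label[child[child <= n_tip]]
  support <- rep(NA_real_, length(child))
  internal <- child > n_tip
  support[internal] <- as.numeric(tr$node.label[child[internal] - n_tip])
  tibble(parent = tr$edge[, 1], child = child, length = tr$edge.length,
         label = label, support = support)
}

#' Element map plot
#'
#' Draws the annotated element: LTRs, PBS, PPT, ORFs as track rectangles,
#' domain motifs as points, defects as vertical marks.
#'
#' @param object An `element_annotation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.element_annotation <- function(object, ...) {
  feats <- tidy(object)
  if (!nrow(feats)) abort("nothing to plot")
  track_of <- c(long_terminal_repeat = 1, primer_binding_site = 2,
                polypurine_tract = 2, open_reading_frame = 3,
                stop_codon = 4, frameshift = 4, protein_motif = 4)
  feats <- mutate(feats, track = track_of[.data$type])
  ggplot2::ggplot(feats) +
    ggplot2::geom_rect(
      data = filter(feats, .data$track <= 3),
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = .data$track - 0.35, ymax = .data$track + 0.35,
                   fill = .data$type)) +
    ggplot2::geom_point(
      data = filter(feats, .data$track == 4),
      ggplot2::aes(x = .data$start, y = 4, shape = .data$type)) +
    ggplot2::scale_y_continuous(breaks = 1:4,
                                labels = c("LTR", "PBS/PPT", "ORF", "motifs"),
                                limits = c(0.5, 4.5)) +
    ggplot2::labs(x = "position (bp)", y = NULL,
                  title = sprintf("%s element, %d bp (%s)", object$superfamily,
                                  object$length, object$completeness)) +
    ggplot2::theme_minimal()
}

#' Intra- vs inter-family distance histogram
#'
#' Visual check of the family criterion: the intra- and inter-family
#' p-distance distributions of a partition must not overlap.
#'
#' @param partition A `family_partition`.
#' @return A ggplot object.
#' @export
plot_family_divergence <- function(partition) {
  d <- partition$distances
  fam <- setNames(partition$assignment$family, partition$assignment$id)
  ids <- rownames(d)
  ut <- which(upper.tri(d), arr.ind = TRUE)
  df <- tibble(dist = d[ut],
               kind = ifelse(fam[ids[ut[, 1]]] == fam[ids[ut[, 2]]],
                             "intra-family", "inter-family"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dist, fill = .data$kind)) +
    ggplot2::geom_histogram(bins = 30, position = "identity", alpha = 0.6) +
    ggplot2::labs(x = "p-distance", y = "pairs", fill = NULL) +
    ggplot2::theme_minimal()
}
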