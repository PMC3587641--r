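# Formats, configuration and the end-to-end pipeline driver.
#
# FASTA goes through Biostrings; GFF3 and BED through rtracklayer (GFF3
# carries 1-based inclusive coordinates, BED 0-based half-open). The
# pipeline chains: simulate -> scan-pcr -> cluster -> assemble -> annotate ->
# classify -> tree, writing every stage's outputs plus a JSON run log.

#' Read a FASTA file
#'
#' @param path File path.
#' @param type `"dna"` or `"aa"`.
#' @return Named character vector (ids verbatim, wraps joined); empty file
#'   gives an empty vector; duplicate ids are an error.
#' @export
read_fasta <- function(path, type = c("dna", "aa")) {
  type <- match.arg(type)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (!length(nonempty)) return(setNames(character(0), character(0)))
  first <- lines[nonempty[1]]
  if (!startsWith(first, ">")) {
    abort(sprintf("malformed FASTA: line %d does not start a record", nonempty[1]),
          class = "ltrtrace_parse_error")
  }
  set <- if (type == "dna") Biostrings::readDNAStringSet(path) else
    Biostrings::readAAStringSet(path)
  out <- setNames(as.character(set), names(set))
  dup <- names(out)[duplicated(names(out))]
  if (length(dup)) {
    abort(sprintf("duplicate FASTA id: %s", paste(unique(dup), collapse = ", ")),
          class = "ltrtrace_parse_error")
  }
  out
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param type `"dna"` or `"aa"`.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, type = c("dna", "aa")) {
  type <- match.arg(type)
  set <- if (type == "dna") Biostrings::DNAStringSet(seqs) else
    Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

.features_to_granges <- function(features) {
  if (any(features$start < 1L)) {
    abort("coordinates must be >= 1", class = "ltrtrace_validation_error")
  }
  gr <- GenomicRanges::GRanges(
    seqnames = features$seqid,
    ranges = IRanges::IRanges(features$start, features$end),
    strand = features$strand %||% "+")
  meta <- features[setdiff(names(features), c("seqid", "start", "end", "strand"))]
  for (nm in names(meta)) S4Vectors::mcols(gr)[[nm]] <- meta[[nm]]
  gr
}

#' Write a feature table as GFF3
#'
#' @param features Tibble with columns `seqid`, `type`, `start`, `end`
#'   (1-based inclusive), `strand`, plus any attribute columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path) {
  gr <- .features_to_granges(features)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a GFF3 file back into a feature tibble
#'
#' @param path File path.
#' @return Tibble with `seqid`, `type`, `start`, `end`, `strand` and
#'   attribute columns.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  tb <- tibble(seqid = as.character(GenomicRanges::seqnames(gr)),
               type = as.character(gr$type),
               start = GenomicRanges::start(gr),
               end = GenomicRanges::end(gr),
               strand = as.character(GenomicRanges::strand(gr)))
  mc <- as.data.frame(S4Vectors::mcols(gr))
  for (nm in setdiff(names(mc), c("type", "source", "phase", "score"))) {
    v <- mc[[nm]]
    if (!is.atomic(v)) {
      v <- vapply(as.list(v), function(x) paste(x, collapse = ","), character(1))
    }
    tb[[nm]] <- v
  }
  tb
}

#' Write intervals as BED (0-based half-open)
#'
#' @param intervals Tibble with `seqid`, `start`, `end` (1-based inclusive),
#'   optional `name`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = intervals$seqid,
    ranges = IRanges::IRanges(intervals$start, intervals$end),
    strand = intervals$strand %||% "+")
  if (!is.null(intervals$name)) gr$name <- intervals$name
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

# ---- pipeline ----------------------------------------------------------------

#' Pipeline configuration
#'
#' Stage parameters with defaults equal to the workflow's printed
#' thresholds: 50 bp minimum overlap and 95% identity for joins, a 1e-10
#' E-value gap for the GalEa rule, 100 bootstrap replicates.
#'
#' @param seed Master seed.
#' @param min_overlap,min_identity Assembly thresholds.
#' @param galea_threshold E-value gap threshold.
#' @param bootstrap_reps Bootstrap replicates for the tree stage.
#' @param amplicon_min,amplicon_max In-silico PCR product window (bp).
#' @param n_families,copies_per_family,intra_divergence,inter_divergence
#'   Simulation stage settings.
#' @param background_length Simulated genome length (bp).
#' @param max_mismatches Per-primer mismatch tolerance for the PCR screen
#'   (0 by default, matching [find_primer_sites()]; bench tolerance at
#'   permissive annealing is not quantifiable and stays a knob).
#' @param annotate Named list of overrides passed to [annotate_element()].
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, min_overlap = 50L, min_identity = 0.95,
                            galea_threshold = 1e-10, bootstrap_reps = 100L,
                            amplicon_min = 300L, amplicon_max = 500L,
                            n_families = 2L, copies_per_family = 3L,
                            intra_divergence = 0.02, inter_divergence = 0.20,
                            background_length = 60000L, max_mismatches = 0L,
                            annotate = list()) {
  structure(list(seed = as.integer(seed), min_overlap = as.integer(min_overlap),
                 min_identity = min_identity, galea_threshold = galea_threshold,
                 bootstrap_reps = as.integer(bootstrap_reps),
                 amplicon_min = as.integer(amplicon_min),
                 amplicon_max = as.integer(amplicon_max),
                 n_families = as.integer(n_families),
                 copies_per_family = as.integer(copies_per_family),
                 intra_divergence = intra_divergence,
                 inter_divergence = inter_divergence,
                 background_length = as.integer(background_length),
                 max_mismatches = as.integer(max_mismatches),
                 annotate = annotate),
            class = "pipeline_config")
}

#' Run the whole in-silico workflow
#'
#' With `genome = NULL` the simulation stage generates the study conditions:
#' a Copia element diversified into `n_families` families planted in a
#' random background, plus walking fragments for one representative element.
#' The pipeline then runs the degenerate-primer screen, clusters the
#' amplicons into families, assembles the walking fragments into a chimeric
#' consensus, annotates it, ranks its RT/RH protein against the bundled
#' reference library under the GalEa rule, and builds a bootstrap
#' neighbor-joining tree of the amplicon translations and references. Every
#' stage writes its outputs under `out_dir` together with a JSON run log;
#' stage failure leaves earlier outputs intact.
#'
#' @param config [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param genome Optional genome DNA string (skips simulation).
#' @param fragments Optional named character vector of walking fragments.
#' @return Named list of stage results, invisibly: `amplicons`, `families`,
#'   `consensus`, `annotation`, `clade_call`, `tree`, `log`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, genome = NULL,
                         fragments = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list(started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
              seed = config$seed,
              package_version = as.character(utils::packageVersion("ltrtrace")),
              stages = list())
  primers <- bundled_primers()
  truth <- NULL
  if (is.null(genome)) {
    el <- make_element(blueprint_copia_full(), seed = config$seed)
    # the degenerate-primer footprints (KARLVA / YxDD codons) stay conserved
    # across families, as purifying selection keeps them in real elements
    mt <- el$truth[el$truth$type == "protein_motif" &
                     el$truth$label %in% c("RT_KARLVA", "RT_YxDD"), ]
    fam <- diversify_family(el$sequence, config$n_families,
                            config$copies_per_family, config$intra_divergence,
                            config$inter_divergence, seed = config$seed + 1L,
                            conserved = cbind(mt$start, mt$start + 17L))
    g <- plant_elements(config$background_length, setNames(fam$sequence, fam$id),
                        seed = config$seed + 2L)
    genome <- g$sequence
    truth <- g$truth
    write_fasta(c(genome = genome), file.path(out_dir, "genome.fasta"))
    write_gff3(truth, file.path(out_dir, "genome_truth.gff3"))
    if (is.null(fragments)) {
      fr <- make_walk_fragments(el$sequence, anchor = c(2001L, 2400L),
                                step = 400L, overlap = 60L,
                                seed = config$seed + 3L)
      fragments <- setNames(fr$sequence, fr$id)
    }
    log$stages$simulate <- list(n_copies = nrow(fam))
  }

  # scan-pcr: both template orientations (bench PCR is orientation-blind);
  # minus-orientation products are reported in forward coordinates with
  # orientation-normalised sequence, as sequencing a gel band would give
  cd1 <- primers[primers$name == "CD1", ]
  cd2 <- primers[primers$name == "CD2", ]
  amp_plus <- in_silico_pcr(genome, cd1, cd2, config$amplicon_min,
                            config$amplicon_max, config$max_mismatches)
  rc_genome <- revcomp(genome)
  amp_minus <- in_silico_pcr(rc_genome, cd1, cd2, config$amplicon_min,
                             config$amplicon_max, config$max_mismatches)
  n_g <- nchar(genome)
  if (nrow(amp_minus)) {
    amp_minus <- amp_minus %>%
      mutate(start0 = n_g - .data$end + 1L, end = n_g - .data$start + 1L,
             start = .data$start0) %>%
      select(-"start0", -"fwd_start", -"rev_start")
    amp_plus <- select(amp_plus, -"fwd_start", -"rev_start")
    amplicons <- bind_rows(mutate(amp_plus, strand = "+"),
                           mutate(amp_minus, strand = "-")) %>%
      arrange(.data$start)
  } else {
    amplicons <- mutate(select(amp_plus, -"fwd_start", -"rev_start"),
                        strand = "+")
  }
  if (nrow(amplicons)) {
    write_fasta(setNames(amplicons$sequence,
                         sprintf("amplicon_%02d", seq_len(nrow(amplicons)))),
                file.path(out_dir, "amplicons.fasta"))
    write_bed(mutate(amplicons, seqid = "genome",
                     name = sprintf("amplicon_%02d", row_number())),
              file.path(out_dir, "amplicons.bed"))
  }
  # amplicon sequences are already orientation-normalised: sense strand first
  log$stages$scan_pcr <- list(n_amplicons = nrow(amplicons))

  # cluster amplicons into families (substitution-only copies align as-is)
  families <- NULL
  if (nrow(amplicons) >= 2L && length(unique(nchar(amplicons$sequence))) == 1L) {
    dmat <- pairwise_p_distance(setNames(amplicons$sequence,
                                         sprintf("amplicon_%02d", seq_len(nrow(amplicons)))))
    families <- partition_families(dmat)
    write.table(tidy(families), file.path(out_dir, "families.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(round(dmat, 5), file.path(out_dir, "distance_matrix.tsv"),
                sep = "\t", quote = FALSE, col.names = NA)
    log$stages$cluster <- list(n_families = families$n_families)
  }

  # assemble walking fragments
  consensus <- NULL
  if (!is.null(fragments)) {
    consensus <- assemble_chimeric_consensus(
      fragments, assembly_params(config$min_overlap, config$min_identity))
    write_fasta(c(consensus = consensus$sequence),
                file.path(out_dir, "consensus.fasta"))
    write.table(consensus$joins, file.path(out_dir, "joins.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    log$stages$assemble <- list(consensus_length = nchar(consensus$sequence),
                                n_joins = nrow(consensus$joins))
  }

  # annotate the consensus
  annotation <- NULL
  if (!is.null(consensus)) {
    annotation <- do.call(annotate_element,
                          c(list(seq = consensus$sequence), config$annotate))
    write_gff3(tidy(annotation), file.path(out_dir, "annotation.gff3"))
    jsonlite::write_json(as.list(glance(annotation)),
                         file.path(out_dir, "annotation.json"), auto_unbox = TRUE)
    log$stages$annotate <- list(superfamily = annotation$superfamily,
                                completeness = annotation$completeness)
  }

  # classify against the reference library
  clade_call <- NULL
  if (!is.null(annotation)) {
    qp <- rt_rh_protein(annotation)
    if (!is.null(qp)) {
      lib <- galea_reference_library()
      hits <- rank_hits(qp, lib)
      clade_call <- assign_clade_galea(hits, config$galea_threshold)
      write.table(hits, file.path(out_dir, "clade_hits.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(as.list(as_tibble(clade_call)),
                           file.path(out_dir, "clade_call.json"), auto_unbox = TRUE)
      log$stages$classify <- list(assigned = clade_call$assigned)
    }
  }

  # tree over amplicon translations + references
  tree <- NULL
  if (!is.null(families) && nrow(amplicons) >= 3L) {
    prots <- vapply(amplicons$sequence, function(s) {
      gsub("*", "X", translate_frame(s, 1L), fixed = TRUE)
    }, character(1))
    names(prots) <- sprintf("amplicon_%02d", seq_len(nrow(amplicons)))
    if (length(prots) >= 3L && length(unique(nchar(prots))) == 1L) {
      st <- bootstrap_support(prots, n_reps = config$bootstrap_reps,
                              seed = config$seed + 4L)
      ape::write.tree(st$tree, file.path(out_dir, "tree.nwk"))
      tree <- st
      log$stages$tree <- list(n_tips = length(st$tree$tip.label))
    }
  }

  log$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(list(amplicons = amplicons, families = families,
                 consensus = consensus, annotation = annotation,
                 clade_call = clade_call, tree = tree, truth = truth,
                 log = log))
}
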