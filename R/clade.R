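# Reference-library similarity ranking and the two-condition GalEa clade
# assignment rule: a query is assigned to the GalEa clade iff (i) the five
# best hits are exactly the five GalEa references, and (ii) the difference
# between the best E-values obtained with GalEa and with any other reference
# exceeds a threshold (1e-10 by default). Scores are affine-gap local
# alignment scores (BLOSUM62, gap open 11 / extend 1) turned into E-values
# with the standard Karlin-Altschul formula E = K * m * n * exp(-lambda * S).

.blosum62_x_neutral <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <- e$BLOSUM62
      m["X", ] <- 0L
      m[, "X"] <- 0L
      cache <<- m
    }
    cache
  }
})

.assert_protein <- function(x, what = "protein") {
  if (!is.character(x) || length(x) != 1L || !nchar(x)) {
    abort(sprintf("%s must be a non-empty string", what))
  }
  bad <- setdiff(unique(seq_chars(toupper(x))), c(AA_STANDARD, "X"))
  if (length(bad)) {
    abort(sprintf("%s contains non-standard residues: %s", what,
                  paste(bad, collapse = ", ")), class = "ltrtrace_encoding_error")
  }
  toupper(x)
}

#' Local alignment score
#'
#' Maximal affine-gap local alignment (Smith-Waterman) score between two
#' proteins. `X` is scored as neutral (0); the empty alignment bounds the
#' score below at 0.
#'
#' @param query,ref Amino-acid strings.
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @return Numeric score.
#' @export
local_align_score <- function(query, ref, gap_open = 11, gap_extend = 1) {
  query <- .assert_protein(query, "query")
  ref <- .assert_protein(ref, "ref")
  s <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(ref), type = "local",
    substitutionMatrix = .blosum62_x_neutral(),
    gapOpening = gap_open, gapExtension = gap_extend, scoreOnly = TRUE)
  max(0, s)
}

#' Karlin-Altschul parameters
#'
#' Defaults are the standard gapped BLOSUM62 (open 11 / extend 1) constants.
#'
#' @param lambda Scale parameter (per score unit, > 0).
#' @param K Dimensionless prefactor (> 0).
#' @param search_space Effective search space m*n (query length times summed
#'   library length).
#' @return Object of class `ka_params`.
#' @export
karlin_altschul_params <- function(lambda = 0.267, K = 0.041, search_space) {
  if (lambda <= 0 || K <= 0) abort("lambda and K must be positive")
  if (missing(search_space) || search_space <= 0) {
    abort("search_space (m*n) must be positive")
  }
  structure(list(lambda = lambda, K = K, search_space = search_space),
            class = "ka_params")
}

#' E-value of a local alignment score
#'
#' `E = K * m * n * exp(-lambda * score)`.
#'
#' @param score Raw alignment score.
#' @param ka [karlin_altschul_params()].
#' @return Expected number of chance hits at least this good.
#' @export
evalue <- function(score, ka) {
  stopifnot(inherits(ka, "ka_params"))
  ka$K * ka$search_space * exp(-ka$lambda * score)
}

#' Rank a query against a reference library
#'
#' One hit per reference, sorted by ascending E-value; ties broken by
#' descending raw score, then reference id.
#'
#' @param query Amino-acid string.
#' @param library Tibble with columns `id`, `clade`, `sequence` (see
#'   [galea_reference_library()]).
#' @param lambda,K,gap_open,gap_extend Scoring parameters.
#' @return Tibble with columns `ref_id`, `clade`, `score`, `e_value`.
#' @export
rank_hits <- function(query, library, lambda = 0.267, K = 0.041,
                      gap_open = 11, gap_extend = 1) {
  query <- .assert_protein(query, "query")
  if (!nrow(library)) abort("library is empty")
  mn <- nchar(query) * sum(nchar(library$sequence))
  ka <- karlin_altschul_params(lambda, K, mn)
  scores <- vapply(library$sequence, local_align_score, numeric(1),
                   query = query, gap_open = gap_open, gap_extend = gap_extend)
  tibble(ref_id = library$id, clade = library$clade,
         score = unname(scores), e_value = evalue(unname(scores), ka)) %>%
    arrange(.data$e_value, desc(.data$score), .data$ref_id)
}

#' Apply the two-condition GalEa assignment rule
#'
#' Condition (i): the 5 best hits are exactly the 5 GalEa-labelled
#' references. Condition (ii): the E-value gap — best non-GalEa E minus best
#' GalEa E, taken literally as an arithmetic difference (a `log10` mode is
#' available) — exceeds `threshold`. The query is assigned to GalEa iff both
#' hold; `ambiguous` when only the top-5 condition holds; `none` otherwise.
#' Note the arithmetic reading makes condition (ii) approximately "the best
#' non-GalEa hit is weaker than `threshold`".
#'
#' @param hits Ranked hits from [rank_hits()] (at least 6).
#' @param threshold E-value gap threshold (default 1e-10).
#' @param mode `"difference"` (literal arithmetic gap) or `"log10"` (gap in
#'   orders of magnitude, compared against `log10_threshold`).
#' @param log10_threshold Orders-of-magnitude threshold for the log mode.
#' @return Object of class `clade_call`: one-row tibble with `assigned`
#'   (`"GalEa"`, `"ambiguous"`, `"none"`), `condition_top5`, `condition_gap`,
#'   `evalue_gap`, `best_galea_e`, `best_other_e`.
#' @export
assign_clade_galea <- function(hits, threshold = 1e-10,
                               mode = c("difference", "log10"),
                               log10_threshold = 10) {
  mode <- match.arg(mode)
  if (nrow(hits) < 6L) {
    abort("need at least 6 hits (5 GalEa references plus 1 other)",
          class = "ltrtrace_insufficient_library")
  }
  galea_ids <- hits$ref_id[hits$clade == "GalEa"]
  if (length(galea_ids) != 5L) {
    abort("library must contain exactly 5 GalEa references",
          class = "ltrtrace_insufficient_library")
  }
  top5 <- hits$ref_id[1:5]
  condition_top5 <- setequal(top5, galea_ids)
  best_galea <- min(hits$e_value[hits$clade == "GalEa"])
  best_other <- min(hits$e_value[hits$clade != "GalEa"])
  gap <- best_other - best_galea
  condition_gap <- if (mode == "difference") {
    gap > threshold
  } else {
    (log10(best_other) - log10(best_galea)) > log10_threshold
  }
  assigned <- if (condition_top5 && condition_gap) "GalEa"
    else if (condition_top5) "ambiguous" else "none"
  out <- tibble(assigned = assigned, condition_top5 = condition_top5,
                condition_gap = condition_gap, evalue_gap = gap,
                best_galea_e = best_galea, best_other_e = best_other)
  class(out) <- c("clade_call", class(out))
  out
}

# mutate a protein at a given per-residue substitution rate
.mutate_protein <- function(protein, rate) {
  chars <- seq_chars(protein)
  hit <- which(runif(length(chars)) < rate)
  for (i in hit) chars[i] <- sample(setdiff(AA_STANDARD, chars[i]), 1L)
  paste0(chars, collapse = "")
}

#' Bundled GalEa reference library (synthetic)
#'
#' A deterministic, synthetic stand-in for a curated reference database:
#' five GalEa references derived from the canonical Copia RT/RH domain
#' region this package's generator plants (5% residue divergence each),
#' three unrelated Copia-architecture references (independent inter-motif
#' sequence, so they share only the conserved motifs), and three Gypsy
#' references derived from the canonical Gypsy RT/RH region. User-replaceable
#' by any tibble with `id`, `clade`, `sequence`.
#'
#' @return Tibble with columns `id`, `clade`, `sequence`.
#' @export
galea_reference_library <- function() {
  core <- .pol_core("copia")
  rt_lo <- min(core$motifs$aa_off[core$motifs$domain == "RT"]) - 10L
  rt_hi <- max(core$motifs$aa_off[core$motifs$domain == "RH"]) + 15L
  copia_rtrh <- paste0(core$aa[rt_lo:rt_hi], collapse = "")
  gcore <- .pol_core("gypsy")
  g_lo <- min(gcore$motifs$aa_off[gcore$motifs$domain == "RT"]) - 10L
  g_hi <- max(gcore$motifs$aa_off[gcore$motifs$domain == "RH"]) + 15L
  gypsy_rtrh <- paste0(gcore$aa[g_lo:g_hi], collapse = "")
  rows <- list()
  for (i in 1:5) {
    rows[[length(rows) + 1L]] <- with_seed(7200L + i, tibble(
      id = sprintf("GalEa%d", i), clade = "GalEa",
      sequence = .mutate_protein(copia_rtrh, 0.05)))
  }
  scaffold <- function(seed, len) {
    with_seed(seed, {
      aa <- random_aa(len)
      # keep the conserved islands any Copia RT/RH shares
      aa[10:15] <- seq_chars("KARLVA")
      aa[90:93] <- seq_chars("YVDD")
      aa[140:144] <- seq_chars("TRPDI")
      paste0(aa, collapse = "")
    })
  }
  other <- c("CopiaRef1", "CopiaRef2", "CopiaRef3")
  for (i in seq_along(other)) {
    rows[[length(rows) + 1L]] <- tibble(id = other[i], clade = "Copia_other",
                                        sequence = scaffold(7100L + i, 180L))
  }
  for (i in 1:3) {
    rows[[length(rows) + 1L]] <- with_seed(7300L + i, tibble(
      id = sprintf("GypsyRef%d", i), clade = "Gypsy",
      sequence = .mutate_protein(gypsy_rtrh, 0.10)))
  }
  bind_rows(rows)
}
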