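# IUPAC degenerate-primer matching and in-silico PCR.
#
# Site finding is delegated to Biostrings::matchPattern(fixed = FALSE), which
# treats ambiguity codes on both the primer and the template permissively (an
# N in a masked genome matches any primer code). Coordinates are 0-based
# half-open internally and in BED output; the tibbles below carry 1-based
# inclusive starts/ends like the rest of the package.

#' Bundled degenerate primers
#'
#' The five RT/RH-region degenerate primers used for the PCR screens: CD1
#' ('KARLVA' motif) and CD2 ('YVDD') amplify the Copia reverse transcriptase;
#' GD1 ('RMPFGL'), GD2 ('LTTDAS') and GD3 ('ADALSR') target Gypsy RT/RH.
#' Shipped as an editable TSV under `inst/extdata`.
#'
#' @return Tibble with columns `name`, `iupac`, `motif`, `direction`.
#' @export
bundled_primers <- function() {
  path <- system.file("extdata", "degenerate_primers.tsv", package = "ltrtrace")
  as_tibble(read.delim(path, comment.char = "#", stringsAsFactors = FALSE))
}

#' Does a template base match an IUPAC code?
#'
#' @param base Template base(s): A/C/G/T or N.
#' @param code IUPAC code(s) from the primer.
#' @return Logical vector; `TRUE` when the base (or any base, for N) lies in
#'   the code's expansion set.
#' @examples
#' iupac_matches("A", "R")  # TRUE
#' iupac_matches("C", "R")  # FALSE
#' @export
iupac_matches <- function(base, code) {
  base <- toupper(base)
  code <- toupper(code)
  n <- max(length(base), length(code))
  base <- rep_len(base, n)
  code <- rep_len(code, n)
  bad_b <- !base %in% c(DNA_BASES, "N")
  bad_c <- !code %in% names(IUPAC_SETS)
  if (any(bad_b) || any(bad_c)) {
    abort(sprintf("invalid nucleotide or IUPAC code: %s",
                  paste(unique(c(base[bad_b], code[bad_c])), collapse = ", ")),
          class = "ltrtrace_encoding_error")
  }
  vapply(seq_len(n), function(i) {
    if (base[i] == "N") return(TRUE)
    base[i] %in% IUPAC_SETS[[code[i]]]
  }, logical(1))
}

#' Degeneracy of a primer
#'
#' Number of distinct plain-ACGT oligos a degenerate primer encodes: the
#' product over positions of the IUPAC expansion-set sizes.
#'
#' @param primer IUPAC primer string (or a row of [bundled_primers()]).
#' @return Integer count.
#' @examples
#' primer_degeneracy("ARRGCNMGNYTNGTNGC")
#' @export
primer_degeneracy <- function(primer) {
  iupac <- if (is.list(primer) || is.data.frame(primer)) primer$iupac else primer
  chars <- seq_chars(toupper(iupac))
  bad <- setdiff(chars, names(IUPAC_SETS))
  if (length(bad)) abort(sprintf("invalid IUPAC code: %s", paste(bad, collapse = ", ")),
                         class = "ltrtrace_encoding_error")
  prod(vapply(chars, function(ch) length(IUPAC_SETS[[ch]]), numeric(1)))
}

.primer_iupac <- function(primer) {
  if (is.list(primer) || is.data.frame(primer)) toupper(primer$iupac[1]) else toupper(primer)
}
.primer_name <- function(primer) {
  if (is.list(primer) || is.data.frame(primer)) primer$name[1] else "primer"
}

#' Find degenerate-primer binding sites
#'
#' Scans both strands for positions where the primer matches under IUPAC
#' compatibility with at most `max_mismatches` mismatches. Minus-strand sites
#' are matched against the reverse complement and reported in forward-strand
#' coordinates.
#'
#' @param seq Template DNA (single string).
#' @param primer IUPAC primer string or a row of [bundled_primers()].
#' @param max_mismatches Maximum mismatches tolerated (default 0; bench PCR
#'   tolerance at permissive annealing is not quantifiable, so it is exposed
#'   rather than guessed).
#' @return Tibble with columns `primer`, `start`, `end` (1-based inclusive),
#'   `strand`, `mismatches`, sorted by `start`.
#' @export
find_primer_sites <- function(seq, primer, max_mismatches = 0L) {
  seq <- assert_dna(seq, "seq", allow_iupac = TRUE)
  iupac <- .primer_iupac(primer)
  subj <- Biostrings::DNAString(seq)
  pat <- Biostrings::DNAString(iupac)
  scan1 <- function(subject, strand) {
    m <- Biostrings::matchPattern(pat, subject, max.mismatch = max_mismatches,
                                  fixed = FALSE)
    if (!length(m)) {
      return(tibble(start = integer(0), end = integer(0), strand = character(0),
                    mismatches = integer(0)))
    }
    mm <- Biostrings::neditStartingAt(pat, subject,
                                      starting.at = IRanges::start(m), fixed = FALSE)
    tibble(start = IRanges::start(m), end = IRanges::end(m),
           strand = strand, mismatches = as.integer(mm))
  }
  plus <- scan1(subj, "+")
  minus <- scan1(Biostrings::reverseComplement(subj), "-")
  n <- nchar(seq)
  if (nrow(minus)) {
    st <- n - minus$end + 1L
    minus$end <- n - minus$start + 1L
    minus$start <- st
  }
  bind_rows(plus, minus) %>%
    mutate(primer = .primer_name(primer), .before = 1) %>%
    arrange(.data$start, .data$strand)
}

#' In-silico PCR
#'
#' Pairs every plus-strand site of the forward primer with every downstream
#' minus-strand site of the reverse primer and keeps products whose length
#' (primer start to primer end, both footprints included, matching gel-size
#' semantics) lies in `[min_len, max_len]`.
#'
#' @param seq Template DNA.
#' @param fwd,rev Primers (IUPAC strings or rows of [bundled_primers()]).
#' @param min_len,max_len Product length window (bp).
#' @param max_mismatches Per-primer mismatch tolerance.
#' @return Tibble of amplicons: `start`, `end`, `length`, `fwd_start`,
#'   `fwd_mismatches`, `rev_start`, `rev_mismatches`, `sequence`.
#' @examples
#' pr <- bundled_primers()
#' el <- make_element(blueprint_copia_full(), seed = 1)
#' in_silico_pcr(el$sequence, pr[pr$name == "CD1", ], pr[pr$name == "CD2", ],
#'               min_len = 300, max_len = 500)
#' @export
in_silico_pcr <- function(seq, fwd, rev, min_len = 0L, max_len = Inf,
                          max_mismatches = 0L) {
  if (min_len > max_len) abort("min_len must be <= max_len")
  fs <- find_primer_sites(seq, fwd, max_mismatches) %>% filter(.data$strand == "+")
  rs <- find_primer_sites(seq, rev, max_mismatches) %>% filter(.data$strand == "-")
  out <- list()
  if (nrow(fs) && nrow(rs)) {
    for (i in seq_len(nrow(fs))) {
      for (j in seq_len(nrow(rs))) {
        if (rs$start[j] <= fs$start[i]) next
        len <- rs$end[j] - fs$start[i] + 1L
        if (len < min_len || len > max_len) next
        out[[length(out) + 1L]] <- tibble(
          start = fs$start[i], end = rs$end[j], length = len,
          fwd_start = fs$start[i], fwd_mismatches = fs$mismatches[i],
          rev_start = rs$start[j], rev_mismatches = rs$mismatches[j],
          sequence = substr(seq, fs$start[i], rs$end[j]))
      }
    }
  }
  if (!length(out)) {
    return(tibble(start = integer(0), end = integer(0), length = integer(0),
                  fwd_start = integer(0), fwd_mismatches = integer(0),
                  rev_start = integer(0), rev_mismatches = integer(0),
                  sequence = character(0)))
  }
  bind_rows(out) %>% arrange(.data$start, .data$end)
}
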