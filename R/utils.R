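# Internal sequence helpers. Sequences cross the user surface as plain
# character strings (named character vectors for sets); Biostrings does the
# heavy lifting internally.

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC ambiguity expansions (nucleotide)
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Translate a nucleotide string in a given frame
#' @noRd
translate_frame <- function(seq, frame = 1L) {
  sub <- substr(seq, frame, nchar(seq))
  sub <- substr(sub, 1L, 3L * (nchar(sub) %/% 3L))
  if (nchar(sub) < 3L) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                     if.fuzzy.codon = "X", no.init.codon = TRUE))
}

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

random_dna <- function(n) {
  if (n <= 0L) return("")
  paste0(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# random DNA whose 3 reading frames all contain a stop within the first 11 nt,
# so planted ORFs cannot leak across spacers
STOP_GUARD <- "TAAGTAAGTAA"

# spacers carry the guard at both ends so ORFs flanking the spacer stay more
# than a stitching gap apart
spacer_dna <- function(n) {
  g <- nchar(STOP_GUARD)
  if (n >= 2L * g) {
    paste0(STOP_GUARD, random_dna(n - 2L * g), STOP_GUARD)
  } else {
    stopifnot(n >= g)
    paste0(STOP_GUARD, random_dna(n - g))
  }
}

# random DNA with a pyrimidine forced at every third position (starting at
# the first), so no >= 10 nt window can rival a planted polypurine tract
low_purine_dna <- function(n) {
  if (n <= 0L) return("")
  chars <- sample(DNA_BASES, n, replace = TRUE)
  force_idx <- seq.int(1L, n, by = 3L)
  chars[force_idx] <- sample(c("C", "T"), length(force_idx), replace = TRUE)
  paste0(chars, collapse = "")
}

assert_dna <- function(x, what = "sequence", allow_iupac = FALSE) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("%s must be a single character string", what))
  }
  ok <- if (allow_iupac) names(IUPAC_SETS) else DNA_BASES
  chars <- unique(strsplit(toupper(x), "")[[1]])
  bad <- setdiff(chars, c(ok, "N"))
  if (length(bad)) {
    abort(sprintf("%s contains invalid characters: %s", what,
                  paste(bad, collapse = ", ")))
  }
  invisible(toupper(x))
}

AA_STANDARD <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V")

# purines
is_purine <- function(chars) chars %in% c("A", "G")

# 1-based inclusive <-> 0-based half-open
to_zero_based <- function(start, end) list(start = start - 1L, end = end)
to_one_based <- function(start0, end0) list(start = start0 + 1L, end = end0)

seq_chars <- function(x) strsplit(x, "")[[1]]

substr_safe <- function(x, start, end) {
  if (start < 1L || end > nchar(x) || start > end) {
    abort("substring out of bounds")
  }
  substr(x, start, end)
}
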