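# Structural annotation of candidate LTR-retrotransposons.
#
# User-facing positions are 1-based inclusive (so printed positions like
# "PBS at 219" read off directly); conversions to 0-based half-open happen
# only at the BED boundary. LTR detection is self-comparison of the terminal
# margins (exact k-mer seeding + identity-bounded diagonal extension); the
# PBS is the best reverse-complement match to a bundled tRNA 3'-end library;
# the PPT is the best purine run upstream of the 3' LTR; ORF finding reports
# maximal reading frames and, with defect tolerance on, stitches adjacent
# frames across premature stops and frameshifts, reporting each defect with
# its nucleotide position.

#' Bundled tRNA 3'-end library
#'
#' 3'-terminal sequences of the 20 tRNA acceptors against which primer
#' binding sites are matched. The tRNA-Met and tRNA-Trp entries are the
#' reverse complements of the canonical PBS sequences those tRNAs prime; the
#' other 18 acceptors are synthetic stand-ins (flagged in the `provenance`
#' column of the shipped TSV).
#'
#' @return Tibble with columns `label`, `sequence`, `provenance`.
#' @export
trna_3prime_library <- function() {
  path <- system.file("extdata", "trna_three_prime.tsv", package = "ltrtrace")
  as_tibble(read.delim(path, comment.char = "#", stringsAsFactors = FALSE))
}

#' Protein motif library
#'
#' Patterns for the conserved retroelement domain motifs: the gag
#' zinc-knuckle CX2CX4HX4C, the protease D\[ST\]G\[ACS\] box, the integrase
#' zinc-finger HX4HX30CX2C and DD35E catalytic triad (exactly 35 residues
#' between the second aspartate and the glutamate), reverse-transcriptase
#' motifs (KARLVA for Copia, RMPFGL for Gypsy, the shared Y\[VL\]DD box) and
#' RNase-H motifs (TRPDI for Copia; LTTDAS and ADALSR for Gypsy). `x` in a
#' pattern is a wildcard, `x{n}` repeats it; `max_mismatch` mismatches are
#' tolerated at constrained positions. The `flavor` column records which
#' superfamily a motif is diagnostic of and feeds the Gmr1-like evidence
#' flag. Shipped as an editable TSV under `inst/extdata`.
#'
#' @return Tibble with columns `name`, `domain`, `flavor`, `pattern`,
#'   `max_mismatch`.
#' @export
motif_library <- function() {
  path <- system.file("extdata", "motifs.tsv", package = "ltrtrace")
  as_tibble(read.delim(path, comment.char = "#", stringsAsFactors = FALSE))
}

# ---- LTR pair ----------------------------------------------------------------

#' Find the pair of long terminal repeats
#'
#' Searches for the longest pair of direct repeats with one copy starting
#' within `search_margin` of the 5' end and one ending within `search_margin`
#' of the 3' end. Exact k-mer seeds between the two margins are extended
#' along their diagonal while the running identity stays above
#' `min_identity` (ends trimmed to matching positions), so identical LTRs at
#' the element boundaries are recovered exactly and mildly diverged copies
#' within a couple of basepairs.
#'
#' @param seq Element DNA.
#' @param min_len Minimum LTR length (bp).
#' @param min_identity Minimum identity between the two copies.
#' @param search_margin Margin (bp) at each end within which copies must
#'   start/end.
#' @param k Seed length (exact match) for the self-comparison.
#' @return One-row tibble (`five_start`, `five_end`, `three_start`,
#'   `three_end`, `length`, `identity`, `termini_start`, `termini_end`) or
#'   `NULL` when no pair qualifies.
#' @export
find_ltr_pair <- function(seq, min_len = 50L, min_identity = 0.8,
                          search_margin = 1000L, k = 20L) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n <= 2L * min_len) abort("sequence shorter than twice min_len")
  m <- min(search_margin, n)
  chars <- seq_chars(seq)
  head_idx <- seq_len(max(0L, m - k + 1L))
  tail_lo <- max(1L, n - m + 1L)
  tail_idx <- seq.int(tail_lo, n - k + 1L)
  kmer_at <- function(i) substr(seq, i, i + k - 1L)
  head_map <- split(head_idx, vapply(head_idx, kmer_at, character(1)))
  offsets <- integer(0)
  for (t in tail_idx) {
    hs <- head_map[[kmer_at(t)]]
    if (!is.null(hs)) offsets <- c(offsets, t - hs)
  }
  offsets <- sort(unique(offsets[offsets > 0L]))
  best <- NULL
  for (off in offsets) {
    len_d <- n - off
    v <- chars[seq_len(len_d)] == chars[seq_len(len_d) + off]
    # grow the longest identity-bounded window from each seed on this diagonal
    seed_pos <- head_idx[vapply(head_idx, function(i) {
      i + k - 1L <= len_d && all(v[i:(i + k - 1L)])
    }, logical(1))]
    if (!length(seed_pos)) next
    s <- seed_pos[1]
    a <- s; b <- min(s + k - 1L, len_d)
    matches <- sum(v[a:b])
    repeat {
      grew <- FALSE
      if (a > 1L) {
        a2 <- max(which(v[seq_len(a - 1L)]), 0L)
        if (a2 >= 1L && (matches + 1) / (b - a2 + 1L) >= min_identity) {
          matches <- matches + 1L + 0L; a <- a2; grew <- TRUE
          matches <- sum(v[a:b])
        }
      }
      if (b < len_d) {
        nxt <- which(v[(b + 1L):len_d])
        if (length(nxt)) {
          b2 <- b + nxt[1]
          if ((matches + 1) / (b2 - a + 1L) >= min_identity) {
            b <- b2; matches <- sum(v[a:b]); grew <- TRUE
          }
        }
      }
      if (!grew) break
    }
    len <- b - a + 1L
    ident <- matches / len
    cand_ok <- len >= min_len && ident >= min_identity &&
      a <= m && (b + off) >= (n - m + 1L) && b < a + off
    if (cand_ok && (is.null(best) || len > best$length ||
                    (len == best$length && ident > best$identity))) {
      best <- tibble(five_start = a, five_end = b, three_start = a + off,
                     three_end = b + off, length = len, identity = ident,
                     termini_start = substr(seq, a, a + 1L),
                     termini_end = substr(seq, b + off - 1L, b + off))
    }
  }
  best
}

# ---- PBS ---------------------------------------------------------------------

#' Find the primer binding site
#'
#' Best reverse-complement match (longest, then fewest mismatches, then
#' leftmost) between a window immediately downstream of the 5' LTR and the
#' 3'-terminal end of any library tRNA, at least `min_match` nt long.
#'
#' @param seq Element DNA.
#' @param ltr Result of [find_ltr_pair()].
#' @param trna_library Tibble of tRNA 3' ends ([trna_3prime_library()]).
#' @param window Search window (bp) downstream of the 5' LTR end in which the
#'   PBS must start.
#' @param min_match Minimum matched length (nt).
#' @param max_mismatches Mismatches tolerated (default 0).
#' @return One-row tibble (`position`, `sequence`, `trna_label`,
#'   `matched_length`, `mismatches`) or `NULL`.
#' @export
find_pbs <- function(seq, ltr, trna_library = trna_3prime_library(),
                     window = 20L, min_match = 12L, max_mismatches = 0L) {
  if (is.null(ltr)) abort("ltr must be present")
  if (!nrow(trna_library)) abort("trna_library is empty")
  seq <- toupper(seq)
  n <- nchar(seq)
  lo <- ltr$five_end + 1L
  hi <- min(ltr$five_end + window, n)
  best <- NULL
  for (r in seq_len(nrow(trna_library))) {
    trna <- toupper(trna_library$sequence[r])
    for (klen in seq.int(min(nchar(trna), 18L), min_match)) {
      pat <- seq_chars(revcomp(substr(trna, nchar(trna) - klen + 1L, nchar(trna))))
      for (p in lo:hi) {
        if (p + klen - 1L > n) next
        mm <- sum(seq_chars(substr(seq, p, p + klen - 1L)) != pat)
        if (mm > max_mismatches) next
        better <- is.null(best) || klen > best$matched_length ||
          (klen == best$matched_length && (mm < best$mismatches ||
            (mm == best$mismatches && p < best$position)))
        if (better) {
          best <- tibble(position = as.integer(p),
                         sequence = substr(seq, p, p + klen - 1L),
                         trna_label = trna_library$label[r],
                         matched_length = as.integer(klen),
                         mismatches = as.integer(mm))
        }
      }
    }
  }
  best
}

# ---- PPT ---------------------------------------------------------------------

#' Find the polypurine tract
#'
#' Highest-purine-fraction window of length >= `min_len` within `window` bp
#' upstream of the 3' LTR, requiring fraction >= `min_purine`; ties broken by
#' longer window, then leftmost.
#'
#' @param seq Element DNA.
#' @param ltr Result of [find_ltr_pair()].
#' @param window Search window (bp) upstream of the 3' LTR start.
#' @param min_len Minimum tract length (nt).
#' @param min_purine Minimum purine (A/G) fraction.
#' @return One-row tibble (`position`, `sequence`, `length`,
#'   `purine_fraction`) or `NULL`.
#' @export
find_ppt <- function(seq, ltr, window = 30L, min_len = 10L, min_purine = 0.8) {
  if (is.null(ltr)) abort("ltr must be present")
  seq <- toupper(seq)
  lo <- max(1L, ltr$three_start - window)
  hi <- ltr$three_start - 1L
  if (hi - lo + 1L < min_len) return(NULL)
  pur <- cumsum(c(0L, is_purine(seq_chars(substr(seq, lo, hi)))))
  w <- hi - lo + 1L
  best <- NULL
  for (len in seq.int(w, min_len)) {
    for (i in seq_len(w - len + 1L)) {
      frac <- (pur[i + len] - pur[i]) / len
      if (frac < min_purine) next
      better <- is.null(best) || frac > best$purine_fraction ||
        (frac == best$purine_fraction && (len > best$length ||
          (len == best$length && lo + i - 1L < best$position)))
      if (better) {
        best <- tibble(position = as.integer(lo + i - 1L),
                       sequence = substr(seq, lo + i - 1L, lo + i + len - 2L),
                       length = as.integer(len), purine_fraction = frac)
      }
    }
  }
  best
}

# ---- ORFs --------------------------------------------------------------------

.orf_segments <- function(seq, min_aa) {
  n <- nchar(seq)
  segs <- list()
  for (f in 1:3) {
    aa <- translate_frame(seq, f)
    if (!nchar(aa)) next
    runs <- gregexpr("[^*]+", aa)[[1]]
    if (runs[1] == -1L) next
    lens <- attr(runs, "match.length")
    for (i in seq_along(runs)) {
      if (lens[i] < min_aa) next
      nt_start <- f + 3L * (runs[i] - 1L)
      nt_end <- f + 3L * (runs[i] + lens[i] - 1L) - 1L
      segs[[length(segs) + 1L]] <- tibble(
        start = nt_start, end = nt_end, frame = f, aa_length = lens[i],
        protein = substr(aa, runs[i], runs[i] + lens[i] - 1L))
    }
  }
  if (!length(segs)) {
    return(tibble(start = integer(0), end = integer(0), frame = integer(0),
                  aa_length = integer(0), protein = character(0)))
  }
  bind_rows(segs) %>% arrange(.data$start)
}

#' Find open reading frames, with decay reporting
#'
#' Reports maximal (stop-to-stop) reading frames of at least `min_aa` codons
#' on the three forward frames (candidate elements are analysed in sense
#' orientation). With `defect_tolerance`, adjacent frames that continue one
#' conceptual protein are stitched into a single record, and each junction is
#' reported as a premature stop (same frame, in-frame stop codon between the
#' segments) or a frameshift (frame change), with its 1-based nucleotide
#' position. Alternative-frame shadows (frames mostly covered by a stitched
#' chain's span) are dropped.
#'
#' @param seq Element DNA.
#' @param min_aa Minimum length per reading frame (codons).
#' @param defect_tolerance Stitch across stops/frameshifts?
#' @return Tibble with columns `orf`, `start`, `end`, `frame`, `aa_length`,
#'   `n_segments`, and list-columns `segments` (per-segment tibble) and
#'   `defects` (tibble of `kind`, `position`).
#' @export
find_orfs <- function(seq, min_aa = 100L, defect_tolerance = TRUE) {
  seq <- toupper(seq)
  # with defect tolerance, chain over segments down to 15 codons so decayed
  # reading frames fragmented by extra stops still stitch; min_aa applies to
  # the stitched records
  floor_aa <- if (defect_tolerance) min(min_aa, 15L) else min_aa
  segs <- .orf_segments(seq, floor_aa)
  empty <- tibble(orf = integer(0), start = integer(0), end = integer(0),
                  frame = integer(0), aa_length = integer(0),
                  n_segments = integer(0), segments = list(), defects = list())
  if (!nrow(segs)) return(empty)
  groups <- list()
  if (defect_tolerance) {
    # repeatedly extract the maximal-coverage chain of linkable segments;
    # segments mostly covered by an extracted chain's span are
    # alternative-frame shadows and are dropped
    pool <- segs %>% arrange(.data$end)
    while (nrow(pool)) {
      np <- nrow(pool)
      len <- pool$end - pool$start + 1L
      score <- as.numeric(len)
      pred <- rep(NA_integer_, np)
      for (i in seq_len(np)) {
        # both sides of a genuine junction contribute >= 10 codons of their
        # own sequence (shadows stop at the next in-frame stop); score
        # counts new coverage only, each junction costs 25 nt, so
        # overlapping shadows cannot buy their way into a chain
        cand_j <- integer(0)
        cand_s <- numeric(0)
        for (j in seq_len(np)) {
          if (j == i) next
          linkable <- pool$end[i] - pool$end[j] >= 30L &&
            pool$start[i] - pool$start[j] >= 30L &&
            pool$start[i] - pool$end[j] - 1L <= 3L
          if (!linkable) next
          cand_j <- c(cand_j, j)
          cand_s <- c(cand_s, score[j] + (pool$end[i] - pool$end[j]) - 25)
        }
        if (length(cand_j)) {
          # within a 12 nt band (frame jitter at the spacer stop guards) the
          # longer predecessor segment is the real continuation, not a
          # chance same-span shadow in another frame
          near <- which(cand_s >= max(cand_s) - 12)
          pickj <- near[order(-len[cand_j[near]], -cand_s[near])][1]
          if (cand_s[pickj] > score[i]) {
            score[i] <- cand_s[pickj]
            pred[i] <- cand_j[pickj]
          }
        }
      }
      tip <- which.max(score)
      chain <- tip
      while (!is.na(pred[chain[1]])) chain <- c(pred[chain[1]], chain)
      g <- pool[chain, ]
      groups[[length(groups) + 1L]] <- g
      span_lo <- min(g$start); span_hi <- max(g$end)
      keep <- setdiff(seq_len(np), chain)
      if (length(keep)) {
        cov <- pmax(0L, pmin(pool$end[keep], span_hi) -
                      pmax(pool$start[keep], span_lo) + 1L)
        keep <- keep[cov < 0.8 * (pool$end[keep] - pool$start[keep] + 1L)]
      }
      pool <- pool[keep, , drop = FALSE]
    }
  } else {
    groups <- lapply(seq_len(nrow(segs)), function(i) segs[i, ])
  }
  out <- list()
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    defects <- tibble(kind = character(0), position = integer(0))
    if (nrow(g) > 1L) {
      for (i in 2:nrow(g)) {
        jpos <- g$end[i - 1L] + 1L
        if (g$frame[i] == g$frame[i - 1L]) {
          codon <- substr(seq, jpos, jpos + 2L)
          if (codon %in% c("TAA", "TAG", "TGA")) {
            defects <- bind_rows(defects, tibble(kind = "stop", position = jpos))
          }
        } else {
          defects <- bind_rows(defects, tibble(kind = "frameshift", position = jpos))
        }
      }
    }
    overlap_aa <- 0L
    if (nrow(g) > 1L) {
      for (i in 2:nrow(g)) {
        ov <- g$end[i - 1L] - g$start[i] + 1L
        if (ov > 0L) overlap_aa <- overlap_aa + ov %/% 3L
      }
    }
    out[[gi]] <- tibble(
      orf = gi, start = min(g$start), end = max(g$end), frame = g$frame[1],
      aa_length = sum(g$aa_length) - overlap_aa, n_segments = nrow(g),
      segments = list(select(g, "start", "end", "frame", "aa_length", "protein")),
      defects = list(defects))
  }
  bind_rows(out) %>%
    filter(.data$aa_length >= min_aa) %>%
    arrange(.data$start) %>%
    mutate(orf = row_number())
}

# ---- protein motifs ----------------------------------------------------------

.parse_motif_pattern <- function(pattern) {
  # tokens: single residue, [CLASS], x, x{n}
  toks <- list()
  i <- 1L
  n <- nchar(pattern)
  while (i <= n) {
    ch <- substr(pattern, i, i)
    if (ch == "[") {
      j <- regexpr("]", substr(pattern, i, n), fixed = TRUE)
      set <- seq_chars(substr(pattern, i + 1L, i + j - 2L))
      toks[[length(toks) + 1L]] <- set
      i <- i + j
    } else if (ch == "x") {
      reps <- 1L
      if (i < n && substr(pattern, i + 1L, i + 1L) == "{") {
        j <- regexpr("}", substr(pattern, i, n), fixed = TRUE)
        reps <- as.integer(substr(pattern, i + 2L, i + j - 2L))
        i <- i + j
      } else i <- i + 1L
      for (r in seq_len(reps)) toks[[length(toks) + 1L]] <- NULL_SET
    } else {
      toks[[length(toks) + 1L]] <- ch
      i <- i + 1L
    }
  }
  toks
}
NULL_SET <- "."

.match_pattern_positions <- function(chars, toks, max_mismatch) {
  m <- length(toks)
  n <- length(chars)
  if (n < m) return(integer(0))
  constrained <- which(!vapply(toks, identical, logical(1), NULL_SET))
  hits <- integer(0)
  for (p in seq_len(n - m + 1L)) {
    mm <- 0L
    for (q in constrained) {
      if (!chars[p + q - 1L] %in% toks[[q]]) {
        mm <- mm + 1L
        if (mm > max_mismatch) break
      }
    }
    if (mm <= max_mismatch) hits <- c(hits, p)
  }
  hits
}

.match_dde <- function(chars, spacing = 35L) {
  # catalytic triad D..D(spacing)E; returns positions of the first D
  d_pos <- which(chars == "D")
  hits <- integer(0)
  for (j in d_pos) {
    if (j + spacing + 1L <= length(chars) && chars[j + spacing + 1L] == "E") {
      firsts <- d_pos[d_pos < j]
      if (length(firsts)) hits <- c(hits, max(firsts))
    }
  }
  sort(unique(hits))
}

#' Scan a protein for conserved domain motifs
#'
#' @param protein Amino-acid string.
#' @param lib Motif library ([motif_library()]).
#' @return Tibble with columns `motif`, `domain`, `flavor`, `position`
#'   (1-based aa) and `weight` (constrained pattern positions net of the
#'   mismatch allowance — a specificity score).
#' @export
scan_protein_motifs <- function(protein, lib = motif_library()) {
  if (!nchar(protein)) abort("protein must be non-empty")
  chars <- seq_chars(toupper(protein))
  out <- list()
  for (r in seq_len(nrow(lib))) {
    if (identical(lib$pattern[r], "DDE35")) {
      pos <- .match_dde(chars)
      weight <- 3L
    } else {
      toks <- .parse_motif_pattern(lib$pattern[r])
      pos <- .match_pattern_positions(chars, toks, lib$max_mismatch[r])
      weight <- sum(!vapply(toks, identical, logical(1), NULL_SET)) -
        lib$max_mismatch[r]
    }
    if (length(pos)) {
      out[[length(out) + 1L]] <- tibble(motif = lib$name[r], domain = lib$domain[r],
                                        flavor = lib$flavor[r], position = pos,
                                        weight = as.integer(weight))
    }
  }
  if (!length(out)) {
    return(tibble(motif = character(0), domain = character(0),
                  flavor = character(0), position = integer(0),
                  weight = integer(0)))
  }
  bind_rows(out) %>% arrange(.data$position)
}

# ---- domain order & superfamily ---------------------------------------------

#' Order domains along the element
#'
#' @param hits Tibble of domain hits with `domain` and `position` columns.
#' @return Domain order string (e.g. `"PR-INT-RT-RH"`); duplicates collapse
#'   to the first occurrence; `""` for no hits.
#' @export
order_domains <- function(hits) {
  if (is.null(hits) || !nrow(hits)) return("")
  doms <- hits %>% arrange(.data$position) %>% pull("domain")
  paste(doms[!duplicated(doms)], collapse = "-")
}

#' Classify the superfamily from pol domain order
#'
#' Copia elements carry the integrase upstream of the reverse transcriptase
#' (PR-INT-RT-RH); Gypsy elements carry it last (PR-RT-RH-INT); Gmr1-like
#' elements are unconventional Gypsy retrotransposons whose INT lies upstream
#' of the RT, so an INT-before-RT order is called `gmr1_gypsy` when the
#' caller flags Gypsy-type motif evidence.
#'
#' @param order Domain order string from [order_domains()].
#' @param gypsy_evidence Were Gypsy-diagnostic RT/RH motifs observed?
#' @return One of `"copia"`, `"gypsy"`, `"gmr1_gypsy"`, `"unclassified"`.
#' @export
classify_superfamily <- function(order, gypsy_evidence = FALSE) {
  doms <- strsplit(order, "-", fixed = TRUE)[[1]]
  i_int <- match("INT", doms)
  i_rt <- match("RT", doms)
  i_rh <- match("RH", doms)
  if (is.na(i_int) || is.na(i_rt)) return("unclassified")
  if (i_int < i_rt) {
    if (isTRUE(gypsy_evidence)) "gmr1_gypsy" else "copia"
  } else {
    if (!is.na(i_rh) && i_int < i_rh) "unclassified" else "gypsy"
  }
}

# ---- full annotation ---------------------------------------------------------

#' Annotate a candidate element
#'
#' Composes [find_ltr_pair()], [find_pbs()], [find_ppt()], [find_orfs()] and
#' [scan_protein_motifs()] into one structural annotation and classifies the
#' superfamily from the pol domain order. Completeness is `"full_length"`
#' when an LTR pair and all four pol domains (PR, INT, RT, RH) are present,
#' `"partial"` otherwise.
#'
#' @param seq Element DNA (single string).
#' @param min_ltr_len,ltr_min_identity,search_margin LTR detection settings.
#' @param pbs_window,pbs_min_match,pbs_max_mismatches PBS settings.
#' @param ppt_window,ppt_min_len,ppt_min_purine PPT settings.
#' @param min_orf_aa,defect_tolerance ORF settings.
#' @param trna_library,motifs Reference libraries.
#' @return Object of class `element_annotation` with fields `ltr`, `pbs`,
#'   `ppt`, `orfs`, `domains`, `domain_order`, `superfamily`, `completeness`,
#'   `length`. Use [tidy()] for a feature table and [autoplot()] for an
#'   element map.
#' @examples
#' el <- make_element(blueprint_copia_full(), seed = 1)
#' ann <- annotate_element(el$sequence)
#' glance(ann)
#' @export
annotate_element <- function(seq,
                             min_ltr_len = 50L, ltr_min_identity = 0.8,
                             search_margin = 1000L,
                             pbs_window = 20L, pbs_min_match = 12L,
                             pbs_max_mismatches = 0L,
                             ppt_window = 30L, ppt_min_len = 10L,
                             ppt_min_purine = 0.8,
                             min_orf_aa = 100L, defect_tolerance = TRUE,
                             trna_library = trna_3prime_library(),
                             motifs = motif_library()) {
  seq <- toupper(seq)
  if (!nchar(seq)) abort("seq must be non-empty")
  ltr <- find_ltr_pair(seq, min_ltr_len, ltr_min_identity, search_margin)
  pbs <- if (!is.null(ltr)) {
    find_pbs(seq, ltr, trna_library, pbs_window, pbs_min_match, pbs_max_mismatches)
  }
  ppt <- if (!is.null(ltr)) find_ppt(seq, ltr, ppt_window, ppt_min_len, ppt_min_purine)
  orfs <- find_orfs(seq, min_orf_aa, defect_tolerance)
  domains <- list()
  if (nrow(orfs)) {
    for (i in seq_len(nrow(orfs))) {
      segs <- orfs$segments[[i]]
      aa_off <- 0L
      for (s in seq_len(nrow(segs))) {
        hits <- scan_protein_motifs(segs$protein[s], motifs)
        if (nrow(hits)) {
          hits <- hits %>%
            mutate(orf = orfs$orf[i],
                   nt_position = segs$start[s] + 3L * (.data$position - 1L),
                   position = .data$position + aa_off)
          # a stitched segment's overlap with its predecessor re-reads the
          # predecessor's codons in another frame; hits starting there are
          # translation artifacts, not protein motifs
          if (s > 1L) hits <- filter(hits, .data$nt_position > segs$end[s - 1L])
          if (nrow(hits)) domains[[length(domains) + 1L]] <- hits
        }
        aa_off <- aa_off + segs$aa_length[s]
      }
    }
  }
  domains <- if (length(domains)) {
    bind_rows(domains) %>% distinct(.data$motif, .data$nt_position, .keep_all = TRUE) %>%
      arrange(.data$nt_position)
  } else {
    tibble(motif = character(0), domain = character(0), flavor = character(0),
           position = integer(0), weight = integer(0), orf = integer(0),
           nt_position = integer(0))
  }
  pol_hits <- filter(domains, .data$domain != "GAG")
  # the domain order is read off each domain's most specific hit (longest
  # pattern net of its mismatch allowance), so a weak chance match in filler
  # sequence cannot displace a domain
  reps <- pol_hits %>%
    group_by(.data$domain) %>%
    arrange(desc(.data$weight), .data$nt_position, .by_group = TRUE) %>%
    slice(1L) %>%
    ungroup()
  ord <- order_domains(rename_position_nt(reps))
  # superfamily-diagnostic evidence by specificity-weighted majority
  gypsy_evidence <- sum(pol_hits$weight[pol_hits$flavor == "gypsy"]) >
    sum(pol_hits$weight[pol_hits$flavor == "copia"])
  superfamily <- classify_superfamily(ord, gypsy_evidence)
  complete <- !is.null(ltr) && all(c("PR", "INT", "RT", "RH") %in% pol_hits$domain)
  structure(list(
    ltr = ltr, pbs = pbs, ppt = ppt, orfs = orfs, domains = domains,
    domain_order = ord, gypsy_evidence = gypsy_evidence,
    superfamily = superfamily,
    completeness = if (complete) "full_length" else "partial",
    length = nchar(seq), sequence = seq
  ), class = "element_annotation")
}

# order_domains expects a `position` column; order along the element
rename_position_nt <- function(hits) {
  if (!nrow(hits)) return(hits)
  mutate(hits, position = .data$nt_position)
}

#' Extract the RT/RH domain region protein from an annotation
#'
#' Slices the stitched ORF translation from just before the first reverse
#' transcriptase motif to just after the last RNase-H motif — the region
#' ranked against the reference library for clade assignment.
#'
#' @param ann An `element_annotation`.
#' @param flank Flanking residues kept on each side.
#' @return Amino-acid string, or `NULL` when RT/RH motifs are absent.
#' @export
rt_rh_protein <- function(ann, flank = 10L) {
  hits <- filter(ann$domains, .data$domain %in% c("RT", "RH"))
  if (!nrow(hits) || !any(hits$domain == "RT") || !any(hits$domain == "RH")) {
    return(NULL)
  }
  orf_id <- hits$orf[which.max(hits$domain == "RT")]
  hits <- filter(hits, .data$orf == orf_id)
  segs <- ann$orfs$segments[[match(orf_id, ann$orfs$orf)]]
  protein <- paste0(segs$protein, collapse = "")
  lo <- max(1L, min(hits$position) - flank)
  hi <- min(nchar(protein), max(hits$position) + 10L + flank)
  substr(protein, lo, hi)
}

#' @export
print.element_annotation <- function(x, ...) {
  cat(sprintf("<element_annotation> %d bp, %s, %s\n", x$length,
              x$superfamily, x$completeness))
  if (!is.null(x$ltr)) {
    cat(sprintf("  LTR pair: %d bp, identity %.3f, termini %s..%s\n",
                x$ltr$length, x$ltr$identity, x$ltr$termini_start, x$ltr$termini_end))
  }
  if (!is.null(x$pbs)) {
    cat(sprintf("  PBS: %s at %d (%s)\n", x$pbs$sequence, x$pbs$position,
                x$pbs$trna_label))
  }
  if (!is.null(x$ppt)) {
    cat(sprintf("  PPT: %s at %d (purine %.2f)\n", x$ppt$sequence,
                x$ppt$position, x$ppt$purine_fraction))
  }
  cat(sprintf("  ORFs: %d; domain order: %s\n", nrow(x$orfs),
              if (nzchar(x$domain_order)) x$domain_order else "(none)"))
  invisible(x)
}
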