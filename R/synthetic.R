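# Synthetic LTR-retrotransposon generator.
#
# Elements are laid out as
#   [5' LTR][gap][PBS][spacer][gag ORF][spacer][pol ORF][spacer][PPT][gap][3' LTR]
# with both LTR copies identical, the PBS reverse-complementary to a bundled
# tRNA 3' end, a purine PPT, and gag/pol ORFs that translate to proteins
# carrying the conserved domain motifs in the order characteristic of the
# requested superfamily (Copia: PR-INT-RT-RH; Gypsy: PR-RT-RH-INT; Gmr1-like
# Gypsy: INT upstream of RT). Every planted feature is recorded in a
# GFF3-style truth table so annotation can be scored exactly.
#
# The pol domain region ("core") is a canonical amino-acid sequence fixed per
# superfamily, so that independently generated elements of the same
# superfamily are recognisably homologous across their RT/RH domains (the
# property real clade classification relies on); codon choice, spacers, gag
# filler and LTRs are drawn from the element seed.

AA_CODONS <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
})

# amino acids used as neutral filler: excludes C/H/D/E so that zinc-finger,
# DDE and protease motifs can only occur where planted
FILLER_AA <- c("A", "R", "N", "G", "I", "L", "K", "M", "F", "P", "Q", "S",
               "T", "W", "Y", "V")

# fixed-codon motif blocks guaranteeing exact degenerate-primer footprints
KARLVA_DNA <- "AAAGCCAGGCTGGTGGCA"   # KARLVA; exact CD1 site
YVDDLV_DNA <- "TATGTGGATGATCTGGTG"   # YVDDLV; exact CD2 site (reverse)
RMPFGL_DNA <- "AGGATGCCATTTGGCCTG"   # RMPFGL; exact GD1 site
GD2SITE_DNA <- "CTGGCCACAGATGCCGAA"  # LATDAE; exact GD2 site (reverse)
ADALSR_DNA <- "GCCGATGCACTGTCACGA"   # ADALSR; exact GD3 site (reverse)

# long domain-core motifs (12 aa, matched with up to 3 mismatches) make the
# domain calls robust to scattered substitutions; they avoid C/H/D/E so they
# cannot shadow the zinc-finger, protease or DD35E patterns
RT_CORE_COPIA <- "WKQLTGMSPFLV"
RT_CORE_GYPSY <- "FNSPLMTKWQVG"
INT_CORE <- "GQKLAVRMTWPF"
RH_CORE_COPIA <- "MSVPWFKQTLRG"
RH_CORE_GYPSY <- "KPLWGQMVFTRS"

random_aa <- function(n) {
  if (n <= 0L) return(character(0))
  sample(FILLER_AA, n, replace = TRUE)
}

# "LKAK" with these exact codons places a stop codon in both alternative
# reading frames (CTA|AAA reads TAA in frame +1; GCT|AAA reads TAA in frame
# +2), so pol filler carrying the guard every ~12 codons cannot host long
# stop-free alternative-frame runs that would shadow the real reading frame
FRAME_GUARD_AA <- c("L", "K", "A", "K")
FRAME_GUARD_DNA <- c("CTA", "AAA", "GCT", "AAA")

# filler with a frame guard every 12 residues; returns aa and a per-base
# template (NA = free codon choice)
guarded_fill <- function(n) {
  aa <- character(0)
  dna <- character(0)
  left <- n
  while (left >= 12L) {
    aa <- c(aa, random_aa(8L), FRAME_GUARD_AA)
    dna <- c(dna, rep(NA_character_, 24L), unlist(strsplit(FRAME_GUARD_DNA, "")))
    left <- left - 12L
  }
  aa <- c(aa, random_aa(left))
  dna <- c(dna, rep(NA_character_, 3L * left))
  list(aa = aa, dna = dna)
}

# ---- protein block designs ---------------------------------------------------

.block <- function(aa, motifs = NULL, dna = NULL) {
  list(aa = aa, motifs = motifs, dna = dna)
}

.zf_gag_block <- function() {
  aa <- c("C", random_aa(2), "C", random_aa(4), "H", random_aa(4), "C")
  .block(aa, tibble(name = "GAG_ZF", domain = "GAG", aa_off = 1L))
}

.pr_block <- function(superfamily) {
  motif <- if (superfamily == "copia") c("D", "T", "G", "C") else c("D", "T", "G", "A")
  .block(motif, tibble(name = "PR_DxG", domain = "PR", aa_off = 1L))
}

# helpers composing aa + per-base templates
.lit <- function(aa_string, dna_string = NULL) {
  aa <- seq_chars(aa_string)
  dna <- if (is.null(dna_string)) rep(NA_character_, 3L * length(aa)) else
    seq_chars(dna_string)
  list(aa = aa, dna = dna)
}
.cat_parts <- function(...) {
  parts <- list(...)
  list(aa = unlist(lapply(parts, `[[`, "aa")),
       dna = unlist(lapply(parts, `[[`, "dna")))
}

.int_block <- function() {
  zf <- .cat_parts(.lit("H"), guarded_fill(4), .lit("H"), guarded_fill(30),
                   .lit("C"), guarded_fill(2), .lit("C"))
  dde <- .cat_parts(.lit("D"), guarded_fill(20), .lit("D"), guarded_fill(35),
                    .lit("E"))
  p <- .cat_parts(zf, .lit(INT_CORE), guarded_fill(5), dde)
  .block(p$aa, tibble(name = c("INT_ZF", "INT_CORE", "INT_DDE"), domain = "INT",
                      aa_off = c(1L, 41L, 58L)), p$dna)
}

.rt_block <- function(superfamily) {
  if (superfamily == "copia") {
    p <- .cat_parts(.lit("KARLVA", KARLVA_DNA), guarded_fill(20),
                    .lit(RT_CORE_COPIA), guarded_fill(89),
                    .lit("YVDDLV", YVDDLV_DNA))
    .block(p$aa, tibble(name = c("RT_KARLVA", "RT_CORE_COPIA", "RT_YxDD"),
                        domain = "RT", aa_off = c(1L, 27L, 128L)), p$dna)
  } else {
    p <- .cat_parts(.lit("RMPFGL", RMPFGL_DNA), guarded_fill(10),
                    .lit(RT_CORE_GYPSY), guarded_fill(38), .lit("YLDD"),
                    guarded_fill(10))
    .block(p$aa, tibble(name = c("RT_RMPFGL", "RT_CORE_GYPSY", "RT_YxDD"),
                        domain = "RT", aa_off = c(1L, 17L, 67L)), p$dna)
  }
}

.rh_block <- function(superfamily) {
  if (superfamily == "copia") {
    p <- .cat_parts(guarded_fill(4), .lit(RH_CORE_COPIA), guarded_fill(2),
                    .lit("TRPDI"), guarded_fill(4))
    .block(p$aa, tibble(name = c("RH_CORE_COPIA", "RH_TRPDI"), domain = "RH",
                        aa_off = c(5L, 19L)), p$dna)
  } else {
    p <- .cat_parts(.lit("LATDAE", GD2SITE_DNA), guarded_fill(8),
                    .lit("LTTDAS"), .lit(RH_CORE_GYPSY),
                    .lit("ADALSR", ADALSR_DNA), guarded_fill(4))
    .block(p$aa, tibble(name = c("RH_LTTDAS", "RH_CORE_GYPSY", "RH_ADALSR"),
                        domain = "RH", aa_off = c(15L, 21L, 33L)), p$dna)
  }
}

POL_DOMAIN_ORDER <- list(
  copia = c("PR", "INT", "RT", "RH"),
  gypsy = c("PR", "RT", "RH", "INT"),
  gmr1_gypsy = c("PR", "INT", "RT", "RH")
)

# canonical pol domain cores, one per superfamily, memoised
.pol_core_cache <- new.env(parent = emptyenv())

.pol_core <- function(superfamily) {
  if (!is.null(.pol_core_cache[[superfamily]])) {
    return(.pol_core_cache[[superfamily]])
  }
  core <- with_seed(7000L + match(superfamily, names(POL_DOMAIN_ORDER)), {
    order <- POL_DOMAIN_ORDER[[superfamily]]
    makers <- list(PR = function() .pr_block(superfamily),
                   INT = .int_block,
                   RT = function() .rt_block(superfamily),
                   RH = function() .rh_block(superfamily))
    head_pad <- guarded_fill(12)
    aa <- head_pad$aa
    dna <- head_pad$dna
    motifs <- list()
    for (dom in order) {
      blk <- makers[[dom]]()
      if (!is.null(blk$motifs)) {
        motifs[[dom]] <- mutate(blk$motifs, aa_off = .data$aa_off + length(aa))
      }
      aa <- c(aa, blk$aa)
      dna <- c(dna, blk$dna %||% rep(NA_character_, 3 * length(blk$aa)))
      link <- guarded_fill(12)
      aa <- c(aa, link$aa)
      dna <- c(dna, link$dna)
    }
    list(aa = aa, dna = dna, motifs = bind_rows(motifs))
  })
  .pol_core_cache[[superfamily]] <- core
  core
}

# ---- blueprints --------------------------------------------------------------

#' Describe a synthetic LTR-retrotransposon element
#'
#' A blueprint fixes the structural layout of one element: superfamily (which
#' sets the pol domain order and motif set), LTR length and bordering
#' dinucleotides, PBS sequence and its offset from the 5' LTR, PPT sequence
#' and its offset from the 3' LTR, gag length, total length, and any decay
#' defects (premature stops, frameshifts) to plant in pol.
#'
#' @param superfamily `"copia"`, `"gypsy"` or `"gmr1_gypsy"`.
#' @param ltr_length Length of each long terminal repeat (bp, >= 50).
#' @param ltr_termini Two dinucleotides bordering each LTR (start, end).
#' @param pbs_sequence Primer-binding-site sequence (12-18 nt), reverse
#'   complementary to the 3' end of the tRNA named by `trna_label`.
#' @param trna_label tRNA whose 3' end primes minus-strand synthesis; must be
#'   present in [trna_3prime_library()].
#' @param pbs_offset Gap (nt) between the 5' LTR end and the PBS start.
#' @param ppt_sequence Polypurine-tract sequence planted upstream of the 3' LTR.
#' @param ppt_offset Gap (nt) between the PPT end and the 3' LTR start.
#' @param gag_length gag ORF length in amino acids.
#' @param gag_zinc_finger Plant the gag zinc-finger motif CX2CX4HX4C?
#' @param total_length Full element length (bp), LTRs included.
#' @param defect_spec List of `list(kind = "stop"|"frameshift", position = <nt>)`
#'   records, positions 1-based on the element; all must fall inside pol.
#' @return An object of class `ltr_blueprint`.
#' @seealso [make_element()], [blueprint_copia_full()]
#' @export
element_blueprint <- function(superfamily = c("copia", "gypsy", "gmr1_gypsy"),
                              ltr_length = 217L,
                              ltr_termini = c("TG", "CA"),
                              pbs_sequence = "TGGTAGCAGAGC",
                              trna_label = "tRNA-Met",
                              pbs_offset = 1L,
                              ppt_sequence = "AAAGAAAGAGGACGAG",
                              ppt_offset = 2L,
                              gag_length = 288L,
                              gag_zinc_finger = TRUE,
                              total_length = 4949L,
                              defect_spec = list()) {
  superfamily <- match.arg(superfamily)
  if (ltr_length < 50L) abort("ltr_length must be >= 50")
  if (nchar(pbs_sequence) < 12L || nchar(pbs_sequence) > 18L) {
    abort("pbs_sequence length must be in [12, 18]")
  }
  assert_dna(pbs_sequence, "pbs_sequence")
  assert_dna(ppt_sequence, "ppt_sequence")
  if (length(ltr_termini) != 2L || any(nchar(ltr_termini) != 2L)) {
    abort("ltr_termini must be two dinucleotides")
  }
  internal <- total_length - 2L * ltr_length
  if (internal <= 0L) abort("total_length must exceed twice the LTR length")
  for (d in defect_spec) {
    if (!d$kind %in% c("stop", "frameshift")) {
      abort("defect kind must be 'stop' or 'frameshift'")
    }
  }
  structure(list(
    superfamily = superfamily,
    ltr_length = as.integer(ltr_length),
    ltr_termini = toupper(ltr_termini),
    pbs_sequence = toupper(pbs_sequence),
    trna_label = trna_label,
    pbs_offset = as.integer(pbs_offset),
    ppt_sequence = toupper(ppt_sequence),
    ppt_offset = as.integer(ppt_offset),
    gag_length = as.integer(gag_length),
    gag_zinc_finger = isTRUE(gag_zinc_finger),
    total_length = as.integer(total_length),
    internal_length = as.integer(internal),
    pol_domain_order = POL_DOMAIN_ORDER[[superfamily]],
    defect_spec = defect_spec
  ), class = "ltr_blueprint")
}

#' Preset blueprints
#'
#' Four ready-made blueprints spanning the structures the annotation stage
#' must handle: a full-length Copia element (217 bp LTRs bordered by TG..CA,
#' PBS at position 219, purine tract just upstream of the 3' LTR), a decayed
#' Copia element (133 bp LTRs; pol carries a premature stop at nt 1537 and
#' frameshifts at nt 1202 and 3934), a full-length Gypsy element (358 bp LTRs
#' bordered by CT..AA, tRNA-Trp primed PBS at position 467, distal PPT) and a
#' Gmr1-like Gypsy element whose integrase lies upstream of the RT.
#'
#' @return An `ltr_blueprint`.
#' @export
blueprint_copia_full <- function() element_blueprint()

#' @rdname blueprint_copia_full
#' @export
blueprint_copia_decayed <- function() {
  element_blueprint(
    superfamily = "copia",
    ltr_length = 133L,
    total_length = 4875L,
    gag_length = 174L,
    ppt_sequence = "AAGAGAAAAAGGAGGGGGAGA",
    ppt_offset = 106L,
    defect_spec = list(
      list(kind = "frameshift", position = 1202L),
      list(kind = "stop", position = 1537L),
      list(kind = "frameshift", position = 3934L)
    )
  )
}

#' @rdname blueprint_copia_full
#' @export
blueprint_gypsy_full <- function() {
  element_blueprint(
    superfamily = "gypsy",
    ltr_length = 358L,
    ltr_termini = c("CT", "AA"),
    pbs_sequence = "TGGTGACCCTGAAGTA",
    trna_label = "tRNA-Trp",
    pbs_offset = 108L,
    ppt_sequence = "AAGAAATTAGGGAG",
    ppt_offset = 83L,
    gag_length = 235L,
    gag_zinc_finger = FALSE,
    total_length = 5585L
  )
}

#' @rdname blueprint_copia_full
#' @export
blueprint_gmr1 <- function() {
  element_blueprint(
    superfamily = "gmr1_gypsy",
    ltr_length = 220L,
    ppt_sequence = "AAAGAAAGAGGAAGAG",
    gag_length = 250L,
    total_length = 5200L
  )
}

# ---- element construction ----------------------------------------------------

.encode_aa <- function(aa, fixed_dna = NULL) {
  n <- length(aa)
  out <- character(n)
  for (i in seq_len(n)) {
    if (!is.null(fixed_dna) && !is.na(fixed_dna[3 * i - 2])) {
      out[i] <- paste0(fixed_dna[(3 * i - 2):(3 * i)], collapse = "")
    } else {
      cods <- AA_CODONS[[aa[i]]]
      out[i] <- if (length(cods) == 1L) cods else sample(cods, 1L)
    }
  }
  out
}

.random_ltr <- function(len, termini) {
  # all-frame stop guards every ~55 bp keep the (non-coding) repeat free of
  # long chance reading frames
  g <- nchar(STOP_GUARD)
  chunks <- character(0)
  left <- len - 4L
  # period 31 + 11 = 42 nt, a multiple of 3, so every reading frame meets a
  # stop at a fixed 42 nt spacing (runs of at most 13 codons)
  while (left >= 31L + g) {
    chunks <- c(chunks, random_dna(31L), STOP_GUARD)
    left <- left - 31L - g
  }
  chunks <- c(chunks, random_dna(left))
  paste0(termini[1], paste0(chunks, collapse = ""), termini[2])
}

# design the pol amino-acid sequence: canonical domain core placed so that it
# avoids defect cut points, random filler elsewhere; K forced after each
# frameshift cut so the engineered junction reads as a stop in the old frame
.design_pol_aa <- function(superfamily, n_codons, cut_aa) {
  core <- .pol_core(superfamily)
  core_len <- length(core$aa)
  if (n_codons < core_len + 8L) {
    abort("internal_length too small for the requested ORFs", class = "ltrtrace_layout_error")
  }
  forbidden <- sort(unique(c(cut_aa, cut_aa + 1L)))
  start <- 9L
  repeat {
    span <- seq.int(start, start + core_len - 1L)
    hit <- forbidden[forbidden >= start - 1L & forbidden <= start + core_len - 1L]
    if (!length(hit)) break
    start <- max(hit) + 2L
    if (start + core_len - 1L > n_codons - 4L) {
      abort("cannot place pol domain core clear of planted defects",
            class = "ltrtrace_layout_error")
    }
  }
  pad <- guarded_fill(n_codons)
  aa <- pad$aa
  dna <- pad$dna
  aa[span] <- core$aa
  dna[(3L * (start - 1L) + 1L):(3L * (start + core_len - 1L))] <- core$dna
  # the residue after a frameshift cut is a lysine whose codon starts AA, so
  # the engineered junction reads as a stop in the old frame; free its codon
  # in case it lands on a guard position
  kpos <- pmin(cut_aa + 1L, n_codons)
  aa[kpos] <- "K"
  for (k in kpos) dna[(3L * k - 2L):(3L * k)] <- NA_character_
  motifs <- mutate(core$motifs, aa_off = .data$aa_off + start - 1L)
  list(aa = aa, dna = dna, motifs = motifs, core_start = start)
}

# emit pol DNA with planted defects; returns dna string, nt position of each
# codon, and defect truth rows
.encode_pol <- function(aa, dna_template, pol_start, pol_nt, defects) {
  defects <- defects[order(map_dbl(defects, "position"))]
  out <- character(0)
  nt_of_aa <- integer(length(aa))
  pos <- pol_start
  aa_idx <- 1L
  emit_codons <- function(n) {
    if (n < 0L) abort("defect positions out of order or outside pol",
                      class = "ltrtrace_layout_error")
    if (n == 0L) return(invisible())
    idx <- seq.int(aa_idx, aa_idx + n - 1L)
    cods <- character(n)
    for (k in seq_along(idx)) {
      i <- idx[k]
      tpl <- dna_template[(3L * i - 2L):(3L * i)]
      if (!is.na(tpl[1])) {
        cods[k] <- paste0(tpl, collapse = "")
      } else {
        choices <- AA_CODONS[[aa[i]]]
        cods[k] <- if (length(choices) == 1L) choices else sample(choices, 1L)
      }
    }
    nt_of_aa[idx] <<- pos + 3L * (seq_len(n) - 1L)
    out <<- c(out, cods)
    pos <<- pos + 3L * n
    aa_idx <<- aa_idx + n
  }
  truth <- list()
  for (d in defects) {
    dpos <- as.integer(d$position)
    if (dpos <= pos || dpos >= pol_start + pol_nt) {
      abort(sprintf("defect position %d falls outside pol", dpos),
            class = "ltrtrace_layout_error")
    }
    gap <- dpos - pos
    if (gap %% 3L != 0L) {
      abort(sprintf("defect position %d is not codon-aligned with pol frame", dpos),
            class = "ltrtrace_layout_error")
    }
    emit_codons(gap %/% 3L)
    if (d$kind == "stop") {
      out <- c(out, "TAA")
      pos <- pos + 3L
      truth[[length(truth) + 1L]] <- tibble(type = "stop_codon", start = dpos,
                                            end = dpos + 2L)
    } else {
      j <- (d$j %||% 0L)
      out <- c(out, if (j == 0L) "T" else "TA")
      pos <- pos + 1L + j
      truth[[length(truth) + 1L]] <- tibble(type = "frameshift", start = dpos,
                                            end = dpos)
    }
  }
  tail_codons <- (pol_start + pol_nt - pos) %/% 3L
  if ((pol_start + pol_nt - pos) %% 3L != 0L) {
    abort("pol length not codon-consistent with defects", class = "ltrtrace_layout_error")
  }
  emit_codons(tail_codons)
  if (aa_idx != length(aa) + 1L) abort("pol codon accounting failed")
  list(dna = paste0(out, collapse = ""), nt_of_aa = nt_of_aa,
       truth = bind_rows(truth))
}

# choose frameshift pads (j in {0,1}) so downstream defects stay codon-aligned
.solve_defect_frames <- function(defects, pol_start) {
  anchor <- pol_start
  for (i in seq_along(defects)) {
    d <- defects[[i]]
    if ((d$position - anchor) %% 3L != 0L) {
      abort(sprintf("defect at %d cannot be codon-aligned", d$position),
            class = "ltrtrace_layout_error")
    }
    if (d$kind == "stop") {
      anchor <- d$position + 3L
    } else {
      nxt <- if (i < length(defects)) defects[[i + 1L]]$position else NA_integer_
      j <- 0L
      if (!is.na(nxt)) {
        for (jj in 0:1) {
          if ((nxt - (d$position + 1L + jj)) %% 3L == 0L) { j <- jj; break }
          if (jj == 1L) abort(sprintf("defects at %d and %d cannot both be codon-aligned",
                                      d$position, nxt), class = "ltrtrace_layout_error")
        }
      }
      defects[[i]]$j <- j
      anchor <- d$position + 1L + j
    }
  }
  defects
}

#' Generate a synthetic element from a blueprint
#'
#' Builds the element sequence and an exact truth table of every planted
#' feature: both LTR copies, PBS, PPT, gag and pol coding regions, planted
#' decay defects, and the nucleotide position of every protein domain motif.
#'
#' @param blueprint An [element_blueprint()].
#' @param seed Integer seed; identical seeds give byte-identical elements.
#' @return An object of class `ltr_element`: a list with `$sequence` (single
#'   DNA string), `$truth` (tibble of planted features with 1-based inclusive
#'   coordinates), `$pol_protein` and `$gag_protein` (the conceptual
#'   translations), and `$blueprint`.
#' @examples
#' el <- make_element(blueprint_copia_full(), seed = 1)
#' nchar(el$sequence)
#' dplyr::count(el$truth, type)
#' @export
make_element <- function(blueprint, seed = 1L) {
  stopifnot(inherits(blueprint, "ltr_blueprint"))
  bp <- blueprint
  with_seed(seed, {
    ltr <- .random_ltr(bp$ltr_length, bp$ltr_termini)
    pbs_len <- nchar(bp$pbs_sequence)
    ppt_len <- nchar(bp$ppt_sequence)
    s1 <- 45L
    s2 <- 30L
    s3 <- 40L
    defects <- bp$defect_spec
    pre <- bp$ltr_length + bp$pbs_offset + pbs_len + s1 + 3L * bp$gag_length
    if (length(defects)) {
      defects <- defects[order(map_dbl(defects, "position"))]
      # pick s2 in {28,29,30} so the first defect is codon-aligned with pol
      t <- (defects[[1]]$position - pre - 1L) %% 3L
      s2 <- 28L + ((t - 28L) %% 3L)
    }
    pol_start <- pre + s2 + 1L
    fixed <- bp$pbs_offset + pbs_len + s1 + 3L * bp$gag_length + s2 + s3 +
      ppt_len + bp$ppt_offset
    pol_nt <- bp$internal_length - fixed
    defects <- .solve_defect_frames(defects, pol_start)
    overhead <- sum(map_int(defects, function(d) {
      if (d$kind == "stop") 3L else 1L + (d$j %||% 0L)
    }))
    rem <- (pol_nt - overhead) %% 3L
    s3 <- s3 + rem
    pol_nt <- pol_nt - rem
    n_codons <- (pol_nt - overhead) %/% 3L
    if (n_codons < 60L) {
      abort("internal_length too small for the requested ORFs",
            class = "ltrtrace_layout_error")
    }
    # aa-boundary cut indices implied by the defects
    cuts <- integer(0)
    anchor <- pol_start
    acc <- 0L
    for (d in defects) {
      acc <- acc + (d$position - anchor) %/% 3L
      cuts <- c(cuts, acc)
      anchor <- d$position + if (d$kind == "stop") 3L else 1L + (d$j %||% 0L)
    }
    pol <- .design_pol_aa(bp$superfamily, n_codons, cuts)
    enc <- .encode_pol(pol$aa, pol$dna, pol_start, pol_nt, defects)

    # gag
    gag_aa <- random_aa(bp$gag_length)
    gag_motif_off <- NA_integer_
    if (bp$gag_zinc_finger) {
      zf <- .zf_gag_block()
      gag_motif_off <- 11L
      gag_aa[11:24] <- zf$aa
    }
    gag_dna <- paste0(.encode_aa(gag_aa), collapse = "")

    # tRNA-derived guard: stop a chance PBS extension one base past the PBS
    lib <- trna_3prime_library()
    trna <- lib$sequence[match(bp$trna_label, lib$label)]
    guard_after_pbs <- NA_character_
    if (!is.na(trna) && nchar(trna) > pbs_len) {
      ext <- substr(trna, nchar(trna) - pbs_len, nchar(trna) - pbs_len)
      guard_after_pbs <- sample(setdiff(DNA_BASES, revcomp(ext)), 1L)
    }

    pre_pbs <- random_dna(bp$pbs_offset)
    s1_dna <- spacer_dna(s1)
    if (!is.na(guard_after_pbs)) {
      # guard base first, then the all-frame stop guards
      s1_dna <- paste0(guard_after_pbs, spacer_dna(s1 - 1L))
    }
    s2_dna <- spacer_dna(s2)
    # pre-/post-PPT sequence is kept purine-poor so the planted tract is the
    # best-scoring window in its search neighbourhood
    g <- nchar(STOP_GUARD)
    s3_dna <- paste0(STOP_GUARD, low_purine_dna(s3 - 2L * g - 1L), STOP_GUARD,
                     sample(c("C", "T"), 1L))
    post_ppt <- low_purine_dna(bp$ppt_offset)

    sequence <- paste0(ltr, pre_pbs, bp$pbs_sequence, s1_dna, gag_dna, s2_dna,
                       enc$dna, s3_dna, bp$ppt_sequence, post_ppt, ltr)
    stopifnot(nchar(sequence) == bp$total_length)

    # truth table (1-based inclusive, plus strand)
    ltr5 <- c(1L, bp$ltr_length)
    ltr3 <- c(bp$total_length - bp$ltr_length + 1L, bp$total_length)
    pbs_start <- bp$ltr_length + bp$pbs_offset + 1L
    gag_start <- pbs_start + pbs_len + s1
    ppt_start <- bp$total_length - bp$ltr_length - bp$ppt_offset - ppt_len + 1L
    motif_truth <- mutate(pol$motifs, start = enc$nt_of_aa[.data$aa_off])
    rows <- list(
      tibble(type = "long_terminal_repeat", start = ltr5[1], end = ltr5[2],
             label = "five_prime_LTR"),
      tibble(type = "long_terminal_repeat", start = ltr3[1], end = ltr3[2],
             label = "three_prime_LTR"),
      tibble(type = "primer_binding_site", start = pbs_start,
             end = pbs_start + pbs_len - 1L, label = bp$trna_label),
      tibble(type = "polypurine_tract", start = ppt_start,
             end = ppt_start + ppt_len - 1L, label = "PPT"),
      tibble(type = "CDS", start = gag_start, end = gag_start + 3L * bp$gag_length - 1L,
             label = "gag"),
      tibble(type = "CDS", start = pol_start, end = pol_start + pol_nt - 1L,
             label = "pol"),
      tibble(type = "protein_motif", start = motif_truth$start,
             end = motif_truth$start + 2L, label = motif_truth$name)
    )
    if (bp$gag_zinc_finger) {
      zf_nt <- gag_start + 3L * (gag_motif_off - 1L)
      rows[[length(rows) + 1L]] <- tibble(type = "protein_motif", start = zf_nt,
                                          end = zf_nt + 2L, label = "GAG_ZF")
    }
    if (nrow(enc$truth)) {
      rows[[length(rows) + 1L]] <- mutate(enc$truth, label = .data$type)
    }
    truth <- bind_rows(rows) %>%
      mutate(seqid = "element", strand = "+", .before = 1) %>%
      arrange(.data$start, .data$type)

    structure(list(sequence = sequence, truth = truth,
                   gag_protein = paste0(gag_aa, collapse = ""),
                   pol_protein = paste0(pol$aa, collapse = ""),
                   pol_core_start = pol$core_start,
                   blueprint = bp, seed = as.integer(seed)),
              class = "ltr_element")
  })
}

#' @export
print.ltr_element <- function(x, ...) {
  cat(sprintf("<ltr_element> %s, %d bp, %d truth features (seed %d)\n",
              x$blueprint$superfamily, nchar(x$sequence), nrow(x$truth), x$seed))
  invisible(x)
}

# ---- family diversification --------------------------------------------------

# per-branch substitution probability whose two-branch composition gives the
# requested pairwise p-distance (Jukes-Cantor composition of p-distances)
.branch_p <- function(pairwise) {
  if (pairwise < 0 || pairwise > 0.75) abort("divergence must lie in [0, 0.75]")
  0.75 * (1 - sqrt(1 - 4 * pairwise / 3))
}

.mutate_seq <- function(seq, p, mask = NULL) {
  if (p <= 0) return(seq)
  chars <- seq_chars(seq)
  hit <- which(runif(length(chars)) < p)
  if (!is.null(mask)) hit <- setdiff(hit, mask)
  for (i in hit) chars[i] <- sample(setdiff(DNA_BASES, chars[i]), 1L)
  paste0(chars, collapse = "")
}

#' Expand one element into divergent families
#'
#' Simulates families of element copies with controlled intra- and
#' inter-family divergence. Each family descends from its own ancestor
#' (derived from `element`), and each copy from its family ancestor, with
#' uniform per-site substitutions to a random different base. Branch
#' substitution rates are chosen so that the *pairwise* p-distances have the
#' requested expectations.
#'
#' @param element Element DNA (single string) to diversify.
#' @param n_families Number of families.
#' @param copies_per_family Copies per family.
#' @param intra_divergence Expected pairwise p-distance within a family.
#' @param inter_divergence Expected pairwise p-distance between families;
#'   must satisfy `0 <= intra < inter <= 0.75`.
#' @param seed Integer seed.
#' @param conserved Optional two-column matrix/data frame of 1-based
#'   inclusive intervals protected from substitution — the analogue of
#'   purifying selection on catalytic motifs (degenerate-primer screens rely
#'   on those motifs staying conserved across families). The protected
#'   footprint should be a negligible fraction of the element for the
#'   realized distances to stay calibrated.
#' @return Tibble with columns `family`, `copy`, `id`, `sequence`.
#' @export
diversify_family <- function(element, n_families = 2L, copies_per_family = 4L,
                             intra_divergence = 0.02, inter_divergence = 0.20,
                             seed = 1L, conserved = NULL) {
  if (intra_divergence == 0 && inter_divergence == 0 && n_families == 1L) {
    # degenerate but allowed: identical copies of one family
  } else if (!(intra_divergence >= 0 && intra_divergence < inter_divergence &&
               inter_divergence <= 0.75)) {
    abort("need 0 <= intra_divergence < inter_divergence <= 0.75")
  }
  assert_dna(element, "element")
  r <- .branch_p(intra_divergence)
  # inter pair crosses two family branches and two copy branches
  q_target <- (1 - 4 * inter_divergence / 3) / (1 - 4 * intra_divergence / 3)
  s <- 0.75 * (1 - sqrt(q_target))
  mask <- NULL
  if (!is.null(conserved)) {
    conserved <- as.matrix(conserved)
    mask <- unlist(lapply(seq_len(nrow(conserved)), function(i) {
      seq.int(conserved[i, 1], conserved[i, 2])
    }))
  }
  with_seed(seed, {
    rows <- list()
    for (f in seq_len(n_families)) {
      anc <- .mutate_seq(element, s, mask)
      for (k in seq_len(copies_per_family)) {
        rows[[length(rows) + 1L]] <- tibble(
          family = sprintf("fam%02d", f), copy = k,
          id = sprintf("fam%02d_c%02d", f, k),
          sequence = .mutate_seq(anc, r, mask))
      }
    }
    bind_rows(rows)
  })
}

# ---- genome planting ---------------------------------------------------------

#' Plant elements into a random background genome
#'
#' Elements replace stretches of an i.i.d. uniform-ACGT background at
#' non-overlapping positions on randomly chosen strands; the truth table
#' records exact coordinates and strands.
#'
#' @param background_length Genome length (bp).
#' @param elements Named character vector of element sequences (names become
#'   truth labels). May be empty.
#' @param seed Integer seed.
#' @return Object of class `synthetic_genome`: list with `$sequence` and
#'   `$truth` (tibble: seqid, type, start, end, strand, label).
#' @export
plant_elements <- function(background_length, elements = character(0), seed = 1L) {
  lens <- nchar(elements)
  if (sum(lens) > background_length) {
    abort("elements do not fit in the background", class = "ltrtrace_placement_error")
  }
  with_seed(seed, {
    genome <- random_dna(background_length)
    rows <- list()
    k <- length(elements)
    if (k) {
      # allocate the free background into k+1 random gaps (always succeeds
      # when the elements fit), then lay elements in shuffled order
      ord <- sample.int(k)
      free <- background_length - sum(lens)
      w <- runif(k + 1L)
      gaps <- floor(free * w / sum(w))
      gaps[k + 1L] <- free - sum(gaps[seq_len(k)])
      pos <- 1L
      for (idx in seq_len(k)) {
        i <- ord[idx]
        st <- pos + gaps[idx]
        en <- st + lens[i] - 1L
        strand <- sample(c("+", "-"), 1L)
        ins <- if (strand == "+") elements[[i]] else revcomp(elements[[i]])
        genome <- paste0(substr(genome, 1L, st - 1L), ins,
                         substr(genome, en + 1L, background_length))
        rows[[length(rows) + 1L]] <- tibble(
          seqid = "genome", type = "mobile_genetic_element",
          start = as.integer(st), end = as.integer(en), strand = strand,
          label = names(elements)[i] %||% sprintf("element_%d", i))
        pos <- en + 1L
      }
    }
    truth <- if (length(rows)) bind_rows(rows) %>% arrange(.data$start) else
      tibble(seqid = character(0), type = character(0), start = integer(0),
             end = integer(0), strand = character(0), label = character(0))
    structure(list(sequence = genome, truth = truth), class = "synthetic_genome")
  })
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf("<synthetic_genome> %d bp, %d planted elements\n",
              nchar(x$sequence), nrow(x$truth)))
  invisible(x)
}

# ---- walking fragments -------------------------------------------------------

#' Split an element into overlapping walking fragments
#'
#' Emulates PCR/TE walking: starting from an anchor interval, fragments tile
#' the element outward with a fixed mutual overlap, so that overlap-validated
#' assembly reconstructs the element exactly. Tiling is deterministic; the
#' seed only shuffles the output order (assembly must not depend on it).
#'
#' @param element Element DNA (single string).
#' @param anchor Integer pair `c(start, end)` (1-based) of the initial
#'   fragment; must lie inside the element.
#' @param step Distance between consecutive fragment starts (bp, > overlap).
#' @param overlap Mutual overlap between adjacent fragments (bp, >= 1).
#' @param seed Integer seed (order shuffling only).
#' @return Tibble with columns `id`, `start`, `end`, `sequence`.
#' @export
make_walk_fragments <- function(element, anchor, step = 400L, overlap = 60L,
                                seed = 1L) {
  n <- nchar(element)
  if (overlap < 1L || step <= overlap) abort("need overlap >= 1 and step > overlap")
  if (anchor[1] < 1L || anchor[2] > n || anchor[1] > anchor[2]) {
    abort("anchor outside element", class = "ltrtrace_bounds_error")
  }
  flen <- step + overlap
  if (flen > n) abort("step + overlap exceeds the element length")
  # walk left from the anchor, then right, in steps of `step`
  left <- rev(seq.int(anchor[1], 1L, by = -step))
  if (left[1] > 1L) left <- c(1L, left)
  right <- if (anchor[1] + step <= n) seq.int(anchor[1] + step, n, by = step) else integer(0)
  starts <- unique(c(left, right))
  starts <- starts[starts + overlap - 1L <= n]
  frags <- tibble(start = as.integer(starts)) %>%
    mutate(end = pmin(.data$start + flen - 1L, n))
  # guarantee the element tail is covered with the stated overlap
  if (max(frags$end) < n) {
    frags <- bind_rows(frags, tibble(start = n - flen + 1L, end = n))
  }
  frags <- frags %>%
    distinct() %>%
    arrange(.data$start) %>%
    mutate(id = sprintf("walk_%02d", row_number()),
           sequence = substr(rep(element, n()), .data$start, .data$end)) %>%
    select("id", "start", "end", "sequence")
  with_seed(seed, frags[sample.int(nrow(frags)), ])
}
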