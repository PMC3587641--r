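test_that("iupac_matches follows the expansion sets", {
  expect_true(iupac_matches("A", "R"))
  expect_false(iupac_matches("C", "R"))
  expect_true(iupac_matches("G", "N"))
  expect_true(iupac_matches("N", "C"))  # N in the template matches anything
  expect_equal(iupac_matches(c("A", "C", "T"), c("M", "M", "M")),
               c(TRUE, TRUE, FALSE))
  expect_error(iupac_matches("A", "Z"), class = "ltrtrace_encoding_error")
})

test_that("primer_degeneracy equals brute-force expansion counts", {
  expect_equal(primer_degeneracy("ACGTACGTACGTACGTA"), 1)
  primers <- bundled_primers()
  expect_setequal(primers$name, c("CD1", "CD2", "GD1", "GD2", "GD3"))
  for (i in seq_len(nrow(primers))) {
    expect_equal(primer_degeneracy(primers$iupac[i]),
                 length(oracle_expansions(primers$iupac[i])),
                 info = primers$name[i])
  }
})

test_that("find_primer_sites matches the naive scan oracle", {
  primers <- bundled_primers()
  cd1 <- primers[primers$name == "CD1", ]
  # planted exact expansion
  withr::with_seed(101, {
    site <- sample(oracle_expansions(cd1$iupac), 1)
    seq <- paste0(rand_dna(200), site, rand_dna(150))
  })
  hits <- find_primer_sites(seq, cd1)
  plus <- hits[hits$strand == "+", ]
  expect_equal(nrow(plus), 1L)
  expect_equal(plus$start, 201L)
  expect_equal(plus$mismatches, 0L)
  # one substitution, tolerated at max_mismatches = 1
  seq_mut <- seq
  substr(seq_mut, 205, 205) <- if (substr(seq, 205, 205) == "C") "A" else "C"
  expect_equal(nrow(find_primer_sites(seq_mut, cd1)[
    find_primer_sites(seq_mut, cd1)$strand == "+", ]), 0L)
  h1 <- find_primer_sites(seq_mut, cd1, max_mismatches = 1)
  h1 <- h1[h1$strand == "+", ]
  expect_equal(h1$start, 201L)
  expect_equal(h1$mismatches, 1L)
  # random 10 kb sequence equals the sliding-window oracle, both strands
  withr::with_seed(77, big <- rand_dna(10000))
  for (p in c("CD1", "CD2", "GD2")) {
    pr <- primers[primers$name == p, ]
    got <- find_primer_sites(big, pr, max_mismatches = 2)
    oplus <- oracle_scan_strand(big, pr$iupac, 2L)
    ominus <- oracle_scan_strand(oracle_revcomp(big), pr$iupac, 2L)
    gplus <- got[got$strand == "+", ]
    expect_equal(gplus$start, oplus$start, info = p)
    expect_equal(gplus$mismatches, oplus$mismatches, info = p)
    gminus <- got[got$strand == "-", ]
    expect_equal(sort(nchar(big) - gminus$end + 1L), sort(ominus$start), info = p)
  }
})

test_that("in_silico_pcr pairs sites exhaustively within the length window", {
  fwd <- "ACGTACGTAC"
  rev_site <- "TTTTCCCCGG"   # minus-strand site: template carries its revcomp
  template <- paste0("GG", fwd, rand_dna(80), oracle_revcomp(rev_site),
                     rand_dna(20), fwd, rand_dna(60), oracle_revcomp(rev_site))
  amps <- in_silico_pcr(template, fwd, rev_site, 0, Inf)
  # 2 fwd x 2 rev downstream pairings = 3 valid (second fwd precedes only one rev)
  fs <- find_primer_sites(template, fwd)
  rs <- find_primer_sites(template, rev_site)
  n_expected <- 0L
  for (i in which(fs$strand == "+")) for (j in which(rs$strand == "-")) {
    if (rs$start[j] > fs$start[i]) n_expected <- n_expected + 1L
  }
  expect_equal(nrow(amps), n_expected)
  expect_true(all(amps$length == amps$end - amps$start + 1L))
  expect_true(all(substr(amps$sequence, 1, 10) == fwd))
  # empty when no site
  expect_equal(nrow(in_silico_pcr(rand_dna(500), "AAAAAAAAAACCCCCCCCCC",
                                  "GGGGGGGGGGTTTTTTTTTT", 0, Inf)), 0L)
})

test_that("CD1/CD2 amplify a ~400 bp product from a Copia element", {
  primers <- bundled_primers()
  el <- make_element(blueprint_copia_full(), seed = 21)
  amps <- in_silico_pcr(el$sequence, primers[primers$name == "CD1", ],
                        primers[primers$name == "CD2", ], 300, 500)
  expect_equal(nrow(amps), 1L)
  expect_lt(abs(amps$length - 400), 25)
  # the product spans the KARLVA -> YxDD region of the RT
  motifs <- truth_of(el, "protein_motif")
  expect_equal(amps$start, motifs$start[motifs$label == "RT_KARLVA"])
  expect_gte(amps$end, motifs$start[motifs$label == "RT_YxDD"])
})

test_that("pcr on the reverse complement mirrors sites and amplicons", {
  primers <- bundled_primers()
  el <- make_element(blueprint_gypsy_full(), seed = 8)
  gd1 <- primers[primers$name == "GD1", ]
  gd2 <- primers[primers$name == "GD2", ]
  fwd_amp <- in_silico_pcr(el$sequence, gd1, gd2, 100, 800)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(el$sequence)))
  rev_amp <- in_silico_pcr(rc, gd2, gd1, 100, 800)
  expect_equal(nrow(fwd_amp), nrow(rev_amp))
  n <- nchar(el$sequence)
  expect_setequal(n - rev_amp$end + 1L, fwd_amp$start)
  expect_setequal(n - rev_amp$start + 1L, fwd_amp$end)
})
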