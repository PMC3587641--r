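test_that("blueprints validate their invariants", {
  expect_error(element_blueprint(ltr_length = 40), "ltr_length")
  expect_error(element_blueprint(pbs_sequence = "TGGTAGCAG"), "pbs_sequence")
  expect_error(element_blueprint(total_length = 300, ltr_length = 200), "total_length")
  bp <- blueprint_copia_full()
  expect_s3_class(bp, "ltr_blueprint")
  expect_equal(bp$internal_length, bp$total_length - 2L * bp$ltr_length)
  expect_equal(bp$pol_domain_order, c("PR", "INT", "RT", "RH"))
  expect_equal(blueprint_gypsy_full()$pol_domain_order, c("PR", "RT", "RH", "INT"))
  # Gmr1-like: integrase upstream of the RT despite Gypsy-type motifs
  expect_equal(blueprint_gmr1()$pol_domain_order, c("PR", "INT", "RT", "RH"))
})

test_that("make_element plants the advertised structure", {
  el <- make_element(blueprint_copia_full(), seed = 11)
  s <- el$sequence
  bp <- el$blueprint
  expect_equal(nchar(s), bp$total_length)
  # identical LTR copies with the stated termini
  ltr5 <- substr(s, 1, bp$ltr_length)
  ltr3 <- substr(s, nchar(s) - bp$ltr_length + 1, nchar(s))
  expect_identical(ltr5, ltr3)
  expect_identical(substr(s, 1, 2), "TG")
  expect_identical(substr(s, bp$ltr_length - 1, bp$ltr_length), "CA")
  # PBS just downstream of the 5' LTR, PPT just upstream of the 3' LTR
  pbs <- truth_of(el, "primer_binding_site")
  expect_identical(substr(s, pbs$start, pbs$end), bp$pbs_sequence)
  expect_equal(pbs$start, bp$ltr_length + bp$pbs_offset + 1L)
  ppt <- truth_of(el, "polypurine_tract")
  expect_identical(substr(s, ppt$start, ppt$end), bp$ppt_sequence)
  expect_equal(ppt$end, bp$total_length - bp$ltr_length - bp$ppt_offset)
  # gag/pol translate cleanly and carry the Copia motif set in order
  expect_false(grepl("*", el$pol_protein, fixed = TRUE))
  expect_match(el$pol_protein, "KARLVA")
  expect_match(el$pol_protein, "YVDD")
  expect_match(el$pol_protein, "TRPDI")
  motifs <- truth_of(el, "protein_motif")
  pr <- motifs$start[motifs$label == "PR_DxG"]
  int <- motifs$start[motifs$label == "INT_ZF"]
  rt <- motifs$start[motifs$label == "RT_KARLVA"]
  rh <- motifs$start[motifs$label == "RH_TRPDI"]
  expect_true(pr < int && int < rt && rt < rh)
})

test_that("elements without planted defects translate defect-free", {
  el <- make_element(blueprint_gypsy_full(), seed = 5)
  expect_false(grepl("*", el$pol_protein, fixed = TRUE))
  expect_equal(nrow(truth_of(el, "stop_codon")), 0L)
  expect_equal(nrow(truth_of(el, "frameshift")), 0L)
})

test_that("gmr1 blueprints put INT upstream of RT in the truth", {
  el <- make_element(blueprint_gmr1(), seed = 2)
  motifs <- truth_of(el, "protein_motif")
  int <- min(motifs$start[grepl("^INT", motifs$label)])
  rt <- min(motifs$start[grepl("^RT", motifs$label)])
  expect_lt(int, rt)
  # Gypsy-flavoured RT/RH motifs are the ones planted
  expect_true("RT_RMPFGL" %in% motifs$label)
  expect_true("RH_LTTDAS" %in% motifs$label)
})

test_that("make_element is deterministic and layout errors are caught", {
  a <- make_element(blueprint_copia_full(), seed = 7)
  b <- make_element(blueprint_copia_full(), seed = 7)
  expect_identical(a$sequence, b$sequence)
  expect_identical(a$truth, b$truth)
  tiny <- element_blueprint(total_length = 1300L, ltr_length = 100L,
                            gag_length = 60L)
  expect_error(make_element(tiny, seed = 1), class = "ltrtrace_layout_error")
})

test_that("diversify_family calibrates intra/inter p-distances", {
  base <- make_element(blueprint_copia_full(), seed = 1)$sequence
  # zero divergence: identical copies
  same <- diversify_family(base, n_families = 1, copies_per_family = 3,
                           intra_divergence = 0, inter_divergence = 0.1, seed = 2)
  expect_true(all(same$sequence == same$sequence[1]))
  # determinism
  d1 <- diversify_family(base, 2, 4, 0.02, 0.2, seed = 3)
  d2 <- diversify_family(base, 2, 4, 0.02, 0.2, seed = 3)
  expect_identical(d1, d2)
  # calibration, tolerance 3 SE over independent replicates (pairs within
  # one simulation share branches, so per-pair SEs would be too small)
  short <- substr(base, 1, 2000)
  intra_reps <- vapply(1:25, function(r) {
    fam <- diversify_family(short, n_families = 1, copies_per_family = 2,
                            intra_divergence = 0.02, inter_divergence = 0.2,
                            seed = 4000 + r)
    oracle_p_distance(fam$sequence[1], fam$sequence[2])
  }, numeric(1))
  expect_lt(abs(mean(intra_reps) - 0.02), 3 * sd(intra_reps) / sqrt(25))
  inter_reps <- vapply(1:25, function(r) {
    fam <- diversify_family(short, n_families = 2, copies_per_family = 1,
                            intra_divergence = 0.02, inter_divergence = 0.2,
                            seed = 4100 + r)
    oracle_p_distance(fam$sequence[1], fam$sequence[2])
  }, numeric(1))
  expect_lt(abs(mean(inter_reps) - 0.20), 3 * sd(inter_reps) / sqrt(25))
  # a large family's mean intra distance sits near the target too
  fam50 <- diversify_family(short, n_families = 1, copies_per_family = 50,
                            intra_divergence = 0.02, inter_divergence = 0.2,
                            seed = 4)
  dm <- pairwise_p_distance(setNames(fam50$sequence, fam50$id))
  expect_lt(abs(mean(dm[upper.tri(dm)]) - 0.02), 0.004)
  expect_error(diversify_family(base, 2, 2, 0.3, 0.2, seed = 1), "intra")
})

test_that("plant_elements places on recorded strands, deterministically", {
  g0 <- plant_elements(5000L, character(0), seed = 1)
  expect_equal(nchar(g0$sequence), 5000L)
  expect_equal(nrow(g0$truth), 0L)
  el <- substr(make_element(blueprint_copia_full(), seed = 1)$sequence, 1, 800)
  g <- plant_elements(20000L, c(e1 = el, e2 = el, e3 = el, e4 = el, e5 = el),
                      seed = 9)
  expect_equal(nrow(g$truth), 5L)
  expect_true(all(g$truth$end <= 20000L))
  o <- order(g$truth$start)
  expect_true(all(g$truth$start[o][-1] > g$truth$end[o][-5]))
  for (i in seq_len(5)) {
    found <- substr(g$sequence, g$truth$start[i], g$truth$end[i])
    want <- if (g$truth$strand[i] == "+") el else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(el)))
    expect_identical(found, want)
  }
  g2 <- plant_elements(20000L, c(e1 = el, e2 = el, e3 = el, e4 = el, e5 = el),
                       seed = 9)
  expect_identical(g$sequence, g2$sequence)
  expect_error(plant_elements(1000L, c(a = el, b = el), seed = 1),
               class = "ltrtrace_placement_error")
})

test_that("walk fragments tile with the stated overlap and reassemble", {
  el <- make_element(blueprint_copia_full(), seed = 3)$sequence
  fr <- make_walk_fragments(el, anchor = c(2001L, 2400L), step = 400L,
                            overlap = 60L, seed = 5)
  srt <- fr[order(fr$start), ]
  expect_equal(srt$start[1], 1L)
  expect_equal(max(srt$end), nchar(el))
  ovl <- srt$end[-nrow(srt)] - srt$start[-1] + 1L
  expect_true(all(ovl >= 60L))
  # every adjacent pair passes the default join rule at 100% identity
  for (i in seq_len(nrow(srt) - 1L)) {
    vj <- validate_join(srt$sequence[i], srt$sequence[i + 1L])
    expect_true(vj$accepted)
    expect_equal(vj$identity, 1.0)
  }
  expect_error(make_walk_fragments(el, anchor = c(-5L, 100L), step = 400L,
                                   overlap = 60L), class = "ltrtrace_bounds_error")
  # overlap below the join rule threshold fails the rule by construction
  fr49 <- make_walk_fragments(el, anchor = c(1L, 449L), step = 400L,
                              overlap = 49L, seed = 1)
  srt49 <- fr49[order(fr49$start), ]
  vj <- validate_join(srt49$sequence[1], srt49$sequence[2])
  expect_false(vj$accepted)
  expect_identical(vj$reason, "overlap_below_minimum")
})
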