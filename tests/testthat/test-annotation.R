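test_that("find_ltr_pair recovers planted repeats and their termini", {
  el <- make_element(blueprint_copia_full(), seed = 41)
  ltr <- find_ltr_pair(el$sequence)
  expect_equal(ltr$length, 217L)
  expect_equal(ltr$five_start, 1L)
  expect_equal(ltr$three_end, nchar(el$sequence))
  expect_equal(ltr$identity, 1.0)
  expect_identical(ltr$termini_start, "TG")
  expect_identical(ltr$termini_end, "CA")
  elg <- make_element(blueprint_gypsy_full(), seed = 41)
  ltrg <- find_ltr_pair(elg$sequence)
  expect_equal(ltrg$length, 358L)
  expect_identical(ltrg$termini_start, "CT")
  expect_identical(ltrg$termini_end, "AA")
  # random sequence has no repeat of the required length
  withr::with_seed(9, r <- rand_dna(3000))
  expect_null(find_ltr_pair(r))
})

test_that("find_pbs matches tRNA 3' ends by reverse complement", {
  el <- make_element(blueprint_copia_full(), seed = 12)
  ltr <- find_ltr_pair(el$sequence)
  pbs <- find_pbs(el$sequence, ltr)
  expect_identical(pbs$sequence, "TGGTAGCAGAGC")
  expect_identical(pbs$trna_label, "tRNA-Met")
  expect_equal(pbs$position, 219L)
  elg <- make_element(blueprint_gypsy_full(), seed = 12)
  ltrg <- find_ltr_pair(elg$sequence)
  pbsg <- find_pbs(elg$sequence, ltrg, window = 125L)
  expect_identical(pbsg$sequence, "TGGTGACCCTGAAGTA")
  expect_identical(pbsg$trna_label, "tRNA-Trp")
  expect_equal(pbsg$position, 467L)
  # no complementary stretch: nothing reported
  withr::with_seed(10, {
    plain <- paste0(strrep("CT", 400), strrep("GA", 60), strrep("CT", 400))
  })
  ltr_fake <- tibble::tibble(five_start = 1L, five_end = 100L,
                             three_start = 700L, three_end = 800L)
  expect_null(find_pbs(plain, ltr_fake))
})

test_that("find_ppt scores purine windows with the documented tie rules", {
  el <- make_element(blueprint_copia_full(), seed = 13)
  ltr <- find_ltr_pair(el$sequence)
  ppt <- find_ppt(el$sequence, ltr)
  expect_equal(ppt$position, 4715L)
  expect_gte(ppt$purine_fraction, 0.9)
  # pure pyrimidine window: nothing
  ct <- strrep("CT", 400)
  ltr_fake <- tibble::tibble(five_start = 1L, five_end = 50L,
                             three_start = 700L, three_end = 800L)
  expect_null(find_ppt(ct, ltr_fake))
  # two equal tracts: leftmost wins
  two <- paste0(strrep("CT", 250), "AAAAAGGGGG", "CTCTCT", "AAAAAGGGGG",
                "CT", strrep("AC", 100))
  ltr2 <- tibble::tibble(five_start = 1L, five_end = 50L,
                         three_start = 539L, three_end = 700L)
  hit <- find_ppt(two, ltr2, window = 40L)
  expect_equal(hit$position, 501L)
})

test_that("find_orfs reports clean ORFs and planted decay exactly", {
  el <- make_element(blueprint_copia_full(), seed = 14)
  orfs <- find_orfs(el$sequence)
  expect_equal(nrow(orfs), 2L)
  expect_true(all(vapply(orfs$defects, nrow, integer(1)) == 0L))
  gag <- truth_of(el, "CDS")
  expect_lte(orfs$start[1], gag$start[gag$label == "gag"])
  # planted stop and frameshifts recovered at their exact positions
  eld <- make_element(blueprint_copia_decayed(), seed = 14)
  orfd <- find_orfs(eld$sequence)
  defects <- dplyr::bind_rows(orfd$defects)
  expect_setequal(defects$position, c(1202L, 1537L, 3934L))
  expect_identical(defects$kind[defects$position == 1537L], "stop")
  expect_setequal(defects$kind[defects$position != 1537L], "frameshift")
  # all-stop sequence yields nothing
  expect_equal(nrow(find_orfs(strrep("TAAGTAAGTAA", 55))), 0L)
})

test_that("scan_protein_motifs matches patterns and the DD35E spacing", {
  lib <- motif_library()
  gagzf <- paste0(rand_protein(10), "CAACAAAAHAAAAC", rand_protein(10))
  hits <- scan_protein_motifs(gagzf, lib)
  expect_true("GAG_ZF" %in% hits$motif)
  expect_equal(hits$position[hits$motif == "GAG_ZF"], 11L)
  trp <- paste0(rand_protein(20), "TRPDI", rand_protein(20))
  expect_true("RH_TRPDI" %in% scan_protein_motifs(trp, lib)$motif)
  # DD35E: exactly 35 residues between the second D and the E
  ok35 <- paste0("LLL", "D", strrep("A", 10), "D", strrep("A", 35), "E", "LLL")
  expect_true("INT_DDE" %in% scan_protein_motifs(ok35, lib)$motif)
  bad34 <- paste0("LLL", "D", strrep("A", 10), "D", strrep("A", 34), "E", "LLL")
  expect_false("INT_DDE" %in% scan_protein_motifs(bad34, lib)$motif)
})

test_that("order_domains and classify_superfamily implement the order rule", {
  hits <- tibble::tibble(domain = c("PR", "INT", "RT", "RH"),
                         position = c(10, 200, 600, 900))
  expect_identical(order_domains(hits), "PR-INT-RT-RH")
  expect_identical(order_domains(hits[0, ]), "")
  expect_identical(order_domains(tibble::tibble(domain = c("RT", "INT"),
                                                position = c(100, 400))), "RT-INT")
  expect_identical(classify_superfamily("PR-INT-RT-RH"), "copia")
  expect_identical(classify_superfamily("PR-RT-RH-INT"), "gypsy")
  expect_identical(classify_superfamily("RT-RH"), "unclassified")
  expect_identical(classify_superfamily("PR-INT-RT-RH", gypsy_evidence = TRUE),
                   "gmr1_gypsy")
})

test_that("annotate_element recovers every planted coordinate at 0% divergence", {
  for (s in c(51, 52, 53)) {
    for (mk in list(blueprint_copia_full, blueprint_gypsy_full, blueprint_gmr1)) {
      el <- make_element(mk(), seed = s)
      ann <- annotate_preset(el)
      tr <- el$truth
      expect_equal(ann$ltr$length, tr$end[1] - tr$start[1] + 1L)
      expect_equal(ann$pbs$position, tr$start[tr$type == "primer_binding_site"])
      expect_equal(ann$ppt$position, tr$start[tr$type == "polypurine_tract"])
      expect_identical(ann$superfamily, el$blueprint$superfamily)
      expect_identical(ann$completeness, "full_length")
    }
  }
  # partial input: RT/RH fragment only
  el <- make_element(blueprint_copia_full(), seed = 54)
  motifs <- truth_of(el, "protein_motif")
  lo <- motifs$start[motifs$label == "RT_KARLVA"] - 30L
  hi <- motifs$start[motifs$label == "RH_TRPDI"] + 60L
  frag_ann <- annotate_element(substr(el$sequence, lo, hi), min_orf_aa = 50L)
  expect_identical(frag_ann$completeness, "partial")
  expect_null(frag_ann$ltr)
})

test_that("superfamily calls survive 2% divergence", {
  for (s in 61:70) {
    mk <- list(blueprint_copia_full, blueprint_gypsy_full,
               blueprint_gmr1)[[(s %% 3) + 1]]
    el <- make_element(mk(), seed = s)
    div <- diversify_family(el$sequence, n_families = 1, copies_per_family = 1,
                            intra_divergence = 0.019, inter_divergence = 0.02,
                            seed = s)
    ann <- annotate_element(div$sequence[1])
    expect_identical(ann$superfamily, el$blueprint$superfamily,
                     info = paste("seed", s))
  }
})

test_that("coordinates round-trip through the 0-based convention", {
  start1 <- 219L; end1 <- 230L
  z <- ltrtrace:::to_zero_based(start1, end1)
  expect_equal(z$start, 218L)
  back <- ltrtrace:::to_one_based(z$start, z$end)
  expect_equal(back$start, start1)
  expect_equal(back$end, end1)
})

test_that("tidy/glance/autoplot summarise an annotation", {
  el <- make_element(blueprint_copia_full(), seed = 15)
  ann <- annotate_element(el$sequence)
  feats <- tidy(ann)
  expect_true(all(c("long_terminal_repeat", "primer_binding_site",
                    "polypurine_tract", "open_reading_frame") %in% feats$type))
  g <- glance(ann)
  expect_equal(g$ltr_length, 217L)
  expect_identical(g$superfamily, "copia")
  p <- autoplot(ann)
  expect_s3_class(p, "ggplot")
  prot <- rt_rh_protein(ann)
  expect_match(prot, "KARLVA")
  expect_match(prot, "TRPDI")
})
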