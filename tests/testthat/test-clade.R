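test_that("local_align_score equals the DP oracle and handles degenerate cases", {
  m <- ltrtrace:::.blosum62_x_neutral()
  # self-alignment of an ungapped word = sum of diagonal scores
  w <- "KARLVA"
  expect_equal(local_align_score(w, w),
               sum(diag(m[strsplit(w, "")[[1]], strsplit(w, "")[[1]]])))
  # disjoint alphabets: empty local alignment, score 0
  expect_equal(local_align_score(strrep("K", 30), strrep("D", 30)), 0)
  # random 50-mers equal the quadratic DP oracle
  for (s in 1:8) {
    withr::with_seed(200 + s, {
      a <- rand_protein(50)
      b <- rand_protein(50)
    })
    expect_equal(local_align_score(a, b), oracle_sw_score(a, b, m),
                 info = paste("seed", s))
  }
  expect_error(local_align_score("KAR*LVA", "KARLVA"),
               class = "ltrtrace_encoding_error")
})

test_that("evalue implements the Karlin-Altschul closed form", {
  ka <- karlin_altschul_params(lambda = 0.267, K = 0.041, search_space = 1e6)
  expect_equal(evalue(100, ka), 0.041 * 1e6 * exp(-0.267 * 100))
  expect_equal(evalue(0, ka), 0.041 * 1e6)
  expect_lt(evalue(5000, ka), 1e-300)
  # monotonicity: higher score, strictly lower E
  scores <- seq(0, 300, by = 25)
  es <- evalue(scores, ka)
  expect_true(all(diff(es) < 0))
  expect_error(karlin_altschul_params(lambda = -1, K = 0.1, search_space = 10))
})

test_that("rank_hits orders by E-value with deterministic ties", {
  lib <- galea_reference_library()
  expect_equal(sum(lib$clade == "GalEa"), 5L)
  expect_gte(sum(lib$clade != "GalEa"), 1L)
  # query equal to a GalEa reference ranks it first
  hits <- rank_hits(lib$sequence[lib$id == "GalEa2"], lib)
  expect_identical(hits$ref_id[1], "GalEa2")
  expect_true(!is.unsorted(hits$e_value))
  # ranking equals oracle recomputation via DP + closed form
  withr::with_seed(33, q <- rand_protein(120))
  hits_q <- rank_hits(q, lib)
  m <- ltrtrace:::.blosum62_x_neutral()
  mn <- nchar(q) * sum(nchar(lib$sequence))
  oracle <- vapply(lib$sequence, function(r) {
    0.041 * mn * exp(-0.267 * oracle_sw_score(q, r, m))
  }, numeric(1))
  expect_equal(hits_q$e_value[match(lib$id, hits_q$ref_id)], unname(oracle))
})

test_that("the GalEa rule truth table covers both boundary failures", {
  mk_hits <- function(e_galea, e_other) {
    tibble::tibble(
      ref_id = c(sprintf("GalEa%d", 1:5), sprintf("O%d", 1:3)),
      clade = c(rep("GalEa", 5), rep("Copia_other", 3)),
      score = 8:1,
      e_value = c(e_galea, e_other)) |>
      dplyr::arrange(e_value)
  }
  # both conditions hold
  call1 <- assign_clade_galea(mk_hits(c(9e-50, 1e-40, 1e-30, 1e-25, 1e-20),
                                      c(1e-3, 1e-2, 1)))
  expect_identical(call1$assigned, "GalEa")
  expect_true(call1$condition_top5 && call1$condition_gap)
  expect_equal(call1$evalue_gap, 1e-3 - 9e-50)
  # a non-GalEa intruder in the top 5 blocks assignment regardless of gap
  call2 <- assign_clade_galea(mk_hits(c(9e-50, 1e-40, 1e-30, 1e-25, 1),
                                      c(1e-28, 2, 3)))
  expect_false(call2$condition_top5)
  expect_identical(call2$assigned, "none")
  # top-5 holds but the gap is below 1e-10: ambiguous
  call3 <- assign_clade_galea(mk_hits(c(9e-50, 1e-45, 1e-42, 1e-41, 1e-40),
                                      c(1e-20, 1e-19, 1e-18)))
  expect_true(call3$condition_top5)
  expect_false(call3$condition_gap)
  expect_identical(call3$assigned, "ambiguous")
  # boundary: gap exactly at the threshold fails the strict inequality
  call4 <- assign_clade_galea(mk_hits(c(0, 1e-45, 1e-42, 1e-41, 1e-40),
                                      c(1e-10, 1e-9, 1e-8)))
  expect_false(call4$condition_gap)
  expect_error(assign_clade_galea(mk_hits(c(1, 2, 3, 4, 5), c(6, 7, 8))[1:5, ]),
               class = "ltrtrace_insufficient_library")
})

test_that("equal-E tie reordering never changes a GalEa assignment", {
  base <- tibble::tibble(
    ref_id = c(sprintf("GalEa%d", 1:5), "O1", "O2", "O3"),
    clade = c(rep("GalEa", 5), rep("Gypsy", 3)),
    score = c(500, 400, 400, 300, 200, 20, 20, 10),
    e_value = c(1e-60, 1e-45, 1e-45, 1e-30, 1e-20, 0.5, 0.5, 2))
  c1 <- assign_clade_galea(base)
  c2 <- assign_clade_galea(base[c(1, 3, 2, 4, 5, 7, 6, 8), ])
  expect_identical(c1$assigned, c2$assigned)
  expect_identical(c1$assigned, "GalEa")
})

test_that("a generated Copia element is assigned to GalEa end-to-end", {
  el <- make_element(blueprint_copia_full(), seed = 71)
  ann <- annotate_element(el$sequence)
  q <- rt_rh_protein(ann)
  hits <- rank_hits(q, galea_reference_library())
  call <- assign_clade_galea(hits)
  expect_identical(call$assigned, "GalEa")
  # a Gypsy element is not
  elg <- make_element(blueprint_gypsy_full(), seed = 71)
  anng <- annotate_element(elg$sequence)
  callg <- assign_clade_galea(rank_hits(rt_rh_protein(anng),
                                        galea_reference_library()))
  expect_identical(callg$assigned, "none")
})
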