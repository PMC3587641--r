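test_that("trim_alignment removes gappy and saturated columns", {
  same <- setNames(rep(strrep("ACDEFGHIKL", 5), 4), paste0("t", 1:4))
  tr <- trim_alignment(same)
  expect_equal(tr$kept, 1:50)
  # a 100%-gap column is removed
  rows <- c(a = "AAAA-AAAA", b = "AAAA-AAAA", c = "AAAA-AAAA")
  tr2 <- trim_alignment(rows)
  expect_false(5L %in% tr2$kept)
  expect_equal(nchar(tr2$alignment[[1]]), 8L)
  # a planted high-entropy block is exactly what goes (hand entropy oracle)
  withr::with_seed(21, {
    conserved <- strrep("K", 30)
    rows3 <- vapply(1:10, function(i) {
      noisy <- rand_protein(10)
      paste0(substr(conserved, 1, 15), noisy, substr(conserved, 16, 30))
    }, character(1))
    names(rows3) <- paste0("s", 1:10)
  })
  tr3 <- trim_alignment(rows3, entropy_cutoff = 0.3, window = 1L)
  # hand-computed per-column entropy decides membership
  for (j in c(1, 15, 16, 25, 26, 40)) {
    col <- substr(rows3, j, j)
    p <- table(col) / 10
    h <- -sum(p * log(p)) / log(20)
    expect_equal(j %in% tr3$kept, h <= 0.3, info = paste("column", j))
  }
  expect_error(trim_alignment(rows3, entropy_cutoff = -1),
               class = "ltrtrace_empty_alignment")
})

test_that("JTT distances behave in the small-divergence limit and match phangorn", {
  pair <- c(a = strrep("ACDEFGHIKLMNPQRSTVWY", 10),
            b = strrep("ACDEFGHIKLMNPQRSTVWY", 10))
  expect_equal(unname(jtt_gamma_distance(pair)["a", "b"]), 0)
  # ~1% p-distance: JTT distance within 10% of p
  withr::with_seed(22, {
    x <- strsplit(strrep("ACDEFGHIKLMNPQRSTVWY", 10), "")[[1]]
    y <- x
    idx <- sample(200, 2)
    for (i in idx) y[i] <- sample(setdiff(LETTERS[LETTERS %in% x], y[i]), 1)
  })
  d01 <- jtt_gamma_distance(c(a = paste(x, collapse = ""),
                              b = paste(y, collapse = "")), gamma = FALSE)["a", "b"]
  expect_lt(abs(d01 - 0.01) / 0.01, 0.10)
  # agreement with an independent implementation (no gamma)
  withr::with_seed(23, {
    t2 <- ape::read.tree(text = "(a:0.2,b:0.2);")
    sim <- phangorn::simSeq(t2, l = 1000, type = "AA", model = "JTT")
  })
  rows <- apply(as.character(sim), 1, paste, collapse = "")
  mine <- jtt_gamma_distance(rows, gamma = FALSE)["a", "b"]
  ref <- as.matrix(phangorn::dist.ml(sim, model = "JTT"))["a", "b"]
  expect_lt(abs(mine - ref), 0.01)
})

test_that("JTT+Gamma recovers simulated distances within 3 SE", {
  # phangorn::simSeq is the independent sampler; discrete-gamma site rates
  rates <- ltrtrace:::.gamma_rates(1.0, 4L)
  d_true <- 0.3
  est <- vapply(1:8, function(r) {
    sim <- withr::with_seed(300 + r, {
      per_cat <- lapply(rates, function(rr) {
        t2 <- ape::read.tree(text = sprintf("(a:%f,b:%f);", d_true * rr / 2,
                                            d_true * rr / 2))
        as.character(phangorn::simSeq(t2, l = 500, type = "AA", model = "JTT"))
      })
      do.call(cbind, per_cat)
    })
    rows <- apply(sim, 1, paste, collapse = "")
    jtt_gamma_distance(rows, alpha = 1.0)["a", "b"]
  }, numeric(1))
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - d_true), 3 * se + 1e-8)
})

test_that("JTT+Gamma distance never undershoots the p-distance", {
  withr::with_seed(24, {
    t4 <- ape::rtree(4, br = function(n) runif(n, 0.05, 0.4))
    sim <- as.character(phangorn::simSeq(t4, l = 400, type = "AA", model = "JTT"))
  })
  rows <- apply(sim, 1, paste, collapse = "")
  dj <- jtt_gamma_distance(rows)
  dp <- pairwise_p_distance(rows)
  expect_true(all(dj >= dp - 1e-9))
})

test_that("neighbor joining matches the 3-taxon closed form to 1e-12", {
  d <- matrix(c(0, 0.3, 0.5, 0.3, 0, 0.6, 0.5, 0.6, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(d)
  b <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(b["a"]), (0.3 + 0.5 - 0.6) / 2, tolerance = 1e-12)
  expect_equal(unname(b["b"]), (0.3 + 0.6 - 0.5) / 2, tolerance = 1e-12)
  expect_equal(unname(b["c"]), (0.5 + 0.6 - 0.3) / 2, tolerance = 1e-12)
})

test_that("NJ recovers additive matrices exactly (topology and lengths)", {
  for (s in 1:25) {
    withr::with_seed(400 + s, {
      n <- sample(4:8, 1)
      t0 <- ape::rtree(n, br = function(k) runif(k, 0.05, 0.5))
    })
    t0 <- ape::unroot(t0)
    d <- cophenetic(t0)
    tr <- neighbor_joining(d)
    expect_equal(as.numeric(ape::dist.topo(tr, t0)), 0,
                 info = paste("seed", s))
    # path distances reproduce the input matrix exactly
    dd <- cophenetic(tr)[rownames(d), colnames(d)]
    expect_equal(dd, d, tolerance = 1e-10)
    # cross-check against the reference NJ implementation
    ref <- ape::nj(d)
    expect_equal(as.numeric(ape::dist.topo(tr, ref)), 0)
  }
})

test_that("equidistant taxa give a zero-length internal branch and clamping works", {
  ids <- letters[1:4]
  d <- matrix(0.4, 4, 4, dimnames = list(ids, ids)); diag(d) <- 0
  tr <- neighbor_joining(d)
  internal <- tr$edge.length[tr$edge[, 2] > 4]
  expect_true(all(abs(internal) < 1e-12))
  expect_true(all(tr$edge.length >= 0))
  bad <- d; bad[1, 2] <- 0.9
  expect_error(neighbor_joining(bad), "symmetric")
})

test_that("bootstrap gives full support to a clean split and is seed-stable", {
  withr::with_seed(25, {
    blockA <- rand_protein(120)
    blockB <- rand_protein(120)
  })
  aln <- c(a1 = blockA, a2 = blockA,
           b1 = blockB, b2 = blockB)
  st <- bootstrap_support(aln, n_reps = 30, seed = 5)
  expect_true(any(st$supports == 100))
  st2 <- bootstrap_support(aln, n_reps = 30, seed = 5)
  expect_identical(st$supports, st2$supports)
  # leaf-order permutation leaves supports invariant
  st3 <- bootstrap_support(aln[c(3, 1, 4, 2)], n_reps = 30, seed = 5)
  expect_identical(sort(st$supports), sort(st3$supports))
  td <- tidy(st)
  expect_true(all(c("parent", "child", "length", "support") %in% names(td)))
})

test_that("no-signal alignments rarely reach high support", {
  high <- 0L
  for (s in 1:5) {
    withr::with_seed(500 + s, {
      aln <- setNames(vapply(1:5, function(i) rand_protein(80), character(1)),
                      paste0("t", 1:5))
    })
    st <- bootstrap_support(aln, n_reps = 40, seed = s)
    if (any(st$supports[-1] >= 70)) high <- high + 1L
  }
  expect_lte(high, 1L)
})
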