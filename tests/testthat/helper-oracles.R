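# Independent oracles used by the tests. These deliberately avoid the code
# paths they check: naive scans, exhaustive enumeration, textbook DP.

IUPAC_ORACLE <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
            R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
            B = "V", V = "B", D = "H", H = "D")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

# brute-force enumeration of all expansions of a degenerate primer
oracle_expansions <- function(iupac) {
  sets <- IUPAC_ORACLE[strsplit(iupac, "")[[1]]]
  out <- ""
  for (s in sets) out <- as.vector(outer(out, s, paste0))
  out
}

# naive O(n*m) sliding-window primer scan on one strand
oracle_scan_strand <- function(seq, iupac, max_mm) {
  sc <- strsplit(seq, "")[[1]]
  pc <- strsplit(iupac, "")[[1]]
  m <- length(pc)
  hits <- list()
  for (p in seq_len(length(sc) - m + 1L)) {
    mm <- 0L
    for (q in seq_len(m)) {
      base <- sc[p + q - 1L]
      ok <- base == "N" || base %in% IUPAC_ORACLE[[pc[q]]]
      if (!ok) mm <- mm + 1L
      if (mm > max_mm) break
    }
    if (mm <= max_mm) hits[[length(hits) + 1L]] <- c(start = p, mismatches = mm)
  }
  if (!length(hits)) return(data.frame(start = integer(0), mismatches = integer(0)))
  as.data.frame(do.call(rbind, hits))
}

# hand p-distance with pairwise deletion
oracle_p_distance <- function(a, b) {
  ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
  ok <- !(ac %in% c("-", ".")) & !(bc %in% c("-", "."))
  sum(ac[ok] != bc[ok]) / sum(ok)
}

# all set partitions of 1..n (restricted growth strings), memoised per n
.partition_cache <- new.env()
oracle_set_partitions <- function(n) {
  key <- as.character(n)
  if (!is.null(.partition_cache[[key]])) return(.partition_cache[[key]])
  out <- list()
  rec <- function(assign, k) {
    i <- length(assign) + 1L
    if (i > n) { out[[length(out) + 1L]] <<- assign; return(invisible()) }
    for (g in seq_len(k + 1L)) rec(c(assign, g), max(k, g))
  }
  rec(integer(0), 0L)
  .partition_cache[[key]] <- out
  out
}

# does a partition satisfy the non-overlap family criterion? (all singletons:
# vacuously yes; a single family only when its members are identical)
oracle_criterion_ok <- function(d, groups) {
  same <- outer(groups, groups, "==")
  ut <- upper.tri(d)
  intra <- d[ut & same]
  inter <- d[ut & !same]
  if (!length(intra)) return(TRUE)
  if (!length(inter)) return(max(intra) == 0)
  max(intra) < min(inter)
}

# minimum family count over all criterion-satisfying partitions (n <= 8)
oracle_min_families <- function(d) {
  n <- nrow(d)
  parts <- oracle_set_partitions(n)
  best <- n
  for (p in parts) {
    k <- max(p)
    if (k < best && oracle_criterion_ok(d, p)) best <- k
  }
  best
}

# textbook affine-gap Smith-Waterman (floored at 0)
oracle_sw_score <- function(a, b, mat, gap_open = 11, gap_extend = 1) {
  ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
  n <- length(ac); m <- length(bc)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in b (deletion)
  Y <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- mat[ac[i - 1], bc[j - 1]]
      M[i, j] <- max(0, s + max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]))
      X[i, j] <- max(M[i - 1, j] - gap_open - gap_extend, X[i - 1, j] - gap_extend)
      Y[i, j] <- max(M[i, j - 1] - gap_open - gap_extend, Y[i, j - 1] - gap_extend)
      best <- max(best, M[i, j])
    }
  }
  best
}

# random protein / dna helpers for tests
rand_protein <- function(n) {
  paste(sample(c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
                 "P","S","T","W","Y","V"), n, replace = TRUE), collapse = "")
}
rand_dna <- function(n) paste(sample(c("A","C","G","T"), n, replace = TRUE),
                              collapse = "")

# annotate a preset element with windows wide enough for its offsets
annotate_preset <- function(el) {
  bp <- el$blueprint
  args <- list(seq = el$sequence)
  if (bp$pbs_offset > 10L) args$pbs_window <- bp$pbs_offset + 15L
  if (bp$ppt_offset > 20L) args$ppt_window <- bp$ppt_offset + 40L
  do.call(annotate_element, args)
}

truth_of <- function(el, type) el$truth[el$truth$type == type, , drop = FALSE]
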