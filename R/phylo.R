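# Distance phylogenetics: alignment trimming, pairwise maximum-likelihood
# distances under the JTT amino-acid replacement model with discrete-gamma
# rate heterogeneity, Saitou-Nei neighbor joining with deterministic
# tie-breaking and negative-branch clamping, and nonparametric bootstrap
# supports. The JTT rates and frequencies are read from phangorn (the
# published Jones-Taylor-Thornton 1992 matrix); the ML optimiser here is
# independent of phangorn's.

# ---- alignment utilities -----------------------------------------------------

.aln_matrix <- function(aln) {
  lens <- nchar(aln)
  if (length(unique(lens)) != 1L) abort("alignment rows must have equal length")
  ids <- names(aln) %||% sprintf("seq%d", seq_along(aln))
  m <- do.call(rbind, lapply(aln, function(s) seq_chars(toupper(s))))
  rownames(m) <- ids
  m
}

#' Trim ambiguously aligned columns
#'
#' Removes columns whose smoothed Shannon entropy (normalised to \[0, 1\] by
#' log 20, gaps excluded from the frequencies) exceeds `entropy_cutoff`, or
#' whose gap fraction exceeds `gap_cutoff`. Entropy is smoothed by a moving
#' average of width `window`. A documented simplification of block-mapping
#' trimmers: a per-column entropy/gap filter keeps the same intent
#' (drop saturated or gappy sites before distance estimation).
#'
#' @param aln Named character vector of aligned protein rows.
#' @param entropy_cutoff Maximum smoothed normalised entropy.
#' @param gap_cutoff Maximum gap fraction.
#' @param window Smoothing window (columns).
#' @return Object of class `trimmed_alignment`: `$alignment` (trimmed rows),
#'   `$kept` (column indices), `$score` (per-column smoothed entropy).
#' @export
trim_alignment <- function(aln, entropy_cutoff = 0.5, gap_cutoff = 0.2,
                           window = 3L) {
  m <- .aln_matrix(aln)
  nc <- ncol(m)
  ent <- numeric(nc)
  gapf <- numeric(nc)
  for (j in seq_len(nc)) {
    col <- m[, j]
    gap <- col %in% c("-", ".", "X")
    gapf[j] <- mean(gap)
    res <- col[!gap]
    if (!length(res)) { ent[j] <- 1; next }
    p <- table(res) / length(res)
    ent[j] <- -sum(p * log(p)) / log(20)
  }
  half <- (window - 1L) %/% 2L
  sm <- vapply(seq_len(nc), function(j) {
    mean(ent[max(1L, j - half):min(nc, j + half)])
  }, numeric(1))
  kept <- which(sm <= entropy_cutoff & gapf <= gap_cutoff)
  if (!length(kept)) abort("all columns removed", class = "ltrtrace_empty_alignment")
  trimmed <- apply(m[, kept, drop = FALSE], 1L, paste0, collapse = "")
  structure(list(alignment = setNames(trimmed, rownames(m)), kept = kept,
                 score = sm), class = "trimmed_alignment")
}

# ---- JTT + gamma model -------------------------------------------------------

# order of residues used by the phangorn JTT tables
.JTT_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                "M", "F", "P", "S", "T", "W", "Y", "V")

.jtt_cache <- new.env(parent = emptyenv())

.jtt_model <- function() {
  if (!is.null(.jtt_cache$model)) return(.jtt_cache$model)
  jtt <- get(".JTT", envir = asNamespace("phangorn"))
  bf <- unname(jtt$bf)
  S <- matrix(0, 20, 20)
  S[lower.tri(S)] <- jtt$Q
  S <- S + t(S)
  R <- S %*% diag(bf)
  diag(R) <- -rowSums(R)
  mu <- -sum(bf * diag(R))
  R <- R / mu
  # symmetric eigen-decomposition for stable P(t)
  D2 <- diag(sqrt(bf))
  D2i <- diag(1 / sqrt(bf))
  B <- D2 %*% R %*% D2i
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  model <- list(bf = bf, R = R,
                U = D2i %*% eig$vectors, Uinv = t(eig$vectors) %*% D2,
                lambda = eig$values)
  dimnames(model$R) <- list(.JTT_ORDER, .JTT_ORDER)
  .jtt_cache$model <- model
  model
}

.jtt_P <- function(t) {
  m <- .jtt_model()
  P <- m$U %*% diag(exp(m$lambda * t)) %*% m$Uinv
  P[P < 0] <- 0
  P
}

# discrete gamma category rates (means of quantile bins)
.gamma_rates <- function(alpha, k = 4L) {
  if (k == 1L) return(1)
  q <- qgamma(seq_len(k - 1L) / k, shape = alpha, rate = alpha)
  bounds <- c(0, q, Inf)
  k * (pgamma(bounds[-1L] * alpha, shape = alpha + 1, rate = 1) -
         pgamma(bounds[-(k + 1L)] * alpha, shape = alpha + 1, rate = 1))
}

# pair count matrix over comparable (ungapped, standard-residue) sites
.pair_counts <- function(x, y) {
  ok <- x %in% .JTT_ORDER & y %in% .JTT_ORDER
  if (!any(ok)) return(NULL)
  ix <- match(x[ok], .JTT_ORDER)
  iy <- match(y[ok], .JTT_ORDER)
  N <- matrix(0, 20, 20)
  for (s in seq_along(ix)) N[ix[s], iy[s]] <- N[ix[s], iy[s]] + 1
  N
}

.ml_distance <- function(N, rates) {
  m <- .jtt_model()
  if (sum(N * (1 - diag(20))) == 0) return(0)
  nll <- function(d) {
    M <- matrix(0, 20, 20)
    for (r in rates) M <- M + .jtt_P(d * r) / length(rates)
    L <- diag(m$bf) %*% M
    L[L < 1e-300] <- 1e-300
    -sum(N * log(L))
  }
  optimize(nll, c(1e-6, 10), tol = 1e-6)$minimum
}

#' Pairwise JTT(+Gamma) maximum-likelihood distances
#'
#' Per-pair ML distance under the JTT replacement matrix, with
#' gamma-distributed rate heterogeneity handled by `k` discrete categories
#' (means of quantile bins), pairwise deletion of gapped sites, bounded
#' scalar optimisation on \[1e-6, 10\] (tolerance 1e-6). Identical pairs get
#' distance 0.
#'
#' @param aln Named character vector of aligned protein rows.
#' @param alpha Gamma shape (> 0); the default 1.0 is a documented choice.
#' @param k Number of discrete rate categories.
#' @param gamma Set `FALSE` to disable rate heterogeneity.
#' @return Symmetric distance matrix (substitutions/site).
#' @export
jtt_gamma_distance <- function(aln, alpha = 1.0, k = 4L, gamma = TRUE) {
  if (alpha <= 0) abort("alpha must be positive")
  m <- .aln_matrix(aln)
  n <- nrow(m)
  if (n < 2L) abort("need at least 2 sequences")
  rates <- if (gamma) .gamma_rates(alpha, k) else 1
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      N <- .pair_counts(m[i, ], m[j, ])
      if (is.null(N)) {
        abort(sprintf("no comparable sites between '%s' and '%s'",
                      rownames(m)[i], rownames(m)[j]),
              class = "ltrtrace_undefined_distance")
      }
      d[i, j] <- d[j, i] <- .ml_distance(N, rates)
    }
  }
  d
}

# ---- neighbor joining --------------------------------------------------------

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration with deterministic tie-breaking (smallest label
#' pair) and negative branch lengths clamped to zero, the deficit moved to
#' the sister branch so path lengths are preserved.
#'
#' @param d Symmetric distance matrix with labelled rows/columns.
#' @return An unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(d) {
  if (!isSymmetric(unname(d), tol = 1e-8)) abort("distance matrix must be symmetric")
  labels <- rownames(d)
  n <- length(labels)
  if (n < 3L) abort("need at least 3 taxa")
  D <- d
  # active nodes: negative = leaf index, positive = internal node id
  node_ids <- -seq_len(n)
  next_internal <- 1L
  edges <- list() # list(parent internal id, child id, length)
  repeat {
    nn <- nrow(D)
    if (nn == 2L) break
    r <- rowSums(D)
    Q <- (nn - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin < 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pair_lab <- cbind(rownames(D)[cand[, 1]], rownames(D)[cand[, 2]])
    ord <- order(pmin(pair_lab[, 1], pair_lab[, 2]),
                 pmax(pair_lab[, 1], pair_lab[, 2]))
    i <- cand[ord[1], 1]; j <- cand[ord[1], 2]
    bi <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (nn - 2))
    bj <- D[i, j] - bi
    # clamp negatives, transfer the deficit to the sister branch
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    new_id <- next_internal
    next_internal <- next_internal + 1L
    edges[[length(edges) + 1L]] <- list(new_id, node_ids[i], bi)
    edges[[length(edges) + 1L]] <- list(new_id, node_ids[j], bj)
    du <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(nn), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]), c(du[keep], 0))
    lab2 <- c(rownames(D)[keep], paste0("&node", new_id))
    dimnames(D2) <- list(lab2, lab2)
    node_ids <- c(node_ids[keep], new_id)
    D <- D2
  }
  # join the last two nodes with a single edge
  root_id <- next_internal
  b <- max(D[1, 2], 0)
  if (node_ids[1] > 0) {
    # attach the remaining branch between the two last nodes via the root
    edges[[length(edges) + 1L]] <- list(node_ids[1], node_ids[2], b)
    root_internal <- node_ids[1]
  } else if (node_ids[2] > 0) {
    edges[[length(edges) + 1L]] <- list(node_ids[2], node_ids[1], b)
    root_internal <- node_ids[2]
  } else {
    abort("degenerate matrix")
  }
  n_internal <- next_internal - 1L
  # build ape phylo: tips 1..n; internals renumbered n+1.. from the root
  # downwards (ape requires the root to be node n+1)
  parents <- vapply(edges, function(e) e[[1]], numeric(1))
  children <- vapply(edges, function(e) e[[2]], numeric(1))
  root_old <- setdiff(unique(parents), children[children > 0])
  new_num <- integer(n_internal)
  new_num[root_old] <- n + 1L
  queue <- root_old
  nxt <- n + 2L
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    kids <- children[parents == cur & children > 0]
    for (k in kids) {
      new_num[k] <- nxt
      nxt <- nxt + 1L
      queue <- c(queue, k)
    }
  }
  remap <- function(id) if (id < 0) -id else new_num[id]
  em <- do.call(rbind, lapply(edges, function(e) {
    c(remap(e[[1]]), remap(e[[2]]))
  }))
  storage.mode(em) <- "integer"
  lens <- vapply(edges, function(e) e[[3]], numeric(1))
  tr <- list(edge = em, edge.length = lens, tip.label = labels,
             Nnode = n_internal)
  class(tr) <- "phylo"
  tr <- ape::reorder.phylo(tr, "cladewise")
  ape::unroot(tr)
}

# ---- bootstrap ---------------------------------------------------------------

#' Bootstrap supports for the JTT+Gamma neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds each replicate
#' tree with [jtt_gamma_distance()] + [neighbor_joining()], and reports the
#' percentage of replicates containing each internal bipartition of the
#' point-estimate tree (stored as node labels). Replicates with undefined
#' distances are dropped with a warning and counted.
#'
#' @param aln Named character vector of aligned protein rows (>= 3).
#' @param n_reps Bootstrap replicates (default 100).
#' @param alpha Gamma shape.
#' @param seed Integer seed.
#' @param gamma Disable rate heterogeneity with `FALSE`.
#' @return Object of class `supported_tree`: `$tree` (point-estimate
#'   `phylo` with supports in `node.label`), `$supports` (numeric),
#'   `$n_reps`, `$n_dropped`.
#' @export
bootstrap_support <- function(aln, n_reps = 100L, alpha = 1.0, seed = 1L,
                              gamma = TRUE) {
  if (n_reps < 1L) abort("n_reps must be >= 1")
  m <- .aln_matrix(aln)
  point <- neighbor_joining(jtt_gamma_distance(aln, alpha, gamma = gamma))
  reps <- list()
  n_dropped <- 0L
  with_seed(seed, {
    for (b in seq_len(n_reps)) {
      cols <- sample.int(ncol(m), replace = TRUE)
      rows <- apply(m[, cols, drop = FALSE], 1L, paste0, collapse = "")
      tr <- tryCatch(
        neighbor_joining(jtt_gamma_distance(setNames(rows, rownames(m)),
                                            alpha, gamma = gamma)),
        ltrtrace_undefined_distance = function(e) NULL)
      if (is.null(tr)) {
        n_dropped <- n_dropped + 1L
        warn(sprintf("bootstrap replicate %d dropped (undefined distance)", b))
      } else {
        reps[[length(reps) + 1L]] <- tr
      }
    }
  })
  counts <- ape::prop.clades(point, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  supports <- round(100 * counts / max(1L, length(reps)))
  tree <- point
  tree$node.label <- as.character(supports)
  structure(list(tree = tree, supports = supports, n_reps = n_reps,
                 n_dropped = n_dropped), class = "supported_tree")
}

#' @export
print.supported_tree <- function(x, ...) {
  cat(sprintf("<supported_tree> %d tips, %d bootstrap replicates (%d dropped)\n",
              length(x$tree$tip.label), x$n_reps, x$n_dropped))
  invisible(x)
}
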