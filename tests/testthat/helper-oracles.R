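# Independent reference implementations used as oracles. These are written
# deliberately naively (loops, exhaustive enumeration) and must stay
# independent of the package code paths they check.

# Brute-force cohesion and per-gene pair sums via an explicit double loop.
brute_cohesion <- function(W, group) {
  W <- as.matrix(W)[, group, drop = FALSE]
  m <- ncol(W)
  per_gene <- rep(0, nrow(W))
  names(per_gene) <- rownames(W)
  total <- 0
  npairs <- 0L
  for (i in seq_len(m - 1)) {
    for (j in seq(i + 1, m)) {
      prod_ij <- W[, i] * W[, j]
      per_gene <- per_gene + prod_ij
      total <- total + sum(prod_ij)
      npairs <- npairs + 1L
    }
  }
  list(
    score = total / npairs,
    contributions = 100 * (per_gene / npairs) / (total / npairs)
  )
}

# Exhaustive permutation P: enumerate every size-m subset of the universe.
exhaustive_pvalue <- function(W, group) {
  W <- as.matrix(W)
  ids <- colnames(W)
  m <- length(group)
  subsets <- utils::combn(ids, m, simplify = FALSE)
  observed <- brute_cohesion(W, group)$score
  hits <- vapply(subsets, function(s) {
    brute_cohesion(W, s)$score >= observed - 1e-12
  }, logical(1))
  mean(hits)
}

# Naive O(n^3) UPGMA: average distance between clusters, smallest first,
# lexicographic tie-break on member names. Returns merge heights and the
# leaf partition at each merge.
naive_upgma <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(rownames(d))
  heights <- numeric(0)
  merges <- list()
  while (length(clusters) > 1) {
    best <- NULL
    best_h <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best_h - 1e-12) {
          best <- c(i, j); best_h <- h
        }
      }
    }
    heights <- c(heights, best_h)
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    merges[[length(merges) + 1L]] <- merged
    clusters[[best[1]]] <- merged
    clusters[[best[2]]] <- NULL
  }
  list(heights = heights, merges = merges)
}

# Orthogonal Procrustes RMS after centring: how far Y is from X up to
# rotation/reflection/translation.
procrustes_rms <- function(X, Y) {
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  s <- svd(crossprod(Yc, Xc))
  R <- s$u %*% t(s$v)
  sqrt(mean((Yc %*% R - Xc)^2))
}

# Two-pass reference filter: count per-reference support, then keep edges
# with at least one reference at or under the cap.
brute_reference_filter <- function(edges, max_links) {
  support <- list()
  for (i in seq_len(nrow(edges)))
    for (r in unique(edges$refs[[i]]))
      support[[r]] <- (if (is.null(support[[r]])) 0L else support[[r]]) + 1L
  keep <- logical(nrow(edges))
  for (i in seq_len(nrow(edges)))
    keep[i] <- any(vapply(edges$refs[[i]], function(r) support[[r]] <= max_links,
                          logical(1)))
  keep
}

# Random unit-normalised non-negative sparse profile matrix.
random_profile_matrix <- function(n_genes, n_concepts, seed,
                                  density = 0.4) {
  set.seed(seed)
  W <- matrix(stats::runif(n_genes * n_concepts), n_genes, n_concepts)
  W[matrix(stats::runif(n_genes * n_concepts) > density,
           n_genes, n_concepts)] <- 0
  # ensure no all-zero column
  for (j in seq_len(n_concepts))
    if (all(W[, j] == 0)) W[sample(n_genes, 1), j] <- stats::runif(1)
  dimnames(W) <- list(sprintf("g%03d", seq_len(n_genes)),
                      sprintf("c%02d", seq_len(n_concepts)))
  sweep(W, 2, sqrt(colSums(W^2)), "/")
}

# Random referenced edge table with a mix of private and shared references.
random_edge_table <- function(seed, n_edges = 60, n_nodes = 25, n_refs = 20) {
  set.seed(seed)
  a <- sprintf("N%02d", sample(n_nodes, n_edges, replace = TRUE))
  b <- sprintf("N%02d", sample(n_nodes, n_edges, replace = TRUE))
  ok <- a != b
  a <- a[ok]; b <- b[ok]
  refs <- lapply(seq_along(a), function(i)
    sprintf("r%02d", sample(n_refs, sample(1:3, 1))))
  referenced_edges(a, b, refs, source = "rnd")
}
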