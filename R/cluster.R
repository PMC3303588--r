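# Exploration of the profile similarity structure: agglomerative clustering
# on the distance d = 1 - similarity, and a classical (Torgerson) metric MDS
# projection onto the plane. Both are deterministic; ties in the clustering
# are broken by lexicographic concept id order.

check_similarity <- function(sim) {
  if (!is.matrix(sim) || nrow(sim) != ncol(sim))
    stop("similarity must be a square matrix")
  if (is.null(rownames(sim)) || !identical(rownames(sim), colnames(sim)))
    stop("similarity matrix must carry matching concept id dimnames")
  if (max(abs(sim - t(sim))) > 1e-8)
    stop("similarity matrix is not symmetric")
  if (max(abs(diag(sim) - 1)) > 1e-9)
    stop("similarity diagonal must be 1")
  invisible(sim)
}

#' Hierarchical clustering of concept similarities
#'
#' Agglomerative clustering of the distance `1 - similarity`, with average
#' linkage (UPGMA) by default. Concepts are ordered lexicographically before
#' clustering so tied merges resolve deterministically.
#'
#' @param sim square symmetric similarity matrix with unit diagonal and
#'   concept ids as dimnames (see [similarity_matrix()]).
#' @param linkage agglomeration rule.
#' @return An [stats::hclust] tree; merge heights are non-decreasing.
#' @export
hierarchical_cluster <- function(sim,
                                 linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  check_similarity(sim)
  ord <- order(rownames(sim))
  sim <- sim[ord, ord]
  hclust(as.dist(1 - sim), method = linkage)
}

#' Newick export of a cluster tree
#'
#' Serialises an [stats::hclust] tree as a Newick string. Branch lengths are
#' derived from the merge heights (each leaf sits at depth merge-height / 2
#' below its parent, the usual ultrametric convention).
#'
#' @param hc an [stats::hclust] object.
#' @return A single Newick string.
#' @export
dendrogram_newick <- function(hc) {
  stopifnot(inherits(hc, "hclust"))
  ape::write.tree(ape::as.phylo(hc))
}

#' Project concepts onto the plane
#'
#' Classical (Torgerson) metric multidimensional scaling of the distances
#' `1 - similarity`: the double-centred squared-distance matrix is
#' eigendecomposed and the top two eigencoordinates retained. Coordinates are
#' defined only up to rotation, reflection and translation.
#'
#' @param sim similarity matrix as for [hierarchical_cluster()].
#' @return Numeric matrix (concepts x 2, columns `x`, `y`) with attributes
#'   `eig` (all eigenvalues; negative ones flag non-Euclidean distances) and
#'   `stress` (relative residual between input and embedded distances).
#' @export
project_2d <- function(sim) {
  check_similarity(sim)
  d <- 1 - sim
  n <- nrow(sim)
  ids <- rownames(sim)
  if (all(d == 0)) {
    warning("all concepts are identical; projecting every point to the origin",
            call. = FALSE)
    out <- matrix(0, n, 2, dimnames = list(ids, c("x", "y")))
    attr(out, "eig") <- rep(0, n)
    attr(out, "stress") <- 0
    return(out)
  }
  k <- min(2L, n - 1L)
  mds <- cmdscale(as.dist(d), k = k, eig = TRUE)
  pts <- mds$points
  if (ncol(pts) < 2L)
    pts <- cbind(pts, matrix(0, n, 2L - ncol(pts)))
  dimnames(pts) <- list(ids, c("x", "y"))
  neg <- sum(mds$eig < -1e-9)
  if (neg > 0)
    message(sprintf("projection: %d negative eigenvalue(s); distances are not exactly planar", neg))
  dhat <- as.matrix(stats::dist(pts))
  attr(pts, "eig") <- mds$eig
  attr(pts, "stress") <- sqrt(sum((d - dhat)^2) / sum(d^2))
  pts
}

#' Write a similarity matrix to TSV
#'
#' Square matrix with a concept-id header row and column.
#'
#' @param sim similarity matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_similarity <- function(sim, path) {
  check_similarity(sim)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("concept_id", colnames(sim)), collapse = "\t"), con)
  for (i in seq_len(nrow(sim)))
    writeLines(paste(c(rownames(sim)[i], sprintf("%.12g", sim[i, ])),
                     collapse = "\t"), con)
  invisible(path)
}

#' Write a 2-D projection to TSV
#' @param pts matrix returned by [project_2d()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_projection <- function(pts, path) {
  stopifnot(is.matrix(pts), ncol(pts) == 2L, !is.null(rownames(pts)))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("concept_id\tx\ty", con)
  writeLines(sprintf("%s\t%.12g\t%.12g", rownames(pts), pts[, 1], pts[, 2]),
             con)
  invisible(path)
}
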