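#' Matching score between two profiles
#'
#' The inner product of two unit-normalised non-negative profiles; lies in
#' `[0, 1]`, reaching 1 only for identical profiles and 0 for disjoint
#' support.
#'
#' @param p1,p2 `concept_profile` objects (see [build_profile()]) sharing a
#'   gene vocabulary.
#' @return Numeric score in `[0, 1]`.
#' @export
matching_score <- function(p1, p2) {
  stopifnot(inherits(p1, "concept_profile"), inherits(p2, "concept_profile"))
  if (p1$degenerate || p2$degenerate)
    stop("cannot match a degenerate profile")
  shared <- intersect(names(p1$weights), names(p2$weights))
  min(1, sum(p1$weights[shared] * p2$weights[shared]))
}

#' Pairwise similarity matrix of a profile set
#'
#' All pairwise matching scores (inner products of the unit profiles).
#' Symmetric, unit diagonal, off-diagonals in `[0, 1]`.
#'
#' @param pset a [profile_set()].
#' @return Square numeric matrix with concept ids as dimnames.
#' @export
similarity_matrix <- function(pset) {
  stopifnot(inherits(pset, "profile_set"))
  s <- as.matrix(crossprod(pset$W))
  s <- pmin(pmax(s, 0), 1)
  s <- (s + t(s)) / 2
  diag(s) <- 1
  s
}

# Mean of the upper triangle of a similarity submatrix.
mean_pairwise <- function(s) {
  mean(s[upper.tri(s)])
}

#' Cohesion score of a concept group
#'
#' The average of the inner products over all pairs of profiles in the group;
#' 1 for identical profiles, 0 for pairwise-orthogonal ones.
#'
#' @param pset a [profile_set()] holding the group (and possibly more).
#' @param group concept ids of the group (default: all profiles in `pset`);
#'   at least two.
#' @return Numeric score in `[0, 1]`.
#' @export
cohesion_score <- function(pset, group = NULL) {
  stopifnot(inherits(pset, "profile_set"))
  if (is.null(group)) group <- pset$concepts
  if (length(group) < 2L)
    stop("cohesion requires a group of at least 2 profiles")
  sub <- subset_profiles(pset, group)
  mean_pairwise(similarity_matrix(sub))
}

#' Per-gene contribution percentages to a cohesion score
#'
#' Each gene's share of the group's cohesion: the mean over profile pairs of
#' the product of that gene's weights, expressed as a percentage of the
#' cohesion score. Contributions are non-negative and sum to 100 whenever the
#' cohesion score is positive.
#'
#' @inheritParams cohesion_score
#' @return Named numeric vector over the full gene vocabulary, in percent.
#' @export
gene_contributions <- function(pset, group = NULL) {
  stopifnot(inherits(pset, "profile_set"))
  if (is.null(group)) group <- pset$concepts
  if (length(group) < 2L)
    stop("contributions require a group of at least 2 profiles")
  W <- as.matrix(subset_profiles(pset, group)$W)
  # sum over pairs i<j of w_i(g) w_j(g) == (rowsum^2 - rowsum of squares)/2
  per_gene <- (rowSums(W)^2 - rowSums(W^2)) / 2
  total <- sum(per_gene)
  if (total <= 0)
    stop("zero cohesion: contributions are undefined")
  setNames(100 * per_gene / total, rownames(W))
}

#' Permutation P-value for a group's cohesion
#'
#' Draws `iterations` uniformly random groups of the same size (concepts
#' sampled without replacement within a draw, draws independent and allowed
#' to overlap the observed group) from the comparison universe, and reports
#' the fraction of draws whose cohesion is at least the observed score. The
#' returned P-value is `r / iterations`, an exact multiple of
#' `1/iterations`; the whole computation is deterministic given `rng_seed`.
#'
#' @param group concept ids of the observed group.
#' @param universe a [profile_set()] containing the group and the concepts a
#'   random group may be drawn from; must be strictly larger than the group.
#' @param iterations number of random draws (default 200).
#' @param rng_seed integer seed (default 17); the caller's RNG state is
#'   preserved.
#' @return A `cohesion_result` list: `group`, `score`, `p_value`,
#'   `iterations`, `contributions` (percentages, `NULL` when the score is 0).
#' @export
permutation_pvalue <- function(group, universe, iterations = 200,
                               rng_seed = 17) {
  stopifnot(inherits(universe, "profile_set"))
  if (iterations < 1L) stop("iterations must be at least 1")
  missing <- setdiff(group, universe$concepts)
  if (length(missing))
    stop("group concept(s) not in universe: ", paste(missing, collapse = ", "))
  m <- length(group)
  if (m < 2L) stop("group must contain at least 2 concepts")
  n <- n_profiles(universe)
  if (n <= m)
    stop("universe must be strictly larger than the group")
  s <- similarity_matrix(universe)
  observed <- mean_pairwise(s[group, group, drop = FALSE])
  hits <- with_seed(rng_seed, {
    h <- 0L
    for (i in seq_len(iterations)) {
      idx <- sample.int(n, m)
      if (mean_pairwise(s[idx, idx, drop = FALSE]) >= observed)
        h <- h + 1L
    }
    h
  })
  contributions <- if (observed > 0) gene_contributions(universe, group)
  structure(
    list(group = group, score = observed, p_value = hits / iterations,
         iterations = iterations, contributions = contributions),
    class = "cohesion_result"
  )
}

#' @export
print.cohesion_result <- function(x, ...) {
  cat(sprintf(
    "<cohesion_result> {%s}: score %.4f, P = %.4g (%d iterations)\n",
    paste(x$group, collapse = ", "), x$score, x$p_value, x$iterations
  ))
  invisible(x)
}
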