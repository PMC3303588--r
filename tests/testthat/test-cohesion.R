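as_profile <- function(weights, id = "p") {
  structure(list(concept_id = id, weights = weights[weights > 0],
                 normalized = TRUE, degenerate = FALSE),
            class = "concept_profile")
}

test_that("matching score is the inner product of unit profiles", {
  p1 <- as_profile(c(g1 = 0.6, g2 = 0.8))
  expect_equal(matching_score(p1, p1), 1)
  expect_equal(matching_score(p1, as_profile(c(g3 = 1))), 0)
  expect_equal(matching_score(p1, as_profile(c(g1 = 0.8, g2 = 0.6))), 0.96)
  bad <- structure(list(concept_id = "x", weights = numeric(0),
                        normalized = FALSE, degenerate = TRUE),
                   class = "concept_profile")
  expect_error(matching_score(p1, bad), "degenerate")
})

test_that("cohesion averages all pairwise scores and honours invariants", {
  # two identical profiles
  W <- cbind(a = c(0.6, 0.8, 0), b = c(0.6, 0.8, 0))
  rownames(W) <- paste0("g", 1:3)
  expect_equal(cohesion_score(profile_set(W)), 1)
  # three pairwise-orthogonal profiles
  expect_equal(cohesion_score(profile_set(diag(3,
    x = 1) |> `dimnames<-`(list(paste0("g", 1:3), paste0("c", 1:3))))), 0)
  # hand-built pairwise scores 0.5 / 0.2 / 0.3 average to 1/3
  ps <- known_score_profiles()
  expect_equal(cohesion_score(ps), 1 / 3, tolerance = 1e-12)
  # invariant under group reordering
  expect_equal(cohesion_score(ps, c("p3", "p1", "p2")), cohesion_score(ps))
  expect_error(cohesion_score(ps, "p1"), "at least 2")
})

test_that("contributions decompose the cohesion score exactly", {
  W <- cbind(a = c(g1 = 0.6, g2 = 0.8), b = c(g1 = 0.6, g2 = 0.8))
  contrib <- gene_contributions(profile_set(W))
  expect_equal(contrib, c(g1 = 36, g2 = 64))
  # a gene absent from every profile contributes 0
  W2 <- rbind(W, g3 = 0)
  expect_equal(gene_contributions(profile_set(W2))[["g3"]], 0)
  # orthogonal profiles: zero cohesion has no decomposition
  D <- diag(2); dimnames(D) <- list(c("g1", "g2"), c("c1", "c2"))
  expect_error(gene_contributions(profile_set(D)), "zero cohesion")
})

test_that("cohesion and contributions match the brute-force double loop", {
  for (seed in 1:5) {
    W <- random_profile_matrix(25, 5, seed = seed)
    ps <- profile_set(W)
    oracle <- brute_cohesion(W, colnames(W))
    expect_equal(cohesion_score(ps), oracle$score, tolerance = 1e-9)
    expect_equal(gene_contributions(ps), oracle$contributions,
                 tolerance = 1e-9)
    expect_equal(sum(gene_contributions(ps)), 100, tolerance = 1e-6)
    # permutation invariance over profiles
    perm <- sample(colnames(W))
    expect_equal(gene_contributions(ps, perm), gene_contributions(ps),
                 tolerance = 1e-12)
  }
})

test_that("permutation P is deterministic and counts qualifying draws", {
  # an identical pair inside an otherwise orthogonal universe: only draws
  # re-selecting that pair can reach the observed score of 1
  W <- diag(6)
  dimnames(W) <- list(paste0("g", 1:6), paste0("c", 1:6))
  W[, 2] <- W[, 1]
  ps <- profile_set(W, normalize = TRUE)
  r <- permutation_pvalue(c("c1", "c2"), ps, iterations = 200, rng_seed = 7)
  expect_equal(r$score, 1)
  # replay the identical draw sequence and count pair re-selections
  set.seed(7)
  redraws <- sum(vapply(1:200, function(i)
    all(sort(sample.int(6, 2)) == c(1, 2)), logical(1)))
  expect_equal(r$p_value, redraws / 200)
  # quantised to multiples of 1/iterations
  expect_equal(r$p_value * r$iterations, round(r$p_value * r$iterations))
  # deterministic given the seed
  r2 <- permutation_pvalue(c("c1", "c2"), ps, iterations = 200, rng_seed = 7)
  expect_identical(r2$p_value, r$p_value)
  # an orthogonal observed group scores 0, so every draw qualifies
  r3 <- permutation_pvalue(c("c3", "c4"), ps, iterations = 50, rng_seed = 3)
  expect_equal(r3$score, 0)
  expect_equal(r3$p_value, 1)
})

test_that("permutation matches exhaustive enumeration on small universes", {
  W <- random_profile_matrix(20, 4, seed = 8)
  # make one pair strictly the most cohesive
  W[, 1] <- W[, 2] * 0.9 + W[, 1] * 0.1
  W <- sweep(W, 2, sqrt(colSums(W^2)), "/")
  ps <- profile_set(W)
  exact <- exhaustive_pvalue(W, c("c01", "c02"))
  expect_equal(exact, 1 / 6)
  est <- permutation_pvalue(c("c01", "c02"), ps, iterations = 10000,
                            rng_seed = 13)$p_value
  se <- sqrt(exact * (1 - exact) / 10000)
  expect_lt(abs(est - exact), 3 * se)
  # a second universe, exhaustively checked for a larger group
  W5 <- random_profile_matrix(15, 6, seed = 21)
  ps5 <- profile_set(W5)
  grp <- c("c02", "c04", "c05")
  exact5 <- exhaustive_pvalue(W5, grp)
  est5 <- permutation_pvalue(grp, ps5, iterations = 10000,
                             rng_seed = 2)$p_value
  se5 <- sqrt(max(exact5 * (1 - exact5), 1e-6) / 10000)
  expect_lt(abs(est5 - exact5), 3 * se5 + 1e-9)
})

test_that("permutation rejects a universe no larger than the group", {
  W <- random_profile_matrix(10, 3, seed = 4)
  ps <- profile_set(W)
  expect_error(permutation_pvalue(colnames(W), ps, 10, 1),
               "strictly larger")
  expect_error(permutation_pvalue(c("c01", "nope"), ps, 10, 1),
               "not in universe")
  expect_error(permutation_pvalue(c("c01", "c02"), ps, 0, 1), "at least 1")
})
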