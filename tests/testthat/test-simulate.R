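small_spec <- function(seed = 17) {
  corpus_spec(n_diseases = 5, n_genes = 60, n_documents = 1500,
              planted_pairs = list(c(1, 2), c(3, 4)), pool_size = 8,
              rng_seed = seed)
}

test_that("corpus generation is bit-reproducible per seed", {
  s1 <- simulate_corpus(small_spec())
  s2 <- simulate_corpus(small_spec())
  expect_identical(as.matrix(s1$corpus$M), as.matrix(s2$corpus$M))
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_corpus(small_spec(seed = 18))
  expect_false(identical(as.matrix(s1$corpus$M), as.matrix(s3$corpus$M)))
})

test_that("corpus spec validation catches infeasible settings", {
  expect_error(corpus_spec(n_genes = 10, pool_size = 9,
                           planted_pairs = list(c(1, 2), c(3, 4))),
               "infeasible")
  expect_error(corpus_spec(planted_pairs = list(c(1, 2), c(2, 3))),
               "disjoint")
  expect_error(corpus_spec(p_comention_shared = 0.001,
                           p_comention_background = 0.005), "at least")
  expect_error(corpus_spec(planted_pairs = list(c(1, 9))), "out of range")
})

test_that("the null generator produces no pair structure", {
  spec <- corpus_spec(n_diseases = 5, n_genes = 60, n_documents = 1500,
                      planted_pairs = list(c(1, 2), c(3, 4)), pool_size = 8,
                      p_comention_shared = 0.005,
                      p_comention_background = 0.005, rng_seed = 17)
  sim <- simulate_corpus(spec)
  ps <- suppressWarnings(build_profiles(sim$corpus, th = sim$thesaurus))
  s <- similarity_matrix(subset_profiles(ps, sprintf("D%d", 1:5)))
  offdiag <- s[upper.tri(s)]
  # planted pairs are indistinguishable from the background noise level
  expect_lt(max(offdiag), 0.2)
})

test_that("planted pairs dominate cohesion in the signal generator", {
  sim <- simulate_corpus(small_spec())
  ps <- suppressWarnings(build_profiles(sim$corpus, th = sim$thesaurus))
  s <- similarity_matrix(subset_profiles(ps, sprintf("D%d", 1:5)))
  planted <- vapply(sim$truth$planted_pairs,
                    function(p) s[p[1], p[2]], numeric(1))
  others <- s[upper.tri(s)]
  others <- setdiff(others, planted)
  expect_gt(min(planted), max(others))
  # profiles put weight on the planted pools
  for (i in seq_along(sim$truth$planted_pairs)) {
    pair <- sim$truth$planted_pairs[[i]]
    pool <- sim$truth$pools[[i]]
    w <- as.matrix(ps$W[, pair[1]])[, 1]
    expect_gt(sum(w[pool]^2), 0.5)
  }
})

test_that("network generation is reproducible and honours its ground truth", {
  spec <- network_spec(rng_seed = 41)
  n1 <- simulate_network(spec)
  n2 <- simulate_network(spec)
  expect_identical(n1$edges, n2$edges)
  expect_identical(n1$truth, n2$truth)

  filtered <- filter_by_reference(n1$edges, 4)
  all_keys <- paste(n1$edges$protein_a, n1$edges$protein_b)
  kept_keys <- paste(filtered$protein_a, filtered$protein_b)
  purged_keys <- paste(n1$truth$purged_edges$protein_a,
                       n1$truth$purged_edges$protein_b)
  expect_setequal(setdiff(all_keys, kept_keys), purged_keys)
})

test_that("zero planted intermediates in a sparse background leaves seeds only", {
  spec <- network_spec(n_proteins = 40, p_edge = 0.04, n_seeds = 4,
                       n_intermediates = 0, n_seed_links = 2,
                       n_hub_references = 0, rng_seed = 6)
  net <- simulate_network(spec)
  bg <- build_background(filter_by_reference(net$edges))
  sn <- suppressMessages(extract_subnetwork(bg, net$truth$seeds))
  expect_equal(sn$intermediates, character(0))
})

test_that("a lone high-throughput reference empties the background", {
  e <- referenced_edges(sprintf("A%02d", 1:50), sprintf("B%02d", 1:50),
                        rep("rHT", 50))
  filtered <- filter_by_reference(e, 4)
  expect_equal(nrow(filtered), 0)
  expect_error(build_background(filtered), "no edges")
})

test_that("planted intermediates carry exact, recoverable counts", {
  spec <- network_spec(rng_seed = 5)
  net <- simulate_network(spec)
  bg <- build_background(filter_by_reference(net$edges))
  sn <- suppressMessages(extract_subnetwork(bg, net$truth$seeds))
  expect_true(all(net$truth$intermediates %in% sn$intermediates))
  sc <- score_intermediates(sn, bg)
  planted <- sc[sc$gene %in% net$truth$intermediates, ]
  # every planted node keeps its wired seed links
  expect_true(all(planted$seed_links >= spec$n_seed_links))
  # z recomputed from the planted counts matches the scored value
  for (i in seq_len(nrow(planted)))
    expect_equal(planted$z[i],
                 intermediate_zscore(planted$n_links[i],
                                     planted$seed_links[i],
                                     sn$n_links, bg$n_links))
})
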