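test_that("edge lists parse, uppercase, merge duplicates and drop loops", {
  p <- write_tsv_lines(c(
    "a\tB\tr1;r2\tdbX",
    "B\tA\tr3\tdbY",
    "C\tC\tr4\tdbX",
    "C\tD\tr5\tdbX"
  ))
  expect_warning(edges <- suppressMessages(read_edge_lists(p)), "self-loop")
  expect_equal(nrow(edges), 2)
  ab <- edges[edges$protein_a == "A", ]
  expect_equal(ab$protein_b, "B")
  expect_equal(ab$refs[[1]], c("r1", "r2", "r3"))
  expect_setequal(ab$sources[[1]], c("dbX", "dbY"))

  bad <- write_tsv_lines(c("A\tB\tr1\tdb", "A\tB"))
  expect_error(suppressMessages(read_edge_lists(bad)), "line 2")
  noref <- write_tsv_lines("A\tB\t\tdb")
  expect_error(suppressMessages(read_edge_lists(noref)), "reference")
})

test_that("reference filter purges high-throughput references", {
  # one reference supporting 5 edges, each edge having only it: all removed
  e1 <- referenced_edges(paste0("A", 1:5), paste0("B", 1:5),
                         rep("rbig", 5))
  expect_equal(nrow(filter_by_reference(e1, 4)), 0)
  # an edge with one hub and one small reference survives
  e2 <- referenced_edges(c(paste0("A", 1:10), "X"), c(paste0("B", 1:10), "Y"),
                         c(rep("rbig", 10), "rbig;rsmall"))
  kept <- filter_by_reference(e2, 4)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$refs[[1]], "rsmall")
})

test_that("reference filter equals the two-pass counting oracle and is idempotent", {
  for (seed in c(3, 14, 27)) {
    edges <- random_edge_table(seed)
    filtered <- filter_by_reference(edges, 4)
    keep <- brute_reference_filter(edges, 4)
    expect_equal(paste(filtered$protein_a, filtered$protein_b),
                 paste(edges$protein_a[keep], edges$protein_b[keep]))
    again <- filter_by_reference(filtered, 4)
    expect_identical(paste(again$protein_a, again$protein_b),
                     paste(filtered$protein_a, filtered$protein_b))
    expect_identical(again$refs, filtered$refs)
  }
})

test_that("background network counts merged links once", {
  tri <- referenced_edges(c("A", "B", "C"), c("B", "C", "A"),
                          c("r1", "r2", "r3"))
  bg <- build_background(tri)
  expect_equal(bg$n_links, 3)
  expect_equal(unname(igraph::degree(bg$graph)), c(2, 2, 2))
  dup <- referenced_edges(c("A", "B"), c("B", "A"), c("r1", "r2"))
  expect_equal(build_background(dup)$n_links, 1)
  expect_error(build_background(filter_by_reference(
    referenced_edges(paste0("A", 1:6), paste0("B", 1:6), rep("rbig", 6)), 4
  )), "no edges")
})

test_that("subnetwork extraction finds exactly the length-2 intermediates", {
  edges <- referenced_edges(
    c("A", "X", "A", "A"), c("B", "B", "X", "C"),
    c("r1", "r2", "r3", "r4")
  )
  bg <- build_background(edges)
  # direct seed-seed edge, no intermediates
  sn0 <- extract_subnetwork(bg, c("A", "B"), max_path_length = 1)
  expect_equal(sn0$intermediates, character(0))
  expect_equal(sn0$n_links, 1)
  # X bridges A and B; C touches one seed only and is excluded
  sn <- extract_subnetwork(bg, c("A", "B"))
  expect_equal(sn$intermediates, "X")
  expect_setequal(c(sn$seeds, sn$intermediates), c("A", "B", "X"))
  sc <- score_intermediates(sn, bg)
  expect_equal(sc$seed_links, 2)
  # parallel records to a single seed never make an intermediate
  par <- referenced_edges(c("A", "A", "A", "B"), c("X", "X", "B", "Y"),
                          c("r1", "r2", "r3", "r4"))
  bg2 <- build_background(par)
  sn2 <- extract_subnetwork(bg2, c("A", "B"))
  expect_equal(sn2$intermediates, character(0))
  # seeds absent from the background are reported, not fatal
  expect_message(sn3 <- extract_subnetwork(bg, c("A", "B", "ZZ")), "absent")
  expect_equal(sn3$absent_seeds, "ZZ")
  expect_error(extract_subnetwork(bg, c("A", "ZZ")), "fewer than 2")
})

test_that("subnetwork extraction ignores seed and edge input order", {
  net <- simulate_network(network_spec(n_proteins = 60, p_edge = 0.05,
                                       n_seeds = 6, n_intermediates = 2,
                                       n_seed_links = 3,
                                       n_hub_references = 1,
                                       hub_reference_links = 6,
                                       rng_seed = 23))
  filtered <- filter_by_reference(net$edges)
  bg1 <- build_background(filtered)
  shuf <- filtered[rev(seq_len(nrow(filtered))), ]
  class(shuf) <- class(filtered)
  bg2 <- build_background(shuf)
  s1 <- extract_subnetwork(bg1, net$truth$seeds)
  s2 <- extract_subnetwork(bg2, rev(net$truth$seeds))
  expect_equal(s1$intermediates, s2$intermediates)
  expect_equal(s1$seeds, s2$seeds)
  expect_equal(s1$n_links, s2$n_links)
})

test_that("the binomial-proportion z matches published anchor rows", {
  expect_equal(intermediate_zscore(3, 2, 60, 11429), 15.852,
               tolerance = 0.005 / 15.852)
  expect_equal(intermediate_zscore(18, 2, 60, 11429), 6.215,
               tolerance = 0.005 / 6.215)
  # null proportion
  expect_equal(intermediate_zscore(100, 2, 60, 3000), 0)
  # strictly increasing in k at fixed n, K, N
  z <- intermediate_zscore(rep(20, 5), 0:4, 60, 11429)
  expect_true(all(diff(z) > 0))
  expect_error(intermediate_zscore(5, 2, 10, 10), "1 <= K < N")
  expect_error(intermediate_zscore(5, 6, 10, 100), "k must")
})

test_that("intermediate scoring sorts by z and applies a strict cutoff", {
  edges <- referenced_edges(
    c("S1", "S2", "X", "X", "Y", "Y", "Y", "U", "U"),
    c("S2", "S3", "S1", "S2", "S1", "S3", "U", "V", "W"),
    sprintf("r%d", 1:9)
  )
  bg <- build_background(edges)
  sn <- extract_subnetwork(bg, c("S1", "S2", "S3"))
  sc <- score_intermediates(sn, bg)
  expect_equal(sc$gene, c("X", "Y"))  # X: 2/2 vs Y: 2/3 seed links
  expect_true(all(diff(sc$z) <= 0))
  none <- score_intermediates(sn, bg, cutoff = 1e6)
  expect_false(any(none$significant))
  at <- score_intermediates(sn, bg, cutoff = sc$z[1])
  expect_false(at$significant[1])  # strict inequality at the cutoff
})

test_that("subnetwork export round-trips and mirrors the published layout", {
  edges <- referenced_edges(
    c("A", "X", "A", "U"), c("B", "B", "X", "V"), c("r1", "r2", "r3", "r4")
  )
  bg <- build_background(edges)
  sn <- extract_subnetwork(bg, c("A", "B"))
  sc <- score_intermediates(sn, bg)
  gml <- withr::local_tempfile(fileext = ".graphml")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_subnetwork(sn, sc, gml, tsv)
  back <- igraph::read_graph(gml, format = "graphml")
  expect_setequal(igraph::V(back)$name, igraph::V(sn$graph)$name)
  ends_back <- apply(igraph::as_edgelist(back), 1,
                     function(e) paste(sort(e), collapse = "-"))
  ends_orig <- apply(igraph::as_edgelist(sn$graph), 1,
                     function(e) paste(sort(e), collapse = "-"))
  expect_setequal(ends_back, ends_orig)
  expect_setequal(igraph::V(back)$role[igraph::V(back)$name %in% sn$seeds],
                  "seed")
  header <- readLines(tsv, n = 1)
  expect_identical(header, paste("Gene name", "Link", "Link in background",
                                 "Links to seed", "Links in subnetwork",
                                 "z-score", sep = "\t"))
  # empty intermediate set still writes valid files
  snd <- extract_subnetwork(bg, c("A", "B"), max_path_length = 1)
  scd <- score_intermediates(snd, bg)
  write_subnetwork(snd, scd, gml, tsv)
  expect_length(readLines(tsv), 1)
  expect_s3_class(igraph::read_graph(gml, format = "graphml"), "igraph")
})
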