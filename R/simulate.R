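# Synthetic-data generators. The corpus generator emulates a MedLine-like
# literature in which each document mentions exactly one disease and a
# random set of genes; planted disease pairs share a gene pool that is
# co-mentioned at an elevated rate, so their profiles are similar by
# construction. The network generator emulates referenced interaction edge
# lists: an Erdos-Renyi background, planted intermediates wired to several
# seeds, and "high-throughput" hub references supporting more links than the
# reference filter allows.

#' Specification of a synthetic occurrence corpus
#'
#' Defaults plant three disease pairs among seven diseases, mirroring the
#' paired cluster structure the cohesion analysis is meant to detect.
#'
#' @param n_diseases number of disease concepts.
#' @param n_genes number of gene concepts.
#' @param n_documents number of documents.
#' @param planted_pairs list of integer pairs (disease indices) sharing a
#'   gene pool; pairs must be disjoint.
#' @param pool_size genes in each pair's shared pool.
#' @param p_comention_shared probability that a document of a paired disease
#'   mentions a given pool gene.
#' @param p_comention_background baseline gene mention probability; must be
#'   below `p_comention_shared`.
#' @param rng_seed integer seed.
#' @return A validated `corpus_spec` list.
#' @export
corpus_spec <- function(n_diseases = 7, n_genes = 500, n_documents = 20000,
                        planted_pairs = list(c(1, 2), c(3, 4), c(5, 6)),
                        pool_size = 20,
                        p_comention_shared = 0.05,
                        p_comention_background = 0.005,
                        rng_seed = 17) {
  stopifnot(n_diseases >= 1, n_genes >= 1, n_documents >= 1, pool_size >= 1)
  probs <- c(p_comention_shared, p_comention_background)
  if (any(probs < 0) || any(probs > 1))
    stop("co-mention probabilities must lie in [0, 1]")
  # equality is the null generator (no planted signal); below is nonsense
  if (p_comention_shared < p_comention_background)
    stop("p_comention_shared must be at least p_comention_background")
  members <- unlist(planted_pairs)
  if (length(planted_pairs)) {
    if (any(lengths(planted_pairs) != 2L))
      stop("planted pairs must each contain exactly 2 disease indices")
    if (anyDuplicated(members))
      stop("planted pairs must be disjoint")
    if (any(members < 1) || any(members > n_diseases))
      stop("planted pair indices out of range")
  }
  if (pool_size * length(planted_pairs) > n_genes)
    stop("infeasible spec: shared pools exceed the gene vocabulary")
  structure(
    list(n_diseases = n_diseases, n_genes = n_genes,
         n_documents = n_documents, planted_pairs = planted_pairs,
         pool_size = pool_size, p_comention_shared = p_comention_shared,
         p_comention_background = p_comention_background,
         rng_seed = rng_seed),
    class = "corpus_spec"
  )
}

#' Simulate an occurrence corpus with planted disease pairs
#'
#' Each document mentions exactly one disease (uniformly assigned); gene
#' mentions are independent Bernoulli draws whose probability is elevated for
#' a planted pair's shared pool. Deterministic given the spec's seed.
#'
#' @param spec a [corpus_spec()].
#' @return A `synthetic_corpus` list: `corpus` (an [occurrence_corpus()]),
#'   `thesaurus`, and `truth` with the planted pair ids and shared pools.
#' @export
simulate_corpus <- function(spec = corpus_spec()) {
  stopifnot(inherits(spec, "corpus_spec"))
  diseases <- sprintf("D%d", seq_len(spec$n_diseases))
  genes <- sprintf("G%04d", seq_len(spec$n_genes))
  docs <- sprintf("M%06d", seq_len(spec$n_documents))
  sim <- with_seed(spec$rng_seed, {
    pool_genes <- sample(genes, spec$pool_size * length(spec$planted_pairs))
    pools <- if (length(spec$planted_pairs))
      split(pool_genes, rep(seq_along(spec$planted_pairs),
                            each = spec$pool_size))
    else list()
    disease_of_doc <- sample.int(spec$n_diseases, spec$n_documents,
                                 replace = TRUE)
    doc_id <- docs
    concept_id <- diseases[disease_of_doc]
    for (d in seq_len(spec$n_diseases)) {
      d_docs <- docs[disease_of_doc == d]
      if (length(d_docs) == 0L) next
      p <- rep(spec$p_comention_background, spec$n_genes)
      names(p) <- genes
      for (i in seq_along(spec$planted_pairs))
        if (d %in% spec$planted_pairs[[i]])
          p[pools[[i]]] <- spec$p_comention_shared
      counts <- rbinom(spec$n_genes, length(d_docs), p)
      for (g in which(counts > 0)) {
        hit <- sample(d_docs, counts[g])
        doc_id <- c(doc_id, hit)
        concept_id <- c(concept_id, rep(genes[g], counts[g]))
      }
    }
    list(doc_id = doc_id, concept_id = concept_id, pools = pools)
  })
  th <- thesaurus(
    concept_id = c(diseases, genes),
    name = c(paste("disease", diseases), paste("gene", genes)),
    class = c(rep("disease", spec$n_diseases), rep("gene", spec$n_genes))
  )
  pairs <- lapply(spec$planted_pairs, function(p) diseases[p])
  pools <- sim$pools
  if (length(pools)) {
    names(pools) <- vapply(pairs, paste, character(1), collapse = "-")
    pools <- lapply(pools, sort)
  }
  structure(
    list(corpus = occurrence_corpus(sim$doc_id, sim$concept_id),
         thesaurus = th,
         truth = list(planted_pairs = pairs, pools = pools),
         spec = spec),
    class = "synthetic_corpus"
  )
}

#' Write a synthetic corpus to disk
#'
#' Emits `occurrences.tsv` and `thesaurus.tsv` in the formats consumed by
#' [read_occurrences()] and [read_thesaurus()], plus a `ground_truth.yaml`
#' sidecar with the planted structure.
#'
#' @param sim a [simulate_corpus()] result.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_corpus <- function(sim, dir) {
  stopifnot(inherits(sim, "synthetic_corpus"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_occurrences(sim$corpus, file.path(dir, "occurrences.tsv"))
  write_thesaurus(sim$thesaurus, file.path(dir, "thesaurus.tsv"))
  yaml::write_yaml(sim$truth, file.path(dir, "ground_truth.yaml"))
  invisible(dir)
}

#' Specification of a synthetic referenced interaction network
#'
#' @param n_proteins number of proteins.
#' @param p_edge Erdos-Renyi background edge probability.
#' @param seed_genes seed protein symbols, or `NULL` to sample `n_seeds`.
#' @param n_seeds number of seeds sampled when `seed_genes` is `NULL`.
#' @param n_intermediates planted intermediates, each wired to
#'   `n_seed_links` distinct seeds.
#' @param n_seed_links seed links per planted intermediate.
#' @param n_hub_references number of "high-throughput" references, each
#'   assigned `hub_reference_links` edges (which must exceed the downstream
#'   reference cap for the filter to act).
#' @param hub_reference_links edges per hub reference.
#' @param rng_seed integer seed.
#' @return A validated `network_spec` list.
#' @export
network_spec <- function(n_proteins = 300, p_edge = 0.01, seed_genes = NULL,
                         n_seeds = 10, n_intermediates = 3, n_seed_links = 5,
                         n_hub_references = 2, hub_reference_links = 8,
                         rng_seed = 17) {
  stopifnot(n_proteins >= 2, p_edge >= 0, p_edge <= 1, n_intermediates >= 0,
            n_hub_references >= 0, hub_reference_links >= 1)
  if (is.null(seed_genes)) {
    if (n_seeds < 2 || n_seeds > n_proteins)
      stop("need 2 <= n_seeds <= n_proteins")
  } else {
    seed_genes <- unique(toupper(as.character(seed_genes)))
    n_seeds <- length(seed_genes)
    if (n_seeds < 2) stop("need at least 2 seed genes")
  }
  if (n_seed_links < 2 || n_seed_links > n_seeds)
    stop("n_seed_links must lie in [2, number of seeds]")
  if (n_intermediates > n_proteins - n_seeds)
    stop("infeasible spec: more intermediates than non-seed proteins")
  structure(
    list(n_proteins = n_proteins, p_edge = p_edge, seed_genes = seed_genes,
         n_seeds = n_seeds, n_intermediates = n_intermediates,
         n_seed_links = n_seed_links, n_hub_references = n_hub_references,
         hub_reference_links = hub_reference_links, rng_seed = rng_seed),
    class = "network_spec"
  )
}

#' Simulate a referenced interaction network with planted structure
#'
#' Generates an Erdos-Renyi background in which every edge is supported by
#' its own reference, replaces the references of some background edges with
#' shared "hub" references exceeding the link cap (so [filter_by_reference()]
#' must purge them), and wires each planted intermediate to `n_seed_links`
#' distinct seeds with individually referenced edges. Deterministic given the
#' spec's seed.
#'
#' @param spec a [network_spec()].
#' @return A `synthetic_network` list: `edges` (a [referenced_edges()]
#'   table) and `truth` with `seeds`, `intermediates` and `purged_edges`
#'   (the records the reference filter must remove).
#' @export
simulate_network <- function(spec = network_spec()) {
  stopifnot(inherits(spec, "network_spec"))
  proteins <- if (is.null(spec$seed_genes))
    sprintf("P%04d", seq_len(spec$n_proteins))
  else
    unique(c(spec$seed_genes,
             sprintf("P%04d", seq_len(spec$n_proteins))))[seq_len(spec$n_proteins)]
  out <- with_seed(spec$rng_seed, {
    seeds <- if (is.null(spec$seed_genes)) sample(proteins, spec$n_seeds)
    else spec$seed_genes
    inter <- sample(setdiff(proteins, seeds), spec$n_intermediates)
    # background: every unordered pair flips the same coin
    pair_idx <- which(upper.tri(diag(spec$n_proteins)), arr.ind = TRUE)
    sel <- stats::runif(nrow(pair_idx)) < spec$p_edge
    a <- proteins[pair_idx[sel, 1L]]
    b <- proteins[pair_idx[sel, 2L]]
    refs <- as.list(sprintf("RBG%05d", seq_along(a)))
    # hub references: replace the single-edge references of eligible edges
    eligible <- which(!(a %in% inter) & !(b %in% inter))
    need <- spec$n_hub_references * spec$hub_reference_links
    if (length(eligible) < need)
      stop("infeasible spec: not enough background edges for hub references")
    hub_edges <- sample(eligible, need)
    hub_of <- rep(seq_len(spec$n_hub_references),
                  each = spec$hub_reference_links)
    for (i in seq_along(hub_edges))
      refs[[hub_edges[i]]] <- sprintf("RHUB%02d", hub_of[i])
    purged <- data.frame(
      protein_a = pmin(a[hub_edges], b[hub_edges]),
      protein_b = pmax(a[hub_edges], b[hub_edges]),
      stringsAsFactors = FALSE
    )
    # planted intermediates, each edge individually referenced
    pa <- character(0); pb <- character(0)
    for (x in inter) {
      to <- sample(seeds, spec$n_seed_links)
      pa <- c(pa, rep(x, length(to)))
      pb <- c(pb, to)
    }
    prefs <- as.list(sprintf("RPL%05d", seq_along(pa)))
    # a planted edge may coincide with a background edge; merging unions refs
    purged <- purged[!paste(purged$protein_a, purged$protein_b) %in%
                       paste(pmin(pa, pb), pmax(pa, pb)), , drop = FALSE]
    list(
      edges = referenced_edges(c(a, pa), c(b, pb), c(refs, prefs),
                               source = "synthetic"),
      seeds = sort(seeds), intermediates = sort(inter), purged = purged
    )
  })
  structure(
    list(edges = out$edges,
         truth = list(seeds = out$seeds, intermediates = out$intermediates,
                      purged_edges = out$purged[order(out$purged$protein_a,
                                                      out$purged$protein_b), ,
                                                drop = FALSE]),
         spec = spec),
    class = "synthetic_network"
  )
}
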