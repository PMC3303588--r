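# Interaction-network validation stage: referenced edge lists are filtered
# for high-throughput references, merged into a simple undirected background
# graph, the seed subnetwork is extracted at path length <= 2, and every
# intermediate node is scored with a one-sample binomial-proportion z
# statistic against the background link rate.

# Normalise raw edge records into a merged, undirected, simple edge table.
# refs/sources are list columns of character vectors.
merge_edges <- function(a, b, refs, sources) {
  a <- toupper(as.character(a))
  b <- toupper(as.character(b))
  loops <- a == b
  if (any(loops)) {
    warning(sprintf("dropped %d self-loop record(s)", sum(loops)),
            call. = FALSE)
    a <- a[!loops]; b <- b[!loops]
    refs <- refs[!loops]; sources <- sources[!loops]
  }
  if (length(a) == 0L)
    return(empty_edges())
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  grp <- split(seq_along(key), key)
  ord <- order(names(grp))
  grp <- grp[ord]
  first <- vapply(grp, `[[`, integer(1), 1L)
  out <- data.frame(
    protein_a = lo[first], protein_b = hi[first], stringsAsFactors = FALSE
  )
  out$refs <- lapply(grp, function(i) sort(unique(unlist(refs[i]))))
  out$sources <- lapply(grp, function(i) sort(unique(unlist(sources[i]))))
  rownames(out) <- NULL
  class(out) <- c("referenced_edges", "data.frame")
  out
}

empty_edges <- function() {
  out <- data.frame(protein_a = character(0), protein_b = character(0),
                    stringsAsFactors = FALSE)
  out$refs <- list()
  out$sources <- list()
  class(out) <- c("referenced_edges", "data.frame")
  out
}

#' Construct a referenced edge table
#'
#' Undirected protein-protein interaction records with supporting reference
#' ids. Symbols are uppercased, self-loops dropped with a warning, duplicate
#' records (in either orientation) merged with references unioned.
#'
#' @param protein_a,protein_b character vectors of interactor symbols.
#' @param refs supporting references per record: a list of character vectors,
#'   or a character vector of `;`-separated ids. Every record needs at least
#'   one reference.
#' @param source source database label(s), recycled.
#' @return A `referenced_edges` data frame with list columns `refs` and
#'   `sources`.
#' @export
referenced_edges <- function(protein_a, protein_b, refs, source = "user") {
  if (is.character(refs)) refs <- strsplit(refs, ";", fixed = TRUE)
  stopifnot(is.list(refs))
  refs <- lapply(refs, function(r) r[nzchar(r)])
  if (any(lengths(refs) == 0L))
    stop("every edge record needs at least one reference")
  n <- length(protein_a)
  if (length(protein_b) != n || length(refs) != n)
    stop("protein_a, protein_b and refs must have equal length")
  sources <- as.list(rep_len(as.character(source), n))
  merge_edges(protein_a, protein_b, refs, sources)
}

#' Read SIF-like referenced edge lists
#'
#' Each file is a TSV `proteinA<TAB>proteinB<TAB>refs<TAB>source` with
#' `;`-separated reference ids and no header (a header line naming the
#' columns is tolerated and skipped). Records from all files are merged.
#'
#' @param paths character vector of file paths.
#' @return A [referenced_edges()] table.
#' @export
read_edge_lists <- function(paths) {
  a <- character(0); b <- character(0)
  refs <- list(); sources <- list()
  for (path in paths) {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L) stop("empty edge list: ", path)
    start <- 1L
    f1 <- tolower(strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]])
    if (length(f1) >= 2L && f1[[1L]] %in% c("proteina", "protein_a"))
      start <- 2L
    for (i in seq(start, length(lines))) {
      p <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
      if (length(p) < 4L)
        stop(sprintf("malformed edge record at %s line %d (expected 4 fields)",
                     path, i))
      r <- strsplit(p[[3L]], ";", fixed = TRUE)[[1L]]
      r <- r[nzchar(r)]
      if (length(r) == 0L)
        stop(sprintf("edge record without references at %s line %d", path, i))
      a <- c(a, p[[1L]]); b <- c(b, p[[2L]])
      refs <- c(refs, list(r)); sources <- c(sources, list(p[[4L]]))
    }
    message(sprintf("read %d edge record(s) from %s",
                    length(seq(start, length(lines))), path))
  }
  merge_edges(a, b, refs, sources)
}

#' Write a referenced edge table as SIF-like TSV
#' @param edges a [referenced_edges()] table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(edges, path) {
  stopifnot(inherits(edges, "referenced_edges"))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf(
    "%s\t%s\t%s\t%s", edges$protein_a, edges$protein_b,
    vapply(edges$refs, paste, character(1), collapse = ";"),
    vapply(edges$sources, paste, character(1), collapse = ";")
  ), con)
  invisible(path)
}

#' Remove high-throughput references
#'
#' A reference supporting more than `max_links_per_reference` edges is
#' treated as a high-throughput artifact and invalidated everywhere. An edge
#' survives if it retains at least one valid reference (there is no minimum
#' reference count beyond one). The operation is idempotent.
#'
#' @param edges a [referenced_edges()] table.
#' @param max_links_per_reference link cap per reference (default 4).
#' @return The surviving edges with invalid references stripped.
#' @export
filter_by_reference <- function(edges, max_links_per_reference = 4) {
  stopifnot(inherits(edges, "referenced_edges"))
  if (max_links_per_reference < 1) stop("max_links_per_reference must be >= 1")
  if (nrow(edges) == 0L) return(edges)
  support <- table(unlist(lapply(edges$refs, unique)))
  invalid <- names(support)[support > max_links_per_reference]
  kept_refs <- lapply(edges$refs, setdiff, invalid)
  keep <- lengths(kept_refs) > 0L
  out <- edges[keep, , drop = FALSE]
  out$refs <- kept_refs[keep]
  rownames(out) <- NULL
  class(out) <- c("referenced_edges", "data.frame")
  out
}

#' Build the background interaction network
#'
#' Simple undirected graph over the (filtered) edge table; `n_links` is the
#' total edge count N used as the denominator of the intermediate z
#' statistic.
#'
#' @param edges a [referenced_edges()] table, normally after
#'   [filter_by_reference()]; must be non-empty.
#' @return A `background_network` list with fields `graph` (igraph) and
#'   `n_links`.
#' @export
build_background <- function(edges) {
  stopifnot(inherits(edges, "referenced_edges"))
  if (nrow(edges) == 0L)
    stop("no edges left to build a background network")
  g <- igraph::graph_from_data_frame(
    edges[, c("protein_a", "protein_b")], directed = FALSE
  )
  igraph::E(g)$refs <- vapply(edges$refs, paste, character(1), collapse = ";")
  igraph::E(g)$sources <-
    vapply(edges$sources, paste, character(1), collapse = ";")
  structure(list(graph = g, n_links = igraph::ecount(g)),
            class = "background_network")
}

#' @export
print.background_network <- function(x, ...) {
  cat(sprintf("<background_network> %d proteins, %d links\n",
              igraph::vcount(x$graph), x$n_links))
  invisible(x)
}

#' Extract the seed subnetwork at path length <= 2
#'
#' The subnetwork contains every seed present in the background plus every
#' intermediate: a non-seed node adjacent to at least two distinct seeds
#' (the only way a length-2 path can join two seeds). Edges are the
#' background edges induced on that node set; their count is K.
#'
#' @param bg a [build_background()] network.
#' @param seeds character vector of seed gene symbols; at least two must be
#'   present in the background. Absent seeds are reported.
#' @param max_path_length 1 (direct seed-seed edges only) or 2 (default).
#' @param count_intermediate_links if `FALSE`, edges between two
#'   intermediates are excluded from K (they remain in the graph).
#' @return A `subnetwork` list: `graph`, `seeds` (present in background),
#'   `intermediates`, `n_links` (K), `absent_seeds`.
#' @export
extract_subnetwork <- function(bg, seeds, max_path_length = 2,
                               count_intermediate_links = TRUE) {
  stopifnot(inherits(bg, "background_network"))
  if (!max_path_length %in% c(1, 2))
    stop("max_path_length must be 1 or 2")
  seeds <- unique(toupper(as.character(seeds)))
  nodes <- igraph::V(bg$graph)$name
  present <- intersect(seeds, nodes)
  absent <- setdiff(seeds, nodes)
  if (length(absent))
    message(sprintf("%d of %d seed(s) absent from background: %s",
                    length(absent), length(seeds),
                    paste(absent, collapse = ", ")))
  if (length(present) < 2L)
    stop("fewer than 2 seeds present in the background network")
  intermediates <- character(0)
  if (max_path_length == 2) {
    nb <- igraph::adjacent_vertices(bg$graph, present)
    counts <- table(unlist(lapply(nb, function(v) v$name)))
    counts <- counts[!names(counts) %in% present]
    intermediates <- sort(names(counts)[counts >= 2])
  }
  sub <- igraph::induced_subgraph(bg$graph, c(present, intermediates))
  k <- igraph::ecount(sub)
  if (!count_intermediate_links && k > 0) {
    ep <- igraph::as_edgelist(sub)
    k <- sum(!(ep[, 1] %in% intermediates & ep[, 2] %in% intermediates))
  }
  structure(
    list(graph = sub, seeds = sort(present), intermediates = intermediates,
         n_links = k, absent_seeds = sort(absent)),
    class = "subnetwork"
  )
}

#' @export
print.subnetwork <- function(x, ...) {
  cat(sprintf("<subnetwork> %d seeds, %d intermediates, %d links\n",
              length(x$seeds), length(x$intermediates), x$n_links))
  invisible(x)
}

#' Binomial-proportion z statistic for an intermediate node
#'
#' Compares the node's observed proportion of seed-directed links, `k/n`,
#' against the background link rate `p0 = K/N`:
#' `z = (k/n - p0) / sqrt(p0 (1 - p0) / n)`. Large z marks nodes whose
#' connectivity is specific to the seed set. Vectorised over the first two
#' arguments.
#'
#' @param n node degree in the background network (>= 1).
#' @param k number of links from the node to distinct seeds (0 <= k <= n).
#' @param K subnetwork link count (1 <= K < N).
#' @param N background link count.
#' @return Numeric z-score(s).
#' @export
intermediate_zscore <- function(n, k, K, N) {
  if (any(n < 1)) stop("n must be at least 1")
  if (any(k < 0) || any(k > n)) stop("k must satisfy 0 <= k <= n")
  if (K < 1 || K >= N)
    stop("degenerate background rate: need 1 <= K < N")
  p0 <- K / N
  (k / n - p0) / sqrt(p0 * (1 - p0) / n)
}

#' Score all intermediate nodes of a subnetwork
#'
#' For each intermediate: `n` is its background degree, `k` its number of
#' distinct-seed neighbours, `K` the subnetwork link count and `N` the
#' background link count. Nodes are sorted by decreasing z (gene symbol
#' breaking ties); a node is significant when `z > cutoff` (strict).
#'
#' @param subnet an [extract_subnetwork()] result.
#' @param bg the [build_background()] network it came from.
#' @param cutoff significance threshold on z (default 2.5).
#' @return An `intermediate_scores` data frame with columns `gene`,
#'   `n_links`, `background_links`, `seed_links`, `subnetwork_links`, `z`,
#'   `significant`.
#' @export
score_intermediates <- function(subnet, bg, cutoff = 2.5) {
  stopifnot(inherits(subnet, "subnetwork"), inherits(bg, "background_network"))
  inter <- subnet$intermediates
  if (length(inter) == 0L) {
    out <- data.frame(gene = character(0), n_links = integer(0),
                      background_links = integer(0), seed_links = integer(0),
                      subnetwork_links = integer(0), z = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE)
    class(out) <- c("intermediate_scores", "data.frame")
    return(out)
  }
  deg <- igraph::degree(bg$graph)[inter]
  nb <- igraph::adjacent_vertices(bg$graph, inter)
  k <- vapply(nb, function(v) length(intersect(v$name, subnet$seeds)),
              integer(1))
  z <- intermediate_zscore(as.numeric(deg), as.numeric(k),
                           subnet$n_links, bg$n_links)
  out <- data.frame(
    gene = inter, n_links = as.integer(deg),
    background_links = bg$n_links, seed_links = as.integer(k),
    subnetwork_links = subnet$n_links, z = z,
    significant = z > cutoff, stringsAsFactors = FALSE
  )
  out <- out[order(-out$z, out$gene), ]
  rownames(out) <- NULL
  class(out) <- c("intermediate_scores", "data.frame")
  out
}

#' Write a scored subnetwork
#'
#' Writes (i) a GraphML file with node attributes `role` (`seed` or
#' `intermediate`), `z` and `significant`, and (ii) a TSV score table whose
#' column header is, in order: Gene name, Link, Link in background, Links to
#' seed, Links in subnetwork, z-score.
#'
#' @param subnet an [extract_subnetwork()] result.
#' @param scores the matching [score_intermediates()] table.
#' @param graphml_path,table_path output file paths.
#' @return Invisibly, a character vector of the two paths.
#' @export
write_subnetwork <- function(subnet, scores, graphml_path, table_path) {
  stopifnot(inherits(subnet, "subnetwork"),
            inherits(scores, "intermediate_scores"))
  g <- subnet$graph
  nm <- igraph::V(g)$name
  igraph::V(g)$role <- ifelse(nm %in% subnet$seeds, "seed", "intermediate")
  idx <- match(nm, scores$gene)
  igraph::V(g)$z <- ifelse(is.na(idx), NA_real_, scores$z[idx])
  igraph::V(g)$significant <- ifelse(is.na(idx), FALSE, scores$significant[idx])
  igraph::write_graph(g, graphml_path, format = "graphml")
  df <- data.frame(
    "Gene name" = scores$gene, "Link" = scores$n_links,
    "Link in background" = scores$background_links,
    "Links to seed" = scores$seed_links,
    "Links in subnetwork" = scores$subnetwork_links,
    "z-score" = scores$z, check.names = FALSE, stringsAsFactors = FALSE
  )
  write.table(df, table_path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(c(graphml_path, table_path))
}
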