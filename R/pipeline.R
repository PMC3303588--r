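#' Pipeline configuration
#'
#' Bundles the input locations and every tunable parameter of the two-stage
#' analysis. Defaults follow the published settings: 200 permutation
#' iterations, a 0.1% contribution shortlist cutoff, at most 4 links per
#' reference, path length 2, and a z cutoff of 2.5 (strict, with no minimum
#' reference count beyond one).
#'
#' @param occurrences path to the occurrence TSV ([read_occurrences()]).
#' @param thesaurus path to the thesaurus TSV ([read_thesaurus()]).
#' @param concepts character vector of disease concept names to analyse
#'   (mapped against the thesaurus; ambiguous names are excluded).
#' @param edge_files character vector of SIF-like edge list paths for the
#'   network stage; `NULL` skips that stage.
#' @param out_dir output directory for artifacts.
#' @param weight_method association weighting, see [association_weight()].
#' @param linkage clustering linkage, see [hierarchical_cluster()].
#' @param iterations permutation iterations (>= 1).
#' @param rng_seed integer seed for all stochastic steps.
#' @param contribution_cutoff shortlist cutoff in percent: a gene enters the
#'   network stage when its contribution to any significant group exceeds it.
#' @param p_threshold permutation-P threshold defining the significant groups
#'   whose contributions feed the shortlist.
#' @param max_links_per_reference reference cap, see [filter_by_reference()].
#' @param max_path_length subnetwork path length (1 or 2).
#' @param z_cutoff intermediate significance threshold.
#' @param count_intermediate_links whether K counts intermediate-intermediate
#'   links, see [extract_subnetwork()].
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(occurrences, thesaurus, concepts,
                            edge_files = NULL, out_dir = ".",
                            weight_method = "uncertainty",
                            linkage = "average", iterations = 200,
                            rng_seed = 17, contribution_cutoff = 0.1,
                            p_threshold = 0.05,
                            max_links_per_reference = 4, max_path_length = 2,
                            z_cutoff = 2.5,
                            count_intermediate_links = TRUE) {
  weight_method <- match.arg(weight_method, c("uncertainty", "pmi", "raw"))
  linkage <- match.arg(linkage, c("average", "complete", "single"))
  if (!is.numeric(iterations) || iterations < 1)
    stop("iterations must be at least 1")
  if (!max_path_length %in% c(1, 2)) stop("max_path_length must be 1 or 2")
  if (max_links_per_reference < 1)
    stop("max_links_per_reference must be >= 1")
  if (contribution_cutoff < 0 || p_threshold < 0 || p_threshold > 1)
    stop("invalid cutoff")
  structure(
    list(occurrences = occurrences, thesaurus = thesaurus,
         concepts = as.character(concepts), edge_files = edge_files,
         out_dir = out_dir, weight_method = weight_method, linkage = linkage,
         iterations = as.integer(iterations),
         rng_seed = as.integer(rng_seed),
         contribution_cutoff = contribution_cutoff,
         p_threshold = p_threshold,
         max_links_per_reference = max_links_per_reference,
         max_path_length = max_path_length, z_cutoff = z_cutoff,
         count_intermediate_links = count_intermediate_links),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' The YAML keys are the [pipeline_config()] arguments; unknown keys are
#' rejected.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- setdiff(names(formals(pipeline_config)), "")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if ("edge_files" %in% names(raw) && length(raw$edge_files))
    raw$edge_files <- unlist(raw$edge_files)
  if ("concepts" %in% names(raw)) raw$concepts <- unlist(raw$concepts)
  do.call(pipeline_config, raw)
}

#' Run the two-stage pipeline
#'
#' Maps the input disease names, builds genetic concept profiles for every
#' corpus concept (the permutation universe), clusters and projects the
#' disease profiles, scores every disease pair with cohesion, contribution
#' percentages and a permutation P-value, shortlists the genes contributing
#' more than the cutoff to any significant pair, and (when edge lists are
#' supplied) runs the interaction-network stage on that shortlist. All
#' artifacts are written under `config$out_dir`; any stage failure aborts
#' with the stage name and removes partial outputs.
#'
#' Artifacts: `similarity.tsv`, `dendrogram.nwk`, `projection.tsv`,
#' `cohesion.tsv`, `contributions.tsv`, `shortlist.txt`, `report.yaml`, and
#' with a network stage `network.graphml` + `intermediate_scores.tsv`.
#'
#' @param config a [pipeline_config()].
#' @return A `run_report` list with per-stage counts, the parameter echo,
#'   and the main result objects (`cohesion`, `scores`, ...), invisibly
#'   usable for further analysis.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(name) {
    p <- file.path(config$out_dir, name)
    written <<- c(written, p)
    p
  }
  stages <- list()
  current_stage <- NA_character_
  run_stage <- function(name, expr) {
    current_stage <<- name
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  inputs <- run_stage("read_inputs", {
    corpus <- read_occurrences(config$occurrences)
    th <- read_thesaurus(config$thesaurus)
    list(corpus = corpus, th = th)
  })
  stages$read_inputs <- list(documents = n_documents(inputs$corpus),
                             concepts = length(inputs$corpus$concept_ids),
                             thesaurus_entries = nrow(inputs$th))

  mapping <- run_stage("map_concepts", {
    m <- map_concepts(config$concepts, inputs$th)
    if (length(m$resolved) < 2L)
      stop("fewer than 2 input names resolved unambiguously")
    m
  })
  stages$map_concepts <- list(resolved = length(mapping$resolved),
                              ambiguous = length(mapping$ambiguous),
                              unmapped = length(mapping$unmapped))

  universe <- run_stage("build_profiles", {
    build_profiles(inputs$corpus, th = inputs$th,
                   method = config$weight_method)
  })
  disease_ids <- unname(mapping$resolved)
  missing <- setdiff(disease_ids, universe$concepts)
  if (length(missing))
    stages$build_profiles_degenerate <- missing
  disease_ids <- intersect(disease_ids, universe$concepts)
  if (length(disease_ids) < 2L) {
    unlink(written)
    stop("pipeline stage 'build_profiles' failed: fewer than 2 non-degenerate disease profiles",
         call. = FALSE)
  }
  stages$build_profiles <- list(profiles = n_profiles(universe),
                                vocabulary = length(universe$genes),
                                diseases = length(disease_ids))

  sim <- run_stage("similarity", {
    s <- similarity_matrix(subset_profiles(universe, disease_ids))
    write_similarity(s, emit("similarity.tsv"))
    s
  })

  hc <- run_stage("clustering", {
    h <- hierarchical_cluster(sim, linkage = config$linkage)
    writeLines(dendrogram_newick(h), emit("dendrogram.nwk"))
    h
  })

  proj <- run_stage("projection", {
    p <- project_2d(sim)
    write_projection(p, emit("projection.tsv"))
    p
  })

  cohesion <- run_stage("cohesion", {
    pairs <- utils::combn(sort(disease_ids), 2, simplify = FALSE)
    res <- vector("list", length(pairs))
    for (i in seq_along(pairs))
      res[[i]] <- permutation_pvalue(pairs[[i]], universe,
                                     iterations = config$iterations,
                                     rng_seed = config$rng_seed + i)
    tab <- data.frame(
      cluster = vapply(res, function(r) paste(r$group, collapse = "-"),
                       character(1)),
      score = vapply(res, `[[`, numeric(1), "score"),
      p_value = vapply(res, `[[`, numeric(1), "p_value"),
      iterations = config$iterations, stringsAsFactors = FALSE
    )
    write.table(tab, emit("cohesion.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE, fileEncoding = "UTF-8")
    list(results = res, table = tab)
  })
  stages$cohesion <- list(groups = nrow(cohesion$table),
                          significant = sum(cohesion$table$p_value <=
                                              config$p_threshold))

  shortlist <- run_stage("shortlist", {
    sig <- cohesion$results[cohesion$table$p_value <= config$p_threshold]
    rows <- list()
    genes <- character(0)
    for (r in sig) {
      if (is.null(r$contributions)) next
      keep <- r$contributions[r$contributions > config$contribution_cutoff]
      keep <- keep[order(-keep, names(keep))]
      if (length(keep))
        rows[[length(rows) + 1L]] <- data.frame(
          cluster = paste(r$group, collapse = "-"), gene = names(keep),
          contribution_pct = unname(keep), stringsAsFactors = FALSE
        )
      genes <- union(genes, names(keep))
    }
    ctab <- if (length(rows)) do.call(rbind, rows)
    else data.frame(cluster = character(0), gene = character(0),
                    contribution_pct = numeric(0))
    write.table(ctab, emit("contributions.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE, fileEncoding = "UTF-8")
    genes <- sort(genes)
    writeLines(genes, emit("shortlist.txt"))
    genes
  })
  stages$shortlist <- list(genes = length(shortlist))

  scores <- NULL
  if (length(config$edge_files)) {
    net <- run_stage("network", {
      edges <- read_edge_lists(config$edge_files)
      n_raw <- nrow(edges)
      filtered <- filter_by_reference(edges, config$max_links_per_reference)
      bg <- build_background(filtered)
      subnet <- extract_subnetwork(
        bg, shortlist, max_path_length = config$max_path_length,
        count_intermediate_links = config$count_intermediate_links
      )
      sc <- score_intermediates(subnet, bg, cutoff = config$z_cutoff)
      write_subnetwork(subnet, sc, emit("network.graphml"),
                       emit("intermediate_scores.tsv"))
      list(bg = bg, subnet = subnet, scores = sc, n_raw = n_raw)
    })
    scores <- net$scores
    stages$network <- list(
      input_edges = net$n_raw,
      background_links = net$bg$n_links,
      seeds_in_background = length(net$subnet$seeds),
      absent_seeds = length(net$subnet$absent_seeds),
      intermediates = length(net$subnet$intermediates),
      subnetwork_links = net$subnet$n_links,
      significant = sum(scores$significant)
    )
  }

  report <- structure(
    list(stages = stages,
         parameters = unclass(config),
         version = as.character(packageVersion("gcpnet")),
         cohesion = cohesion$table, shortlist = shortlist, scores = scores,
         dendrogram = hc, projection = proj, similarity = sim),
    class = "run_report"
  )
  yaml::write_yaml(
    list(stages = stages, parameters = unclass(config),
         version = report$version),
    emit("report.yaml")
  )
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> gcpnet", x$version, "\n")
  for (nm in names(x$stages)) {
    s <- x$stages[[nm]]
    cat(sprintf("  %s: %s\n", nm,
                paste(names(s), unlist(s), sep = "=", collapse = ", ")))
  }
  invisible(x)
}
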