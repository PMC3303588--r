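#' Construct a profile set from a weight matrix
#'
#' A profile set holds unit-normalised genetic concept profiles (GCPs) over a
#' shared gene vocabulary as a genes-by-concepts matrix. Mostly useful in
#' tests and for composing profiles built elsewhere; profiles are normally
#' created with [build_profiles()].
#'
#' @param W numeric matrix, genes in rows (rownames = gene ids), concepts in
#'   columns (colnames = concept ids); all entries finite and non-negative.
#' @param normalize if `TRUE`, columns are L2-normalised; if `FALSE` they must
#'   already have unit norm (within 1e-9).
#' @param method label recording the weighting scheme.
#' @return An object of class `profile_set`.
#' @export
profile_set <- function(W, normalize = FALSE, method = "uncertainty") {
  W <- as(as(Matrix(W, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  if (is.null(rownames(W)) || is.null(colnames(W)))
    stop("W must have gene rownames and concept colnames")
  if (anyDuplicated(colnames(W))) stop("duplicate concept ids")
  if (any(!is.finite(W@x)) || any(W@x < 0))
    stop("profile weights must be finite and non-negative")
  nrm <- sqrt(Matrix::colSums(W^2))
  if (any(nrm == 0))
    stop("degenerate (all-zero) profile: ",
         paste(colnames(W)[nrm == 0], collapse = ", "))
  if (normalize) {
    W <- W %*% Matrix::Diagonal(ncol(W), 1 / nrm)
    colnames(W) <- names(nrm)
  } else if (any(abs(nrm - 1) > 1e-9)) {
    stop("profiles are not unit-normalised (set normalize = TRUE)")
  }
  structure(
    list(W = W, genes = rownames(W), concepts = colnames(W), method = method),
    class = "profile_set"
  )
}

#' @export
print.profile_set <- function(x, ...) {
  cat(sprintf("<profile_set> %d profiles over %d genes (%s weights)\n",
              length(x$concepts), length(x$genes), x$method))
  invisible(x)
}

#' Number of profiles in a set
#' @param pset a [profile_set()].
#' @return Integer count.
#' @export
n_profiles <- function(pset) {
  stopifnot(inherits(pset, "profile_set"))
  length(pset$concepts)
}

#' Subset a profile set by concept id
#' @param pset a [profile_set()].
#' @param ids concept ids to keep (order preserved).
#' @return A [profile_set()].
#' @export
subset_profiles <- function(pset, ids) {
  stopifnot(inherits(pset, "profile_set"))
  missing <- setdiff(ids, pset$concepts)
  if (length(missing))
    stop("concepts not in profile set: ", paste(missing, collapse = ", "))
  profile_set(as.matrix(pset$W[, ids, drop = FALSE]), method = pset$method)
}

#' Build genetic concept profiles from a corpus
#'
#' For each requested concept, computes the association weight between the
#' concept and every gene-class thesaurus entry present in the corpus (from
#' the document-level 2x2 co-occurrence table), then L2-normalises the
#' resulting weight vector. For gene concepts the trivial self-dimension is
#' zeroed before normalisation. Concepts whose profile is all-zero are
#' degenerate: they are dropped with a warning and recorded in the
#' `degenerate` field.
#'
#' @param corpus an [occurrence_corpus()].
#' @param concepts concept ids to profile; default all corpus concepts.
#' @param th a [thesaurus()] whose gene-class entries define the vocabulary.
#' @param method weighting scheme, see [association_weight()].
#' @return A [profile_set()] with an additional `degenerate` field listing
#'   excluded concept ids.
#' @export
build_profiles <- function(corpus, concepts = NULL, th,
                           method = c("uncertainty", "pmi", "raw")) {
  stopifnot(inherits(corpus, "occurrence_corpus"))
  method <- match.arg(method)
  if (is.null(concepts)) concepts <- corpus$concept_ids
  missing <- setdiff(concepts, corpus$concept_ids)
  if (length(missing))
    stop("concept(s) absent from corpus: ", paste(missing, collapse = ", "))
  genes <- intersect(gene_vocabulary(th), corpus$concept_ids)
  if (length(genes) == 0L)
    stop("no gene-class thesaurus entries occur in the corpus")
  M <- corpus$M
  a <- as.matrix(crossprod(M[, concepts, drop = FALSE], M[, genes, drop = FALSE]))
  nn <- Matrix::colSums(M)
  n1 <- matrix(nn[concepts], nrow = length(concepts), ncol = length(genes))
  n2 <- matrix(nn[genes], nrow = length(concepts), ncol = length(genes),
               byrow = TRUE)
  tt <- n_documents(corpus)
  w <- switch(method,
    uncertainty = uncertainty_weight(a, n1, n2, tt),
    pmi = pmi_weight(a, n1, n2, tt),
    raw = a
  )
  dimnames(w) <- list(concepts, genes)
  # a gene trivially co-occurs with itself; that dimension carries no signal
  self <- intersect(concepts, genes)
  w[cbind(self, self)] <- 0
  nrm <- sqrt(rowSums(w^2))
  degenerate <- concepts[nrm == 0]
  if (length(degenerate))
    warning("degenerate profile(s) excluded: ",
            paste(degenerate, collapse = ", "), call. = FALSE)
  keep <- concepts[nrm > 0]
  if (length(keep) == 0L) stop("all requested profiles are degenerate")
  ps <- profile_set(t(w[keep, , drop = FALSE] / nrm[keep]), method = method)
  ps$degenerate <- degenerate
  ps
}

#' Build a single genetic concept profile
#'
#' Convenience wrapper around [build_profiles()] for one concept. Unlike the
#' set builder, a degenerate (all-zero) profile is returned flagged rather
#' than dropped, so callers can report it.
#'
#' @inheritParams build_profiles
#' @param concept a single concept id, which must occur in the corpus.
#' @return A `concept_profile` list: `concept_id`, `weights` (named numeric,
#'   non-zero entries only), `normalized`, `degenerate`.
#' @export
build_profile <- function(corpus, concept, th,
                          method = c("uncertainty", "pmi", "raw")) {
  stopifnot(length(concept) == 1L)
  if (!concept %in% corpus$concept_ids)
    stop("concept '", concept, "' absent from corpus")
  ps <- withCallingHandlers(
    tryCatch(build_profiles(corpus, concept, th, method),
             error = function(e) NULL),
    warning = function(w) invokeRestart("muffleWarning")
  )
  if (is.null(ps) || !concept %in% ps$concepts) {
    warning("profile for '", concept, "' is degenerate (no gene association)",
            call. = FALSE)
    return(structure(
      list(concept_id = concept, weights = numeric(0),
           normalized = FALSE, degenerate = TRUE),
      class = "concept_profile"
    ))
  }
  v <- as.numeric(ps$W[, concept])
  names(v) <- ps$genes
  structure(
    list(concept_id = concept, weights = v[v > 0],
         normalized = TRUE, degenerate = FALSE),
    class = "concept_profile"
  )
}

#' @export
print.concept_profile <- function(x, ...) {
  cat(sprintf("<concept_profile> %s: %d non-zero gene weights%s\n",
              x$concept_id, length(x$weights),
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Write profiles to TSV
#'
#' One row per non-zero weight: `concept_id<TAB>gene_id<TAB>weight`, weights
#' printed with 12 significant digits so the file round-trips.
#'
#' @param pset a [profile_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(pset, path) {
  stopifnot(inherits(pset, "profile_set"))
  idx <- Matrix::which(pset$W != 0, arr.ind = TRUE)
  df <- data.frame(
    concept_id = pset$concepts[idx[, 2L]],
    gene_id = pset$genes[idx[, 1L]],
    weight = pset$W[idx],
    stringsAsFactors = FALSE
  )
  df <- df[order(df$concept_id, df$gene_id), ]
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("concept_id\tgene_id\tweight", con)
  writeLines(sprintf("%s\t%s\t%.12g", df$concept_id, df$gene_id, df$weight),
             con)
  invisible(path)
}

#' Read profiles written by [write_profiles()]
#' @param path file path.
#' @return A [profile_set()].
#' @export
read_profiles <- function(path) {
  df <- read.delim(path, colClasses = c("character", "character", "numeric"),
                   fileEncoding = "UTF-8")
  if (!identical(names(df), c("concept_id", "gene_id", "weight")))
    stop("expected header 'concept_id<TAB>gene_id<TAB>weight' in ", path)
  genes <- sort(unique(df$gene_id))
  concepts <- sort(unique(df$concept_id))
  W <- sparseMatrix(
    i = match(df$gene_id, genes), j = match(df$concept_id, concepts),
    x = df$weight, dims = c(length(genes), length(concepts)),
    dimnames = list(genes, concepts)
  )
  ps <- profile_set(as.matrix(W))
  ps
}
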