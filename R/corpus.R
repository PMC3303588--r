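#' Occurrence corpus
#'
#' A corpus of binary document-concept occurrences: a concept either appears
#' in a document or it does not; term frequencies are ignored. Internally a
#' sparse document-by-concept indicator matrix.
#'
#' @param doc_id character vector of document identifiers.
#' @param concept_id character vector of the same length; `concept_id[i]`
#'   occurs in `doc_id[i]`. Duplicate pairs are collapsed.
#' @return An object of class `occurrence_corpus` with fields `M` (sparse
#'   indicator matrix, documents in rows), `doc_ids`, `concept_ids`.
#' @export
occurrence_corpus <- function(doc_id, concept_id) {
  doc_id <- as.character(doc_id)
  concept_id <- as.character(concept_id)
  if (length(doc_id) != length(concept_id))
    stop("doc_id and concept_id must have the same length")
  if (length(doc_id) == 0L)
    stop("corpus is empty: at least one occurrence pair is required")
  if (any(!nzchar(doc_id)) || any(!nzchar(concept_id)))
    stop("empty document or concept identifier")
  docs <- sort(unique(doc_id))
  concepts <- sort(unique(concept_id))
  M <- sparseMatrix(
    i = match(doc_id, docs), j = match(concept_id, concepts), x = 1,
    dims = c(length(docs), length(concepts)),
    dimnames = list(docs, concepts)
  )
  # collapse duplicate pairs to a 0/1 indicator
  M <- as(M > 0, "CsparseMatrix") * 1
  structure(
    list(M = M, doc_ids = docs, concept_ids = concepts),
    class = "occurrence_corpus"
  )
}

#' @export
print.occurrence_corpus <- function(x, ...) {
  cat(sprintf(
    "<occurrence_corpus> %d documents, %d concepts, %d occurrence pairs\n",
    n_documents(x), length(x$concept_ids), length(x$M@x)
  ))
  invisible(x)
}

#' Number of documents in a corpus
#' @param corpus an [occurrence_corpus()].
#' @return Integer document count (the contingency total T).
#' @export
n_documents <- function(corpus) {
  stopifnot(inherits(corpus, "occurrence_corpus"))
  nrow(corpus$M)
}

# Document ids containing a concept (empty if the concept is unknown).
concept_docs <- function(corpus, concept) {
  if (!concept %in% corpus$concept_ids) return(character(0))
  corpus$doc_ids[corpus$M[, concept] > 0]
}

#' Read an occurrence corpus from TSV
#'
#' Expects a UTF-8 TSV with header `doc_id<TAB>concept_id`, one occurrence
#' pair per line. Duplicate pairs are collapsed.
#'
#' @param path file path.
#' @return An [occurrence_corpus()].
#' @export
read_occurrences <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    stop("empty occurrence file: ", path)
  if (!identical(strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]],
                 c("doc_id", "concept_id")))
    stop("expected header 'doc_id<TAB>concept_id' in ", path)
  if (length(lines) == 1L)
    stop("occurrence file has a header but no records: ", path)
  parts <- strsplit(lines[-1L], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 2L)) {
    bad <- which(nf != 2L)[1L] + 1L
    stop(sprintf("malformed occurrence line %d in %s (expected 2 fields)",
                 bad, path))
  }
  doc <- vapply(parts, `[[`, character(1), 1L)
  con <- vapply(parts, `[[`, character(1), 2L)
  corpus <- occurrence_corpus(doc, con)
  message(sprintf("read %d documents, %d concepts from %s",
                  n_documents(corpus), length(corpus$concept_ids), path))
  corpus
}

#' Write an occurrence corpus to TSV
#'
#' Inverse of [read_occurrences()]; the written file round-trips losslessly.
#'
#' @param corpus an [occurrence_corpus()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(corpus, path) {
  stopifnot(inherits(corpus, "occurrence_corpus"))
  idx <- Matrix::which(corpus$M > 0, arr.ind = TRUE)
  df <- data.frame(
    doc_id = corpus$doc_ids[idx[, 1L]],
    concept_id = corpus$concept_ids[idx[, 2L]],
    stringsAsFactors = FALSE
  )
  df <- df[order(df$doc_id, df$concept_id), ]
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("doc_id\tconcept_id", con)
  writeLines(paste(df$doc_id, df$concept_id, sep = "\t"), con)
  invisible(path)
}

#' Read a thesaurus from TSV
#'
#' Expects header `concept_id<TAB>name<TAB>class<TAB>synonyms`; synonyms are
#' `;`-separated (empty allowed); class must be one of `disease`, `gene`,
#' `other`. Gene-class entries define the profile vocabulary.
#'
#' @param path file path.
#' @return A `thesaurus` data frame with columns `concept_id`, `name`,
#'   `class`, `synonyms`.
#' @export
read_thesaurus <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty thesaurus file: ", path)
  if (!identical(strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]],
                 c("concept_id", "name", "class", "synonyms")))
    stop("expected header 'concept_id<TAB>name<TAB>class<TAB>synonyms' in ",
         path)
  parts <- strsplit(lines[-1L], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L | nf > 4L)) {
    bad <- which(nf < 3L | nf > 4L)[1L] + 1L
    stop(sprintf("malformed thesaurus line %d in %s", bad, path))
  }
  field <- function(p, i) if (length(p) >= i) p[[i]] else ""
  thesaurus(
    concept_id = vapply(parts, field, character(1), 1L),
    name = vapply(parts, field, character(1), 2L),
    class = vapply(parts, field, character(1), 3L),
    synonyms = vapply(parts, field, character(1), 4L)
  )
}

#' Construct a thesaurus
#'
#' @param concept_id,name,class character vectors of equal length; `class`
#'   values must lie in `disease`, `gene`, `other`.
#' @param synonyms character vector of `;`-separated synonyms (default none).
#' @return A `thesaurus` data frame.
#' @export
thesaurus <- function(concept_id, name, class,
                      synonyms = rep("", length(concept_id))) {
  concept_id <- as.character(concept_id)
  if (anyDuplicated(concept_id))
    stop("duplicate concept ids in thesaurus")
  class <- as.character(class)
  bad <- setdiff(unique(class), c("disease", "gene", "other"))
  if (length(bad))
    stop("unknown semantic class: ", paste(bad, collapse = ", "))
  out <- data.frame(
    concept_id = concept_id, name = as.character(name), class = class,
    synonyms = as.character(synonyms), stringsAsFactors = FALSE
  )
  class(out) <- c("thesaurus", "data.frame")
  out
}

#' Write a thesaurus to TSV
#' @param th a [thesaurus()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_thesaurus <- function(th, path) {
  stopifnot(inherits(th, "thesaurus"))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("concept_id\tname\tclass\tsynonyms", con)
  writeLines(paste(th$concept_id, th$name, th$class, th$synonyms, sep = "\t"),
             con)
  invisible(path)
}

#' Gene vocabulary of a thesaurus
#'
#' The ids of all gene-class entries; these are the dimensions along which
#' genetic concept profiles are built.
#'
#' @param th a [thesaurus()].
#' @return Character vector of gene concept ids.
#' @export
gene_vocabulary <- function(th) {
  stopifnot(inherits(th, "thesaurus"))
  th$concept_id[th$class == "gene"]
}

#' Map input concept names against a thesaurus
#'
#' A name is matched case-insensitively and exactly against canonical names
#' and synonyms. Names matching exactly one entry resolve to its concept id;
#' names matching several entries are ambiguous and must be excluded from
#' profile building; names matching nothing are unmapped.
#'
#' @param names non-empty character vector of input names.
#' @param th a [thesaurus()].
#' @return A `concept_mapping` list with fields `resolved` (named character:
#'   input name -> concept id), `ambiguous` (named list of candidate id
#'   vectors) and `unmapped` (character). The three partition `names`.
#' @export
map_concepts <- function(names, th) {
  stopifnot(inherits(th, "thesaurus"))
  names <- as.character(names)
  if (length(names) == 0L) stop("no input names to map")
  syn <- strsplit(th$synonyms, ";", fixed = TRUE)
  keys <- data.frame(
    key = tolower(c(th$name, unlist(syn))),
    id = c(th$concept_id, rep(th$concept_id, lengths(syn))),
    stringsAsFactors = FALSE
  )
  keys <- keys[nzchar(keys$key), ]
  resolved <- character(0)
  ambiguous <- list()
  unmapped <- character(0)
  for (nm in names) {
    hits <- unique(keys$id[keys$key == tolower(nm)])
    if (length(hits) == 1L) resolved[nm] <- hits
    else if (length(hits) > 1L) ambiguous[[nm]] <- sort(hits)
    else unmapped <- c(unmapped, nm)
  }
  if (length(ambiguous))
    warning("ambiguous concept name(s) excluded: ",
            paste(names(ambiguous), collapse = ", "), call. = FALSE)
  structure(
    list(resolved = resolved, ambiguous = ambiguous, unmapped = unmapped),
    class = "concept_mapping"
  )
}

#' @export
print.concept_mapping <- function(x, ...) {
  cat(sprintf("<concept_mapping> %d resolved, %d ambiguous, %d unmapped\n",
              length(x$resolved), length(x$ambiguous), length(x$unmapped)))
  invisible(x)
}

#' Document-level 2x2 contingency table for two concepts
#'
#' Cell `a` counts documents containing both concepts, `b` / `c` documents
#' with only the first / second, `d` documents with neither; `t = a+b+c+d`
#' equals the corpus document count. A concept absent from the corpus simply
#' occurs in zero documents.
#'
#' @param corpus an [occurrence_corpus()].
#' @param concept1,concept2 concept ids.
#' @return A `contingency_table` list with fields `a`, `b`, `c`, `d`, `t`.
#' @export
contingency <- function(corpus, concept1, concept2) {
  stopifnot(inherits(corpus, "occurrence_corpus"))
  d1 <- concept_docs(corpus, concept1)
  d2 <- concept_docs(corpus, concept2)
  a <- length(intersect(d1, d2))
  tt <- n_documents(corpus)
  structure(
    list(a = a, b = length(d1) - a, c = length(d2) - a,
         d = tt - length(d1) - length(d2) + a, t = tt),
    class = "contingency_table"
  )
}
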