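# Small fixtures built in code.

# A corpus where D1 co-occurs with G1 only, D2 with G1 and G2, and D3 with
# no gene at all; 6 documents.
tiny_corpus <- function() {
  pairs <- rbind(
    c("d1", "D1"), c("d1", "G1"),
    c("d2", "D1"), c("d2", "G1"),
    c("d3", "D2"), c("d3", "G1"),
    c("d4", "D2"), c("d4", "G2"),
    c("d5", "D3"),
    c("d6", "G2")
  )
  occurrence_corpus(pairs[, 1], pairs[, 2])
}

tiny_thesaurus <- function() {
  thesaurus(
    concept_id = c("D1", "D2", "D3", "G1", "G2"),
    name = c("lupus", "arthritis", "thyroiditis", "geneA", "geneB"),
    class = c("disease", "disease", "disease", "gene", "gene"),
    synonyms = c("sle", "ra;chronic arthritis", "", "gA", "gB")
  )
}

# Profile set with hand-picked unit vectors over 6 genes whose pairwise
# inner products are exactly 0.5, 0.2 and 0.3.
known_score_profiles <- function() {
  W <- matrix(0, 6, 3,
              dimnames = list(paste0("g", 1:6), c("p1", "p2", "p3")))
  W[, "p1"] <- c(sqrt(.5), sqrt(.2), 0, sqrt(.3), 0, 0)
  W[, "p2"] <- c(sqrt(.5), 0, sqrt(.3), 0, sqrt(.2), 0)
  W[, "p3"] <- c(0, sqrt(.2), sqrt(.3), 0, 0, sqrt(.5))
  profile_set(W)
}

write_tsv_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
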