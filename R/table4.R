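#' Reference table of intermediate-node counts
#'
#' The shipped 20-row table of intermediate nodes from the published
#' autoimmune-disease seed network: per node its background degree (`n_links`),
#' links to seeds (`seed_links`), the constant subnetwork link count K = 60
#' and background link count N = 11429, and the published z-score. Decimal
#' commas in the z column (the published dialect) are accepted.
#'
#' @param path optional path to an alternative table in the same format.
#' @return A data frame with columns `gene`, `n_links`, `background_links`,
#'   `seed_links`, `subnetwork_links`, `z`.
#' @export
table4_intermediates <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "table4_intermediates.tsv",
                        package = "gcpnet", mustWork = TRUE)
  df <- read.delim(path, colClasses = "character", fileEncoding = "UTF-8")
  expected <- c("gene", "n_links", "background_links", "seed_links",
                "subnetwork_links", "z")
  if (!identical(names(df), expected))
    stop("unexpected column layout in ", path)
  for (col in c("n_links", "background_links", "seed_links",
                "subnetwork_links"))
    df[[col]] <- as.integer(df[[col]])
  # tolerate the decimal-comma dialect of the published table
  df$z <- as.numeric(gsub(",", ".", df$z, fixed = TRUE))
  df
}

#' Verify the z statistic against the reference table
#'
#' Recomputes [intermediate_zscore()] for every row of
#' [table4_intermediates()] and compares with the published values: the
#' reconstruction is considered valid when every row agrees within 0.005,
#' the descending z order matches the published row order, and the
#' significant count at the published cutoff is reproduced.
#'
#' @param cutoff significance threshold on z (default 2.5, strict).
#' @param path optional alternative table, see [table4_intermediates()].
#' @return A `table4_verification` list: `table` (with recomputed `z_recomputed`
#'   and `deviation` columns), `max_abs_deviation`, `n_significant`,
#'   `nonsignificant` (gene symbols), `order_ok`.
#' @export
verify_table4 <- function(cutoff = 2.5, path = NULL) {
  tab <- table4_intermediates(path)
  tab$z_recomputed <- intermediate_zscore(
    tab$n_links, tab$seed_links,
    tab$subnetwork_links[1L], tab$background_links[1L]
  )
  tab$deviation <- tab$z_recomputed - tab$z
  sig <- tab$z_recomputed > cutoff
  structure(
    list(
      table = tab,
      max_abs_deviation = max(abs(tab$deviation)),
      n_significant = sum(sig),
      nonsignificant = tab$gene[!sig],
      order_ok = identical(order(-tab$z_recomputed), seq_len(nrow(tab)))
    ),
    class = "table4_verification"
  )
}

#' @export
print.table4_verification <- function(x, ...) {
  cat(sprintf(
    paste0("<table4_verification> %d rows; max |z deviation| %.4g; ",
           "%d significant (%s below cutoff); order %s\n"),
    nrow(x$table), x$max_abs_deviation, x$n_significant,
    if (length(x$nonsignificant)) paste(x$nonsignificant, collapse = ", ")
    else "none",
    if (x$order_ok) "reproduced" else "NOT reproduced"
  ))
  invisible(x)
}
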