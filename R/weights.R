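# Association weighting for concept profiles.
#
# The default weight is the symmetric uncertainty coefficient
#   U = 2 * MI / (H1 + H2)
# computed on the 2x2 document co-occurrence cell probabilities with natural
# logarithms (0 * log 0 == 0), clamped to zero when the observed
# co-occurrence rate a/T does not exceed the independence expectation
# (a+b)(a+c)/T^2. U is symmetric in the two concepts and bounded in [0, 1];
# it is 1 for perfect co-occurrence and 0 at (or below) independence.

# x * log(x / y) with the 0 log 0 convention; vectorised.
xlogxy <- function(x, y) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- x[pos] * log(x[pos] / y[pos])
  dim(out) <- dim(x)
  out
}

# Binary entropy of a marginal probability, natural log.
entropy2 <- function(p) {
  -(xlogxy(p, rep(1, length(p))) + xlogxy(1 - p, rep(1, length(p))))
}

# Vectorised symmetric uncertainty for cell count a with marginal counts
# n1, n2 out of T documents. All arguments recycle elementwise.
uncertainty_weight <- function(a, n1, n2, t) {
  p11 <- a / t
  p1 <- n1 / t
  p2 <- n2 / t
  mi <- xlogxy(p11, p1 * p2) +
    xlogxy(p1 - p11, p1 * (1 - p2)) +
    xlogxy(p2 - p11, (1 - p1) * p2) +
    xlogxy(1 - p1 - p2 + p11, (1 - p1) * (1 - p2))
  h <- entropy2(p1) + entropy2(p2)
  w <- numeric(length(mi))
  dim(w) <- dim(mi)
  degen <- h <= 0
  if (any(degen & (n1 > 0 | n2 > 0) & a > 0))
    warning("degenerate marginal entropy; weight set to 0", call. = FALSE)
  ok <- !degen
  w[ok] <- 2 * mi[ok] / h[ok]
  # negative or null association carries no weight
  w[p11 <= p1 * p2] <- 0
  pmin(pmax(w, 0), 1)
}

# Positive pointwise mutual information; 0 when a == 0.
pmi_weight <- function(a, n1, n2, t) {
  w <- numeric(length(a + n1 + n2))
  pos <- a > 0
  w[pos] <- pmax(0, log((a / t) / ((n1 / t) * (n2 / t)))[pos])
  dim(w) <- dim(a)
  w
}

#' Association weight from a 2x2 contingency table
#'
#' Converts document-level co-occurrence into a non-negative association
#' strength. `uncertainty` (the default) is the symmetric uncertainty
#' coefficient 2*MI/(H1+H2), clamped to 0 at or below independence; `pmi` is
#' positive pointwise mutual information; `raw` is the co-occurrence count
#' itself. All methods return 0 when the concepts never co-occur, and all are
#' symmetric in the two concepts.
#'
#' @param table a [contingency()] table.
#' @param method weighting scheme.
#' @return A single non-negative weight; `uncertainty` lies in `[0, 1]`.
#' @export
association_weight <- function(table,
                               method = c("uncertainty", "pmi", "raw")) {
  stopifnot(inherits(table, "contingency_table"))
  method <- match.arg(method)
  if (table$t <= 0) stop("contingency total must be positive")
  with(table, switch(method,
    uncertainty = uncertainty_weight(a, a + b, a + c, t),
    pmi = pmi_weight(a, a + b, a + c, t),
    raw = as.numeric(a)
  ))
}
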