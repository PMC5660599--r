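# Shared-interaction-partner scoring: every interacting pair is weighted by
# the significance of the overlap of their neighbor sets, measured as the
# -log10 upper-tail p-value of a hypergeometric test. The two endpoints are
# excluded from both neighbor sets and from the universe (their mutual edge
# is already the evidence that gates which pairs get scored); both choices
# are exposed as arguments.

# upper-tail P(X >= q) for overlap q of two neighbor sets of sizes deg_a and
# deg_b in a universe of size n_universe, in log10 space. The tail is
# symmetric in (deg_a, deg_b); the arguments are ordered canonically so that
# score(a, b) == score(b, a) bit-exactly.
hyper_upper_log10 <- function(q, deg_a, deg_b, n_universe) {
  hi <- pmax(deg_a, deg_b)
  lo <- pmin(deg_a, deg_b)
  # phyper(q - 1, ..., lower.tail = FALSE) = P(X >= q); log space avoids
  # underflow for large hubs
  stats::phyper(q - 1, hi, pmax(n_universe - hi, 0), lo,
                lower.tail = FALSE, log.p = TRUE) / log(10)
}

SCORE_CAP <- 300  # -log10 p capped where p underflows below 1e-300

#' Shared-partner score for one pair of network proteins
#'
#' Tests whether proteins `a` and `b` share more interaction partners than
#' expected by chance. With both endpoints excluded, the universe holds
#' `N = n_nodes - 2` proteins, of which `deg_a` are partners of `a`; the
#' `deg_b` partners of `b` are the draws, and the upper-tail hypergeometric
#' probability of seeing at least the observed number of shared partners is
#' transformed to `score = -log10(p)`.
#'
#' @param network A `ppi_network`.
#' @param a,b Distinct gene identifiers present in the network.
#' @param exclude_pair Exclude `a` and `b` from both neighbor sets (default
#'   `TRUE`).
#' @param universe `"network"` (all network nodes, minus the excluded pair)
#'   or a character vector giving an explicit universe.
#' @return One-row tibble: `gene_a`, `gene_b`, `score`, `p_log10`, `deg_a`,
#'   `deg_b`, `n_shared`, `universe_size`.
#' @export
shared_partner_score <- function(network, a, b, exclude_pair = TRUE,
                                 universe = "network") {
  if (a == b) stop("a and b must be distinct")
  if (!all(c(a, b) %in% network$nodes)) stop("a and b must be network nodes")
  e <- network$edges
  nbrs <- function(g) unique(c(e$gene_b[e$gene_a == g], e$gene_a[e$gene_b == g]))
  na_ <- nbrs(a)
  nb_ <- nbrs(b)
  if (identical(universe, "network")) {
    uni <- network$nodes
  } else {
    uni <- as.character(universe)
    na_ <- intersect(na_, uni)
    nb_ <- intersect(nb_, uni)
  }
  if (exclude_pair) {
    na_ <- setdiff(na_, c(a, b))
    nb_ <- setdiff(nb_, c(a, b))
    uni <- setdiff(uni, c(a, b))
  }
  q <- length(intersect(na_, nb_))
  lp <- hyper_upper_log10(q, length(na_), length(nb_), length(uni))
  tibble::tibble(
    gene_a = min(a, b), gene_b = max(a, b),
    score = min(-lp, SCORE_CAP), p_log10 = lp,
    deg_a = length(na_), deg_b = length(nb_),
    n_shared = q, universe_size = length(uni)
  )
}

#' Weight every network edge by shared-partner significance
#'
#' Assigns each existing edge the [shared_partner_score()] of its endpoints.
#' Non-edges are never scored: direct interaction evidence is required before
#' a pair carries interaction weight. Two proteins that interact and share
#' all their partners score higher than two that interact but share none.
#'
#' @param network A non-empty `ppi_network`.
#' @inheritParams shared_partner_score
#' @return The network with a `score` column on its edges.
#' @export
weight_network <- function(network, exclude_pair = TRUE) {
  e <- network$edges
  if (!nrow(e)) stop("cannot weight an empty network")
  nodes <- network$nodes
  n <- length(nodes)
  ia <- match(e$gene_a, nodes)
  ib <- match(e$gene_b, nodes)
  adj <- Matrix::sparseMatrix(i = c(ia, ib), j = c(ib, ia),
                              x = 1, dims = c(n, n))
  deg <- Matrix::rowSums(adj)
  # common neighbors of (a, b): never include a or b themselves because the
  # graph is simple (no self-loops)
  shared <- as.numeric((adj %*% adj)[cbind(ia, ib)])
  if (exclude_pair) {
    deg_a <- deg[ia] - 1  # remove b from N(a), a from N(b)
    deg_b <- deg[ib] - 1
    uni <- n - 2
  } else {
    deg_a <- deg[ia]
    deg_b <- deg[ib]
    uni <- n
  }
  lp <- hyper_upper_log10(shared, deg_a, deg_b, uni)
  network$edges$score <- pmin(-lp, SCORE_CAP)
  network
}
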