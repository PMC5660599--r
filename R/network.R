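#' Construct a protein-protein interaction network
#'
#' An undirected simple graph over gene identifiers, stored as an edge-list
#' tibble with canonically ordered endpoints (`gene_a < gene_b`). Self-loops
#' and duplicate edges are rejected; use [read_network()] for permissive
#' parsing of raw edge lists.
#'
#' @param edges Data frame with character columns `gene_a` and `gene_b`, and
#'   optionally `score` (non-negative shared-partner edge weight).
#' @param nodes Optional character vector of node identifiers; the union of
#'   `nodes` and all edge endpoints is used, so isolated nodes can be declared.
#' @return An object of class `ppi_network`: a list with elements `nodes`
#'   (character) and `edges` (tibble).
#' @export
#' @examples
#' ppi_network(data.frame(gene_a = c("A", "B"), gene_b = c("B", "C")))
ppi_network <- function(edges, nodes = NULL) {
  edges <- tibble::as_tibble(edges)
  if (nrow(edges)) {
    a <- as.character(edges$gene_a)
    b <- as.character(edges$gene_b)
    if (any(a == b)) stop("self-loops are not allowed in a ppi_network")
    o <- orient_pairs(a, b)
    edges$gene_a <- o$gene_a
    edges$gene_b <- o$gene_b
    if (anyDuplicated(pair_key(o$gene_a, o$gene_b))) {
      stop("duplicate edges (in either order) are not allowed")
    }
    edges <- dplyr::arrange(edges, .data$gene_a, .data$gene_b)
  } else {
    edges <- tibble::tibble(gene_a = character(), gene_b = character())
  }
  nodes <- sort(unique(c(as.character(nodes), edges$gene_a, edges$gene_b)))
  structure(list(nodes = nodes, edges = edges), class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("ppi_network: %d nodes, %d edges%s\n",
              length(x$nodes), nrow(x$edges),
              if ("score" %in% names(x$edges)) " (weighted)" else ""))
  invisible(x)
}

#' Number of nodes / edges of a network
#' @param x A `ppi_network`.
#' @return Integer count.
#' @export
n_nodes <- function(x) length(x$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(x) nrow(x$edges)

# igraph view (vertex names = gene ids), used for triangle enumeration
as_igraph <- function(x) {
  igraph::graph_from_data_frame(
    x$edges[, c("gene_a", "gene_b")],
    directed = FALSE,
    vertices = data.frame(name = x$nodes)
  )
}
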