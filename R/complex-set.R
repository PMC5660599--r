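#' Construct a set of protein complexes
#'
#' A `complex_set` is a tibble with one row per complex: a unique `complex`
#' name, a `members` list-column of gene identifiers, the member count `n`,
#' and optionally the per-complex LLR score decomposition (`llr_expr`,
#' `llr_int`, `llr_integrated`). Reference catalogues may contain overlapping
#' complexes (`disjoint = FALSE`); discovered complexes are disjoint.
#'
#' @param members Named list of character vectors of gene identifiers.
#'   Members are deduplicated within each complex.
#' @param scores Optional data frame with columns `llr_expr`, `llr_int`,
#'   `llr_integrated`, one row per complex (in the same order as `members`).
#' @param disjoint Logical; if `TRUE`, no gene may appear in two complexes
#'   (checked).
#' @param description Optional character vector of free-text descriptions.
#' @return A tibble of class `complex_set` with attribute `disjoint`.
#' @export
#' @examples
#' complex_set(list(C1 = c("A", "B", "C"), C2 = c("D", "E")))
complex_set <- function(members, scores = NULL, disjoint = FALSE,
                        description = NULL) {
  stopifnot(is.list(members))
  if (length(members) == 0L) {
    out <- tibble::tibble(complex = character(), members = list(),
                          n = integer())
    if (!is.null(scores)) {
      out$llr_expr <- numeric()
      out$llr_int <- numeric()
      out$llr_integrated <- numeric()
    }
    return(structure(out, disjoint = disjoint,
                     class = c("complex_set", class(out))))
  }
  if (is.null(names(members)) || anyDuplicated(names(members)) ||
      any(!nzchar(names(members)))) {
    stop("complexes must have unique, non-empty names")
  }
  members <- lapply(members, function(m) unique(as.character(m)))
  if (any(lengths(members) == 0L)) stop("complex member sets must be non-empty")
  if (disjoint && anyDuplicated(unlist(members, use.names = FALSE))) {
    stop("disjoint complex set contains a gene assigned to two complexes")
  }
  out <- tibble::tibble(
    complex = names(members),
    members = unname(members),
    n = lengths(members)
  )
  if (!is.null(description)) out$description <- description
  if (!is.null(scores)) {
    stopifnot(nrow(scores) == nrow(out))
    out$llr_expr <- scores$llr_expr
    out$llr_int <- scores$llr_int
    out$llr_integrated <- scores$llr_integrated
  }
  structure(out, disjoint = disjoint,
            class = c("complex_set", class(out)))
}

#' Is a complex set flagged disjoint?
#' @param x A `complex_set`.
#' @return Logical flag.
#' @export
is_disjoint <- function(x) isTRUE(attr(x, "disjoint"))

#' @export
print.complex_set <- function(x, ...) {
  cat(sprintf("# A complex_set: %d complexes, %d genes%s\n",
              nrow(x), length(unique(unlist(x$members))),
              if (is_disjoint(x)) " (disjoint)" else ""))
  NextMethod()
  invisible(x)
}

# named list view of the member sets
complex_members <- function(x) stats::setNames(x$members, x$complex)
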