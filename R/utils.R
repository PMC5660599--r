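#' @keywords internal
"_PACKAGE"

#' @importFrom Rcpp sourceCpp
#' @useDynLib coregcomplex, .registration = TRUE
#' @importFrom rlang .data
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

# canonical unordered pair key: two id vectors -> "smaller\texplicit sep\tlarger"
pair_key <- function(a, b) {
  swap <- a > b
  tmp <- a[swap]
  a[swap] <- b[swap]
  b[swap] <- tmp
  paste(a, b, sep = "\t")
}

# order the two id columns of a pair tibble so that gene_a < gene_b
orient_pairs <- function(a, b) {
  swap <- a > b
  tmp <- a[swap]
  a[swap] <- b[swap]
  b[swap] <- tmp
  list(gene_a = a, gene_b = b)
}

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot
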