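# Expression-matrix cleaning and the pairwise correlation table that all
# downstream scoring consumes. The documented pipeline order is
# collapse_isoforms() -> filter_missing() -> (log2_transform() when the input
# is on a ratio/intensity scale), then pairwise_correlation().

#' Drop proteins with too many missing values
#'
#' Retains exactly the genes whose missing fraction is `<= max_missing_frac`;
#' genes missing in strictly more than that fraction of samples are dropped
#' (a gene missing in exactly 40% of samples is kept under the default).
#'
#' @param x Numeric genes-by-samples matrix (`NA` = missing).
#' @param max_missing_frac Maximum tolerated missing fraction in `[0, 1]`;
#'   default 0.4.
#' @return The filtered matrix; the number of dropped genes is reported with
#'   a message.
#' @export
filter_missing <- function(x, max_missing_frac = 0.4) {
  stopifnot(is.matrix(x), max_missing_frac >= 0, max_missing_frac <= 1)
  frac <- rowMeans(is.na(x))
  keep <- frac <= max_missing_frac
  if (any(!keep)) {
    message("filter_missing: dropped ", sum(!keep), " of ", nrow(x), " genes")
  }
  x[keep, , drop = FALSE]
}

#' Collapse protein isoforms to gene-level profiles
#'
#' Rows mapping to the same gene are averaged per sample with missing values
#' ignored; a sample where every isoform is missing stays missing. Rows absent
#' from the map are dropped with a warning.
#'
#' @param x Numeric matrix whose rownames are isoform/protein identifiers.
#' @param isoform_to_gene Named character vector mapping row identifiers to
#'   gene identifiers (see [read_alias_map()]).
#' @return Numeric matrix with one row per gene, rows ordered by first
#'   appearance of each gene.
#' @export
collapse_isoforms <- function(x, isoform_to_gene) {
  stopifnot(is.matrix(x))
  if (!length(isoform_to_gene)) stop("empty isoform-to-gene map")
  mapped <- rownames(x) %in% names(isoform_to_gene)
  if (any(!mapped)) {
    warning("dropping ", sum(!mapped), " unmapped row(s)")
    x <- x[mapped, , drop = FALSE]
  }
  if (!nrow(x)) return(x)
  gene <- unname(isoform_to_gene[rownames(x)])
  glev <- unique(gene)
  obs <- !is.na(x)
  vals <- x
  vals[!obs] <- 0
  gfac <- factor(gene, levels = glev)
  sums <- rowsum(vals, gfac, reorder = FALSE)
  counts <- rowsum(obs + 0, gfac, reorder = FALSE)
  out <- sums / counts  # 0/0 -> NaN where all isoforms missing
  out[counts == 0] <- NA
  rownames(out) <- glev
  out
}

#' Log2-transform an expression matrix
#'
#' Elementwise `log2`; missing values are preserved. Intended for SILAC
#' ratios or raw LFQ intensities, which must be strictly positive.
#'
#' @param x Numeric matrix with all observed values `> 0`.
#' @return The transformed matrix.
#' @export
log2_transform <- function(x) {
  stopifnot(is.matrix(x))
  bad <- which(!is.na(x) & x <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    show <- utils::head(bad, 5)
    stop("non-positive value(s) cannot be log2-transformed: ",
         paste(sprintf("[%s, %s]", rownames(x)[show[, 1]],
                       colnames(x)[show[, 2]]), collapse = ", "))
  }
  log2(x)
}

# gene x gene Pearson matrix on pairwise-complete samples, entries with
# overlap < min_overlap (or undefined r) set to NA; used by the discovery
# fast path. Returns list(r = matrix, n = overlap-count matrix).
correlation_matrices <- function(x, min_overlap = 10) {
  obs <- !is.na(x)
  n_overlap <- tcrossprod(obs + 0)
  r <- suppressWarnings(stats::cor(t(x), use = "pairwise.complete.obs"))
  r[n_overlap < min_overlap] <- NA
  list(r = r, n = n_overlap)
}

#' Pairwise Pearson correlations over pairwise-complete samples
#'
#' Computes the Pearson correlation between gene expression profiles using,
#' for each pair, the samples where both genes are observed. Pairs with fewer
#' than `min_overlap` shared samples, or with a zero-variance profile over
#' the overlap, are omitted from the table (downstream they contribute zero
#' expression evidence rather than being penalized).
#'
#' @param x Numeric genes-by-samples matrix (`NA` = missing).
#' @param pairs Optional two-column data frame (`gene_a`, `gene_b`) limiting
#'   the computation; default all unordered gene pairs.
#' @param min_overlap Minimum number of shared observed samples for a
#'   correlation to be defined (default 10, must be >= 3).
#' @return Tibble with columns `gene_a`, `gene_b` (`gene_a < gene_b`), `r`,
#'   `n_overlap`.
#' @export
#' @examples
#' m <- rbind(g1 = c(1, 2, 3, 4), g2 = c(2, 4, 6, 8), g3 = c(4, 3, 2, 1))
#' colnames(m) <- paste0("s", 1:4)
#' pairwise_correlation(m, min_overlap = 3)
pairwise_correlation <- function(x, pairs = NULL, min_overlap = 10) {
  stopifnot(is.matrix(x), min_overlap >= 3)
  if (anyDuplicated(rownames(x))) {
    stop("duplicate gene IDs; collapse isoforms before correlating")
  }
  cm <- correlation_matrices(x, min_overlap)
  if (is.null(pairs)) {
    idx <- which(upper.tri(cm$r), arr.ind = TRUE)
    a <- rownames(x)[idx[, 1]]
    b <- rownames(x)[idx[, 2]]
    r <- cm$r[idx]
    n <- cm$n[idx]
  } else {
    o <- orient_pairs(as.character(pairs$gene_a), as.character(pairs$gene_b))
    a <- o$gene_a
    b <- o$gene_b
    i <- match(a, rownames(x))
    j <- match(b, rownames(x))
    ok <- !is.na(i) & !is.na(j)
    a <- a[ok]; b <- b[ok]; i <- i[ok]; j <- j[ok]
    r <- cm$r[cbind(i, j)]
    n <- cm$n[cbind(i, j)]
  }
  keep <- !is.na(r)
  if (any(!keep)) {
    message("pairwise_correlation: ", sum(!keep),
            " pair(s) undefined (low overlap or zero variance)")
  }
  o <- orient_pairs(a[keep], b[keep])
  tibble::tibble(gene_a = o$gene_a, gene_b = o$gene_b,
                 r = r[keep], n_overlap = as.integer(n[keep])) |>
    dplyr::arrange(.data$gene_a, .data$gene_b)
}
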