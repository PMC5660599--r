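# Readers and writers for the plain-text dialects the pipeline consumes:
# genes x samples TSV matrices, 2-column edge lists, GMT gene sets, MAF-lite
# mutation tables, GISTIC-style integer copy-number matrices, sample
# annotations and gene -> chromosome maps. All readers are strict about the
# documented dialect and never reorder samples relative to file order.

check_rectangular <- function(path) {
  nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(nf) && length(unique(nf)) != 1L) {
    bad <- which(nf != nf[1])[1]
    stop(sprintf("ragged TSV '%s': line %d has %d fields, expected %d",
                 path, bad, nf[bad], nf[1]))
  }
  invisible(nf)
}

read_tsv_char <- function(path) {
  check_rectangular(path)
  utils::read.delim(path, header = FALSE, sep = "\t", quote = "",
                    colClasses = "character", check.names = FALSE,
                    na.strings = character(), comment.char = "",
                    stringsAsFactors = FALSE)
}

#' Read a genes-by-samples expression matrix from TSV
#'
#' The first column holds gene identifiers, the header row holds sample
#' identifiers. Empty cells or any of `missing_tokens` are read as missing.
#' Duplicate gene-identifier rows are preserved (collapsing protein isoforms
#' to gene level is a separate preprocessing step, [collapse_isoforms()]);
#' duplicate sample identifiers are an error.
#'
#' @param path Path to a TSV file.
#' @param missing_tokens Character values treated as missing (default: the
#'   empty string and `"NA"`).
#' @return Numeric matrix with gene rownames and sample colnames; missing
#'   entries are `NA`.
#' @export
read_expression_matrix <- function(path, missing_tokens = c("", "NA")) {
  tab <- read_tsv_char(path)
  if (nrow(tab) < 1L || ncol(tab) < 2L) {
    stop("expression file needs a header row and at least one gene/sample: ", path)
  }
  samples <- as.character(tab[1, -1])
  if (anyDuplicated(samples)) {
    stop("duplicate sample IDs in header: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  genes <- as.character(tab[-1, 1])
  raw <- as.matrix(tab[-1, -1, drop = FALSE])
  raw[raw %in% missing_tokens] <- NA_character_
  vals <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(vals) & !is.na(raw))
  if (length(bad)) {
    stop("non-numeric expression value(s), e.g. '", raw[bad[1]], "'")
  }
  matrix(vals, nrow = length(genes), dimnames = list(genes, samples))
}

#' Write an expression matrix as TSV
#'
#' Values are serialized with `%.17g` so that a write-then-read round trip
#' reproduces doubles bit-exactly; missing entries are written as `na`.
#'
#' @param x Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @param na Token used for missing values.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path, na = "NA") {
  chr <- matrix(sprintf("%.17g", x), nrow = nrow(x))
  chr[is.na(x)] <- na
  lines <- c(
    paste(c("gene_id", colnames(x)), collapse = "\t"),
    paste(rownames(x), apply(chr, 1, paste, collapse = "\t"), sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read an interaction network from a 2-column edge list
#'
#' Each line names two interacting genes (an optional third column is
#' ignored). Self-loops are dropped with a message; duplicate edges in either
#' order are deduplicated.
#'
#' @param path Path to a TSV edge list.
#' @return A [ppi_network()].
#' @export
read_network <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(ppi_network(tibble::tibble(gene_a = character(), gene_b = character())))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 2L)
  if (length(short)) {
    stop(sprintf("edge list '%s': line %d has fewer than 2 fields", path, short[1]))
  }
  a <- vapply(parts, `[[`, character(1), 1L)
  b <- vapply(parts, `[[`, character(1), 2L)
  loops <- a == b
  if (any(loops)) {
    message("dropped ", sum(loops), " self-loop(s)")
    a <- a[!loops]
    b <- b[!loops]
  }
  o <- orient_pairs(a, b)
  keep <- !duplicated(pair_key(o$gene_a, o$gene_b))
  ppi_network(tibble::tibble(gene_a = o$gene_a[keep], gene_b = o$gene_b[keep]))
}

#' Write a network edge list (optionally with edge scores)
#' @param x A `ppi_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(x, path) {
  e <- x$edges
  if ("score" %in% names(e)) {
    lines <- paste(e$gene_a, e$gene_b, sprintf("%.10g", e$score), sep = "\t")
  } else {
    lines <- paste(e$gene_a, e$gene_b, sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

parse_gmt_scores <- function(desc) {
  out <- list(llr_expr = NA_real_, llr_int = NA_real_, llr_integrated = NA_real_)
  if (!grepl("=", desc, fixed = TRUE)) return(out)
  for (kv in strsplit(desc, ";", fixed = TRUE)[[1]]) {
    parts <- strsplit(kv, "=", fixed = TRUE)[[1]]
    if (length(parts) == 2 && parts[1] %in% names(out)) {
      out[[parts[1]]] <- suppressWarnings(as.numeric(parts[2]))
    }
  }
  out
}

#' Read a gene-set catalogue in GMT format
#'
#' One complex per line: name, description, then member genes, tab-separated.
#' Members repeated on a line are deduplicated within the set; complexes may
#' overlap (the result is flagged non-disjoint). Per-complex LLR scores
#' written by [write_complexes()] are recovered from `key=value` pairs in the
#' description field.
#'
#' @param path Path to a GMT file.
#' @return A [complex_set()] with `disjoint = FALSE`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(complex_set(stats::setNames(list(), character()), disjoint = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short)) {
    stop(sprintf("GMT '%s': line %d has fewer than 3 fields", path, short[1]))
  }
  nm <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate complex names in GMT: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  desc <- vapply(parts, `[[`, character(1), 2L)
  members <- stats::setNames(lapply(parts, function(p) unique(p[-(1:2)])), nm)
  scores <- do.call(rbind, lapply(desc, function(d) tibble::as_tibble(parse_gmt_scores(d))))
  has_scores <- any(!is.na(scores$llr_integrated))
  complex_set(members,
              scores = if (has_scores) scores else NULL,
              disjoint = FALSE, description = desc)
}

#' Write a complex set as GMT
#'
#' Per-complex LLR scores, when present, are serialized into the description
#' field as `key=value` pairs (kept GMT-valid).
#'
#' @param x A `complex_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_complexes <- function(x, path) {
  if (!nrow(x)) {
    writeLines(character(), path)
    return(invisible(path))
  }
  desc <- if ("llr_integrated" %in% names(x)) {
    sprintf("llr_expr=%.10g;llr_int=%.10g;llr_integrated=%.10g",
            x$llr_expr, x$llr_int, x$llr_integrated)
  } else if ("description" %in% names(x)) {
    x$description
  } else {
    rep(".", nrow(x))
  }
  lines <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(x$complex[i], desc[i], x$members[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a GISTIC-style integer copy-number matrix
#'
#' Same layout as [read_expression_matrix()] but entries must be integer
#' calls in `{-2, -1, 0, 1, 2}` (-2 homozygous deletion, -1 hemizygous
#' deletion, 0 neutral, 1 gain, 2 amplification); anything else is an error.
#'
#' @param path Path to a TSV file.
#' @return Integer matrix with gene rownames and sample colnames.
#' @export
read_copy_number <- function(path) {
  tab <- read_tsv_char(path)
  if (nrow(tab) < 2L || ncol(tab) < 2L) stop("copy-number file is empty: ", path)
  samples <- as.character(tab[1, -1])
  if (anyDuplicated(samples)) stop("duplicate sample IDs in header")
  genes <- as.character(tab[-1, 1])
  raw <- as.matrix(tab[-1, -1, drop = FALSE])
  vals <- suppressWarnings(as.integer(raw))
  ok <- !is.na(vals) & vals %in% -2:2 & as.character(vals) == trimws(raw)
  if (!all(ok)) {
    stop("copy-number entry outside {-2,...,2}: '", raw[which(!ok)[1]], "'")
  }
  matrix(vals, nrow = length(genes), dimnames = list(genes, samples))
}

# closed vocabulary + common aliases (MAF-style names, case-insensitive)
mutation_class_aliases <- c(
  missense = "missense", missense_mutation = "missense",
  splice_site = "splice_site", splice_site_mutation = "splice_site",
  splice = "splice_site",
  insertion = "insertion", ins = "insertion",
  frame_shift_ins = "insertion", in_frame_ins = "insertion",
  deletion = "deletion", del = "deletion",
  frame_shift_del = "deletion", in_frame_del = "deletion",
  nonsense = "nonsense", nonsense_mutation = "nonsense",
  synonymous = "synonymous", silent = "synonymous",
  synonymous_mutation = "synonymous",
  other = "other"
)

normalize_mutation_class <- function(x) {
  key <- tolower(trimws(x))
  out <- unname(mutation_class_aliases[key])
  unknown <- is.na(out)
  if (any(unknown)) {
    warning("unknown mutation class(es) mapped to 'other': ",
            paste(unique(x[unknown]), collapse = ", "))
    out[unknown] <- "other"
  }
  out
}

#' Read a MAF-lite mutation table
#'
#' Expects a header row and three columns: `sample_id`, `gene_id`,
#' `mutation_class` (matched by name if present, otherwise taken
#' positionally). Mutation classes are normalized to the closed vocabulary
#' `missense`, `splice_site`, `insertion`, `deletion`, `nonsense`,
#' `synonymous`, `other`; unknown strings map to `other` with a warning.
#' Multiple hits per (sample, gene) are allowed.
#'
#' @param path Path to a TSV file.
#' @return Tibble with columns `sample_id`, `gene_id`, `mutation_class`.
#' @export
read_mutations <- function(path) {
  tab <- read_tsv_char(path)
  if (ncol(tab) < 3L) stop("mutation table needs at least 3 columns: ", path)
  header <- as.character(tab[1, ])
  idx <- match(c("sample_id", "gene_id", "mutation_class"), header)
  if (anyNA(idx)) idx <- 1:3
  body <- tab[-1, , drop = FALSE]
  out <- tibble::tibble(
    sample_id = as.character(body[[idx[1]]]),
    gene_id = as.character(body[[idx[2]]]),
    mutation_class = if (nrow(body)) normalize_mutation_class(body[[idx[3]]]) else character()
  )
  out
}

#' Read sample subtype annotations
#'
#' First column `sample_id`, second column `subtype`; any further columns are
#' kept as covariates. Duplicate sample identifiers are an error.
#'
#' @param path Path to a TSV file with a header row.
#' @return Tibble with at least `sample_id` and `subtype`.
#' @export
read_annotations <- function(path) {
  check_rectangular(path)
  tab <- utils::read.delim(path, sep = "\t", quote = "", check.names = FALSE,
                           colClasses = "character")
  names(tab)[1:2] <- c("sample_id", "subtype")
  if (anyDuplicated(tab$sample_id)) stop("duplicate sample IDs in annotations")
  tibble::as_tibble(tab)
}

#' Read a gene-to-chromosome map
#'
#' Two tab-separated columns: gene identifier, chromosome label. A gene
#' mapped to two different chromosomes is an error; identical duplicate rows
#' are deduplicated.
#'
#' @param path Path to a TSV file (no header).
#' @return Named character vector: chromosome label per gene.
#' @export
read_chromosomes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2L)) stop("chromosome map line with fewer than 2 fields")
  gene <- vapply(parts, `[[`, character(1), 1L)
  chrom <- vapply(parts, `[[`, character(1), 2L)
  dup <- duplicated(paste(gene, chrom, sep = "\t"))
  gene <- gene[!dup]
  chrom <- chrom[!dup]
  if (anyDuplicated(gene)) {
    stop("gene mapped to multiple chromosomes: ",
         paste(unique(gene[duplicated(gene)]), collapse = ", "))
  }
  stats::setNames(chrom, gene)
}

#' Write a gene-to-chromosome map
#' @param map Named character vector (chromosome per gene).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chromosomes <- function(map, path) {
  writeLines(paste(names(map), map, sep = "\t"), path)
  invisible(path)
}

#' Read a protein/isoform-to-gene alias map
#'
#' Two tab-separated columns: row identifier (e.g. protein isoform),
#' gene identifier. Suitable as the `isoform_to_gene` argument of
#' [collapse_isoforms()].
#'
#' @param path Path to a TSV file (no header).
#' @return Named character vector: gene per row identifier.
#' @export
read_alias_map <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2L)) stop("alias map line with fewer than 2 fields")
  stats::setNames(vapply(parts, `[[`, character(1), 2L),
                  vapply(parts, `[[`, character(1), 1L))
}
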