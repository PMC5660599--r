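# Inference on top of a complex catalogue: subtype-specific complex
# expression (a rank-based variant of 1D annotation enrichment),
# genotype-associated collateral loss of complex abundance (within-sample
# mean-rank Mann-Whitney tests), reference-catalogue overlap, and the
# isogenic differential-expression pipeline.

#' Mann-Whitney U test
#'
#' The U statistic counts, over all cross pairs, how often an `x` value
#' exceeds a `y` value (ties count one half). The p-value is exact (via the
#' null U distribution) when `n_x + n_y <= 12` and there are no ties, and a
#' normal approximation with tie correction and continuity correction
#' otherwise. When every value is tied across both groups, `p = 1`.
#'
#' @param x,y Numeric vectors, both non-empty.
#' @param alternative `"less"` (x stochastically smaller), `"greater"`, or
#'   `"two_sided"`.
#' @return Named list: `U` (statistic for `x`), `p`.
#' @export
#' @examples
#' mann_whitney(c(1, 2), c(3, 4), "less")  # p = 1/6
mann_whitney <- function(x, y, alternative = c("two_sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  nx <- length(x)
  ny <- length(y)
  stopifnot(nx > 0, ny > 0)
  all_v <- c(x, y)
  r <- rank(all_v)
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  n <- nx + ny
  ties <- table(all_v)
  has_ties <- any(ties > 1)
  if (all(ties == n)) {
    return(list(U = u, p = 1))
  }
  if (!has_ties && n <= 12) {
    p_less <- stats::pwilcox(u, nx, ny)                    # P(U <= u)
    p_greater <- stats::pwilcox(u - 1, nx, ny, lower.tail = FALSE)
    p <- switch(alternative,
                less = p_less,
                greater = p_greater,
                two_sided = min(1, 2 * min(p_less, p_greater)))
  } else {
    mu <- nx * ny / 2
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma <- sqrt(nx * ny / 12 * ((n + 1) - tie_term))
    if (sigma == 0) return(list(U = u, p = 1))
    p_less <- stats::pnorm((u - mu + 0.5) / sigma)
    p_greater <- stats::pnorm((u - mu - 0.5) / sigma, lower.tail = FALSE)
    p <- switch(alternative,
                less = p_less,
                greater = p_greater,
                two_sided = min(1, 2 * min(p_less, p_greater)))
  }
  list(U = u, p = p)
}

#' Benjamini-Hochberg q-values
#'
#' Standard step-up adjustment (wraps [stats::p.adjust()]).
#'
#' @param p Numeric vector of p-values in `(0, 1]`.
#' @return q-values, same length and order as `p`.
#' @export
benjamini_hochberg <- function(p) {
  stopifnot(all(is.na(p) | (p > 0 & p <= 1)))
  stats::p.adjust(p, method = "BH")
}

# rank-biserial effect size from the U statistic: +1 when every x exceeds
# every y, -1 in the opposite extreme (the s-score operationalization)
rank_biserial <- function(u, nx, ny) 2 * u / (nx * ny) - 1

#' Subtype-specific complex expression
#'
#' A rank-based variant of 1D annotation enrichment. For each subtype, every
#' protein gets a median difference: its median expression in the subtype's
#' samples minus its median in all other samples. For each complex with more
#' than two measured members, a two-sided Mann-Whitney test compares the
#' member median-differences against all non-members', asking whether the
#' complex sits at one extreme of the ranked protein list; the effect size is
#' the rank-biserial s-score in `[-1, 1]` (positive = complex up in the
#' subtype). BH correction is applied across all complex-by-subtype tests.
#'
#' @param expr Genes-by-samples expression matrix.
#' @param ann Tibble with `sample_id`, `subtype` (see [read_annotations()]).
#' @param complexes A `complex_set`.
#' @param fdr_target Significance threshold on the BH q-value (default 0.10).
#' @return Tibble: `complex`, `subtype`, `n_members`, `s_score`, `p`, `q`,
#'   `significant`, sorted by `p`.
#' @export
subtype_complex_enrichment <- function(expr, ann, complexes,
                                       fdr_target = 0.10) {
  samples <- intersect(colnames(expr), ann$sample_id)
  if (length(samples) < 4) stop("too few annotated samples")
  subtype <- ann$subtype[match(samples, ann$sample_id)]
  subtypes <- sort(unique(subtype))
  if (length(subtypes) < 2) stop("need at least 2 subtypes")
  x <- expr[, samples, drop = FALSE]
  genes <- rownames(x)

  rows <- purrr::map(subtypes, function(s) {
    in_s <- subtype == s
    med_diff <- apply(x[, in_s, drop = FALSE], 1, stats::median, na.rm = TRUE) -
      apply(x[, !in_s, drop = FALSE], 1, stats::median, na.rm = TRUE)
    med_diff <- med_diff[is.finite(med_diff)]
    purrr::map(seq_len(nrow(complexes)), function(k) {
      members <- intersect(complexes$members[[k]], names(med_diff))
      if (length(members) <= 2) return(NULL)   # needs > 2 measured members
      mv <- med_diff[members]
      ov <- med_diff[setdiff(names(med_diff), members)]
      mw <- mann_whitney(mv, ov, "two_sided")
      tibble::tibble(
        complex = complexes$complex[k], subtype = s,
        n_members = length(members),
        s_score = rank_biserial(mw$U, length(mv), length(ov)),
        p = mw$p
      )
    }) |> purrr::compact() |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  if (!nrow(rows)) stop("no complex had more than two measured members")
  rows$q <- benjamini_hochberg(rows$p)
  rows$significant <- rows$q <= fdr_target
  dplyr::arrange(rows, .data$p)
}

# mutation classes that count as damaging; synonymous/other never do
DAMAGING_CLASSES <- c("missense", "splice_site", "insertion", "deletion",
                      "nonsense")

#' Per-gene altered-sample profiles from mutations and copy number
#'
#' Annotates, for every gene, the set of samples carrying the alteration of
#' interest. Modes: `"mut_or_homdel"` (damaging mutation or GISTIC -2),
#' `"homozygous"` (GISTIC -2 only), `"hemizygous"` (GISTIC -1 only),
#' `"mutation_only"` (damaging mutation only). Synonymous and `other`
#' mutation classes never count. The sample universe is the intersection of
#' the provided sources (the copy-number columns, restricted to `samples` if
#' given); mutation calls outside the universe are ignored.
#'
#' @param mutations Tibble from [read_mutations()] (may have zero rows).
#' @param cnv Integer GISTIC-style matrix from [read_copy_number()], or
#'   `NULL` for `mode = "mutation_only"` with explicit `samples`.
#' @param mode Alteration definition, see above.
#' @param samples Optional character vector fixing the sample universe.
#' @return Object of class `alteration_profile`: list with `altered` (named
#'   list gene -> altered sample ids), `samples`, `mode`, `definition`.
#' @export
build_alteration_profile <- function(mutations, cnv = NULL,
                                     mode = c("mut_or_homdel", "hemizygous",
                                              "homozygous", "mutation_only"),
                                     samples = NULL) {
  mode <- match.arg(mode)
  universe <- samples
  if (!is.null(cnv)) {
    universe <- if (is.null(universe)) colnames(cnv) else
      intersect(universe, colnames(cnv))
  }
  if (is.null(universe) || !length(universe)) {
    stop("empty sample universe: provide cnv and/or samples")
  }
  altered <- list()
  add <- function(gene, ids) {
    altered[[gene]] <<- union(altered[[gene]], ids)
  }
  if (mode %in% c("mut_or_homdel", "mutation_only") && nrow(mutations)) {
    dm <- mutations[mutations$mutation_class %in% DAMAGING_CLASSES &
                      mutations$sample_id %in% universe, ]
    for (g in unique(dm$gene_id)) add(g, unique(dm$sample_id[dm$gene_id == g]))
  }
  if (mode != "mutation_only") {
    if (is.null(cnv)) stop("copy-number matrix required for mode ", mode)
    call <- switch(mode, mut_or_homdel = -2L, homozygous = -2L,
                   hemizygous = -1L)
    cn <- cnv[, universe, drop = FALSE]
    hit <- which(cn == call, arr.ind = TRUE)
    if (nrow(hit)) {
      for (g in unique(rownames(cn)[hit[, 1]])) {
        add(g, colnames(cn)[hit[hit[, 1] == match(g, rownames(cn)), 2]])
      }
    }
  }
  definition <- switch(mode,
    mut_or_homdel = "damaging mutation or GISTIC -2",
    homozygous = "GISTIC -2",
    hemizygous = "GISTIC -1",
    mutation_only = "damaging mutation")
  structure(list(altered = altered, samples = universe, mode = mode,
                 definition = definition),
            class = "alteration_profile")
}

#' @export
print.alteration_profile <- function(x, ...) {
  cat(sprintf("alteration_profile (%s): %d genes altered in >= 1 of %d samples\n",
              x$mode, length(x$altered), length(x$samples)))
  invisible(x)
}

#' Does alteration of a gene reduce its own protein abundance?
#'
#' One-sided Mann-Whitney test that samples carrying the alteration have
#' lower abundance of the gene's own protein than unaltered samples.
#'
#' @param expr Genes-by-samples expression matrix.
#' @param profile An [build_alteration_profile()] result.
#' @param gene Gene identifier (must be measured).
#' @return Tibble: `gene`, `n_altered`, `n_unaltered`, `p`, `direction`.
#' @export
single_gene_alteration_test <- function(expr, profile, gene) {
  if (!gene %in% rownames(expr)) stop("gene not measured: ", gene)
  samples <- intersect(colnames(expr), profile$samples)
  alt <- intersect(profile$altered[[gene]], samples)
  una <- setdiff(samples, alt)
  v <- expr[gene, ]
  x <- v[alt][!is.na(v[alt])]
  y <- v[una][!is.na(v[una])]
  if (!length(x) || !length(y)) {
    stop("need at least one altered and one unaltered sample with data")
  }
  mw <- mann_whitney(x, y, "less")
  tibble::tibble(gene = gene, n_altered = length(x), n_unaltered = length(y),
                 p = mw$p, direction = "down")
}

# within-sample abundance ranks: rank 1 = lowest abundance in that sample,
# ties averaged, missing values excluded from the ranking
within_sample_ranks <- function(expr) {
  apply(expr, 2, rank, na.last = "keep", ties.method = "average")
}

#' Collateral loss of complex abundance upon subunit alteration
#'
#' For every altered gene belonging to a complex: protein measurements are
#' converted to within-sample rank orders, the per-sample mean rank of the
#' complex members is computed with the altered gene excluded (and, for
#' deletion-containing modes, members on the same chromosome as the altered
#' gene also excluded, so co-deletion in cis cannot masquerade as a complex
#' effect), and a one-sided Mann-Whitney test asks whether altered samples
#' show lower mean rank. BH correction is applied across all tested
#' (gene, complex) pairs.
#'
#' @param expr Genes-by-samples expression matrix.
#' @param profile An [build_alteration_profile()] result.
#' @param complexes A `complex_set`.
#' @param chrom Named chromosome-per-gene vector (see [read_chromosomes()]);
#'   required for deletion-containing modes.
#' @param fdr_target Significance threshold on the BH q-value (default 0.10).
#' @param min_altered Minimum altered samples for a gene to be tested
#'   (default 3).
#' @return Tibble: `gene`, `complex`, `n_members_used`, `n_altered`,
#'   `n_unaltered`, `effect` (rank-biserial), `p`, `q`, `significant`.
#' @export
complex_collateral_test <- function(expr, profile, complexes, chrom = NULL,
                                    fdr_target = 0.10, min_altered = 3) {
  samples <- intersect(colnames(expr), profile$samples)
  if (length(samples) < 4) stop("too few samples shared by expression and profile")
  deletion_mode <- profile$mode %in% c("mut_or_homdel", "hemizygous",
                                       "homozygous")
  if (deletion_mode && is.null(chrom)) {
    stop("chromosome map required for deletion-containing modes")
  }
  ranks <- within_sample_ranks(expr[, samples, drop = FALSE])
  measured <- rownames(expr)

  rows <- purrr::map(names(profile$altered), function(g) {
    alt <- intersect(profile$altered[[g]], samples)
    if (length(alt) < min_altered) return(NULL)
    una <- setdiff(samples, alt)
    in_cx <- which(vapply(complexes$members, function(m) g %in% m, logical(1)))
    purrr::map(in_cx, function(k) {
      members <- setdiff(complexes$members[[k]], g)
      if (deletion_mode && g %in% names(chrom)) {
        same <- members[!is.na(chrom[members]) & chrom[members] == chrom[[g]]]
        members <- setdiff(members, same)
      }
      members <- intersect(members, measured)
      if (length(members) < 2) return(NULL)
      mean_rank <- colMeans(ranks[members, , drop = FALSE], na.rm = TRUE)
      x <- mean_rank[alt][is.finite(mean_rank[alt])]
      y <- mean_rank[una][is.finite(mean_rank[una])]
      if (!length(x) || !length(y)) return(NULL)
      mw <- mann_whitney(x, y, "less")
      tibble::tibble(gene = g, complex = complexes$complex[k],
                     n_members_used = length(members),
                     n_altered = length(x), n_unaltered = length(y),
                     effect = rank_biserial(mw$U, length(x), length(y)),
                     p = mw$p)
    }) |> purrr::compact() |> purrr::list_rbind()
  }) |> purrr::compact() |> purrr::list_rbind()
  if (is.null(rows) || !nrow(rows)) {
    return(tibble::tibble(gene = character(), complex = character(),
                          n_members_used = integer(), n_altered = integer(),
                          n_unaltered = integer(), effect = numeric(),
                          p = numeric(), q = numeric(),
                          significant = logical()))
  }
  rows$q <- benjamini_hochberg(rows$p)
  rows$significant <- rows$q <= fdr_target
  dplyr::arrange(rows, .data$p)
}

#' Overlap of discovered complexes with a reference catalogue
#'
#' For each discovered complex, finds the reference complex with the most
#' significant overlap by upper-tail hypergeometric test over the given gene
#' universe (the genes present in both the expression data and the network),
#' and reports the BH-corrected p-value, Jaccard index and coverage (fraction
#' of the reference complex recovered).
#'
#' @param complexes Discovered `complex_set`.
#' @param reference Reference `complex_set`.
#' @param universe Character vector of background genes; sets are intersected
#'   with it.
#' @return Tibble: `complex`, `best_reference`, `n_overlap`, `jaccard`,
#'   `coverage`, `p`, `q`.
#' @export
catalogue_overlap <- function(complexes, reference, universe) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty gene universe")
  N <- length(universe)
  ref_sets <- lapply(complex_members(reference), intersect, universe)
  rows <- purrr::map(seq_len(nrow(complexes)), function(i) {
    dset <- intersect(complexes$members[[i]], universe)
    if (!length(dset)) return(NULL)
    stats_per_ref <- purrr::imap(ref_sets, function(rset, rn) {
      if (!length(rset)) return(NULL)
      k <- length(intersect(dset, rset))
      p <- stats::phyper(k - 1, length(rset), N - length(rset), length(dset),
                         lower.tail = FALSE)
      tibble::tibble(best_reference = rn, n_overlap = k,
                     jaccard = k / length(union(dset, rset)),
                     coverage = k / length(rset), p = p)
    }) |> purrr::compact() |> purrr::list_rbind()
    if (is.null(stats_per_ref) || !nrow(stats_per_ref)) return(NULL)
    best <- dplyr::slice_min(stats_per_ref, .data$p, n = 1, with_ties = FALSE)
    dplyr::bind_cols(tibble::tibble(complex = complexes$complex[i]), best)
  }) |> purrr::compact() |> purrr::list_rbind()
  if (is.null(rows) || !nrow(rows)) stop("no discovered complex overlaps the universe")
  rows$q <- benjamini_hochberg(rows$p)
  rows
}

#' Isogenic differential-expression pipeline
#'
#' For label-free quantification of paired isogenic lines: technical
#' replicates are averaged, missing values are imputed with each sample's
#' minimum observed intensity (absent proteins are assumed at or below the
#' detection limit), intensities are log2-transformed, and each protein is
#' tested with a two-sided Welch (heteroscedastic) t-test; BH controls the
#' FDR. Proteins observed in no sample are dropped.
#'
#' @param lfq Proteins-by-runs matrix of raw LFQ intensities (`NA` missing).
#' @param condition Condition label per run (two levels).
#' @param bio_replicate Biological-replicate identifier per run; runs sharing
#'   an identifier are technical replicates and are averaged. Default: each
#'   run its own replicate.
#' @return Tibble: `gene`, `effect` (mean log2 difference, second condition
#'   level minus first), `t`, `p`, `q`, sorted by `p`.
#' @export
isogenic_differential_expression <- function(lfq, condition,
                                             bio_replicate = colnames(lfq)) {
  stopifnot(is.matrix(lfq), length(condition) == ncol(lfq),
            length(bio_replicate) == ncol(lfq))
  condition <- as.factor(condition)
  bio_replicate <- as.character(bio_replicate)
  if (nlevels(condition) != 2) stop("exactly two condition levels required")
  # technical replicates share a biological id and must agree on condition
  rep_cond <- tapply(as.character(condition), bio_replicate,
                     function(v) unique(v))
  if (any(lengths(rep_cond) != 1)) {
    stop("technical replicates of one biological sample have mixed conditions")
  }
  reps <- unique(bio_replicate)
  avg <- vapply(reps, function(rp) {
    rowMeans(lfq[, bio_replicate == rp, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(lfq)))
  avg <- matrix(avg, nrow = nrow(lfq), dimnames = list(rownames(lfq), reps))
  avg[is.nan(avg)] <- NA
  keep <- rowSums(!is.na(avg)) > 0
  avg <- avg[keep, , drop = FALSE]
  # per-sample minimum imputation, then log2
  for (j in seq_len(ncol(avg))) {
    mn <- min(avg[, j], na.rm = TRUE)
    avg[is.na(avg[, j]), j] <- mn
  }
  lavg <- log2_transform(avg)
  cond <- factor(unlist(rep_cond)[reps], levels = levels(condition))
  g1 <- lavg[, cond == levels(cond)[1], drop = FALSE]
  g2 <- lavg[, cond == levels(cond)[2], drop = FALSE]
  if (ncol(g1) < 2 || ncol(g2) < 2) {
    stop("need >= 2 biological replicates per condition")
  }
  res <- purrr::map(seq_len(nrow(lavg)), function(i) {
    a <- g2[i, ]
    b <- g1[i, ]
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      eq <- isTRUE(all.equal(mean(a), mean(b)))
      tt <- list(statistic = c(t = if (eq) 0 else sign(mean(a) - mean(b)) * Inf),
                 p.value = if (eq) 1 else .Machine$double.xmin)
    } else {
      tt <- stats::t.test(a, b, var.equal = FALSE)
    }
    tibble::tibble(gene = rownames(lavg)[i], effect = mean(a) - mean(b),
                   t = unname(tt$statistic), p = tt$p.value)
  }) |> purrr::list_rbind()
  res$q <- benjamini_hochberg(res$p)
  dplyr::arrange(res, .data$p)
}
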