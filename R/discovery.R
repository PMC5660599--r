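# Discovery of disjoint protein complexes maximizing summed integrated LLR
# under the dual-evidence constraint, with an empirical FDR from
# gene-label-shuffled reruns.

#' Configuration for complex discovery
#'
#' @param fdr_target Target empirical FDR for the reported complex set
#'   (default 0.10).
#' @param n_random Number of gene-label randomizations for the FDR estimate
#'   (default 100).
#' @param min_overlap Minimum pairwise-complete sample count for a
#'   correlation to be defined (default 10).
#' @param neg_ratio Negatives per positive when calibrating LLR models
#'   (default 300).
#' @param max_complex_size Largest reference complex used for LLR training
#'   positives (default 30).
#' @param iteration_cap Maximum number of local-search moves (default 10000).
#' @param seed Integer seed governing training-pair sampling and the FDR
#'   randomizations.
#' @return A list of class `discovery_config`.
#' @export
discovery_config <- function(fdr_target = 0.10, n_random = 100,
                             min_overlap = 10, neg_ratio = 300,
                             max_complex_size = 30, iteration_cap = 10000,
                             seed = 1L) {
  structure(list(fdr_target = fdr_target, n_random = n_random,
                 min_overlap = min_overlap, neg_ratio = neg_ratio,
                 max_complex_size = max_complex_size,
                 iteration_cap = iteration_cap, seed = as.integer(seed)),
            class = "discovery_config")
}

#' Score a protein set on both evidence sources
#'
#' Sums the pair LLRs over all `|S|(|S|-1)/2` unordered pairs of the set;
#' pairs absent from the table contribute 0. Sets of size 0 or 1 score
#' `(0, 0, 0)`.
#'
#' @param genes Character vector of gene identifiers.
#' @param pairs Pair LLR table from [score_pairs()].
#' @return Named numeric vector `llr_expr`, `llr_int`, `llr_integrated`.
#' @export
score_set <- function(genes, pairs) {
  genes <- unique(as.character(genes))
  if (length(genes) < 2) {
    return(c(llr_expr = 0, llr_int = 0, llr_integrated = 0))
  }
  sub <- pairs[pairs$gene_a %in% genes & pairs$gene_b %in% genes, ]
  c(llr_expr = sum(sub$llr_expr), llr_int = sum(sub$llr_int),
    llr_integrated = sum(sub$llr_expr) + sum(sub$llr_int))
}

#' Enumerate seed candidates: interacting pairs and 3-cliques
#'
#' Every network edge and every triangle is scored with its summed pair LLRs;
#' only candidates with `llr_expr > 0` **and** `llr_int > 0` (support from
#' both evidence sources) are retained.
#'
#' @param network A `ppi_network`.
#' @param pairs Pair LLR table from [score_pairs()].
#' @return Tibble with `members` (list-column), `kind` (`pair`/`triangle`),
#'   `llr_expr`, `llr_int`, `llr_integrated`.
#' @export
enumerate_seeds <- function(network, pairs) {
  key <- pair_key(pairs$gene_a, pairs$gene_b)
  le <- stats::setNames(pairs$llr_expr, key)
  li <- stats::setNames(pairs$llr_int, key)
  look <- function(a, b, tab) {
    v <- unname(tab[pair_key(a, b)])
    v[is.na(v)] <- 0
    v
  }
  e <- network$edges
  cand_members <- c(
    purrr::map2(e$gene_a, e$gene_b, c),
    tri_list <- triangle_list(network)
  )
  kind <- rep(c("pair", "triangle"), c(nrow(e), length(tri_list)))
  expr_sum <- vapply(cand_members, function(m) {
    cmb <- utils::combn(m, 2)
    sum(look(cmb[1, ], cmb[2, ], le))
  }, numeric(1))
  int_sum <- vapply(cand_members, function(m) {
    cmb <- utils::combn(m, 2)
    sum(look(cmb[1, ], cmb[2, ], li))
  }, numeric(1))
  out <- tibble::tibble(members = cand_members, kind = kind,
                        llr_expr = expr_sum, llr_int = int_sum,
                        llr_integrated = expr_sum + int_sum)
  out[out$llr_expr > 0 & out$llr_int > 0, ]
}

# triangles of the network as a list of 3-member character vectors
triangle_list <- function(network) {
  if (!nrow(network$edges)) return(list())
  g <- as_igraph(network)
  tri <- igraph::triangles(g)
  if (!length(tri)) return(list())
  nm <- igraph::V(g)$name[as.integer(tri)]
  unname(split(nm, rep(seq_len(length(nm) / 3), each = 3)))
}

#' Greedy disjoint selection of seed clusters
#'
#' Repeatedly takes the highest-scoring remaining candidate (ties broken by
#' the lexicographically smallest sorted member tuple) and discards all
#' candidates overlapping it; proteins left unassigned become singleton
#' clusters.
#'
#' @param candidates Output of [enumerate_seeds()].
#' @param genes Optional gene universe for the singleton fill-in; default the
#'   union of candidate members.
#' @return A `cluster_state`: list with `clusters` (list of character
#'   vectors, singletons included) and an empty `move_log`.
#' @export
greedy_seed_clusters <- function(candidates, genes = NULL) {
  members <- candidates$members
  keys <- vapply(members, function(m) paste(sort(m), collapse = "\r"),
                 character(1))
  ord <- order(-candidates$llr_integrated, keys)
  taken <- character()
  picked <- list()
  for (i in ord) {
    m <- members[[i]]
    if (!any(m %in% taken)) {
      picked[[length(picked) + 1L]] <- m
      taken <- c(taken, m)
    }
  }
  universe <- sort(unique(c(unlist(members), as.character(genes))))
  singletons <- as.list(setdiff(universe, taken))
  new_cluster_state(c(picked, singletons))
}

new_cluster_state <- function(clusters, move_log = NULL, capped = FALSE) {
  if (is.null(move_log)) {
    move_log <- tibble::tibble(iteration = integer(), move = character(),
                               delta_llr_expr = numeric(),
                               delta_llr_int = numeric())
  }
  structure(list(clusters = clusters, move_log = move_log, capped = capped),
            class = "cluster_state")
}

#' @export
print.cluster_state <- function(x, ...) {
  sz <- lengths(x$clusters)
  cat(sprintf("cluster_state: %d clusters (%d of size >= 2), %d logged moves\n",
              length(sz), sum(sz >= 2), nrow(x$move_log)))
  invisible(x)
}

# dense expression-LLR matrix and integer edge list over a gene index
pairs_to_matrices <- function(pairs, genes) {
  n <- length(genes)
  E <- matrix(0, n, n, dimnames = list(genes, genes))
  ia <- match(pairs$gene_a, genes)
  ib <- match(pairs$gene_b, genes)
  E[cbind(ia, ib)] <- pairs$llr_expr
  E[cbind(ib, ia)] <- pairs$llr_expr
  is_edge <- if (!is.null(pairs$has_int)) pairs$has_int else pairs$llr_int != 0
  list(E = E,
       edge_a = ia[is_edge], edge_b = ib[is_edge],
       edge_w = pairs$llr_int[is_edge])
}

#' Refine clusters by constrained merge/remove/switch local search
#'
#' Repeatedly applies the move (merging two clusters, removing a protein into
#' a singleton, or switching a protein between clusters) with the largest
#' integrated LLR gain, accepting only moves that increase both the
#' expression LLR and the interaction LLR. Terminates when no move qualifies
#' or at `iteration_cap` (with a warning).
#'
#' @param state A `cluster_state` from [greedy_seed_clusters()].
#' @param pairs Pair LLR table from [score_pairs()].
#' @param iteration_cap Maximum number of accepted moves.
#' @return The refined `cluster_state`; `move_log` records every accepted
#'   move with its two deltas.
#' @export
refine_clusters <- function(state, pairs, iteration_cap = 10000) {
  genes <- sort(unique(unlist(state$clusters)))
  mats <- pairs_to_matrices(pairs, genes)
  init <- integer(length(genes))
  for (k in seq_along(state$clusters)) {
    init[match(state$clusters[[k]], genes)] <- k - 1L
  }
  res <- refine_clusters_cpp(mats$E, mats$edge_a - 1L, mats$edge_b - 1L,
                             mats$edge_w, init, iteration_cap)
  if (res$capped) warning("refine_clusters: iteration cap reached")
  clusters <- unname(split(genes, res$assign))
  new_cluster_state(clusters, tibble::as_tibble(res$log), res$capped)
}

# ---------------------------------------------------------------------------
# fast path shared by discover_complexes() and estimate_fdr(): everything in
# integer index space over a fixed gene universe

# candidate seeds in index space; llr_int per candidate is fixed across
# randomizations, llr_expr is recomputed from the (possibly permuted) E
index_candidates <- function(network, genes, edge_w_llr) {
  e <- network$edges
  ia <- match(e$gene_a, genes)
  ib <- match(e$gene_b, genes)
  wkey <- stats::setNames(edge_w_llr, pair_key(e$gene_a, e$gene_b))
  tri <- triangle_list(network)
  tri_idx <- if (length(tri)) {
    t(vapply(tri, function(m) sort(match(m, genes)), integer(3)))
  } else {
    matrix(integer(), 0, 3)
  }
  tri_int <- if (length(tri)) {
    vapply(tri, function(m) {
      cmb <- utils::combn(sort(m), 2)
      sum(wkey[pair_key(cmb[1, ], cmb[2, ])])
    }, numeric(1))
  } else numeric()
  list(
    pair_idx = cbind(ia, ib),
    pair_int = unname(edge_w_llr),
    tri_idx = tri_idx,
    tri_int = tri_int,
    # lexicographic tie-break keys on sorted member gene ids
    pair_tie = pair_key(e$gene_a, e$gene_b),
    tri_tie = vapply(tri, function(m) paste(sort(m), collapse = "\r"),
                     character(1))
  )
}

# one full seeding + refinement pass; returns clusters (size >= 2, as integer
# index vectors) with their score decomposition, plus the move log
run_discovery_core <- function(E, cand, edge_a, edge_b, edge_w, n,
                               iteration_cap) {
  pair_expr <- E[cand$pair_idx]
  if (nrow(cand$tri_idx)) {
    i <- cand$tri_idx
    tri_expr <- E[cbind(i[, 1], i[, 2])] + E[cbind(i[, 1], i[, 3])] +
      E[cbind(i[, 2], i[, 3])]
  } else {
    tri_expr <- numeric()
  }
  keep_p <- which(pair_expr > 0 & cand$pair_int > 0)
  keep_t <- which(tri_expr > 0 & cand$tri_int > 0)
  memb <- c(
    lapply(keep_p, function(k) cand$pair_idx[k, ]),
    lapply(keep_t, function(k) cand$tri_idx[k, ])
  )
  score <- c(pair_expr[keep_p] + cand$pair_int[keep_p],
             tri_expr[keep_t] + cand$tri_int[keep_t])
  ties <- c(cand$pair_tie[keep_p], cand$tri_tie[keep_t])

  assign <- rep(-1L, n)
  cl <- 0L
  if (length(memb)) {
    ord <- order(-score, ties)
    taken <- logical(n)
    for (k in ord) {
      m <- memb[[k]]
      if (!any(taken[m])) {
        assign[m] <- cl
        cl <- cl + 1L
        taken[m] <- TRUE
      }
    }
  }
  free <- which(assign < 0L)
  assign[free] <- cl + seq_along(free) - 1L

  res <- refine_clusters_cpp(E, edge_a - 1L, edge_b - 1L, edge_w, assign,
                             iteration_cap)
  fin <- res$assign + 1L
  sizes <- tabulate(fin)
  keep <- which(sizes >= 2)
  clusters <- unname(split(seq_len(n), fin))[keep]
  # interaction score per cluster: sum of edge LLRs with both endpoints inside
  within <- fin[edge_a] == fin[edge_b]
  int_by_cluster <- numeric(max(fin))
  if (any(within)) {
    agg <- rowsum(edge_w[within], fin[edge_a][within])
    int_by_cluster[as.integer(rownames(agg))] <- agg[, 1]
  }
  llr_expr <- vapply(clusters, function(ix) sum(E[ix, ix]) / 2, numeric(1))
  llr_int <- int_by_cluster[keep]
  list(clusters = clusters, llr_expr = llr_expr, llr_int = llr_int,
       llr_integrated = llr_expr + llr_int,
       move_log = tibble::as_tibble(res$log),
       capped = res$capped, assign = fin)
}

# genes assigned to clusters with score >= each threshold
genes_above <- function(sizes, scores, thresholds) {
  vapply(thresholds, function(t) sum(sizes[scores >= t]), numeric(1))
}

fdr_curve_from_runs <- function(real_sizes, real_scores, random_runs) {
  thresholds <- sort(unique(real_scores))
  if (!length(thresholds)) {
    return(tibble::tibble(threshold = numeric(), genes_real = numeric(),
                          mean_genes_random = numeric(), fdr = numeric(),
                          fdr_smoothed = numeric()))
  }
  g_real <- genes_above(real_sizes, real_scores, thresholds)
  g_rand <- vapply(random_runs, function(r) {
    genes_above(r$sizes, r$scores, thresholds)
  }, numeric(length(thresholds)))
  if (is.null(dim(g_rand))) g_rand <- matrix(g_rand, nrow = length(thresholds))
  mean_rand <- rowMeans(g_rand)
  fdr <- mean_rand / g_real
  tibble::tibble(threshold = thresholds, genes_real = g_real,
                 mean_genes_random = mean_rand, fdr = fdr,
                 # running minimum from loose to strict thresholds enforces
                 # an FDR curve non-increasing in the threshold
                 fdr_smoothed = cummin(fdr))
}

# internal engine shared by discover_complexes() and estimate_fdr()
fdr_engine <- function(expression, network, expr_model, int_model,
                       n_random, seed, min_overlap, iteration_cap) {
  genes <- sort(unique(c(rownames(expression), network$nodes)))
  n <- length(genes)
  expr_idx <- match(rownames(expression), genes)

  cm <- correlation_matrices(expression, min_overlap)
  Ex <- llr(expr_model, cm$r)
  Ex[is.na(Ex)] <- 0
  diag(Ex) <- 0
  E <- matrix(0, n, n)
  E[expr_idx, expr_idx] <- Ex

  if (!"score" %in% names(network$edges)) network <- weight_network(network)
  edge_w <- llr(int_model, network$edges$score)
  cand <- index_candidates(network, genes, edge_w)
  edge_a <- match(network$edges$gene_a, genes)
  edge_b <- match(network$edges$gene_b, genes)

  real <- run_discovery_core(E, cand, edge_a, edge_b, edge_w, n, iteration_cap)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  random_runs <- lapply(seq_len(n_random), function(k) {
    # shuffle the gene-ID <-> expression-profile map; the network, the LLR
    # models and the interaction evidence stay fixed
    perm <- seq_len(n)
    perm[expr_idx] <- expr_idx[sample(length(expr_idx))]
    Ep <- E[perm, perm]
    r <- run_discovery_core(Ep, cand, edge_a, edge_b, edge_w, n, iteration_cap)
    list(sizes = lengths(r$clusters), scores = r$llr_integrated)
  })

  curve <- fdr_curve_from_runs(lengths(real$clusters), real$llr_integrated,
                               random_runs)
  list(genes = genes, real = real, curve = curve)
}

#' Empirical FDR curve from gene-label randomizations
#'
#' Reruns the full seeding-plus-refinement discovery on `n_random` copies of
#' the input in which the gene-identifier-to-expression-profile assignment
#' has been shuffled (network and LLR models fixed), and compares, for each
#' observed cluster score threshold, the genes assigned to clusters in the
#' real versus the randomized runs: `fdr(t) = mean_genes_random(t) /
#' genes_real(t)`, regularized to be non-increasing in `t`.
#'
#' @param expression Preprocessed genes-by-samples matrix.
#' @param network A `ppi_network` (weighted with [weight_network()] if it is
#'   not already).
#' @param expr_model,int_model Fitted [fit_llr_model()] objects.
#' @param n_random Number of randomizations (default 100).
#' @param seed Integer seed for the shuffles.
#' @param min_overlap,iteration_cap See [discovery_config()].
#' @return Tibble `threshold`, `genes_real`, `mean_genes_random`, `fdr`,
#'   `fdr_smoothed`, with attributes `n_random` and `seed`.
#' @export
estimate_fdr <- function(expression, network, expr_model, int_model,
                         n_random = 100, seed = 1L, min_overlap = 10,
                         iteration_cap = 10000) {
  stopifnot(n_random >= 1)
  eng <- fdr_engine(expression, network, expr_model, int_model,
                    n_random, seed, min_overlap, iteration_cap)
  out <- eng$curve
  attr(out, "n_random") <- n_random
  attr(out, "seed") <- seed
  out
}

#' Discover co-regulated protein complexes
#'
#' End-to-end pipeline: pairwise correlations on the expression matrix,
#' shared-partner weighting of the interaction network, LLR calibration of
#' both evidence sources against the reference catalogue, greedy seeding from
#' interacting pairs and 3-cliques, constrained merge/remove/switch
#' refinement, and an empirical FDR from gene-label-shuffled reruns. The
#' reported complexes are the clusters of size >= 2 whose integrated LLR
#' meets the smallest threshold achieving `fdr <= config$fdr_target`.
#'
#' @param expression Preprocessed genes-by-samples matrix (see
#'   [collapse_isoforms()], [filter_missing()]).
#' @param network A `ppi_network`.
#' @param reference A `complex_set` reference catalogue for LLR training.
#' @param config A [discovery_config()].
#' @return Object of class `complex_discovery`: `complexes` (a disjoint
#'   [complex_set()] with score decomposition), `all_clusters` (pre-FDR),
#'   `fdr_curve`, `threshold`, `move_log`, `models`, `config`.
#' @export
discover_complexes <- function(expression, network, reference,
                               config = discovery_config()) {
  stopifnot(is.matrix(expression), inherits(network, "ppi_network"))
  if (anyDuplicated(rownames(expression))) {
    stop("expression matrix has duplicate gene IDs; collapse isoforms first")
  }
  network <- weight_network(network)

  corr <- pairwise_correlation(expression, min_overlap = config$min_overlap)
  expr_feat <- dplyr::rename(corr[, c("gene_a", "gene_b", "r")], feature = "r")
  int_feat <- dplyr::rename(network$edges[, c("gene_a", "gene_b", "score")],
                            feature = "score")
  measured <- rownames(expression)
  expr_train <- sample_training_pairs(reference, measured, expr_feat,
                                      neg_ratio = config$neg_ratio,
                                      max_complex_size = config$max_complex_size,
                                      seed = config$seed)
  # background for the interaction LLR is the set of ALL measured pairs, not
  # the set of edges: a pair without interaction evidence carries a
  # shared-partner feature of 0
  int_train <- sample_training_pairs(reference, measured, int_feat,
                                     neg_ratio = config$neg_ratio,
                                     max_complex_size = config$max_complex_size,
                                     seed = config$seed + 1L,
                                     default_feature = 0)
  expr_model <- fit_llr_model(expr_train, "expression")
  int_model <- fit_llr_model(int_train, "interaction")

  eng <- fdr_engine(expression, network, expr_model, int_model,
                    config$n_random, config$seed + 2L,
                    config$min_overlap, config$iteration_cap)
  real <- eng$real
  curve <- eng$curve

  nm <- sprintf("C%04d", seq_along(real$clusters))
  all_clusters <- complex_set(
    stats::setNames(lapply(real$clusters, function(ix) eng$genes[ix]), nm),
    scores = tibble::tibble(llr_expr = real$llr_expr, llr_int = real$llr_int,
                            llr_integrated = real$llr_integrated),
    disjoint = TRUE
  )
  ok <- which(curve$fdr_smoothed <= config$fdr_target)
  threshold <- if (length(ok)) curve$threshold[min(ok)] else Inf
  kept <- all_clusters[all_clusters$llr_integrated >= threshold, ]
  # renumber by decreasing score, mirroring catalogue conventions
  kept <- kept[order(-kept$llr_integrated), ]
  complexes <- complex_set(
    stats::setNames(kept$members, sprintf("C%04d", seq_len(nrow(kept)))),
    scores = kept[, c("llr_expr", "llr_int", "llr_integrated")],
    disjoint = TRUE
  )
  structure(
    list(complexes = complexes, all_clusters = all_clusters,
         fdr_curve = curve, threshold = threshold,
         move_log = real$move_log, capped = real$capped,
         models = list(expression = expr_model, interaction = int_model),
         config = config),
    class = "complex_discovery"
  )
}

#' @export
print.complex_discovery <- function(x, ...) {
  cat(sprintf(
    "complex_discovery: %d complexes (%d genes) at FDR <= %.2g (threshold %.3g)\n",
    nrow(x$complexes), length(unique(unlist(x$complexes$members))),
    x$config$fdr_target, x$threshold))
  invisible(x)
}

#' Tidy a complex discovery result
#' @param x A `complex_discovery`.
#' @param ... Unused.
#' @return Tibble of reported complexes with their score decomposition.
#' @exportS3Method generics::tidy
tidy.complex_discovery <- function(x, ...) {
  tibble::as_tibble(x$complexes)
}

#' One-row summary of a complex discovery result
#' @param x A `complex_discovery`.
#' @param ... Unused.
#' @return Tibble with complex, gene and move counts, threshold and FDR.
#' @exportS3Method generics::glance
glance.complex_discovery <- function(x, ...) {
  at <- x$fdr_curve$fdr_smoothed[match(x$threshold, x$fdr_curve$threshold)]
  tibble::tibble(
    n_complexes = nrow(x$complexes),
    n_genes = length(unique(unlist(x$complexes$members))),
    mean_size = mean(lengths(x$complexes$members)),
    threshold = x$threshold,
    fdr_at_threshold = if (length(at)) at else NA_real_,
    n_moves = nrow(x$move_log),
    capped = x$capped
  )
}

#' Plot the empirical FDR curve of a discovery run
#' @param object A `complex_discovery`.
#' @param ... Unused.
#' @return A ggplot: FDR (capped at 1 for display) against the integrated LLR
#'   threshold, with the selected threshold marked.
#' @exportS3Method ggplot2::autoplot
autoplot.complex_discovery <- function(object, ...) {
  d <- dplyr::mutate(object$fdr_curve, fdr_display = pmin(.data$fdr_smoothed, 1))
  ggplot2::ggplot(d, ggplot2::aes(.data$threshold, .data$fdr_display)) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(yintercept = object$config$fdr_target,
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$threshold, colour = "red") +
    ggplot2::labs(x = "integrated LLR threshold", y = "empirical FDR") +
    ggplot2::theme_minimal()
}
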