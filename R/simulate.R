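# Synthetic tumor-proteome generator with planted structure: latent-factor
# co-regulated complexes, a PPI graph densely connected within planted
# complexes, missing-at-random values, subtype-shifted complexes, and
# alteration events that depress one subunit plus (at the protein level only)
# its complex partners. Ground truth is returned for recovery evaluation.

#' Simulation configuration
#'
#' Each planted complex follows a one-factor model: member `g` in complex `c`
#' has expression `x_g = a * f_c + eps` with `f_c, eps ~ N(0, 1)` and loading
#' `a = sqrt(r / (1 - r))`, so the expected within-complex pairwise Pearson
#' correlation is exactly `within_complex_r`. Background genes are
#' independent standard normals. Subtype shifts and collateral depressions
#' are expressed in SD units of the member's marginal distribution
#' (`sqrt(a^2 + 1)` for members, 1 for background genes).
#'
#' @param n_genes Total genes (planted + decoy + background).
#' @param n_samples Tumor samples.
#' @param n_complexes Planted complexes.
#' @param complex_size Integer range (min, max) of planted complex sizes.
#' @param within_complex_r Target within-complex pairwise correlation in
#'   `[0, 1)`.
#' @param p_edge_within Probability of a network edge between two members of
#'   the same planted complex (also used for clique-free decoy wiring checks).
#' @param n_background_edges Edges sampled uniformly over non-planted pairs.
#' @param missing_rate Range of the per-gene missing-at-random rate.
#' @param n_subtypes Number of equally likely sample subtypes.
#' @param subtype_shifts Either an integer (that many planted complexes get a
#'   `subtype_shift_delta` SD shift in one random subtype) or a tibble with
#'   columns `complex` (index), `subtype` (label index), `delta`.
#' @param subtype_shift_delta Default shift size in SD units.
#' @param collateral_events Either an integer count (events take the
#'   defaults below, one per complex) or a tibble with columns `complex`
#'   (index), `frac_altered`, `delta_gene`, `delta_partners`, `type` (one of
#'   `"hemizygous"`, `"homozygous"`, `"mutation"`).
#' @param collateral_frac,collateral_delta_gene,collateral_delta_partners
#'   Defaults for integer-valued `collateral_events`: fraction of samples
#'   altered (0.15), own-gene depression (1.5 SD) and partner depression
#'   (0.8 SD).
#' @param collateral_type Default alteration type (`"hemizygous"`).
#' @param n_corr_decoys,n_clique_decoys Numbers of correlated-but-unwired and
#'   wired-but-uncorrelated decoy gene sets.
#' @param n_chromosomes Chromosome labels assigned uniformly at random.
#' @param same_chrom_rate Fraction of planted complexes placed entirely on a
#'   single chromosome (default 0).
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1000, n_samples = 60, n_complexes = 25,
                       complex_size = c(3, 12), within_complex_r = 0.7,
                       p_edge_within = 0.9, n_background_edges = 2000,
                       missing_rate = c(0, 0.3), n_subtypes = 3,
                       subtype_shifts = 0, subtype_shift_delta = 1.0,
                       collateral_events = 0, collateral_frac = 0.15,
                       collateral_delta_gene = 1.5,
                       collateral_delta_partners = 0.8,
                       collateral_type = "hemizygous",
                       n_corr_decoys = 0, n_clique_decoys = 0,
                       n_chromosomes = 23, same_chrom_rate = 0,
                       seed = 1L) {
  stopifnot(within_complex_r >= 0, within_complex_r < 1,
            p_edge_within >= 0, p_edge_within <= 1,
            complex_size[1] >= 2, n_samples >= 4)
  structure(as.list(environment()), class = "sim_config")
}

# one-factor block: k genes x n samples with pairwise correlation r
factor_block <- function(k, n, r) {
  a <- sqrt(r / (1 - r))
  f <- stats::rnorm(n)
  sweep(matrix(stats::rnorm(k * n), k, n), 2, a * f, `+`)
}

# sample k sizes from an inclusive range (robust to a degenerate range,
# where sample(x) would misbehave)
sample_sizes <- function(range, k) {
  if (k == 0L) return(integer())
  if (range[1] == range[2]) return(rep(as.integer(range[1]), k))
  sample(range[1]:range[2], k, replace = TRUE)
}

#' Generate a synthetic dataset with planted structure
#'
#' See [sim_config()] for the generative model. The protein and mRNA matrices
#' share the planted factor structure and subtype shifts; collateral events
#' depress the altered gene in both matrices but its complex partners in the
#' protein matrix only, reproducing the post-transcriptional signature that
#' collateral loss is visible in proteomes but not transcriptomes.
#' Missingness is applied to the protein matrix only.
#'
#' @param config A [sim_config()].
#' @return List: `protein`, `mrna` (matrices), `network` (`ppi_network`),
#'   `annotations`, `mutations` (tibbles), `copy_number` (integer matrix),
#'   `chromosomes` (named vector), `truth` (list with planted `complexes`,
#'   `corr_decoys`, `clique_decoys`, `subtype_shifts`, `collateral_events`).
#' @export
simulate_dataset <- function(config = sim_config()) {
  cfg <- config
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)

  sizes <- sample_sizes(cfg$complex_size, cfg$n_complexes)
  decoy_sizes_c <- sample_sizes(cfg$complex_size, cfg$n_corr_decoys)
  decoy_sizes_q <- sample_sizes(cfg$complex_size, cfg$n_clique_decoys)
  need <- sum(sizes) + sum(decoy_sizes_c) + sum(decoy_sizes_q)
  if (need > cfg$n_genes) {
    stop("infeasible config: planted structure needs ", need,
         " genes, budget is ", cfg$n_genes)
  }
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  samples <- sprintf("S%03d", seq_len(cfg$n_samples))
  shuffled <- sample(genes)
  take <- function(k) {
    out <- shuffled[seq_len(k)]
    shuffled <<- shuffled[-seq_len(k)]
    sort(out)
  }
  planted <- lapply(sizes, take)
  names(planted) <- sprintf("P%03d", seq_along(planted))
  corr_decoys <- lapply(decoy_sizes_c, take)
  if (length(corr_decoys)) names(corr_decoys) <- sprintf("DCORR%02d", seq_along(corr_decoys))
  clique_decoys <- lapply(decoy_sizes_q, take)
  if (length(clique_decoys)) names(clique_decoys) <- sprintf("DCLIQ%02d", seq_along(clique_decoys))

  n <- cfg$n_genes
  ns <- cfg$n_samples
  protein <- matrix(stats::rnorm(n * ns), n, ns, dimnames = list(genes, samples))
  mrna <- matrix(stats::rnorm(n * ns), n, ns, dimnames = list(genes, samples))
  sd_gene <- stats::setNames(rep(1, n), genes)
  a <- sqrt(cfg$within_complex_r / (1 - cfg$within_complex_r))
  for (set in c(planted, corr_decoys)) {
    f <- stats::rnorm(ns)
    protein[set, ] <- protein[set, ] + rep(a * f, each = length(set))
    g2 <- stats::rnorm(ns)      # mRNA shares correlation structure, not noise
    mrna[set, ] <- mrna[set, ] + rep(a * g2, each = length(set))
    sd_gene[set] <- sqrt(a^2 + 1)
  }

  subtype <- factor(sample(rep_len(seq_len(cfg$n_subtypes), ns)),
                    labels = paste0("subtype", seq_len(cfg$n_subtypes)))
  shifts <- cfg$subtype_shifts
  if (is.numeric(shifts) && length(shifts) == 1) {
    k <- min(shifts, cfg$n_complexes)
    shifts <- tibble::tibble(
      complex = if (k) sample(cfg$n_complexes, k) else integer(),
      subtype = if (k) sample(cfg$n_subtypes, k, replace = TRUE) else integer(),
      delta = rep(cfg$subtype_shift_delta, k)
    )
  }
  for (i in seq_len(nrow(shifts))) {
    set <- planted[[shifts$complex[i]]]
    cols <- which(as.integer(subtype) == shifts$subtype[i])
    bump <- shifts$delta[i] * sd_gene[set]
    protein[set, cols] <- protein[set, cols] + bump
    mrna[set, cols] <- mrna[set, cols] + bump
  }

  events <- cfg$collateral_events
  if (is.numeric(events) && length(events) == 1) {
    k <- min(events, cfg$n_complexes)
    events <- tibble::tibble(
      complex = if (k) sample(cfg$n_complexes, k) else integer(),
      frac_altered = rep(cfg$collateral_frac, k),
      delta_gene = rep(cfg$collateral_delta_gene, k),
      delta_partners = rep(cfg$collateral_delta_partners, k),
      type = rep(cfg$collateral_type, k)
    )
  }
  copy_number <- matrix(0L, n, ns, dimnames = list(genes, samples))
  mutations <- tibble::tibble(sample_id = character(), gene_id = character(),
                              mutation_class = character())
  event_rows <- list()
  for (i in seq_len(nrow(events))) {
    set <- planted[[events$complex[i]]]
    g <- set[1]
    partners <- setdiff(set, g)
    alt <- sort(sample(samples, max(1, round(events$frac_altered[i] * ns))))
    protein[g, alt] <- protein[g, alt] - events$delta_gene[i] * sd_gene[g]
    protein[partners, alt] <- protein[partners, alt] -
      events$delta_partners[i] * sd_gene[partners]
    mrna[g, alt] <- mrna[g, alt] - events$delta_gene[i] * sd_gene[g]
    type <- events$type[i]
    if (type == "mutation") {
      mutations <- dplyr::bind_rows(mutations, tibble::tibble(
        sample_id = alt, gene_id = g, mutation_class = "missense"))
    } else {
      copy_number[g, alt] <- if (type == "homozygous") -2L else -1L
    }
    event_rows[[i]] <- tibble::tibble(
      gene = g, complex = names(planted)[events$complex[i]],
      n_altered = length(alt), type = type,
      delta_gene = events$delta_gene[i],
      delta_partners = events$delta_partners[i],
      altered_samples = list(alt))
  }
  event_tbl <- if (length(event_rows)) purrr::list_rbind(event_rows) else
    tibble::tibble(gene = character(), complex = character(),
                   n_altered = integer(), type = character(),
                   delta_gene = numeric(), delta_partners = numeric(),
                   altered_samples = list())

  # missingness (protein only), completely at random with a per-gene rate
  rate <- stats::runif(n, cfg$missing_rate[1], cfg$missing_rate[2])
  drop <- matrix(stats::runif(n * ns) < rate, n, ns)
  protein[drop] <- NA

  # network: dense within planted complexes and clique decoys, plus uniform
  # background edges over all remaining pairs
  edge_env <- new.env()
  edges_a <- character()
  edges_b <- character()
  add_edges <- function(a, b) {
    edges_a <<- c(edges_a, a)
    edges_b <<- c(edges_b, b)
    for (k in pair_key(a, b)) assign(k, TRUE, envir = edge_env)
  }
  for (set in planted) {
    cmb <- utils::combn(set, 2)
    on_ <- stats::runif(ncol(cmb)) < cfg$p_edge_within
    if (any(on_)) add_edges(cmb[1, on_], cmb[2, on_])
  }
  for (set in clique_decoys) {
    cmb <- utils::combn(set, 2)
    add_edges(cmb[1, ], cmb[2, ])
  }
  planted_keys <- unlist(lapply(c(planted, corr_decoys), function(set) {
    cmb <- utils::combn(set, 2)
    pair_key(cmb[1, ], cmb[2, ])
  }))
  n_bg <- 0L
  guard <- 0L
  while (n_bg < cfg$n_background_edges && guard < 50L * cfg$n_background_edges) {
    guard <- guard + 1L
    cand <- sample(genes, 2)
    k <- pair_key(cand[1], cand[2])
    if (k %in% planted_keys || exists(k, envir = edge_env)) next
    add_edges(cand[1], cand[2])
    n_bg <- n_bg + 1L
  }
  o <- orient_pairs(edges_a, edges_b)
  network <- ppi_network(tibble::tibble(gene_a = o$gene_a, gene_b = o$gene_b),
                         nodes = genes)

  chrom <- stats::setNames(
    sample(paste0("chr", seq_len(cfg$n_chromosomes)), n, replace = TRUE), genes)
  same_chrom <- which(stats::runif(cfg$n_complexes) < cfg$same_chrom_rate)
  for (i in same_chrom) {
    chrom[planted[[i]]] <- sample(paste0("chr", seq_len(cfg$n_chromosomes)), 1)
  }

  list(
    protein = protein, mrna = mrna, network = network,
    annotations = tibble::tibble(sample_id = samples,
                                 subtype = as.character(subtype)),
    mutations = mutations, copy_number = copy_number, chromosomes = chrom,
    truth = list(
      complexes = complex_set(planted, disjoint = TRUE),
      corr_decoys = if (length(corr_decoys)) complex_set(corr_decoys, disjoint = TRUE) else NULL,
      clique_decoys = if (length(clique_decoys)) complex_set(clique_decoys, disjoint = TRUE) else NULL,
      subtype_shifts = shifts, collateral_events = event_tbl,
      config = cfg)
  )
}

#' Perturb a reference catalogue to emulate imperfect curation
#'
#' Randomly drops and adds a fraction of members per complex (never below two
#' remaining members), producing the imperfect training reference used when
#' benchmarking discovery against planted truth.
#'
#' @param complexes A `complex_set`.
#' @param universe Gene pool for added members.
#' @param drop_frac,add_frac Fractions of each complex dropped/added
#'   (default 0.2).
#' @param seed Integer seed.
#' @return A perturbed `complex_set` (non-disjoint).
#' @export
perturb_reference <- function(complexes, universe, drop_frac = 0.2,
                              add_frac = 0.2, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  members <- lapply(complexes$members, function(m) {
    n_drop <- min(floor(drop_frac * length(m)), length(m) - 2)
    if (n_drop > 0) m <- setdiff(m, sample(m, n_drop))
    n_add <- stats::rbinom(1, length(m), add_frac)
    if (n_add > 0) m <- union(m, sample(setdiff(universe, m), n_add))
    m
  })
  names(members) <- complexes$complex
  complex_set(members, disjoint = FALSE)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

#' Evaluate recovery of planted complexes
#'
#' Matches each planted complex to its best-Jaccard discovered complex.
#' Recall is the fraction of planted complexes with best Jaccard at least
#' `jaccard_min`; precision is the fraction of discovered complexes whose
#' best Jaccard against any planted complex is at least 0.2. Decoy capture
#' rates (best Jaccard >= `jaccard_min` per decoy) are reported separately
#' for each decoy class.
#'
#' @param found Discovered `complex_set` (or `complex_discovery`).
#' @param truth Ground-truth list from [simulate_dataset()].
#' @param jaccard_min Jaccard threshold for a planted complex to count as
#'   recovered (default 0.5).
#' @return List: `recall`, `precision` (`NA` when nothing was found),
#'   `false_gene_fraction` (reported genes outside any planted complex),
#'   `per_complex` tibble, `corr_decoy_capture`, `clique_decoy_capture`.
#' @export
evaluate_recovery <- function(found, truth, jaccard_min = 0.5) {
  if (inherits(found, "complex_discovery")) found <- found$complexes
  fsets <- found$members
  best_j <- function(target_sets) {
    vapply(target_sets, function(m) {
      if (!length(fsets)) return(0)
      max(vapply(fsets, jaccard, numeric(1), b = m))
    }, numeric(1))
  }
  planted <- truth$complexes$members
  pj <- best_j(planted)
  per_complex <- tibble::tibble(complex = truth$complexes$complex,
                                best_jaccard = pj,
                                recovered = pj >= jaccard_min)
  precision <- if (length(fsets)) {
    mean(vapply(fsets, function(f) {
      max(vapply(planted, jaccard, numeric(1), b = f)) >= 0.2
    }, logical(1)))
  } else NA_real_
  planted_genes <- unique(unlist(planted))
  found_genes <- unique(unlist(fsets))
  list(
    recall = mean(per_complex$recovered),
    precision = precision,
    false_gene_fraction = if (length(found_genes)) {
      mean(!found_genes %in% planted_genes)
    } else NA_real_,
    per_complex = per_complex,
    corr_decoy_capture = if (!is.null(truth$corr_decoys)) {
      mean(best_j(truth$corr_decoys$members) >= jaccard_min)
    } else NA_real_,
    clique_decoy_capture = if (!is.null(truth$clique_decoys)) {
      mean(best_j(truth$clique_decoys$members) >= jaccard_min)
    } else NA_real_
  )
}
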