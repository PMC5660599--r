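# Shared fixtures, built in code.

# small complete expression matrix with named genes/samples
toy_expression <- function(values, genes = NULL, samples = NULL) {
  m <- matrix(unlist(values), nrow = length(values), byrow = TRUE)
  rownames(m) <- genes %||% sprintf("g%02d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("s%02d", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic correlated block matrix: k genes sharing a factor + noise
corr_block_matrix <- function(k, n, r, seed = 1, sd_noise = 1) {
  set.seed(seed)
  a <- sqrt(r / (1 - r)) * sd_noise
  f <- rnorm(n)
  m <- matrix(rnorm(k * n, sd = sd_noise), k, n) + rep(a * f, each = k)
  rownames(m) <- sprintf("g%02d", seq_len(k))
  colnames(m) <- sprintf("s%02d", seq_len(n))
  m
}

# tiny weighted network + pair table for discovery unit tests: builds the
# full score_pairs() pipeline from an expression matrix and an edge list
toy_pair_table <- function(expr, edges, reference, seed = 1L,
                           min_overlap = 3) {
  net <- weight_network(ppi_network(edges, nodes = rownames(expr)))
  corr <- pairwise_correlation(expr, min_overlap = min_overlap)
  expr_feat <- dplyr::rename(corr[, c("gene_a", "gene_b", "r")], feature = "r")
  int_feat <- dplyr::rename(net$edges[, c("gene_a", "gene_b", "score")],
                            feature = "score")
  et <- sample_training_pairs(reference, rownames(expr), expr_feat,
                              neg_ratio = 10, seed = seed)
  it <- sample_training_pairs(reference, rownames(expr), int_feat,
                              neg_ratio = 10, seed = seed + 1L,
                              default_feature = 0)
  list(
    network = net,
    pairs = score_pairs(corr, net,
                        fit_llr_model(et, "expression"),
                        fit_llr_model(it, "interaction"))
  )
}

# hand-specified LLR model, for tests of scoring mechanics
fake_model <- function(beta0, beta1, ratio, kind = "expression") {
  structure(list(kind = kind, beta0 = beta0, beta1 = beta1,
                 neg_ratio = ratio, feature_range = c(-Inf, Inf)),
            class = "llr_model")
}

# brute-force oracles -------------------------------------------------------

# hypergeometric upper tail by exhaustive enumeration of all draws
enum_hyper_upper <- function(q, n_success, n_draw, n_universe) {
  if (n_draw == 0) return(if (q <= 0) 1 else 0)
  draws <- utils::combn(n_universe, n_draw)
  hits <- colSums(draws <= n_success)  # successes are items 1..n_success
  mean(hits >= q)
}

# Mann-Whitney p by enumeration of all group assignments of the ranks
enum_mw_p <- function(x, y, alternative) {
  nx <- length(x)
  v <- c(x, y)
  r <- rank(v)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  splits <- utils::combn(length(v), nx)
  u_all <- apply(splits, 2, function(ix) sum(r[ix]) - nx * (nx + 1) / 2)
  switch(alternative,
         less = mean(u_all <= u_obs),
         greater = mean(u_all >= u_obs),
         two_sided = min(1, 2 * min(mean(u_all <= u_obs),
                                    mean(u_all >= u_obs))))
}

# BH step-up from first principles
enum_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  pmin(1, q)[order(o)]
}
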