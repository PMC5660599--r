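# Calibration of raw pair features (co-expression r, shared-partner score)
# into additive log-likelihood ratios for co-complex membership. A logistic
# regression of co-annotation on the single feature gives the posterior
# p(feature); because training used a fixed negative:positive ratio, the
# exact Bayes identity
#     LLR(f) = logit(p(f)) - logit(prior) = beta0 + beta1 * f + log(ratio)
# equals log[ P(f | co-complex) / P(f | background) ] without any density
# binning of the background.

#' Sample labeled training pairs from a reference catalogue
#'
#' Positives are unordered pairs co-annotated in at least one reference
#' complex of size `<= max_complex_size` (larger complexes are excluded so
#' that giant assemblies do not dominate the training set); positives are
#' deduplicated across overlapping complexes. Negatives are sampled without
#' replacement from the pairs of measured genes that carry the feature and
#' are not co-annotated in any reference complex, at `neg_ratio` negatives
#' per positive (truncated to availability).
#'
#' @param reference A `complex_set` reference catalogue.
#' @param measured_genes Character vector of genes with measured data.
#' @param features Data frame with columns `gene_a`, `gene_b`, `feature`:
#'   the pairs carrying the feature. Pairs without features are skipped
#'   (logged) unless `default_feature` is given.
#' @param neg_ratio Negatives per positive (default 300, matching interactome
#'   size estimates).
#' @param max_complex_size Largest reference complex used for positives
#'   (default 30).
#' @param seed Integer seed; sampling is deterministic given the seed.
#' @param default_feature If non-`NULL`, pairs absent from `features` take
#'   this feature value instead of being skipped, and negatives are sampled
#'   from all measured gene pairs. Used for the interaction model, where a
#'   non-interacting background pair carries a shared-partner score of 0 and
#'   the background is the set of all pairs, not the set of edges.
#' @return Tibble `gene_a`, `gene_b`, `feature`, `label` (factor
#'   negative/positive) with provenance attributes `neg_ratio`,
#'   `realized_ratio`, `seed`.
#' @export
sample_training_pairs <- function(reference, measured_genes, features,
                                  neg_ratio = 300, max_complex_size = 30,
                                  seed = 1L, default_feature = NULL) {
  stopifnot(nrow(reference) > 0, neg_ratio > 0)
  features <- tibble::as_tibble(features)
  o <- orient_pairs(as.character(features$gene_a), as.character(features$gene_b))
  fkey <- pair_key(o$gene_a, o$gene_b)
  feat <- stats::setNames(features$feature, fkey)

  measured <- sort(unique(as.character(measured_genes)))
  co_pairs <- function(members) {
    m <- sort(intersect(members, measured))
    if (length(m) < 2) return(character())
    idx <- utils::combn(m, 2)
    pair_key(idx[1, ], idx[2, ])
  }
  small <- reference$members[lengths(reference$members) <= max_complex_size]
  if (!length(small)) stop("no reference complexes pass the size filter")
  pos_keys <- unique(unlist(lapply(small, co_pairs), use.names = FALSE))
  # co-annotation anywhere in the reference (any size) disqualifies a negative
  all_keys <- unique(unlist(lapply(reference$members, co_pairs), use.names = FALSE))
  if (is.null(default_feature)) {
    skipped <- sum(!pos_keys %in% names(feat))
    if (skipped) message("sample_training_pairs: skipped ", skipped,
                         " positive pair(s) without features")
    pos_keys <- pos_keys[pos_keys %in% names(feat)]
  }
  if (!length(pos_keys)) stop("no positive training pairs with features")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n_want <- round(neg_ratio * length(pos_keys))
  if (is.null(default_feature)) {
    neg_pool <- setdiff(names(feat), all_keys)
    neg_keys <- sort(sample(neg_pool, min(length(neg_pool), n_want)))
  } else {
    # sample negatives from all measured gene pairs by rejection
    total_pairs <- choose(length(measured), 2) - length(all_keys)
    n_want <- min(n_want, total_pairs)
    neg_keys <- character()
    while (length(neg_keys) < n_want) {
      k <- 2L * (n_want - length(neg_keys)) + 16L
      a <- sample(measured, k, replace = TRUE)
      b <- sample(measured, k, replace = TRUE)
      ok <- a != b
      cand <- pair_key(a[ok], b[ok])
      cand <- cand[!cand %in% all_keys]
      neg_keys <- unique(c(neg_keys, cand))
    }
    neg_keys <- sort(neg_keys[seq_len(n_want)])
  }

  keys <- c(pos_keys, neg_keys)
  ab <- do.call(rbind, strsplit(keys, "\t", fixed = TRUE))
  fv <- unname(feat[keys])
  if (!is.null(default_feature)) fv[is.na(fv)] <- default_feature
  out <- tibble::tibble(
    gene_a = ab[, 1], gene_b = ab[, 2],
    feature = fv,
    label = factor(rep(c("positive", "negative"),
                       c(length(pos_keys), length(neg_keys))),
                   levels = c("negative", "positive"))
  )
  attr(out, "neg_ratio") <- neg_ratio
  attr(out, "realized_ratio") <- length(neg_keys) / length(pos_keys)
  attr(out, "seed") <- seed
  out
}

# save/restore the global RNG state so seeded helpers do not perturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# ridge-penalized logistic fit by BFGS; fallback when glm separates
logistic_ridge <- function(f, y, lambda = 1e-3) {
  nll <- function(beta) {
    eta <- beta[1] + beta[2] * f
    sum(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta) +
      lambda * beta[2]^2 / 2
  }
  stats::optim(c(0, 0), nll, method = "BFGS")$par
}

#' Fit a single-feature logistic LLR model
#'
#' Logistic regression of the positive/negative label on the feature. The
#' fitted intercept and slope, together with the realized negative:positive
#' ratio, define the log-likelihood ratio via
#' `llr(f) = beta0 + beta1 * f + log(ratio)`. Perfect separation triggers a
#' ridge-penalized refit (reported with a message).
#'
#' @param training Output of [sample_training_pairs()].
#' @param kind `"expression"` or `"interaction"` (metadata only).
#' @return Object of class `llr_model`: list with `kind`, `beta0`, `beta1`,
#'   `neg_ratio` (realized), `feature_range`.
#' @export
fit_llr_model <- function(training, kind = c("expression", "interaction")) {
  kind <- match.arg(kind)
  y <- as.integer(training$label == "positive")
  if (length(unique(y)) < 2) stop("both classes must be present")
  f <- training$feature
  fit <- suppressWarnings(stats::glm(y ~ f, family = stats::binomial()))
  beta <- stats::coef(fit)
  mu <- stats::fitted(fit)
  separated <- !fit$converged || any(!is.finite(beta)) ||
    all(abs(mu - y) < 1e-8)
  if (separated) {
    message("fit_llr_model: perfect separation, using ridge-penalized fit")
    beta <- logistic_ridge(f, y)
  }
  ratio <- attr(training, "realized_ratio")
  if (is.null(ratio)) ratio <- sum(y == 0) / sum(y == 1)
  structure(
    list(kind = kind, beta0 = unname(beta[1]), beta1 = unname(beta[2]),
         neg_ratio = ratio, feature_range = range(f)),
    class = "llr_model"
  )
}

#' @export
print.llr_model <- function(x, ...) {
  cat(sprintf(
    "llr_model (%s): llr(f) = %.4g + %.4g * f + log(%.4g)\n",
    x$kind, x$beta0, x$beta1, x$neg_ratio))
  invisible(x)
}

#' Evaluate a log-likelihood ratio model
#'
#' `llr(f) = logit(posterior(f)) - logit(prior)` with
#' `prior = 1 / (1 + neg_ratio)`, i.e. `beta0 + beta1 * f + log(neg_ratio)`.
#' An LLR of 0 means the feature carries no evidence either way; the LLR is
#' strictly monotone in the feature whenever `beta1 != 0`.
#'
#' @param model An `llr_model`.
#' @param feature Numeric vector of finite feature values.
#' @return Numeric vector of LLRs.
#' @export
llr <- function(model, feature) {
  stopifnot(inherits(model, "llr_model"))
  model$beta0 + model$beta1 * feature + log(model$neg_ratio)
}

#' Score candidate pairs on both evidence sources
#'
#' Combines the co-expression LLR (from the correlation table through the
#' expression model) and the interaction LLR (from shared-partner edge scores
#' through the interaction model) into a pair LLR table. A pair missing an
#' evidence source contributes 0 from that source (neutral), so
#' `llr_integrated = llr_expr + llr_int` is always defined.
#'
#' @param corr Correlation table from [pairwise_correlation()].
#' @param weighted_net A `ppi_network` with edge scores
#'   (see [weight_network()]).
#' @param expr_model,int_model Fitted [fit_llr_model()] objects.
#' @param candidate_pairs Optional two-column data frame restricting the
#'   table; default: the union of correlated pairs and network edges.
#' @return Tibble `gene_a`, `gene_b`, `llr_expr`, `llr_int`,
#'   `llr_integrated`, plus coverage flags `has_expr`, `has_int`.
#' @export
score_pairs <- function(corr, weighted_net, expr_model, int_model,
                        candidate_pairs = NULL) {
  ckey <- pair_key(corr$gene_a, corr$gene_b)
  cexpr <- stats::setNames(llr(expr_model, corr$r), ckey)
  e <- weighted_net$edges
  if (!"score" %in% names(e)) stop("network must be weighted; see weight_network()")
  ekey <- pair_key(e$gene_a, e$gene_b)
  cint <- stats::setNames(llr(int_model, e$score), ekey)

  if (is.null(candidate_pairs)) {
    keys <- union(ckey, ekey)
    ab <- do.call(rbind, strsplit(keys, "\t", fixed = TRUE))
    a <- ab[, 1]; b <- ab[, 2]
  } else {
    o <- orient_pairs(as.character(candidate_pairs$gene_a),
                      as.character(candidate_pairs$gene_b))
    a <- o$gene_a; b <- o$gene_b
    keys <- pair_key(a, b)
  }
  le <- unname(cexpr[keys])
  li <- unname(cint[keys])
  has_expr <- !is.na(le)
  has_int <- !is.na(li)
  le[!has_expr] <- 0
  li[!has_int] <- 0
  tibble::tibble(gene_a = a, gene_b = b,
                 llr_expr = le, llr_int = li,
                 llr_integrated = le + li,
                 has_expr = has_expr, has_int = has_int) |>
    dplyr::arrange(.data$gene_a, .data$gene_b)
}
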