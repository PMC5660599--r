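test_that("Mann-Whitney: exact small-sample values and degenerate inputs", {
  expect_equal(mann_whitney(c(1, 2), c(3, 4), "less")$p, 1 / 6)
  expect_equal(mann_whitney(c(3, 4), c(1, 2), "greater")$p, 1 / 6)
  # identical samples: two-sided p = 1
  expect_equal(mann_whitney(c(5, 5, 5), c(5, 5, 5))$p, 1)
  expect_equal(mann_whitney(1:3, 1:3)$p, 1)
})

test_that("Mann-Whitney exact p matches full enumeration for all n <= 10", {
  set.seed(14)
  for (nx in 1:5) for (ny in nx:(10 - nx)) {
    if (ny < 1) next
    x <- rnorm(nx)
    y <- rnorm(ny)
    for (alt in c("less", "greater", "two_sided")) {
      expect_equal(mann_whitney(x, y, alt)$p, enum_mw_p(x, y, alt),
                   tolerance = 1e-12,
                   label = sprintf("nx=%d ny=%d alt=%s", nx, ny, alt))
    }
  }
})

test_that("Mann-Whitney normal approximation tracks enumeration with moderate n", {
  set.seed(3)
  worst <- 0
  for (rep in 1:200) {
    # n = 14 exceeds the exact-path cutoff, so this exercises the
    # tie-corrected, continuity-corrected normal approximation
    x <- rnorm(7)
    y <- rnorm(7)
    p_app <- mann_whitney(x, y, "less")$p
    p_enum <- enum_mw_p(x, y, "less")
    worst <- max(worst, abs(p_app - p_enum))
  }
  expect_lt(worst, 0.01)
})

test_that("BH wrapper matches a first-principles step-up on random vectors", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  expect_equal(benjamini_hochberg(rep(1, 5)), rep(1, 5))
  set.seed(6)
  for (rep in 1:50) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(benjamini_hochberg(p), enum_bh(p), tolerance = 1e-14)
  }
  expect_error(benjamini_hochberg(c(0.5, 0)), "is.na")
})

test_that("rank statistics are invariant to monotone transforms", {
  set.seed(33)
  expr <- matrix(rnorm(30 * 24), 30, 24,
                 dimnames = list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:24)))
  ann <- tibble::tibble(sample_id = colnames(expr),
                        subtype = rep(c("A", "B", "C"), each = 8))
  cx <- complex_set(list(K1 = sprintf("g%02d", 1:5), K2 = sprintf("g%02d", 6:11)))
  r1 <- subtype_complex_enrichment(expr, ann, cx)
  # exp() shifts medians but the enrichment ranks differences, which change;
  # the truly rank-invariant statistic is the collateral mean-rank test:
  prof <- structure(list(altered = list(g01 = colnames(expr)[1:6]),
                         samples = colnames(expr), mode = "mutation_only",
                         definition = "damaging mutation"),
                    class = "alteration_profile")
  c1 <- complex_collateral_test(expr, prof, cx, fdr_target = 0.1)
  c2 <- complex_collateral_test(exp(expr), prof, cx, fdr_target = 0.1)
  expect_equal(c1$p, c2$p)
  expect_equal(c1$effect, c2$effect)
  expect_s3_class(r1, "tbl_df")
})

test_that("subtype enrichment: extreme separation, s-score bounds, skip rule", {
  set.seed(2)
  n_genes <- 40
  expr <- matrix(rnorm(n_genes * 30), n_genes, 30,
                 dimnames = list(sprintf("g%02d", 1:n_genes),
                                 sprintf("s%02d", 1:30)))
  ann <- tibble::tibble(sample_id = colnames(expr),
                        subtype = rep(c("X", "Y"), each = 15))
  # complex members hugely up in X -> member median-differences top the list
  expr[1:5, 1:15] <- expr[1:5, 1:15] + 50
  cx <- complex_set(list(UP = sprintf("g%02d", 1:5),
                         TINY = c("g06", "g07")))          # <3 members: skipped
  res <- subtype_complex_enrichment(expr, ann, cx, fdr_target = 0.1)
  expect_false("TINY" %in% res$complex)
  up_x <- res[res$complex == "UP" & res$subtype == "X", ]
  expect_equal(up_x$s_score, 1)
  expect_lt(up_x$q, 0.1)
  up_y <- res[res$complex == "UP" & res$subtype == "Y", ]
  expect_equal(up_y$s_score, -1)
  expect_true(all(res$s_score >= -1 & res$s_score <= 1))
  expect_true(all(res$q >= res$p))
})

test_that("subtype test is calibrated under label permutation", {
  set.seed(99)
  n_genes <- 150
  expr <- matrix(rnorm(n_genes * 36), n_genes, 36,
                 dimnames = list(sprintf("g%03d", 1:n_genes),
                                 sprintf("s%02d", 1:36)))
  rejections <- 0L
  total <- 0L
  s_scores <- numeric()
  for (perm in 1:10) {
    ann <- tibble::tibble(sample_id = colnames(expr),
                          subtype = sample(rep(c("A", "B"), 18)))
    sets <- lapply(1:25, function(i) sample(rownames(expr), 6))
    names(sets) <- sprintf("K%02d", 1:25)
    res <- subtype_complex_enrichment(expr, ann, complex_set(sets))
    rejections <- rejections + sum(res$p < 0.05)
    total <- total + nrow(res)
    s_scores <- c(s_scores, res$s_score)
  }
  # 99% binomial band around 0.05
  band <- qbinom(c(0.005, 0.995), total, 0.05) / total
  rate <- rejections / total
  expect_gte(rate, band[1])
  expect_lte(rate, band[2])
  # s-score centred on zero under the null
  expect_lt(abs(mean(s_scores)), 0.05)
})

test_that("alteration profiles follow the GISTIC and mutation-class rules", {
  cn <- matrix(0L, 2, 4, dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
  cn["g1", "s1"] <- -2L
  cn["g1", "s2"] <- -1L
  mut <- tibble::tibble(sample_id = c("s3", "s4", "s4"),
                        gene_id = c("g1", "g1", "g2"),
                        mutation_class = c("synonymous", "missense", "other"))
  hom <- build_alteration_profile(mut, cn, "homozygous")
  expect_identical(hom$altered$g1, "s1")
  hemi <- build_alteration_profile(mut, cn, "hemizygous")
  expect_identical(hemi$altered$g1, "s2")
  both <- build_alteration_profile(mut, cn, "mut_or_homdel")
  expect_setequal(both$altered$g1, c("s1", "s4"))   # -2 plus missense only
  mo <- build_alteration_profile(mut, cn, "mutation_only")
  expect_identical(mo$altered$g1, "s4")             # synonymous never counts
  expect_null(mo$altered$g2)                        # "other" never counts
  expect_error(build_alteration_profile(mut, NULL, "hemizygous"), "universe")
})

test_that("single-gene test flags own-protein reduction in altered samples", {
  set.seed(12)
  expr <- matrix(rnorm(5 * 12), 5, 12,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:12)))
  alt <- paste0("s", 1:4)
  expr["g1", alt] <- expr["g1", alt] - 10   # all altered below all unaltered
  prof <- structure(list(altered = list(g1 = alt), samples = colnames(expr),
                         mode = "mut_or_homdel", definition = "x"),
                    class = "alteration_profile")
  res <- single_gene_alteration_test(expr, prof, "g1")
  # minimal achievable one-sided p for 4 vs 8
  expect_equal(res$p, 1 / choose(12, 4))
  expect_error(single_gene_alteration_test(expr, prof, "g9"), "not measured")
})

test_that("collateral mean-rank test: hand-ranked example and exclusions", {
  # 4 proteins, one sample with values (10, 9, 2, 1) -> ranks (4, 3, 2, 1)
  expr <- matrix(c(10, 9, 2, 1), 4, 1,
                 dimnames = list(paste0("P", 1:4), "s1"))
  rk <- coregcomplex:::within_sample_ranks(expr)
  expect_equal(unname(rk[, 1]), c(4, 3, 2, 1))
  expect_equal(mean(rk[c("P1", "P2"), 1]), 3.5)

  # same-chromosome members are excluded under deletion modes
  set.seed(4)
  expr2 <- matrix(rnorm(6 * 12), 6, 12,
                  dimnames = list(paste0("g", 1:6), paste0("s", 1:12)))
  cx <- complex_set(list(K = paste0("g", 1:4)))
  chrom_all_same <- c(g1 = "chr5", g2 = "chr5", g3 = "chr5", g4 = "chr5",
                      g5 = "chr1", g6 = "chr2")
  prof <- structure(list(altered = list(g1 = paste0("s", 1:4)),
                         samples = colnames(expr2), mode = "hemizygous",
                         definition = "GISTIC -1"),
                    class = "alteration_profile")
  res_same <- complex_collateral_test(expr2, prof, cx, chrom_all_same)
  expect_equal(nrow(res_same), 0)   # every partner shares the chromosome
  chrom_mixed <- c(g1 = "chr5", g2 = "chr1", g3 = "chr2", g4 = "chr5",
                   g5 = "chr1", g6 = "chr2")
  res_mixed <- complex_collateral_test(expr2, prof, cx, chrom_mixed)
  expect_equal(res_mixed$n_members_used, 2)  # g4 (same chr) and g1 excluded
  # mutation-only mode excludes just the altered gene
  prof$mode <- "mutation_only"
  res_mut <- complex_collateral_test(expr2, prof, cx, chrom_all_same)
  expect_equal(res_mut$n_members_used, 3)
  expect_error(complex_collateral_test(expr2, structure(prof,
    class = "alteration_profile"), cx, NULL, min_altered = 3),
    NA)  # chromosome map optional for mutation-only
})

test_that("catalogue overlap: perfect, disjoint, and enumeration oracle", {
  universe <- sprintf("u%03d", 1:60)
  ref <- complex_set(list(R1 = universe[1:5], R2 = universe[11:16]))
  found <- complex_set(list(F1 = universe[1:5],      # identical to R1
                            F2 = universe[30:34]))   # disjoint from both
  res <- catalogue_overlap(found, ref, universe)
  f1 <- res[res$complex == "F1", ]
  expect_equal(f1$best_reference, "R1")
  expect_equal(f1$jaccard, 1)
  expect_equal(f1$coverage, 1)
  expect_equal(f1$p, 1 / choose(60, 5), tolerance = 1e-10)
  f2 <- res[res$complex == "F2", ]
  expect_equal(f2$jaccard, 0)
  expect_gte(f2$p, 0.5)

  # p matches exhaustive enumeration in a small universe
  uni <- sprintf("v%02d", 1:12)
  refs <- complex_set(list(R = uni[1:4]))
  fnds <- complex_set(list(F1 = c(uni[1:2], uni[5:6])))
  p_pkg <- catalogue_overlap(fnds, refs, uni)$p
  p_enum <- enum_hyper_upper(2, 4, 4, 12)
  expect_equal(p_pkg, p_enum, tolerance = 1e-10)
  expect_error(catalogue_overlap(fnds, refs, character()), "universe")
})

test_that("isogenic DE: tech-rep averaging, min imputation, Welch test", {
  # protein absent in one sample is imputed with that sample's minimum
  lfq <- matrix(c(100, 100, 110, 105, 400, 410, 405, 395,
                  NA, 900, 80, 82, 300, 310, 305, 295),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("pA", "pB"),
                                c("wt1", "wt2", "wt3", "wt4",
                                  "ko1", "ko2", "ko3", "ko4")))
  cond <- factor(rep(c("wt", "ko"), each = 4), levels = c("wt", "ko"))
  res <- isogenic_differential_expression(lfq, cond)  # effect = ko - wt
  expect_identical(sort(res$gene), c("pA", "pB"))
  # pA: identical-ish groups in log2 space around log2(400/102.5) for effect
  pa <- res[res$gene == "pA", ]
  expect_equal(pa$effect, mean(log2(c(400, 410, 405, 395))) -
                 mean(log2(c(100, 100, 110, 105))))
  # pB wt1 value NA -> imputed with min of wt1 column (= 100 from pA)
  pb <- res[res$gene == "pB", ]
  imputed_wt1 <- log2(100)
  expect_equal(pb$effect, mean(log2(c(300, 310, 305, 295))) -
                 mean(c(imputed_wt1, log2(900), log2(80), log2(82))))

  # identical groups give p = 1
  same <- matrix(rep(c(50, 60, 70, 50, 60, 70), 2), nrow = 2, byrow = TRUE,
                 dimnames = list(c("x", "y"), paste0("r", 1:6)))
  res_same <- isogenic_differential_expression(same, rep(c("a", "b"), each = 3))
  expect_true(all(res_same$p == 1))

  # technical replicates averaged before testing
  tech <- matrix(c(10, 12, 20, 22, 30, 32, 40, 42), nrow = 1,
                 dimnames = list("p", paste0("run", 1:8)))
  tech_res <- isogenic_differential_expression(
    tech, condition = rep(c("a", "b"), each = 4),
    bio_replicate = c("A1", "A1", "A2", "A2", "B1", "B1", "B2", "B2"))
  manual <- t.test(log2(c(31, 41)), log2(c(11, 21)), var.equal = FALSE)
  expect_equal(tech_res$p, manual$p.value)
  expect_error(isogenic_differential_expression(
    tech, rep(c("a", "b"), 4),
    bio_replicate = c("A1", "A1", "A2", "A2", "B1", "B1", "B2", "B2")),
    "mixed conditions")
})

test_that("downstream tests are calibrated on permuted null data", {
  # type-I error of the collateral test under random alteration labels
  set.seed(55)
  expr <- matrix(rnorm(60 * 40), 60, 40,
                 dimnames = list(sprintf("g%02d", 1:60), sprintf("s%02d", 1:40)))
  cx <- complex_set(stats::setNames(
    lapply(1:12, function(i) sample(rownames(expr), 5)), sprintf("K%02d", 1:12)))
  hits <- 0L
  total <- 0L
  for (rep in 1:40) {
    g <- sample(unlist(cx$members), 1)
    prof <- structure(list(altered = stats::setNames(
      list(sample(colnames(expr), 8)), g),
      samples = colnames(expr), mode = "mutation_only", definition = "null"),
      class = "alteration_profile")
    res <- complex_collateral_test(expr, prof, cx)
    hits <- hits + sum(res$p < 0.05)
    total <- total + nrow(res)
  }
  band <- qbinom(c(0.005, 0.995), total, 0.05) / total
  expect_gte(hits / total, band[1] * 0.5)  # one-sided test is discrete
  expect_lte(hits / total, band[2])
})
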