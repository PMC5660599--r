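# hand-built pair LLR table for mechanics tests
pair_table <- function(df) {
  o <- coregcomplex:::orient_pairs(df$gene_a, df$gene_b)
  tibble::tibble(gene_a = o$gene_a, gene_b = o$gene_b,
                 llr_expr = df$llr_expr, llr_int = df$llr_int,
                 llr_integrated = df$llr_expr + df$llr_int,
                 has_expr = df$llr_expr != 0, has_int = df$llr_int != 0)
}

test_that("score_set sums unordered pair LLRs; singletons score zero", {
  pt <- pair_table(data.frame(gene_a = c("A", "A", "B"),
                              gene_b = c("B", "C", "C"),
                              llr_expr = c(1, 3, 5),
                              llr_int = c(2, 4, 6)))
  expect_equal(score_set(c("A", "B", "C"), pt),
               c(llr_expr = 9, llr_int = 12, llr_integrated = 21))
  expect_equal(score_set("A", pt),
               c(llr_expr = 0, llr_int = 0, llr_integrated = 0))
  expect_equal(score_set(character(), pt)[["llr_integrated"]], 0)
  # additivity: disjoint union = parts + cross pairs
  pt2 <- pair_table(data.frame(gene_a = c("A", "C"), gene_b = c("B", "D"),
                               llr_expr = c(1, 2), llr_int = c(1, 2)))
  u <- score_set(c("A", "B", "C", "D"), pt2)
  expect_equal(u, score_set(c("A", "B"), pt2) + score_set(c("C", "D"), pt2))
})

test_that("seed enumeration lists edges and triangles, dual-filtered", {
  # K4 graph: 6 pairs + 4 triangles before filtering
  nodes <- c("A", "B", "C", "D")
  cmb <- utils::combn(nodes, 2)
  k4 <- ppi_network(data.frame(gene_a = cmb[1, ], gene_b = cmb[2, ]))
  pt <- pair_table(data.frame(gene_a = cmb[1, ], gene_b = cmb[2, ],
                              llr_expr = rep(1, 6), llr_int = rep(1, 6)))
  cand <- enumerate_seeds(k4, pt)
  expect_equal(sum(cand$kind == "pair"), 6)
  expect_equal(sum(cand$kind == "triangle"), 4)

  # triangle-free graph -> pairs only
  path <- ppi_network(data.frame(gene_a = c("A", "B"), gene_b = c("B", "C")))
  ptp <- pair_table(data.frame(gene_a = c("A", "B"), gene_b = c("B", "C"),
                               llr_expr = c(1, 1), llr_int = c(1, 1)))
  expect_true(all(enumerate_seeds(path, ptp)$kind == "pair"))

  # dual filter: positive integrated score is not enough
  one_sided <- pair_table(data.frame(gene_a = "A", gene_b = "B",
                                     llr_expr = 5, llr_int = -1))
  ab <- ppi_network(data.frame(gene_a = "A", gene_b = "B"))
  expect_equal(nrow(enumerate_seeds(ab, one_sided)), 0)
})

test_that("triangle enumeration matches brute force on random graphs", {
  set.seed(5)
  for (rep in 1:25) {
    g <- igraph::sample_gnp(30, 0.2)
    el <- igraph::as_edgelist(g)
    if (!nrow(el)) next
    net <- ppi_network(data.frame(gene_a = sprintf("n%02d", el[, 1]),
                                  gene_b = sprintf("n%02d", el[, 2])),
                       nodes = sprintf("n%02d", 1:30))
    tri <- coregcomplex:::triangle_list(net)
    # brute force: check all 3-subsets of nodes with all edges present
    adj <- matrix(FALSE, 30, 30)
    adj[el] <- TRUE
    adj <- adj | t(adj)
    cnt <- 0
    for (i in 1:28) for (j in (i + 1):29) for (k in (j + 1):30) {
      if (adj[i, j] && adj[i, k] && adj[j, k]) cnt <- cnt + 1
    }
    expect_equal(length(tri), cnt)
  }
})

test_that("greedy seeding respects overlap and breaks ties lexicographically", {
  cand <- tibble::tibble(
    members = list(c("A", "B"), c("C", "D"), c("B", "C", "E")),
    kind = c("pair", "pair", "triangle"),
    llr_expr = c(3, 2, 2), llr_int = c(2, 1, 2),
    llr_integrated = c(5, 3, 4))
  st <- greedy_seed_clusters(cand)
  picked <- st$clusters[lengths(st$clusters) >= 2]
  # AB (5) first, then BCE (4) overlaps B -> dropped, CD (3) kept; E singleton
  expect_identical(picked, list(c("A", "B"), c("C", "D")))
  expect_true("E" %in% unlist(st$clusters[lengths(st$clusters) == 1]))

  # exact tie -> lexicographically smaller member tuple wins
  tie <- tibble::tibble(
    members = list(c("X", "Z"), c("A", "Z")),
    kind = "pair", llr_expr = c(1, 1), llr_int = c(1, 1),
    llr_integrated = c(2, 2))
  st2 <- greedy_seed_clusters(tie)
  expect_identical(st2$clusters[lengths(st2$clusters) == 2][[1]], c("A", "Z"))
})

test_that("refinement recovers a planted 4-clique from a pair seed", {
  nodes <- c("A", "B", "C", "D")
  cmb <- utils::combn(nodes, 2)
  pt <- pair_table(data.frame(gene_a = cmb[1, ], gene_b = cmb[2, ],
                              llr_expr = 2, llr_int = 1))
  st <- greedy_seed_clusters(
    tibble::tibble(members = list(c("A", "B")), kind = "pair",
                   llr_expr = 2, llr_int = 1, llr_integrated = 3),
    genes = nodes)
  out <- refine_clusters(st, pt)
  big <- out$clusters[lengths(out$clusters) == 4]
  expect_equal(length(big), 1)
  expect_identical(sort(big[[1]]), nodes)
  # every accepted move increased both scores
  expect_true(all(out$move_log$delta_llr_expr > 0))
  expect_true(all(out$move_log$delta_llr_int > 0))
})

test_that("dual constraint blocks moves that improve only one source", {
  # merging would gain +5 expression but lose interaction -> no move
  pt <- pair_table(data.frame(gene_a = c("A", "C", "A", "A", "B", "B"),
                              gene_b = c("B", "D", "C", "D", "C", "D"),
                              llr_expr = c(2, 2, 5, 5, 5, 5),
                              llr_int = c(2, 2, -1, -1, -1, -1)))
  st <- coregcomplex:::new_cluster_state(list(c("A", "B"), c("C", "D")))
  out <- refine_clusters(st, pt)
  expect_equal(nrow(out$move_log), 0)
  expect_identical(out$clusters, list(c("A", "B"), c("C", "D")))
})

test_that("final state is a constrained local optimum on toy instances", {
  # exhaustive single-move check on a 10-gene instance with two planted blocks
  set.seed(21)
  genes <- sprintf("g%02d", 1:10)
  cmb <- utils::combn(genes, 2)
  in_b1 <- cmb[1, ] %in% genes[1:4] & cmb[2, ] %in% genes[1:4]
  in_b2 <- cmb[1, ] %in% genes[5:8] & cmb[2, ] %in% genes[5:8]
  df <- data.frame(gene_a = cmb[1, ], gene_b = cmb[2, ],
                   llr_expr = ifelse(in_b1 | in_b2, 1.5, -0.5) + rnorm(45, 0, 0.1),
                   llr_int = ifelse(in_b1 | in_b2, 1.0, -0.3) + rnorm(45, 0, 0.1))
  pt <- pair_table(df)
  net <- ppi_network(data.frame(gene_a = cmb[1, ], gene_b = cmb[2, ])[
    df$llr_int > 0, ], nodes = genes)
  st <- greedy_seed_clusters(enumerate_seeds(net, pt), genes = genes)
  out <- refine_clusters(st, pt)

  delta <- function(clusters) {
    tot <- colSums(do.call(rbind, lapply(clusters, score_set, pairs = pt)))
    c(tot[["llr_expr"]], tot[["llr_int"]])
  }
  base <- delta(out$clusters)
  improves_both <- function(clusters) {
    d <- delta(clusters) - base
    d[1] > 1e-9 && d[2] > 1e-9
  }
  cl <- out$clusters
  # all merges
  for (i in seq_along(cl)) for (j in seq_along(cl)) {
    if (i < j) {
      expect_false(improves_both(c(cl[-c(i, j)], list(c(cl[[i]], cl[[j]])))))
    }
  }
  # all removals and switches
  for (i in seq_along(cl)) {
    if (length(cl[[i]]) < 2) next
    for (g in cl[[i]]) {
      rest <- setdiff(cl[[i]], g)
      expect_false(improves_both(c(cl[-i], list(rest), list(g))))
      for (j in seq_along(cl)) {
        if (j == i) next
        moved <- cl
        moved[[i]] <- rest
        moved[[j]] <- c(moved[[j]], g)
        expect_false(improves_both(moved))
      }
    }
  }
})

test_that("cached cluster scores equal recomputation from the pair table", {
  expr <- rbind(corr_block_matrix(5, 50, 0.75, seed = 3),
                corr_block_matrix(4, 50, 0.75, seed = 4),
                matrix(rnorm(21 * 50), 21, 50))
  rownames(expr) <- sprintf("g%02d", 1:30)
  colnames(expr) <- sprintf("s%02d", 1:50)
  planted <- list(K1 = sprintf("g%02d", 1:5), K2 = sprintf("g%02d", 6:9))
  cmb1 <- utils::combn(planted$K1, 2)
  cmb2 <- utils::combn(planted$K2, 2)
  set.seed(8)
  bg <- matrix(sample(rownames(expr), 30), ncol = 2)
  edges <- data.frame(gene_a = c(cmb1[1, ], cmb2[1, ], bg[, 1]),
                      gene_b = c(cmb1[2, ], cmb2[2, ], bg[, 2]))
  edges <- edges[edges$gene_a != edges$gene_b, ]
  o <- coregcomplex:::orient_pairs(edges$gene_a, edges$gene_b)
  edges <- unique(data.frame(gene_a = o$gene_a, gene_b = o$gene_b))
  tp <- toy_pair_table(expr, edges, complex_set(planted), seed = 5L)
  st <- greedy_seed_clusters(enumerate_seeds(tp$network, tp$pairs),
                             genes = rownames(expr))
  out <- refine_clusters(st, tp$pairs)
  for (cl in out$clusters[lengths(out$clusters) >= 2]) {
    direct <- score_set(cl, tp$pairs)
    expect_gt(direct[["llr_expr"]], 0)
    expect_gt(direct[["llr_int"]], 0)
  }
  # integrated total strictly increases along the move log
  if (nrow(out$move_log)) {
    steps <- out$move_log$delta_llr_expr + out$move_log$delta_llr_int
    expect_true(all(steps > 0))
  }
})

test_that("end-to-end discovery on a small planted dataset is deterministic", {
  cfg <- sim_config(n_genes = 120, n_samples = 40, n_complexes = 5,
                    complex_size = c(3, 6), n_background_edges = 80,
                    missing_rate = c(0, 0.15), seed = 42L)
  d <- simulate_dataset(cfg)
  ref <- perturb_reference(d$truth$complexes, rownames(d$protein), seed = 1L)
  dc <- discovery_config(n_random = 4, seed = 9L)
  suppressMessages({
    r1 <- discover_complexes(d$protein, d$network, ref, dc)
    r2 <- discover_complexes(d$protein, d$network, ref, dc)
  })
  # reruns are identical, down to the serialized GMT
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  write_complexes(r1$complexes, f1)
  write_complexes(r2$complexes, f2)
  expect_identical(readLines(f1), readLines(f2))

  # output complexes are disjoint and dual-supported
  genes <- unlist(r1$complexes$members)
  expect_false(anyDuplicated(genes) > 0)
  expect_true(all(r1$complexes$llr_expr > 0))
  expect_true(all(r1$complexes$llr_int > 0))
  expect_true(all(r1$move_log$delta_llr_expr > 0))
  expect_true(all(r1$move_log$delta_llr_int > 0))

  # most planted complexes recovered on this easy instance
  ev <- evaluate_recovery(r1, d$truth)
  expect_gte(ev$recall, 0.6)

  # tidy/glance accessors agree with the object
  td <- tidy(r1)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), nrow(r1$complexes))
  gl <- glance(r1)
  expect_equal(gl$n_complexes, nrow(r1$complexes))
  expect_s3_class(autoplot(r1), "ggplot")
})

test_that("fdr curve bookkeeping: ratio definition and monotone smoothing", {
  real <- list(sizes = c(5, 4, 3), scores = c(10, 6, 2))
  rand <- list(list(sizes = c(2, 2), scores = c(7, 1)),
               list(sizes = 3, scores = 3))
  curve <- coregcomplex:::fdr_curve_from_runs(real$sizes, real$scores, rand)
  expect_equal(curve$threshold, c(2, 6, 10))
  expect_equal(curve$genes_real, c(12, 9, 5))
  # randomization genes >= t: t=2: (2+3)/2, t=6: (2+0)/2, t=10: 0
  expect_equal(curve$mean_genes_random, c(2.5, 1, 0))
  expect_equal(curve$fdr, c(2.5 / 12, 1 / 9, 0))
  expect_true(all(diff(curve$fdr_smoothed) <= 0))
})
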