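# Correlation, thresholded co-expression, k-core decomposition, interaction
# network, core-gene nomination.

test_that("pairwise Pearson matches the covariance formula", {
  m <- rbind(g1 = c(1, 2, 3, 4, 5, 6),
             g2 = c(1, 2, 3, 4, 5, 6),
             g3 = -c(1, 2, 3, 4, 5, 6))
  x <- make_expr(m, groups = letters[1:6], genes = rownames(m))
  r <- pairwise_pearson(x)
  expect_equal(r["g1", "g2"], 1)
  expect_equal(r["g1", "g3"], -1)
  set.seed(2)
  m2 <- matrix(rnorm(120), nrow = 20,
               dimnames = list(sprintf("g%02d", 1:20), sprintf("a%d", 1:6)))
  x2 <- expression_matrix(m2, data.frame(array = colnames(m2), group = "all",
                                         subgroup = "all"))
  r2 <- pairwise_pearson(x2)
  for (i in 1:5) for (j in 6:10) {
    a <- m2[i, ]; b <- m2[j, ]
    oracle <- mean((a - mean(a)) * (b - mean(b))) / (sd(a) * sd(b)) * 6 / 5
    expect_equal(r2[i, j], oracle, tolerance = 1e-12)
  }
  expect_error(pairwise_pearson(make_expr(matrix(1:4, 2), c("a", "b"))),
               "3 arrays")
  m3 <- rbind(m2, gXX = rep(1, 6))
  x3 <- expression_matrix(m3, x2$design)
  expect_warning(r3 <- pairwise_pearson(x3), "zero-variance")
  expect_false("gXX" %in% rownames(r3))
})

test_that("hard thresholding builds the expected edges", {
  r <- matrix(0.95, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  diag(r) <- 1
  net <- build_coexpression(r, r_min = 0.9)
  expect_equal(nrow(net$edges), 3L)
  expect_true(all(net$degree == 2))
  expect_true(all(net$core == 2))
  # r_min = 1 on noisy data: only exact duplicates connect
  set.seed(4)
  x <- make_expr(matrix(rnorm(60), 10), groups = letters[1:6])
  net1 <- build_coexpression(pairwise_pearson(x), r_min = 1)
  expect_equal(nrow(net1$edges), 0L)
  expect_length(net1$nodes, 10L)  # isolated nodes retained
  # negative correlations admitted via |r| unless positive_only
  rn <- matrix(c(1, -0.95, -0.95, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(nrow(build_coexpression(rn, 0.9)$edges), 1L)
  expect_equal(nrow(build_coexpression(rn, 0.9, positive_only = TRUE)$edges), 0L)
})

test_that("k-core numbers match the definition on canonical graphs", {
  tri <- gene_network(c("a", "b", "c"),
                      data.frame(from = c("a", "a", "b"), to = c("b", "c", "c")))
  expect_true(all(tri$core == 2))
  star <- gene_network(c("h", sprintf("l%d", 1:5)),
                       data.frame(from = "h", to = sprintf("l%d", 1:5)))
  expect_true(all(star$core == 1))
  # K5 plus a pendant vertex: max core is K5 at k = 4
  k5 <- t(combn(sprintf("k%d", 1:5), 2))
  net <- gene_network(c(sprintf("k%d", 1:5), "p"),
                      data.frame(from = c(k5[, 1], "k1"), to = c(k5[, 2], "p")))
  mk <- max_kcore(net)
  expect_equal(mk$k, 4L)
  expect_setequal(mk$genes, sprintf("k%d", 1:5))
  # forest: every node in the 1-core
  forest <- gene_network(letters[1:6],
                         data.frame(from = c("a", "b", "d"), to = c("b", "c", "e")))
  expect_equal(max_kcore(forest)$k, 1L)
  expect_setequal(max_kcore(forest)$genes, c("a", "b", "c", "d", "e"))
  # empty network
  empty <- gene_network(character(0))
  expect_equal(max_kcore(empty)$k, 0L)
  expect_length(max_kcore(empty)$genes, 0L)
})

test_that("k-core decomposition equals brute force and the igraph reference", {
  set.seed(6)
  for (rep in 1:40) {
    n <- sample(5:50, 1)
    net <- er_network(n, sample(c(0.1, 0.3), 1), seed = rep)
    oracle <- kcore_oracle(net$edges, net$nodes)
    expect_identical(net$core, oracle)
    if (nrow(net$edges) > 0) {
      g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                         vertices = net$nodes)
      ig <- igraph::coreness(g)
      expect_equal(unname(net$core[names(ig)]), unname(as.integer(ig)))
    }
  }
})

test_that("removing an edge never increases a core number", {
  set.seed(9)
  for (rep in 1:20) {
    net <- er_network(sample(8:25, 1), 0.3, seed = 100 + rep)
    if (nrow(net$edges) == 0) next
    drop <- sample(nrow(net$edges), 1)
    sub <- gene_network(net$nodes, net$edges[-drop, , drop = FALSE])
    expect_true(all(sub$core <= net$core[names(sub$core)]))
  }
})

test_that("degree and core numbers are invariant to relabeling", {
  net <- er_network(20, 0.3, seed = 55)
  perm <- setNames(sprintf("z%02d", sample(20)), net$nodes)
  relabeled <- gene_network(unname(perm[net$nodes]),
                            data.frame(from = unname(perm[net$edges$from]),
                                       to = unname(perm[net$edges$to])))
  expect_equal(sort(unname(relabeled$degree)), sort(unname(net$degree)))
  expect_equal(sort(unname(relabeled$core)), sort(unname(net$core)))
})

test_that("interaction networks restrict to attributed genes plus partners", {
  edges <- canonical_edges(c("a", "b"), c("b", "c"))
  attrs <- data.frame(gene = "b", membership = "intersection", direction = "up",
                      stringsAsFactors = FALSE)
  net <- interaction_network(edges, attrs)
  expect_equal(unname(net$degree[c("a", "b", "c")]), c(1L, 2L, 1L))
  # handshake lemma on a random edge list
  set.seed(10)
  rnd <- er_network(30, 0.2, seed = 3)
  expect_equal(sum(rnd$degree), 2L * nrow(rnd$edges))
  # empty edge list -> edgeless network; unknown-gene attributes dropped
  expect_warning(
    e0 <- interaction_network(canonical_edges(character(0), character(0)), attrs),
    "absent")
  expect_equal(nrow(e0$edges), 0L)
  expect_true(all(e0$degree == 0))
})

test_that("core-gene nomination combines max k-core and top interaction degree", {
  # triangle in co-expression, star hub in interaction, no overlap required
  r <- matrix(0.99, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  diag(r) <- 1
  coexpr <- build_coexpression(r, 0.9)
  inter <- gene_network(c("h", sprintf("x%d", 1:9)),
                        data.frame(from = "h", to = sprintf("x%d", 1:9)))
  core <- identify_core_genes(coexpr, inter, top_fraction = 0.1)
  # a, b, c enter via the k-core arm though absent from the interaction network
  expect_true(all(c("a", "b", "c") %in% core$gene))
  expect_true("h" %in% core$gene)   # top-degree arm
  # ranking: core_number desc first, so the triangle precedes the hub
  expect_identical(core$gene[1:3], c("a", "b", "c"))
  # all-isolated networks nominate nothing
  iso <- gene_network(c("a", "b"))
  expect_equal(nrow(identify_core_genes(iso, iso)), 0L)
})

test_that("a planted module hub is recovered as the top core gene", {
  for (s in 1:2) {
    d <- cohort_design(n_genes = 1500)
    e <- planted_effects(d, seed = s, n_de_shared = 0L, n_de_mild_only = 0L,
                         n_de_severe_only = 0L, n_modules = 1L, module_size = 30L)
    x <- pool_samples(simulate_individuals(d, e), d, e)
    vars <- apply(x$values, 1, var)
    cand <- names(sort(vars, decreasing = TRUE))[1:120]
    net <- build_coexpression(pairwise_pearson(x, genes = cand), r_min = 0.8)
    inter <- suppressWarnings(interaction_network(
      simulate_interactions(d, e), data.frame(gene = cand)))
    core <- identify_core_genes(net, inter)
    expect_identical(core$gene[1], e$hubs[1])
  }
})
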