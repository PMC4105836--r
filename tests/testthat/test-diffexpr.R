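# Group-means fit, empirical-Bayes moderation, BH adjustment, DE gates,
# set algebra, clustering.

fit_fixture <- function() {
  make_expr(rbind(c(1, 1, 2, 2, 3, 3),
                  c(0, 2, 1, 1, 1, 1)),
            groups = c("healthy", "healthy", "mild", "mild", "severe", "severe"))
}

test_that("group means and pooled variance match hand arithmetic", {
  fit <- fit_group_means(fit_fixture())
  expect_equal(unname(fit$means["g01", ]), c(1, 2, 3))
  expect_equal(unname(fit$s2[["g01"]]), 0)
  # healthy (0,2): mean 1, SS contribution 2; other groups contribute 0
  expect_equal(unname(fit$means["g02", "healthy"]), 1)
  expect_equal(unname(fit$s2[["g02"]]), 2 / 3)
  expect_equal(fit$dg, 3)
  # a group with a single array has no within-group variance
  bad <- make_expr(matrix(1:9, 3), groups = c("h", "h", "m"))
  expect_error(fit_group_means(bad), "fewer than two arrays")
})

test_that("the fit equals the closed-form least-squares solution", {
  set.seed(3)
  groups <- rep(c("healthy", "mild", "severe"), each = 2)
  x <- make_expr(matrix(rnorm(180), nrow = 30), groups = groups)
  fit <- fit_group_means(x)
  for (i in seq_len(30)) {
    lmfit <- lm(x$values[i, ] ~ 0 + factor(groups, levels = fit$groups))
    expect_equal(unname(fit$means[i, ]), unname(coef(lmfit)), tolerance = 1e-12)
    expect_equal(unname(fit$s2[[i]]), sum(resid(lmfit)^2) / 3, tolerance = 1e-12)
  }
})

test_that("moderation limits: d0 = 0 gives the ordinary t, d0 = Inf pools fully", {
  set.seed(8)
  groups <- rep(c("healthy", "mild", "severe"), each = 2)
  x <- make_expr(matrix(rnorm(600), nrow = 100), groups = groups)
  fit <- fit_group_means(x)
  de0 <- run_de(x, d0 = 0)
  ord_t <- (fit$means[, "mild"] - fit$means[, "healthy"]) / sqrt(fit$s2 * (1 / 2 + 1 / 2))
  got <- de0$moderated_t[de0$contrast == "mild_vs_healthy"]
  expect_equal(got, unname(ord_t), tolerance = 1e-10)

  ebi <- ebayes_moderate(fit$s2, fit$dg, d0 = Inf)
  expect_true(all(ebi$s2_post == ebi$s0_sq))
  expect_error(ebayes_moderate(rep(0, 20), 3), "zero")
})

test_that("hyperparameters are recovered from a planted scaled-F prior", {
  set.seed(21)
  d0_true <- 4; s0_true <- 0.04; dg <- 3
  sigma2 <- d0_true * s0_true / rchisq(5000, d0_true)
  s2 <- sigma2 * rchisq(5000, dg) / dg
  eb <- ebayes_moderate(s2, dg)
  expect_lt(abs(eb$d0 - d0_true) / d0_true, 0.4)
  expect_lt(abs(eb$s0_sq - s0_true) / s0_true, 0.15)
  # trigamma inversion is a true inverse
  for (y in c(1e-5, 0.01, 0.7, 3, 1e6)) {
    expect_equal(trigamma(trigamma_inverse(y)), y, tolerance = 1e-8)
  }
})

test_that("moderated statistics agree with the reference empirical-Bayes fit", {
  set.seed(17)
  groups <- rep(c("healthy", "mild", "severe"), each = 2)
  sigma2 <- 4 * 0.04 / rchisq(300, 4)
  m <- t(vapply(sigma2, function(s) rnorm(6, 8, sqrt(s)), numeric(6)))
  x <- make_expr(m, groups = groups)
  de <- run_de(x)
  eb <- attr(de, "ebayes")
  design <- model.matrix(~0 + factor(groups, levels = c("healthy", "mild", "severe")))
  colnames(design) <- c("healthy", "mild", "severe")
  lf <- limma::lmFit(x$values, design)
  lf <- limma::contrasts.fit(lf, limma::makeContrasts(mild - healthy, levels = design))
  lf <- limma::eBayes(lf)
  expect_lt(abs(eb$d0 - lf$df.prior) / lf$df.prior, 0.2)
  expect_lt(abs(eb$s0_sq - lf$s2.prior) / lf$s2.prior, 0.1)
  ours <- de$moderated_t[de$contrast == "mild_vs_healthy"]
  expect_gt(cor(ours, lf$t[, 1]), 0.999)
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_bh(1), 1)
  expect_error(adjust_bh(c(0.5, 1.2)), "0, 1")
  set.seed(13)
  for (rep in 1:200) {
    p <- runif(sample(1:20, 1))
    expect_equal(adjust_bh(p), bh_oracle(p))
  }
  # permutation invariance
  p <- runif(15)
  perm <- sample(15)
  expect_equal(adjust_bh(p)[perm], adjust_bh(p[perm]))
})

test_that("the three DE gates act as stated at their boundaries", {
  de <- data.frame(gene = c("a", "b", "c"),
                   contrast = "mild_vs_healthy",
                   log2fc = c(log2(1.5), 1, 1),
                   moderated_t = 5,
                   p = c(0.01, 0.05, 0.01),
                   fdr = c(0.01, 0.01, 0.05),
                   stringsAsFactors = FALSE)
  called <- select_de(de)
  expect_identical(called$gene, "a")   # FC gate inclusive, p/fdr gates exclusive
  expect_identical(called$call, "up")
  # calls shrink as any threshold tightens
  set.seed(5)
  big <- data.frame(gene = sprintf("g%03d", 1:200), contrast = "c",
                    log2fc = rnorm(200), moderated_t = 0,
                    p = runif(200), fdr = runif(200), stringsAsFactors = FALSE)
  n_calls <- function(...) nrow(select_de(big, ...))
  expect_gte(n_calls(fc_threshold = 1.2), n_calls(fc_threshold = 1.8))
  expect_gte(n_calls(p_threshold = 0.2), n_calls(p_threshold = 0.01))
  expect_gte(n_calls(fdr_threshold = 0.5), n_calls(fdr_threshold = 0.05))
})

test_that("DE set algebra partitions the union with directions", {
  mk <- function(genes, calls, contrast)
    data.frame(gene = genes, contrast = contrast, log2fc = 1, moderated_t = 5,
               p = 0.001, fdr = 0.001, call = calls, stringsAsFactors = FALSE)
  res <- de_set_algebra(list(mk(c("a", "b"), c("up", "down"), "mild"),
                             mk(c("b", "c"), c("up", "up"), "severe")))
  expect_equal(res$intersection$gene, "b")
  expect_equal(res$intersection$direction_a, "down")
  expect_equal(res$intersection$direction_b, "up")
  expect_equal(res$first_only$gene, "a")
  expect_equal(res$second_only$gene, "c")
  # disjoint and equal cases
  dis <- de_set_algebra(list(mk("a", "up", "m"), mk("b", "up", "s")))
  expect_equal(nrow(dis$intersection), 0L)
  eq <- de_set_algebra(list(mk(c("a", "b"), "up", "m"), mk(c("a", "b"), "up", "s")))
  expect_equal(nrow(eq$first_only), 0L)
  expect_equal(nrow(eq$second_only), 0L)
})

test_that("hierarchical clustering uses correlation distance with average linkage", {
  m <- rbind(g1 = c(1, 2, 3, 4), g2 = c(2, 4, 6, 8), g3 = c(4, 3, 2, 1))
  x <- make_expr(m, groups = c("a", "b", "c", "d"), genes = rownames(m))
  hc <- hierarchical_cluster(x)
  h <- hc$gene_hclust
  # identical profiles (r = 1) merge at height 0; anti-correlated at 2
  expect_equal(min(h$height), 0, tolerance = 1e-12)
  expect_equal(max(h$height), 2, tolerance = 1e-12)
  expect_match(hc$gene_newick, "^\\(")
  expect_setequal(ape::read.tree(text = hc$gene_newick)$tip.label,
                  c("g1", "g2", "g3"))
  # constant gene: r fixed at 0, with a warning
  m2 <- rbind(m, g4 = c(5, 5, 5, 5))
  expect_warning(hc2 <- hierarchical_cluster(
    make_expr(m2, groups = c("a", "b", "c", "d"), genes = rownames(m2))),
    "constant")
})

test_that("linkage heights match a naive agglomeration oracle", {
  set.seed(19)
  m <- matrix(rnorm(60), nrow = 10,
              dimnames = list(sprintf("g%02d", 1:10), sprintf("a%d", 1:6)))
  x <- expression_matrix(m, data.frame(array = colnames(m), group = "all",
                                       subgroup = "all"))
  hc <- hierarchical_cluster(x)
  d <- 1 - cor(t(m))
  expect_equal(sort(hc$gene_hclust$height), average_linkage_heights(as.dist(d)),
               tolerance = 1e-10)
  da <- dist(t(m))
  expect_equal(sort(hc$array_hclust$height), average_linkage_heights(da),
               tolerance = 1e-10)
})

test_that("moderated p-values are calibrated under the global null", {
  for (s in 1:3) {
    d <- cohort_design(n_genes = 2000)
    e <- planted_effects(d, seed = s, n_de_shared = 0L, n_de_mild_only = 0L,
                         n_de_severe_only = 0L, n_modules = 0L)
    x <- pool_samples(simulate_individuals(d, e), d, e)
    de <- run_de(x)
    p <- de$p[de$contrast == "severe_vs_healthy"]
    ks <- suppressWarnings(stats::ks.test(p, "punif", alternative = "greater"))
    expect_gt(ks$p.value, 0.01)  # not anti-conservative
  }
})
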