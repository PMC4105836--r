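# Synthetic-cohort generator: determinism, degenerate limits, and
# Monte-Carlo recovery of the planted structure.

test_that("the whole cohort is a pure function of the seed", {
  d <- cohort_design(n_genes = 300)
  run <- function() {
    e <- planted_effects(d, seed = 11)
    ind <- simulate_individuals(d, e)
    x <- pool_samples(ind, d, e)
    list(ind = ind, x = x$values,
         flags = simulate_flags(x, seed = 11),
         ann = simulate_annotation(d, e),
         edges = suppressWarnings(simulate_interactions(d, e)),
         qpcr = simulate_qpcr(d, e, genes = e$hubs),
         morpho = simulate_morphometry(d, seed = 11))
  }
  expect_identical(run(), run())
  # and a different seed changes the draw
  e2 <- planted_effects(d, seed = 12)
  expect_false(identical(simulate_individuals(d, e2)[1, 1],
                         run()$ind[1, 1]))
})

test_that("zero noise and no planted effects reproduce the baseline exactly", {
  d <- cohort_design(n_genes = 40)
  e <- planted_effects(d, seed = 1, n_de_shared = 0L, n_de_mild_only = 0L,
                       n_de_severe_only = 0L, n_modules = 0L,
                       individual_sd = 0, measurement_sd = 0)
  ind <- simulate_individuals(d, e)
  expect_true(all(ind == e$baseline))
  x <- pool_samples(ind, d, e)
  # pool of identical individuals equals that individual
  expect_equal(unname(x$values[, 1]), unname(e$baseline), tolerance = 1e-12)
})

test_that("pooling averages linear-scale intensities", {
  d <- cohort_design(n_genes = 3, individuals_per_group = 2L, pool_size = 2L,
                     arrays_per_group = 1L)
  e <- planted_effects(d, seed = 1, n_de_shared = 0L, n_de_mild_only = 0L,
                       n_de_severe_only = 0L, n_modules = 0L,
                       individual_sd = 0, measurement_sd = 0)
  ind <- simulate_individuals(d, e)
  ind[1, ] <- rep(c(log2(2), log2(4)), times = 3)  # linear 2 and 4 per pool
  x <- pool_samples(ind, d, e)
  expect_equal(unname(x$values[1, ]), rep(log2(3), 3), tolerance = 1e-12)
  expect_equal(ncol(x$values), length(d$groups) * d$arrays_per_group)
})

test_that("planted fold change is recovered by Monte-Carlo means", {
  # individual level: 200 individuals per group, planted log2FC = 1
  d <- cohort_design(n_genes = 30, individuals_per_group = 200L,
                     pool_size = 5L, arrays_per_group = 40L)
  de <- list(
    mild_vs_healthy = data.frame(gene = "g00001", log2fc = 1),
    severe_vs_healthy = data.frame(gene = "g00001", log2fc = 1))
  e <- planted_effects(d, seed = 5, de_genes = de, n_modules = 0L)
  ind <- simulate_individuals(d, e)
  grp <- design_individuals(d)$group
  diff <- mean(ind["g00001", grp == "severe"]) - mean(ind["g00001", grp == "healthy"])
  se <- e$individual_sd * sqrt(2 / 200)
  expect_lt(abs(diff - 1), 3 * se)

  # array level: pooled group-mean difference across 50 seeds
  d2 <- cohort_design(n_genes = 30)
  diffs <- vapply(1:50, function(s) {
    e2 <- planted_effects(d2, seed = s, de_genes = de, n_modules = 0L)
    x <- pool_samples(simulate_individuals(d2, e2), d2, e2)
    grp2 <- x$design$group
    mean(x$values["g00001", grp2 == "severe"]) -
      mean(x$values["g00001", grp2 == "healthy"])
  }, numeric(1))
  arr_var <- e$individual_sd^2 / d2$pool_size + e$measurement_sd^2
  se50 <- sqrt(arr_var * (1 / 2 + 1 / 2) / 50)
  expect_lt(abs(mean(diffs) - 1), 3 * se50)
})

test_that("planted genes outside the universe are rejected by name", {
  d <- cohort_design(n_genes = 20)
  expect_error(
    planted_effects(d, seed = 1, n_modules = 0L,
                    de_genes = list(mild_vs_healthy =
                                      data.frame(gene = "g99999", log2fc = 1))),
    "g99999")
})

test_that("detection flags follow the stated Bernoulli model", {
  d <- cohort_design(n_genes = 1000)
  e <- planted_effects(d, seed = 3, n_modules = 0L)
  x <- pool_samples(simulate_individuals(d, e), d, e)
  expect_true(all(simulate_flags(x, 1, seed = 1)))
  f0 <- simulate_flags(x, 0, seed = 1)
  expect_false(any(f0))
  expect_equal(nrow(filter_by_flags(set_flags(x, f0), 2)$values), 0L)
  # detect_prob 0.5: P(gene kept by a 2-of-6 rule) = 1 - 0.5^6 - 6*0.5^6
  f5 <- simulate_flags(x, 0.5, seed = 1)
  frac <- mean(rowSums(f5) >= 2)
  expected <- 1 - 0.5^6 - 6 * 0.5^6
  se <- sqrt(expected * (1 - expected) / 1000)
  expect_lt(abs(frac - expected), 3 * se)
  expect_error(simulate_flags(x, 1.5), "probabilities")
})

test_that("annotation planting forces the requested DE overlap", {
  d <- cohort_design(n_genes = 2000)
  e <- planted_effects(d, seed = 9, n_modules = 0L)
  e$enriched_terms <- data.frame(term = "T_enr01", source = "any",
                                 size = 20L, de_fraction = 1.0,
                                 stringsAsFactors = FALSE)
  ann <- simulate_annotation(d, e, n_terms = 10)
  de_all <- unique(unlist(lapply(e$de_genes, `[[`, "gene")))
  planted <- ann$gene[ann$term == "T_enr01"]
  expect_length(planted, 20L)
  expect_true(all(planted %in% de_all))
  # impossible request: more DE members than DE genes exist
  e$enriched_terms$size <- 500L
  expect_error(simulate_annotation(d, e, n_terms = 0), "only")
  # no terms at all -> empty table, enrichment returns no rows
  e$enriched_terms <- e$enriched_terms[0, ]
  empty <- simulate_annotation(d, e, n_terms = 0)
  expect_equal(nrow(empty), 0L)
  expect_equal(nrow(enrich_all(de_all[1:5], empty, design_genes(d))), 0L)
})

test_that("noise-free qPCR inverts exactly to the planted fold change", {
  d <- cohort_design(n_genes = 50)
  de <- list(mild_vs_healthy = data.frame(gene = "g00001", log2fc = 1),
             severe_vs_healthy = data.frame(gene = "g00001", log2fc = 2))
  e <- planted_effects(d, seed = 2, de_genes = de, n_modules = 0L)
  q <- simulate_qpcr(d, e, genes = "g00001", loading_sd = 0,
                     individual_sd_ct = 0, replicate_sd = 0)
  res <- ddct_fold_change(q)
  folds <- res$per_group
  expect_equal(folds$mean_fold[folds$group == "healthy"], 1, tolerance = 1e-12)
  expect_equal(folds$mean_fold[folds$group == "mild"], 2, tolerance = 1e-12)
  expect_equal(folds$mean_fold[folds$group == "severe"], 4, tolerance = 1e-12)
})

test_that("qPCR folds estimate the planted fold within Monte-Carlo error", {
  d <- cohort_design(n_genes = 50)
  de <- list(mild_vs_healthy = data.frame(gene = "g00001", log2fc = 1),
             severe_vs_healthy = data.frame(gene = "g00001", log2fc = 1))
  est <- vapply(1:20, function(s) {
    e <- planted_effects(d, seed = s, de_genes = de, n_modules = 0L)
    q <- simulate_qpcr(d, e, genes = "g00001", individual_sd_ct = 0.2)
    res <- ddct_fold_change(q)
    res$per_group$mean_fold[res$per_group$group == "mild"]
  }, numeric(1))
  expect_lt(abs(mean(est) - 2), 3 * stats::sd(est) / sqrt(20))
})

test_that("morphometry counts follow the stated Poisson model", {
  d <- cohort_design(n_genes = 10)
  zero <- lapply(default_morphometry_means(), function(m) m * 0)
  m0 <- simulate_morphometry(d, group_means = zero, seed = 1)
  expect_true(all(m0[c("capillaries", "villi", "cd45", "cd3", "cd19")] == 0))
  # all villus totals are zero: every placenta is undefined
  expect_error(suppressWarnings(capillaries_per_villus(m0)), "villus")
  expect_error(simulate_morphometry(
    d, group_means = lapply(default_morphometry_means(), function(m) -m)),
    "negative")
  # capillary mean 6, villus mean 2 -> pooled ratio centers on 3
  means <- lapply(default_morphometry_means(), function(m) {
    m[c("capillaries", "villi")] <- c(6, 2); m
  })
  ratios <- vapply(1:20, function(s) {
    mm <- simulate_morphometry(d, group_means = means, seed = s)
    mean(capillaries_per_villus(mm)$per_placenta$ratio)
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 3), 3 * stats::sd(ratios) / sqrt(20))
})

test_that("invalid pooling maps are rejected", {
  d <- cohort_design(n_genes = 5)
  e <- planted_effects(d, seed = 1, n_de_shared = 0L, n_de_mild_only = 0L,
                       n_de_severe_only = 0L, n_modules = 0L)
  ind <- simulate_individuals(d, e)
  pools <- icpnet:::default_pools(d)
  pools[["healthy_p1"]][1] <- pools[["healthy_p1"]][2]  # duplicate, not a partition
  expect_error(pool_samples(ind, d, e, pools = pools), "partition")
})

test_that("design invariants are enforced", {
  expect_error(cohort_design(individuals_per_group = 9L), "pool_size")
  expect_error(cohort_design(bile_acid_strata = list(healthy = c(0, 20),
                                                     mild = c(10, 40),
                                                     severe = c(40, Inf))),
               "disjoint")
  expect_error(planted_effects(cohort_design(n_genes = 20), seed = 1,
                               log2fc_range = c(0.2, 0.4)),
               "log2")
})
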