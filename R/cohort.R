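# Synthetic cohorts mirroring the study design: three bile-acid strata
# (healthy / mild / severe ICP), ten individuals per group, RNA from five
# individuals pooled onto each of two arrays per group, with planted
# differential expression, latent-factor co-expression modules, enriched
# annotation terms, a gene-interaction edge list with a planted hub, qPCR
# triplicates and per-field morphometry counts -- all with recorded ground
# truth and full determinism under one integer seed.

#' Define a pooled-cohort study design
#'
#' @param n_genes Number of genes on the simulated array (the study design
#'   assumes thousands; default 4000).
#' @param groups Group labels, control first.
#' @param individuals_per_group Individuals recruited per group (default 10).
#' @param pool_size Individuals pooled onto one array (default 5).
#' @param arrays_per_group Arrays (pools) per group (default 2).
#' @param bile_acid_strata Named list of serum bile-acid intervals in uM, one
#'   per group; must be disjoint and ordered (healthy < 10, mild 10-40,
#'   severe > 40).
#' @return A `cohort_design` object.
#' @export
cohort_design <- function(n_genes = 4000L,
                          groups = c("healthy", "mild", "severe"),
                          individuals_per_group = 10L,
                          pool_size = 5L,
                          arrays_per_group = 2L,
                          bile_acid_strata = list(healthy = c(0, 10),
                                                  mild = c(10, 40),
                                                  severe = c(40, Inf))) {
  stopifnot(length(groups) >= 2L, !anyDuplicated(groups))
  if (individuals_per_group != pool_size * arrays_per_group) {
    stop("individuals_per_group must equal pool_size * arrays_per_group", call. = FALSE)
  }
  if (!identical(sort(names(bile_acid_strata)), sort(groups))) {
    stop("bile_acid_strata must be named by group", call. = FALSE)
  }
  lims <- do.call(rbind, bile_acid_strata[groups])
  if (any(lims[, 1] >= lims[, 2]) ||
      any(lims[-1, 1] < lims[-nrow(lims), 2])) {
    stop("bile_acid_strata intervals must be ordered and disjoint", call. = FALSE)
  }
  structure(list(n_genes = as.integer(n_genes),
                 groups = groups,
                 individuals_per_group = as.integer(individuals_per_group),
                 pool_size = as.integer(pool_size),
                 arrays_per_group = as.integer(arrays_per_group),
                 bile_acid_strata = bile_acid_strata),
            class = "cohort_design")
}

#' Gene, individual and array identifiers of a design
#' @param design A `cohort_design`.
#' @return Character vectors / data frames of identifiers.
#' @export
design_genes <- function(design) {
  sprintf("g%05d", seq_len(design$n_genes))
}

#' @rdname design_genes
#' @export
design_individuals <- function(design) {
  data.frame(
    individual = unlist(lapply(design$groups, function(g)
      sprintf("%s_%02d", g, seq_len(design$individuals_per_group)))),
    group = rep(design$groups, each = design$individuals_per_group),
    stringsAsFactors = FALSE)
}

#' @rdname design_genes
#' @export
design_arrays <- function(design) {
  data.frame(
    array = unlist(lapply(design$groups, function(g)
      sprintf("%s_p%d", g, seq_len(design$arrays_per_group)))),
    group = rep(design$groups, each = design$arrays_per_group),
    subgroup = rep(sprintf("p%d", seq_len(design$arrays_per_group)),
                   times = length(design$groups)),
    stringsAsFactors = FALSE)
}

# default pooling map: consecutive blocks of pool_size individuals per group
default_pools <- function(design) {
  ind <- design_individuals(design)
  arrays <- design_arrays(design)
  pools <- vector("list", nrow(arrays))
  names(pools) <- arrays$array
  for (g in design$groups) {
    members <- ind$individual[ind$group == g]
    for (a in seq_len(design$arrays_per_group)) {
      idx <- ((a - 1L) * design$pool_size + 1L):(a * design$pool_size)
      pools[[sprintf("%s_p%d", g, a)]] <- members[idx]
    }
  }
  pools
}

#' Plant ground-truth effects for a synthetic cohort
#'
#' Draws (deterministically from `seed`) per-gene baselines, differentially
#' expressed gene sets for the mild and severe contrasts, latent-factor
#' co-expression modules with a designated hub gene, and annotation terms to
#' be enriched in the DE sets. Planted DE genes and module genes are drawn
#' from the expressed stratum (baseline above its 20th percentile), since
#' genes below the detection floor cannot be called differential.
#'
#' @param design A `cohort_design`.
#' @param seed Integer master seed; together with `design` it fully determines
#'   every simulator output.
#' @param n_de_shared,n_de_mild_only,n_de_severe_only Counts of planted DE
#'   genes altered in both contrasts / mild only / severe only.
#' @param log2fc_range Magnitude range for planted log2 fold changes (default
#'   2.5- to 6-fold; must stay at or above log2(1.5)).
#' @param prop_up Probability that a planted effect is up-regulation.
#' @param n_modules,module_size Latent-factor co-expression modules (disjoint
#'   gene sets).
#' @param module_factor_sd Standard deviation of the per-individual module
#'   latent factor on the log2 scale.
#' @param loading_range Range of per-gene factor loadings.
#' @param enriched_term_size,enriched_term_fraction Size and planted DE
#'   fraction of each enriched annotation term.
#' @param baseline_log2_mean,gene_baseline_sd Mean and spread of per-gene
#'   baseline log2 intensities (log-normal intensities on the linear scale).
#' @param individual_sd Biological noise sd per individual (log2 scale).
#' @param measurement_sd Array measurement noise sd (log2 scale).
#' @param de_genes Optional explicit list of per-contrast data frames
#'   (gene, log2fc) overriding the random draw.
#' @return A `planted_effects` object.
#' @export
planted_effects <- function(design, seed,
                            n_de_shared = 50L,
                            n_de_mild_only = 30L,
                            n_de_severe_only = 70L,
                            log2fc_range = c(log2(2.5), log2(6)),
                            prop_up = 0.5,
                            n_modules = 1L,
                            module_size = 30L,
                            module_factor_sd = 5,
                            loading_range = c(0.6, 1.0),
                            enriched_term_size = 25L,
                            enriched_term_fraction = 0.6,
                            baseline_log2_mean = 8,
                            gene_baseline_sd = 1.5,
                            individual_sd = 0.5,
                            measurement_sd = 0.2,
                            de_genes = NULL) {
  stopifnot(inherits(design, "cohort_design"))
  assert_scalar_number(seed, "seed")
  if (min(log2fc_range) < log2(1.5) - 1e-12) {
    stop("planted |log2FC| must be >= log2(1.5)", call. = FALSE)
  }
  genes <- design_genes(design)
  set.seed(derive_seed(seed, 1L))
  baseline <- stats::rnorm(design$n_genes, baseline_log2_mean, gene_baseline_sd)
  names(baseline) <- genes
  expressed <- genes[baseline >= stats::quantile(baseline, 0.2)]

  draw_fc <- function(n) {
    mag <- stats::runif(n, log2fc_range[1], log2fc_range[2])
    sgn <- ifelse(stats::runif(n) < prop_up, 1, -1)
    mag * sgn
  }

  contrasts <- paste0(setdiff(design$groups, design$groups[1]),
                      "_vs_", design$groups[1])
  if (is.null(de_genes)) {
    n_total <- n_de_shared + n_de_mild_only + n_de_severe_only
    if (n_total > length(expressed)) {
      stop("more planted DE genes than expressed genes", call. = FALSE)
    }
    picked <- sample(expressed, n_total)
    shared <- picked[seq_len(n_de_shared)]
    mild_only <- picked[n_de_shared + seq_len(n_de_mild_only)]
    severe_only <- picked[n_de_shared + n_de_mild_only + seq_len(n_de_severe_only)]
    shared_fc <- draw_fc(n_de_shared)
    de_genes <- list(
      data.frame(gene = c(shared, mild_only),
                 log2fc = c(shared_fc, draw_fc(n_de_mild_only)),
                 stringsAsFactors = FALSE),
      # shared genes keep their direction but draw a fresh severe magnitude
      data.frame(gene = c(shared, severe_only),
                 log2fc = c(sign(shared_fc) *
                              stats::runif(n_de_shared, log2fc_range[1], log2fc_range[2]),
                            draw_fc(n_de_severe_only)),
                 stringsAsFactors = FALSE))
    names(de_genes) <- contrasts[seq_len(min(2L, length(contrasts)))]
  }
  for (ctr in names(de_genes)) {
    bad <- setdiff(de_genes[[ctr]]$gene, genes)
    if (length(bad) > 0L) {
      stop(sprintf("planted gene outside gene universe: %s", bad[1]), call. = FALSE)
    }
    if (any(abs(de_genes[[ctr]]$log2fc) < log2(1.5) - 1e-12)) {
      stop("planted |log2FC| must be >= log2(1.5)", call. = FALSE)
    }
  }

  # modules: disjoint gene sets among expressed genes not planted as DE
  de_universe <- unique(unlist(lapply(de_genes, `[[`, "gene")))
  module_pool <- setdiff(expressed, de_universe)
  modules <- list()
  hubs <- character(0)
  if (n_modules > 0L) {
    if (n_modules * module_size > length(module_pool)) {
      stop("not enough non-DE expressed genes for the requested modules", call. = FALSE)
    }
    mg <- sample(module_pool, n_modules * module_size)
    for (m in seq_len(n_modules)) {
      members <- mg[((m - 1L) * module_size + 1L):(m * module_size)]
      loadings <- stats::runif(module_size, loading_range[1], loading_range[2])
      # the hub is the module's driver: strongest coupling to the factor
      loadings[1] <- max(loadings)
      modules[[sprintf("module%d", m)]] <-
        data.frame(gene = members, loading = loadings, stringsAsFactors = FALSE)
      hubs <- c(hubs, members[1])
    }
  }

  # planted enriched terms: drawn from shared / mild-only / severe-only DE genes
  enriched <- data.frame(term = character(), source = character(),
                         size = integer(), de_fraction = numeric(),
                         stringsAsFactors = FALSE)
  if (length(de_genes) >= 2L && nrow(de_genes[[1]]) > 0L && nrow(de_genes[[2]]) > 0L) {
    g1 <- de_genes[[1]]$gene; g2 <- de_genes[[2]]$gene
    src <- list(shared = intersect(g1, g2),
                mild_only = setdiff(g1, g2),
                severe_only = setdiff(g2, g1))
    plan <- c("shared", "shared", "mild_only", "severe_only")
    plan <- plan[vapply(plan, function(s)
      length(src[[s]]) >= ceiling(enriched_term_fraction * enriched_term_size),
      logical(1))]
    if (length(plan) > 0L) {
      enriched <- data.frame(term = sprintf("T_enr%02d", seq_along(plan)),
                             source = plan,
                             size = as.integer(enriched_term_size),
                             de_fraction = enriched_term_fraction,
                             stringsAsFactors = FALSE)
    }
  }

  structure(list(seed = as.integer(seed),
                 baseline = baseline,
                 de_genes = de_genes,
                 modules = modules,
                 hubs = hubs,
                 enriched_terms = enriched,
                 module_factor_sd = module_factor_sd,
                 baseline_log2_mean = baseline_log2_mean,
                 gene_baseline_sd = gene_baseline_sd,
                 individual_sd = individual_sd,
                 measurement_sd = measurement_sd),
            class = "planted_effects")
}

#' Extract the recorded ground truth of a cohort
#'
#' @param effects A `planted_effects` object.
#' @return A `cohort_truth` list: per-contrast DE gene sets with signs and
#'   planted log2 fold changes, module memberships, hub genes and enriched
#'   terms. Serializable with [write_truth()].
#' @export
cohort_truth <- function(effects) {
  stopifnot(inherits(effects, "planted_effects"))
  structure(list(
    true_de = lapply(effects$de_genes, function(d)
      list(gene = d$gene, sign = sign(d$log2fc), log2fc = d$log2fc)),
    true_modules = lapply(effects$modules, `[[`, "gene"),
    true_hubs = effects$hubs,
    true_enriched_terms = effects$enriched_terms$term
  ), class = "cohort_truth")
}

# planted log2 effect of gene g for the individuals of group `group`
planted_effect_for_group <- function(effects, design, group) {
  out <- stats::setNames(numeric(design$n_genes), names(effects$baseline))
  if (group == design$groups[1]) return(out)
  ctr <- paste0(group, "_vs_", design$groups[1])
  d <- effects$de_genes[[ctr]]
  if (!is.null(d) && nrow(d) > 0L) out[d$gene] <- d$log2fc
  out
}

#' Simulate per-individual log2 expression
#'
#' Each individual's profile is baseline + group effect (planted log2 fold
#' change applied to the mild/severe individuals) + module latent factor x
#' loading + individual biological noise. Deterministic given the effects
#' seed.
#'
#' @param design A `cohort_design`.
#' @param effects A `planted_effects` object.
#' @return Numeric matrix, genes x individuals.
#' @export
simulate_individuals <- function(design, effects) {
  stopifnot(inherits(design, "cohort_design"), inherits(effects, "planted_effects"))
  genes <- design_genes(design)
  if (!identical(names(effects$baseline), genes)) {
    stop("effects were planted for a different gene universe", call. = FALSE)
  }
  ind <- design_individuals(design)
  set.seed(derive_seed(effects$seed, 2L))
  x <- matrix(effects$baseline, nrow = design$n_genes, ncol = nrow(ind),
              dimnames = list(genes, ind$individual))
  for (g in design$groups[-1]) {
    eff <- planted_effect_for_group(effects, design, g)
    cols <- ind$group == g
    x[, cols] <- x[, cols] + eff
  }
  for (mod in effects$modules) {
    z <- stats::rnorm(nrow(ind), 0, effects$module_factor_sd)
    x[mod$gene, ] <- x[mod$gene, ] + outer(mod$loading, z)
  }
  if (effects$individual_sd > 0) {
    x <- x + matrix(stats::rnorm(length(x), 0, effects$individual_sd), nrow = nrow(x))
  }
  x
}

#' Pool individual profiles into arrays
#'
#' RNA mixing is additive in concentration, so pooling averages LINEAR-scale
#' intensities (then re-logs), not log2 values. Per-array measurement noise
#' (`measurement_sd`, log2 scale) is added afterwards.
#'
#' @param individuals Genes x individuals log2 matrix from
#'   [simulate_individuals()].
#' @param design A `cohort_design`.
#' @param effects A `planted_effects` object (supplies `measurement_sd` and
#'   the noise sub-stream seed).
#' @param pools Optional named list (array id -> individual ids) overriding
#'   the default consecutive-block pooling; must partition each group.
#' @return An `expr_matrix` with `n_groups * arrays_per_group` arrays.
#' @export
pool_samples <- function(individuals, design, effects, pools = NULL) {
  stopifnot(is.matrix(individuals), inherits(design, "cohort_design"),
            inherits(effects, "planted_effects"))
  arrays <- design_arrays(design)
  if (is.null(pools)) pools <- default_pools(design)
  ind <- design_individuals(design)
  # validate: pools partition each group's individuals into sets of pool_size
  for (g in design$groups) {
    members <- unlist(pools[arrays$array[arrays$group == g]])
    expected <- ind$individual[ind$group == g]
    if (anyDuplicated(members) || !setequal(members, expected) ||
        any(lengths(pools[arrays$array[arrays$group == g]]) != design$pool_size)) {
      stop(sprintf("pooling map does not partition group '%s' into pools of %d",
                   g, design$pool_size), call. = FALSE)
    }
  }
  linear <- 2^individuals
  vals <- vapply(arrays$array, function(a)
    log2(rowMeans(linear[, pools[[a]], drop = FALSE])),
    numeric(nrow(individuals)))
  dimnames(vals) <- list(rownames(individuals), arrays$array)
  if (effects$measurement_sd > 0) {
    set.seed(derive_seed(effects$seed, 3L))
    vals <- vals + matrix(stats::rnorm(length(vals), 0, effects$measurement_sd),
                          nrow = nrow(vals))
  }
  expression_matrix(vals, arrays)
}

#' Simulate per-array detection flags
#'
#' Detection ("Present") calls are Bernoulli draws whose success probability
#' depends on the gene's mean-intensity quantile bin: dim genes are less
#' likely to be detected, mimicking scanner Present/Absent calls without
#' modeling image physics.
#'
#' @param x An `expr_matrix`.
#' @param detect_prob_by_quantile Either a single probability applied to all
#'   genes, or a vector of probabilities for equal-width quantile bins of mean
#'   gene intensity, dimmest bin first.
#' @param seed Integer seed for the flag sub-stream.
#' @return Logical matrix of detection flags (genes x arrays).
#' @export
simulate_flags <- function(x,
                           detect_prob_by_quantile = c(0.25, 0.7, 0.9, 0.97, 1, 1, 1, 1, 1, 1),
                           seed = 1L) {
  stopifnot(inherits(x, "expr_matrix"))
  p <- detect_prob_by_quantile
  if (!is.numeric(p) || any(p < 0 | p > 1)) {
    stop("detection probabilities must lie in [0, 1]", call. = FALSE)
  }
  n <- nrow(x$values); na <- ncol(x$values)
  if (length(p) == 1L) {
    pg <- rep(p, n)
  } else {
    m <- rowMeans(x$values)
    bins <- ceiling(rank(m, ties.method = "first") / n * length(p))
    pg <- p[bins]
  }
  set.seed(derive_seed(seed, 4L))
  flags <- matrix(stats::rbinom(n * na, 1L, rep(pg, times = na)) == 1L,
                  nrow = n, dimnames = dimnames(x$values))
  flags
}

#' Simulate a gene-to-term annotation table
#'
#' Background terms are populated uniformly at random over the gene universe;
#' each planted enriched term draws its stated fraction of members from the
#' corresponding planted DE gene set (shared / mild-only / severe-only).
#'
#' @param design A `cohort_design`.
#' @param effects A `planted_effects` object.
#' @param n_terms Number of background terms.
#' @param term_size_range Integer range of background term sizes.
#' @return Data frame (gene, term).
#' @export
simulate_annotation <- function(design, effects, n_terms = 150L,
                                term_size_range = c(10L, 60L)) {
  stopifnot(inherits(design, "cohort_design"), inherits(effects, "planted_effects"))
  genes <- design_genes(design)
  set.seed(derive_seed(effects$seed, 5L))
  rows <- vector("list", n_terms + nrow(effects$enriched_terms))
  for (i in seq_len(n_terms)) {
    sz <- sample(seq(term_size_range[1], term_size_range[2]), 1L)
    rows[[i]] <- data.frame(gene = sample(genes, sz),
                            term = sprintf("T%04d", i),
                            stringsAsFactors = FALSE)
  }
  de1 <- if (length(effects$de_genes) >= 1L) effects$de_genes[[1]]$gene else character(0)
  de2 <- if (length(effects$de_genes) >= 2L) effects$de_genes[[2]]$gene else character(0)
  src <- list(shared = intersect(de1, de2),
              mild_only = setdiff(de1, de2),
              severe_only = setdiff(de2, de1),
              any = union(de1, de2))
  et <- effects$enriched_terms
  for (j in seq_len(nrow(et))) {
    pool <- src[[et$source[j]]]
    k <- round(et$de_fraction[j] * et$size[j])
    if (k > length(pool)) {
      stop(sprintf("term %s requests %d DE genes but only %d exist in source '%s'",
                   et$term[j], k, length(pool), et$source[j]), call. = FALSE)
    }
    members <- c(sample(pool, k), sample(setdiff(genes, pool), et$size[j] - k))
    rows[[n_terms + j]] <- data.frame(gene = members, term = et$term[j],
                                      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(gene = character(), term = character(),
                                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  unique(out)
}

#' Simulate a gene-interaction edge list with a planted hub
#'
#' Emulates the externally supplied (database-derived) interaction network: a
#' sparse random background over planted-plus-random genes, with each planted
#' hub gene wired to `hub_degree` partners so the interaction-degree signal of
#' a core regulator is present by construction.
#'
#' @param design A `cohort_design`.
#' @param effects A `planted_effects` object.
#' @param n_nodes Total node count of the background network.
#' @param background_mean_degree Mean background degree (kept well below the
#'   hub degree).
#' @param hub_degree Degree given to each planted hub.
#' @return Canonical edge data frame.
#' @export
simulate_interactions <- function(design, effects, n_nodes = 300L,
                                  background_mean_degree = 2,
                                  hub_degree = 25L) {
  stopifnot(inherits(design, "cohort_design"), inherits(effects, "planted_effects"))
  genes <- design_genes(design)
  set.seed(derive_seed(effects$seed, 6L))
  anchored <- unique(c(unlist(lapply(effects$de_genes, `[[`, "gene")),
                       unlist(lapply(effects$modules, `[[`, "gene"))))
  extra <- setdiff(genes, anchored)
  n_fill <- max(0L, n_nodes - length(anchored))
  nodes <- c(anchored, sample(extra, min(n_fill, length(extra))))
  n <- length(nodes)
  n_edges <- round(background_mean_degree * n / 2)
  from <- sample(nodes, n_edges, replace = TRUE)
  to <- sample(nodes, n_edges, replace = TRUE)
  keep <- from != to
  from <- from[keep]; to <- to[keep]
  for (h in effects$hubs) {
    partners <- sample(setdiff(nodes, h), min(hub_degree, n - 1L))
    from <- c(from, rep(h, length(partners)))
    to <- c(to, partners)
  }
  canonical_edges(from, to)
}

#' Simulate triplicate qPCR Ct values
#'
#' The Ct model inverts the planted expression effects: for individual i and
#' target gene g, mean Ct(target) = mean Ct(reference) + offset - planted
#' log2 effect of g in i's group. The reference gene (GAPDH role) carries no
#' group effect; per-individual RNA loading shifts reference and targets
#' equally and cancels in the delta-Ct.
#'
#' @param design A `cohort_design`.
#' @param effects A `planted_effects` object.
#' @param genes Target genes to assay (default: hub genes plus the first few
#'   planted DE genes).
#' @param reference_gene Reference gene id (default "GAPDH").
#' @param ct_ref_base Baseline reference Ct.
#' @param target_offset Constant Ct offset of targets above the reference.
#' @param loading_sd Per-individual RNA-loading shift sd (cancels in ddCt).
#' @param individual_sd_ct Per-individual biological Ct noise sd.
#' @param replicate_sd Replicate (technical) Ct noise sd.
#' @return Long data frame (individual, group, gene, replicate, ct); the
#'   reference gene appears as ordinary rows.
#' @export
simulate_qpcr <- function(design, effects, genes = NULL,
                          reference_gene = "GAPDH",
                          ct_ref_base = 15, target_offset = 4,
                          loading_sd = 0.5, individual_sd_ct = 0.25,
                          replicate_sd = 0.2) {
  stopifnot(inherits(design, "cohort_design"), inherits(effects, "planted_effects"))
  if (is.null(genes)) {
    de_head <- unique(unlist(lapply(effects$de_genes, function(d) utils::head(d$gene, 5))))
    genes <- unique(c(effects$hubs, de_head))
  }
  ind <- design_individuals(design)
  set.seed(derive_seed(effects$seed, 7L))
  loading <- stats::rnorm(nrow(ind), 0, loading_sd)
  rows <- list()
  for (i in seq_len(nrow(ind))) {
    ref_i <- ct_ref_base + loading[i]
    rows[[length(rows) + 1L]] <- data.frame(
      individual = ind$individual[i], group = ind$group[i], gene = reference_gene,
      replicate = 1:3, ct = ref_i + stats::rnorm(3, 0, replicate_sd),
      stringsAsFactors = FALSE)
    eff <- planted_effect_for_group(effects, design, ind$group[i])
    for (g in genes) {
      mu <- ref_i + target_offset - eff[[g]] + stats::rnorm(1, 0, individual_sd_ct)
      rows[[length(rows) + 1L]] <- data.frame(
        individual = ind$individual[i], group = ind$group[i], gene = g,
        replicate = 1:3, ct = mu + stats::rnorm(3, 0, replicate_sd),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Default group means for the morphometry simulator
#'
#' Per-field Poisson means emulating the reported histology pattern: capillary
#' density falls with ICP severity while immune-cell infiltration (CD45+
#' leukocytes, CD3+ T cells, CD19+ B cells) rises sharply.
#'
#' @param groups Group labels.
#' @return Named list of per-group mean vectors.
#' @export
default_morphometry_means <- function(groups = c("healthy", "mild", "severe")) {
  means <- list(
    healthy = c(capillaries = 6,   villi = 2, cd45 = 2,  cd3 = 1,  cd19 = 0.5),
    mild    = c(capillaries = 4.5, villi = 2, cd45 = 10, cd3 = 5,  cd19 = 3),
    severe  = c(capillaries = 3.5, villi = 2, cd45 = 30, cd3 = 15, cd19 = 8))
  means[groups]
}

#' Simulate per-field morphometry counts
#'
#' Each placenta contributes `n_fields` microscope fields (10 sections x 5
#' random fields in the study protocol); counts of capillaries, terminal
#' villi and CD45+/CD3+/CD19+ cells per field are Poisson at the group means.
#'
#' @param design A `cohort_design`.
#' @param group_means Named list (group -> named vector of Poisson means for
#'   capillaries, villi, cd45, cd3, cd19); see [default_morphometry_means()].
#' @param n_fields Fields per placenta (default 50).
#' @param seed Integer seed.
#' @return Data frame (placenta, group, field, capillaries, villi, cd45, cd3,
#'   cd19).
#' @export
simulate_morphometry <- function(design, group_means = NULL, n_fields = 50L,
                                 seed = 1L) {
  stopifnot(inherits(design, "cohort_design"))
  if (is.null(group_means)) group_means <- default_morphometry_means(design$groups)
  markers <- c("capillaries", "villi", "cd45", "cd3", "cd19")
  for (g in design$groups) {
    mu <- group_means[[g]]
    if (is.null(mu) || !all(markers %in% names(mu))) {
      stop(sprintf("group_means for '%s' must name %s", g,
                   paste(markers, collapse = ", ")), call. = FALSE)
    }
    if (any(mu[markers] < 0)) {
      stop(sprintf("negative Poisson mean for group '%s'", g), call. = FALSE)
    }
  }
  ind <- design_individuals(design)
  set.seed(derive_seed(seed, 8L))
  rows <- lapply(seq_len(nrow(ind)), function(i) {
    mu <- group_means[[ind$group[i]]]
    df <- data.frame(placenta = ind$individual[i], group = ind$group[i],
                     field = seq_len(n_fields), stringsAsFactors = FALSE)
    for (mk in markers) df[[mk]] <- stats::rpois(n_fields, mu[[mk]])
    df
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
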