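# Per-gene linear models with empirical-Bayes variance moderation, BH FDR,
# fold-change gating, DE-set algebra and hierarchical clustering.
#
# The model is a one-way group-means fit (the pooled design has no other
# covariates): for the study layout of 6 arrays in 3 groups the residual
# degrees of freedom are dg = N - G = 3 per gene. Per-gene variances s2_g are
# shrunk toward a prior (d0, s0^2) estimated by moment matching of log s2_g
# against a scaled-F sampling model, giving the moderated t-statistic
#   t_g = log2FC_g / sqrt(s2_post_g * (1/n1 + 1/n2)),  df = d0 + dg,
# with s2_post_g = (d0*s0^2 + dg*s2_g) / (d0 + dg).

#' Fit per-gene group means and pooled residual variance
#'
#' @param x An `expr_matrix` with a design of at least two groups, each with
#'   at least two arrays.
#' @return A `group_fit` list: `means` (genes x groups), `n` (arrays per
#'   group), `s2` (per-gene pooled within-group variance), `dg` (residual df,
#'   `n_arrays - n_groups`).
#' @export
fit_group_means <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  groups <- unique(x$design$group)
  if (length(groups) < 2L) stop("need at least two groups", call. = FALSE)
  n <- vapply(groups, function(g) sum(x$design$group == g), integer(1))
  if (any(n < 2L)) {
    stop(sprintf("group '%s' has fewer than two arrays; variance undefined",
                 groups[which(n < 2L)[1]]), call. = FALSE)
  }
  v <- x$values
  means <- vapply(groups, function(g)
    rowMeans(v[, x$design$group == g, drop = FALSE]), numeric(nrow(v)))
  dimnames(means) <- list(rownames(v), groups)
  fitted <- means[, x$design$group, drop = FALSE]
  dg <- ncol(v) - length(groups)
  s2 <- rowSums((v - fitted)^2) / dg
  structure(list(genes = rownames(v), groups = groups, means = means,
                 n = n, s2 = s2, dg = dg),
            class = "group_fit")
}

#' Invert the trigamma function
#'
#' Newton iteration on the monotone map x -> trigamma(x); used to match the
#' observed spread of log sample variances to the scaled-F prior.
#'
#' @param y Positive values.
#' @return x with trigamma(x) = y.
#' @export
trigamma_inverse <- function(y) {
  vapply(y, function(yi) {
    if (!is.finite(yi) || yi <= 0) return(NaN)
    if (yi > 1e7) return(1 / sqrt(yi))
    if (yi < 1e-6) return(1 / yi)
    x <- 0.5 + 1 / yi
    for (iter in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yi) / psigamma(x, deriv = 2L)
      x <- x + dif
      if (-dif / x < 1e-10) break
    }
    x
  }, numeric(1))
}

#' Empirical-Bayes moderation of per-gene variances
#'
#' Estimates the prior degrees of freedom d0 and prior variance s0^2 by
#' matching the first two moments of log s2_g to the scaled-F sampling model
#' (trigamma inversion), then forms the posterior variances
#' `s2_post = (d0*s0^2 + dg*s2) / (d0 + dg)`. If the observed spread of log
#' variances is no larger than the pure chi-square sampling spread, d0 is
#' infinite and every posterior variance equals s0^2. Genes with s2 = 0 are
#' excluded from estimation and rescued by moderation (`s2_post =
#' d0*s0^2/(d0+dg)`).
#'
#' @param s2 Per-gene sample variances (at least 10 genes for estimation).
#' @param dg Residual degrees of freedom per gene.
#' @param d0,s0_sq Optional forced hyperparameters (d0 = 0 reproduces the
#'   ordinary per-gene t; d0 = Inf fully pools the variance).
#' @return An `ebayes_fit` list: `d0`, `s0_sq`, `s2_post`, `dg`.
#' @export
ebayes_moderate <- function(s2, dg, d0 = NULL, s0_sq = NULL) {
  stopifnot(is.numeric(s2), all(s2 >= 0))
  assert_scalar_number(dg, "dg", 1)
  if (all(s2 == 0)) {
    stop("all per-gene variances are zero; add noise to the data", call. = FALSE)
  }
  forced_zero <- !is.null(d0) && is.finite(d0) && d0 == 0
  if (is.null(d0) || (is.null(s0_sq) && !forced_zero)) {
    pos <- s2[s2 > 0]
    if (length(pos) < 10L) stop("need at least 10 genes with positive variance", call. = FALSE)
    z <- log(pos)
    e <- z - digamma(dg / 2) + log(dg / 2)
    evar <- stats::var(e) - trigamma(dg / 2)
    if (is.null(d0)) {
      d0 <- if (evar > 0) 2 * trigamma_inverse(evar) else Inf
    }
    if (is.null(s0_sq)) {
      s0_sq <- if (is.finite(d0) && d0 > 0) {
        exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
      } else {
        exp(mean(e))
      }
    }
  }
  if (forced_zero && is.null(s0_sq)) s0_sq <- mean(s2)
  s2_post <- if (is.infinite(d0)) {
    rep(s0_sq, length(s2))
  } else {
    (d0 * s0_sq + dg * s2) / (d0 + dg)
  }
  names(s2_post) <- names(s2)
  structure(list(d0 = d0, s0_sq = s0_sq, s2_post = s2_post, dg = dg),
            class = "ebayes_fit")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up FDR: on sorted p-values, q(i) = min over j >= i of
#' m*p(j)/j, capped at 1 and mapped back to input order.
#'
#' @param p P-values in \[0, 1\].
#' @return Adjusted values, same order as the input.
#' @export
adjust_bh <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Moderated-t differential expression over all contrasts versus control
#'
#' Fits group means, moderates variances, tests every non-control group
#' against the control and applies the study's three gates (fold change,
#' p-value, FDR) via [select_de()] semantics.
#'
#' @param x A preprocessed `expr_matrix`.
#' @param control Control (denominator) group; default the design's first
#'   group.
#' @param fc_threshold Linear fold-change gate, inclusive (default 1.5).
#' @param p_threshold Raw p gate, exclusive (default 0.05).
#' @param fdr_threshold BH FDR gate, exclusive (default 0.05).
#' @param d0,s0_sq Optional forced empirical-Bayes hyperparameters.
#' @return A `de_result` data frame: gene, contrast, log2fc, moderated_t, p,
#'   fdr, call (up/down/ns); the `ebayes` attribute carries the fitted
#'   hyperparameters.
#' @export
run_de <- function(x, control = NULL, fc_threshold = 1.5,
                   p_threshold = 0.05, fdr_threshold = 0.05,
                   d0 = NULL, s0_sq = NULL) {
  fit <- fit_group_means(x)
  control <- control %||% fit$groups[1]
  if (!control %in% fit$groups) stop(sprintf("unknown control group '%s'", control), call. = FALSE)
  eb <- ebayes_moderate(fit$s2, fit$dg, d0 = d0, s0_sq = s0_sq)
  df_t <- eb$d0 + fit$dg
  out <- list()
  for (g in setdiff(fit$groups, control)) {
    log2fc <- fit$means[, g] - fit$means[, control]
    cc <- 1 / fit$n[[g]] + 1 / fit$n[[control]]
    tt <- log2fc / sqrt(eb$s2_post * cc)
    p <- if (is.finite(df_t)) 2 * stats::pt(abs(tt), df = df_t, lower.tail = FALSE)
         else 2 * stats::pnorm(abs(tt), lower.tail = FALSE)
    out[[g]] <- data.frame(gene = fit$genes,
                           contrast = paste0(g, "_vs_", control),
                           log2fc = log2fc, moderated_t = tt,
                           p = p, fdr = adjust_bh(p),
                           stringsAsFactors = FALSE, row.names = NULL)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$call <- de_call(res$log2fc, res$p, res$fdr,
                      fc_threshold, p_threshold, fdr_threshold)
  attr(res, "ebayes") <- eb
  class(res) <- c("de_result", class(res))
  res
}

# gate logic: FC inclusive ("1.5-fold or greater"), p and FDR strict
de_call <- function(log2fc, p, fdr, fc_threshold, p_threshold, fdr_threshold) {
  lfc <- log2(fc_threshold)
  pass <- abs(log2fc) >= lfc & p < p_threshold & fdr < fdr_threshold
  ifelse(pass & log2fc > 0, "up", ifelse(pass, "down", "ns"))
}

#' Apply the three DE gates and return the called set
#'
#' call = up/down iff linear |FC| >= `fc_threshold` (inclusive) AND p <
#' `p_threshold` AND fdr < `fdr_threshold` (both exclusive).
#'
#' @param de A `de_result` data frame from [run_de()].
#' @inheritParams run_de
#' @return The called rows (call != "ns") with the call column recomputed.
#' @export
select_de <- function(de, fc_threshold = 1.5, p_threshold = 0.05,
                      fdr_threshold = 0.05) {
  stopifnot(all(c("gene", "contrast", "log2fc", "p", "fdr") %in% names(de)))
  if (fc_threshold <= 0 || p_threshold <= 0 || fdr_threshold <= 0) {
    stop("thresholds must be positive", call. = FALSE)
  }
  de$call <- de_call(de$log2fc, de$p, de$fdr,
                     fc_threshold, p_threshold, fdr_threshold)
  out <- de[de$call != "ns", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Intersection / mild-only / severe-only DE-set algebra
#'
#' Partitions the union of two contrasts' called genes into genes called in
#' both, in the first only, and in the second only, keeping each contrast's
#' own direction. A gene called in opposite directions lands in the
#' intersection with both directions recorded.
#'
#' @param called A called `de_result` (from [select_de()]) covering exactly
#'   two contrasts, or a list of two such data frames.
#' @return List with data frames `intersection` (gene, direction_a,
#'   direction_b), `first_only`, `second_only` (gene, direction), plus the
#'   contrast names.
#' @export
de_set_algebra <- function(called) {
  if (is.data.frame(called)) {
    ctr <- unique(called$contrast)
    if (length(ctr) != 2L) stop("need exactly two contrasts", call. = FALSE)
    called <- split(called, factor(called$contrast, levels = ctr))
  }
  stopifnot(length(called) == 2L)
  a <- called[[1]]; b <- called[[2]]
  dir_a <- stats::setNames(a$call, a$gene)
  dir_b <- stats::setNames(b$call, b$gene)
  both <- sort(intersect(a$gene, b$gene))
  only_a <- sort(setdiff(a$gene, b$gene))
  only_b <- sort(setdiff(b$gene, a$gene))
  list(
    contrasts = c(unique(a$contrast), unique(b$contrast)),
    intersection = data.frame(gene = both,
                              direction_a = unname(dir_a[both]),
                              direction_b = unname(dir_b[both]),
                              stringsAsFactors = FALSE),
    first_only = data.frame(gene = only_a, direction = unname(dir_a[only_a]),
                            stringsAsFactors = FALSE),
    second_only = data.frame(gene = only_b, direction = unname(dir_b[only_b]),
                             stringsAsFactors = FALSE))
}

#' Hierarchical clustering of genes and arrays
#'
#' Agglomerative average-linkage clustering with correlation distance
#' (1 - Pearson r) for genes and Euclidean distance for arrays -- the common
#' heatmap convention. Constant genes get r fixed at 0 (distance 1 to every
#' other gene) with a warning. Dendrograms are also returned serialized in
#' Newick format.
#'
#' @param x An `expr_matrix` (typically restricted to called DE genes).
#' @param genes Optional subset of genes to cluster.
#' @return List with `gene_hclust`, `array_hclust`, `gene_newick`,
#'   `array_newick` and `heatmap`, the matrix reordered by both dendrograms.
#' @export
hierarchical_cluster <- function(x, genes = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  v <- x$values
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  if (nrow(v) < 2L || ncol(v) < 2L) stop("need at least 2 genes and 2 arrays", call. = FALSE)
  sds <- apply(v, 1L, stats::sd)
  r <- suppressWarnings(stats::cor(t(v)))
  if (any(sds == 0)) {
    warning(sprintf("%d constant gene(s); correlation set to 0", sum(sds == 0)),
            call. = FALSE)
    r[sds == 0, ] <- 0
    r[, sds == 0] <- 0
  }
  diag(r) <- 1
  gene_hc <- stats::hclust(stats::as.dist(1 - r), method = "average")
  array_hc <- stats::hclust(stats::dist(t(v)), method = "average")
  to_newick <- function(hc) ape::write.tree(ape::as.phylo(hc))
  list(gene_hclust = gene_hc,
       array_hclust = array_hc,
       gene_newick = to_newick(gene_hc),
       array_newick = to_newick(array_hc),
       heatmap = v[gene_hc$order, array_hc$order, drop = FALSE])
}
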