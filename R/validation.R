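# Validation-arm statistics: delta-delta-Ct relative quantification, one-way
# ANOVA with Dunnett many-to-one post-tests, and morphometry aggregation
# (capillaries per terminal villus, immune cells per field).

#' Delta-delta-Ct relative quantification
#'
#' Classical 2^-ddCt model with amplification efficiency fixed at 2 per
#' cycle. Per individual, dCt = meanCt(target) - meanCt(reference) over the
#' triplicates; the fold change is 2^-(dCt - mean dCt of the calibrator
#' group), so the calibrator group's geometric-mean fold is 1 by construction
#' ("expression in the healthy group defined as 1"). Group summaries are
#' mean +/- sd over individuals, with ANOVA + Dunnett on the dCt scale.
#'
#' @param records Long data frame (individual, group, gene, replicate, ct),
#'   containing the reference gene as ordinary rows.
#' @param reference_gene Reference (normalizer) gene id, default "GAPDH".
#' @param calibrator_group Group whose mean dCt defines fold 1 (default
#'   "healthy").
#' @param test_scale Scale for the group comparison: "dct" (default; closer
#'   to normal) or "fold".
#' @return List with `per_individual` (individual, group, gene, dct, fold)
#'   and `per_group` (gene, group, mean_fold, sd_fold, n, dunnett_p, stars;
#'   calibrator rows carry NA p).
#' @export
ddct_fold_change <- function(records, reference_gene = "GAPDH",
                             calibrator_group = "healthy",
                             test_scale = c("dct", "fold")) {
  test_scale <- match.arg(test_scale)
  need <- c("individual", "group", "gene", "replicate", "ct")
  stopifnot(all(need %in% names(records)))
  mean_ct <- stats::aggregate(ct ~ individual + group + gene, data = records, FUN = mean)
  ref <- mean_ct[mean_ct$gene == reference_gene, c("individual", "ct")]
  names(ref)[2] <- "ref_ct"
  targets <- mean_ct[mean_ct$gene != reference_gene, , drop = FALSE]
  if (nrow(targets) == 0L) stop("no target genes in records", call. = FALSE)
  no_ref <- setdiff(unique(targets$individual), ref$individual)
  if (length(no_ref) > 0L) {
    stop(sprintf("no reference-gene measurement for individual %s", no_ref[1]),
         call. = FALSE)
  }
  d <- merge(targets, ref, by = "individual", sort = FALSE)
  d$dct <- d$ct - d$ref_ct
  if (!calibrator_group %in% d$group) {
    stop(sprintf("calibrator group '%s' absent from records", calibrator_group),
         call. = FALSE)
  }
  per_ind <- do.call(rbind, lapply(split(d, d$gene), function(dg) {
    cal <- mean(dg$dct[dg$group == calibrator_group])
    dg$fold <- 2^(-(dg$dct - cal))
    dg
  }))
  o <- order(per_ind$gene, per_ind$group, per_ind$individual)
  per_ind <- per_ind[o, c("individual", "group", "gene", "dct", "fold")]
  rownames(per_ind) <- NULL

  groups <- unique(records$group)
  per_group <- do.call(rbind, lapply(split(per_ind, per_ind$gene), function(dg) {
    # degenerate (noise-free) inputs have no ANOVA; report folds with NA p
    comp <- tryCatch(
      anova_dunnett(if (test_scale == "dct") dg$dct else dg$fold,
                    dg$group, control = calibrator_group),
      error = function(e) list(comparisons = data.frame(group = character(),
                                                        p_adj = numeric())))
    pg <- data.frame(gene = dg$gene[1],
                     group = groups,
                     mean_fold = vapply(groups, function(g) mean(dg$fold[dg$group == g]), 0),
                     sd_fold = vapply(groups, function(g) stats::sd(dg$fold[dg$group == g]), 0),
                     n = vapply(groups, function(g) sum(dg$group == g), 0L),
                     stringsAsFactors = FALSE)
    m <- match(pg$group, comp$comparisons$group)
    pg$dunnett_p <- comp$comparisons$p_adj[m]
    pg$stars <- ifelse(is.na(pg$dunnett_p), "", stars_for_p(pg$dunnett_p))
    pg
  }))
  rownames(per_group) <- NULL
  list(per_individual = per_ind, per_group = per_group)
}

#' One-way ANOVA with Dunnett many-to-one post-tests
#'
#' Overall F test followed by Dunnett comparisons of every group against the
#' control, with family-wise adjustment via the multivariate-t distribution
#' (numeric integration as implemented in multcomp; the integration seed is
#' fixed internally so results are deterministic to its documented tolerance).
#'
#' @param values Numeric response vector.
#' @param groups Group labels, same length as `values`.
#' @param control Control group name.
#' @return List: `f` (F statistic), `p_overall`, and `comparisons`, a data
#'   frame (group, estimate, t, p_adj, stars) for each non-control group.
#' @export
anova_dunnett <- function(values, groups, control) {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  if (!control %in% groups) stop(sprintf("control group '%s' absent", control), call. = FALSE)
  lv <- c(control, setdiff(unique(groups), control))
  if (length(lv) < 2L) stop("need at least two groups", call. = FALSE)
  if (any(table(groups) < 2L)) stop("need at least two values per group", call. = FALSE)
  d <- data.frame(y = values, g = factor(groups, levels = lv))
  wss <- sum(unlist(lapply(split(d$y, d$g), function(v) sum((v - mean(v))^2))))
  if (wss == 0) stop("zero within-group variance in every group", call. = FALSE)
  fit <- stats::aov(y ~ g, data = d)
  an <- summary(fit)[[1]]
  fstat <- an[["F value"]][1]
  p_overall <- an[["Pr(>F)"]][1]
  gl <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(20140707L)  # deterministic multivariate-t integration
  sm <- summary(gl)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  cmp <- data.frame(group = lv[-1],
                    estimate = as.numeric(sm$test$coefficients),
                    t = as.numeric(sm$test$tstat),
                    p_adj = as.numeric(sm$test$pvalues),
                    stringsAsFactors = FALSE)
  cmp$stars <- stars_for_p(cmp$p_adj)
  list(f = fstat, p_overall = p_overall, comparisons = cmp)
}

#' Capillaries per terminal villus
#'
#' Per placenta, the ratio of the TOTAL capillary count to the TOTAL terminal
#' villus count over its fields (a ratio of totals, not a mean of per-field
#' ratios), followed by group summaries and ANOVA + Dunnett against the
#' control group. Placentas whose villus total is zero are undefined and are
#' excluded with a warning.
#'
#' @param records Morphometry data frame (placenta, group, field,
#'   capillaries, villi, ...).
#' @param control Control group (default "healthy").
#' @return List: `per_placenta` (placenta, group, ratio), `per_group` (group,
#'   mean, sd, n, dunnett_p, stars), `anova` from [anova_dunnett()].
#' @export
capillaries_per_villus <- function(records, control = "healthy") {
  stopifnot(all(c("placenta", "group", "capillaries", "villi") %in% names(records)))
  agg <- stats::aggregate(cbind(capillaries, villi) ~ placenta + group,
                          data = records, FUN = sum)
  zero <- agg$villi == 0
  if (any(zero)) {
    warning(sprintf("excluding %d placenta(s) with zero villus count", sum(zero)),
            call. = FALSE)
    agg <- agg[!zero, , drop = FALSE]
  }
  if (nrow(agg) == 0L) stop("no placenta with a nonzero villus count", call. = FALSE)
  agg$ratio <- agg$capillaries / agg$villi
  per_placenta <- agg[order(agg$group, agg$placenta),
                      c("placenta", "group", "ratio")]
  rownames(per_placenta) <- NULL
  summarize_by_group(per_placenta$ratio, per_placenta$group, control,
                     per_placenta = per_placenta)
}

#' Mean immune cells per field
#'
#' Per placenta, the arithmetic mean count of the chosen marker over its
#' fields; group summaries and ANOVA + Dunnett against the control.
#'
#' @param records Morphometry data frame.
#' @param marker One of "cd45", "cd3", "cd19".
#' @param control Control group (default "healthy").
#' @return As [capillaries_per_villus()], with `mean_count` in place of
#'   `ratio`.
#' @export
mean_cells_per_field <- function(records, marker = c("cd45", "cd3", "cd19"),
                                 control = "healthy") {
  marker <- match.arg(marker)
  stopifnot(all(c("placenta", "group", marker) %in% names(records)))
  f <- stats::as.formula(paste(marker, "~ placenta + group"))
  agg <- stats::aggregate(f, data = records, FUN = mean)
  names(agg)[3] <- "mean_count"
  agg <- agg[order(agg$group, agg$placenta), , drop = FALSE]
  rownames(agg) <- NULL
  summarize_by_group(agg$mean_count, agg$group, control, per_placenta = agg)
}

summarize_by_group <- function(values, groups, control, per_placenta) {
  lv <- unique(groups)
  # degenerate inputs (e.g. all-zero counts) have no ANOVA; report NA p
  comp <- tryCatch(anova_dunnett(values, groups, control),
                   error = function(e) list(f = NA_real_, p_overall = NA_real_,
                                            comparisons = data.frame(
                                              group = character(),
                                              p_adj = numeric())))
  per_group <- data.frame(
    group = lv,
    mean = vapply(lv, function(g) mean(values[groups == g]), 0),
    sd = vapply(lv, function(g) stats::sd(values[groups == g]), 0),
    n = vapply(lv, function(g) sum(groups == g), 0L),
    stringsAsFactors = FALSE)
  m <- match(per_group$group, comp$comparisons$group)
  per_group$dunnett_p <- comp$comparisons$p_adj[m]
  per_group$stars <- ifelse(is.na(per_group$dunnett_p), "",
                            stars_for_p(per_group$dunnett_p))
  rownames(per_group) <- NULL
  list(per_placenta = per_placenta, per_group = per_group, anova = comp)
}
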