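# GO-style term over-representation: one-sided Fisher's exact test, BH FDR,
# the fold-enrichment ratio Re = (nf/n)/(Nf/N), and the intersection /
# mild-only / severe-only term categorization.

validate_counts <- function(nf, n, Nf, N) {
  ok <- is.finite(nf) & is.finite(n) & is.finite(Nf) & is.finite(N) &
    nf >= 0 & n >= 0 & Nf >= 0 & N >= 0 &
    nf <= pmin(n, Nf) & n <= N & Nf <= N & nf >= pmax(0, n + Nf - N)
  if (!all(ok)) {
    i <- which(!ok)[1]
    stop(sprintf("invalid enrichment counts (nf=%s, n=%s, Nf=%s, N=%s)",
                 nf[i], n[i], Nf[i], N[i]), call. = FALSE)
  }
  invisible(TRUE)
}

#' One-sided Fisher over-representation test
#'
#' Probability of observing at least `nf` differential genes in a term of
#' size `n`, given `Nf` differential genes among `N` genes on the array:
#' the hypergeometric upper tail P(X >= nf) for X ~ Hypergeom(N, Nf, n).
#'
#' @param nf Differential genes within the term.
#' @param n Genes within the term.
#' @param Nf Differential genes on the array.
#' @param N Genes on the array. All arguments vectorize.
#' @return One-sided p-value(s).
#' @export
fisher_term_test <- function(nf, n, Nf, N) {
  validate_counts(nf, n, Nf, N)
  stats::phyper(nf - 1, Nf, N - Nf, n, lower.tail = FALSE)
}

#' Fold-enrichment ratio Re
#'
#' Re = (nf/n) / (Nf/N): the term's differential fraction relative to the
#' array-wide differential fraction. Re = 1 means no enrichment; Re = 0 when
#' the term contains no differential gene. Undefined (NA, with a warning)
#' when n = 0 or Nf = 0.
#'
#' @inheritParams fisher_term_test
#' @return Numeric ratio(s).
#' @export
enrichment_ratio <- function(nf, n, Nf, N) {
  validate_counts(nf, n, Nf, N)
  len <- max(length(nf), length(n), length(Nf), length(N))
  nf <- rep_len(nf, len); n <- rep_len(n, len)
  Nf <- rep_len(Nf, len); N <- rep_len(N, len)
  bad <- n == 0 | Nf == 0 | N == 0
  if (any(bad)) warning(sprintf("%d term(s) with undefined Re skipped", sum(bad)),
                        call. = FALSE)
  out <- rep(NA_real_, length(nf))
  out[!bad] <- (nf[!bad] / n[!bad]) / (Nf[!bad] / N[!bad])
  out
}

#' Term enrichment over a differential gene set
#'
#' One test per annotation term with at least one universe gene; BH
#' adjustment across all tested terms; results sorted by (fdr, Re descending,
#' term id). The universe is the flag-filtered gene set -- the genes that
#' could have been called differential.
#'
#' @param de_genes Character vector of differential genes (must be a subset
#'   of `universe`).
#' @param annotation Data frame (gene, term), as from [read_annotation()] or
#'   [simulate_annotation()].
#' @param universe Character vector of background genes (N = its size).
#' @return An `enrichment_result` data frame: term, nf, n, Nf, N, p, fdr, Re.
#' @export
enrich_all <- function(de_genes, annotation, universe) {
  de_genes <- unique(as.character(de_genes))
  universe <- unique(as.character(universe))
  offenders <- setdiff(de_genes, universe)
  if (length(offenders) > 0L) {
    stop(sprintf("DE genes not in universe: %s",
                 paste(utils::head(offenders, 5), collapse = ", ")), call. = FALSE)
  }
  ann <- unique(annotation[annotation$gene %in% universe, c("gene", "term")])
  if (nrow(ann) == 0L) {
    return(structure(data.frame(term = character(), nf = integer(), n = integer(),
                                Nf = integer(), N = integer(), p = numeric(),
                                fdr = numeric(), Re = numeric(),
                                stringsAsFactors = FALSE),
                     class = c("enrichment_result", "data.frame")))
  }
  N <- length(universe)
  Nf <- length(de_genes)
  n_by_term <- table(ann$term)
  nf_by_term <- table(factor(ann$term[ann$gene %in% de_genes],
                             levels = names(n_by_term)))
  terms <- names(n_by_term)
  n <- as.integer(n_by_term)
  nf <- as.integer(nf_by_term)
  p <- fisher_term_test(nf, n, Nf, N)
  Re <- if (Nf > 0) enrichment_ratio(nf, n, Nf, N) else rep(0, length(nf))
  out <- data.frame(term = terms, nf = nf, n = n, Nf = Nf, N = N,
                    p = p, fdr = adjust_bh(p), Re = Re,
                    stringsAsFactors = FALSE)
  out <- out[order(out$fdr, -out$Re, out$term), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Categorize enriched terms across two contrasts
#'
#' Set algebra on significant terms of the two contrasts followed by
#' truncation: the top `top_k_intersection` terms enriched in both contrasts
#' (ranked by the best rank across the two result lists) and the top
#' `top_k_unique` terms unique to each contrast (ranked by that contrast's
#' own ordering).
#'
#' @param first,second `enrichment_result` data frames (already ranked).
#' @param fdr_threshold Significance gate on each contrast's FDR (default
#'   0.05).
#' @param top_k_intersection,top_k_unique Truncation sizes (defaults 10 and
#'   5; no padding when fewer terms exist).
#' @return List of character vectors `intersection`, `first_only`,
#'   `second_only`.
#' @export
categorize_terms <- function(first, second, fdr_threshold = 0.05,
                             top_k_intersection = 10L, top_k_unique = 5L) {
  sig1 <- first$term[first$fdr < fdr_threshold]
  sig2 <- second$term[second$fdr < fdr_threshold]
  rank1 <- stats::setNames(seq_along(sig1), sig1)
  rank2 <- stats::setNames(seq_along(sig2), sig2)
  both <- intersect(sig1, sig2)
  both <- both[order(pmin(rank1[both], rank2[both]), both)]
  only1 <- sig1[!sig1 %in% sig2]
  only2 <- sig2[!sig2 %in% sig1]
  list(intersection = utils::head(both, top_k_intersection),
       first_only = utils::head(only1, top_k_unique),
       second_only = utils::head(only2, top_k_unique))
}
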