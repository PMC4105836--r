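# Co-expression and gene-interaction networks: pairwise Pearson correlation
# with hard thresholding, degree centrality, k-core decomposition by
# minimum-degree peeling, and core-gene nomination combining the two
# networks.

#' Construct a gene network
#'
#' Light container for an undirected graph over gene ids: canonical edges,
#' per-node degree, k-core numbers and optional node attributes (direction of
#' regulation, contrast membership).
#'
#' @param nodes Character vector of gene ids (isolated nodes allowed).
#' @param edges Data frame with columns from, to (and optionally weight);
#'   canonicalized on construction.
#' @param attributes Optional data frame with a `gene` column plus attribute
#'   columns (e.g. membership, direction).
#' @return A `gene_network` object with `degree` and `core` filled in.
#' @export
gene_network <- function(nodes, edges = NULL, attributes = NULL) {
  nodes <- unique(as.character(nodes))
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(from = character(), to = character(), stringsAsFactors = FALSE)
  } else {
    edges <- canonical_edges(edges$from, edges$to, edges$weight)
    missing_nodes <- setdiff(unique(c(edges$from, edges$to)), nodes)
    nodes <- c(nodes, missing_nodes)
  }
  nodes <- sort(nodes)
  deg <- stats::setNames(integer(length(nodes)), nodes)
  if (nrow(edges) > 0L) {
    tab <- table(c(edges$from, edges$to))
    deg[names(tab)] <- as.integer(tab)
  }
  net <- structure(list(nodes = nodes, edges = edges, degree = deg,
                        core = NULL, attributes = attributes),
                   class = "gene_network")
  net$core <- kcore_decompose(net)
  net
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("<gene_network> %d nodes, %d edges, max core %s\n",
              length(x$nodes), nrow(x$edges),
              if (length(x$core)) max(x$core) else 0L))
  invisible(x)
}

#' Pairwise Pearson correlations across arrays
#'
#' Correlations of the normalized signal intensities of each gene pair across
#' all arrays jointly. Zero-variance genes have undefined correlation and are
#' excluded with a warning.
#'
#' @param x An `expr_matrix` with at least 3 arrays.
#' @param genes Optional gene subset.
#' @return Symmetric correlation matrix (class `gene_correlations`).
#' @export
pairwise_pearson <- function(x, genes = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  v <- x$values
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(v))
    if (length(missing) > 0L) {
      stop(sprintf("genes not in matrix: %s",
                   paste(utils::head(missing, 5), collapse = ", ")), call. = FALSE)
    }
    v <- v[genes, , drop = FALSE]
  }
  if (ncol(v) < 3L) stop("need at least 3 arrays for correlation", call. = FALSE)
  sds <- apply(v, 1L, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("excluding %d zero-variance gene(s)", sum(sds == 0)), call. = FALSE)
    v <- v[sds > 0, , drop = FALSE]
  }
  r <- stats::cor(t(v))
  class(r) <- c("gene_correlations", class(r))
  r
}

#' Build a co-expression network by hard thresholding
#'
#' An edge joins two genes iff |r| >= `r_min`; the signed correlation is kept
#' as the edge weight and isolated genes remain as nodes. The default
#' threshold 0.9 is discussed in the methods vignette (with 6 arrays the
#' p < 0.05 point is |r| = 0.811; 0.9 adds margin) and is configurable.
#'
#' @param correlations Correlation matrix from [pairwise_pearson()].
#' @param r_min Absolute-correlation threshold in (0, 1].
#' @param positive_only If TRUE, only positive correlations form edges.
#' @param attributes Optional node attribute data frame (gene, ...).
#' @return A `gene_network`.
#' @export
build_coexpression <- function(correlations, r_min = 0.9,
                               positive_only = FALSE, attributes = NULL) {
  assert_scalar_number(r_min, "r_min", 0, 1)
  if (r_min <= 0) stop("r_min must be in (0, 1]", call. = FALSE)
  r <- unclass(correlations)
  genes <- rownames(r)
  sel <- if (positive_only) r >= r_min else abs(r) >= r_min
  sel[lower.tri(sel, diag = TRUE)] <- FALSE
  idx <- which(sel, arr.ind = TRUE)
  edges <- data.frame(from = genes[idx[, 1]], to = genes[idx[, 2]],
                      weight = r[idx], stringsAsFactors = FALSE)
  gene_network(genes, edges, attributes = attributes)
}

#' k-core decomposition by minimum-degree peeling
#'
#' The core number of a node is the largest k such that it belongs to a
#' maximal subgraph of minimum degree >= k. Computed by iteratively removing
#' a minimum-degree node (ties broken by lexicographic gene id, so the
#' decomposition is deterministic).
#'
#' @param network A `gene_network` (the empty graph is allowed).
#' @return Named integer vector of core numbers.
#' @export
kcore_decompose <- function(network) {
  stopifnot(inherits(network, "gene_network"))
  nodes <- network$nodes
  n <- length(nodes)
  core <- stats::setNames(integer(n), nodes)
  if (n == 0L) return(core)
  adj <- rep(list(character(0)), n)
  names(adj) <- nodes
  e <- network$edges
  if (nrow(e) > 0L) {
    sp1 <- split(e$to, e$from)
    sp2 <- split(e$from, e$to)
    for (nm in names(sp1)) adj[[nm]] <- c(adj[[nm]], sp1[[nm]])
    for (nm in names(sp2)) adj[[nm]] <- c(adj[[nm]], sp2[[nm]])
  }
  deg <- vapply(adj, length, integer(1))
  alive <- stats::setNames(rep(TRUE, n), nodes)
  k <- 0L
  for (step in seq_len(n)) {
    cand <- names(deg)[alive]
    dmin <- min(deg[cand])
    v <- sort(cand[deg[cand] == dmin])[1]
    k <- max(k, deg[[v]])
    core[[v]] <- k
    alive[[v]] <- FALSE
    for (u in adj[[v]]) if (alive[[u]]) deg[[u]] <- deg[[u]] - 1L
  }
  core
}

#' Genes of the highest non-empty k-core
#'
#' @param network A `gene_network`.
#' @return List with `k` (0 for an empty network) and `genes`, the members of
#'   the maximum k-core.
#' @export
max_kcore <- function(network) {
  stopifnot(inherits(network, "gene_network"))
  if (length(network$core) == 0L) return(list(k = 0L, genes = character(0)))
  k <- max(network$core)
  list(k = as.integer(k), genes = sort(names(network$core)[network$core == k]))
}

#' Build the gene-interaction network around attributed genes
#'
#' Restricts a supplied (database-derived) edge list to edges touching at
#' least one gene carrying DE attributes, so the network contains the
#' differential genes plus their direct partners, and computes degrees.
#' Attributes for genes absent from the edge list are dropped with a warning.
#'
#' @param edges Canonical edge data frame (e.g. from [read_edges()]).
#' @param gene_attributes Data frame with a `gene` column plus attribute
#'   columns (membership, direction).
#' @return A `gene_network`.
#' @export
interaction_network <- function(edges, gene_attributes) {
  stopifnot(is.data.frame(gene_attributes), "gene" %in% names(gene_attributes))
  edge_genes <- unique(c(edges$from, edges$to))
  unknown <- setdiff(gene_attributes$gene, edge_genes)
  if (length(unknown) > 0L) {
    warning(sprintf("dropping attributes for %d gene(s) absent from the edge list",
                    length(unknown)), call. = FALSE)
    gene_attributes <- gene_attributes[!gene_attributes$gene %in% unknown, , drop = FALSE]
  }
  attr_genes <- gene_attributes$gene
  keep <- edges$from %in% attr_genes | edges$to %in% attr_genes
  sub <- edges[keep, , drop = FALSE]
  nodes <- unique(c(attr_genes, sub$from, sub$to))
  gene_network(nodes, sub, attributes = gene_attributes)
}

#' Nominate core regulatory genes from the two networks
#'
#' Default (pluggable) rule: a gene is core iff it belongs to the maximum
#' k-core of the co-expression network OR its interaction-network degree lies
#' in the top `top_fraction`. Ranking is deterministic: co-expression core
#' number (desc), interaction degree (desc), co-expression degree (desc),
#' then gene id.
#'
#' @param coexpr Co-expression `gene_network`.
#' @param interaction Interaction `gene_network`.
#' @param top_fraction Fraction of interaction nodes counted as high degree
#'   (default 0.05).
#' @param rule Optional function(coexpr, interaction) -> character vector of
#'   core genes, replacing the default OR rule.
#' @return A `core_gene_set` data frame: gene, core_number, degree_coexpr,
#'   degree_interaction, plus any node attributes, in rank order.
#' @export
identify_core_genes <- function(coexpr, interaction, top_fraction = 0.05,
                                rule = NULL) {
  stopifnot(inherits(coexpr, "gene_network"), inherits(interaction, "gene_network"))
  if (is.null(rule)) {
    mk <- max_kcore(coexpr)
    kc_genes <- if (mk$k > 0L) mk$genes else character(0)
    top_genes <- character(0)
    if (length(interaction$degree) > 0L && any(interaction$degree > 0L)) {
      kth <- ceiling(top_fraction * length(interaction$degree))
      thr <- sort(interaction$degree, decreasing = TRUE)[kth]
      top_genes <- names(interaction$degree)[interaction$degree >= max(thr, 1L)]
    }
    core_genes <- union(kc_genes, top_genes)
  } else {
    core_genes <- rule(coexpr, interaction)
  }
  if (length(core_genes) == 0L) {
    return(structure(data.frame(gene = character(), core_number = integer(),
                                degree_coexpr = integer(),
                                degree_interaction = integer(),
                                stringsAsFactors = FALSE),
                     class = c("core_gene_set", "data.frame")))
  }
  get0i <- function(v, g) ifelse(g %in% names(v), v[g], 0L)
  out <- data.frame(gene = core_genes,
                    core_number = as.integer(get0i(coexpr$core, core_genes)),
                    degree_coexpr = as.integer(get0i(coexpr$degree, core_genes)),
                    degree_interaction = as.integer(get0i(interaction$degree, core_genes)),
                    stringsAsFactors = FALSE)
  for (net in list(coexpr, interaction)) {
    if (!is.null(net$attributes)) {
      extra <- setdiff(names(net$attributes), c("gene", names(out)))
      if (length(extra) > 0L) {
        m <- match(out$gene, net$attributes$gene)
        for (col in extra) out[[col]] <- net$attributes[[col]][m]
      }
    }
  }
  out <- out[order(-out$core_number, -out$degree_interaction,
                   -out$degree_coexpr, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("core_gene_set", "data.frame")
  out
}
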