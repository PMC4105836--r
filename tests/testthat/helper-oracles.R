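# Independent oracles and small fixture builders shared across the suite.
# Each oracle is a deliberately naive implementation, kept independent of the
# package code paths it checks.

# exhaustive Benjamini-Hochberg step-up: q_i = min over ranks j >= rank(i) of
# m * p_(j) / j, computed with plain loops
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) best <- min(best, m * ps[j] / j)
    q[i] <- min(best, 1)
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# direct hypergeometric-pmf summation for the over-representation tail
fisher_oracle <- function(nf, n, Nf, N) {
  ks <- nf:min(n, Nf)
  sum(stats::dhyper(ks, Nf, N - Nf, n))
}

# brute-force core numbers: for each k, prune nodes of degree < k to a fixed
# point; a node's core number is the largest k it survives
kcore_oracle <- function(edges, nodes) {
  core <- stats::setNames(integer(length(nodes)), nodes)
  n <- length(nodes)
  for (k in seq_len(n)) {
    alive <- nodes
    repeat {
      e <- edges[edges$from %in% alive & edges$to %in% alive, , drop = FALSE]
      deg <- stats::setNames(integer(length(alive)), alive)
      if (nrow(e) > 0) {
        tab <- table(c(e$from, e$to))
        deg[names(tab)] <- as.integer(tab)
      }
      drop <- alive[deg < k]
      if (length(drop) == 0) break
      alive <- setdiff(alive, drop)
    }
    if (length(alive) == 0) break
    core[alive] <- k
  }
  core
}

# naive O(n^3) average-linkage agglomeration; returns sorted merge heights
average_linkage_heights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  active <- seq_len(n)
  while (length(active) > 1) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(active)) {
      for (j in seq_len(i - 1)) {
        a <- clusters[[active[i]]]; b <- clusters[[active[j]]]
        h <- mean(d[a, b])
        if (h < best_h) { best_h <- h; best <- c(active[j], active[i]) }
      }
    }
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    active <- setdiff(active, best[2])
  }
  sort(heights)
}

# Erdos-Renyi gene_network with gene-style node labels
er_network <- function(n, p, seed) {
  set.seed(seed)
  nodes <- sprintf("g%03d", seq_len(n))
  pairs <- utils::combn(nodes, 2)
  keep <- stats::runif(ncol(pairs)) < p
  gene_network(nodes, data.frame(from = pairs[1, keep], to = pairs[2, keep],
                                 stringsAsFactors = FALSE))
}

# small expression fixture: values by column, one array per group label
make_expr <- function(values, groups, genes = NULL) {
  m <- as.matrix(values)
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(m)))
  arrays <- sprintf("%s_a%d", groups, stats::ave(seq_along(groups), groups,
                                                 FUN = seq_along))
  dimnames(m) <- list(genes, arrays)
  expression_matrix(m, data.frame(array = arrays, group = groups,
                                  subgroup = arrays, stringsAsFactors = FALSE))
}

# long qPCR record block for one individual and gene (identical replicates)
qpcr_rows <- function(individual, group, gene, ct, reps = 3) {
  data.frame(individual = individual, group = group, gene = gene,
             replicate = seq_len(reps), ct = ct, stringsAsFactors = FALSE)
}
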