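# Readers and writers for every table the pipeline touches, with strict
# validation. All files are tab-separated UTF-8 text without quoting; missing
# values are disallowed (the detection-flag filter is the only missingness
# mechanism in this data model).

#' Construct an expression matrix with design metadata
#'
#' The central container of the pipeline: a genes x arrays matrix of log2
#' intensities, an optional same-shaped logical detection-flag matrix, and a
#' design table mapping each array to its group and pooling sub-group.
#'
#' @param values Numeric matrix (genes x arrays) of log2 intensities with
#'   unique row (gene) and column (array) names.
#' @param design Data frame with columns `array`, `group`, `subgroup`; one row
#'   per array, in column order of `values`.
#' @param flags Optional logical matrix of per-gene, per-array detection calls,
#'   same dimnames as `values`.
#' @return An object of class `expr_matrix`.
#' @export
expression_matrix <- function(values, design, flags = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix", call. = FALSE)
  }
  if ((nrow(values) > 0L && is.null(rownames(values))) ||
      (ncol(values) > 0L && is.null(colnames(values)))) {
    stop("'values' must carry gene rownames and array colnames", call. = FALSE)
  }
  if (is.null(rownames(values))) rownames(values) <- character(0)
  if (is.null(colnames(values))) colnames(values) <- character(0)
  if (anyDuplicated(rownames(values))) {
    dup <- rownames(values)[duplicated(rownames(values))][1]
    stop(sprintf("duplicate gene id: %s", dup), call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    dup <- colnames(values)[duplicated(colnames(values))][1]
    stop(sprintf("duplicate array id: %s", dup), call. = FALSE)
  }
  if (!is.data.frame(design) || !all(c("array", "group", "subgroup") %in% names(design))) {
    stop("'design' must be a data.frame with columns array, group, subgroup", call. = FALSE)
  }
  if (!identical(as.character(design$array), colnames(values))) {
    stop("design rows must match array columns (same ids, same order)", call. = FALSE)
  }
  if (!is.null(flags)) {
    if (!is.matrix(flags) || !identical(dim(flags), dim(values))) {
      stop("'flags' must be a matrix with the same shape as 'values'", call. = FALSE)
    }
    if (nrow(values) == 0L) {
      dimnames(flags) <- dimnames(values)
    } else if (!identical(dimnames(flags), dimnames(values))) {
      stop("'flags' must carry the same dimnames as 'values'", call. = FALSE)
    }
    storage.mode(flags) <- "logical"
  }
  structure(list(values = values, flags = flags,
                 design = data.frame(array = as.character(design$array),
                                     group = as.character(design$group),
                                     subgroup = as.character(design$subgroup),
                                     stringsAsFactors = FALSE)),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d arrays (%s flags)\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$flags)) "no" else "with"))
  cat("groups:", paste(unique(x$design$group), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Attach detection flags to an expression matrix
#'
#' @param x An `expr_matrix`.
#' @param flags Logical matrix with the same dimnames as `x$values`.
#' @return `x` with flags attached.
#' @export
set_flags <- function(x, flags) {
  stopifnot(inherits(x, "expr_matrix"))
  expression_matrix(x$values, x$design, flags = flags)
}

# -- low-level TSV machinery -------------------------------------------------

read_tsv_cells <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(list())
  cells <- strsplit(lines, "\t", fixed = TRUE)
  ncol1 <- length(cells[[1]])
  widths <- lengths(cells)
  bad <- which(widths != ncol1)
  if (length(bad) > 0L) {
    stop(sprintf("ragged row at line %d of %s (%d fields, expected %d)",
                 bad[1], path, widths[bad[1]], ncol1), call. = FALSE)
  }
  cells
}

parse_numeric_cell <- function(txt, path, line) {
  suppressWarnings(v <- as.numeric(txt))
  bad <- which(is.na(v) | txt %in% c("NA", "NaN", ""))
  if (length(bad) > 0L) {
    stop(sprintf("non-numeric or missing cell '%s' at line %d of %s",
                 txt[bad[1]], line, path), call. = FALSE)
  }
  v
}

write_tsv <- function(df, path, numeric_cols = NULL) {
  cols <- lapply(names(df), function(nm) {
    v <- df[[nm]]
    if (is.numeric(v) && !is.integer(v)) format_num(v) else as.character(v)
  })
  lines <- c(paste(names(df), collapse = "\t"),
             do.call(paste, c(cols, sep = "\t")))
  if (nrow(df) == 0L) lines <- lines[1]
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

read_matrix_tsv <- function(path, what = c("numeric", "binary")) {
  what <- match.arg(what)
  cells <- read_tsv_cells(path)
  if (length(cells) < 2L) stop(sprintf("%s: no data rows", path), call. = FALSE)
  header <- cells[[1]]
  array_ids <- header[-1]
  if (anyDuplicated(array_ids)) {
    stop(sprintf("duplicate array id '%s' in %s",
                 array_ids[duplicated(array_ids)][1], path), call. = FALSE)
  }
  genes <- vapply(cells[-1], `[[`, character(1), 1L)
  if (anyDuplicated(genes)) {
    stop(sprintf("duplicate gene id '%s' in %s",
                 genes[duplicated(genes)][1], path), call. = FALSE)
  }
  vals <- matrix(NA_real_, nrow = length(genes), ncol = length(array_ids),
                 dimnames = list(genes, array_ids))
  for (i in seq_along(genes)) {
    vals[i, ] <- parse_numeric_cell(cells[[i + 1L]][-1], path, i + 1L)
  }
  if (what == "binary") {
    if (!all(vals %in% c(0, 1))) stop(sprintf("%s: flag cells must be 0/1", path), call. = FALSE)
    vals <- vals == 1
  }
  vals
}

write_matrix_tsv <- function(m, path, binary = FALSE) {
  body <- if (binary) {
    apply(m, 1L, function(r) paste(as.integer(r), collapse = "\t"))
  } else {
    apply(m, 1L, function(r) paste(format_num(r), collapse = "\t"))
  }
  lines <- c(paste(c("gene", colnames(m)), collapse = "\t"),
             paste(rownames(m), body, sep = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# -- public readers / writers ------------------------------------------------

#' Read a log2 expression matrix from TSV
#'
#' Expects a header row of array ids (first cell is a label for the gene
#' column) and one row per gene. Ragged rows, non-numeric cells and duplicate
#' gene/array ids are rejected with the offending line or id named.
#'
#' @param path Path to the values TSV.
#' @param design_path Optional path to the design TSV (array, group, subgroup).
#' @param flags_path Optional path to a 0/1 flag TSV of the same shape.
#' @return An `expr_matrix` (with a placeholder single-group design when
#'   `design_path` is missing).
#' @export
read_expression <- function(path, design_path = NULL, flags_path = NULL) {
  vals <- read_matrix_tsv(path, "numeric")
  design <- if (!is.null(design_path)) {
    read_design(design_path)
  } else {
    data.frame(array = colnames(vals), group = "all", subgroup = "all",
               stringsAsFactors = FALSE)
  }
  flags <- if (!is.null(flags_path)) read_matrix_tsv(flags_path, "binary") else NULL
  expression_matrix(vals, design, flags = flags)
}

#' Write an expression matrix (and optionally its flags/design) to TSV
#'
#' @param x An `expr_matrix`.
#' @param path Output path for the values TSV.
#' @param flags_path,design_path Optional output paths for the flag and design
#'   tables.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, flags_path = NULL, design_path = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  write_matrix_tsv(x$values, path)
  if (!is.null(flags_path)) {
    if (is.null(x$flags)) stop("no flags attached to write", call. = FALSE)
    write_matrix_tsv(x$flags, flags_path, binary = TRUE)
  }
  if (!is.null(design_path)) write_tsv(x$design, design_path)
  invisible(path)
}

#' Read an array design table (array, group, subgroup)
#' @param path Path to the design TSV.
#' @return Data frame with character columns array, group, subgroup.
#' @export
read_design <- function(path) {
  cells <- read_tsv_cells(path)
  header <- cells[[1]]
  if (!all(c("array", "group", "subgroup") %in% header)) {
    stop(sprintf("%s: design header must contain array, group, subgroup", path),
         call. = FALSE)
  }
  rows <- do.call(rbind, cells[-1])
  df <- as.data.frame(rows, stringsAsFactors = FALSE)
  names(df) <- header
  df[c("array", "group", "subgroup")]
}

#' Read a gene-to-term annotation table
#'
#' Two-column TSV (gene, term). Duplicate identical (gene, term) rows are
#' deduplicated; a gene may belong to many terms.
#'
#' @param path Path to the annotation TSV.
#' @return Data frame with columns gene, term.
#' @export
read_annotation <- function(path) {
  cells <- read_tsv_cells(path)
  if (length(cells) == 0L) {
    return(data.frame(gene = character(), term = character(), stringsAsFactors = FALSE))
  }
  header <- cells[[1]]
  has_header <- identical(tolower(header[1:2]), c("gene", "term"))
  body <- if (has_header) cells[-1] else cells
  if (length(body) == 0L) {
    return(data.frame(gene = character(), term = character(), stringsAsFactors = FALSE))
  }
  df <- data.frame(gene = vapply(body, `[[`, character(1), 1L),
                   term = vapply(body, `[[`, character(1), 2L),
                   stringsAsFactors = FALSE)
  unique(df)
}

#' @rdname read_annotation
#' @param annotation Data frame with columns gene, term.
#' @export
write_annotation <- function(annotation, path) {
  write_tsv(annotation[c("gene", "term")], path)
}

#' Canonicalize an undirected edge list
#'
#' Self-loops are dropped (with a warning carrying the drop count), endpoints
#' are ordered lexicographically and duplicate edges removed.
#'
#' @param from,to Character vectors of endpoint gene ids.
#' @param weight Optional numeric edge weights (first occurrence wins on
#'   duplicates).
#' @return Data frame with columns from, to (and weight when supplied);
#'   attribute `n_self_loops` counts dropped self-loops.
#' @export
canonical_edges <- function(from, to, weight = NULL) {
  from <- as.character(from); to <- as.character(to)
  self <- from == to
  n_self <- sum(self)
  if (n_self > 0L) {
    warning(sprintf("dropped %d self-loop edge(s)", n_self), call. = FALSE)
    from <- from[!self]; to <- to[!self]
    if (!is.null(weight)) weight <- weight[!self]
  }
  a <- pmin(from, to); b <- pmax(from, to)
  keep <- !duplicated(paste(a, b, sep = "\r"))
  out <- data.frame(from = a[keep], to = b[keep], stringsAsFactors = FALSE)
  if (!is.null(weight)) out$weight <- weight[keep]
  o <- order(out$from, out$to)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_self_loops") <- n_self
  out
}

#' Read a gene-interaction edge list
#'
#' Two- or three-column TSV (gene1, gene2, optional weight). Edges are
#' canonicalized via [canonical_edges()]; an empty file yields an empty edge
#' list, not an error.
#'
#' @param path Path to the edge TSV.
#' @return Canonical edge data frame.
#' @export
read_edges <- function(path) {
  cells <- read_tsv_cells(path)
  if (length(cells) == 0L) {
    return(canonical_edges(character(), character()))
  }
  header <- cells[[1]]
  has_header <- identical(tolower(header[1:2]), c("from", "to")) ||
    identical(tolower(header[1:2]), c("gene1", "gene2"))
  body <- if (has_header) cells[-1] else cells
  if (length(body) == 0L) return(canonical_edges(character(), character()))
  from <- vapply(body, `[[`, character(1), 1L)
  to <- vapply(body, `[[`, character(1), 2L)
  w <- if (length(body[[1]]) >= 3L) {
    parse_numeric_cell(vapply(body, `[[`, character(1), 3L), path, NA_integer_)
  } else NULL
  canonical_edges(from, to, w)
}

#' @rdname read_edges
#' @param edges Canonical edge data frame.
#' @export
write_edges <- function(edges, path) {
  cols <- intersect(c("from", "to", "weight"), names(edges))
  write_tsv(edges[cols], path)
}

#' Write / read planted ground truth as JSON
#'
#' Truth files round-trip losslessly (write then read yields an equal
#' structure), so recovery metrics can be computed from persisted runs.
#'
#' @param truth A `cohort_truth` list (see [cohort_truth()]).
#' @param path Output path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = FALSE, digits = NA,
                       null = "list", pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @return For `read_truth`, the truth list.
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  # jsonlite turns empty arrays into list(); normalize to character(0)
  norm_chr <- function(v) if (length(v) == 0L) character(0) else as.character(v)
  x$true_hubs <- norm_chr(x$true_hubs)
  x$true_enriched_terms <- norm_chr(x$true_enriched_terms)
  x$true_de <- lapply(x$true_de, function(d) {
    list(gene = norm_chr(d$gene), sign = as.numeric(d$sign), log2fc = as.numeric(d$log2fc))
  })
  x$true_modules <- lapply(x$true_modules, norm_chr)
  class(x) <- "cohort_truth"
  x
}
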