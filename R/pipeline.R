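# End-to-end orchestration: simulate -> preprocess -> DE -> enrichment ->
# networks -> core genes -> validation, with a manifest and (in synthetic
# mode) a truth-vs-called recovery report. Stage outputs are plain TSV/JSON
# files so any stage can be inspected or re-run; no output file contains a
# timestamp, so fixed-seed reruns are byte-identical.

#' Build a pipeline run configuration
#'
#' Defaults reproduce the study's stated gates: detection on at least 2 of 6
#' arrays, fold change at least 1.5, p < 0.05, FDR < 0.05.
#'
#' @param n_genes Simulated gene count (synthetic mode).
#' @param seed Master seed.
#' @param min_flagged_arrays Flag-filter threshold.
#' @param fc_threshold,p_threshold,fdr_threshold DE gates.
#' @param enrich_fdr Significance gate for enriched terms.
#' @param r_min Co-expression |r| threshold.
#' @param top_fraction Interaction-degree fraction for core-gene nomination.
#' @param n_core_qpcr Number of top core genes carried into the qPCR arm.
#' @param n_variable_genes Most-variable filtered genes added to the
#'   co-expression candidate set.
#' @param expression_path,flags_path,design_path,annotation_path,edges_path
#'   Optional real-mode input files; when `expression_path` is set the
#'   simulator is skipped and these inputs are used instead.
#' @param effects_args Named list of overrides passed to [planted_effects()].
#' @return A `run_config` list.
#' @export
run_config <- function(n_genes = 4000L, seed = 1L,
                       min_flagged_arrays = 2L,
                       fc_threshold = 1.5, p_threshold = 0.05,
                       fdr_threshold = 0.05, enrich_fdr = 0.05,
                       r_min = 0.9, top_fraction = 0.05,
                       n_core_qpcr = 19L, n_variable_genes = 100L,
                       expression_path = NULL, flags_path = NULL,
                       design_path = NULL, annotation_path = NULL,
                       edges_path = NULL, effects_args = list()) {
  cfg <- list(n_genes = as.integer(n_genes), seed = as.integer(seed),
              min_flagged_arrays = as.integer(min_flagged_arrays),
              fc_threshold = fc_threshold, p_threshold = p_threshold,
              fdr_threshold = fdr_threshold, enrich_fdr = enrich_fdr,
              r_min = r_min, top_fraction = top_fraction,
              n_core_qpcr = as.integer(n_core_qpcr),
              n_variable_genes = as.integer(n_variable_genes),
              expression_path = expression_path, flags_path = flags_path,
              design_path = design_path, annotation_path = annotation_path,
              edges_path = edges_path, effects_args = effects_args)
  for (nm in c("fc_threshold", "p_threshold", "fdr_threshold", "enrich_fdr",
               "r_min", "top_fraction")) {
    assert_scalar_number(cfg[[nm]], nm, 0, ifelse(nm == "fc_threshold", Inf, 1))
  }
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

log_line <- function(path, ...) {
  msg <- paste0(...)
  message(msg)
  cat(msg, "\n", file = path, sep = "", append = TRUE)
}

#' Run the full pipeline
#'
#' Executes every stage, writing each stage's inputs and outputs under
#' `out_dir` together with a manifest (seed, configuration, per-file MD5
#' checksums) and, in synthetic mode, a recovery report scoring the called
#' results against the planted truth.
#'
#' @param config A `run_config`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the main in-memory results (expression,
#'   de, called, enrichment, networks, core_genes, validation, recovery).
#' @export
run_all <- function(config = run_config(), out_dir) {
  stopifnot(inherits(config, "run_config"))
  dirs <- file.path(out_dir, c("inputs", "preprocess", "de", "enrichment",
                               "network", "validation", "report"))
  for (d in dirs) dir.create(d, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "report", "run.log")
  unlink(log_path)
  synthetic <- is.null(config$expression_path)
  t0 <- Sys.time()

  # -- stage: inputs ---------------------------------------------------------
  if (synthetic) {
    log_line(log_path, "stage simulate: n_genes=", config$n_genes,
             " seed=", config$seed)
    design <- cohort_design(n_genes = config$n_genes)
    effects <- do.call(planted_effects,
                       c(list(design = design, seed = config$seed),
                         config$effects_args))
    truth <- cohort_truth(effects)
    ind <- simulate_individuals(design, effects)
    expr <- pool_samples(ind, design, effects)
    expr <- set_flags(expr, simulate_flags(expr, seed = config$seed))
    annotation <- simulate_annotation(design, effects)
    edges <- suppressWarnings(simulate_interactions(design, effects))
    write_expression(expr, file.path(out_dir, "inputs", "expression.tsv"),
                     flags_path = file.path(out_dir, "inputs", "flags.tsv"),
                     design_path = file.path(out_dir, "inputs", "design.tsv"))
    write_annotation(annotation, file.path(out_dir, "inputs", "annotation.tsv"))
    write_edges(edges, file.path(out_dir, "inputs", "interactions.tsv"))
    write_truth(truth, file.path(out_dir, "inputs", "truth.json"))
  } else {
    log_line(log_path, "stage load: ", config$expression_path)
    expr <- read_expression(config$expression_path, config$design_path,
                            config$flags_path)
    annotation <- read_annotation(config$annotation_path)
    edges <- read_edges(config$edges_path)
    design <- NULL; effects <- NULL; truth <- NULL
  }

  # -- stage: preprocess -----------------------------------------------------
  log_line(log_path, "stage preprocess: quantile normalization + ",
           config$min_flagged_arrays, "-of-", ncol(expr$values), " flag filter")
  norm <- quantile_normalize(expr)
  filt <- filter_by_flags(norm, config$min_flagged_arrays)
  write_expression(filt, file.path(out_dir, "preprocess", "filtered_normalized.tsv"))
  universe <- rownames(filt$values)

  # -- stage: differential expression ---------------------------------------
  log_line(log_path, "stage de: fc>=", config$fc_threshold,
           " p<", config$p_threshold, " fdr<", config$fdr_threshold)
  de <- run_de(filt, fc_threshold = config$fc_threshold,
               p_threshold = config$p_threshold,
               fdr_threshold = config$fdr_threshold)
  called <- de[de$call != "ns", , drop = FALSE]
  contrasts <- unique(de$contrast)
  write_tsv(de, file.path(out_dir, "de", "de_results.tsv"))
  write_tsv(called, file.path(out_dir, "de", "de_called.tsv"))
  algebra <- NULL
  if (length(contrasts) == 2L && nrow(called) > 0L) {
    algebra <- de_set_algebra(split(called, factor(called$contrast, levels = contrasts)))
    alg_rows <- rbind(
      data.frame(category = "intersection", gene = algebra$intersection$gene,
                 direction = paste(algebra$intersection$direction_a,
                                   algebra$intersection$direction_b, sep = "/"),
                 stringsAsFactors = FALSE),
      data.frame(category = paste0(contrasts[1], "_only"),
                 gene = algebra$first_only$gene,
                 direction = algebra$first_only$direction, stringsAsFactors = FALSE),
      data.frame(category = paste0(contrasts[2], "_only"),
                 gene = algebra$second_only$gene,
                 direction = algebra$second_only$direction, stringsAsFactors = FALSE))
    write_tsv(alg_rows, file.path(out_dir, "de", "set_algebra.tsv"))
  }
  if (length(unique(called$gene)) >= 2L) {
    hc <- suppressWarnings(hierarchical_cluster(filt, genes = unique(called$gene)))
    writeLines(hc$gene_newick, file.path(out_dir, "de", "gene_dendrogram.nwk"))
    writeLines(hc$array_newick, file.path(out_dir, "de", "array_dendrogram.nwk"))
    write_matrix_tsv(hc$heatmap, file.path(out_dir, "de", "heatmap_matrix.tsv"))
  }

  # -- stage: enrichment -----------------------------------------------------
  log_line(log_path, "stage enrichment: fdr<", config$enrich_fdr)
  enr <- lapply(contrasts, function(ctr)
    enrich_all(called$gene[called$contrast == ctr], annotation, universe))
  names(enr) <- contrasts
  for (ctr in contrasts) {
    write_tsv(enr[[ctr]], file.path(out_dir, "enrichment",
                                    paste0("enrichment_", ctr, ".tsv")))
  }
  categories <- NULL
  if (length(contrasts) == 2L) {
    categories <- categorize_terms(enr[[1]], enr[[2]], fdr_threshold = config$enrich_fdr)
    cat_rows <- data.frame(
      category = rep(c("intersection", paste0(contrasts, "_only")),
                     times = lengths(categories)),
      term = unlist(categories, use.names = FALSE), stringsAsFactors = FALSE)
    write_tsv(cat_rows, file.path(out_dir, "enrichment", "term_categories.tsv"))
  }

  # -- stage: networks -------------------------------------------------------
  # candidate set: called genes, genes of significant terms, and the most
  # variable filtered genes (so strong latent modules are always candidates)
  sig_terms <- unique(unlist(lapply(enr, function(e) e$term[e$fdr < config$enrich_fdr])))
  term_genes <- annotation$gene[annotation$term %in% sig_terms]
  vars <- apply(filt$values, 1L, stats::var)
  top_var <- names(sort(vars, decreasing = TRUE))[
    seq_len(min(config$n_variable_genes, length(vars)))]
  candidates <- sort(unique(c(called$gene, intersect(term_genes, universe), top_var)))
  log_line(log_path, "stage network: ", length(candidates),
           " candidate genes, r_min=", config$r_min)
  node_attr <- network_attributes(called, contrasts)
  coexpr <- NULL; inter <- NULL; core <- NULL
  if (length(candidates) >= 2L) {
    corr <- suppressWarnings(pairwise_pearson(filt, genes = candidates))
    coexpr <- build_coexpression(corr, r_min = config$r_min, attributes = node_attr)
    inter <- suppressWarnings(interaction_network(edges, node_attr))
    core <- identify_core_genes(coexpr, inter, top_fraction = config$top_fraction)
    write_tsv(coexpr$edges, file.path(out_dir, "network", "coexpr_edges.tsv"))
    write_tsv(data.frame(gene = coexpr$nodes,
                         degree = as.integer(coexpr$degree),
                         core_number = as.integer(coexpr$core),
                         stringsAsFactors = FALSE),
              file.path(out_dir, "network", "coexpr_nodes.tsv"))
    write_tsv(data.frame(gene = inter$nodes,
                         degree = as.integer(inter$degree),
                         stringsAsFactors = FALSE),
              file.path(out_dir, "network", "interaction_nodes.tsv"))
    write_tsv(core, file.path(out_dir, "network", "core_genes.tsv"))
  }

  # -- stage: validation -----------------------------------------------------
  validation <- NULL
  if (synthetic) {
    qpcr_genes <- if (!is.null(core) && nrow(core) > 0L) {
      utils::head(core$gene, config$n_core_qpcr)
    } else {
      utils::head(unique(called$gene), config$n_core_qpcr)
    }
    qpcr_genes <- intersect(qpcr_genes, design_genes(design))
    log_line(log_path, "stage validation: ", length(qpcr_genes),
             " qPCR genes + morphometry")
    validation <- list()
    if (length(qpcr_genes) > 0L) {
      qpcr <- simulate_qpcr(design, effects, genes = qpcr_genes)
      write_tsv(qpcr, file.path(out_dir, "inputs", "qpcr.tsv"))
      validation$qpcr <- ddct_fold_change(qpcr)
      write_tsv(validation$qpcr$per_individual,
                file.path(out_dir, "validation", "qpcr_folds.tsv"))
      write_tsv(validation$qpcr$per_group,
                file.path(out_dir, "validation", "qpcr_group_stats.tsv"))
    }
    morpho <- simulate_morphometry(design, seed = config$seed)
    write_tsv(morpho, file.path(out_dir, "inputs", "morphometry.tsv"))
    validation$vessels <- capillaries_per_villus(morpho)
    validation$cells <- lapply(c(cd45 = "cd45", cd3 = "cd3", cd19 = "cd19"),
                               function(mk) mean_cells_per_field(morpho, mk))
    write_tsv(validation$vessels$per_group,
              file.path(out_dir, "validation", "morphometry_vessels.tsv"))
    cell_rows <- do.call(rbind, lapply(names(validation$cells), function(mk) {
      pg <- validation$cells[[mk]]$per_group
      cbind(data.frame(marker = mk, stringsAsFactors = FALSE), pg)
    }))
    write_tsv(cell_rows, file.path(out_dir, "validation", "morphometry_cells.tsv"))
  }

  # -- stage: recovery report (synthetic mode) ------------------------------
  recovery <- NULL
  if (synthetic) {
    recovery <- recovery_report(truth, called, contrasts, enr, coexpr, core,
                                config)
    jsonlite::write_json(recovery, file.path(out_dir, "report", "recovery.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  # -- manifest --------------------------------------------------------------
  files <- sort(list.files(out_dir, recursive = TRUE, full.names = FALSE))
  files <- setdiff(files, file.path("report", "manifest.json"))
  sums <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(sums) <- files
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                               null = "null")
  manifest <- list(seed = config$seed,
                   config = unclass(config),
                   config_md5 = digest_string(as.character(cfg_json)),
                   checksums = sums)
  jsonlite::write_json(manifest, file.path(out_dir, "report", "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message(sprintf("run complete in %.1f s: %s",
                  as.numeric(difftime(Sys.time(), t0, units = "secs")), out_dir))
  invisible(list(expression = expr, filtered = filt, de = de, called = called,
                 algebra = algebra, enrichment = enr, categories = categories,
                 coexpression = coexpr, interaction = inter, core_genes = core,
                 validation = validation, truth = truth, recovery = recovery))
}

# md5 of a string via a temp file (tools::md5sum is file-based)
digest_string <- function(s) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(s, tf, useBytes = TRUE)
  unname(tools::md5sum(tf))
}

# node attributes for the network stage: membership + direction per gene
network_attributes <- function(called, contrasts) {
  if (nrow(called) == 0L || length(contrasts) != 2L) {
    return(data.frame(gene = unique(called$gene),
                      membership = if (nrow(called)) "single" else character(0),
                      direction = if (nrow(called)) called$call[!duplicated(called$gene)] else character(0),
                      stringsAsFactors = FALSE))
  }
  g1 <- called$gene[called$contrast == contrasts[1]]
  g2 <- called$gene[called$contrast == contrasts[2]]
  genes <- sort(unique(c(g1, g2)))
  membership <- ifelse(genes %in% g1 & genes %in% g2, "intersection",
                       ifelse(genes %in% g1, paste0(contrasts[1], "_only"),
                              paste0(contrasts[2], "_only")))
  dir_map <- stats::setNames(called$call, called$gene)  # last call wins on overlap
  data.frame(gene = genes, membership = membership,
             direction = unname(dir_map[genes]), stringsAsFactors = FALSE)
}

# truth-vs-called metrics for the synthetic mode
recovery_report <- function(truth, called, contrasts, enr, coexpr, core, config) {
  per_contrast <- lapply(contrasts, function(ctr) {
    true_genes <- truth$true_de[[ctr]]$gene %||% character(0)
    called_genes <- unique(called$gene[called$contrast == ctr])
    tp <- length(intersect(called_genes, true_genes))
    list(contrast = ctr,
         n_true = length(true_genes),
         n_called = length(called_genes),
         sensitivity = if (length(true_genes)) tp / length(true_genes) else NA,
         empirical_fdr = if (length(called_genes)) 1 - tp / length(called_genes) else 0)
  })
  module_recovery <- NULL
  if (length(truth$true_modules) > 0L && !is.null(coexpr)) {
    mk <- max_kcore(coexpr)
    module_recovery <- lapply(names(truth$true_modules), function(m) {
      genes <- truth$true_modules[[m]]
      list(module = m, size = length(genes),
           fraction_in_max_kcore = mean(genes %in% mk$genes))
    })
  }
  hub_ranks <- if (length(truth$true_hubs) > 0L && !is.null(core) && nrow(core) > 0L) {
    r <- match(truth$true_hubs, core$gene)
    stats::setNames(as.list(r), truth$true_hubs)
  } else NULL
  sig_terms <- unique(unlist(lapply(enr, function(e) e$term[e$fdr < config$enrich_fdr])))
  list(de = per_contrast,
       modules = module_recovery,
       hub_rank = hub_ranks,
       enriched_term_recovery =
         if (length(truth$true_enriched_terms))
           mean(truth$true_enriched_terms %in% sig_terms) else NA)
}
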