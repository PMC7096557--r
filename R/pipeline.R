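#' Pipeline run configuration
#'
#' Collects every threshold of the workflow with its default: enrichment
#' alpha 0.1, minimum module size 30, minimum |kME| 0.2, eigengene merge cut
#' height 0.2, top-500 specificity panels, top-50 hub exports, Zsummary cutoff
#' 2, HVG FDR 0.1, and a minimum of 30 nuclei for a class to get its own
#' network.
#'
#' @param alpha Enrichment q-value threshold.
#' @param min_module_size Minimum module size.
#' @param min_kme Minimum |kME| to stay in a module.
#' @param merge_cut_height Eigengene dissimilarity below which modules merge.
#' @param top_n_specific Panel size for cell type-specific genes.
#' @param top_n_hub Hub genes exported per final module.
#' @param zsummary_cutoff Median Zsummary below which a module is specific.
#' @param n_perm Preservation permutations.
#' @param hvg_fdr FDR threshold of highly variable gene selection.
#' @param min_nuclei Minimum nuclei for a class to be analyzed.
#' @param pseudocount Specificity pseudocount (CPM units).
#' @param qc_n_mads QC lower-tail threshold in MADs.
#' @param label_column Annotation column defining the cell types analyzed
#'   (`"cell_class"` or `"cell_cluster"`).
#' @param exclude_label Optional label excluded from specificity and networks
#'   (e.g. an unclassified class).
#' @param exclude_genes Genes removed at QC (e.g. mitochondrial).
#' @param specificity_on `"all"` (default) or `"hvg"`: gene universe for the
#'   specificity statistic.
#' @param powers Candidate soft-threshold powers.
#' @param r2_target Scale-free fit target.
#' @param cut_height Dendrogram cut height for module detection (`NULL` uses
#'   the `deep_split` mapping).
#' @param deep_split Branch-splitting sensitivity 0-4.
#' @param seed Root seed for all stochastic stages.
#' @return A `run_config` list.
#' @export
run_config <- function(alpha = 0.1, min_module_size = 30L, min_kme = 0.2,
                       merge_cut_height = 0.2, top_n_specific = 500L,
                       top_n_hub = 50L, zsummary_cutoff = 2, n_perm = 100L,
                       hvg_fdr = 0.1, min_nuclei = 30L, pseudocount = 1,
                       qc_n_mads = 3, label_column = "cell_class",
                       exclude_label = NULL, exclude_genes = character(),
                       specificity_on = c("all", "hvg"),
                       powers = 1:10, r2_target = 0.8, cut_height = NULL,
                       deep_split = 2L, seed = 1L) {
  specificity_on <- match.arg(specificity_on)
  cfg <- list(
    alpha = alpha, min_module_size = min_module_size, min_kme = min_kme,
    merge_cut_height = merge_cut_height, top_n_specific = top_n_specific,
    top_n_hub = top_n_hub, zsummary_cutoff = zsummary_cutoff, n_perm = n_perm,
    hvg_fdr = hvg_fdr, min_nuclei = min_nuclei, pseudocount = pseudocount,
    qc_n_mads = qc_n_mads, label_column = label_column,
    exclude_label = exclude_label, exclude_genes = exclude_genes,
    specificity_on = specificity_on, powers = powers, r2_target = r2_target,
    cut_height = cut_height, deep_split = deep_split, seed = as.integer(seed)
  )
  for (nm in c("alpha", "min_module_size", "min_kme", "merge_cut_height",
               "top_n_specific", "top_n_hub", "zsummary_cutoff", "n_perm",
               "hvg_fdr", "min_nuclei", "pseudocount", "qc_n_mads")) {
    assert_scalar_number(cfg[[nm]], nm, positive = TRUE)
  }
  structure(cfg, class = "run_config")
}

#' Run the full cell type-specific module analysis
#'
#' Preprocesses the dataset (QC, library-size normalization, batch
#' adjustment when a multi-level batch column is present, HVG selection),
#' computes CPM-based cell type specificity and top-N panels, builds a
#' signed-TOM co-expression network with modules per analyzed cell type,
#' evaluates every module's preservation in every other analyzed type's
#' network, tests disease-gene and panel enrichment, and selects the final
#' cell type-specific disease-associated modules.
#'
#' @param dataset An [expression_dataset()].
#' @param disease_genes Character vector of disease candidate genes.
#' @param config A [run_config()].
#' @param gmt Optional GMT collection (path or named list) for functional
#'   annotation of the detected modules.
#' @return A `ctsnet_run` list: `config`, `qc_log`, `hvg`, `specificity`,
#'   `panels`, `analyzed_classes`, `network_summary`, `networks`,
#'   `module_sets`, `module_genes`, `preservation`, `preservation_summary`,
#'   `enrichment`, `verdicts`, `hub_networks`, `annotation` (or `NULL`).
#' @export
run_pipeline <- function(dataset, disease_genes, config = run_config(),
                         gmt = NULL) {
  stopifnot(inherits(dataset, "expression_dataset"))
  cfg <- config

  ds <- qc_filter(dataset, n_mads = cfg$qc_n_mads, exclude_genes = cfg$exclude_genes)
  qc_log <- attr(ds, "qc_log")
  ds <- size_factor_normalize(ds)
  if ("batch" %in% names(ds$annotations) &&
      dplyr::n_distinct(ds$annotations$batch) > 1L) {
    ds <- correct_batch(ds, "batch")
  }
  hvg <- select_hvgs(ds, fdr = cfg$hvg_fdr)
  hvg_genes <- hvg$gene[hvg$selected]
  if (length(hvg_genes) < cfg$min_module_size) {
    abort("Stage 'preprocess': too few highly variable genes to build networks.")
  }
  cpm_mat <- cpm(ds)

  labels_all <- ds$annotations[[cfg$label_column]]
  spec_genes <- if (cfg$specificity_on == "hvg") hvg_genes else rownames(cpm_mat)
  spec <- compute_specificity(cpm_mat[spec_genes, , drop = FALSE], labels_all,
                              pseudocount = cfg$pseudocount,
                              exclude_label = cfg$exclude_label)
  types <- colnames(spec$scores)
  panels <- lapply(setNames(types, types), function(ct) {
    top_specific_genes(spec, ct, n = min(cfg$top_n_specific, nrow(spec$scores)))
  })

  sizes <- class_sizes(ds, cfg$label_column) |>
    dplyr::filter(!.data$label %in% cfg$exclude_label)
  sizes <- sizes |>
    dplyr::mutate(
      analyzed = .data$n_nuclei >= cfg$min_nuclei,
      reason = ifelse(.data$analyzed, "analyzed",
                      sprintf("skipped: %d nuclei < min_nuclei (%d)",
                              .data$n_nuclei, as.integer(cfg$min_nuclei)))
    )
  analyzed <- sizes$label[sizes$analyzed]
  if (length(analyzed) < 2L) {
    abort("Stage 'network': fewer than 2 cell types meet the minimum nucleus count.")
  }

  networks <- list()
  module_sets <- list()
  for (ct in analyzed) {
    sub <- ds$lognorm[hvg_genes, labels_all == ct, drop = FALSE]
    nw <- build_network(sub, cell_type = ct, powers = cfg$powers,
                        r2_target = cfg$r2_target)
    ms <- detect_module_set(nw, sub, min_module_size = cfg$min_module_size,
                            deep_split = cfg$deep_split,
                            cut_height = cfg$cut_height,
                            merge_cut_height = cfg$merge_cut_height,
                            min_kme = cfg$min_kme)
    networks[[ct]] <- nw
    module_sets[[ct]] <- ms
  }
  network_summary <- purrr::imap_dfr(networks, function(nw, ct) {
    lab <- module_sets[[ct]]$labels
    tibble(cell_type = ct, n_genes = length(nw$genes), beta = nw$beta,
           n_modules = length(unique(lab[lab > 0])), n_unassigned = sum(lab == 0))
  })

  # global module id "<class>_M<k>"
  module_genes <- list()
  module_cell_types <- character()
  for (ct in analyzed) {
    lab <- module_sets[[ct]]$labels
    for (m in sort(unique(lab[lab > 0]))) {
      id <- sprintf("%s_M%d", ct, m)
      module_genes[[id]] <- names(lab)[lab == m]
      module_cell_types[id] <- ct
    }
  }

  pres_seed <- stage_seed(cfg$seed, "preservation")
  preservation <- purrr::imap_dfr(module_sets, function(ms, ct) {
    rep <- module_preservation(networks[[ct]], ms, networks,
                               n_perm = cfg$n_perm, seed = pres_seed)
    if (nrow(rep)) rep$module <- sprintf("%s_M%d", ct, rep$module)
    rep
  })
  preservation_summary <- if (nrow(preservation)) {
    median_zsummary(preservation, cfg$zsummary_cutoff)
  } else {
    tibble(module = character(), median_zsummary = double(),
           n_evaluable = integer(), n_not_evaluable = integer(),
           verdict = character())
  }

  universe <- hvg_genes
  gene_sets <- c(list(disease = intersect(disease_genes, universe)),
                 lapply(panels, function(p) intersect(p$gene, universe)))
  enrichment <- enrichment_matrix(module_genes, gene_sets, universe,
                                  alpha = cfg$alpha)
  verdicts <- select_modules(
    enrichment, module_cell_types, preservation_summary,
    disease_set = "disease",
    panel_sets = setNames(types, types),
    alpha = cfg$alpha, zsummary_cutoff = cfg$zsummary_cutoff
  )

  finals <- verdicts$module[verdicts$final_specific]
  hub_networks <- lapply(setNames(finals, finals), function(id) {
    ct <- module_cell_types[[id]]
    m <- as.integer(sub(".*_M", "", id))
    export_top_hub_network(module_sets[[ct]], networks[[ct]]$tom, m,
                           n = cfg$top_n_hub, disease_genes = disease_genes)
  })

  annotation <- if (!is.null(gmt)) {
    annotate_modules_gmt(module_genes, gmt, universe, alpha = cfg$alpha)
  }

  structure(
    list(
      config = cfg, qc_log = qc_log, hvg = hvg, specificity = spec,
      panels = panels, analyzed_classes = sizes,
      network_summary = network_summary, networks = networks,
      module_sets = module_sets, module_genes = module_genes,
      module_cell_types = module_cell_types,
      preservation = preservation, preservation_summary = preservation_summary,
      enrichment = enrichment, verdicts = verdicts,
      hub_networks = hub_networks, annotation = annotation
    ),
    class = "ctsnet_run"
  )
}

#' @export
print.ctsnet_run <- function(x, ...) {
  cat(sprintf(
    "<ctsnet_run> %d cell types analyzed, %d modules, %d candidates, %d final specific\n",
    sum(x$analyzed_classes$analyzed), length(x$module_genes),
    sum(x$verdicts$candidate), sum(x$verdicts$final_specific)
  ))
  if (any(x$verdicts$final_specific)) {
    cat("final:", paste(x$verdicts$module[x$verdicts$final_specific], collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname run_pipeline
#' @param x A `ctsnet_run`.
#' @param ... Unused.
#' @method tidy ctsnet_run
#' @export
tidy.ctsnet_run <- function(x, ...) as_tibble(x$verdicts)

#' @rdname run_pipeline
#' @method glance ctsnet_run
#' @export
glance.ctsnet_run <- function(x, ...) {
  tibble(
    n_classes_analyzed = sum(x$analyzed_classes$analyzed),
    n_classes_skipped = sum(!x$analyzed_classes$analyzed),
    n_hvgs = sum(x$hvg$selected),
    n_modules = length(x$module_genes),
    n_candidates = sum(x$verdicts$candidate),
    n_final_specific = sum(x$verdicts$final_specific),
    seed = x$config$seed
  )
}

#' Write a run report to TSV files
#'
#' Deterministic plain-text exports: module assignments, specificity matrix,
#' per-type panels, network summary, preservation tables, enrichment table,
#' verdicts, eigengene matrices, and hub node/edge tables for the final
#' modules.
#'
#' @param run A `ctsnet_run`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_run_report <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  wt <- function(df, name) {
    p <- file.path(dir, name)
    df <- dplyr::mutate(df, dplyr::across(dplyr::where(is.list),
                                          ~ vapply(.x, paste, "", collapse = ";")))
    readr::write_tsv(df, p, progress = FALSE)
    paths[[name]] <<- p
  }
  assign_tbl <- purrr::imap_dfr(run$module_sets, function(ms, ct) {
    tidy(ms) |> dplyr::mutate(cell_type = ct, .before = 1)
  })
  wt(assign_tbl, "module_assignments.tsv")
  wt(as_tibble(run$specificity$scores, rownames = "gene"), "specificity.tsv")
  for (ct in names(run$panels)) {
    p <- file.path(dir, sprintf("panel_%s.txt", ct))
    writeLines(run$panels[[ct]]$gene, p)
    paths[[basename(p)]] <- p
  }
  wt(run$analyzed_classes, "classes.tsv")
  wt(run$network_summary, "network_summary.tsv")
  wt(run$preservation, "preservation.tsv")
  wt(run$preservation_summary, "preservation_summary.tsv")
  wt(run$enrichment, "enrichment.tsv")
  wt(run$verdicts, "verdicts.tsv")
  for (ct in names(run$module_sets)) {
    eg <- run$module_sets[[ct]]$eigengenes
    if (!is.null(eg)) {
      wt(as_tibble(eg, rownames = "nucleus_id"), sprintf("eigengenes_%s.tsv", ct))
    }
  }
  for (id in names(run$hub_networks)) {
    hn <- run$hub_networks[[id]]
    wt(hn$nodes, sprintf("hub_nodes_%s.tsv", id))
    wt(hn$edges, sprintf("hub_edges_%s.tsv", id))
  }
  if (!is.null(run$annotation)) wt(run$annotation, "annotation.tsv")
  invisible(paths)
}

#' Selection heatmap of module enrichment and preservation
#'
#' A matrix-style view: one row per module, one column per gene-set family
#' (`-log10 q`), plus the median Zsummary, echoing the selection logic.
#'
#' @param run A `ctsnet_run`.
#' @return A ggplot object.
#' @export
plot_selection_heatmap <- function(run) {
  enr <- run$enrichment |>
    dplyr::filter(.data$evaluable) |>
    dplyr::mutate(value = -log10(pmax(.data$q, 1e-300)))
  ggplot2::ggplot(enr, ggplot2::aes(.data$set, .data$module, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "-log10 q") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
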