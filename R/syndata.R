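#' Planted co-expression module description
#'
#' A planted module is a set of genes that share a latent activity factor in
#' the nuclei of the cell classes listed in `active_in`, producing within-module
#' correlation there and none elsewhere.
#'
#' @param module_id Character scalar identifying the module.
#' @param genes Character vector of at least two gene identifiers.
#' @param active_in Character vector of cell class labels, or `"all"`.
#' @param latent_strength Number in (0, 1): the log-scale loading of the shared
#'   latent factor, which controls the within-module Pearson correlation.
#' @return A `planted_module` list.
#' @export
planted_module <- function(module_id, genes, active_in, latent_strength) {
  if (length(genes) < 2L) abort("A planted module needs at least 2 genes.")
  if (length(active_in) < 1L) abort("`active_in` must be non-empty.")
  assert_scalar_number(latent_strength, "latent_strength", positive = TRUE)
  if (latent_strength >= 1) abort("`latent_strength` must be in (0, 1).")
  structure(
    list(
      module_id = as.character(module_id), genes = as.character(genes),
      active_in = as.character(active_in), latent_strength = latent_strength
    ),
    class = "planted_module"
  )
}

#' Synthetic single-nucleus dataset configuration
#'
#' Describes a synthetic gene x nucleus counts experiment with planted
#' structure: overdispersed baseline counts, per-class marker up-regulation,
#' shared latent factors for planted co-expression modules, and additive
#' log-scale batch shifts.
#'
#' @param n_genes Number of genes.
#' @param cell_classes Data frame with columns `label` and `n_nuclei` (each
#'   class must have at least one nucleus).
#' @param n_batches Number of sequencing batches (nuclei assigned at random).
#' @param batch_effect_sd Standard deviation of the gene x batch additive shift
#'   on the natural-log mean scale; 0 disables batch structure.
#' @param planted_modules List of [planted_module()] objects with pairwise
#'   disjoint gene sets.
#' @param disease_genes Character vector: the planted disease candidate list.
#' @param marker_genes Named list, one entry per cell class, each a list with
#'   elements `genes` (character) and `fold_up` (single number > 1): these
#'   genes are multiplicatively up-regulated in that class.
#' @param baseline_mean Median of the log-normal distribution the per-gene
#'   baseline mean counts are drawn from.
#' @param baseline_sdlog Log-sd of that baseline distribution.
#' @param dispersion Negative-binomial dispersion (variance = mu + dispersion
#'   * mu^2), shared by all genes.
#' @param gene_ids Optional explicit gene identifiers (default `g0001`...).
#' @param seed Integer seed; identical configurations produce bit-identical
#'   datasets.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_genes,
                         cell_classes,
                         n_batches = 2L,
                         batch_effect_sd = 0.3,
                         planted_modules = list(),
                         disease_genes = character(),
                         marker_genes = list(),
                         baseline_mean = 5,
                         baseline_sdlog = 0.8,
                         dispersion = 0.3,
                         gene_ids = NULL,
                         seed = 1L) {
  assert_scalar_number(n_genes, "n_genes", positive = TRUE)
  assert_scalar_number(n_batches, "n_batches", positive = TRUE)
  assert_scalar_number(batch_effect_sd, "batch_effect_sd", non_negative = TRUE)
  assert_scalar_number(baseline_mean, "baseline_mean", positive = TRUE)
  assert_scalar_number(dispersion, "dispersion", positive = TRUE)
  cell_classes <- as_tibble(cell_classes)
  if (!all(c("label", "n_nuclei") %in% names(cell_classes))) {
    abort("`cell_classes` needs columns `label` and `n_nuclei`.")
  }
  if (any(cell_classes$n_nuclei < 1)) abort("Each cell class needs >= 1 nucleus.")
  if (anyDuplicated(cell_classes$label)) abort("Duplicate cell class labels.")
  if (is.null(gene_ids)) {
    gene_ids <- sprintf(paste0("g%0", max(4L, nchar(n_genes)), "d"), seq_len(n_genes))
  }
  if (length(gene_ids) != n_genes || anyDuplicated(gene_ids)) {
    abort("`gene_ids` must be `n_genes` unique identifiers.")
  }

  module_genes <- unlist(lapply(planted_modules, `[[`, "genes"))
  if (anyDuplicated(module_genes)) {
    abort("Planted module gene sets must be pairwise disjoint.")
  }
  known <- c("all", cell_classes$label)
  for (pm in planted_modules) {
    if (!inherits(pm, "planted_module")) abort("`planted_modules` must contain planted_module objects.")
    bad <- setdiff(pm$active_in, known)
    if (length(bad)) {
      abort(sprintf("Unknown cell class in `active_in` of %s: %s",
                    pm$module_id, paste(bad, collapse = ", ")))
    }
  }
  all_named <- c(module_genes, as.character(disease_genes),
                 unlist(lapply(marker_genes, `[[`, "genes")))
  missing <- setdiff(all_named, gene_ids)
  if (length(missing)) {
    abort(sprintf("Genes referenced but not in the gene universe: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  if (length(marker_genes)) {
    bad <- setdiff(names(marker_genes), cell_classes$label)
    if (length(bad)) abort(sprintf("Marker classes not in `cell_classes`: %s", paste(bad, collapse = ", ")))
    for (mk in marker_genes) {
      if (!is.numeric(mk$fold_up) || mk$fold_up <= 1) abort("Marker `fold_up` must be > 1.")
    }
  }

  structure(
    list(
      n_genes = as.integer(n_genes), cell_classes = cell_classes,
      n_batches = as.integer(n_batches), batch_effect_sd = batch_effect_sd,
      planted_modules = planted_modules, disease_genes = as.character(disease_genes),
      marker_genes = marker_genes, baseline_mean = baseline_mean,
      baseline_sdlog = baseline_sdlog, dispersion = dispersion,
      gene_ids = gene_ids, seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

#' Default synthetic study configuration
#'
#' The reference scenario the package's planted-truth evaluations run on:
#' 3,000 genes across five cell classes with strongly unbalanced nucleus counts
#' (one dominant class, mimicking cortical snRNA-seq class skew), 50 markers
#' per class at 8-fold up-regulation, two batches, and three planted 60-gene
#' modules: one active only in the astrocyte-like class and overlapping the
#' disease list, one active in all classes and overlapping the disease list,
#' and one active only in the interneuron-like class with no disease overlap.
#' The disease list additionally contains 100 background genes.
#'
#' @param seed Integer seed passed to [synth_config()].
#' @param n_per_class Optional integer vector of length 5 overriding the
#'   default nucleus counts `c(800, 400, 200, 120, 80)`.
#' @return A `synth_config`.
#' @export
default_synth_config <- function(seed = 1L, n_per_class = c(800L, 400L, 200L, 120L, 80L)) {
  stopifnot(length(n_per_class) == 5L)
  classes <- tibble(
    label = c("Ex", "Inh", "Ast", "Oligo", "OPC"),
    n_nuclei = as.integer(n_per_class)
  )
  ids <- sprintf("g%04d", 1:3000)
  marker_slices <- split(ids[1:250], rep(classes$label, each = 50))
  markers <- lapply(marker_slices, function(g) list(genes = g, fold_up = 8))
  mod_ast <- planted_module("mod_ast", ids[251:310], "Ast", 0.8)
  mod_shared <- planted_module("mod_shared", ids[311:370], "all", 0.8)
  mod_inh <- planted_module("mod_inh", ids[371:430], "Inh", 0.8)
  disease <- c(ids[251:286], ids[311:346], ids[431:530])
  synth_config(
    n_genes = 3000L, cell_classes = classes, n_batches = 2L,
    batch_effect_sd = 0.3,
    planted_modules = list(mod_ast, mod_shared, mod_inh),
    disease_genes = disease, marker_genes = markers,
    seed = seed
  )
}

#' Small example study configuration
#'
#' A fast three-class scenario (220/120/70 nuclei, 600 genes) with 20 markers
#' per class at 8-fold up-regulation, one 40-gene module restricted to class
#' `A`, one 40-gene module shared by all classes, and a disease list
#' overlapping both modules plus background genes. Used by the documentation
#' examples and the command-line wrapper's `tiny` preset.
#'
#' @param seed Integer seed.
#' @param n_batches,batch_effect_sd Batch structure, as in [synth_config()].
#' @return A `synth_config`.
#' @export
example_synth_config <- function(seed = 1L, n_batches = 2L, batch_effect_sd = 0.3) {
  ids <- sprintf("g%04d", 1:600)
  classes <- tibble(label = c("A", "B", "C"), n_nuclei = c(220L, 120L, 70L))
  markers <- list(
    A = list(genes = ids[1:20], fold_up = 8),
    B = list(genes = ids[21:40], fold_up = 8),
    C = list(genes = ids[41:60], fold_up = 8)
  )
  synth_config(
    n_genes = 600L, cell_classes = classes, n_batches = n_batches,
    batch_effect_sd = batch_effect_sd,
    planted_modules = list(
      planted_module("mod_a", ids[61:100], "A", 0.8),
      planted_module("mod_all", ids[101:140], "all", 0.8)
    ),
    disease_genes = c(ids[61:85], ids[101:125], ids[541:580]),
    marker_genes = markers, seed = seed
  )
}

#' Generate a synthetic dataset with ground truth
#'
#' Counts are negative binomial around a per-gene log-normal baseline mean,
#' with (on the natural-log mean scale) additive marker effects `log(fold_up)`
#' in the marker's class, a shared standard-normal latent factor per planted
#' module scaled by `latent_strength` in nuclei of its active classes, and
#' gene x batch shifts with sd `batch_effect_sd`. The same configuration
#' (including seed) always yields bit-identical output.
#'
#' @param config A [synth_config()].
#' @return List with elements `dataset` (an [expression_dataset()]) and
#'   `truth` (a `ground_truth` list: module memberships, marker sets, disease
#'   genes, per-nucleus batch assignment).
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "synth_config")) abort("`config` must be a synth_config.")
  cls <- config$cell_classes
  n_nuclei <- sum(cls$n_nuclei)
  genes <- config$gene_ids
  withr::with_seed(config$seed, {
    baseline <- rlnorm(config$n_genes, meanlog = log(config$baseline_mean),
                       sdlog = config$baseline_sdlog)
    nucleus_class <- rep(cls$label, times = cls$n_nuclei)
    nucleus_id <- sprintf(paste0("n%0", max(5L, nchar(n_nuclei)), "d"), seq_len(n_nuclei))
    batch <- paste0("b", sample.int(config$n_batches, n_nuclei, replace = TRUE))
    # big classes get two cell clusters, small ones a single cluster
    cluster <- nucleus_class
    for (lab in cls$label[cls$n_nuclei >= 300L]) {
      idx <- which(nucleus_class == lab)
      cluster[idx] <- paste0(lab, "_c", sample.int(2L, length(idx), replace = TRUE))
    }
    cluster[!grepl("_c[12]$", cluster)] <- paste0(cluster[!grepl("_c[12]$", cluster)], "_c1")

    logmu <- matrix(log(baseline), nrow = config$n_genes, ncol = n_nuclei)
    dimnames(logmu) <- list(genes, nucleus_id)
    if (config$n_batches > 1L && config$batch_effect_sd > 0) {
      shifts <- matrix(rnorm(config$n_genes * config$n_batches, sd = config$batch_effect_sd),
                       nrow = config$n_genes)
      logmu <- logmu + shifts[, match(batch, paste0("b", seq_len(config$n_batches)))]
    }
    for (lab in names(config$marker_genes)) {
      mk <- config$marker_genes[[lab]]
      logmu[mk$genes, nucleus_class == lab] <-
        logmu[mk$genes, nucleus_class == lab] + log(mk$fold_up)
    }
    for (pm in config$planted_modules) {
      active <- if (identical(pm$active_in, "all")) rep(TRUE, n_nuclei) else nucleus_class %in% pm$active_in
      f <- rnorm(sum(active))
      logmu[pm$genes, active] <- logmu[pm$genes, active] +
        pm$latent_strength * matrix(f, nrow = length(pm$genes), ncol = sum(active), byrow = TRUE)
    }
    counts <- matrix(
      rnbinom(length(logmu), size = 1 / config$dispersion, mu = exp(logmu)),
      nrow = config$n_genes, dimnames = dimnames(logmu)
    )
    ann <- tibble(
      nucleus_id = nucleus_id, cell_class = nucleus_class,
      cell_cluster = cluster, batch = batch
    )
    dataset <- expression_dataset(counts, ann)
    membership <- unlist(lapply(
      config$planted_modules,
      function(pm) setNames(rep(pm$module_id, length(pm$genes)), pm$genes)
    )) %||% setNames(character(), character())
    truth <- structure(
      list(
        module_membership = membership,
        modules = lapply(config$planted_modules, unclass),
        marker_genes = config$marker_genes,
        disease_genes = config$disease_genes,
        batch = setNames(batch, nucleus_id),
        cell_class = setNames(nucleus_class, nucleus_id),
        seed = config$seed
      ),
      class = "ground_truth"
    )
    list(dataset = dataset, truth = truth)
  })
}

#' Write a dataset and its ground truth to disk
#'
#' Counts go to Matrix Market (`counts.mtx` with `genes.tsv` / `barcodes.tsv`),
#' annotations to `annotations.tsv`, ground truth to `ground_truth.json`.
#' Reading the directory back reproduces the matrices exactly.
#'
#' @param dataset An [expression_dataset()].
#' @param truth Optional `ground_truth` object.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written (invisibly).
#' @export
write_dataset <- function(dataset, truth = NULL, dir) {
  if (!is.character(dir) || length(dir) != 1L || !nzchar(dir)) {
    abort(sprintf("Invalid output directory path: '%s'", paste(dir, collapse = "")))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) abort(sprintf("Could not create directory '%s'.", dir))
  paths <- c(
    counts = file.path(dir, "counts.mtx"),
    genes = file.path(dir, "genes.tsv"),
    barcodes = file.path(dir, "barcodes.tsv"),
    annotations = file.path(dir, "annotations.tsv")
  )
  Matrix::writeMM(Matrix::Matrix(dataset$counts, sparse = TRUE), paths[["counts"]])
  writeLines(rownames(dataset$counts), paths[["genes"]])
  writeLines(colnames(dataset$counts), paths[["barcodes"]])
  readr::write_tsv(dataset$annotations, paths[["annotations"]], progress = FALSE)
  if (!is.null(truth)) {
    paths <- c(paths, ground_truth = file.path(dir, "ground_truth.json"))
    tr <- unclass(truth)
    # named atomic vectors must go out as JSON objects, not bare arrays
    for (nm in c("module_membership", "batch", "cell_class")) {
      tr[[nm]] <- as.list(tr[[nm]])
    }
    jsonlite::write_json(tr, paths[["ground_truth"]],
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(paths)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Directory containing `counts.mtx`, `genes.tsv`, `barcodes.tsv`
#'   and `annotations.tsv`.
#' @return An [expression_dataset()].
#' @export
read_dataset <- function(dir) {
  needed <- file.path(dir, c("counts.mtx", "genes.tsv", "barcodes.tsv", "annotations.tsv"))
  missing <- needed[!file.exists(needed)]
  if (length(missing)) {
    abort(sprintf("Missing dataset files: %s", paste(missing, collapse = ", ")))
  }
  counts <- as.matrix(Matrix::readMM(needed[1]))
  rownames(counts) <- readLines(needed[2])
  colnames(counts) <- readLines(needed[3])
  ann <- readr::read_tsv(needed[4], show_col_types = FALSE, progress = FALSE)
  expression_dataset(counts, ann)
}

#' Read a ground-truth JSON file
#'
#' @param path Path to `ground_truth.json`.
#' @return A `ground_truth` list.
#' @export
read_ground_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$module_membership <- unlist(raw$module_membership)
  raw$batch <- unlist(raw$batch)
  raw$cell_class <- unlist(raw$cell_class)
  structure(raw, class = "ground_truth")
}
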