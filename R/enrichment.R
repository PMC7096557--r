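#' Hypergeometric over-representation test
#'
#' Upper-tail probability of drawing at least the observed overlap when
#' `n = |module|` genes are sampled without replacement from a universe of
#' `N` genes containing `K = |set in universe|` set members. Evaluated
#' through [stats::phyper()], which works in log space internally.
#'
#' @param module_genes Character vector; must be a subset of `universe`.
#' @param gene_set Character vector; intersected with the universe (a message
#'   reports dropped genes).
#' @param universe Character vector of all testable genes.
#' @return List: `x` (overlap), `p`, `n`, `K`, `N`, `overlap_genes`.
#' @export
hypergeom_test <- function(module_genes, gene_set, universe) {
  universe <- unique(universe)
  module_genes <- unique(module_genes)
  outside <- setdiff(module_genes, universe)
  if (length(outside)) {
    abort(sprintf("Module genes absent from the universe: %s%s",
                  paste(head(outside, 5), collapse = ", "),
                  if (length(outside) > 5) ", ..." else ""))
  }
  set_in <- intersect(unique(gene_set), universe)
  if (length(set_in) < length(unique(gene_set))) {
    inform(sprintf("Gene set: %d of %d genes are in the universe.",
                   length(set_in), length(unique(gene_set))))
  }
  n <- length(module_genes)
  K <- length(set_in)
  N <- length(universe)
  overlap <- intersect(module_genes, set_in)
  x <- length(overlap)
  p <- phyper(x - 1, K, N - K, n, lower.tail = FALSE)
  list(x = x, p = p, n = n, K = K, N = N, overlap_genes = sort(overlap))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment `q_(i) = min_(j>=i) m p_(j) / j`, capped at one and
#' returned in the input order (delegates to [stats::p.adjust()]).
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values.
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values) | p_values < 0 | p_values > 1)) {
    abort("All p-values must lie in [0, 1].")
  }
  p.adjust(p_values, method = "BH")
}

#' Enrichment of gene sets across modules
#'
#' Tests every module against every gene set with [hypergeom_test()] and
#' applies Benjamini-Hochberg correction per gene set (one BH family per set,
#' spanning all modules of all cell-type networks in the run).
#'
#' @param module_list Named list: module id -> character vector of genes.
#' @param gene_sets Named list: set name -> character vector of genes.
#' @param universe Character vector; the run's gene universe.
#' @param alpha Significance threshold on q for the `enriched` flag.
#' @return An `enrichment_result` tibble: `module`, `set`, `n`, `N`, `K`,
#'   `x`, `p`, `q`, `enriched`, `evaluable`, `overlap_genes` (list column).
#' @export
enrichment_matrix <- function(module_list, gene_sets, universe, alpha = 0.1) {
  if (is.null(names(module_list)) || is.null(names(gene_sets))) {
    abort("`module_list` and `gene_sets` must be named.")
  }
  rows <- purrr::imap_dfr(gene_sets, function(set_genes, set_name) {
    set_in <- intersect(unique(set_genes), unique(universe))
    fam <- purrr::imap_dfr(module_list, function(mod_genes, mod_name) {
      if (!length(set_in)) {
        return(tibble(module = mod_name, set = set_name,
                      n = length(unique(mod_genes)), N = length(unique(universe)),
                      K = 0L, x = 0L, p = NA_real_, evaluable = FALSE,
                      overlap_genes = list(character())))
      }
      ht <- hypergeom_test(mod_genes, set_in, universe)
      tibble(module = mod_name, set = set_name, n = ht$n, N = ht$N,
             K = ht$K, x = ht$x, p = ht$p, evaluable = TRUE,
             overlap_genes = list(ht$overlap_genes))
    })
    fam$q <- NA_real_
    if (any(fam$evaluable)) fam$q[fam$evaluable] <- bh_adjust(fam$p[fam$evaluable])
    fam
  })
  rows <- rows |>
    dplyr::mutate(enriched = !is.na(.data$q) & .data$q < alpha) |>
    dplyr::select("module", "set", "n", "N", "K", "x", "p", "q",
                  "enriched", "evaluable", "overlap_genes")
  class(rows) <- c("enrichment_result", class(rows))
  attr(rows, "alpha") <- alpha
  rows
}

#' Candidate and final module selection
#'
#' A module is a candidate cell type-specific disease module when it is
#' enriched with the disease gene set, enriched with its own cell type's
#' specific-gene panel, and enriched with no other cell type's panel. A
#' candidate is finally selected when its median Zsummary across the other
#' cell types' networks is below the cutoff (no evidence of preservation
#' elsewhere).
#'
#' @param enrichments An `enrichment_result` covering the disease set and one
#'   panel per cell type.
#' @param module_cell_types Named character vector: module id -> the cell type
#'   whose network the module came from.
#' @param preservation_summary Tibble from [median_zsummary()] with a `module`
#'   column holding the same module ids.
#' @param disease_set Name of the disease gene set in `enrichments`.
#' @param panel_sets Named character vector mapping cell type -> panel set
#'   name (defaults to the cell types themselves).
#' @param alpha Enrichment threshold (only used for reporting; flags come from
#'   `enrichments`).
#' @param zsummary_cutoff Median Zsummary cutoff.
#' @return A `selection_verdict` tibble, one row per module: enrichment flags,
#'   `candidate`, `median_zsummary`, `final_specific`, `status`.
#' @export
select_modules <- function(enrichments, module_cell_types, preservation_summary,
                           disease_set = "disease",
                           panel_sets = NULL, alpha = 0.1, zsummary_cutoff = 2) {
  if (is.null(panel_sets)) {
    cts <- unique(unname(module_cell_types))
    panel_sets <- setNames(cts, cts)
  }
  if (!length(module_cell_types)) {
    out <- tibble(module = character(), cell_type = character(),
                  asd_enriched = logical(), own_type_marker_enriched = logical(),
                  other_type_marker_enriched = logical(), candidate = logical(),
                  median_zsummary = double(), final_specific = logical(),
                  status = character())
    class(out) <- c("selection_verdict", class(out))
    return(out)
  }
  flag <- function(mod, set_name) {
    row <- enrichments[enrichments$module == mod & enrichments$set == set_name, ]
    if (!nrow(row) || !row$evaluable[1]) NA else row$enriched[1]
  }
  out <- purrr::imap_dfr(module_cell_types, function(ct, mod) {
    asd <- flag(mod, disease_set)
    own <- flag(mod, panel_sets[[ct]])
    others <- vapply(panel_sets[setdiff(names(panel_sets), ct)],
                     function(s) flag(mod, s), logical(1))
    other_any <- if (all(is.na(others))) NA else any(others, na.rm = TRUE)
    candidate <- isTRUE(asd) && isTRUE(own) && !isTRUE(other_any)
    pres <- preservation_summary[preservation_summary$module == mod, ]
    med_z <- if (nrow(pres)) pres$median_zsummary[1] else NA_real_
    status <- if (candidate && nrow(pres) && pres$verdict[1] != "undetermined") {
      "determined"
    } else if (candidate) "undetermined" else "determined"
    tibble(
      module = mod, cell_type = ct,
      asd_enriched = asd, own_type_marker_enriched = own,
      other_type_marker_enriched = other_any,
      candidate = candidate, median_zsummary = med_z,
      final_specific = candidate & !is.na(med_z) & med_z < zsummary_cutoff,
      status = status
    )
  })
  class(out) <- c("selection_verdict", class(out))
  attr(out, "alpha") <- alpha
  attr(out, "zsummary_cutoff") <- zsummary_cutoff
  out
}

#' Read a GMT gene-set collection
#'
#' Tab-separated lines: set name, description, then one gene per field.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors, with a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  descs <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      abort(sprintf("Malformed GMT line %d: expected name, description and >= 1 gene.", i))
    }
    sets[[fields[1]]] <- unique(fields[-(1:2)])
    descs[fields[1]] <- fields[2]
  }
  attr(sets, "descriptions") <- descs
  sets
}

#' Read a plain-text gene list (one symbol per line)
#'
#' @param path File path.
#' @return Character vector of unique, non-empty symbols.
#' @export
read_gene_list <- function(path) {
  unique(trimws(readLines(path))) |> (\(x) x[nzchar(x)])()
}

#' Functional annotation of modules against a GMT collection
#'
#' Over-representation of every module in every term, Benjamini-Hochberg
#' corrected per collection (one family across all modules and terms). A term
#' row is flagged `reported` when `q < alpha` and the gene count is at least
#' `min_genes` — by default counted as the module/term overlap, switchable to
#' the term's size in the universe.
#'
#' @param module_list Named list: module id -> gene vector.
#' @param gmt Named list of term gene sets (see [read_gmt()]) or a GMT path.
#' @param universe Gene universe.
#' @param alpha q-value threshold for reporting.
#' @param min_genes Minimum gene count for reporting.
#' @param min_genes_on `"overlap"` (default) or `"term"`: what `min_genes`
#'   applies to.
#' @return An `enrichment_result` tibble with an extra `reported` flag.
#' @export
annotate_modules_gmt <- function(module_list, gmt, universe, alpha = 0.1,
                                 min_genes = 5L, min_genes_on = c("overlap", "term")) {
  min_genes_on <- match.arg(min_genes_on)
  if (is.character(gmt) && length(gmt) == 1L) gmt <- read_gmt(gmt)
  if (!length(gmt)) {
    warn("Empty GMT collection; returning an empty result.")
    out <- tibble(module = character(), set = character(), n = integer(),
                  N = integer(), K = integer(), x = integer(), p = double(),
                  q = double(), enriched = logical(), evaluable = logical(),
                  overlap_genes = list(), reported = logical())
    class(out) <- c("enrichment_result", class(out))
    return(out)
  }
  res <- enrichment_matrix(module_list, gmt, universe, alpha = alpha)
  # single BH family across the whole collection
  res$q <- NA_real_
  res$q[res$evaluable] <- bh_adjust(res$p[res$evaluable])
  res$enriched <- !is.na(res$q) & res$q < alpha
  gene_count <- if (min_genes_on == "overlap") res$x else res$K
  res$reported <- res$enriched & gene_count >= min_genes
  res
}

#' Enrichment dot plot
#'
#' @param object An `enrichment_result`.
#' @param ... Unused.
#' @return A ggplot of -log10 q per (module, set), sized by overlap.
#' @method autoplot enrichment_result
#' @export
autoplot.enrichment_result <- function(object, ...) {
  object |>
    dplyr::filter(.data$evaluable) |>
    ggplot2::ggplot(ggplot2::aes(.data$set, .data$module,
                                 size = .data$x, colour = -log10(pmax(.data$q, 1e-300)))) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, size = "overlap", colour = "-log10 q") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
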