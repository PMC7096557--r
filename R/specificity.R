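#' Cell type specificity of genes (minimum fold change)
#'
#' For each gene and cell type, specificity is the minimum fold change of the
#' gene's mean CPM between the type of interest and each other type:
#' `min over r != c of (mean_c + eps) / (mean_r + eps)`. A pseudocount `eps`
#' keeps the ratio finite when a gene is silent in a reference type.
#'
#' @param cpm_matrix Gene x nucleus CPM matrix (see [cpm()]).
#' @param class_labels Character/factor vector, one label per column.
#' @param pseudocount Pseudocount `eps` (CPM units) added to both means.
#' @param exclude_label Optional label (e.g. an "unclassified" class) removed
#'   from both the interest set and the reference set.
#' @return A `specificity_matrix`: list with `scores` (gene x type matrix),
#'   `class_means`, `n_per_class`, `pseudocount`.
#' @export
compute_specificity <- function(cpm_matrix, class_labels, pseudocount = 1.0,
                                exclude_label = NULL) {
  cpm_matrix <- as.matrix(cpm_matrix)
  if (length(class_labels) != ncol(cpm_matrix)) {
    abort("`class_labels` must have one entry per CPM column.")
  }
  assert_scalar_number(pseudocount, "pseudocount", non_negative = TRUE)
  keep <- !(class_labels %in% exclude_label)
  cpm_matrix <- cpm_matrix[, keep, drop = FALSE]
  class_labels <- as.character(class_labels[keep])
  types <- sort(unique(class_labels))
  if (length(types) < 2L) {
    abort("Specificity needs at least two cell types after exclusions.")
  }
  n_per_class <- table(class_labels)[types]
  means <- t(rowsum(t(cpm_matrix), group = class_labels)) # gene x type sums
  means <- sweep(means[, types, drop = FALSE], 2, as.vector(n_per_class), "/")
  shifted <- means + pseudocount
  scores <- vapply(seq_along(types), function(ci) {
    ref_max <- do.call(pmax, as.data.frame(shifted[, -ci, drop = FALSE]))
    shifted[, ci] / ref_max
  }, numeric(nrow(means)))
  dimnames(scores) <- list(rownames(cpm_matrix), types)
  structure(
    list(scores = scores, class_means = means,
         n_per_class = setNames(as.vector(n_per_class), types),
         pseudocount = pseudocount),
    class = "specificity_matrix"
  )
}

#' @export
print.specificity_matrix <- function(x, ...) {
  cat(sprintf("<specificity_matrix> %d genes x %d cell types (pseudocount %g)\n",
              nrow(x$scores), ncol(x$scores), x$pseudocount))
  invisible(x)
}

#' @rdname compute_specificity
#' @param x A `specificity_matrix`.
#' @param ... Unused.
#' @method tidy specificity_matrix
#' @export
tidy.specificity_matrix <- function(x, ...) {
  as_tibble(x$scores, rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "cell_type", values_to = "specificity")
}

#' Top-N cell type-specific gene panel
#'
#' The `n` genes with the highest specificity for one cell type, ties broken
#' by lexicographic gene identifier so panels are deterministic.
#'
#' @param spec A `specificity_matrix` from [compute_specificity()].
#' @param cell_type Cell type label.
#' @param n Panel size (default 500).
#' @return A `marker_panel` tibble: `gene`, `specificity`, `rank`; attributes
#'   `cell_type` and `n`.
#' @export
top_specific_genes <- function(spec, cell_type, n = 500L) {
  if (!inherits(spec, "specificity_matrix")) abort("`spec` must be a specificity_matrix.")
  if (!is.numeric(n) || length(n) != 1L || n <= 0) abort("`n` must be a positive integer.")
  if (!cell_type %in% colnames(spec$scores)) {
    abort(sprintf("Unknown cell type '%s'.", cell_type))
  }
  s <- spec$scores[, cell_type]
  ord <- order(-s, names(s))
  if (n > length(s)) {
    inform(sprintf("Only %d genes available for a panel of %d; returning all.",
                   length(s), as.integer(n)))
    n <- length(s)
  }
  sel <- ord[seq_len(n)]
  out <- tibble(gene = names(s)[sel], specificity = unname(s[sel]),
                rank = seq_len(n))
  class(out) <- c("marker_panel", class(out))
  attr(out, "cell_type") <- cell_type
  attr(out, "n") <- as.integer(n)
  out
}

#' Specificity heatmap of the top genes per cell type
#'
#' @param object A `specificity_matrix`.
#' @param top_n Genes shown per cell type (by specificity rank).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot specificity_matrix
#' @export
autoplot.specificity_matrix <- function(object, top_n = 10L, ...) {
  top <- lapply(colnames(object$scores), function(ct) {
    top_specific_genes(object, ct, n = top_n)$gene
  })
  genes <- unique(unlist(top))
  tidy(object) |>
    dplyr::filter(.data$gene %in% genes) |>
    ggplot2::ggplot(ggplot2::aes(.data$cell_type, .data$gene,
                                 fill = log2(.data$specificity))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white", high = "firebrick") +
    ggplot2::labs(x = "cell type", y = NULL, fill = "log2 specificity")
}
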