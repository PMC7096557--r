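#' Expression dataset container
#'
#' Bundles a gene x nucleus count matrix with per-nucleus annotations and,
#' once normalization has run, a log-normalized expression matrix. This is the
#' object every pipeline stage consumes and returns.
#'
#' @param counts Non-negative numeric matrix, genes in rows and nuclei in
#'   columns, with unique rownames (gene identifiers) and colnames (nucleus
#'   identifiers).
#' @param annotations Data frame with one row per nucleus, containing at least
#'   `nucleus_id` and `cell_class`; `cell_cluster` and `batch` are optional.
#'   Rows must match the columns of `counts` one-to-one (same order).
#' @param lognorm Optional log-normalized matrix of the same shape as `counts`.
#'
#' @return An object of class `expression_dataset`: a list with elements
#'   `counts`, `lognorm` (possibly `NULL`), and `annotations` (a tibble).
#' @export
expression_dataset <- function(counts, annotations, lognorm = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("`counts` must have gene rownames and nucleus colnames.")
  }
  if (anyDuplicated(rownames(counts))) abort("Duplicate gene identifiers in `counts`.")
  if (anyDuplicated(colnames(counts))) abort("Duplicate nucleus identifiers in `counts`.")
  if (any(counts < 0)) abort("`counts` must be non-negative.")
  annotations <- as_tibble(annotations)
  if (!all(c("nucleus_id", "cell_class") %in% names(annotations))) {
    abort("`annotations` must contain columns `nucleus_id` and `cell_class`.")
  }
  if (nrow(annotations) != ncol(counts) ||
      !identical(as.character(annotations$nucleus_id), colnames(counts))) {
    abort("`annotations` rows must match `counts` columns one-to-one (same order).")
  }
  if (!is.null(lognorm)) {
    if (!identical(dim(lognorm), dim(counts))) {
      abort("`lognorm` must have the same shape as `counts`.")
    }
  }
  structure(
    list(counts = counts, lognorm = lognorm, annotations = annotations),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf(
    "<expression_dataset> %d genes x %d nuclei; %d cell classes%s%s\n",
    nrow(x$counts), ncol(x$counts),
    dplyr::n_distinct(x$annotations$cell_class),
    if ("batch" %in% names(x$annotations)) {
      sprintf("; %d batches", dplyr::n_distinct(x$annotations$batch))
    } else "",
    if (is.null(x$lognorm)) "; lognorm: empty" else "; lognorm: filled"
  ))
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$counts)

gene_ids <- function(dataset) rownames(dataset$counts)

#' Per-class nucleus counts
#'
#' @param dataset An [expression_dataset()].
#' @param label_column Annotation column to tabulate (default `cell_class`).
#' @return Tibble with columns `label` and `n_nuclei`.
#' @export
class_sizes <- function(dataset, label_column = "cell_class") {
  dataset$annotations |>
    dplyr::count(label = .data[[label_column]], name = "n_nuclei") |>
    dplyr::arrange(dplyr::desc(.data$n_nuclei))
}
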