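#' Quality-control filter for nuclei and genes
#'
#' Removes nuclei whose log library size or log detected-gene count lies more
#' than `n_mads` median absolute deviations below the median (lower tail only,
#' the standard scran-style rule), then removes user-excluded genes (e.g.
#' mitochondrial) and genes detected in no remaining nucleus.
#'
#' @param dataset An [expression_dataset()].
#' @param n_mads Lower-tail threshold in median absolute deviations.
#' @param exclude_genes Character vector of gene identifiers to drop.
#' @return The filtered [expression_dataset()], with a `qc_log` attribute
#'   recording how many nuclei/genes each rule removed.
#' @export
qc_filter <- function(dataset, n_mads = 3, exclude_genes = character()) {
  counts <- dataset$counts
  lib <- colSums(counts)
  det <- colSums(counts > 0)
  llib <- suppressWarnings(log(lib))
  ldet <- suppressWarnings(log(det))
  lower_ok <- function(x) {
    fin <- is.finite(x)
    m <- median(x[fin])
    s <- mad(x[fin])
    fin & (x >= m - n_mads * max(s, .Machine$double.eps))
  }
  keep_lib <- lower_ok(llib)
  keep_det <- lower_ok(ldet)
  keep_nuc <- keep_lib & keep_det
  if (!any(keep_nuc)) {
    abort("QC removed every nucleus; review `n_mads` or the input data.")
  }
  counts <- counts[, keep_nuc, drop = FALSE]
  excl <- rownames(counts) %in% exclude_genes
  zero <- rowSums(counts) == 0 & !excl
  counts <- counts[!excl & !zero, , drop = FALSE]
  out <- expression_dataset(counts, dataset$annotations[keep_nuc, , drop = FALSE])
  attr(out, "qc_log") <- structure(list(
    sprintf("nuclei removed by library-size rule: %d", sum(!keep_lib)),
    sprintf("nuclei removed by detected-genes rule: %d", sum(keep_lib & !keep_det)),
    sprintf("genes removed by exclusion list: %d", sum(excl)),
    sprintf("all-zero genes removed: %d", sum(zero))
  ), class = "ctsnet_log")
  out
}

#' Library-size normalization
#'
#' Size factor per nucleus = library size / geometric-mean library size,
#' rescaled to mean 1. The log-normalized matrix is
#' `log2(count / size_factor + 1)`, so every rescaled library equals the mean
#' library size and equal-size libraries give `log2(count + 1)` unchanged.
#'
#' @param dataset An [expression_dataset()] (after QC).
#' @return The dataset with `lognorm` filled and a `size_factors` attribute.
#' @export
size_factor_normalize <- function(dataset) {
  lib <- colSums(dataset$counts)
  if (any(lib == 0)) {
    abort(sprintf("Zero library size for nuclei: %s (run qc_filter first).",
                  paste(head(colnames(dataset$counts)[lib == 0], 3), collapse = ", ")))
  }
  sf <- lib / exp(mean(log(lib)))
  sf <- sf / mean(sf)
  lognorm <- log2(sweep(dataset$counts, 2, sf, "/") + 1)
  out <- expression_dataset(dataset$counts, dataset$annotations, lognorm = lognorm)
  attr(out, "size_factors") <- setNames(sf, colnames(dataset$counts))
  out
}

#' Counts per million
#'
#' Library-size-scaled expression via [edgeR::cpm()]; every column sums to
#' one million.
#'
#' @param dataset An [expression_dataset()] or a counts matrix.
#' @return Gene x nucleus CPM matrix.
#' @export
cpm <- function(dataset) {
  counts <- if (inherits(dataset, "expression_dataset")) dataset$counts else as.matrix(dataset)
  if (any(colSums(counts) == 0)) abort("CPM undefined for zero-library nuclei.")
  edgeR::cpm(counts)
}

#' Empirical-Bayes batch correction of log-normalized expression
#'
#' Parametric location/scale adjustment in the ComBat family: per gene the
#' data are standardized against the batch-design fit, per-gene-per-batch
#' location and scale estimates are shrunk toward their across-gene priors
#' (normal prior for location, inverse-gamma for scale) with the standard
#' iterative posterior updates, the batch effect is removed, and the original
#' scale is restored.
#'
#' @param dataset An [expression_dataset()] with `lognorm` filled.
#' @param batch_key Annotation column holding the batch label.
#' @param conv Convergence tolerance of the iterative posterior solver.
#' @param max_iter Maximum solver iterations.
#' @return The dataset with `lognorm` batch-adjusted. A single batch is
#'   returned unchanged with a message.
#' @export
correct_batch <- function(dataset, batch_key = "batch", conv = 1e-4, max_iter = 100L) {
  if (is.null(dataset$lognorm)) abort("`lognorm` is empty; normalize first.")
  if (!batch_key %in% names(dataset$annotations)) {
    abort(sprintf("Annotation column '%s' not found.", batch_key))
  }
  batch <- factor(dataset$annotations[[batch_key]])
  if (nlevels(batch) < 2L) {
    inform("Single batch: nothing to correct, returning input unchanged.")
    return(dataset)
  }
  nb <- table(batch)
  if (any(nb < 2L)) {
    abort(sprintf("Batches with fewer than 2 nuclei: %s",
                  paste(names(nb)[nb < 2], collapse = ", ")))
  }
  y <- dataset$lognorm
  n <- ncol(y)
  levs <- levels(batch)
  idx <- lapply(levs, function(b) which(batch == b))

  batch_means <- vapply(idx, function(i) rowMeans(y[, i, drop = FALSE]), numeric(nrow(y)))
  grand <- as.vector(batch_means %*% (as.vector(nb) / n))
  resid <- y - batch_means[, as.integer(batch)]
  var_pooled <- rowSums(resid^2) / n
  ok <- var_pooled > .Machine$double.eps
  sd_pooled <- sqrt(var_pooled)
  z <- (y - grand) / sd_pooled
  z[!ok, ] <- 0

  gamma_hat <- vapply(idx, function(i) rowMeans(z[, i, drop = FALSE]), numeric(nrow(z)))
  delta_hat <- vapply(idx, function(i) apply(z[, i, drop = FALSE], 1, var), numeric(nrow(z)))

  aprior <- function(d) { m <- mean(d); s2 <- var(d); (2 * s2 + m^2) / s2 }
  bprior <- function(d) { m <- mean(d); s2 <- var(d); (m * s2 + m^3) / s2 }

  z_adj <- z
  for (b in seq_along(levs)) {
    g_hat <- gamma_hat[, b]
    d_hat <- delta_hat[, b]
    g_bar <- mean(g_hat); t2 <- var(g_hat)
    a <- aprior(d_hat); bp <- bprior(d_hat)
    nb_b <- as.vector(nb)[b]
    zs <- z[, idx[[b]], drop = FALSE]
    g_old <- g_hat; d_old <- d_hat
    for (it in seq_len(max_iter)) {
      g_new <- (t2 * nb_b * g_hat + d_old * g_bar) / (t2 * nb_b + d_old)
      sum2 <- rowSums((zs - g_new)^2)
      d_new <- (0.5 * sum2 + bp) / (nb_b / 2 + a - 1)
      change <- max(abs(g_new - g_old) / pmax(abs(g_old), 1e-8),
                    abs(d_new - d_old) / pmax(abs(d_old), 1e-8))
      g_old <- g_new; d_old <- d_new
      if (change < conv) break
    }
    z_adj[, idx[[b]]] <- (zs - g_old) / sqrt(pmax(d_old, .Machine$double.eps))
  }
  y_adj <- z_adj * sd_pooled + grand
  y_adj[!ok, ] <- y[!ok, ]
  dimnames(y_adj) <- dimnames(y)
  expression_dataset(dataset$counts, dataset$annotations, lognorm = y_adj)
}

#' Highly variable gene selection
#'
#' Decomposes each gene's log-expression variance into a fitted mean-variance
#' technical trend (robust loess of variance on mean) and a biological
#' component (total minus trend). The biological component is tested one-sided
#' against zero with a z-test using the analytic standard error of a sample
#' variance under approximate normality, `trend * sqrt(2 / (n - 1))`, and
#' p-values are Benjamini-Hochberg adjusted.
#'
#' @param dataset An [expression_dataset()] with `lognorm` filled.
#' @param fdr Adjusted-p threshold for the `selected` flag.
#' @param span Loess span of the trend fit.
#' @return An `hvg_result` tibble: `gene`, `mean`, `total_var`, `trend`,
#'   `bio`, `p`, `fdr`, `selected`.
#' @export
select_hvgs <- function(dataset, fdr = 0.1, span = 0.3) {
  if (is.null(dataset$lognorm)) abort("`lognorm` is empty; normalize first.")
  y <- dataset$lognorm
  if (nrow(y) < 10L) abort("Need at least 10 genes to fit a mean-variance trend.")
  n <- ncol(y)
  mu <- rowMeans(y)
  v <- apply(y, 1, var)
  fit <- loess(v ~ mu, span = span, degree = 2, family = "symmetric",
               control = stats::loess.control(surface = "direct"))
  trend <- pmax(predict(fit, mu), .Machine$double.eps)
  bio <- v - trend
  se <- trend * sqrt(2 / (n - 1))
  p <- pnorm(bio / se, lower.tail = FALSE)
  q <- p.adjust(p, method = "BH")
  sel <- q < fdr & bio > 0
  out <- tibble(
    gene = rownames(y), mean = mu, total_var = v, trend = trend,
    bio = bio, p = p, fdr = q, selected = sel
  )
  class(out) <- c("hvg_result", class(out))
  attr(out, "fdr_threshold") <- fdr
  out
}

#' @export
print.hvg_result <- function(x, ...) {
  cat(sprintf("<hvg_result> %d genes, %d selected at FDR %.3g\n",
              nrow(x), sum(x$selected), attr(x, "fdr_threshold")))
  NextMethod()
}
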