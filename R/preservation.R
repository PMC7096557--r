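# Internal: observed statistics for a module-sized gene set placed in the
# test network, compared against the reference module quantities.
# ref_kim / ref_cor_vec come from the reference network's module genes, in a
# fixed gene order; test_genes supplies the (possibly permuted) placement.
module_placement_stats <- function(test_network, test_genes, ref_kim, ref_cor_vec) {
  a <- abs(test_network$cor[test_genes, test_genes, drop = FALSE])^test_network$beta
  diag(a) <- 0
  m <- length(test_genes)
  density <- sum(a) / (m * (m - 1))
  kim <- rowSums(a)
  cor_kim <- suppressWarnings(cor(ref_kim, kim))
  cor_cor <- suppressWarnings(
    cor(ref_cor_vec, upper_tri_vec(test_network$cor[test_genes, test_genes]))
  )
  c(mean_adj = density, cor_kim = cor_kim, cor_cor = cor_cor)
}

#' Observed module preservation statistics
#'
#' Density preservation: mean off-diagonal adjacency among the module genes in
#' the test network. Connectivity preservation: (a) correlation between
#' intramodular connectivity (kIM, row sums of within-module adjacency)
#' computed in the reference vs the test network; (b) correlation between the
#' vectorized within-module correlation entries of the two networks. The
#' module is restricted to genes present in both networks.
#'
#' @param ref_network,test_network `coexpression_network` objects.
#' @param module_genes Character vector of module genes.
#' @return List with `evaluable`, `n_shared`, and (when evaluable) `mean_adj`,
#'   `cor_kim`, `cor_cor`.
#' @export
preservation_stats <- function(ref_network, test_network, module_genes) {
  shared <- intersect(intersect(module_genes, ref_network$genes), test_network$genes)
  if (length(shared) < length(module_genes)) {
    inform(sprintf("Using %d of %d module genes shared by both networks.",
                   length(shared), length(module_genes)))
  }
  if (length(shared) < 3L) {
    return(list(evaluable = FALSE, n_shared = length(shared)))
  }
  a_ref <- abs(ref_network$cor[shared, shared])^ref_network$beta
  diag(a_ref) <- 0
  ref_kim <- rowSums(a_ref)
  ref_cor_vec <- upper_tri_vec(ref_network$cor[shared, shared])
  obs <- module_placement_stats(test_network, shared, ref_kim, ref_cor_vec)
  c(list(evaluable = TRUE, n_shared = length(shared)), as.list(obs))
}

#' Permutation Zsummary for one module in one test network
#'
#' The null is `n_perm` random gene sets of the module's size drawn from the
#' test network's gene universe; each statistic's Z is
#' `(observed - mean_null) / sd_null`. `Zdensity` is the Z of the mean
#' adjacency, `Zconnectivity` the median of the two connectivity Zs, and
#' `Zsummary = (Zdensity + Zconnectivity) / 2`. Zsummary below 2 is read as
#' no evidence of preservation.
#'
#' @inheritParams preservation_stats
#' @param n_perm Number of permutations (>= 50).
#' @param seed Integer seed making the draw deterministic.
#' @return List with the observed statistics, per-statistic Z, `z_density`,
#'   `z_connectivity`, `z_summary`, `evaluable`, `n_shared`, `n_perm`, `seed`.
#' @export
zsummary <- function(ref_network, test_network, module_genes, n_perm = 100L,
                     seed = 1L) {
  if (n_perm < 50L) abort("`n_perm` must be at least 50.")
  obs <- preservation_stats(ref_network, test_network, module_genes)
  if (!obs$evaluable) {
    return(list(evaluable = FALSE, n_shared = obs$n_shared,
                z_summary = NA_real_, n_perm = n_perm, seed = seed))
  }
  shared <- intersect(intersect(module_genes, ref_network$genes), test_network$genes)
  a_ref <- abs(ref_network$cor[shared, shared])^ref_network$beta
  diag(a_ref) <- 0
  ref_kim <- rowSums(a_ref)
  ref_cor_vec <- upper_tri_vec(ref_network$cor[shared, shared])
  universe <- test_network$genes
  nulls <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      draw <- sample(universe, length(shared))
      module_placement_stats(test_network, draw, ref_kim, ref_cor_vec)
    }, c(mean_adj = 0, cor_kim = 0, cor_cor = 0))
  })
  mu <- rowMeans(nulls)
  sdev <- apply(nulls, 1, sd)
  observed <- c(mean_adj = obs$mean_adj, cor_kim = obs$cor_kim, cor_cor = obs$cor_cor)
  z <- rep(NA_real_, 3)
  names(z) <- names(observed)
  ok <- sdev > 0 & is.finite(observed)
  z[ok] <- (observed[ok] - mu[ok]) / sdev[ok]
  z_density <- z[["mean_adj"]]
  z_connectivity <- median(z[c("cor_kim", "cor_cor")], na.rm = TRUE)
  z_summary <- mean(c(z_density, z_connectivity))
  list(
    evaluable = all(ok), n_shared = obs$n_shared,
    observed = observed, null_mean = mu, null_sd = sdev, z = z,
    z_density = z_density, z_connectivity = z_connectivity,
    z_summary = z_summary, n_perm = as.integer(n_perm), seed = as.integer(seed)
  )
}

#' Preservation report across modules and test networks
#'
#' Runs [zsummary()] for every (module, test network) pair and appends the
#' per-module median Zsummary across test networks.
#'
#' @param ref_network The network the modules were detected in.
#' @param module_set The `module_set` of `ref_network`.
#' @param test_networks Named list of `coexpression_network` objects to test
#'   against (the reference itself is skipped if present).
#' @param n_perm Permutations per pair.
#' @param seed Root seed; each pair uses a distinct derived seed.
#' @return A `preservation_report` tibble: `module`, `test_network`,
#'   `mean_adj`, `cor_kim`, `cor_cor`, `z_density`, `z_connectivity`,
#'   `z_summary`, `evaluable`, `n_shared`.
#' @export
module_preservation <- function(ref_network, module_set, test_networks,
                                n_perm = 100L, seed = 1L) {
  mods <- sort(unique(module_set$labels[module_set$labels > 0]))
  test_networks <- test_networks[
    !vapply(test_networks, function(nw) identical(nw$cell_type, ref_network$cell_type),
            logical(1))
  ]
  if (!length(mods) || !length(test_networks)) {
    out <- tibble(module = integer(), test_network = character(),
                  mean_adj = double(), cor_kim = double(), cor_cor = double(),
                  z_density = double(), z_connectivity = double(),
                  z_summary = double(), evaluable = logical(), n_shared = integer())
    class(out) <- c("preservation_report", class(out))
    return(out)
  }
  grid <- tidyr::expand_grid(module = mods, test_network = names(test_networks))
  rows <- purrr::pmap_dfr(grid, function(module, test_network) {
    genes <- module_set$genes[module_set$labels == module]
    pair_seed <- (as.numeric(seed) * 131 + module * 977 +
                    match(test_network, names(test_networks)) * 7919) %% 2147483647
    zz <- zsummary(ref_network, test_networks[[test_network]], genes,
                   n_perm = n_perm, seed = as.integer(pair_seed))
    tibble(
      module = module, test_network = test_network,
      mean_adj = if (zz$evaluable) zz$observed[["mean_adj"]] else NA_real_,
      cor_kim = if (zz$evaluable) zz$observed[["cor_kim"]] else NA_real_,
      cor_cor = if (zz$evaluable) zz$observed[["cor_cor"]] else NA_real_,
      z_density = zz$z_density %||% NA_real_,
      z_connectivity = zz$z_connectivity %||% NA_real_,
      z_summary = zz$z_summary,
      evaluable = zz$evaluable, n_shared = as.integer(zz$n_shared)
    )
  })
  class(rows) <- c("preservation_report", class(rows))
  rows
}

#' Median Zsummary verdict per module
#'
#' @param report A `preservation_report` tibble.
#' @param zsummary_cutoff Median Zsummary below which a module counts as
#'   cell type-specific (no evidence of preservation elsewhere).
#' @return Tibble: `module`, `median_zsummary`, `n_evaluable`,
#'   `n_not_evaluable`, `verdict` (`"specific"`, `"preserved"`, or
#'   `"undetermined"` when no test network was evaluable).
#' @export
median_zsummary <- function(report, zsummary_cutoff = 2) {
  report |>
    dplyr::group_by(.data$module) |>
    dplyr::summarise(
      median_zsummary = if (any(.data$evaluable))
        median(.data$z_summary[.data$evaluable]) else NA_real_,
      n_evaluable = sum(.data$evaluable),
      n_not_evaluable = sum(!.data$evaluable),
      .groups = "drop"
    ) |>
    dplyr::mutate(verdict = dplyr::case_when(
      n_evaluable == 0 ~ "undetermined",
      median_zsummary < zsummary_cutoff ~ "specific",
      TRUE ~ "preserved"
    ))
}

#' Zsummary dot plot per module and test network
#'
#' @param object A `preservation_report`.
#' @param ... Unused.
#' @return A ggplot with the Zsummary = 2 reference line.
#' @method autoplot preservation_report
#' @export
autoplot.preservation_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(factor(.data$module), .data$z_summary,
                                       colour = .data$test_network)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = 2, linetype = "dashed") +
    ggplot2::labs(x = "module", y = "Zsummary", colour = "test network")
}
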