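#' Pearson correlation matrix for one cell type's expression
#'
#' @param x Gene x nucleus log-normalized matrix restricted to one cell type.
#' @param cell_type Label used in error messages.
#' @return Symmetric correlation matrix with unit diagonal. Zero-variance
#'   genes are dropped with a message and recorded in the `dropped` attribute.
#' @export
correlation_matrix <- function(x, cell_type = "network") {
  x <- as.matrix(x)
  if (ncol(x) < 3L) {
    abort(sprintf("Cell type '%s' has %d nuclei; at least 3 are required.",
                  cell_type, ncol(x)))
  }
  v <- apply(x, 1, var)
  dropped <- rownames(x)[v <= .Machine$double.eps]
  if (length(dropped)) {
    inform(sprintf("Dropping %d zero-variance genes for '%s'.",
                   length(dropped), cell_type))
    x <- x[v > .Machine$double.eps, , drop = FALSE]
  }
  r <- cor(t(x))
  diag(r) <- 1
  attr(r, "dropped") <- dropped
  r
}

#' Choose a soft-threshold power by scale-free topology fit
#'
#' For each candidate power the weighted connectivity `k_i = sum_j |r_ij|^beta`
#' is computed, `k` is binned, and `log10 p(k)` is regressed on `log10 k`; the
#' fit index is R-squared signed by the slope (a positive slope counts as no
#' fit). The smallest power reaching `r2_target` is returned; if none does
#' (or connectivities are degenerate) the conventional fallback power 6 is
#' returned with a warning.
#'
#' @param cor_matrix Correlation matrix.
#' @param powers Candidate powers.
#' @param r2_target Scale-free fit target.
#' @param n_bins Histogram bins for the connectivity distribution.
#' @return Integer power with attribute `fit` (a tibble of per-power fits).
#' @export
pick_soft_threshold <- function(cor_matrix, powers = 1:10, r2_target = 0.8,
                                n_bins = 10L) {
  a0 <- abs(cor_matrix)
  diag(a0) <- 0
  fits <- purrr::map_dfr(powers, function(beta) {
    k <- colSums(a0^beta)
    if (sd(k) <= .Machine$double.eps || any(k <= 0)) {
      return(tibble(power = beta, r_squared = NA_real_, slope = NA_real_,
                    mean_k = mean(k)))
    }
    bins <- cut(k, breaks = n_bins)
    dk <- tapply(k, bins, mean)
    pk <- tapply(k, bins, length) / length(k)
    keep <- !is.na(dk) & pk > 0
    if (sum(keep) < 3L) {
      return(tibble(power = beta, r_squared = NA_real_, slope = NA_real_,
                    mean_k = mean(k)))
    }
    fit <- lm(log10(pk[keep]) ~ log10(dk[keep]))
    r2 <- summary(fit)$r.squared
    slope <- coef(fit)[[2]]
    tibble(power = beta,
           r_squared = if (is.finite(slope) && slope < 0) r2 else 0,
           slope = slope, mean_k = mean(k))
  })
  hit <- which(!is.na(fits$r_squared) & fits$r_squared >= r2_target)
  if (length(hit)) {
    beta <- as.integer(fits$power[hit[1]])
  } else {
    warn("No candidate power reached the scale-free fit target; falling back to power 6.")
    beta <- 6L
  }
  attr(beta, "fit") <- fits
  beta
}

#' Unsigned weighted adjacency
#'
#' `A_ij = |r_ij|^beta` off-diagonal, `A_ii = 1`.
#'
#' @param cor_matrix Correlation matrix.
#' @param beta Soft-threshold power (>= 1).
#' @return Adjacency matrix in `[0, 1]`.
#' @export
adjacency <- function(cor_matrix, beta) {
  assert_scalar_number(beta, "beta", positive = TRUE)
  if (beta < 1) abort("`beta` must be >= 1.")
  a <- abs(cor_matrix)^beta
  diag(a) <- 1
  a
}

#' Signed topological overlap matrix
#'
#' Shared-neighbor similarity in which the neighbor products keep the
#' correlation signs:
#' `TOM_ij = |l_ij + s_ij a_ij| / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_u s_iu a_iu s_uj a_uj`, `s = sign(r)`, `a = |r|^beta`, and
#' `k_i = sum_u a_iu` (off-diagonal). The diagonal is 1.
#'
#' @param adj Unsigned adjacency from [adjacency()].
#' @param cor_matrix The correlation matrix the adjacency was built from.
#' @return Symmetric TOM with entries in `[0, 1]` and unit diagonal.
#' @export
signed_tom <- function(adj, cor_matrix) {
  assert_symmetric(adj, "adj")
  assert_symmetric(cor_matrix, "cor_matrix")
  if (!identical(dim(adj), dim(cor_matrix))) abort("`adj` and `cor_matrix` must conform.")
  a0 <- adj
  diag(a0) <- 0
  w <- sign(cor_matrix) * a0
  l <- w %*% w
  k <- colSums(a0)
  denom <- outer(k, k, pmin) + 1 - a0
  tom <- abs(l + w) / denom
  diag(tom) <- 1
  tom[tom > 1] <- 1
  tom[tom < 0] <- 0
  dimnames(tom) <- dimnames(adj)
  (tom + t(tom)) / 2
}

#' Detect modules by adaptive branch cutting of the TOM dendrogram
#'
#' Average-linkage clustering of `1 - TOM`. Because the absolute height at
#' which co-expressed branches complete depends strongly on the soft power,
#' the dendrogram is cut at each of a grid of candidate heights and the cut
#' producing the most branches of at least `min_module_size` genes is kept
#' (ties resolved toward the higher cut, which attaches loose genes that kME
#' pruning later removes). Branches smaller than `min_module_size` are left
#' unassigned (label 0). Labels are renumbered 1, 2, ... by decreasing module
#' size.
#'
#' @param tom Topological overlap matrix.
#' @param min_module_size Smallest branch kept as a module.
#' @param deep_split Integer 0-4 bounding how far up the dendrogram the scan
#'   may cut (higher = deeper into the noise plateau); ignored when
#'   `cut_height` is given.
#' @param cut_height Optional single cut height in `1 - TOM` units, replacing
#'   the adaptive scan.
#' @return Named integer vector of preliminary labels (0 = unassigned), with
#'   the `hclust` tree in attribute `dendro` and the chosen height in
#'   attribute `cut_height`.
#' @export
detect_modules <- function(tom, min_module_size = 30L, deep_split = 2L,
                           cut_height = NULL) {
  assert_symmetric(tom, "tom")
  genes <- rownames(tom)
  if (nrow(tom) < min_module_size) {
    warn("Fewer genes than `min_module_size`; all genes left unassigned.")
    return(setNames(rep(0L, nrow(tom)), genes))
  }
  tree <- hclust(as.dist(1 - tom), method = "average")
  if (is.null(cut_height)) {
    upper <- c(0.99, 0.995, 0.999, 0.9995, 0.9999)[pmin(pmax(deep_split, 0L), 4L) + 1L]
    grid <- c(0.95, 0.96, 0.97, 0.98, 0.985, 0.99, 0.9925, 0.995, 0.997,
              0.999, 0.9995, 0.9999)
    grid <- grid[grid <= upper]
  } else {
    grid <- cut_height
  }
  grid <- pmin(grid, max(tree$height))
  # a cut where one branch swallows most of the network is the noise plateau
  # congealing, not module structure; such cuts are rejected
  n_big <- vapply(grid, function(h) {
    sizes <- table(cutree(tree, h = h))
    if (max(sizes) > 0.6 * length(genes)) return(0L)
    sum(sizes >= min_module_size)
  }, integer(1))
  labels <- setNames(rep(0L, length(genes)), genes)
  if (any(n_big > 0)) {
    best <- max(grid[n_big == max(n_big)])
    raw <- cutree(tree, h = best)
    sizes <- table(raw)
    keep <- names(sizes)[sizes >= min_module_size]
    keep <- keep[order(-sizes[keep])]
    for (i in seq_along(keep)) labels[raw == as.integer(keep[i])] <- i
    attr(labels, "cut_height") <- best
  }
  attr(labels, "dendro") <- tree
  labels
}

#' Module eigengenes
#'
#' Each module's expression submatrix is standardized per gene and the first
#' principal component across nuclei (unit norm) is its eigengene, sign-
#' oriented to correlate positively with the module's mean standardized
#' profile. Zero-variance genes are dropped from the PCA with a message.
#'
#' @param x Gene x nucleus log-normalized matrix.
#' @param labels Integer module labels named by gene (0 = unassigned).
#' @return List with `eigengenes` (nucleus x module matrix, columns `M1`,
#'   `M2`, ...) and `var_explained` (named vector).
#' @export
module_eigengene <- function(x, labels) {
  mods <- sort(unique(labels[labels > 0]))
  if (!length(mods)) abort("No modules to summarize.")
  egs <- matrix(NA_real_, nrow = ncol(x), ncol = length(mods),
                dimnames = list(colnames(x), paste0("M", mods)))
  ve <- setNames(numeric(length(mods)), paste0("M", mods))
  for (j in seq_along(mods)) {
    genes <- names(labels)[labels == mods[j]]
    sub <- x[genes, , drop = FALSE]
    v <- apply(sub, 1, var)
    if (any(v <= .Machine$double.eps)) {
      inform(sprintf("Module M%d: dropping %d zero-variance genes from PCA.",
                     mods[j], sum(v <= .Machine$double.eps)))
      sub <- sub[v > .Machine$double.eps, , drop = FALSE]
    }
    if (nrow(sub) < 2L) abort(sprintf("Module M%d has fewer than 2 usable genes.", mods[j]))
    zs <- t(scale(t(sub)))           # standardize each gene
    sv <- svd(t(zs), nu = 1, nv = 0) # nuclei x genes
    e <- sv$u[, 1]
    m <- colMeans(zs)
    if (sum(e * m) < 0) e <- -e
    egs[, j] <- e
    ve[j] <- sv$d[1]^2 / sum(sv$d^2)
  }
  list(eigengenes = egs, var_explained = ve)
}

#' Merge modules with similar eigengenes
#'
#' Eigengenes are clustered by `1 - cor` with average linkage; module groups
#' joined below `merge_cut_height` are merged and eigengenes recomputed,
#' iterating until no merge occurs.
#'
#' @param x Gene x nucleus log-normalized matrix.
#' @param labels Module labels (named integer vector).
#' @param merge_cut_height Dissimilarity threshold below which modules merge.
#' @param max_rounds Safety cap on merge iterations.
#' @return List with updated `labels`, `eigengenes`, `var_explained`.
#' @export
merge_modules <- function(x, labels, merge_cut_height = 0.2, max_rounds = 10L) {
  for (round in seq_len(max_rounds)) {
    eg <- module_eigengene(x, labels)
    mods <- sort(unique(labels[labels > 0]))
    if (length(mods) < 2L) break
    d <- 1 - cor(eg$eigengenes)
    tree <- hclust(as.dist(d), method = "average")
    groups <- cutree(tree, h = merge_cut_height)
    if (max(groups) == length(mods)) break
    remap <- setNames(groups, mods) # old label -> group id
    new_labels <- labels
    new_labels[labels > 0] <- unname(remap[as.character(labels[labels > 0])])
    labels <- relabel_by_size(new_labels)
  }
  eg <- module_eigengene(x, labels)
  list(labels = labels, eigengenes = eg$eigengenes, var_explained = eg$var_explained)
}

relabel_by_size <- function(labels) {
  mods <- sort(unique(labels[labels > 0]))
  if (!length(mods)) return(labels)
  sizes <- vapply(mods, function(m) sum(labels == m), integer(1))
  remap <- setNames(seq_along(mods), mods[order(-sizes, mods)])
  out <- labels
  out[labels > 0] <- unname(remap[as.character(labels[labels > 0])])
  out
}

#' Prune weak module members by module membership (kME)
#'
#' kME is the Pearson correlation of each gene with each module eigengene.
#' Genes whose |kME| to their own module falls below `min_kme` are moved to
#' the unassigned label, then eigengenes and kME are recomputed once.
#'
#' @param x Gene x nucleus log-normalized matrix.
#' @param labels Module labels.
#' @param eigengenes Nucleus x module eigengene matrix for `labels`.
#' @param min_kme Retention threshold on |own-module kME|.
#' @return A `module_set`: list with `labels`, `eigengenes`, `var_explained`,
#'   `kme` (gene x module matrix) and `genes`.
#' @export
kme_prune <- function(x, labels, eigengenes, min_kme = 0.2) {
  kme <- cor(t(x), eigengenes)
  own <- rep(NA_real_, length(labels))
  assigned <- labels > 0
  own[assigned] <- kme[cbind(which(assigned), labels[assigned])]
  drop <- assigned & abs(own) < min_kme
  labels[drop] <- 0L
  labels <- relabel_by_size(labels)
  if (any(labels > 0)) {
    eg <- module_eigengene(x, labels)
    kme <- cor(t(x), eg$eigengenes)
    out <- list(labels = labels, eigengenes = eg$eigengenes,
                var_explained = eg$var_explained, kme = kme,
                genes = names(labels))
  } else {
    out <- list(labels = labels, eigengenes = NULL, var_explained = NULL,
                kme = NULL, genes = names(labels))
  }
  structure(out, class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  n_mod <- length(unique(x$labels[x$labels > 0]))
  cat(sprintf("<module_set> %d genes, %d modules, %d unassigned\n",
              length(x$labels), n_mod, sum(x$labels == 0)))
  invisible(x)
}

#' @rdname kme_prune
#' @param x A `module_set`.
#' @param ... Unused.
#' @method tidy module_set
#' @export
tidy.module_set <- function(x, ...) {
  own <- rep(NA_real_, length(x$labels))
  assigned <- x$labels > 0
  if (any(assigned) && !is.null(x$kme)) {
    own[assigned] <- x$kme[cbind(which(assigned), x$labels[assigned])]
  }
  tibble(gene = x$genes, module = x$labels, kme_own = own)
}

#' Build a full per-cell-type co-expression network
#'
#' Correlation, soft power selection, unsigned adjacency and signed TOM in
#' one step.
#'
#' @param x Gene x nucleus log-normalized matrix for one cell type.
#' @param cell_type Label carried in the result.
#' @param beta Soft power; `NULL` selects it by scale-free fit.
#' @inheritParams pick_soft_threshold
#' @return A `coexpression_network`: list with `genes`, `cor`, `beta`,
#'   `adjacency`, `tom`, `cell_type`.
#' @export
build_network <- function(x, cell_type = "network", beta = NULL,
                          powers = 1:10, r2_target = 0.8) {
  r <- correlation_matrix(x, cell_type)
  if (is.null(beta)) beta <- pick_soft_threshold(r, powers, r2_target)
  a <- adjacency(r, as.numeric(beta))
  tom <- signed_tom(a, r)
  structure(
    list(genes = rownames(r), cor = r, beta = as.integer(beta),
         adjacency = a, tom = tom, cell_type = cell_type),
    class = "coexpression_network"
  )
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf("<coexpression_network> '%s': %d genes, soft power %d\n",
              x$cell_type, length(x$genes), x$beta))
  invisible(x)
}

#' Detect, merge and prune modules on a network
#'
#' Runs [detect_modules()], [module_eigengene()], [merge_modules()] and
#' [kme_prune()] on a built network and its expression matrix.
#'
#' @param network A `coexpression_network`.
#' @param x The gene x nucleus matrix the network was built from (rows must
#'   cover `network$genes`).
#' @inheritParams detect_modules
#' @inheritParams merge_modules
#' @inheritParams kme_prune
#' @return A `module_set`.
#' @export
detect_module_set <- function(network, x, min_module_size = 30L, deep_split = 2L,
                              cut_height = NULL, merge_cut_height = 0.2,
                              min_kme = 0.2) {
  x <- x[network$genes, , drop = FALSE]
  labels <- detect_modules(network$tom, min_module_size, deep_split, cut_height)
  attr(labels, "dendro") <- NULL
  if (!any(labels > 0)) {
    return(structure(list(labels = labels, eigengenes = NULL,
                          var_explained = NULL, kme = NULL,
                          genes = names(labels)), class = "module_set"))
  }
  merged <- merge_modules(x, labels, merge_cut_height)
  kme_prune(x, merged$labels, merged$eigengenes, min_kme)
}

#' Export the hub-gene subnetwork of a module
#'
#' The top `n` genes of a module by own-module kME (ties broken
#' lexicographically) and the TOM edges among them at or above `edge_floor`,
#' in the node/edge-table form a graph tool such as Cytoscape imports.
#'
#' @param module_set A `module_set`.
#' @param tom The TOM of the network the modules came from.
#' @param module Integer module label to export.
#' @param n Number of hub genes.
#' @param edge_floor Minimum TOM weight for an edge to be kept.
#' @param disease_genes Optional character vector used to flag nodes.
#' @return A `hub_network`: list of `nodes` (gene, kme, module,
#'   is_disease_gene) and `edges` (gene_a, gene_b, tom_weight), both tibbles
#'   in deterministic order.
#' @export
export_top_hub_network <- function(module_set, tom, module, n = 50L,
                                   edge_floor = 0, disease_genes = character()) {
  genes <- module_set$genes[module_set$labels == module]
  if (!length(genes)) abort(sprintf("Module %s does not exist.", module))
  kme <- module_set$kme[genes, paste0("M", module)]
  if (n > length(genes)) {
    inform(sprintf("Module %d has %d genes (< %d); exporting all.",
                   module, length(genes), as.integer(n)))
    n <- length(genes)
  }
  ord <- order(-kme, genes)
  top <- genes[ord][seq_len(n)]
  nodes <- tibble(
    gene = top, kme = unname(kme[top]), module = module,
    is_disease_gene = top %in% disease_genes
  )
  sub <- tom[top, top, drop = FALSE]
  pairs <- which(upper.tri(sub), arr.ind = TRUE)
  edges <- tibble(
    gene_a = top[pairs[, 1]], gene_b = top[pairs[, 2]],
    tom_weight = sub[pairs]
  ) |>
    dplyr::filter(.data$tom_weight >= edge_floor) |>
    dplyr::arrange(match(.data$gene_a, top), match(.data$gene_b, top))
  structure(list(nodes = nodes, edges = edges), class = "hub_network")
}
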