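# Shared fixtures, all generated in code.

# Two (or more) planted correlation blocks plus optional noise genes:
# block genes load sqrt(r) on a shared factor, so within-block Pearson
# correlation is ~r and between-block correlation is ~0.
make_block_matrix <- function(seed, n_cells = 200, block_sizes = c(40, 40),
                              r = 0.9, n_noise = 0) {
  set.seed(seed)
  g <- sum(block_sizes) + n_noise
  x <- matrix(rnorm(g * n_cells), g, n_cells)
  start <- 1L
  for (b in block_sizes) {
    f <- rnorm(n_cells)
    idx <- start:(start + b - 1L)
    x[idx, ] <- sqrt(r) * matrix(f, b, n_cells, byrow = TRUE) + sqrt(1 - r) * x[idx, ]
    start <- start + b
  }
  dimnames(x) <- list(sprintf("g%03d", seq_len(g)), sprintf("c%03d", seq_len(n_cells)))
  x
}

block_truth <- function(block_sizes, n_noise = 0) {
  c(rep(seq_along(block_sizes), times = block_sizes), rep(0L, n_noise))
}

# A small, fast synthetic study: 3 classes, one class-restricted module and
# one shared module, markers in every class.
tiny_config <- function(seed, n_batches = 2L, batch_effect_sd = 0.3) {
  example_synth_config(seed, n_batches = n_batches,
                       batch_effect_sd = batch_effect_sd)
}

# The 40-gene-module configuration used by the preservation checks.
preservation_config <- function(seed) {
  ids <- sprintf("g%04d", 1:3000)
  classes <- tibble::tibble(label = c("Ex", "Inh", "Ast", "Oligo", "OPC"),
                            n_nuclei = c(800L, 400L, 200L, 120L, 80L))
  synth_config(
    n_genes = 3000L, cell_classes = classes, n_batches = 2L,
    batch_effect_sd = 0.3,
    planted_modules = list(
      planted_module("mod_ast", ids[251:290], "Ast", 0.8),
      planted_module("mod_shared", ids[291:330], "all", 0.8)
    ),
    marker_genes = list(), disease_genes = character(), seed = seed
  )
}

# Gaussian expression with a known technical mean-variance trend and a block
# of variance-inflated genes; used to check HVG selection calibration.
hvg_calibration_dataset <- function(seed, n_cells = 200, n_null = 2000,
                                    n_inflated = 100, inflation = 4) {
  set.seed(seed)
  g <- n_null + n_inflated
  mu <- runif(g, 0.5, 6)
  tech <- 0.2 + 0.1 * mu
  v <- tech
  v[(n_null + 1):g] <- v[(n_null + 1):g] * inflation
  y <- matrix(rnorm(g * n_cells, mean = mu, sd = sqrt(rep(v, n_cells))),
              g, n_cells)
  dimnames(y) <- list(sprintf("g%04d", seq_len(g)), sprintf("c%03d", seq_len(n_cells)))
  ds <- expression_dataset(
    matrix(1, g, n_cells, dimnames = dimnames(y)),
    tibble::tibble(nucleus_id = colnames(y), cell_class = "A"),
    lognorm = y
  )
  list(dataset = ds, null_genes = rownames(y)[1:n_null],
       inflated_genes = rownames(y)[(n_null + 1):g])
}

# Independent brute-force oracle for the hypergeometric upper tail:
# direct log-space enumeration of the tail terms.
hyper_tail_oracle <- function(x, K, N, n) {
  upper <- min(n, K)
  if (x > upper) return(0)
  i <- x:upper
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# Independent min-over-suffix oracle for Benjamini-Hochberg.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- m * p[ord] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

quiet <- function(expr) suppressWarnings(suppressMessages(expr))
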