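# Internal helpers shared across modules.

# Derive a reproducible sub-seed for a named stage from a root seed.
# Kept strictly below 2^31 so it is always a valid R integer.
stage_seed <- function(seed, stage) {
  offsets <- c(
    syndata = 11L, qc = 23L, hvg = 37L, network = 53L,
    preservation = 71L, enrichment = 89L, report = 101L
  )
  off <- offsets[[stage]]
  as.integer((as.numeric(seed) * 7919 + off) %% 2147483647)
}

assert_scalar_number <- function(x, name, positive = FALSE, non_negative = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) abort(sprintf("`%s` must be positive.", name))
  if (non_negative && x < 0) abort(sprintf("`%s` must be non-negative.", name))
  invisible(x)
}

assert_symmetric <- function(m, name, tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    abort(sprintf("`%s` must be a square matrix.", name))
  }
  if (max(abs(m - t(m))) > tol) {
    abort(sprintf("`%s` must be symmetric.", name))
  }
  invisible(m)
}

# Upper-triangle vectorization in a fixed (column-major) order.
upper_tri_vec <- function(m) m[upper.tri(m)]

#' @export
print.ctsnet_log <- function(x, ...) {
  for (line in x) cat("-", line, "\n")
  invisible(x)
}
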