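test_that("QC removes broken nuclei and excluded genes, leaves clean data alone", {
  out <- generate_dataset(tiny_config(1, n_batches = 1L, batch_effect_sd = 0))
  ds <- out$dataset
  ds$counts[, 10] <- 0 # a dead nucleus
  filt <- qc_filter(ds)
  expect_false("n00010" %in% colnames(filt$counts))

  excl <- rownames(ds$counts)[201:205]
  filt2 <- qc_filter(ds, exclude_genes = excl)
  expect_true(all(!excl %in% rownames(filt2$counts)))

  # homogeneous libraries (no planted structure): <=1% falsely removed
  plain <- synth_config(
    n_genes = 400L,
    cell_classes = tibble::tibble(label = "A", n_nuclei = 400L),
    n_batches = 1L, batch_effect_sd = 0, seed = 1L
  )
  removed <- vapply(1:5, function(s) {
    plain$seed <- s
    d <- generate_dataset(plain)$dataset
    1 - ncol(qc_filter(d)$counts) / ncol(d$counts)
  }, numeric(1))
  expect_lte(mean(removed), 0.01)

  ds0 <- ds
  ds0$counts[] <- 0
  expect_error(qc_filter(ds0), "every nucleus")
})

test_that("size-factor normalization is mean-1 and scale-equivariant", {
  out <- generate_dataset(tiny_config(2, n_batches = 1L, batch_effect_sd = 0))
  ds <- qc_filter(out$dataset)
  norm <- size_factor_normalize(ds)
  sf <- attr(norm, "size_factors")
  expect_equal(mean(sf), 1)

  # equal libraries: all factors 1 and lognorm = log2(count + 1)
  eq <- ds
  eq$counts <- matrix(3L, 20, 10,
                      dimnames = list(sprintf("g%02d", 1:20), sprintf("c%02d", 1:10)))
  eq <- expression_dataset(eq$counts,
                           tibble::tibble(nucleus_id = colnames(eq$counts), cell_class = "A"))
  neq <- size_factor_normalize(eq)
  expect_equal(unname(attr(neq, "size_factors")), rep(1, 10))
  expect_equal(neq$lognorm, log2(eq$counts + 1))

  # doubling one nucleus doubles its factor and leaves its lognorm ~unchanged
  dbl <- ds
  dbl$counts[, 1] <- dbl$counts[, 1] * 2L
  ndbl <- size_factor_normalize(dbl)
  expect_equal(attr(ndbl, "size_factors")[[1]] / sf[[1]], 2, tolerance = 0.02)
  expect_equal(ndbl$lognorm[, 1], norm$lognorm[, 1], tolerance = 0.05)
})

test_that("CPM columns sum to one million and follow the definition", {
  m <- matrix(c(2, 3, 5), 3, 1, dimnames = list(c("a", "b", "c"), "n1"))
  expect_equal(as.vector(cpm(m)), c(200000, 300000, 500000))

  out <- generate_dataset(tiny_config(3, n_batches = 1L, batch_effect_sd = 0))
  ds <- qc_filter(out$dataset)
  cp <- cpm(ds)
  expect_equal(unname(colSums(cp)), rep(1e6, ncol(cp)), tolerance = 1e-8)

  zr <- ds
  zr$counts[1, ] <- 0L
  expect_true(all(cpm(zr)[1, ] == 0))
  bad <- ds
  bad$counts[, 2] <- 0L
  expect_error(cpm(bad), "zero-library")
})

test_that("batch correction removes location shifts and matches the EB oracle", {
  set.seed(42)
  g <- 150; n <- 400
  batch <- rep(c("b1", "b2"), each = n / 2)
  shift <- rnorm(g, 0, 0.5)
  y <- matrix(rnorm(g * n, 5, 1), g, n) + outer(shift, as.integer(batch == "b2"))
  dimnames(y) <- list(sprintf("g%03d", 1:g), sprintf("c%03d", 1:n))
  ds <- expression_dataset(
    matrix(1, g, n, dimnames = dimnames(y)),
    tibble::tibble(nucleus_id = colnames(y), cell_class = "A", batch = batch),
    lognorm = y
  )
  adj <- correct_batch(ds)
  expect_identical(dim(adj$lognorm), dim(y))
  gap <- abs(rowMeans(adj$lognorm[, batch == "b1"]) -
               rowMeans(adj$lognorm[, batch == "b2"]))
  expect_lt(median(gap), 0.05)

  # applying the correction twice changes nearly nothing
  adj2 <- correct_batch(adj)
  expect_lt(mean(abs(adj2$lognorm - adj$lognorm)), 0.05)

  # independent implementation of the same empirical-Bayes adjustment
  ref <- sva::ComBat(y, batch = factor(batch))
  expect_lt(max(abs(adj$lognorm - ref)), 1e-6)

  # single batch: unchanged, with a notice
  ds1 <- expression_dataset(ds$counts,
                            dplyr::mutate(ds$annotations, batch = "b1"),
                            lognorm = y)
  expect_message(un <- correct_batch(ds1), "Single batch")
  expect_identical(un$lognorm, y)

  tiny <- expression_dataset(
    ds$counts[, 1:3],
    tibble::tibble(nucleus_id = colnames(y)[1:3], cell_class = "A",
                   batch = c("b1", "b1", "b2")),
    lognorm = y[, 1:3]
  )
  expect_error(correct_batch(tiny), "fewer than 2")
})

test_that("batch correction removes most of the planted batch variance", {
  out <- generate_dataset(tiny_config(4))
  ds <- quiet(correct_batch(size_factor_normalize(qc_filter(out$dataset))))
  raw <- size_factor_normalize(qc_filter(out$dataset))
  batch <- factor(raw$annotations$batch)
  X <- stats::model.matrix(~batch)
  r2 <- function(m) {
    apply(m, 1, function(yy) {
      f <- stats::lm.fit(X, yy)
      1 - sum(f$residuals^2) / sum((yy - mean(yy))^2)
    })
  }
  set.seed(1)
  gs <- sample(rownames(raw$lognorm), 150)
  before <- median(r2(raw$lognorm[gs, ]))
  after <- median(r2(ds$lognorm[gs, ]))
  expect_lt(after, 0.1 * before)
})

test_that("HVG selection finds inflated genes and respects its contract", {
  sim <- hvg_calibration_dataset(1)
  hv <- select_hvgs(sim$dataset, fdr = 0.1)
  expect_equal(hv$bio, hv$total_var - hv$trend)
  sel <- hv$gene[hv$selected]
  expect_gte(sum(sel %in% sim$inflated_genes), 80)

  # a constant gene can never be selected
  ds <- sim$dataset
  ds$lognorm[1, ] <- 2
  hv2 <- select_hvgs(ds)
  expect_lte(hv2$bio[1], 0)
  expect_false(hv2$selected[1])

  # permutation invariance of the selected set
  perm <- sample(nrow(sim$dataset$lognorm))
  dsp <- expression_dataset(sim$dataset$counts[perm, ],
                            sim$dataset$annotations,
                            lognorm = sim$dataset$lognorm[perm, ])
  hvp <- select_hvgs(dsp)
  expect_setequal(hvp$gene[hvp$selected], sel)

  small <- expression_dataset(sim$dataset$counts[1:5, ], sim$dataset$annotations,
                              lognorm = sim$dataset$lognorm[1:5, ])
  expect_error(select_hvgs(small), "at least 10 genes")
})
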