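test_that("correlation matches a brute-force covariance oracle", {
  set.seed(1)
  x <- matrix(rnorm(50 * 40), 50, 40,
              dimnames = list(sprintf("g%02d", 1:50), sprintf("c%02d", 1:40)))
  r <- correlation_matrix(x, "toy")
  # independent two-pass oracle
  oracle <- matrix(0, 50, 50)
  for (i in 1:50) for (j in 1:50) {
    xi <- x[i, ] - mean(x[i, ]); xj <- x[j, ] - mean(x[j, ])
    oracle[i, j] <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
  }
  expect_lt(max(abs(r - oracle)), 1e-10)

  dup <- rbind(x, dup = x[1, ])
  rd <- correlation_matrix(dup, "toy")
  expect_equal(rd["g01", "dup"], 1)
  anti <- rbind(a = x[1, ], b = -x[1, ])
  expect_equal(correlation_matrix(anti, "toy")["a", "b"], -1)

  expect_error(correlation_matrix(x[, 1:2], "Ast"), "Ast")
  expect_message(correlation_matrix(rbind(x, cst = rep(1, 40)), "toy"),
                 "zero-variance")
})

test_that("adjacency is the soft-thresholded absolute correlation", {
  r <- matrix(c(1, -0.8, -0.8, 1), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  a <- adjacency(r, 6)
  expect_equal(a["a", "b"], 0.262144)
  expect_equal(diag(a), c(a = 1, b = 1))
  r0 <- matrix(c(1, 0, 0, 1), 2, 2)
  expect_equal(adjacency(r0, 7)[1, 2], 0)
  r1 <- matrix(1, 2, 2)
  expect_equal(adjacency(r1, 12)[1, 2], 1)
  expect_error(adjacency(r, 0.5), ">= 1")
})

test_that("signed TOM reproduces the hand-worked cases and its bounds", {
  r3 <- matrix(0.5, 3, 3); diag(r3) <- 1
  dimnames(r3) <- list(letters[1:3], letters[1:3])
  a3 <- adjacency(r3, 1)
  tom3 <- signed_tom(a3, r3)
  expect_equal(unname(tom3[1, 2]), 0.5, tolerance = 1e-12) # (0.25+0.5)/(1+1-0.5)
  expect_equal(unname(diag(tom3)), rep(1, 3))

  rp <- matrix(1, 4, 4)
  expect_true(all(abs(signed_tom(adjacency(rp, 3), rp) - 1) < 1e-12))

  # a gene uncorrelated with everything has a zero TOM row
  riso <- matrix(0.6, 4, 4); diag(riso) <- 1
  riso[4, 1:3] <- 0; riso[1:3, 4] <- 0
  dimnames(riso) <- list(letters[1:4], letters[1:4])
  tiso <- signed_tom(adjacency(riso, 2), riso)
  expect_equal(unname(tiso[4, 1:3]), rep(0, 3))

  bad <- riso; bad[1, 2] <- 0.9
  expect_error(signed_tom(adjacency(riso, 2), bad), "symmetric")

  # property: TOM in [0,1], symmetric, unit diagonal, on random networks
  for (s in 1:5) {
    set.seed(s)
    x <- matrix(rnorm(30 * 25), 30, 25, dimnames = list(sprintf("g%02d", 1:30), NULL))
    r <- correlation_matrix(x, "rnd")
    tom <- signed_tom(adjacency(r, 4), r)
    expect_true(all(tom >= 0 & tom <= 1))
    expect_equal(tom, t(tom))
    expect_equal(unname(diag(tom)), rep(1, 30))
  }
})

test_that("signed TOM reduces to the unsigned formula for non-negative correlations", {
  set.seed(3)
  for (s in 1:3) {
    f <- matrix(rnorm(5 * 60), 5, 60)
    load <- matrix(abs(rnorm(20 * 5, 0, 0.4)), 20, 5)
    x <- load %*% f + 0.2 * matrix(rnorm(20 * 60), 20, 60)
    rownames(x) <- sprintf("g%02d", 1:20)
    r <- correlation_matrix(x, "pos")
    r <- abs(r) # force a non-negative correlation structure
    a <- adjacency(r, 3)
    tom <- signed_tom(a, r)
    # independent unsigned oracle
    a0 <- a; diag(a0) <- 0
    l <- a0 %*% a0
    k <- colSums(a0)
    oracle <- (l + a0) / (outer(k, k, pmin) + 1 - a0)
    diag(oracle) <- 1
    expect_lt(max(abs(tom - oracle)), 1e-12)
  }
})

test_that("soft-threshold selection is monotone in connectivity and falls back sanely", {
  set.seed(5)
  x <- make_block_matrix(5, n_cells = 100, block_sizes = c(30, 30), n_noise = 60)
  r <- correlation_matrix(x, "toy")
  beta <- pick_soft_threshold(r)
  fit <- attr(beta, "fit")
  expect_true(all(diff(fit$mean_k) < 0))
  beta2 <- pick_soft_threshold(r)
  expect_identical(as.integer(beta), as.integer(beta2))

  rall <- matrix(1, 40, 40)
  expect_warning(bfall <- pick_soft_threshold(rall), "falling back")
  expect_equal(as.integer(bfall), 6L)
})

test_that("planted blocks are detected and small or noise branches left unassigned", {
  ari <- vapply(1:3, function(s) {
    x <- make_block_matrix(s)
    nw <- quiet(build_network(x, "toy"))
    ms <- quiet(detect_module_set(nw, x))
    expect_equal(length(unique(ms$labels[ms$labels > 0])), 2L)
    mclust::adjustedRandIndex(ms$labels, block_truth(c(40, 40)))
  }, numeric(1))
  expect_true(all(ari >= 0.9))

  # 10-gene blocks are below the minimum module size
  x10 <- make_block_matrix(1, block_sizes = c(10, 10), n_noise = 60)
  nw10 <- quiet(build_network(x10, "toy"))
  ms10 <- quiet(detect_module_set(nw10, x10))
  expect_equal(sum(ms10$labels > 0), 0L)

  # pure noise: the vast majority unassigned
  unassigned <- vapply(1:3, function(s) {
    set.seed(100 + s)
    x <- matrix(rnorm(150 * 200), 150, 200,
                dimnames = list(sprintf("g%03d", 1:150), NULL))
    nw <- quiet(build_network(x, "noise"))
    ms <- quiet(detect_module_set(nw, x))
    mean(ms$labels == 0)
  }, numeric(1))
  expect_true(all(unassigned >= 0.8))

  small_tom <- diag(5)
  rownames(small_tom) <- colnames(small_tom) <- letters[1:5]
  expect_warning(lab <- detect_modules(small_tom, min_module_size = 30),
                 "unassigned")
  expect_true(all(lab == 0))
})

test_that("module eigengenes match an independent spectral oracle", {
  set.seed(9)
  x <- matrix(rnorm(30 * 50), 30, 50,
              dimnames = list(sprintf("g%02d", 1:30), sprintf("c%02d", 1:50)))
  labels <- setNames(rep(1L, 30), rownames(x))
  eg <- module_eigengene(x, labels)
  expect_equal(sum(eg$eigengenes[, 1]^2), 1, tolerance = 1e-10)

  # oracle: leading eigenvector of the nucleus x nucleus Gram matrix of the
  # standardized expression (power-iteration-free, via eigen())
  zs <- t(scale(t(x)))
  gram <- t(zs) %*% zs
  ev <- eigen(gram, symmetric = TRUE)
  u1 <- ev$vectors[, 1]
  if (sum(u1 * colMeans(zs)) < 0) u1 <- -u1
  expect_lt(max(abs(eg$eigengenes[, 1] - u1)), 1e-8)
  expect_equal(eg$var_explained[[1]], ev$values[1] / sum(ev$values), tolerance = 1e-10)

  # identical genes: eigengene proportional to the standardized profile
  prof <- rnorm(40)
  xid <- matrix(rep(prof, each = 6), 6, 40,
                dimnames = list(sprintf("g%02d", 1:6), NULL))
  egid <- module_eigengene(xid, setNames(rep(1L, 6), rownames(xid)))
  expect_equal(egid$var_explained[[1]], 1, tolerance = 1e-10)
  zprof <- as.vector(scale(prof))
  expect_lt(max(abs(egid$eigengenes[, 1] - zprof / sqrt(sum(zprof^2)))), 1e-8)

  # orientation convention holds on random modules
  for (s in 1:5) {
    set.seed(s)
    xs <- matrix(rnorm(12 * 40), 12, 40, dimnames = list(sprintf("g%02d", 1:12), NULL))
    e <- module_eigengene(xs, setNames(rep(1L, 12), rownames(xs)))
    zsum <- colMeans(t(scale(t(xs))))
    expect_gte(cor(e$eigengenes[, 1], zsum), 0)
  }
})

test_that("modules with correlated eigengenes merge, distinct ones do not", {
  set.seed(21)
  n <- 150
  f <- rnorm(n)
  # two modules driven by nearly the same factor, one by an independent factor
  x1 <- sqrt(0.9) * matrix(f, 20, n, byrow = TRUE) + sqrt(0.1) * matrix(rnorm(20 * n), 20, n)
  f2 <- 0.95 * f + sqrt(1 - 0.95^2) * rnorm(n)
  x2 <- sqrt(0.9) * matrix(f2, 20, n, byrow = TRUE) + sqrt(0.1) * matrix(rnorm(20 * n), 20, n)
  g <- rnorm(n)
  x3 <- sqrt(0.9) * matrix(g, 20, n, byrow = TRUE) + sqrt(0.1) * matrix(rnorm(20 * n), 20, n)
  x <- rbind(x1, x2, x3)
  rownames(x) <- sprintf("g%02d", 1:60)
  labels <- setNames(rep(1:3, each = 20), rownames(x))
  merged <- merge_modules(x, labels, merge_cut_height = 0.2)
  expect_equal(length(unique(merged$labels[merged$labels > 0])), 2L)
  # the near-duplicate pair collapsed into one module
  expect_equal(length(unique(merged$labels[1:40])), 1L)
  # the independent module stayed apart
  expect_false(merged$labels[[41]] == merged$labels[[1]])

  single <- merge_modules(x, setNames(rep(1L, 60), rownames(x)))
  expect_equal(length(unique(single$labels)), 1L)
})

test_that("kME pruning drops weak members and matches the correlation oracle", {
  set.seed(31)
  x <- make_block_matrix(31, n_cells = 120, block_sizes = c(25), n_noise = 5)
  labels <- setNames(rep(1L, 30), rownames(x)) # noise genes mislabeled in
  eg <- module_eigengene(x, labels)
  ms <- kme_prune(x, labels, eg$eigengenes, min_kme = 0.2)
  expect_true(all(ms$labels[26:30] == 0)) # noise pruned
  expect_true(all(ms$labels[1:25] == 1))

  kme_oracle <- vapply(seq_len(nrow(x)), function(i) cor(x[i, ], ms$eigengenes[, 1]),
                       numeric(1))
  expect_lt(max(abs(ms$kme[, 1] - kme_oracle)), 1e-10)

  # a gene identical to the eigengene scores kME 1
  xi <- rbind(x[1:25, ], eg1 = as.vector(eg$eigengenes[, 1]))
  li <- setNames(rep(1L, 26), rownames(xi))
  egi <- module_eigengene(xi, li)
  msi <- kme_prune(xi, li, egi$eigengenes)
  expect_gte(msi$kme["eg1", 1], 0.99)
  expect_equal(msi$labels[["eg1"]], 1L)
})

test_that("hub export returns the top-kME subgraph deterministically", {
  set.seed(41)
  x <- make_block_matrix(41, n_cells = 150, block_sizes = c(123), n_noise = 130)
  nw <- quiet(build_network(x, "toy"))
  ms <- quiet(detect_module_set(nw, x))
  expect_gte(sum(ms$labels == 1), 100)
  hub0 <- export_top_hub_network(ms, nw$tom, 1, n = 50)
  hub <- export_top_hub_network(ms, nw$tom, 1, n = 50,
                                disease_genes = hub0$nodes$gene[1:2])
  expect_equal(nrow(hub$nodes), 50)
  expect_equal(nrow(hub$edges), 50 * 49 / 2) # edge_floor 0: complete graph
  expect_true(all(diff(hub$nodes$kme) <= 1e-12))
  expect_identical(hub$nodes$is_disease_gene, c(TRUE, TRUE, rep(FALSE, 48)))

  kms <- ms$kme[ms$genes[ms$labels == 1], "M1"]
  expected_order <- names(kms)[order(-kms, names(kms))][1:50]
  expect_identical(hub$nodes$gene, expected_order)

  expect_message(small <- export_top_hub_network(ms, nw$tom, 1, n = 1e4), "exporting all")
  expect_equal(nrow(small$nodes), sum(ms$labels == 1))
  expect_error(export_top_hub_network(ms, nw$tom, 99), "does not exist")
})
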