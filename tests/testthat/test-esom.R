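# Batch SOM training on the toroidal grid, U-matrix, valley delineation,
# and binning evaluation.

test_that("a single training row attracts every neuron with radius_end 0", {
  f <- features_from_matrix(matrix(c(1, 2, 3), 1, 3))
  m <- train_esom(f, rows = 3, cols = 3, epochs = 5, radius_end = 0, seed = 1)
  expect_equal(max(abs(sweep(m$weights, 2, c(1, 2, 3)))), 0)
  expect_equal(m$bmu$dist, 0)
  expect_true(all(compute_umatrix(m)$u == 0))
})

test_that("one batch epoch at radius zero equals one Lloyd k-means step", {
  # independent Lloyd oracle on a 30-row, 4-neuron instance: assign rows to
  # nearest centroid, replace each non-empty centroid by its cluster mean
  withr::with_seed(42, {
    x <- matrix(rnorm(30 * 5), 30, 5)
  })
  f <- features_from_matrix(x)
  m <- train_esom(f, rows = 2, cols = 2, epochs = 1,
                  radius_start = 0, radius_end = 0, seed = 7)
  init <- withr::with_seed(7, x[sample.int(30, 4), ])
  d2 <- outer(rowSums(x^2), rowSums(init^2), `+`) - 2 * x %*% t(init)
  assign <- apply(d2, 1, which.min)
  lloyd <- init
  for (k in seq_len(4)) {
    if (any(assign == k)) lloyd[k, ] <- colMeans(x[assign == k, , drop = FALSE])
  }
  expect_lt(max(abs(m$weights - lloyd)), 1e-12)
})

test_that("training is deterministic given the seed", {
  f <- features_from_matrix(withr::with_seed(1, matrix(rnorm(200), 50, 4)))
  m1 <- train_esom(f, rows = 4, cols = 5, epochs = 8, seed = 3)
  m2 <- train_esom(f, rows = 4, cols = 5, epochs = 8, seed = 3)
  expect_identical(m1$weights, m2$weights)
  m3 <- train_esom(f, rows = 4, cols = 5, epochs = 8, seed = 4)
  expect_false(identical(m1$weights, m3$weights))
})

test_that("stored BMUs agree with brute-force nearest-neuron search", {
  f <- features_from_matrix(withr::with_seed(5, matrix(rnorm(40 * 3), 40, 3)))
  m <- train_esom(f, rows = 3, cols = 4, epochs = 6, seed = 2)
  x <- as.matrix(f[, -1])
  for (i in seq_len(nrow(x))) {
    d <- sqrt(colSums((t(m$weights) - x[i, ])^2))
    expect_equal(m$bmu$dist[i], min(d))
    expect_equal(d[m$bmu$neuron[i]], min(d))
  }
})

test_that("final quantization error does not exceed the initial one", {
  # meaningful on a map with fewer neurons than rows, where the sampled
  # initialization cannot already interpolate every row
  f <- features_from_matrix(withr::with_seed(8, matrix(rnorm(300 * 6), 300, 6)))
  m <- train_esom(f, rows = 6, cols = 8, epochs = 15, seed = 1)
  expect_lte(m$qe_final, m$qe_initial)
})

test_that("NaN features and bad grids are rejected, sparse maps warned", {
  bad <- features_from_matrix(matrix(c(1, NaN, 3, 4), 2, 2))
  expect_error(train_esom(bad, rows = 2, cols = 2), "non-finite|NA")
  f <- features_from_matrix(matrix(rnorm(4), 2, 2))
  expect_warning(train_esom(f, rows = 25, cols = 25, epochs = 1, seed = 1),
                 "sparse")
})

test_that("the U-matrix uses all 8 toroidal neighbors at every edge", {
  # brute-force oracle: neighbor set of corner (0,0) on a 10x10 grid wraps
  nb <- seriesbin:::toroidal_neighbors(10, 10)
  to_rc <- function(i) c((i - 1) %/% 10, (i - 1) %% 10)
  corner <- t(vapply(nb[[1]], to_rc, numeric(2)))
  expect_equal(nrow(corner), 8)
  for (want in list(c(9, 0), c(0, 9), c(9, 9), c(1, 1), c(0, 1), c(1, 0))) {
    expect_true(any(corner[, 1] == want[1] & corner[, 2] == want[2]))
  }

  f <- features_from_matrix(withr::with_seed(2, matrix(rnorm(100 * 3), 100, 3)))
  m <- train_esom(f, rows = 5, cols = 6, epochs = 4, seed = 1)
  u <- compute_umatrix(m)
  expect_true(all(u$u >= 0))
  # direct recomputation for one interior and one corner neuron
  for (i in c(1, 17)) {
    nb_i <- seriesbin:::toroidal_neighbors(5, 6)[[i]]
    manual <- mean(sqrt(rowSums(
      (m$weights[nb_i, , drop = FALSE] -
         matrix(m$weights[i, ], 8, 3, byrow = TRUE))^2)))
    expect_equal(u$u[i], manual)
  }
})

test_that("the U-matrix is equivariant under toroidal translation", {
  # translating all weights by a fixed grid offset translates the U-matrix
  f <- features_from_matrix(withr::with_seed(3, matrix(rnorm(80 * 3), 80, 3)))
  m <- train_esom(f, rows = 4, cols = 6, epochs = 5, seed = 1)
  u <- compute_umatrix(m)
  shift <- function(i, dr, dc, rows, cols) {
    r <- ((i - 1) %/% cols + dr) %% rows
    c <- ((i - 1) %% cols + dc) %% cols
    r * cols + c + 1
  }
  m2 <- m
  idx <- vapply(seq_len(24), shift, numeric(1), dr = 2, dc = 3,
                rows = 4, cols = 6)
  m2$weights[idx, ] <- m$weights
  u2 <- compute_umatrix(m2)
  expect_equal(u2$u[idx], u$u)
})

test_that("two well-separated blobs are delineated into exactly two pure bins", {
  b <- blob_features()
  m <- train_esom(b$features, rows = 11, cols = 18, epochs = 20,
                  radius_end = 0.6, seed = 1)
  asg <- delineate_bins(m)
  ev <- evaluate_binning(asg, b$truth)
  expect_equal(ev$n_bins, 2)
  expect_equal(ev$ari, 1.0)
  expect_true(all(ev$per_bin$precision == 1))
})

test_that("an extreme valley threshold leaves every scaffold unbinned", {
  b <- blob_features(n_per = 50)
  m <- train_esom(b$features, epochs = 5, seed = 1)
  asg <- delineate_bins(m, u_threshold_quantile = 1e-9)
  expect_true(all(asg$bin == "UNBINNED"))
  expect_error(delineate_bins(m, u_threshold_quantile = 0), "quantile")
  expect_error(delineate_bins(m, u_threshold_quantile = 1), "quantile")
})

test_that("bin assignments are a partition of the input scaffolds", {
  b <- blob_features(n_per = 60)
  m <- train_esom(b$features, epochs = 10, seed = 2)
  asg <- delineate_bins(m)
  expect_setequal(asg$scaffold_id, b$features$scaffold_id)
  expect_equal(anyDuplicated(asg$scaffold_id), 0L)
})

test_that("binning evaluation behaves at the identity and null extremes", {
  truth <- tibble::tibble(scaffold_id = paste0("s", 1:60),
                          genome_id = rep(c("g1", "g2", "g3"), each = 20))
  ident <- tibble::tibble(scaffold_id = truth$scaffold_id,
                          bin = truth$genome_id)
  expect_equal(evaluate_binning(ident, truth)$ari, 1.0)
  lumped <- tibble::tibble(scaffold_id = truth$scaffold_id, bin = "bin_001")
  expect_equal(evaluate_binning(lumped, truth)$ari, 0.0)
  expect_error(
    evaluate_binning(
      tibble::tibble(scaffold_id = "nope", bin = "bin_001"), truth),
    "truth")
})

test_that("randomly permuted labels score near-zero ARI", {
  n <- 1000
  truth <- tibble::tibble(scaffold_id = paste0("s", seq_len(n)),
                          genome_id = rep(paste0("g", 1:10), each = n / 10))
  aris <- vapply(1:100, function(s) {
    perm <- withr::with_seed(s, sample(truth$genome_id))
    evaluate_binning(
      tibble::tibble(scaffold_id = truth$scaffold_id, bin = perm), truth)$ari
  }, numeric(1))
  expect_lt(max(abs(aris)), 0.05)
})
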