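test_that("component distance is the sign-invariant correlation distance", {
  x <- c(1, 0, -1); y <- c(0, 1, 0)
  expect_equal(component_distance(x, x), 0)
  expect_equal(component_distance(x, -x), 0)
  expect_equal(component_distance(x, y), 1)   # hand-computed: rho = 0
  expect_equal(component_distance(x, y), component_distance(y, x))
  expect_error(component_distance(c(1, 1, 1), y), "zero-variance")
})

test_that("PCA dimension estimate finds the planted rank", {
  withr::with_seed(2, {
    u <- rnorm(100); v <- rnorm(12)
    rank1 <- outer(u, v)
    rownames(rank1) <- sprintf("g%d", 1:100); colnames(rank1) <- sprintf("s%d", 1:12)
    expect_equal(estimate_dimension(rank1), 1L)

    # 5 orthogonal factors of equal strength + noise at ~0.1% of the variance
    qs <- qr.Q(qr(matrix(rnorm(200 * 5), 200)))
    qa <- qr.Q(qr(matrix(rnorm(20 * 5), 20)))
    x <- qs %*% (10 * t(qa)) + matrix(rnorm(200 * 20, 0, 0.01), 200)
    dimnames(x) <- list(sprintf("g%d", 1:200), sprintf("s%d", 1:20))
    expect_equal(estimate_dimension(x), 5L)
  })
  expect_error(estimate_dimension(matrix(0, 5, 5,
                                         dimnames = list(letters[1:5], LETTERS[1:5]))),
               "all-zero")
})

test_that("a FastICA restart recovers independent uniform sources", {
  withr::with_seed(10, {
    s0 <- cbind(runif(500, -1, 1), runif(500, -1, 1))
    a0 <- matrix(rnorm(2 * 20, 0, 3), 2, 20)
    x <- s0 %*% a0
    dimnames(x) <- list(sprintf("g%d", 1:500), sprintf("s%d", 1:20))
  })
  run <- run_ica_restart(x, 2, seed = 4)
  expect_equal(colSums(run$S^2), c(1, 1), tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(colMeans(run$S), c(0, 0), tolerance = 1e-6, ignore_attr = TRUE)
  cors <- abs(cor(run$S, s0))
  expect_true(all(apply(cors, 2, max) > 0.99))
  # restarts from different seeds agree up to sign: matched columns < 0.01
  run2 <- run_ica_restart(x, 2, seed = 99)
  d <- 1 - abs(cor(run$S, run2$S))
  expect_true(all(apply(d, 1, min) < 0.01))
})

test_that("a single source is reproduced up to sign", {
  withr::with_seed(12, {
    s0 <- runif(300, -1, 1)
    x <- outer(s0, rnorm(10, 0, 2))
    dimnames(x) <- list(sprintf("g%d", 1:300), sprintf("s%d", 1:10))
  })
  run <- run_ica_restart(x, 1, seed = 1)
  expect_gt(abs(cor(run$S[, 1], s0)), 0.9999)
})

test_that("DBSCAN clustering groups sign-flipped copies and rejects noise", {
  withr::with_seed(21, v <- rnorm(200))
  copies <- matrix(rep(v, 256), ncol = 256)
  labels <- cluster_runs(copies, min_members = 128)
  expect_equal(max(labels), 1L)
  expect_true(all(labels == 1L))

  # 128 copies of v and 128 of -v still form one cluster (distance 0)
  flipped <- cbind(matrix(rep(v, 128), ncol = 128),
                   matrix(rep(-v, 128), ncol = 128))
  labels2 <- cluster_runs(flipped, min_members = 128)
  expect_equal(max(labels2), 1L)
  expect_true(all(labels2 == 1L))

  # two orthogonal populations plus stray noise vectors
  withr::with_seed(22, {
    q <- qr.Q(qr(matrix(rnorm(200 * 2), 200)))
    pool <- cbind(matrix(rep(q[, 1], 130), ncol = 130),
                  matrix(rep(q[, 2], 130), ncol = 130),
                  matrix(rnorm(200 * 20), ncol = 20))
  })
  labels3 <- cluster_runs(pool, min_members = 128)
  expect_equal(max(labels3), 2L)
  expect_true(all(labels3[1:130] == labels3[1]))
  expect_true(all(labels3[131:260] == labels3[131]))
  expect_true(all(labels3[261:280] == 0L))
})

test_that("cluster centroids are sign-aligned, unit-norm, and product-preserving", {
  withr::with_seed(31, v <- rnorm(50))
  v <- v / sqrt(sum(v^2))
  act <- rnorm(8)

  # {v, -v} with matching activity signs averages to the sign representative
  cen <- align_and_centroid(cbind(v, -v), rbind(act, -act))
  expect_equal(abs(cor(cen$component, v)), 1)
  top <- which.max(abs(cen$component))
  expect_gt(cen$component[top], 0)
  expect_equal(cen$component %o% cen$activity, {
    al <- if (v[which.max(abs(v))] > 0) v else -v
    aa <- if (v[which.max(abs(v))] > 0) act else -act
    al %o% aa
  }, tolerance = 1e-12)

  # identical members return the member unchanged
  cen2 <- align_and_centroid(cbind(v, v, v), rbind(act, act, act))
  sgn <- if (v[which.max(abs(v))] > 0) 1 else -1
  expect_equal(cen2$component, sgn * v, tolerance = 1e-12)
  expect_equal(cen2$activity, sgn * act, tolerance = 1e-12)

  # small perturbation: centroid stays within ||delta||/2 of v
  delta <- rnorm(50, 0, 0.01)
  cen3 <- align_and_centroid(cbind(v, v + delta), rbind(act, act))
  expect_lt(sqrt(sum((sgn * cen3$component - v)^2)), sqrt(sum(delta^2)) / 2 + 1e-5)
})

test_that("robust decomposition recovers planted sources and keeps the sign convention", {
  pm <- planted_matrix(n_genes = 500, n_samples = 30, k = 5, noise = 0.02, seed = 41)
  dec <- suppressMessages(
    robust_components(pm$X, n_components = 5, n_restarts = 8,
                      n_repetitions = 3, seed = 7))
  expect_equal(ncol(dec$S), 5L)
  d <- 1 - abs(cor(dec$S, pm$S))
  expect_true(all(apply(d, 2, min) < 0.1))   # every source found
  expect_true(all(apply(d, 1, min) < 0.1))   # no spurious component
  expect_true(all(dec$robustness_count == dec$n_repetitions))
  # sign convention: max-|coefficient| gene positive in every component
  tops <- apply(dec$S, 2, function(v) v[which.max(abs(v))])
  expect_true(all(tops > 0))
  # ordering by descending activity norm
  expect_true(all(diff(rowSums(dec$A^2)) <= 1e-9))
})

test_that("pure-noise input yields no (or almost no) robust components", {
  withr::with_seed(55, {
    x <- matrix(rnorm(400 * 24), 400, 24,
                dimnames = list(sprintf("g%d", 1:400), sprintf("s%d", 1:24)))
  })
  dec <- suppressWarnings(suppressMessages(
    robust_components(x, n_components = 5, n_restarts = 8,
                      n_repetitions = 4, seed = 3)))
  expect_lte(ncol(dec$S), 2L)
})

test_that("different master seeds give equivalent component sets on strong signal", {
  pm <- planted_matrix(n_genes = 400, n_samples = 24, k = 4, noise = 0.02, seed = 61)
  dec1 <- suppressMessages(robust_components(pm$X, n_components = 4, n_restarts = 8,
                                             n_repetitions = 2, seed = 100))
  dec2 <- suppressMessages(robust_components(pm$X, n_components = 4, n_restarts = 8,
                                             n_repetitions = 2, seed = 2222))
  expect_equal(ncol(dec1$S), ncol(dec2$S))
  d <- 1 - abs(cor(dec1$S, dec2$S))
  expect_true(all(apply(d, 1, min) < 0.1))
  expect_true(all(apply(d, 2, min) < 0.1))
})

test_that("cumulative explained variance follows the residual sum-of-squares identity", {
  withr::with_seed(71, {
    s1 <- rnorm(100); s1 <- s1 / sqrt(sum(s1^2))
    s2_raw <- rnorm(100); s2 <- s2_raw - sum(s2_raw * s1) * s1
    s2 <- s2 / sqrt(sum(s2^2))
    a1 <- c(rep(2, 5), rep(0, 5)); a2 <- c(rep(0, 5), rep(2, 5))
  })
  dec <- new_decomposition(cbind(s1, s2), rbind(a1, a2))
  x1 <- s1 %o% a1
  dimnames(x1) <- list(sprintf("g%03d", 1:100), sprintf("s%02d", 1:10))
  expect_equal(cumulative_explained_variance(x1 , new_decomposition(cbind(s1), rbind(a1)), 0), 0)
  expect_equal(cumulative_explained_variance(x1, new_decomposition(cbind(s1), rbind(a1)), 1), 1)
  # orthogonal equal-TSS terms split the variance evenly
  x <- s1 %o% a1 + s2 %o% a2
  dimnames(x) <- dimnames(x1)
  expect_equal(cumulative_explained_variance(x, dec, 1), 0.5, tolerance = 1e-12)
  expect_equal(cumulative_explained_variance(x, dec, 2), 1, tolerance = 1e-12)
  curve <- cumulative_explained_variance(x, dec)
  expect_equal(curve$cev, c(0, 0.5, 1), tolerance = 1e-12)
  expect_error(cumulative_explained_variance(x * 0, dec, 1), "TSS")
})

test_that("reconstruction on synthetic data reaches the retained variance fraction", {
  pm <- planted_matrix(n_genes = 400, n_samples = 24, k = 4, noise = 0.02, seed = 81)
  k99 <- estimate_dimension(pm$X, 0.99)
  dec <- suppressMessages(robust_components(pm$X, n_components = k99,
                                            n_restarts = 8, n_repetitions = 2,
                                            seed = 5))
  cev <- cumulative_explained_variance(pm$X, dec, ncol(dec$S))
  expect_gte(cev, 0.99 - 0.02)
})

test_that("decompositions round-trip through TSV + JSON serialization", {
  pm <- planted_matrix(n_genes = 120, n_samples = 16, k = 2, seed = 91)
  dec <- suppressMessages(robust_components(pm$X, n_components = 2, n_restarts = 6,
                                            n_repetitions = 2, seed = 17))
  dir <- withr::local_tempdir()
  write_decomposition(dec, dir)
  back <- read_decomposition(dir)
  expect_equal(back$S, dec$S, tolerance = 1e-9)
  expect_equal(back$A, dec$A, tolerance = 1e-9)
  expect_equal(back$n_restarts, dec$n_restarts)
})
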