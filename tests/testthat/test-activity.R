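# activities for `n_groups` duplicate pairs where the within-pair absolute
# difference is drawn log-normal(meanlog, sdlog)
lognormal_pair_activities <- function(n_imod, n_groups, meanlog = 0, sdlog = 0.5,
                                      seed = 1) {
  withr::with_seed(seed, {
    a <- matrix(0, n_imod, 2 * n_groups)
    for (i in seq_len(n_imod)) {
      d <- rlnorm(n_groups, meanlog, sdlog) * sample(c(-1, 1), n_groups, TRUE)
      base <- rnorm(n_groups, 0, 3)
      a[i, ] <- as.vector(rbind(base, base + d))
    }
    samples <- as.vector(rbind(sprintf("c%03d__r1", seq_len(n_groups)),
                               sprintf("c%03d__r2", seq_len(n_groups))))
    dimnames(a) <- list(sprintf("IM%02d", seq_len(n_imod)), samples)
    groups <- stats::setNames(rep(sprintf("c%03d", seq_len(n_groups)), each = 2),
                              samples)
    list(A = a, groups = groups)
  })
}

test_that("the log-normal replicate-noise fit recovers known parameters", {
  fx <- lognormal_pair_activities(1, 200, meanlog = 0, sdlog = 0.5, seed = 3)
  nm <- fit_replicate_noise(fx$A, fx$groups)
  expect_false(nm$degenerate)
  expect_true(nm$reliable)
  expect_equal(nm$meanlog, 0, tolerance = 0.1)
  expect_equal(nm$sdlog, 0.5, tolerance = 0.1)
  expect_equal(nm$n_pairs, 200L)
})

test_that("identical replicates are flagged degenerate", {
  a <- matrix(rep(c(1, 1, 2, 2), 2), nrow = 2, byrow = TRUE,
              dimnames = list(c("IM01", "IM02"),
                              c("c1__r1", "c1__r2", "c2__r1", "c2__r2")))
  groups <- stats::setNames(c("c1", "c1", "c2", "c2"), colnames(a))
  expect_warning(nm <- fit_replicate_noise(a, groups), "degenerate")
  expect_true(all(nm$degenerate))
})

test_that("the goodness-of-fit diagnostic accepts data from the fitted family", {
  ok <- vapply(1:100, function(s) {
    fx <- lognormal_pair_activities(1, 200, seed = 6000 + s)
    fit_replicate_noise(fx$A, fx$groups)$ks_p > 0.05
  }, TRUE)
  expect_gte(sum(ok), 90)
})

test_that("differential activity flags planted shifts and nothing for self-comparison", {
  fx <- lognormal_pair_activities(5, 30, seed = 11)
  nm <- fit_replicate_noise(fx$A, fx$groups)
  cond <- fx$groups  # conditions coincide with replicate groups here

  self <- test_differential_activity(fx$A, nm, cond, "c001", "c001")
  expect_true(all(self$delta_a == 0))
  expect_false(any(self$significant))

  # plant a shift of 20 on one i-modulon in a fresh condition pair
  a2 <- cbind(fx$A, x__r1 = 0, x__r2 = 0, y__r1 = 0, y__r2 = 0)
  a2["IM03", c("y__r1", "y__r2")] <- 20
  cond2 <- c(cond, stats::setNames(c("x", "x", "y", "y"),
                                   c("x__r1", "x__r2", "y__r1", "y__r2")))
  res <- test_differential_activity(a2, nm, cond2, "x", "y")
  expect_true(res$significant[res$imodulon == "IM03"])
  expect_equal(res$delta_a[res$imodulon == "IM03"], 20)
  # closed-form check of the upper-tail p-value
  expect_equal(res$p_value[res$imodulon == "IM03"],
               plnorm(20, nm$meanlog[3], nm$sdlog[3], lower.tail = FALSE))
  expect_false(any(res$significant[res$imodulon != "IM03"]))
})

test_that("differential-activity p-values are uniform under the null", {
  fx <- lognormal_pair_activities(10, 100, seed = 21)
  nm <- fit_replicate_noise(fx$A, fx$groups)
  pvals <- unlist(lapply(1:20, function(r) {
    withr::with_seed(3000 + r, {
      d <- rlnorm(10, nm$meanlog, nm$sdlog) * sample(c(-1, 1), 10, TRUE)
    })
    a <- cbind(matrix(0, 10, 2), matrix(rep(d, 2), 10))
    dimnames(a) <- list(sprintf("IM%02d", 1:10),
                        c("u__r1", "u__r2", "v__r1", "v__r2"))
    cond <- stats::setNames(c("u", "u", "v", "v"), colnames(a))
    test_differential_activity(a, nm, cond, "u", "v")$p_value
  }))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_lt(unname(ks$statistic), 0.1)
})

# a tiny imod_set with two planted i-modulons, built through the public path
make_correction_iset <- function(seed = 31) {
  s <- matrix(withr::with_seed(seed, rnorm(300 * 2, 0, 0.01)), 300, 2)
  rownames(s) <- sprintf("g%03d", 1:300)
  s[1:10, 1] <- 0.3
  s[11:25, 2] <- c(rep(0.25, 12), rep(-0.25, 3))
  a <- matrix(0, 2, 4, dimnames = list(NULL, sprintf("s%d", 1:4)))
  colnames(s) <- c("IM01", "IM02")
  compute_imodulons(new_decomposition(s, a), cutoff = 100)
}

test_that("profile correction inverts a constructed i-modulon shift exactly", {
  iset <- make_correction_iset()
  x1 <- withr::with_seed(32, stats::setNames(rnorm(300, 0, 0.3), sprintf("g%03d", 1:300)))
  im1 <- imodulon_genes(iset, "IM01")
  s_tilde <- stats::setNames(rep(0, 300), names(x1))
  s_tilde[im1$gene] <- im1$weight
  x2 <- x1 + s_tilde * (12 - 2)

  fixed <- correct_profile(x2, iset, "IM01",
                           a_ref = c(IM01 = 2), a_target = c(IM01 = 12))
  expect_equal(stats::setNames(fixed$value, fixed$gene), x1, tolerance = 1e-12)
  # empty selection leaves the profile unchanged
  same <- correct_profile(x2, iset, character(0), c(IM01 = 2), c(IM01 = 12))
  expect_equal(same$value, unname(x2))
  # applying the correction with negated differences restores the input
  back <- correct_profile(stats::setNames(fixed$value, fixed$gene), iset, "IM01",
                          a_ref = c(IM01 = 12), a_target = c(IM01 = 2))
  expect_equal(stats::setNames(back$value, back$gene), x2, tolerance = 1e-12)
  expect_error(correct_profile(x1[-1], iset, "IM01", c(IM01 = 2), c(IM01 = 12)),
               "missing gene")
})

test_that("correcting strain differences restores cross-strain agreement", {
  iset <- make_correction_iset(seed = 41)
  genes <- sprintf("g%03d", 1:300)
  x1 <- withr::with_seed(42, stats::setNames(rnorm(300, 0, 0.5), genes))
  affected <- unique(unlist(lapply(c("IM01", "IM02"),
                                   function(im) imodulon_genes(iset, im)$gene)))
  shift <- stats::setNames(rep(0, 300), genes)
  for (im in c("IM01", "IM02")) {
    gt <- imodulon_genes(iset, im)
    shift[gt$gene] <- shift[gt$gene] + gt$weight * 15
  }
  x2 <- x1 + shift + withr::with_seed(43, rnorm(300, 0, 0.05))

  r2_before <- cor(x1[affected], x2[affected])^2
  fixed <- correct_profile(x2, iset, c("IM01", "IM02"),
                           a_ref = c(IM01 = 0, IM02 = 0),
                           a_target = c(IM01 = 15, IM02 = 15))
  x2fix <- stats::setNames(fixed$value, fixed$gene)
  r2_after <- cor(x1[affected], x2fix[affected])^2
  expect_lt(r2_before, 0.5)
  expect_gt(r2_after, 0.95)
})

test_that("projection is exact for exact factorizations and orthogonal in residual", {
  withr::with_seed(51, {
    s <- matrix(rnorm(200 * 4), 200, 4)
    s <- apply(s, 2, function(v) v / sqrt(sum(v^2)))
    rownames(s) <- sprintf("g%03d", 1:200)
    colnames(s) <- sprintf("IC%d", 1:4)
    a <- matrix(rnorm(4 * 3, 0, 5), 4, 3)
  })
  xp <- s %*% a
  colnames(xp) <- sprintf("n%d", 1:3)
  proj <- project_onto_basis(s, xp)
  expect_equal(unname(proj), unname(a), tolerance = 1e-8, ignore_attr = TRUE)

  zero <- project_onto_basis(s, xp * 0)
  expect_true(all(zero == 0))

  noisy <- xp + withr::with_seed(52, matrix(rnorm(600, 0, 0.2), 200))
  proj2 <- project_onto_basis(s, noisy)
  resid <- noisy - s %*% proj2
  expect_lt(max(abs(t(resid) %*% s)), 1e-8)

  # duplicated column makes the basis rank-deficient: minimum-norm + warning
  s_bad <- cbind(s, IC5 = s[, 1])
  expect_warning(project_onto_basis(s_bad, xp), "rank-deficient")
})

test_that("projecting the training data reproduces the decomposition's activities", {
  pm <- planted_matrix(n_genes = 400, n_samples = 24, k = 4, noise = 0.02, seed = 61)
  dec <- suppressMessages(robust_components(pm$X, n_components = 4, n_restarts = 8,
                                            n_repetitions = 2, seed = 9))
  xc <- sweep(pm$X, 2, colMeans(pm$X))  # the part the basis reconstructs
  proj <- project_onto_basis(dec, xc)
  for (i in seq_len(nrow(proj))) {
    expect_gt(cor(proj[i, ], dec$A[i, ])^2, 0.99)
  }
})

test_that("activity-expression association measures linear and threshold patterns", {
  samples <- sprintf("s%02d", 1:50)
  withr::with_seed(71, x <- stats::setNames(rnorm(50, 8, 2), samples))
  y_lin <- 3 * x - 5
  assoc <- activity_expression_association(y_lin, x)
  expect_equal(assoc$r_squared, 1, tolerance = 1e-12)

  # null calibration: independent rows rarely show R^2 above 0.05
  hits <- vapply(1:100, function(s) {
    withr::with_seed(8000 + s, {
      a <- stats::setNames(rnorm(200), sprintf("s%03d", 1:200))
      e <- stats::setNames(rnorm(200), sprintf("s%03d", 1:200))
    })
    activity_expression_association(a, e)$r_squared < 0.05
  }, TRUE)
  expect_gte(sum(hits), 95)

  # threshold activation: flat below a breakpoint, linear above
  withr::with_seed(72, {
    xb <- stats::setNames(runif(60, 0, 10), sprintf("s%02d", 1:60))
    yb <- pmax(xb - 6, 0) * 4 + rnorm(60, 0, 0.2)
  })
  assoc_b <- activity_expression_association(yb, xb)
  expect_gt(assoc_b$pw_adj_r_squared, assoc_b$adj_r_squared)
  expect_equal(assoc_b$pw_breakpoint, 6, tolerance = 1)

  # exclusions are honored and tiny overlap errors
  expect_error(activity_expression_association(y_lin[1:3], x[1:3],
                                               exclude_samples = samples[1]),
               "fewer than 3")
})
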