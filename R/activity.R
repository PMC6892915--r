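#' Fit the replicate-noise model of i-modulon activities
#'
#' Pools, per i-modulon, the absolute pairwise differences of activities
#' between biological replicates (within each replicate group) and fits a
#' log-normal distribution by maximum likelihood on the log-transformed
#' values. The Kolmogorov-Smirnov statistic of the fitted distribution is
#' recorded as a goodness-of-fit diagnostic. I-modulons whose replicate
#' differences are all zero are flagged degenerate; fits on fewer than 5
#' differences are flagged unreliable.
#'
#' @param activities Activity matrix (i-modulons x samples), an `imod_set`,
#'   or a data frame with a leading i-modulon id column.
#' @param replicate_groups Named character vector mapping sample id to
#'   replicate group, or a metadata data frame with `sample_id` and
#'   `replicate_group` columns.
#' @return A tibble of class `imod_noise_model`: one row per i-modulon with
#'   `meanlog`, `sdlog`, `n_pairs`, `ks_stat`, `ks_p`, `degenerate`,
#'   `reliable`.
#' @export
fit_replicate_noise <- function(activities, replicate_groups) {
  a <- activity_matrix(activities)
  groups <- as_group_map(replicate_groups)
  if (!all(colnames(a) %in% names(groups))) abort("every sample needs a replicate-group key")
  groups <- groups[colnames(a)]
  multi <- names(table(groups))[table(groups) >= 2L]
  if (length(multi) < 2L) abort("need at least 2 replicate groups of size >= 2")

  rows <- purrr::map(rownames(a), function(im) {
    diffs <- unlist(lapply(multi, function(g) {
      v <- a[im, groups == g]
      as.numeric(stats::dist(v))
    }))
    nonzero <- diffs[diffs > 0]
    if (!length(nonzero)) {
      return(tibble(imodulon = im, meanlog = NA_real_, sdlog = NA_real_,
                    n_pairs = length(diffs), ks_stat = NA_real_,
                    ks_p = NA_real_, degenerate = TRUE, reliable = FALSE))
    }
    lv <- log(nonzero)
    meanlog <- mean(lv)
    sdlog <- stats::sd(lv)
    if (!is.finite(sdlog) || sdlog == 0) {
      return(tibble(imodulon = im, meanlog = meanlog, sdlog = NA_real_,
                    n_pairs = length(nonzero), ks_stat = NA_real_,
                    ks_p = NA_real_, degenerate = TRUE, reliable = FALSE))
    }
    ks <- suppressWarnings(stats::ks.test(nonzero, "plnorm",
                                          meanlog = meanlog, sdlog = sdlog))
    tibble(imodulon = im, meanlog = meanlog, sdlog = sdlog,
           n_pairs = length(nonzero), ks_stat = unname(ks$statistic),
           ks_p = ks$p.value, degenerate = FALSE,
           reliable = length(nonzero) >= 5L)
  })
  out <- dplyr::bind_rows(rows)
  if (any(out$degenerate)) {
    warn(sprintf("%d i-modulon(s) are degenerate (all-zero replicate differences) and are excluded from testing",
                 sum(out$degenerate)))
  }
  class(out) <- c("imod_noise_model", class(out))
  out
}

activity_matrix <- function(x) {
  if (inherits(x, "imod_set")) return(x$activities)
  if (inherits(x, "imod_decomposition")) return(x$A)
  if (is.data.frame(x)) {
    m <- as.matrix(x[, -1L, drop = FALSE])
    rownames(m) <- as.character(x[[1L]])
    storage.mode(m) <- "double"
    return(m)
  }
  as.matrix(x)
}

as_group_map <- function(x) {
  if (is.data.frame(x)) {
    return(stats::setNames(as.character(x$replicate_group), x$sample_id))
  }
  x
}

as_condition_map <- function(x) {
  if (is.data.frame(x)) {
    return(stats::setNames(as.character(x$condition), x$sample_id))
  }
  x
}

#' Test differential i-modulon activity between two conditions
#'
#' Activities are first averaged over the biological replicates of each
#' condition; the absolute difference of the averages is then compared
#' against the i-modulon's fitted log-normal replicate-noise distribution
#' (upper-tail probability). P-values are corrected by Benjamini-Hochberg
#' across i-modulons, and an i-modulon is called significant when both
#' `|delta_activity| > abs_threshold` and `fdr < fdr_alpha` hold.
#'
#' @inheritParams fit_replicate_noise
#' @param noise_model An `imod_noise_model` from [fit_replicate_noise()].
#' @param conditions Named character vector mapping sample id to condition,
#'   or a metadata data frame with `sample_id` and `condition` columns.
#' @param condition_1,condition_2 Conditions to compare.
#' @param abs_threshold Minimum absolute activity difference (default 5).
#' @param fdr_alpha FDR threshold (default 0.01).
#' @return Tibble with one row per testable i-modulon: `imodulon`,
#'   `condition_1`, `condition_2`, `activity_1`, `activity_2`, `delta_a`,
#'   `p_value`, `fdr`, `significant`.
#' @export
test_differential_activity <- function(activities, noise_model, conditions,
                                       condition_1, condition_2,
                                       abs_threshold = 5, fdr_alpha = 0.01) {
  a <- activity_matrix(activities)
  cond <- as_condition_map(conditions)
  if (!all(colnames(a) %in% names(cond))) abort("every sample needs a condition label")
  cond <- cond[colnames(a)]
  for (cc in c(condition_1, condition_2)) {
    if (!cc %in% cond) abort(sprintf("condition '%s' not present", cc))
  }
  a1 <- rowMeans(a[, cond == condition_1, drop = FALSE])
  a2 <- rowMeans(a[, cond == condition_2, drop = FALSE])

  nm <- noise_model[match(rownames(a), noise_model$imodulon), ]
  usable <- !is.na(nm$sdlog) & !nm$degenerate
  if (any(!usable)) {
    warn(sprintf("skipping %d i-modulon(s) with a degenerate noise model", sum(!usable)))
  }
  delta <- a2 - a1
  p <- rep(NA_real_, length(delta))
  p[usable] <- ifelse(
    abs(delta[usable]) == 0, 1,
    stats::plnorm(abs(delta[usable]), meanlog = nm$meanlog[usable],
                  sdlog = nm$sdlog[usable], lower.tail = FALSE))
  out <- tibble(imodulon = rownames(a),
                condition_1 = condition_1, condition_2 = condition_2,
                activity_1 = unname(a1), activity_2 = unname(a2),
                delta_a = unname(delta), p_value = p)[usable, ]
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- abs(out$delta_a) > abs_threshold & out$fdr < fdr_alpha
  out
}

#' Correct an expression profile by i-modulon subtraction
#'
#' Removes the contribution of selected i-modulons from a centered expression
#' profile: `x2' = x2 - sum_i s_i~ * (a_i2 - a_i1)`, where `s_i~` is zero
#' outside i-modulon i's significant genes. Genes outside every selected
#' i-modulon are unchanged, and applying the correction with negated activity
#' differences restores the original profile exactly.
#'
#' @param profile Centered expression profile: named numeric vector or a
#'   two-column data frame (gene, value).
#' @param iset The `imod_set` the activities were computed from.
#' @param imodulons Names of the i-modulons to subtract.
#' @param a_ref Named numeric vector of reference-condition activities
#'   (`a_i1`), indexed by i-modulon name.
#' @param a_target Named numeric vector of target-condition activities
#'   (`a_i2`).
#' @return Tibble with columns `gene`, `value` (the corrected profile).
#' @export
correct_profile <- function(profile, iset, imodulons, a_ref, a_target) {
  x <- as_named_numeric(profile, "profile")
  out <- x
  for (im in imodulons) {
    gt <- imodulon_genes(iset, im)
    missing <- setdiff(gt$gene, names(x))
    if (length(missing)) {
      abort(sprintf("profile is missing gene(s) of i-modulon '%s': %s",
                    im, paste(utils::head(missing, 5), collapse = ", ")))
    }
    if (!im %in% names(a_ref) || !im %in% names(a_target)) {
      abort(sprintf("activities missing for i-modulon '%s'", im))
    }
    out[gt$gene] <- out[gt$gene] - gt$weight * (a_target[[im]] - a_ref[[im]])
  }
  tibble(gene = names(out), value = unname(out))
}

#' Project new expression profiles onto a fixed component basis
#'
#' Computes the least-squares activities `A' = pinv(S) X'` for new centered
#' profiles over the genes shared with the basis. Rows of `S` and `X'` are
#' intersected first (cross-strain use restricts to core genes present in
#' both); a rank-deficient gene subset triggers a warning and the minimum-norm
#' solution is returned.
#'
#' @param S Component matrix (genes x components) or an `imod_decomposition`.
#' @param profiles Centered profiles: matrix or data frame (genes x samples)
#'   with gene identifiers.
#' @return Matrix of projected activities (components x samples) with
#'   attribute `genes_used` recording the shared-gene subset.
#' @export
project_onto_basis <- function(S, profiles) {
  s <- if (inherits(S, "imod_decomposition")) S$S else as_expr_matrix(S, "S")
  x <- as_expr_matrix(profiles, "profiles")
  shared <- intersect(rownames(s), rownames(x))
  if (!length(shared)) abort("no shared genes between basis and profiles")
  s_sub <- s[shared, , drop = FALSE]
  x_sub <- x[shared, , drop = FALSE]
  pi <- pseudo_inverse(s_sub)
  if (pi$rank < ncol(s_sub)) {
    warn(sprintf("gene subset leaves S rank-deficient (rank %d < %d); returning the minimum-norm solution",
                 pi$rank, ncol(s_sub)))
  }
  a <- pi$pinv %*% x_sub
  rownames(a) <- colnames(s_sub)
  colnames(a) <- colnames(x_sub)
  attr(a, "genes_used") <- shared
  a
}

#' Associate an i-modulon's activity with its regulator's expression
#'
#' Ordinary least-squares fit of the activity row on the regulator gene's
#' expression row across samples (optionally excluding samples such as the
#' regulator's own knockout), reporting R-squared and adjusted R-squared. A
#' single-breakpoint piecewise fit (flat below the breakpoint, linear above,
#' breakpoint chosen by profiling the residual sum of squares over observed
#' expression values) is reported alongside for threshold-activation
#' patterns.
#'
#' @param activity Named numeric vector: activity per sample.
#' @param expression Named numeric vector: regulator expression per sample.
#' @param exclude_samples Samples to drop before fitting (e.g. the
#'   regulator's knockout).
#' @return One-row tibble: `n`, `r_squared`, `adj_r_squared`,
#'   `pw_breakpoint`, `pw_r_squared`, `pw_adj_r_squared`.
#' @export
activity_expression_association <- function(activity, expression,
                                            exclude_samples = NULL) {
  shared <- intersect(names(activity), names(expression))
  shared <- setdiff(shared, exclude_samples)
  if (length(shared) < 3L) abort("fewer than 3 samples after exclusion")
  y <- activity[shared]; x <- expression[shared]
  n <- length(shared)

  fit <- stats::lm(y ~ x)
  r2 <- summary(fit)$r.squared
  adj <- 1 - (1 - r2) * (n - 1) / (n - 2)

  # piecewise: flat below breakpoint c, linear above; profile c over interior
  # observed x values (3 effective parameters: intercept, slope, breakpoint)
  cands <- sort(unique(x))
  cands <- cands[cands > min(x) & cands < max(x)]
  pw_c <- NA_real_; pw_r2 <- NA_real_; pw_adj <- NA_real_
  if (length(cands)) {
    sse <- vapply(cands, function(cc) {
      z <- pmax(x - cc, 0)
      sum(stats::lm(y ~ z)$residuals^2)
    }, 1.0)
    best <- which.min(sse)
    pw_c <- cands[best]
    tss <- sum((y - mean(y))^2)
    pw_r2 <- 1 - sse[best] / tss
    pw_adj <- 1 - (1 - pw_r2) * (n - 1) / (n - 3)
  }
  tibble(n = n, r_squared = r2, adj_r_squared = adj,
         pw_breakpoint = pw_c, pw_r_squared = pw_r2, pw_adj_r_squared = pw_adj)
}
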