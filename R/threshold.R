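#' D'Agostino K-squared normality statistic
#'
#' Omnibus statistic combining the z-transformed sample skewness (D'Agostino's
#' transformation) and kurtosis (Anscombe-Glynn transformation):
#' `K2 = z(skew)^2 + z(kurtosis)^2`. Under normality it is approximately
#' chi-squared with 2 degrees of freedom; heavy tails and outliers inflate it.
#' The statistic is invariant to affine rescaling of the sample.
#'
#' @param values Numeric sample of at least 20 observations.
#' @return Nonnegative statistic.
#' @export
k2_statistic <- function(values) {
  n <- length(values)
  if (n < 20L) abort("K-squared needs at least 20 observations")
  if (stats::sd(values) == 0) abort("constant sample has undefined K-squared")
  z_skew(values)^2 + z_kurt(values)^2
}

# biased central moments
central_moment <- function(x, k) mean((x - mean(x))^k)

z_skew <- function(x) {
  n <- length(x)
  m2 <- central_moment(x, 2)
  b1 <- central_moment(x, 3) / m2^1.5
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(w2))
  alpha <- sqrt(2 / (w2 - 1))
  if (y == 0) y <- 1  # log-argument guard at exactly zero skew
  delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
}

z_kurt <- function(x) {
  n <- length(x)
  m2 <- central_moment(x, 2)
  b2 <- central_moment(x, 4) / m2^2
  e_b2 <- 3 * (n - 1) / (n + 1)
  var_b2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xs <- (b2 - e_b2) / sqrt(var_b2)
  sqrt_beta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqrt_beta1 * (2 / sqrt_beta1 + sqrt(1 + 4 / sqrt_beta1^2))
  term1 <- 1 - 2 / (9 * a)
  denom <- 1 + xs * sqrt(2 / (a - 4))
  term2 <- sign(denom) * abs((1 - 2 / a) / abs(denom))^(1 / 3)
  (term1 - term2) / sqrt(2 / (9 * a))
}

# Iterative-removal trajectory for one component: candidate prefixes of the
# |weight|-sorted gene list (tied |weights| removed as one block) and the
# K-squared of each remainder. Stops once K2 < stop_below or the remainder
# would fall under min_remainder.
k2_trajectory <- function(w, stop_below = 0, min_remainder = 20L) {
  ord <- order(abs(w), decreasing = TRUE)
  aw <- abs(w)[ord]
  # block boundaries: last index of each run of tied |weight|
  boundaries <- which(diff(aw) != 0)
  boundaries <- c(boundaries, length(w))
  prefixes <- 0L
  k2s <- k2_statistic(w)
  if (k2s[1L] >= stop_below) {
    for (b in boundaries) {
      if (length(w) - b < min_remainder) break
      prefixes <- c(prefixes, b)
      k2b <- k2_statistic(w[ord][-seq_len(b)])
      k2s <- c(k2s, k2b)
      if (k2b < stop_below) break
    }
  }
  list(order = ord, prefixes = prefixes, k2 = k2s,
       exhausted = all(k2s >= stop_below))
}

#' Extract the significant genes of a component
#'
#' Genes are removed in strictly descending absolute-coefficient order (tied
#' coefficients removed as a block) and the D'Agostino K-squared statistic of
#' the remaining distribution is recomputed after each removal. The removed
#' prefix at the first point where the statistic drops below `cutoff` is the
#' significant gene set; if the initial statistic is already below the cutoff
#' the set is empty. Removal stops with a warning once fewer than 20 genes
#' would remain.
#'
#' @param component Named numeric vector of gene coefficients (length >= 20).
#' @param cutoff K-squared cutoff (default 550, the regulon-calibrated value).
#' @return Tibble of significant genes with columns `gene`, `weight`, ordered
#'   by descending absolute weight.
#' @export
extract_significant_genes <- function(component, cutoff = 550) {
  if (is.null(names(component))) names(component) <- as.character(seq_along(component))
  if (cutoff <= 0) abort("cutoff must be positive")
  tr <- k2_trajectory(component, stop_below = cutoff)
  n_sig <- significant_prefix(tr, cutoff)
  if (tr$exhausted) {
    warn("K-squared never dropped below the cutoff before the minimum remainder; returning the removed prefix")
  }
  idx <- tr$order[seq_len(n_sig)]
  tibble(gene = names(component)[idx], weight = unname(component[idx]))
}

# Number of genes in the significant prefix for a given cutoff, reusing a
# trajectory computed with stop_below <= cutoff.
significant_prefix <- function(tr, cutoff) {
  hit <- which(tr$k2 < cutoff)
  if (length(hit)) tr$prefixes[hit[1L]] else tr$prefixes[length(tr$prefixes)]
}

#' Orient an i-modulon so positive genes dominate
#'
#' Independent components have no canonical sign; an i-modulon whose negative
#' genes outnumber its positive genes is flipped (weights, full component, and
#' activity row negated together, leaving the reconstruction unchanged). Equal
#' counts leave the i-modulon untouched.
#'
#' @param weights Named numeric vector of significant gene weights.
#' @param component Full component vector.
#' @param activity Activity row for the component.
#' @return List with `weights`, `component`, `activity`, `flipped`.
#' @export
orient_imodulon <- function(weights, component, activity) {
  flip <- sum(weights < 0) > sum(weights > 0)
  if (flip) {
    weights <- -weights; component <- -component; activity <- -activity
  }
  list(weights = weights, component = component, activity = activity,
       flipped = flip)
}

decomposition_s <- function(x) {
  if (inherits(x, "imod_decomposition")) x$S else as.matrix(x)
}

# Link components to their best single regulon: top-`top_n` |weight| genes per
# component, Fisher tested against every regulon, BH across the whole
# component-by-regulator family.
link_components <- function(s, rt, link_fdr = 1e-5, top_n = 20L) {
  universe <- gene_universe(rt)
  regs <- unique(rt$regulator)
  reg_sets <- lapply(regs, function(r) regulon_genes(rt, r))
  names(reg_sets) <- regs
  recs <- purrr::map(seq_len(ncol(s)), function(j) {
    top <- rownames(s)[order(abs(s[, j]), decreasing = TRUE)[seq_len(min(top_n, nrow(s)))]]
    p <- vapply(reg_sets, function(g) fisher_enrichment(top, g, universe)$p_value, 1.0)
    tibble(component = j, regulator = regs, p_value = unname(p))
  })
  fam <- dplyr::bind_rows(recs)
  fam$fdr <- stats::p.adjust(fam$p_value, method = "BH")
  fam |>
    filter(.data$fdr < link_fdr) |>
    group_by(.data$component) |>
    dplyr::slice_min(.data$p_value, n = 1, with_ties = FALSE) |>
    ungroup()
}

#' Calibrate the K-squared cutoff against known regulons
#'
#' Each component is first linked to the regulator whose regulon is most
#' enriched among the component's 20 largest-|weight| genes (Fisher's exact
#' test, BH FDR < `link_fdr`); unlinked components are excluded. The cutoff
#' grid is then scanned and the value maximizing the mean F1-score between
#' each linked component's significant gene set and its linked regulon is
#' returned, ties broken toward the smaller cutoff. The regulator link is
#' fixed before the scan and not recomputed per cutoff.
#'
#' @param x An `imod_decomposition` or component matrix `S`.
#' @param regulon_table An `imod_regulon` table.
#' @param grid Candidate cutoffs (default 200 to 1000 in steps of 50).
#' @param link_fdr FDR threshold for the linking step (default 1e-5).
#' @param top_n Genes used for linking (default 20).
#' @return List with `cutoff` (the calibrated value), `curve` (tibble of
#'   cutoff vs mean F1), and `links` (tibble of component-regulator links).
#' @export
scan_cutoff <- function(x, regulon_table, grid = seq(200, 1000, by = 50),
                        link_fdr = 1e-5, top_n = 20L) {
  s <- decomposition_s(x)
  if (nrow(regulon_table) == 0L) abort("regulon table is empty")
  links <- link_components(s, regulon_table, link_fdr, top_n)
  if (nrow(links) == 0L) {
    abort("no component links to any regulon; use the default cutoff of 550")
  }
  grid <- sort(grid)
  trajs <- lapply(links$component, function(j) {
    w <- s[, j]; names(w) <- rownames(s)
    k2_trajectory(w, stop_below = min(grid))
  })
  reg_sets <- lapply(links$regulator, function(r) regulon_genes(regulon_table, r))
  f1_mat <- vapply(seq_along(grid), function(gi) {
    vapply(seq_along(trajs), function(ci) {
      tr <- trajs[[ci]]
      n_sig <- significant_prefix(tr, grid[gi])
      genes <- rownames(s)[tr$order[seq_len(n_sig)]]
      k <- length(intersect(genes, reg_sets[[ci]]))
      precision_recall_f1(k, length(genes), length(reg_sets[[ci]]))$f1
    }, 1.0)
  }, numeric(length(trajs)))
  f1_mat <- matrix(f1_mat, nrow = length(trajs))
  mean_f1 <- colMeans(f1_mat)
  best <- grid[which.max(mean_f1)]   # which.max takes the first (smallest) tie
  list(cutoff = best,
       curve = tibble(cutoff = grid, mean_f1 = mean_f1),
       links = links)
}

#' Cross-validated cutoff calibration
#'
#' Components are split at random into `folds` groups. For each fold the
#' cutoff is trained with [scan_cutoff()] on the remaining components and
#' applied to the held-out ones, whose significant gene sets are then linked
#' to the regulon with the lowest Fisher p-value (BH FDR < `link_fdr`). The
#' per-fold enriched fraction and mean precision of linked i-modulons measure
#' how well the trained cutoff generalizes.
#'
#' @inheritParams scan_cutoff
#' @param folds Number of folds (default 3).
#' @param seed Seed for the random component partition.
#' @return Tibble with one row per fold: `fold`, `cutoff`, `n_test`,
#'   `n_linked`, `enriched_fraction`, `mean_precision`.
#' @export
cross_validated_cutoff <- function(x, regulon_table, folds = 3L, seed = 1L,
                                   grid = seq(200, 1000, by = 50),
                                   link_fdr = 1e-5, top_n = 20L) {
  s <- decomposition_s(x)
  nc <- ncol(s)
  if (nc < folds) abort("need at least as many components as folds")
  assignment <- with_seed(seed, sample(rep_len(seq_len(folds), nc)))
  universe <- gene_universe(regulon_table)
  regs <- unique(regulon_table$regulator)
  reg_sets <- lapply(regs, function(r) regulon_genes(regulon_table, r))
  names(reg_sets) <- regs

  out <- vector("list", folds)
  for (f in seq_len(folds)) {
    test_idx <- which(assignment == f)
    train_idx <- which(assignment != f)
    sc <- tryCatch(
      scan_cutoff(s[, train_idx, drop = FALSE], regulon_table, grid = grid,
                  link_fdr = link_fdr, top_n = top_n),
      error = function(e) NULL)
    if (is.null(sc)) {
      warn(sprintf("fold %d skipped: no linked components in the training set", f))
      next
    }
    # apply trained cutoff to held-out components, then link the i-modulons
    fam <- purrr::map(test_idx, function(j) {
      w <- s[, j]; names(w) <- rownames(s)
      sig <- suppressWarnings(extract_significant_genes(w, sc$cutoff))
      if (nrow(sig) == 0L) return(NULL)
      p <- vapply(reg_sets, function(g) fisher_enrichment(sig$gene, g, universe)$p_value, 1.0)
      tibble(component = j, regulator = regs, p_value = unname(p),
             n_genes = nrow(sig),
             k = vapply(reg_sets, function(g) length(intersect(sig$gene, g)), 1L))
    })
    fam <- dplyr::bind_rows(fam)
    n_linked <- 0L
    mean_prec <- NA_real_
    if (nrow(fam) > 0L) {
      fam$fdr <- stats::p.adjust(fam$p_value, method = "BH")
      linked <- fam |>
        filter(.data$fdr < link_fdr) |>
        group_by(.data$component) |>
        dplyr::slice_min(.data$p_value, n = 1, with_ties = FALSE) |>
        ungroup()
      n_linked <- nrow(linked)
      if (n_linked > 0L) mean_prec <- mean(linked$k / linked$n_genes)
    }
    out[[f]] <- tibble(fold = f, cutoff = sc$cutoff,
                       n_test = length(test_idx), n_linked = n_linked,
                       enriched_fraction = n_linked / length(test_idx),
                       mean_precision = mean_prec)
  }
  dplyr::bind_rows(out)
}

#' Threshold a decomposition into i-modulons
#'
#' Applies [extract_significant_genes()] to every component, drops components
#' with no significant genes, and orients each i-modulon so its positive genes
#' are at least as numerous as its negative genes (flipping component and
#' activity row consistently).
#'
#' @param decomposition An `imod_decomposition`.
#' @param cutoff K-squared cutoff (default 550); calibrate with
#'   [scan_cutoff()] when a regulon table is available.
#' @return An object of class `imod_set`: list with `gene_table` (tibble
#'   `imodulon`, `gene`, `weight`), oriented `components` (S) and `activities`
#'   (A) matrices, `thresholds` summary tibble, and empty `enrichment` /
#'   `category` slots to be filled by [enrich_imodulons()] and
#'   [categorize_imodulons()].
#' @export
compute_imodulons <- function(decomposition, cutoff = 550) {
  s <- decomposition$S
  a <- decomposition$A
  rows <- list(); thr <- list()
  s_or <- s; a_or <- a
  keep <- logical(ncol(s))
  for (j in seq_len(ncol(s))) {
    w <- s[, j]; names(w) <- rownames(s)
    sig <- suppressWarnings(extract_significant_genes(w, cutoff))
    if (nrow(sig) == 0L) next
    keep[j] <- TRUE
    wv <- stats::setNames(sig$weight, sig$gene)
    orient <- orient_imodulon(wv, s[, j], a[j, ])
    s_or[, j] <- orient$component
    a_or[j, ] <- orient$activity
    name <- colnames(s)[j] %||% sprintf("IM%02d", j)
    rows[[length(rows) + 1L]] <- tibble(imodulon = name,
                                        gene = names(orient$weights),
                                        weight = unname(orient$weights))
    thr[[length(thr) + 1L]] <- tibble(imodulon = name, component_index = j,
                                      cutoff = cutoff,
                                      n_genes = length(orient$weights),
                                      n_positive = sum(orient$weights > 0),
                                      n_negative = sum(orient$weights < 0),
                                      flipped = orient$flipped)
  }
  if (!length(rows)) warn("no component yielded significant genes")
  structure(list(gene_table = dplyr::bind_rows(rows),
                 components = s_or[, keep, drop = FALSE],
                 activities = a_or[keep, , drop = FALSE],
                 thresholds = dplyr::bind_rows(thr),
                 cutoff = cutoff,
                 enrichment = NULL,
                 category = NULL),
            class = "imod_set")
}

#' @export
print.imod_set <- function(x, ...) {
  cat(sprintf("<imod_set> %d i-modulons, %d gene memberships (cutoff %g)\n",
              nrow(x$thresholds), nrow(x$gene_table), x$cutoff))
  invisible(x)
}

#' Genes of one i-modulon
#'
#' @param iset An `imod_set`.
#' @param imodulon I-modulon name.
#' @return Tibble of `gene`, `weight` rows.
#' @export
imodulon_genes <- function(iset, imodulon) {
  out <- iset$gene_table[iset$gene_table$imodulon == imodulon, ]
  if (nrow(out) == 0L) abort(sprintf("unknown i-modulon '%s'", imodulon))
  out
}

#' Serialize an i-modulon set to JSON
#'
#' @param iset An `imod_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_imodulons <- function(iset, path) {
  payload <- list(cutoff = iset$cutoff,
                  thresholds = iset$thresholds,
                  genes = iset$gene_table,
                  enrichment = iset$enrichment,
                  category = as.list(iset$category))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  invisible(path)
}
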