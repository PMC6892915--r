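#' Estimate the decomposition dimension by PCA
#'
#' Returns the smallest number of principal components whose cumulative
#' variance reaches `variance_fraction` of the total. Observations are genes,
#' variables are samples; columns are mean-centered before the singular value
#' decomposition, matching the whitening used by the ICA step.
#'
#' @param x Centered expression matrix or data frame (genes x samples), or an
#'   `imod_compendium`.
#' @param variance_fraction Fraction of variance to reconstruct (default 0.99).
#' @return Integer component count.
#' @export
estimate_dimension <- function(x, variance_fraction = 0.99) {
  m <- compendium_values(x)
  if (all(m == 0)) abort("cannot estimate dimension of an all-zero matrix")
  mc <- sweep(m, 2, colMeans(m))
  d2 <- svd(mc, nu = 0, nv = 0)$d^2
  cum <- cumsum(d2) / sum(d2)
  k <- which(cum >= variance_fraction)[1L]
  max(1L, min(as.integer(k), nrow(m), ncol(m)))
}

compendium_values <- function(x) {
  if (inherits(x, "imod_compendium")) return(x$values)
  as_expr_matrix(x, "x")
}

# PCA whitening shared across restarts: column-center, retain k singular
# directions, scale gene scores to unit variance. `zt` holds the whitened
# gene scores (genes x k, zero column means), `fk` the factor mapping an
# unmixing matrix W to activities: S_raw = zt W^T, A_raw = W fk, and
# S_raw A_raw = U_k D_k V_k^T (the retained part of the centered data).
whiten_expression <- function(m, k) {
  mc <- sweep(m, 2, colMeans(m))
  sv <- svd(mc)
  pos <- sum(sv$d > max(dim(mc)) * .Machine$double.eps * sv$d[1L])
  if (k > pos) abort(sprintf("n_components = %d exceeds the numerical rank %d", k, pos))
  n <- nrow(mc)
  list(zt = sv$u[, seq_len(k), drop = FALSE] * sqrt(n),
       fk = (sv$d[seq_len(k)] * t(sv$v[, seq_len(k), drop = FALSE])) / sqrt(n))
}

# One FastICA solve on pre-whitened data from a seeded random init.
ica_from_whitened <- function(wh, tol, seed, max_iter, genes, samples) {
  k <- ncol(wh$zt)
  w0 <- with_seed(seed, qr.Q(qr(matrix(stats::rnorm(k * k), k))))
  core <- fastica_sym_core(t(wh$zt), w0, tol, as.integer(max_iter), 1.0)
  s <- wh$zt %*% t(core$W)
  a <- core$W %*% wh$fk
  nrm <- sqrt(colSums(s^2))
  s <- sweep(s, 2, nrm, "/")
  a <- a * nrm
  rownames(s) <- genes
  colnames(a) <- samples
  list(S = s, A = a, converged = core$converged, iter = core$iter,
       seed = as.integer(seed))
}

#' One FastICA restart
#'
#' Runs FastICA (logcosh contrast, symmetric/parallel updates, PCA whitening to
#' `n_components` dimensions) from a random orthonormal initialization drawn
#' under `seed`. Returned components are standardized: each column of `S` has
#' mean 0 and unit L2 norm, with the activity rows of `A` rescaled so `S %*% A`
#' is unchanged and reconstructs the whitened-retained part of `x`.
#'
#' @inheritParams estimate_dimension
#' @param n_components Number of components to extract.
#' @param tol Convergence tolerance (default 1e-8).
#' @param seed Integer seed for the random initialization.
#' @param max_iter Iteration cap per restart (default 200).
#' @return List with `S` (genes x components), `A` (components x samples),
#'   `converged`, `iter`, `seed`.
#' @export
run_ica_restart <- function(x, n_components, tol = 1e-8, seed = 1L, max_iter = 200L) {
  m <- compendium_values(x)
  if (n_components > min(dim(m))) abort("n_components exceeds min(genes, samples)")
  wh <- whiten_expression(m, n_components)
  ica_from_whitened(wh, tol, seed, max_iter, rownames(m), colnames(m))
}

#' Correlation distance between components
#'
#' `d = 1 - |Pearson correlation|`: 0 for identical components up to sign and
#' scale, 1 for uncorrelated ones.
#'
#' @param x,y Numeric component vectors of equal length and nonzero variance.
#' @return Distance in `[0, 1]`.
#' @export
component_distance <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) abort("zero-variance component")
  1 - abs(stats::cor(x, y))
}

# Full pairwise correlation-distance matrix between columns of s1 and s2.
component_distance_matrix <- function(s1, s2 = NULL) {
  if (is.null(s2)) s2 <- s1
  d <- 1 - abs(suppressWarnings(stats::cor(s1, s2)))
  d[is.na(d)] <- 1
  d
}

# DBSCAN over a precomputed distance matrix. Neighborhoods use d <= eps and
# include the point itself; points not density-reachable from a core point get
# cluster 0 (noise).
dbscan_distance <- function(d, eps, min_pts) {
  n <- nrow(d)
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(nb, length, 1L) >= min_pts
  labels <- integer(n)   # 0 = noise/unvisited
  visited <- logical(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (visited[i] || !core[i]) next
    cl <- cl + 1L
    queue <- i
    visited[i] <- TRUE
    labels[i] <- cl
    while (length(queue)) {
      p <- queue[[1L]]
      queue <- queue[-1L]
      for (q in nb[[p]]) {
        if (labels[q] == 0L) labels[q] <- cl
        if (!visited[q] && core[q]) {
          visited[q] <- TRUE
          queue <- c(queue, q)
        }
      }
    }
  }
  labels
}

#' Cluster pooled ICA components
#'
#' Pools components from all restarts and clusters them with DBSCAN under the
#' correlation distance (`eps = 0.1`), with the minimum neighborhood size set
#' to half the number of restarts. The number of clusters estimates the data's
#' dimensionality; unclustered components are discarded as unreproducible.
#'
#' @param s_pool Matrix of pooled components (genes x pooled runs).
#' @param eps DBSCAN neighborhood radius in correlation distance (default 0.1).
#' @param min_members Minimum neighborhood size; default
#'   `ceiling(0.5 * n_restarts)`.
#' @param n_restarts Number of restarts that produced the pool (used for the
#'   default `min_members`).
#' @return Integer vector of cluster labels per pooled component (0 = noise).
#' @export
cluster_runs <- function(s_pool, eps = 0.1, min_members = NULL, n_restarts = NULL) {
  if (is.null(min_members)) {
    if (is.null(n_restarts)) abort("supply `min_members` or `n_restarts`")
    min_members <- ceiling(0.5 * n_restarts)
  }
  d <- component_distance_matrix(s_pool)
  labels <- dbscan_distance(d, eps, min_members)
  if (!any(labels > 0L)) warn("DBSCAN found no clusters; decomposition is empty")
  labels
}

#' Sign-align a cluster and take its centroid
#'
#' Members are mutually sign-aligned (flipped to agree with the first member,
#' with paired activity rows flipped consistently), averaged, and the centroid
#' is oriented so the gene with the largest absolute coefficient has a
#' positive weight (ties broken toward the lowest gene index). The component
#' centroid is renormalized to unit L2 norm and the activity centroid rescaled
#' by the same factor, so the reconstruction `S %*% A` is unchanged by the
#' renormalization.
#'
#' @param s_members Matrix (genes x members) of cluster member components.
#' @param a_members Matrix (members x samples) of the paired activity rows.
#' @return List with unit-norm `component` and matching `activity` vectors.
#' @export
align_and_centroid <- function(s_members, a_members) {
  s_members <- as.matrix(s_members)
  a_members <- matrix(a_members, nrow = ncol(s_members))
  if (ncol(s_members) == 0L) abort("empty cluster")
  # Mutual alignment by correlation sign against the first member: flipping
  # each member on its own max-|coefficient| gene is unstable when a
  # component's strongest positive and negative weights are nearly tied
  # (run-to-run noise then flips the argmax and the centroid cancels).
  if (ncol(s_members) > 1L) {
    for (j in 2:ncol(s_members)) {
      if (sum(s_members[, j] * s_members[, 1L]) < 0) {
        s_members[, j] <- -s_members[, j]
        a_members[j, ] <- -a_members[j, ]
      }
    }
  }
  comp <- rowMeans(s_members)
  act <- colMeans(a_members)
  # sign convention applied to the centroid: max-|coefficient| gene positive
  top <- which.max(abs(comp))   # ties: lowest index
  if (comp[top] < 0) {
    comp <- -comp
    act <- -act
  }
  nrm <- sqrt(sum(comp^2))
  if (nrm == 0) abort("degenerate cluster centroid")
  list(component = comp / nrm, activity = act * nrm)
}

# One repetition: restarts -> pool -> DBSCAN -> sign-aligned centroids.
# Restarts hitting the iteration cap are kept (flagged): the restart pooling
# plus DBSCAN density filter is what separates stable components from
# unconverged noise directions. Only non-finite results are dropped.
decompose_once <- function(m, n_components, n_restarts, eps, tol, max_iter, seeds,
                           whitened = NULL) {
  if (is.null(whitened)) whitened <- whiten_expression(m, n_components)
  runs <- vector("list", n_restarts)
  usable <- logical(n_restarts)
  converged <- logical(n_restarts)
  for (r in seq_len(n_restarts)) {
    run <- ica_from_whitened(whitened, tol, seeds[r], max_iter,
                             rownames(m), colnames(m))
    usable[r] <- all(is.finite(run$S)) && all(is.finite(run$A))
    converged[r] <- run$converged
    runs[[r]] <- run
  }
  if (!all(converged)) {
    inform(sprintf("%d of %d restarts hit the iteration cap (kept, flagged)",
                   sum(!converged), n_restarts))
  }
  if (!all(usable)) {
    inform(sprintf("%d of %d restarts produced non-finite output and were excluded",
                   sum(!usable), n_restarts))
  }
  runs <- runs[usable]
  if (length(runs) < 2L) abort("fewer than 2 successful restarts")
  s_pool <- do.call(cbind, lapply(runs, `[[`, "S"))
  a_pool <- do.call(rbind, lapply(runs, `[[`, "A"))
  labels <- cluster_runs(s_pool, eps = eps, n_restarts = n_restarts)
  ncl <- max(labels)
  if (ncl == 0L) {
    return(list(S = matrix(numeric(0), nrow(m), 0), A = matrix(numeric(0), 0, ncol(m)),
                cluster_sizes = integer(0)))
  }
  s_cent <- matrix(0, nrow(m), ncl)
  a_cent <- matrix(0, ncl, ncol(m))
  sizes <- integer(ncl)
  for (k in seq_len(ncl)) {
    idx <- which(labels == k)
    sizes[k] <- length(idx)
    cen <- align_and_centroid(s_pool[, idx, drop = FALSE], a_pool[idx, , drop = FALSE])
    s_cent[, k] <- cen$component
    a_cent[k, ] <- cen$activity
  }
  rownames(s_cent) <- rownames(m)
  colnames(a_cent) <- colnames(m)
  list(S = s_cent, A = a_cent, cluster_sizes = sizes)
}

# Greedy nearest-neighbour matching between reference components (cols of s_ref)
# and candidate components (cols of s_new); returns logical: ref matched?
greedy_match <- function(s_ref, s_new, d_max) {
  matched <- logical(ncol(s_ref))
  if (ncol(s_ref) == 0L || ncol(s_new) == 0L) return(matched)
  d <- component_distance_matrix(s_ref, s_new)
  repeat {
    best <- which(d == min(d), arr.ind = TRUE)[1L, ]
    if (d[best[1L], best[2L]] >= d_max) break
    matched[best[1L]] <- TRUE
    d[best[1L], ] <- Inf
    d[, best[2L]] <- Inf
    if (all(is.infinite(d))) break
  }
  matched
}

#' Robust independent components of a compendium
#'
#' Runs the restart-cluster-centroid procedure `n_repetitions` times with
#' disjoint seed streams and keeps only components that every repetition
#' reproduces at correlation distance below `d_max`; these are the robust
#' components. The reported `S`/`A` are the first repetition's matched
#' centroids, ordered by descending L2 norm of the activity rows.
#'
#' @inheritParams estimate_dimension
#' @param n_components Number of components per ICA run; `NULL` estimates it
#'   with [estimate_dimension()].
#' @param n_restarts FastICA restarts per repetition (default 256).
#' @param n_repetitions Clustering repetitions for the robustness filter
#'   (default 100).
#' @param eps DBSCAN radius (default 0.1).
#' @param d_max Cross-repetition matching threshold (default 0.1).
#' @param tol FastICA convergence tolerance (default 1e-8).
#' @param max_iter FastICA iteration cap (default 200).
#' @param variance_fraction PCA variance fraction when estimating the
#'   dimension (default 0.99).
#' @param seed Master seed; all restart seeds derive from it deterministically.
#' @return An `imod_decomposition`: list with `S`, `A`, `ordering` metadata,
#'   `cluster_sizes`, `robustness_count`, and the run parameters.
#' @export
robust_components <- function(x, n_components = NULL, n_restarts = 256L,
                              n_repetitions = 100L, eps = 0.1, d_max = 0.1,
                              tol = 1e-8, max_iter = 200L,
                              variance_fraction = 0.99, seed = 42L) {
  if (n_repetitions < 1L) abort("n_repetitions must be at least 1")
  m <- compendium_values(x)
  if (is.null(n_components)) n_components <- estimate_dimension(m, variance_fraction)
  seeds <- matrix(derive_seeds(seed, n_restarts * n_repetitions),
                  nrow = n_restarts)
  whitened <- whiten_expression(m, n_components)  # deterministic, shared
  reps <- vector("list", n_repetitions)
  for (r in seq_len(n_repetitions)) {
    reps[[r]] <- decompose_once(m, n_components, n_restarts, eps, tol,
                                max_iter, seeds[, r], whitened = whitened)
  }
  ref <- reps[[1L]]
  n_ref <- ncol(ref$S)
  robustness <- rep(1L, n_ref)
  if (n_repetitions > 1L) {
    for (r in 2:n_repetitions) {
      robustness <- robustness + as.integer(greedy_match(ref$S, reps[[r]]$S, d_max))
    }
  }
  keep <- robustness == n_repetitions
  s <- ref$S[, keep, drop = FALSE]
  a <- ref$A[keep, , drop = FALSE]
  sizes <- ref$cluster_sizes[keep]
  rob <- robustness[keep]
  ord <- order(rowSums(a^2), decreasing = TRUE)
  s <- s[, ord, drop = FALSE]
  a <- a[ord, , drop = FALSE]
  comp_names <- sprintf("IC%02d", seq_len(ncol(s)))
  colnames(s) <- comp_names
  rownames(a) <- comp_names
  new_decomposition(s, a,
                    cluster_sizes = sizes[ord], robustness_count = rob[ord],
                    n_restarts = n_restarts, n_repetitions = n_repetitions,
                    params = list(n_components = n_components, eps = eps,
                                  d_max = d_max, tol = tol,
                                  variance_fraction = variance_fraction,
                                  seed = as.integer(seed)))
}

#' Construct a decomposition object
#'
#' Low-level constructor pairing a component matrix `S` (genes x components)
#' with an activity matrix `A` (components x samples).
#'
#' @param S Component matrix, unit-norm columns.
#' @param A Activity matrix.
#' @param cluster_sizes,robustness_count,n_restarts,n_repetitions,params
#'   Provenance metadata (optional).
#' @return An object of class `imod_decomposition`.
#' @export
new_decomposition <- function(S, A, cluster_sizes = NULL, robustness_count = NULL,
                              n_restarts = NA_integer_, n_repetitions = NA_integer_,
                              params = list()) {
  S <- as.matrix(S); A <- as.matrix(A)
  if (ncol(S) != nrow(A)) abort("ncol(S) must equal nrow(A)")
  structure(list(S = S, A = A,
                 cluster_sizes = cluster_sizes,
                 robustness_count = robustness_count,
                 n_restarts = n_restarts, n_repetitions = n_repetitions,
                 params = params),
            class = "imod_decomposition")
}

#' @export
print.imod_decomposition <- function(x, ...) {
  cat(sprintf("<imod_decomposition> %d robust components over %d genes x %d samples\n",
              ncol(x$S), nrow(x$S), ncol(x$A)))
  if (!is.na(x$n_restarts)) {
    cat(sprintf("  %d restarts x %d repetitions\n", x$n_restarts, x$n_repetitions))
  }
  invisible(x)
}

#' Cumulative explained variance of the leading components
#'
#' `CEV(K) = 1 - TSS(X - S[,1:K] A[1:K,]) / TSS(X)` where `TSS` is the sum of
#' squared entries. With zero components the CEV is 0; an exact factorization
#' reaches 1.
#'
#' @inheritParams estimate_dimension
#' @param decomposition An `imod_decomposition` (components already ordered).
#' @param K Number of leading components; `NULL` evaluates the whole curve.
#' @return A single CEV value, or a tibble with columns `K` and `cev` when `K`
#'   is `NULL`.
#' @export
cumulative_explained_variance <- function(x, decomposition, K = NULL) {
  m <- compendium_values(x)
  tss <- sum(m^2)
  if (tss == 0) abort("TSS(X) is zero")
  cev_at <- function(k) {
    if (k == 0L) return(0)
    rec <- decomposition$S[, seq_len(k), drop = FALSE] %*%
      decomposition$A[seq_len(k), , drop = FALSE]
    1 - sum((m - rec)^2) / tss
  }
  if (!is.null(K)) {
    if (K < 0 || K > ncol(decomposition$S)) abort("K out of range")
    return(cev_at(as.integer(K)))
  }
  ks <- 0:ncol(decomposition$S)
  tibble(K = ks, cev = vapply(ks, cev_at, 1.0))
}

#' Write a decomposition to TSV matrices plus a JSON sidecar
#'
#' @param decomposition An `imod_decomposition`.
#' @param dir Output directory (created if needed).
#' @param digits Significant digits for the TSV serialization (default 10).
#' @return The directory path, invisibly.
#' @export
write_decomposition <- function(decomposition, dir, digits = 10) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_tsv(decomposition$S, file.path(dir, "S.tsv"), id = "gene", digits = digits)
  write_matrix_tsv(decomposition$A, file.path(dir, "A.tsv"), id = "component", digits = digits)
  side <- list(n_restarts = decomposition$n_restarts,
               n_repetitions = decomposition$n_repetitions,
               cluster_sizes = decomposition$cluster_sizes,
               robustness_count = decomposition$robustness_count,
               params = decomposition$params,
               serialized_digits = digits)
  jsonlite::write_json(side, file.path(dir, "decomposition.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a decomposition written by [write_decomposition()]
#'
#' @param dir Directory containing `S.tsv`, `A.tsv`, `decomposition.json`.
#' @return An `imod_decomposition`.
#' @export
read_decomposition <- function(dir) {
  s <- read_matrix_tsv(file.path(dir, "S.tsv"), id = "gene")
  a <- read_matrix_tsv(file.path(dir, "A.tsv"), id = "component")
  side_path <- file.path(dir, "decomposition.json")
  side <- if (file.exists(side_path)) jsonlite::read_json(side_path, simplifyVector = TRUE) else list()
  new_decomposition(s, a,
                    cluster_sizes = side$cluster_sizes,
                    robustness_count = side$robustness_count,
                    n_restarts = side$n_restarts %||% NA_integer_,
                    n_repetitions = side$n_repetitions %||% NA_integer_,
                    params = side$params %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
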