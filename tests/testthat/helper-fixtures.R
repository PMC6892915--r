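# Shared fixture builders and independent oracles used across test files.
# Everything is generated in code; no data files.

# small counts table with named genes/samples
tiny_counts <- function(values, genes = NULL, samples = NULL) {
  m <- matrix(values, nrow = length(values) / max(1, length(samples %||% 1)),
              byrow = TRUE)
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(m)))
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, samples)
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# metadata for a matrix whose columns fall into the given replicate groups
meta_for <- function(samples, groups = samples, reference = character()) {
  tibble::tibble(sample_id = samples, project = "p1", condition = groups,
                 replicate_group = groups,
                 is_reference = samples %in% reference)
}

# planted component: n weights of background noise sd bg, with `members`
# getting large weights
planted_component <- function(n, members, weight = 1, bg = 0.01, seed = 1) {
  withr::with_seed(seed, {
    w <- stats::rnorm(n, 0, bg)
    w[members] <- weight * sample(c(1, 1, 1, -1), length(members), replace = TRUE)
    names(w) <- sprintf("g%04d", seq_len(n))
    w
  })
}

# Independent oracle: two-sided Fisher p-value by enumerating the
# hypergeometric support and summing probabilities no larger than the
# observed table's (the classical definition, computed directly from dhyper
# rather than through fisher.test).
fisher_oracle <- function(k, n, K, N) {
  support <- max(0L, n + K - N):min(n, K)
  probs <- stats::dhyper(support, K, N - K, n)
  p_obs <- stats::dhyper(k, K, N - K, n)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Independent oracle: brute-force significant-gene extraction. Scans every
# prefix of the |coefficient|-sorted gene list (respecting tie blocks) and
# returns the shortest prefix whose complement has K-squared below the
# cutoff; falls back to the largest scanned prefix when none qualifies.
brute_force_prefix <- function(w, cutoff, min_remainder = 20L) {
  ord <- order(abs(w), decreasing = TRUE)
  aw <- abs(w)[ord]
  boundaries <- c(0L, which(diff(aw) != 0), length(w))
  boundaries <- unique(boundaries[length(w) - boundaries >= min_remainder])
  for (b in boundaries) {
    remainder <- if (b == 0L) w[ord] else w[ord][-seq_len(b)]
    if (imodkit::k2_statistic(remainder) < cutoff) {
      return(names(w)[ord][seq_len(b)])
    }
  }
  names(w)[ord][seq_len(boundaries[length(boundaries)])]
}

# Small planted-factor expression matrix: k sparse unit-norm sources with
# block activities, plus iid noise. Used where the full generator is heavier
# than needed.
planted_matrix <- function(n_genes = 500, n_samples = 30, k = 5,
                           members_per = 15, noise = 0.02, seed = 1) {
  withr::with_seed(seed, {
    s0 <- matrix(0, n_genes, k)
    pool <- sample(n_genes)
    for (j in seq_len(k)) {
      idx <- pool[(j - 1) * members_per + seq_len(members_per)]
      w <- stats::runif(members_per, 0.5, 1) *
        sample(c(1, 1, 1, -1), members_per, replace = TRUE)
      s0[idx, j] <- w / sqrt(sum(w^2))
    }
    a0 <- matrix(0, k, n_samples)
    for (j in seq_len(k)) {
      on <- sample(n_samples, ceiling(n_samples / 3))
      a0[j, on] <- sample(c(-1, 1), length(on), replace = TRUE) *
        stats::runif(length(on), 8, 15)
    }
    x <- s0 %*% a0 + matrix(stats::rnorm(n_genes * n_samples, 0, noise), n_genes)
    dimnames(x) <- list(sprintf("g%04d", seq_len(n_genes)),
                        sprintf("s%02d", seq_len(n_samples)))
    list(X = x, S = s0, A = a0)
  })
}

# regulon table from a named list of gene-id vectors
rt_from_list <- function(regulons, universe) {
  df <- dplyr::bind_rows(purrr::imap(regulons, function(g, r) {
    tibble::tibble(regulator = r, gene = g)
  }))
  suppressMessages(imodkit::regulon_table(df, universe))
}

# expression tibble (leading gene column) -> named matrix
as_expr_matrix_for_test <- function(df) {
  m <- as.matrix(df[-1])
  rownames(m) <- df[[1]]
  m
}
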