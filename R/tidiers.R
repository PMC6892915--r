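#' @importFrom generics tidy glance augment
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a decomposition: one row per robust component
#'
#' @param x An `imod_decomposition`.
#' @param ... Unused.
#' @return Tibble with `component`, `activity_norm` (L2 norm of the activity
#'   row, the ordering criterion), `cluster_size`, `robustness_count`.
#' @method tidy imod_decomposition
#' @export
tidy.imod_decomposition <- function(x, ...) {
  tibble(component = colnames(x$S) %||% as.character(seq_len(ncol(x$S))),
         activity_norm = sqrt(rowSums(x$A^2)),
         cluster_size = x$cluster_sizes %||% rep(NA_integer_, ncol(x$S)),
         robustness_count = x$robustness_count %||% rep(NA_integer_, ncol(x$S)))
}

#' @rdname tidy.imod_decomposition
#' @method glance imod_decomposition
#' @export
glance.imod_decomposition <- function(x, ...) {
  tibble(n_genes = nrow(x$S), n_samples = ncol(x$A),
         n_components = ncol(x$S),
         n_restarts = x$n_restarts, n_repetitions = x$n_repetitions)
}

#' Tidy an i-modulon set: the gene membership table
#'
#' @param x An `imod_set`.
#' @param ... Unused.
#' @return The `gene_table` tibble (`imodulon`, `gene`, `weight`), joined
#'   with per-i-modulon category when available.
#' @method tidy imod_set
#' @export
tidy.imod_set <- function(x, ...) {
  out <- x$gene_table
  if (!is.null(x$category)) {
    out <- left_join(out,
                     tibble(imodulon = names(x$category),
                            category = unname(x$category)),
                     by = "imodulon")
  }
  out
}

#' @rdname tidy.imod_set
#' @method glance imod_set
#' @export
glance.imod_set <- function(x, ...) {
  tibble(n_imodulons = nrow(x$thresholds),
         n_memberships = nrow(x$gene_table),
         cutoff = x$cutoff,
         n_regulatory = if (is.null(x$category)) NA_integer_ else sum(x$category == "regulatory"))
}

#' Tidy a replicate-noise model
#'
#' @param x An `imod_noise_model`.
#' @param ... Unused.
#' @return The underlying tibble (one row per i-modulon).
#' @method tidy imod_noise_model
#' @export
tidy.imod_noise_model <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @rdname tidy.imod_noise_model
#' @method glance imod_noise_model
#' @export
glance.imod_noise_model <- function(x, ...) {
  tibble(n_imodulons = nrow(x),
         n_degenerate = sum(x$degenerate),
         median_sdlog = stats::median(x$sdlog, na.rm = TRUE))
}
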