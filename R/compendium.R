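#' Build an expression compendium object
#'
#' A compendium bundles a genes-by-samples expression matrix (log-TPM or
#' reference-centered log fold change) with per-sample metadata. Every sample
#' must carry a replicate-group key; reference samples (wild-type grown under
#' the baseline condition) are flagged so activities computed downstream are
#' zero there by construction.
#'
#' @param expr Expression values: a data frame whose first column holds gene
#'   identifiers (remaining columns one per sample), or a numeric matrix with
#'   gene rownames.
#' @param metadata Data frame with columns `sample_id`, `project`, `condition`,
#'   `replicate_group`, `is_reference`. Missing `project` defaults to a single
#'   project label.
#' @param centered Logical; `TRUE` when `expr` is already centered on the
#'   reference samples.
#' @param reference_samples Character vector of sample identifiers used (or to
#'   be used) for centering. Defaults to the metadata's `is_reference` flags.
#' @return An object of class `imod_compendium`: a list with elements `values`
#'   (numeric matrix), `metadata` (tibble), `centered`, `reference_samples`.
#' @export
compendium <- function(expr, metadata, centered = FALSE, reference_samples = NULL) {
  values <- as_expr_matrix(expr, "expr")
  check_no_missing(values, "expression matrix")
  check_unique(rownames(values), "gene identifiers")
  check_unique(colnames(values), "sample identifiers")

  metadata <- as_tibble(metadata)
  if (!"sample_id" %in% names(metadata)) abort("metadata must have a `sample_id` column")
  if (!"replicate_group" %in% names(metadata)) abort("metadata must have a `replicate_group` column")
  if (anyNA(metadata$replicate_group)) abort("every sample needs a replicate-group key")
  if (!"condition" %in% names(metadata)) abort("metadata must have a `condition` column")
  if (!"project" %in% names(metadata)) metadata$project <- "project_1"
  if (!"is_reference" %in% names(metadata)) metadata$is_reference <- FALSE

  missing <- setdiff(colnames(values), metadata$sample_id)
  if (length(missing)) abort(sprintf("samples missing from metadata: %s", paste(utils::head(missing, 5), collapse = ", ")))
  metadata <- metadata[match(colnames(values), metadata$sample_id), ]

  if (is.null(reference_samples)) {
    reference_samples <- metadata$sample_id[metadata$is_reference]
  }
  unknown <- setdiff(reference_samples, colnames(values))
  if (length(unknown)) abort(sprintf("unknown reference sample(s): %s", paste(unknown, collapse = ", ")))

  if (isTRUE(centered) && length(reference_samples)) {
    dev <- max(abs(rowMeans(values[, reference_samples, drop = FALSE])))
    if (dev > 1e-9) abort("`centered = TRUE` but per-gene reference means are not 0")
  }

  structure(
    list(values = values, metadata = metadata,
         centered = isTRUE(centered),
         reference_samples = as.character(reference_samples)),
    class = "imod_compendium"
  )
}

#' @export
print.imod_compendium <- function(x, ...) {
  cat(sprintf("<imod_compendium> %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$centered) "centered" else "log-TPM"))
  cat(sprintf("  reference samples: %s\n",
              if (length(x$reference_samples)) paste(x$reference_samples, collapse = ", ") else "<none>"))
  invisible(x)
}

#' @method as_tibble imod_compendium
#' @export
as_tibble.imod_compendium <- function(x, ...) expr_as_tibble(x$values)

#' Compute log-TPM from fragment counts
#'
#' Per sample, counts are length-normalized to rates, scaled so transcripts
#' per million sum to 1e6, then transformed as `log2(TPM + 1)`.
#'
#' @param counts Nonnegative count table (data frame with leading gene column,
#'   or matrix with gene rownames).
#' @param lengths Per-gene lengths in nucleotides: named numeric vector or a
#'   two-column data frame (gene, length).
#' @return Tibble of log-TPM values with a leading `gene` column.
#' @export
compute_log_tpm <- function(counts, lengths) {
  m <- as_expr_matrix(counts, "counts")
  check_no_missing(m, "count matrix")
  len <- as_named_numeric(lengths, "lengths")
  missing_len <- setdiff(rownames(m), names(len))
  if (length(missing_len)) {
    abort(sprintf("missing gene length for: %s", paste(utils::head(missing_len, 5), collapse = ", ")))
  }
  len <- len[rownames(m)]
  if (any(len <= 0)) abort("gene lengths must be strictly positive")
  totals <- colSums(m)
  if (any(totals == 0)) {
    abort(sprintf("sample(s) with zero total counts: %s",
                  paste(colnames(m)[totals == 0], collapse = ", ")))
  }
  rates <- m / len
  tpm <- sweep(rates, 2, colSums(rates), "/") * 1e6
  expr_as_tibble(log2(tpm + 1))
}

#' Filter genes by length and expression support
#'
#' Removes genes shorter than `min_length` nucleotides and genes that never
#' reach `min_fpm` fragments per million mapped reads in any sample. A gene is
#' kept if at least one sample supports it; requiring support in every sample
#' would discard condition-specific genes.
#'
#' @inheritParams compute_log_tpm
#' @param min_length Minimum gene length in nucleotides (default 100).
#' @param min_fpm Minimum fragments-per-million in the best sample (default 10).
#' @return Tibble of retained genes with columns `gene`, `length`, `max_fpm`,
#'   in input gene order.
#' @export
qc_filter_genes <- function(counts, lengths, min_length = 100, min_fpm = 10) {
  m <- as_expr_matrix(counts, "counts")
  len <- as_named_numeric(lengths, "lengths")[rownames(m)]
  if (anyNA(len)) abort("lengths must cover every gene in `counts`")
  totals <- colSums(m)
  fpm <- sweep(m, 2, totals, "/") * 1e6
  max_fpm <- apply(fpm, 1, max)
  keep <- len >= min_length & max_fpm >= min_fpm
  if (!any(keep)) abort("all genes filtered")
  tibble(gene = rownames(m)[keep], length = unname(len[keep]),
         max_fpm = unname(max_fpm[keep]))
}

#' Filter discordant biological replicates
#'
#' Within each replicate group of two or more samples, a sample is retained
#' only if its log-TPM profile attains squared Pearson correlation of at least
#' `min_r2` with some other retained member of the group. Discordant pairs are
#' removed wholesale (with only two members there is no arbiter); singleton
#' groups pass through unchanged.
#'
#' @param log_tpm Expression table (leading gene column) or matrix.
#' @param metadata Data frame with `sample_id` and `replicate_group` columns,
#'   or a named character vector mapping sample id to group.
#' @param min_r2 Minimum within-group squared Pearson correlation (default 0.9).
#' @return Tibble of retained samples: `sample_id`, `replicate_group`,
#'   `best_r2` (`NA` for singletons).
#' @export
qc_filter_replicates <- function(log_tpm, metadata, min_r2 = 0.9) {
  m <- as_expr_matrix(log_tpm, "log_tpm")
  if (is.data.frame(metadata)) {
    groups <- stats::setNames(as.character(metadata$replicate_group), metadata$sample_id)
  } else {
    groups <- metadata
  }
  if (!all(colnames(m) %in% names(groups))) abort("every sample needs a replicate-group key")
  groups <- groups[colnames(m)]

  keep <- character(0)
  best <- numeric(0)
  for (g in unique(groups)) {
    ids <- colnames(m)[groups == g]
    if (length(ids) == 1L) {
      keep <- c(keep, ids); best <- c(best, NA_real_)
      next
    }
    r2 <- stats::cor(m[, ids, drop = FALSE])^2
    diag(r2) <- NA
    ok <- ids
    repeat {
      if (length(ok) < 2L) { ok <- character(0); break }
      sub <- r2[ok, ok, drop = FALSE]
      score <- apply(sub, 1, max, na.rm = TRUE)
      bad <- names(score)[score < min_r2]
      if (!length(bad)) break
      ok <- setdiff(ok, bad)
    }
    dropped <- setdiff(ids, ok)
    if (length(dropped)) {
      inform(sprintf("replicate group '%s': removed %s (R2 < %.2g)",
                     g, paste(dropped, collapse = ", "), min_r2))
    }
    if (length(ok)) {
      sub <- r2[ok, ok, drop = FALSE]
      keep <- c(keep, ok)
      best <- c(best, apply(sub, 1, max, na.rm = TRUE))
    }
  }
  ord <- match(intersect(colnames(m), keep), keep)
  tibble(sample_id = keep[ord],
         replicate_group = unname(groups[keep[ord]]),
         best_r2 = unname(best[ord]))
}

#' Center a compendium on its reference samples
#'
#' Subtracts from every column the per-gene mean over the designated reference
#' samples, turning log-TPM values into log fold changes relative to the
#' reference condition. The operation is idempotent and preserves pairwise
#' differences between columns exactly.
#'
#' @param x An `imod_compendium`, expression data frame, or matrix.
#' @param reference_samples Sample identifiers to center on; defaults to the
#'   compendium's reference flags.
#' @inheritParams compendium
#' @return A centered `imod_compendium`.
#' @export
center_to_reference <- function(x, reference_samples = NULL, metadata = NULL) {
  if (inherits(x, "imod_compendium")) {
    if (is.null(reference_samples)) reference_samples <- x$reference_samples
    metadata <- x$metadata
    m <- x$values
  } else {
    m <- as_expr_matrix(x, "x")
    if (is.null(metadata)) {
      metadata <- tibble(sample_id = colnames(m), project = "project_1",
                         condition = colnames(m), replicate_group = colnames(m),
                         is_reference = colnames(m) %in% reference_samples)
    }
  }
  if (is.null(reference_samples) || !length(reference_samples)) {
    abort("`reference_samples` must be nonempty")
  }
  unknown <- setdiff(reference_samples, colnames(m))
  if (length(unknown)) abort(sprintf("unknown reference sample(s): %s", paste(unknown, collapse = ", ")))
  offset <- rowMeans(m[, reference_samples, drop = FALSE])
  centered <- m - offset
  metadata$is_reference <- metadata$sample_id %in% reference_samples
  compendium(centered, metadata, centered = TRUE, reference_samples = reference_samples)
}

#' Read an expression or count table from TSV
#'
#' Expects gene identifiers in the first column and sample identifiers as the
#' header; rejects tables containing missing values.
#'
#' @param path Path to a TSV file.
#' @return Tibble with a leading `gene` column.
#' @export
read_expression <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(df)[1L] <- "gene"
  if (anyNA(df)) abort(sprintf("'%s' contains missing values", path))
  df
}

#' Read sample metadata from TSV
#'
#' @param path Path to a TSV with columns `sample_id`, `project`, `condition`,
#'   `replicate_group`, `is_reference`.
#' @return Tibble of metadata.
#' @export
read_metadata <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("sample_id", "condition", "replicate_group")
  missing <- setdiff(req, names(df))
  if (length(missing)) abort(sprintf("metadata missing column(s): %s", paste(missing, collapse = ", ")))
  if ("is_reference" %in% names(df)) df$is_reference <- as.logical(df$is_reference)
  df
}

#' Read gene lengths from a GFF3 file or a two-column table
#'
#' For GFF3 input, `gene` features are used (CDS as fallback) and the length is
#' the 1-based inclusive span `end - start + 1`; overlapping intervals of the
#' same gene are unioned. Identifiers are taken from the attribute named by
#' `attribute` (bacterial annotations key genes by locus tag).
#'
#' @param path Path to a `.gff`/`.gff3` file or a two-column TSV (gene, length).
#' @param attribute GFF attribute holding the gene identifier.
#' @return Tibble with columns `gene` and `length`.
#' @export
read_gene_lengths <- function(path, attribute = "locus_tag") {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      abort("reading GFF3 requires the rtracklayer package")
    }
    gr <- rtracklayer::import(path)
    type <- as.character(gr$type)
    use <- gr[type == "gene"]
    if (!length(use)) use <- gr[type == "CDS"]
    meta <- as.data.frame(use)
    if (!attribute %in% names(meta)) {
      abort(sprintf("GFF attribute '%s' not found", attribute))
    }
    ids <- as.character(meta[[attribute]])
    # union of intervals per gene
    df <- tibble(gene = ids, start = meta$start, end = meta$end) |>
      filter(!is.na(.data$gene))
    out <- df |>
      group_by(.data$gene) |>
      summarise(length = {
        o <- order(.data$start)
        s <- .data$start[o]; e <- .data$end[o]
        tot <- 0; cur_s <- s[1]; cur_e <- e[1]
        for (i in seq_along(s)[-1]) {
          if (s[i] <= cur_e + 1) cur_e <- max(cur_e, e[i])
          else { tot <- tot + cur_e - cur_s + 1; cur_s <- s[i]; cur_e <- e[i] }
        }
        tot + cur_e - cur_s + 1
      }, .groups = "drop")
    return(out)
  }
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  tibble(gene = as.character(df[[1L]]), length = as.numeric(df[[2L]]))
}

#' Preprocess counts into a reference-centered compendium
#'
#' Convenience wrapper chaining the quality-control and normalization steps:
#' gene filtering by length and fragments-per-million support, log-TPM
#' computation, replicate-concordance filtering, and centering on the
#' reference samples.
#'
#' @inheritParams compute_log_tpm
#' @inheritParams qc_filter_genes
#' @inheritParams qc_filter_replicates
#' @param metadata Sample metadata (see [compendium()]).
#' @param min_rep_r2 Minimum within-group replicate R-squared (default 0.9).
#' @return A centered `imod_compendium`.
#' @export
preprocess_compendium <- function(counts, lengths, metadata,
                                  min_length = 100, min_fpm = 10,
                                  min_rep_r2 = 0.9) {
  len <- as_named_numeric(lengths, "lengths")
  genes_keep <- qc_filter_genes(counts, len, min_length, min_fpm)$gene
  m <- as_expr_matrix(counts, "counts")[genes_keep, , drop = FALSE]
  lt <- as_expr_matrix(compute_log_tpm(m, len))
  samples_keep <- qc_filter_replicates(lt, metadata, min_rep_r2)$sample_id
  lt <- lt[, samples_keep, drop = FALSE]
  metadata <- as_tibble(metadata)
  metadata <- metadata[metadata$sample_id %in% samples_keep, ]
  refs <- metadata$sample_id[as.logical(metadata$is_reference)]
  if (!length(refs)) abort("no reference samples survive preprocessing")
  center_to_reference(lt, refs, metadata = metadata)
}
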