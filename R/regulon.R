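#' Construct a regulon table
#'
#' A regulon table stores regulator-to-target interactions with an optional
#' mode of effect. Interactions whose target gene is absent from the supplied
#' gene universe are dropped (with a message reporting the count), duplicate
#' (regulator, gene) rows are collapsed, and pairs reported with conflicting
#' effects are set to `"unknown"`.
#'
#' @param interactions Data frame with columns `regulator`, `gene`, and
#'   optionally `effect` (one of `"activation"`, `"repression"`, `"unknown"`).
#' @param gene_universe Character vector of genes in the compendium; used to
#'   restrict interactions and as the background for enrichment tests.
#' @return A tibble of class `imod_regulon` with columns `regulator`, `gene`,
#'   `effect`, carrying the universe in attribute `gene_universe`.
#' @export
regulon_table <- function(interactions, gene_universe) {
  df <- as_tibble(interactions)
  req <- c("regulator", "gene")
  missing <- setdiff(req, names(df))
  if (length(missing)) abort(sprintf("regulon table missing column(s): %s", paste(missing, collapse = ", ")))
  if (!"effect" %in% names(df)) df$effect <- "unknown"
  df$effect[is.na(df$effect) | !df$effect %in% c("activation", "repression")] <- "unknown"
  if (nrow(df) == 0L) {
    warn("empty regulon table")
  } else {
    n0 <- nrow(df)
    df <- df[df$gene %in% gene_universe, , drop = FALSE]
    if (nrow(df) < n0) {
      inform(sprintf("dropped %d interaction(s) outside the gene universe", n0 - nrow(df)))
    }
    df <- df |>
      group_by(.data$regulator, .data$gene) |>
      summarise(effect = if (dplyr::n_distinct(.data$effect) > 1L) "unknown" else .data$effect[1L],
                .groups = "drop")
  }
  structure(df[c("regulator", "gene", "effect")],
            gene_universe = as.character(gene_universe),
            class = c("imod_regulon", class(df)))
}

#' Read a regulator-target network table
#'
#' @param path CSV or TSV file with columns `regulator`, `gene`, and optional
#'   `effect`.
#' @inheritParams regulon_table
#' @return An `imod_regulon` tibble.
#' @export
read_regulon_table <- function(path, gene_universe) {
  reader <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) readr::read_tsv else readr::read_csv
  df <- reader(path, show_col_types = FALSE, progress = FALSE)
  regulon_table(df, gene_universe)
}

#' @export
print.imod_regulon <- function(x, ...) {
  cat(sprintf("<imod_regulon> %d interactions, %d regulators, universe of %d genes\n",
              nrow(x), dplyr::n_distinct(x$regulator), length(attr(x, "gene_universe"))))
  NextMethod()
}

gene_universe <- function(rt) attr(rt, "gene_universe")

#' Genes of one regulon
#'
#' @param rt An `imod_regulon` table.
#' @param regulator Regulator name.
#' @return Character vector of target genes (a set: no duplicates).
#' @export
regulon_genes <- function(rt, regulator) {
  if (!regulator %in% rt$regulator) abort(sprintf("unknown regulator '%s'", regulator))
  unique(rt$gene[rt$regulator == regulator])
}

#' Combine regulons by intersection or union
#'
#' Joint regulation is modeled with set algebra over regulons: `"+"` takes the
#' intersection (targets of all listed regulators) and `"/"` the union. Modes
#' compose left to right, so `c("+", "/")` over regulators A, B, C is
#' `(A + B) / C`. Mixed-mode triples are supported but experimental; the
#' homogeneous forms are the ones with established use.
#'
#' @inheritParams regulon_genes
#' @param regulators One to three regulator names.
#' @param modes Character vector of `"+"` (intersection) and/or `"/"` (union),
#'   length `length(regulators) - 1`; a single value is recycled.
#' @return List with `genes` (character vector) and `label` (e.g. `"A+B"`).
#' @export
combine_regulons <- function(rt, regulators, modes = "+") {
  if (length(regulators) < 1L || length(regulators) > 3L) {
    abort("between 1 and 3 regulators are supported")
  }
  if (length(regulators) > 1L && length(modes) == 1L) {
    modes <- rep(modes, length(regulators) - 1L)
  }
  genes <- regulon_genes(rt, regulators[[1L]])
  label <- regulators[[1L]]
  for (i in seq_along(regulators)[-1L]) {
    nxt <- regulon_genes(rt, regulators[[i]])
    mode <- modes[[i - 1L]]
    if (!mode %in% c("+", "/")) abort("modes must be '+' or '/'")
    genes <- if (mode == "+") intersect(genes, nxt) else union(genes, nxt)
    label <- paste0(label, mode, regulators[[i]])
  }
  list(genes = genes, label = label)
}
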