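#' Fisher's exact test for module-regulon overlap
#'
#' Two-sided Fisher's exact test on the 2x2 table classifying every gene of
#' the universe by i-modulon membership and regulon membership. An empty
#' module or regulon yields `p = 1` with zero overlap rather than an error.
#'
#' @param module_genes Character vector of i-modulon genes.
#' @param regulon_genes Character vector of regulon genes.
#' @param universe Character vector (or count) of background genes; both gene
#'   sets must be drawn from it.
#' @return One-row tibble: `k` (overlap), `n` (module size), `K` (regulon
#'   size), `N` (universe size), `p_value`, `precision`, `recall`, `f1`.
#' @export
fisher_enrichment <- function(module_genes, regulon_genes, universe) {
  N <- if (is.numeric(universe) && length(universe) == 1L) as.integer(universe) else length(unique(universe))
  if (N < 2L) abort("universe must contain at least 2 genes")
  module_genes <- unique(module_genes)
  regulon_genes <- unique(regulon_genes)
  n <- length(module_genes); K <- length(regulon_genes)
  k <- length(intersect(module_genes, regulon_genes))
  if (n > N || K > N) abort("gene sets must be subsets of the universe")
  if (n == 0L || K == 0L) {
    p <- 1
  } else {
    tab <- matrix(c(k, n - k, K - k, N - n - K + k), nrow = 2L)
    p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  }
  prf <- precision_recall_f1(k, n, K)
  # new_tibble: this constructor sits in tight loops (candidate enumeration,
  # exhaustive calibration), where tibble()'s validation overhead dominates
  tibble::new_tibble(list(k = k, n = n, K = K, N = N, p_value = p,
                          precision = prf$precision, recall = prf$recall,
                          f1 = prf$f1), nrow = 1L)
}

#' Precision, recall, and F1 of a module-regulon overlap
#'
#' Precision is the fraction of i-modulon genes found in the regulon; recall
#' is the fraction of regulon genes found in the i-modulon; F1 is their
#' harmonic mean (0 when the overlap is empty).
#'
#' @param k Overlap size.
#' @param n Module size.
#' @param K Regulon size.
#' @return List with `precision`, `recall`, `f1`.
#' @export
precision_recall_f1 <- function(k, n, K) {
  precision <- if (n > 0) k / n else 0
  recall <- if (K > 0) k / K else 0
  f1 <- if (k == 0) 0 else 2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1)
}

# mode-combination labels for pairs/triples, composed left to right
combo_modes <- function(size) {
  if (size == 2L) list("+", "/")
  else list(c("+", "+"), c("/", "/"), c("+", "/"), c("/", "+"))
}

#' Test all single and combined regulon candidates against one i-modulon
#'
#' Candidate regulators are those sharing at least one gene with the
#' i-modulon (regulons disjoint from the module cannot improve enrichment).
#' Singles, pairs, and triples of candidates are combined by intersection
#' (`+`) and union (`/`); candidate sets that come out empty are excluded.
#' P-values are corrected by Benjamini-Hochberg across the whole candidate
#' family for this i-modulon, and records passing `fdr_alpha` are returned
#' sorted by p-value.
#'
#' @param module_genes Character vector of i-modulon genes.
#' @param regulon_table An `imod_regulon` table.
#' @param fdr_alpha FDR threshold (default 1e-5).
#' @param max_regulators Largest combination size, 1 to 3 (default 3).
#' @param max_candidates Cap on the number of overlapping regulators entering
#'   pair/triple enumeration (largest-overlap regulators kept; default 20).
#' @return Tibble of enrichment records: `regulator_set`, `n_regulators`,
#'   `k`, `n`, `K`, `N`, `p_value`, `fdr`, `precision`, `recall`, `f1`.
#' @export
enumerate_and_test <- function(module_genes, regulon_table, fdr_alpha = 1e-5,
                               max_regulators = 3L, max_candidates = 20L) {
  universe <- gene_universe(regulon_table)
  module_genes <- unique(module_genes)
  regs <- unique(regulon_table$regulator)
  reg_sets <- lapply(regs, function(r) regulon_genes(regulon_table, r))
  names(reg_sets) <- regs
  overlap <- vapply(reg_sets, function(g) length(intersect(g, module_genes)), 1L)
  cand <- names(overlap)[overlap > 0L]
  if (!length(cand)) {
    return(tibble(regulator_set = character(), n_regulators = integer(),
                  k = integer(), n = integer(), K = integer(), N = integer(),
                  p_value = numeric(), fdr = numeric(), precision = numeric(),
                  recall = numeric(), f1 = numeric()))
  }
  cand_comb <- cand
  if (length(cand_comb) > max_candidates) {
    cand_comb <- names(sort(overlap[cand], decreasing = TRUE))[seq_len(max_candidates)]
  }
  records <- list()
  add_record <- function(label, nreg, genes) {
    if (!length(genes)) return()
    fe <- fisher_enrichment(module_genes, genes, universe)
    records[[length(records) + 1L]] <<- mutate(fe, regulator_set = label,
                                               n_regulators = nreg)
  }
  for (r in cand) add_record(r, 1L, reg_sets[[r]])
  if (max_regulators >= 2L && length(cand_comb) >= 2L) {
    pairs <- utils::combn(cand_comb, 2L, simplify = FALSE)
    for (pr in pairs) {
      for (md in combo_modes(2L)) {
        cc <- combine_regulons(regulon_table, pr, md)
        add_record(cc$label, 2L, cc$genes)
      }
    }
  }
  if (max_regulators >= 3L && length(cand_comb) >= 3L) {
    triples <- utils::combn(cand_comb, 3L, simplify = FALSE)
    for (tr in triples) {
      for (md in combo_modes(3L)) {
        cc <- combine_regulons(regulon_table, tr, md)
        add_record(cc$label, 3L, cc$genes)
      }
    }
  }
  fam <- dplyr::bind_rows(records)
  fam$fdr <- stats::p.adjust(fam$p_value, method = "BH")
  fam |>
    filter(.data$fdr < fdr_alpha) |>
    arrange(.data$p_value) |>
    select("regulator_set", "n_regulators", "k", "n", "K", "N",
           "p_value", "fdr", "precision", "recall", "f1")
}

#' Enrich every i-modulon against the known regulatory network
#'
#' Runs [enumerate_and_test()] for each i-modulon and stores the passing
#' records (and the single best record per i-modulon) on the `imod_set`.
#'
#' @param iset An `imod_set`.
#' @param regulon_table An `imod_regulon` table.
#' @inheritParams enumerate_and_test
#' @param family `"per_imodulon"` (default) corrects p-values within each
#'   i-modulon's candidate family; `"global"` re-corrects across all
#'   i-modulons jointly.
#' @return The `imod_set` with its `enrichment` slot filled (tibble with an
#'   `imodulon` column prepended to the [enumerate_and_test()] records).
#' @export
enrich_imodulons <- function(iset, regulon_table, fdr_alpha = 1e-5,
                             max_regulators = 3L,
                             family = c("per_imodulon", "global")) {
  family <- match.arg(family)
  ims <- unique(iset$gene_table$imodulon)
  recs <- purrr::map(ims, function(im) {
    genes <- iset$gene_table$gene[iset$gene_table$imodulon == im]
    # within-imodulon BH is applied here; the global family re-corrects below
    out <- enumerate_and_test(genes, regulon_table,
                              fdr_alpha = if (family == "global") 1 + 1e-9 else fdr_alpha,
                              max_regulators = max_regulators)
    if (nrow(out)) mutate(out, imodulon = im, .before = 1L) else NULL
  })
  enr <- dplyr::bind_rows(recs)
  if (family == "global" && nrow(enr)) {
    enr$fdr <- stats::p.adjust(enr$p_value, method = "BH")
    enr <- filter(enr, .data$fdr < fdr_alpha) |> arrange(.data$p_value)
  }
  iset$enrichment <- enr
  iset
}

#' Top enrichment per i-modulon
#'
#' @param iset An enriched `imod_set`.
#' @return Tibble with the lowest-p record for each i-modulon that has one.
#' @export
top_enrichment <- function(iset) {
  if (is.null(iset$enrichment) || nrow(iset$enrichment) == 0L) {
    abort("run enrich_imodulons() first")
  }
  iset$enrichment |>
    group_by(.data$imodulon) |>
    dplyr::slice_min(.data$p_value, n = 1, with_ties = FALSE) |>
    ungroup()
}

#' Categorize i-modulons
#'
#' An i-modulon is `regulatory` when it has a passing regulon enrichment;
#' `genomic` when a single gene carries more than half of the squared weight
#' and that gene is knocked out somewhere in the compendium (the signature of
#' a knockout or large genomic change, not a transcriptional signal);
#' `biological` when the user annotates it as such; otherwise
#' `uncharacterized`. Categories are stored, never guessed silently.
#'
#' @param iset An `imod_set` (enrich first for regulatory calls).
#' @param knockouts Character vector of genes knocked out in the compendium.
#' @param annotations Named character vector mapping i-modulon name to
#'   `"biological"` (or any manual category).
#' @return The `imod_set` with its `category` slot filled (named character
#'   vector).
#' @export
categorize_imodulons <- function(iset, knockouts = character(), annotations = NULL) {
  ims <- unique(iset$thresholds$imodulon)
  enriched <- if (!is.null(iset$enrichment) && nrow(iset$enrichment)) {
    unique(iset$enrichment$imodulon)
  } else character()
  cat_of <- vapply(ims, function(im) {
    if (im %in% enriched) return("regulatory")
    w <- iset$gene_table$weight[iset$gene_table$imodulon == im]
    g <- iset$gene_table$gene[iset$gene_table$imodulon == im]
    dominant <- g[which.max(w^2)]
    if (max(w^2) / sum(w^2) > 0.5 && dominant %in% knockouts) return("genomic")
    if (!is.null(annotations) && im %in% names(annotations)) return(annotations[[im]])
    "uncharacterized"
  }, character(1))
  iset$category <- cat_of
  iset
}

#' Write the enrichment summary table
#'
#' TSV with one row per i-modulon mirroring the usual summary layout: name,
#' gene count, linked regulator expression, p-value, FDR, precision, recall,
#' F1, category.
#'
#' @param iset An enriched (and optionally categorized) `imod_set`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(iset, path) {
  top <- tryCatch(top_enrichment(iset), error = function(e) NULL)
  base <- tibble(imodulon = unique(iset$thresholds$imodulon)) |>
    left_join(iset$thresholds |> select("imodulon", "n_genes"), by = "imodulon")
  if (!is.null(top)) {
    base <- left_join(base, top |> select("imodulon", "regulator_set",
                                          "p_value", "fdr", "precision",
                                          "recall", "f1"), by = "imodulon")
  }
  if (!is.null(iset$category)) {
    base$category <- unname(iset$category[base$imodulon])
  }
  readr::write_tsv(base, path)
  invisible(path)
}
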