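#' Assemble a pipeline run configuration
#'
#' All stage parameters default to the workflow's published settings: 256
#' FastICA restarts, 100 clustering repetitions, tolerance 1e-8, DBSCAN
#' epsilon 0.1, cross-repetition matching distance 0.1, PCA variance fraction
#' 0.99, K-squared cutoff 550 (or a 200-1000 step-50 scan when a regulon
#' table is supplied), enrichment FDR 1e-5, and differential-activity
#' thresholds |delta A| > 5 at FDR < 0.01.
#'
#' @param expression,counts,lengths,metadata,trn Input paths (supply either
#'   `expression` for log-TPM, or `counts` plus `lengths`). `trn` is optional.
#' @param fixture_preset If `"default"`, inputs are generated with
#'   [generate_compendium()] defaults instead of read from files.
#' @param out_dir Output directory.
#' @param n_restarts,n_repetitions,tol,eps,d_max,variance_fraction,n_components
#'   Decomposition parameters (see [robust_components()]).
#' @param cutoff,scan_grid Thresholding parameters; `scan_grid = NULL`
#'   disables the calibration scan.
#' @param enrich_fdr,max_regulators Enrichment parameters.
#' @param abs_threshold,diff_fdr Differential-activity parameters.
#' @param seed Master seed.
#' @param digits Significant digits for numeric TSV serialization.
#' @return A named list of class `imod_config`.
#' @export
run_config <- function(expression = NULL, counts = NULL, lengths = NULL,
                       metadata = NULL, trn = NULL, fixture_preset = NULL,
                       out_dir = "imodkit_out",
                       n_restarts = 256L, n_repetitions = 100L, tol = 1e-8,
                       eps = 0.1, d_max = 0.1, variance_fraction = 0.99,
                       n_components = NULL,
                       cutoff = 550, scan_grid = seq(200, 1000, by = 50),
                       enrich_fdr = 1e-5, max_regulators = 3L,
                       abs_threshold = 5, diff_fdr = 0.01,
                       seed = 42L, digits = 10L) {
  cfg <- as.list(environment())
  structure(cfg, class = "imod_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of [run_config()].
#' @return An `imod_config` list.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' Write a pipeline configuration to YAML
#'
#' @param config An `imod_config`.
#' @param path Output path.
#' @return `path`, invisibly. The configuration round-trips unchanged through
#'   [read_run_config()].
#' @export
write_run_config <- function(config, path) {
  vals <- unclass(config)
  vals <- vals[!vapply(vals, is.null, TRUE)]
  yaml::write_yaml(vals, path)
  invisible(path)
}

stage_log <- function(stage, msg) {
  message(sprintf("[%s] %s", stage, msg))
}

#' Run the full i-modulon pipeline
#'
#' Chains preprocessing, robust decomposition, thresholding, and regulon
#' enrichment, writing `compendium.tsv`, `S.tsv`, `A.tsv`,
#' `decomposition.json`, `imodulons.json`, `enrichment.tsv`, and a
#' `manifest.json` with package version, seed, parameters, and input
#' checksums. Without a regulon table the cutoff defaults to 550 and the
#' enrichment stage is skipped with a warning. Runs with the same
#' configuration and seed produce byte-identical numeric outputs at the
#' serialized precision.
#'
#' @param config An `imod_config` from [run_config()] or [read_run_config()].
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- character()

  stage_log("input", "loading inputs")
  trn <- NULL
  if (!is.null(config$fixture_preset)) {
    fx <- generate_compendium(seed = config$seed)
    comp <- fx$compendium
    refs <- comp$reference_samples
    comp <- center_to_reference(comp, refs)
    trn_df <- as_tibble(fx$regulon_table)
  } else {
    if (!is.null(config$counts)) {
      counts <- read_expression(config$counts)
      lengths <- read_gene_lengths(config$lengths)
      meta <- read_metadata(config$metadata)
      inputs <- c(config$counts, config$lengths, config$metadata)
      stage_log("preprocess", "QC filtering and log-TPM")
      comp <- preprocess_compendium(counts, lengths, meta)
    } else if (!is.null(config$expression)) {
      expr <- read_expression(config$expression)
      meta <- read_metadata(config$metadata)
      inputs <- c(config$expression, config$metadata)
      refs <- meta$sample_id[as.logical(meta$is_reference)]
      comp <- center_to_reference(as_expr_matrix(expr), refs, metadata = meta)
    } else {
      abort("config must provide `expression`, `counts`, or `fixture_preset`")
    }
    trn_df <- NULL
    if (!is.null(config$trn)) {
      inputs <- c(inputs, config$trn)
      trn_df <- as_tibble(read_regulon_table(config$trn, rownames(comp$values)))
    }
  }
  if (!is.null(trn_df)) trn <- regulon_table(trn_df, rownames(comp$values))
  write_matrix_tsv(comp$values, file.path(config$out_dir, "compendium.tsv"),
                   digits = config$digits)

  stage_log("decompose", sprintf("robust ICA (%d restarts x %d repetitions)",
                                 config$n_restarts, config$n_repetitions))
  dec <- robust_components(comp, n_components = config$n_components,
                           n_restarts = config$n_restarts,
                           n_repetitions = config$n_repetitions,
                           eps = config$eps, d_max = config$d_max,
                           tol = config$tol,
                           variance_fraction = config$variance_fraction,
                           seed = config$seed)
  write_decomposition(dec, config$out_dir, digits = config$digits)

  stage_log("threshold", "extracting significant genes")
  cutoff <- config$cutoff
  if (!is.null(trn) && !is.null(config$scan_grid)) {
    sc <- tryCatch(scan_cutoff(dec, trn, grid = config$scan_grid,
                               link_fdr = config$enrich_fdr),
                   error = function(e) NULL)
    if (!is.null(sc)) cutoff <- sc$cutoff
  }
  iset <- compute_imodulons(dec, cutoff = cutoff)
  write_imodulons(iset, file.path(config$out_dir, "imodulons.json"))

  if (!is.null(trn)) {
    stage_log("enrich", "regulon enrichment")
    iset <- enrich_imodulons(iset, trn, fdr_alpha = config$enrich_fdr,
                             max_regulators = config$max_regulators)
    iset <- categorize_imodulons(iset)
    write_enrichment(iset, file.path(config$out_dir, "enrichment.tsv"))
  } else {
    warn("no regulon table supplied; enrichment skipped, cutoff 550 used")
  }

  artifacts <- intersect(c("compendium.tsv", "S.tsv", "A.tsv",
                           "decomposition.json", "imodulons.json",
                           "enrichment.tsv"),
                         list.files(config$out_dir))
  manifest <- list(
    package = "imodkit",
    version = as.character(utils::packageVersion("imodkit")),
    r_version = R.version.string,
    seed = config$seed,
    cutoff_used = cutoff,
    parameters = unclass(config)[c("n_restarts", "n_repetitions", "tol", "eps",
                                   "d_max", "variance_fraction", "enrich_fdr",
                                   "abs_threshold", "diff_fdr", "digits")],
    serialization = sprintf("numeric TSVs at %d significant digits", config$digits),
    input_checksums = as.list(tools::md5sum(inputs)),
    artifacts = artifacts)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  stage_log("done", sprintf("%d artifacts in %s", length(artifacts), config$out_dir))
  invisible(manifest)
}
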