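#' Generate a synthetic compendium with planted modules
#'
#' Builds an expression compendium `X = S_true A_true + noise` with known
#' ground truth so every stage of the workflow can be tested without external
#' data. Each planted module is a sparse unit-norm column of `S_true` (member
#' genes carry large mixed-sign weights, non-members are exactly zero).
#' Activities have condition-block structure: a module is active in a random
#' subset of conditions with bimodal, spread-out levels (independent
#' components are only identifiable for non-Gaussian sources), and biological
#' replicates of a condition are jittered around the condition level. Two
#' designated reference samples have exactly zero true activities. A matching
#' toy regulon table assigns one regulator per module, covering a
#' configurable fraction of its members, plus size-matched decoy regulons so
#' enrichment specificity is genuinely exercised.
#'
#' @param n_genes Number of genes (default 4000).
#' @param n_samples Number of samples including the two references
#'   (default 60).
#' @param n_modules Number of planted modules (default 10).
#' @param module_size Two-element range of module sizes (default `c(10, 30)`).
#' @param replicate_size Replicates per condition (default 2).
#' @param noise_sigma Standard deviation of the additive expression noise
#'   (default 0.05).
#' @param activity_jitter Replicate-level jitter of activities (default 0.5).
#' @param positive_fraction Fraction of positive member weights (default 0.8).
#' @param activation_prob Probability a module is active in a non-reference
#'   condition (default 0.4; at least 3 active conditions are enforced).
#' @param regulon_coverage Fraction of module members covered by the true
#'   regulator (default 0.9).
#' @param n_decoy_regulons Number of size-matched decoy regulons (default 10).
#' @param seed Master seed; the fixture is fully reproducible from it.
#' @return List of class `imod_fixture` with elements `compendium` (a
#'   centered `imod_compendium`), `ground_truth` (list with `S_true`,
#'   `A_true`, `modules`, `regulators`, `noise_sigma`, `seed`), and
#'   `regulon_table`.
#' @export
generate_compendium <- function(n_genes = 4000L, n_samples = 60L,
                                n_modules = 10L, module_size = c(10L, 30L),
                                replicate_size = 2L, noise_sigma = 0.05,
                                activity_jitter = 0.5,
                                positive_fraction = 0.8,
                                activation_prob = 0.4,
                                regulon_coverage = 0.9,
                                n_decoy_regulons = 10L, seed = 1L) {
  if (n_modules > n_samples / 2) abort("infeasible: n_modules exceeds n_samples/2")
  if (n_genes < n_modules * max(module_size) + n_modules) {
    abort("infeasible: not enough genes for disjoint modules plus regulator genes")
  }
  if (min(module_size) < 5L) abort("infeasible: planted modules need >= 5 members")
  if (n_samples < replicate_size + 2L) abort("infeasible: too few samples")

  with_seed(seed, {
    genes <- sprintf("g%04d", seq_len(n_genes))
    # conditions: reference (2 replicates) + blocks of replicate_size
    n_cond <- 1L + floor((n_samples - 2L) / replicate_size)
    cond_names <- c("ref", sprintf("cond%02d", seq_len(n_cond - 1L)))
    cond_of <- c(rep("ref", 2L),
                 rep(cond_names[-1L], each = replicate_size))
    cond_of <- cond_of[seq_len(min(length(cond_of), n_samples))]
    extra <- n_samples - length(cond_of)
    if (extra > 0L) cond_of <- c(cond_of, rep(cond_names[n_cond], extra))
    samples <- stats::ave(cond_of, cond_of, FUN = function(v) {
      paste0(v[1], "__rep", seq_along(v))
    })

    # sparse unit-norm module weights on disjoint member sets
    pool <- sample(genes)
    s_true <- matrix(0, n_genes, n_modules, dimnames = list(genes, NULL))
    modules <- vector("list", n_modules)
    taken <- 0L
    for (m in seq_len(n_modules)) {
      sz <- sample(seq(module_size[1], module_size[2]), 1L)
      members <- pool[taken + seq_len(sz)]
      taken <- taken + sz
      sgn <- ifelse(stats::runif(sz) < positive_fraction, 1, -1)
      w <- sgn * stats::runif(sz, 0.5, 1)
      w <- w / sqrt(sum(w^2))
      s_true[members, m] <- w
      modules[[m]] <- members
    }
    reg_names <- sprintf("Reg%02d", seq_len(n_modules))
    regulator_genes <- pool[taken + seq_len(n_modules)]  # outside all modules
    names(regulator_genes) <- reg_names

    # bimodal condition-level activities, zero at the reference
    a_true <- matrix(0, n_modules, n_samples,
                     dimnames = list(NULL, samples))
    for (m in seq_len(n_modules)) {
      nonref <- setdiff(cond_names, "ref")
      active <- nonref[stats::runif(length(nonref)) < activation_prob]
      while (length(active) < 3L) {
        active <- unique(c(active, sample(nonref, 1L)))
      }
      for (cc in active) {
        level <- sample(c(-1, 1), 1L) * stats::runif(1, 5, 15)
        idx <- which(cond_of == cc)
        a_true[m, idx] <- level + stats::rnorm(length(idx), 0, activity_jitter)
      }
    }
    a_true[, cond_of == "ref"] <- 0

    x <- s_true %*% a_true +
      matrix(stats::rnorm(n_genes * n_samples, 0, noise_sigma), n_genes)
    colnames(x) <- samples

    metadata <- tibble(sample_id = samples, project = "synthetic",
                       condition = cond_of, replicate_group = cond_of,
                       is_reference = cond_of == "ref")
    comp <- compendium(x, metadata, centered = FALSE,
                       reference_samples = samples[cond_of == "ref"])

    # true regulons cover a fraction of members; decoys are size-matched
    trn_rows <- purrr::map(seq_len(n_modules), function(m) {
      sz <- max(1L, round(regulon_coverage * length(modules[[m]])))
      tibble(regulator = reg_names[m],
             gene = sample(modules[[m]], sz),
             effect = sample(c("activation", "repression"), 1L))
    })
    true_sizes <- vapply(trn_rows, nrow, 1L)
    decoys <- purrr::map(seq_len(n_decoy_regulons), function(d) {
      sz <- sample(true_sizes, 1L)
      tibble(regulator = sprintf("Dec%02d", d),
             gene = sample(genes, sz), effect = "unknown")
    })
    trn <- regulon_table(dplyr::bind_rows(c(trn_rows, decoys)), genes)

    structure(list(
      compendium = comp,
      ground_truth = list(S_true = s_true, A_true = a_true,
                          modules = stats::setNames(modules, reg_names),
                          regulators = regulator_genes,
                          noise_sigma = noise_sigma,
                          seed = as.integer(seed)),
      regulon_table = trn
    ), class = "imod_fixture")
  })
}

#' @export
print.imod_fixture <- function(x, ...) {
  cat(sprintf("<imod_fixture> %d genes x %d samples, %d planted modules (sigma = %g)\n",
              nrow(x$compendium$values), ncol(x$compendium$values),
              ncol(x$ground_truth$S_true), x$ground_truth$noise_sigma))
  invisible(x)
}

#' Add knockout samples for one regulator to a fixture
#'
#' Appends samples in which the regulator's gene expression is zeroed and the
#' activity of its module is shifted by `effect_size` relative to the
#' reference (a repressor knockout derepresses its module, a positive shift).
#'
#' @param fixture An `imod_fixture` from [generate_compendium()].
#' @param regulator Name of a true (non-decoy) regulator, e.g. `"Reg01"`.
#' @param effect_size Activity shift of the regulator's module in the
#'   knockout samples (default 20).
#' @param n_ko Number of knockout replicates (default 2).
#' @return The fixture with knockout samples appended to its compendium and
#'   `A_true`, and `knockout` metadata recorded in the ground truth.
#' @export
generate_knockout_fixture <- function(fixture, regulator, effect_size = 20,
                                      n_ko = 2L) {
  gt <- fixture$ground_truth
  if (!regulator %in% names(gt$modules)) abort(sprintf("unknown regulator '%s'", regulator))
  m_idx <- which(names(gt$modules) == regulator)
  ko_gene <- gt$regulators[[regulator]]
  n_genes <- nrow(gt$S_true)

  a_ko <- matrix(0, nrow(gt$A_true), n_ko)
  a_ko[m_idx, ] <- effect_size
  ko_ids <- sprintf("ko_%s__rep%d", tolower(regulator), seq_len(n_ko))
  colnames(a_ko) <- ko_ids
  x_ko <- with_seed(gt$seed + 7777L, {
    gt$S_true %*% a_ko +
      matrix(stats::rnorm(n_genes * n_ko, 0, gt$noise_sigma), n_genes)
  })
  colnames(x_ko) <- ko_ids
  x_ko[ko_gene, ] <- 0  # no transcript from the deleted gene

  values <- cbind(fixture$compendium$values, x_ko)
  metadata <- dplyr::bind_rows(
    fixture$compendium$metadata,
    tibble(sample_id = ko_ids, project = "synthetic",
           condition = paste0("ko_", tolower(regulator)),
           replicate_group = paste0("ko_", tolower(regulator)),
           is_reference = FALSE))
  fixture$compendium <- compendium(values, metadata, centered = FALSE,
                                   reference_samples = fixture$compendium$reference_samples)
  fixture$ground_truth$A_true <- cbind(gt$A_true, a_ko)
  fixture$ground_truth$knockout <- list(regulator = regulator, gene = ko_gene,
                                        samples = ko_ids,
                                        effect_size = effect_size)
  fixture
}

#' Write a fixture to the TSV formats the pipeline consumes
#'
#' @param fixture An `imod_fixture`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_tsv(fixture$compendium$values, file.path(dir, "expression.tsv"))
  readr::write_tsv(fixture$compendium$metadata, file.path(dir, "metadata.tsv"))
  readr::write_csv(as_tibble(fixture$regulon_table), file.path(dir, "trn.csv"))
  gt <- fixture$ground_truth
  jsonlite::write_json(
    list(modules = gt$modules, regulators = as.list(gt$regulators),
         noise_sigma = gt$noise_sigma, seed = gt$seed),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
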