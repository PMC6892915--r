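#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_hline labs theme_minimal facet_wrap
#' @export
ggplot2::autoplot

#' Cumulative explained variance curve of a decomposition
#'
#' @param object An `imod_decomposition`.
#' @param x Expression matrix or `imod_compendium` the decomposition was
#'   computed from.
#' @param ... Unused.
#' @return A ggplot of CEV against the number of leading components.
#' @method autoplot imod_decomposition
#' @export
autoplot.imod_decomposition <- function(object, x, ...) {
  curve <- cumulative_explained_variance(x, object)
  ggplot(curve, aes(x = .data$K, y = .data$cev)) +
    geom_line() +
    geom_point(size = 0.8) +
    labs(x = "components (ordered by activity norm)",
         y = "cumulative explained variance") +
    theme_minimal()
}

#' Weight distribution of selected i-modulons
#'
#' @param object An `imod_set`.
#' @param imodulons I-modulon names to show (default: all).
#' @param ... Unused.
#' @return A ggplot of signed member-gene weights per i-modulon.
#' @method autoplot imod_set
#' @export
autoplot.imod_set <- function(object, imodulons = NULL, ...) {
  df <- object$gene_table
  if (!is.null(imodulons)) df <- df[df$imodulon %in% imodulons, ]
  df <- df |>
    group_by(.data$imodulon) |>
    mutate(rank = rank(-abs(.data$weight), ties.method = "first")) |>
    ungroup()
  ggplot(df, aes(x = .data$rank, y = .data$weight)) +
    geom_col(width = 0.8) +
    geom_hline(yintercept = 0, linewidth = 0.3) +
    facet_wrap(~imodulon, scales = "free") +
    labs(x = "member gene (by |weight|)", y = "gene weight") +
    theme_minimal()
}

#' Activity bar plot for one i-modulon
#'
#' @param activities Activity matrix, `imod_set`, or data frame with a
#'   leading i-modulon column.
#' @param imodulon I-modulon name.
#' @param conditions Optional sample-to-condition map (named vector or
#'   metadata data frame) used to label the x axis.
#' @return A ggplot of per-sample activity.
#' @export
plot_activity <- function(activities, imodulon, conditions = NULL) {
  a <- activity_matrix(activities)
  if (!imodulon %in% rownames(a)) abort(sprintf("unknown i-modulon '%s'", imodulon))
  df <- tibble(sample = colnames(a), activity = a[imodulon, ])
  if (!is.null(conditions)) {
    cond <- as_condition_map(conditions)
    df$condition <- unname(cond[df$sample])
  } else {
    df$condition <- df$sample
  }
  df$sample <- factor(df$sample, levels = df$sample)
  ggplot(df, aes(x = .data$sample, y = .data$activity)) +
    geom_col() +
    geom_hline(yintercept = 0, linewidth = 0.3) +
    labs(x = NULL, y = sprintf("%s activity", imodulon)) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
                                                       hjust = 1, size = 6))
}

#' Volcano-style plot of a differential-activity table
#'
#' @param diff Tibble from [test_differential_activity()].
#' @param abs_threshold,fdr_alpha Significance thresholds to draw.
#' @return A ggplot of -log10 FDR against the activity difference.
#' @export
plot_differential_activity <- function(diff, abs_threshold = 5, fdr_alpha = 0.01) {
  ggplot(diff, aes(x = .data$delta_a, y = -log10(pmax(.data$fdr, 1e-300)),
                   colour = .data$significant)) +
    geom_point() +
    geom_hline(yintercept = -log10(fdr_alpha), linetype = 2, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = c(-abs_threshold, abs_threshold),
                        linetype = 2, linewidth = 0.3) +
    labs(x = "activity difference", y = "-log10 FDR", colour = "significant") +
    theme_minimal()
}
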