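#' @exportS3Method ggplot2::autoplot
autoplot.ase_result <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$ref_ratio,
                               y = -log10(pmax(.data$p_raw, 1e-300)),
                               colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.9) +
    ggplot2::geom_vline(xintercept = 0.5, linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "REF / (REF + ALT)", y = expression(-log[10](p)),
                  colour = paste0("FDR < ", 0.05)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.ase_bias <- function(object, ...) {
  ggplot2::ggplot(object$ratio_by_depth_bin,
                  ggplot2::aes(x = .data$depth_bin, y = .data$mean_ref_ratio)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::labs(x = "pooled REF+ALT reads", y = "mean REF ratio",
                  title = "Reference bias by read depth") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.ase_overlap_test <- function(object, ...) {
  ggplot2::ggplot(tibble(overlap = object$perm_null),
                  ggplot2::aes(x = .data$overlap)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "black",
                        linewidth = 1) +
    ggplot2::labs(x = "shared ASE SNPs under the null",
                  y = "permutations",
                  title = sprintf("Observed overlap %d, permutation p = %.3g",
                                  object$observed, object$perm_p)) +
    ggplot2::theme_minimal()
}

#' Volcano-style plot of differential ASE
#'
#' Plots each SNP's between-group ratio difference against the raw LRT
#' p-value.
#'
#' @param results An `ase_differential` table.
#' @param fdr_alpha Highlight SNPs below this FDR level.
#' @return A ggplot object.
#' @export
plot_differential_ase <- function(results, fdr_alpha = 0.05) {
  df <- mutate(results,
               delta = .data$ratio_group1 - .data$ratio_group2,
               sig = .data$p_fdr < fdr_alpha)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta,
                                   y = -log10(pmax(.data$p_raw, 1e-300)),
                                   colour = .data$sig)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "difference in REF ratio between groups",
                  y = expression(-log[10](p)), colour = "significant") +
    ggplot2::theme_minimal()
}
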