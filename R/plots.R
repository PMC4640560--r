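#' Expression distributions by miRNA age class
#'
#' Box-and-jitter plot of log10 total read counts for conserved versus
#' lineage-specific miRNAs, faceted by sample — the visual companion of
#' the Mann-Whitney comparison in [age_expression_report()].
#'
#' @param expr A tibble with `gene_id`, `sample_id`, `total`.
#' @param annotations A tibble with `gene_id`, `age_class`.
#' @return A ggplot object.
#' @export
plot_expression_by_age <- function(expr, annotations) {
  dat <- expr %>%
    inner_join(annotations %>% select("gene_id", "age_class"),
               by = "gene_id") %>%
    filter(.data$total > 0)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$age_class, y = .data$total,
                                    fill = .data$age_class)) +
    ggplot2::geom_boxplot(outlier.shape = NA, alpha = 0.6) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$sample_id)) +
    ggplot2::labs(x = NULL, y = "total mapped reads (log scale)",
                  title = "miRNA expression by evolutionary age") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Fold-change overview of enrichment calls
#'
#' Bar chart of per-sample log2 fold changes for called genes, with
#' reference-undetected (ovary-specific candidate) genes shown as a
#' separate facet strip colour.
#'
#' @param calls An `ovary_calls` tibble from [call_ovary_set()].
#' @param fold_threshold Threshold drawn as a dashed line.
#' @return A ggplot object.
#' @export
plot_fold_changes <- function(calls, fold_threshold = 4) {
  long <- as_tibble(calls) %>%
    tidyr::pivot_longer(dplyr::starts_with("fold_"),
                        names_to = "sample_id", names_prefix = "fold_",
                        values_to = "fold_change") %>%
    filter(.data$call != "not_called")
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$gene_id, y = .data$fold_change,
                               fill = .data$call)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = fold_threshold, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$sample_id)) +
    ggplot2::labs(x = NULL, y = "fold change vs reference (log scale)",
                  title = "Tissue enrichment over whole-body reference") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                       hjust = 1))
}

#' Age composition of a gene set
#'
#' Stacked proportion bar of conserved/lineage-specific (or origin-level)
#' composition, the visual companion of the chi-square comparison.
#'
#' @param composition Output of [age_composition()], or a named list of
#'   such tibbles (one bar per element).
#' @return A ggplot object.
#' @export
plot_age_composition <- function(composition) {
  if (inherits(composition, "data.frame")) {
    composition <- list(set = composition)
  }
  dat <- bind_rows(composition, .id = "set")
  fill_col <- setdiff(names(dat), c("set", "n", "proportion"))[1]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$set, y = .data$proportion,
                                    fill = .data[[fill_col]])) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "proportion",
                  title = "miRNA age composition") +
    ggplot2::theme_minimal()
}

#' @rdname plot_fold_changes
#' @param object An `ovary_calls` object.
#' @param ... Passed on to [plot_fold_changes()].
#' @export
autoplot.ovary_calls <- function(object, ...) {
  plot_fold_changes(object, ...)
}

#' @rdname plot_expression_by_age
#' @param object An `age_expression_report` object (plots its per-sample
#'   U and rho as an annotated dot plot).
#' @param ... Unused.
#' @export
autoplot.age_expression_report <- function(object, ...) {
  dat <- object$per_sample %>% filter(.data$computable)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$sample_id, y = .data$rho)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "Spearman's rho (age vs expression)",
                  title = "Age-expression correlation per sample") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
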