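#' Reads-per-million normalisation
#'
#' Normalises raw read counts against the total number of miRNA-mapped
#' reads in the sample, scaled to per-million.
#'
#' @param raw Raw read count(s).
#' @param denominator Total miRNA-mapped reads in the sample (> 0).
#' @return `raw / denominator * 1e6`.
#' @export
#' @examples
#' normalize_counts(25, 1e6)
normalize_counts <- function(raw, denominator) {
  if (any(denominator <= 0)) {
    abort("normalize_counts: denominator must be > 0")
  }
  raw / denominator * 1e6
}

#' Fold change of tissue over reference expression
#'
#' No pseudocounts are used: when the reference normalised count is zero
#' the fold change is undefined and returned as `NA` (never infinity);
#' such genes are instead candidates for the ovary-specific category.
#'
#' @param tissue_norm,reference_norm Normalised counts (>= 0), vectorised.
#' @return `tissue_norm / reference_norm`, `NA` where `reference_norm`
#'   is 0.
#' @export
fold_change <- function(tissue_norm, reference_norm) {
  if (any(tissue_norm < 0, na.rm = TRUE) ||
      any(reference_norm < 0, na.rm = TRUE)) {
    abort("fold_change: normalised counts must be >= 0")
  }
  if_else(reference_norm == 0, NA_real_, tissue_norm / reference_norm)
}

#' Build a normalised expression table from arm profiles
#'
#' Per-sample denominators are the total miRNA-mapped reads (sum of `total`
#' over genes in that sample); normalised columns are reads per million
#' miRNA reads.
#'
#' @param profiles An arm-profile tibble (possibly merged, see
#'   [merge_shared_arm()]).
#' @return `profiles` with added `denominator`, `norm_total`, `norm_5p`,
#'   `norm_3p` columns.
#' @export
expression_table <- function(profiles) {
  profiles %>%
    group_by(.data$sample_id) %>%
    mutate(denominator = sum(.data$total)) %>%
    ungroup() %>%
    mutate(norm_total = normalize_counts(.data$total, .data$denominator),
           norm_5p = normalize_counts(.data$count_5p, .data$denominator),
           norm_3p = normalize_counts(.data$count_3p, .data$denominator))
}

#' Classify genes from per-sample fold changes and detection flags
#'
#' The classifier behind [call_ovary_set()], usable directly on a tidy
#' table of fold changes (e.g. a published enrichment table). A gene is
#' `ovary_upregulated` when its fold change is strictly greater than
#' `fold_threshold` in every tissue sample; `ovary_specific` when it is
#' undetected in the reference (`reference_detected` FALSE, fold `NA`) and
#' passes the per-sample cutoff in every tissue sample; otherwise
#' `expressed` (detected, passing cutoffs somewhere) or `not_called`.
#'
#' @param folds A tibble with columns `gene_id`, `sample_id`,
#'   `fold_change` (`NA` when the reference count is zero),
#'   `dominant_count`, and `reference_detected` (logical).
#' @param cutoffs A [cutoff_policy()] over the tissue samples.
#' @param fold_threshold Strict fold-change threshold.
#' @return A tibble `gene_id`, `call`, `n_samples`, `n_upregulated`,
#'   `n_specific_pass`, with `call` one of `ovary_upregulated`,
#'   `ovary_specific`, `expressed`, `not_called`.
#' @export
classify_enrichment <- function(folds, cutoffs, fold_threshold = 4) {
  folds %>%
    mutate(above = .data$dominant_count >
             cutoff_for(cutoffs, .data$sample_id)) %>%
    group_by(.data$gene_id) %>%
    summarise(
      n_samples = n(),
      n_upregulated = sum(!is.na(.data$fold_change) &
                            .data$fold_change > fold_threshold & .data$above),
      n_specific_pass = sum(!.data$reference_detected & .data$above),
      n_above = sum(.data$above),
      .groups = "drop") %>%
    mutate(call = case_when(
      .data$n_upregulated == .data$n_samples ~ "ovary_upregulated",
      .data$n_specific_pass == .data$n_samples ~ "ovary_specific",
      .data$n_above > 0 ~ "expressed",
      TRUE ~ "not_called")) %>%
    select("gene_id", "call", "n_samples", "n_upregulated",
           "n_specific_pass")
}

#' Call the ovary set from a normalised expression table
#'
#' Computes fold changes of each tissue sample against the reference
#' sample from normalised total counts (both arms summed), then classifies
#' genes: `ovary_upregulated` (fold strictly > `fold_threshold` in every
#' tissue sample), `ovary_specific` (zero raw reference count and above
#' the expression cutoff in every tissue sample), `expressed`, or
#' `not_called`. The ovary set is the union of the first two classes.
#' Detection in the reference at any level disqualifies a gene from
#' `ovary_specific`.
#'
#' @param expr An [expression_table()] containing the reference sample.
#' @param tissue_samples Character vector of tissue (ovary) sample ids.
#' @param reference_sample The whole-body reference sample id.
#' @param fold_threshold Strict fold-change threshold (default 4).
#' @param cutoffs A [cutoff_policy()] over the tissue samples.
#' @return A tibble of class `ovary_calls`: one row per gene with
#'   per-sample fold changes (`fold_<sample>`), the `call`, and an
#'   `ovary_set` logical.
#' @export
call_ovary_set <- function(expr, tissue_samples, reference_sample,
                           fold_threshold = 4, cutoffs) {
  if (!reference_sample %in% expr$sample_id) {
    abort(paste0("reference sample not in expression table: ",
                 reference_sample))
  }
  ref <- expr %>%
    filter(.data$sample_id == reference_sample) %>%
    select("gene_id", ref_raw = "total", ref_norm = "norm_total")
  folds <- expr %>%
    filter(.data$sample_id %in% tissue_samples) %>%
    left_join(ref, by = "gene_id") %>%
    mutate(ref_raw = tidyr::replace_na(.data$ref_raw, 0),
           ref_norm = tidyr::replace_na(.data$ref_norm, 0),
           fold_change = fold_change(.data$norm_total, .data$ref_norm),
           reference_detected = .data$ref_raw > 0)
  calls <- classify_enrichment(
    folds %>% select("gene_id", "sample_id", "fold_change",
                     "dominant_count", "reference_detected"),
    cutoffs, fold_threshold)
  wide <- folds %>%
    select("gene_id", "sample_id", "fold_change") %>%
    tidyr::pivot_wider(names_from = "sample_id", values_from = "fold_change",
                       names_prefix = "fold_")
  out <- calls %>%
    left_join(wide, by = "gene_id") %>%
    mutate(ovary_set = .data$call %in% c("ovary_upregulated",
                                         "ovary_specific")) %>%
    arrange(desc(.data$ovary_set), .data$gene_id)
  class(out) <- c("ovary_calls", class(out))
  out
}

#' Genes enriched in some but not all tissue samples
#'
#' Lists genes meeting the fold-change or specificity criterion in at
#' least one tissue sample but not in all of them (those meeting it in all
#' belong to the ovary set instead).
#'
#' @inheritParams call_ovary_set
#' @return A tibble of gene ids with the number of qualifying samples.
#' @export
upregulated_in_any <- function(expr, tissue_samples, reference_sample,
                               fold_threshold = 4, cutoffs) {
  ref <- expr %>%
    filter(.data$sample_id == reference_sample) %>%
    select("gene_id", ref_raw = "total", ref_norm = "norm_total")
  expr %>%
    filter(.data$sample_id %in% tissue_samples) %>%
    left_join(ref, by = "gene_id") %>%
    mutate(ref_raw = tidyr::replace_na(.data$ref_raw, 0),
           ref_norm = tidyr::replace_na(.data$ref_norm, 0),
           above = .data$dominant_count >
             cutoff_for(cutoffs, .data$sample_id),
           qualifies = .data$above &
             ((.data$ref_norm > 0 &
                 .data$norm_total / .data$ref_norm > fold_threshold) |
                .data$ref_raw == 0)) %>%
    group_by(.data$gene_id) %>%
    summarise(n_qualifying = sum(.data$qualifies), n_samples = n(),
              .groups = "drop") %>%
    filter(.data$n_qualifying > 0, .data$n_qualifying < .data$n_samples) %>%
    arrange(.data$gene_id)
}

#' Top-n abundance rank table for one sample
#'
#' Genes are ranked by normalised total count, descending; ties are broken
#' lexicographically by gene id. Mirrors the "ten most abundant miRNAs"
#' style of summary table.
#'
#' @param expr An [expression_table()].
#' @param sample Sample id to rank.
#' @param n Number of rows to return (the full list if fewer genes).
#' @return A tibble `rank`, `gene_id`, `norm_total`.
#' @export
rank_table <- function(expr, sample, n = 10L) {
  if (n < 1L) abort("rank_table: `n` must be >= 1")
  expr %>%
    filter(.data$sample_id == sample) %>%
    arrange(desc(.data$norm_total), .data$gene_id) %>%
    head(n) %>%
    mutate(rank = row_number()) %>%
    select("rank", "gene_id", "norm_total")
}
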