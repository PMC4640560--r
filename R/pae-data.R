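#' Novel ovarian miRNAs of the speckled wood butterfly
#'
#' The 11 miRNA precursors discovered in *Pararge aegeria* ovary small-RNA
#' libraries that were absent from the earlier whole-body pooled survey,
#' with their printed 5' and 3' mature products. Bundled as a plain-text
#' fixture; every mature product is an exact substring of its precursor.
#'
#' @return A hairpin catalogue tibble (see [hairpin_catalog()]).
#' @export
pae_novel_mirnas <- function() {
  d <- readr::read_tsv(
    system.file("extdata", "pae_novel_mirnas.tsv", package = "mirovary"),
    col_types = readr::cols(.default = "c"), progress = FALSE)
  hairpin_catalog(d$gene_id, d$precursor, d$mature_5p, d$mature_3p)
}

#' Ovary-set candidate read counts for the speckled wood butterfly
#'
#' Per-gene total, 5'-arm and 3'-arm read counts in the St Hubert
#' (Belgium) and Zonza (Corsica) ovary libraries, with the fold change of
#' normalised total counts over the whole-body reference library (`NA`
#' where the gene was not detected in the reference at all).
#'
#' @return A tidy tibble: `gene_id`, `sample_id`, `total`, `count_5p`,
#'   `count_3p`, `fold_change`.
#' @export
pae_ovary_counts <- function() {
  readr::read_tsv(
    system.file("extdata", "pae_ovary_counts.tsv", package = "mirovary"),
    col_types = readr::cols(gene_id = "c", sample_id = "c", total = "d",
                            count_5p = "d", count_3p = "d",
                            fold_change = "d"),
    progress = FALSE)
}

#' Stand-in mature products for the ovary-set genes
#'
#' Mature 5'/3' sequences for the ovary-set candidate genes, used to
#' exercise the shared-arm merge rule (Par-340 and Par-341 share an
#' identical 3' mature). Sequences for the newly discovered genes are the
#' real printed products; those for the previously catalogued genes are
#' synthetic stand-ins (the survey tables do not print them), constructed
#' so that only Par-340/Par-341 share an arm.
#'
#' @return A tibble `gene_id`, `mature_5p`, `mature_3p`.
#' @export
pae_ovary_matures <- function() {
  readr::read_tsv(
    system.file("extdata", "pae_ovary_matures_synthetic.tsv",
                package = "mirovary"),
    col_types = readr::cols(.default = "c"), progress = FALSE)
}

#' Survey tallies for the speckled wood ovarian miRNA analysis
#'
#' The headline counts of the curation funnel: 139 previously catalogued
#' miRNA genes; 80 and 76 of them with reads in the St Hubert and Zonza
#' ovary libraries; 58 and 57 above the per-sample cutoffs, 52 above
#' cutoff in both; and 11 newly discovered genes (6 St Hubert-only,
#' 2 Zonza-only, 3 shared).
#'
#' @return A named list of integer tallies.
#' @export
pae_survey_tallies <- function() {
  list(known_catalog = 139L,
       known_with_reads = c(st_hubert = 80L, zonza = 76L),
       known_above_cutoff = c(st_hubert = 58L, zonza = 57L),
       known_shared = 52L,
       novel_only = c(st_hubert = 6L, zonza = 2L),
       novel_shared = 3L,
       cutoffs = c(st_hubert = 18, zonza = 50))
}

#' Representative per-sample presence decisions from the survey tallies
#'
#' Constructs gene-id level pass/fail decisions for two samples that are
#' consistent with [pae_survey_tallies()] (58 and 57 known genes above
#' cutoff with 52 shared; 11 novel genes of which 3 are shared), so the
#' set arithmetic of [cross_sample_presence()] can be exercised on them.
#' Gene identities are placeholders; only the set sizes are meaningful.
#'
#' @return A list with `decisions` (tibble `gene_id`, `sample_id`,
#'   `passed`) and `status` (tibble `gene_id`, `status`).
#' @export
pae_presence_sets <- function() {
  t <- pae_survey_tallies()
  known_ids <- sprintf("known-%03d", seq_len(t$known_catalog))
  shared_known <- known_ids[seq_len(t$known_shared)]
  sth_only_known <- known_ids[t$known_shared +
                                seq_len(t$known_above_cutoff[["st_hubert"]] -
                                          t$known_shared)]
  zon_only_known <- known_ids[t$known_above_cutoff[["st_hubert"]] +
                                seq_len(t$known_above_cutoff[["zonza"]] -
                                          t$known_shared)]
  novel_shared <- sprintf("novel-shared-%02d", seq_len(t$novel_shared))
  novel_sth <- sprintf("novel-sth-%02d", seq_len(t$novel_only[["st_hubert"]]))
  novel_zon <- sprintf("novel-zon-%02d", seq_len(t$novel_only[["zonza"]]))
  all_ids <- c(known_ids, novel_shared, novel_sth, novel_zon)
  pass_sth <- c(shared_known, sth_only_known, novel_shared, novel_sth)
  pass_zon <- c(shared_known, zon_only_known, novel_shared, novel_zon)
  decisions <- bind_rows(
    tibble(gene_id = all_ids, sample_id = "st_hubert",
           passed = all_ids %in% pass_sth),
    tibble(gene_id = all_ids, sample_id = "zonza",
           passed = all_ids %in% pass_zon))
  status <- tibble(gene_id = all_ids,
                   status = if_else(startsWith(all_ids, "known-"),
                                    "known", "novel"))
  list(decisions = decisions, status = status)
}
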