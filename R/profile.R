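#' Map collapsed reads onto hairpin precursors
#'
#' A read maps to a gene iff its length lies in `[min_len, max_len]` and it
#' occurs as an exact substring of the precursor (sequences are
#' RNA-normalised, so T/U and case differences do not matter). Reads
#' matching more than one gene are assigned fractionally in equal shares,
#' preserving total counts; within a gene the leftmost occurrence is used.
#'
#' @param library A read library tibble (see [read_library()]).
#' @param hairpins A hairpin catalogue tibble.
#' @param min_len,max_len Read length bounds (nt) for mapping.
#' @return A tibble with columns `sample_id`, `gene_id`, `seq`, `start`
#'   (1-based position in the precursor), `length`, and fractional `count`.
#' @export
map_reads <- function(library, hairpins, min_len = 18L, max_len = 26L) {
  if (min_len > max_len) abort("map_reads: `min_len` must be <= `max_len`")
  reads <- library %>% filter(nchar(.data$seq) >= min_len,
                              nchar(.data$seq) <= max_len)
  if (nrow(reads) == 0L) {
    return(tibble(sample_id = character(), gene_id = character(),
                  seq = character(), start = integer(), length = integer(),
                  count = numeric()))
  }
  hits <- purrr::map_dfr(seq_len(nrow(hairpins)), function(i) {
    loc <- stringr::str_locate(hairpins$precursor[i],
                               stringr::fixed(reads$seq))[, 1]
    ok <- !is.na(loc)
    if (!any(ok)) return(NULL)
    tibble(sample_id = reads$sample_id[ok],
           gene_id = hairpins$gene_id[i],
           seq = reads$seq[ok],
           start = as.integer(loc[ok]),
           length = nchar(reads$seq[ok]),
           count = reads$count[ok])
  })
  if (nrow(hits) == 0L) return(hits)
  hits %>%
    group_by(.data$sample_id, .data$seq) %>%
    mutate(count = .data$count / dplyr::n_distinct(.data$gene_id)) %>%
    ungroup() %>%
    arrange(.data$sample_id, .data$gene_id, .data$start, .data$seq)
}

#' Build per-gene, per-sample arm profiles
#'
#' Each mapped read is assigned to the arm whose mature interval its start
#' position falls in, with a tolerance of `loop_tolerance` nt on either
#' side of each interval; reads starting outside both tolerant intervals
#' (inside the loop or in the flanks) are discarded from arm counts. The
#' 5'-start homogeneity of an arm is the fraction of its reads sharing the
#' modal start position (NA for arms with no reads). The dominant arm is
#' the arm with the larger count, ties going to 5p.
#'
#' @param mapped Output of [map_reads()].
#' @param hairpins A hairpin catalogue tibble.
#' @param loop_tolerance Positional tolerance (nt) around each mature
#'   interval when assigning reads to arms.
#' @param samples Sample ids to profile; defaults to those present in
#'   `mapped`. Every gene in `hairpins` gets a row per sample, including
#'   zero-read profiles.
#' @return A tibble with columns `gene_id`, `sample_id`, `count_5p`,
#'   `count_3p`, `total`, `dominant_arm`, `dominant_count`,
#'   `homogeneity_5p`, `homogeneity_3p`.
#' @export
arm_profiles <- function(mapped, hairpins, loop_tolerance = 3L,
                         samples = NULL) {
  samples <- samples %||% unique(mapped$sample_id)
  skeleton <- tidyr::expand_grid(gene_id = hairpins$gene_id,
                                 sample_id = samples)
  if (nrow(mapped) > 0L) {
    assigned <- mapped %>%
      inner_join(hairpins %>% select("gene_id", "arm5_start", "arm5_end",
                                     "arm3_start", "arm3_end"),
                 by = "gene_id") %>%
      mutate(arm = case_when(
        .data$start >= .data$arm5_start - loop_tolerance &
          .data$start <= .data$arm5_end + loop_tolerance ~ "5p",
        .data$start >= .data$arm3_start - loop_tolerance &
          .data$start <= .data$arm3_end + loop_tolerance ~ "3p",
        TRUE ~ NA_character_)) %>%
      filter(!is.na(.data$arm))
    per_arm <- assigned %>%
      group_by(.data$gene_id, .data$sample_id, .data$arm) %>%
      summarise(arm_count = sum(.data$count),
                modal = max(tapply(.data$count, .data$start, sum)),
                .groups = "drop") %>%
      mutate(homogeneity = .data$modal / .data$arm_count) %>%
      select(-"modal") %>%
      tidyr::pivot_wider(names_from = "arm",
                         values_from = c("arm_count", "homogeneity"))
  } else {
    per_arm <- tibble(gene_id = character(), sample_id = character())
  }
  for (col in c("arm_count_5p", "arm_count_3p",
                "homogeneity_5p", "homogeneity_3p")) {
    if (!col %in% names(per_arm)) per_arm[[col]] <- rep(NA_real_, nrow(per_arm))
  }
  skeleton %>%
    left_join(per_arm, by = c("gene_id", "sample_id")) %>%
    mutate(count_5p = tidyr::replace_na(.data$arm_count_5p, 0),
           count_3p = tidyr::replace_na(.data$arm_count_3p, 0),
           total = .data$count_5p + .data$count_3p,
           dominant_arm = if_else(.data$count_5p >= .data$count_3p, "5p", "3p"),
           dominant_count = pmax(.data$count_5p, .data$count_3p)) %>%
    select("gene_id", "sample_id", "count_5p", "count_3p", "total",
           "dominant_arm", "dominant_count",
           "homogeneity_5p", "homogeneity_3p") %>%
    arrange(.data$sample_id, .data$gene_id)
}

#' Profile one library against a hairpin catalogue
#'
#' Convenience wrapper: [map_reads()] then [arm_profiles()].
#'
#' @inheritParams map_reads
#' @inheritParams arm_profiles
#' @return An arm-profile tibble (see [arm_profiles()]).
#' @export
profile_library <- function(library, hairpins, min_len = 18L, max_len = 26L,
                            loop_tolerance = 3L) {
  sid <- unique(library$sample_id)
  if (length(sid) == 0L) sid <- "sample"
  arm_profiles(map_reads(library, hairpins, min_len, max_len), hairpins,
               loop_tolerance, samples = sid)
}
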