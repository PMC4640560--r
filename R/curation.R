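#' Flag hairpins matching a contaminant catalogue
#'
#' A hairpin is flagged as a contaminant hit when its precursor shares an
#' exact common substring of at least `min_hit_len` nt with any catalogue
#' entry, on either strand of the entry (the reverse complement is also
#' scanned). Used to remove degradation products of rRNA/tRNA/other
#' non-coding RNAs and repetitive elements.
#'
#' @param hairpins A hairpin catalogue tibble.
#' @param contaminants Character vector of contaminant sequences (empty
#'   vector means every hairpin passes).
#' @param min_hit_len Minimum shared-substring length to call a hit.
#' @return A tibble with columns `gene_id`, `contaminant_hit` (logical).
#' @export
filter_contaminants <- function(hairpins, contaminants, min_hit_len = 16L) {
  cat_norm <- rna_normalize(contaminants)
  both <- c(cat_norm, rna_revcomp(cat_norm))
  hit <- vapply(hairpins$precursor, function(p) {
    any(vapply(both, function(s) shares_kmer(p, s, min_hit_len), logical(1)))
  }, logical(1), USE.NAMES = FALSE)
  tibble(gene_id = hairpins$gene_id, contaminant_hit = hit)
}

#' Per-sample dominant-arm read-count cutoffs
#'
#' @param ... Named thresholds, one per sample id (e.g.
#'   `cutoff_policy(st_hubert = 18, zonza = 50)`). A gene passes a sample's
#'   cutoff when its dominant-arm count is strictly greater than the
#'   threshold.
#' @return A named numeric vector of class `cutoff_policy`.
#' @export
cutoff_policy <- function(...) {
  x <- c(...)
  if (is.null(names(x)) || any(names(x) == "")) {
    abort("cutoff_policy: every threshold must be named by sample id")
  }
  if (any(x < 0)) abort("cutoff_policy: thresholds must be >= 0")
  structure(setNames(as.numeric(x), names(x)), class = "cutoff_policy")
}

cutoff_for <- function(cutoffs, sample_id) {
  miss <- setdiff(unique(sample_id), names(cutoffs))
  if (length(miss)) {
    abort(paste0("no cutoff configured for sample(s): ",
                 paste(miss, collapse = ", ")))
  }
  unname(cutoffs[sample_id])
}

#' Apply the both-arm and 5'-start homogeneity filters
#'
#' A profile fails `single_arm` when either arm has zero reads, otherwise
#' fails `low_homogeneity` when either arm's modal 5'-start fraction is
#' below `min_homogeneity` (the boundary is inclusive: exactly
#' `min_homogeneity` passes), otherwise passes.
#'
#' @param profiles An arm-profile tibble (see [arm_profiles()]).
#' @param min_homogeneity Minimum modal 5'-start fraction per arm.
#' @return `profiles` with an added `structural_rule` column
#'   (`"single_arm"`, `"low_homogeneity"`, or `"none"`).
#' @export
apply_structural_filters <- function(profiles, min_homogeneity = 0.95) {
  profiles %>%
    mutate(structural_rule = case_when(
      .data$count_5p == 0 | .data$count_3p == 0 ~ "single_arm",
      .data$homogeneity_5p < min_homogeneity |
        .data$homogeneity_3p < min_homogeneity ~ "low_homogeneity",
      TRUE ~ "none"))
}

#' Apply the per-sample dominant-arm expression cutoff
#'
#' @param profiles An arm-profile tibble.
#' @param cutoffs A [cutoff_policy()].
#' @return `profiles` with an added logical `above_cutoff` column
#'   (`dominant_count` strictly greater than the sample's threshold).
#' @export
apply_expression_cutoff <- function(profiles, cutoffs) {
  profiles %>%
    mutate(above_cutoff = .data$dominant_count >
             cutoff_for(cutoffs, .data$sample_id))
}

#' Run the full curation cascade
#'
#' Applies, in order: contaminant removal, the both-arm rule, the
#' 5'-start homogeneity rule, and the per-sample expression cutoff. Only
#' the first failing rule is recorded. By default the contaminant and
#' structural rules are applied to novel candidates only, while the
#' expression cutoff applies to all genes; pass
#' `apply_structural = "all"` to subject known miRNAs to every rule.
#'
#' @param profiles An arm-profile tibble.
#' @param cutoffs A [cutoff_policy()].
#' @param hairpins Hairpin catalogue (needed when `contaminants` given).
#' @param contaminants Optional contaminant sequence vector.
#' @param status Optional tibble (`gene_id`, `status`) with status
#'   `"known"` or `"novel"` (see [annotate_known()]); when `NULL`, all
#'   genes are treated as novel candidates.
#' @param min_homogeneity Minimum per-arm modal 5'-start fraction.
#' @param min_hit_len Contaminant shared-substring threshold.
#' @param apply_structural `"novel"` (default) or `"all"`: which genes the
#'   contaminant/structural rules apply to.
#' @return A decisions tibble: `gene_id`, `sample_id`, `passed`,
#'   `failed_rule` (`contaminant`, `single_arm`, `low_homogeneity`,
#'   `below_cutoff`, or `none`), `dominant_count`.
#' @export
curate_profiles <- function(profiles, cutoffs, hairpins = NULL,
                            contaminants = NULL, status = NULL,
                            min_homogeneity = 0.95, min_hit_len = 16L,
                            apply_structural = c("novel", "all")) {
  apply_structural <- match.arg(apply_structural)
  d <- profiles
  if (is.null(status)) {
    d$status <- "novel"
  } else {
    d <- d %>% left_join(status %>% select("gene_id", "status"), by = "gene_id")
    d$status[is.na(d$status)] <- "novel"
  }
  d$structural_scope <- apply_structural == "all" | d$status == "novel"

  if (!is.null(contaminants) && length(contaminants) > 0L) {
    if (is.null(hairpins)) {
      abort("curate_profiles: `hairpins` required to screen contaminants")
    }
    ch <- filter_contaminants(hairpins, contaminants, min_hit_len)
    d <- d %>% left_join(ch, by = "gene_id")
    d$contaminant_hit[is.na(d$contaminant_hit)] <- FALSE
  } else {
    d$contaminant_hit <- FALSE
  }

  d <- apply_structural_filters(d, min_homogeneity)
  d <- apply_expression_cutoff(d, cutoffs)
  d %>%
    mutate(failed_rule = case_when(
      .data$structural_scope & .data$contaminant_hit ~ "contaminant",
      .data$structural_scope & .data$structural_rule != "none" ~
        .data$structural_rule,
      !.data$above_cutoff ~ "below_cutoff",
      TRUE ~ "none"),
      passed = .data$failed_rule == "none") %>%
    select("gene_id", "sample_id", "passed", "failed_rule",
           "dominant_count") %>%
    arrange(.data$sample_id, .data$gene_id)
}

#' Annotate candidates as known or novel by mature-product identity
#'
#' A candidate is known when either of its mature products matches a
#' catalogued mature sequence with at most `max_mismatches` substitutions,
#' comparing equal-length windows over a +/-`max_offset`-nt shift (the best
#' window counts).
#'
#' @param hairpins A hairpin catalogue tibble of candidates.
#' @param known A tibble (`id`, `mature`) of catalogued mature sequences,
#'   or a named character vector (names are ids).
#' @param max_mismatches Substitution budget for a match.
#' @param max_offset Window shift allowance (nt).
#' @return A tibble `gene_id`, `known_id` (first matching catalogue id or
#'   NA), `status` (`"known"`/`"novel"`).
#' @export
annotate_known <- function(hairpins, known, max_mismatches = 2L,
                           max_offset = 2L) {
  if (is.character(known)) {
    known <- tibble(id = names(known) %||% paste0("known_", seq_along(known)),
                    mature = unname(known))
  }
  known$mature <- rna_normalize(known$mature)
  hit_id <- vapply(seq_len(nrow(hairpins)), function(i) {
    for (j in seq_len(nrow(known))) {
      if (window_mismatches(hairpins$mature_5p[i], known$mature[j],
                            max_offset) <= max_mismatches ||
          window_mismatches(hairpins$mature_3p[i], known$mature[j],
                            max_offset) <= max_mismatches) {
        return(known$id[j])
      }
    }
    NA_character_
  }, character(1))
  tibble(gene_id = hairpins$gene_id, known_id = hit_id,
         status = if_else(is.na(hit_id), "novel", "known"))
}

#' Merge genes that share identical mature products
#'
#' Genes whose mature products (either arm) are identical sequences are
#' grouped by transitive closure; a group is named by its members' ids
#' joined with `/`. Group arm counts are the per-sample maximum (not sum)
#' over members, so reads shared between paralogues are not double-counted.
#'
#' @param profiles An arm-profile tibble.
#' @param matures A tibble (`gene_id`, `mature_5p`, `mature_3p`), e.g. a
#'   hairpin catalogue.
#' @return A list with `groups` (tibble `gene_id`, `group_id`) and
#'   `profiles` (merged arm-profile tibble keyed by `group_id` in the
#'   `gene_id` column, dominant arm recomputed).
#' @export
merge_shared_arm <- function(profiles, matures) {
  matures <- matures %>%
    mutate(mature_5p = rna_normalize(.data$mature_5p),
           mature_3p = rna_normalize(.data$mature_3p))
  long <- bind_rows(
    matures %>% select("gene_id", mature = "mature_5p"),
    matures %>% select("gene_id", mature = "mature_3p"))
  edges <- long %>%
    inner_join(long, by = "mature", relationship = "many-to-many") %>%
    filter(.data$gene_id.x < .data$gene_id.y) %>%
    distinct(.data$gene_id.x, .data$gene_id.y)
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = tibble(name = matures$gene_id))
  comp <- igraph::components(g)$membership
  groups <- tibble(gene_id = names(comp), comp = unname(comp)) %>%
    group_by(.data$comp) %>%
    mutate(group_id = paste(sort(.data$gene_id), collapse = "/")) %>%
    ungroup() %>%
    select("gene_id", "group_id")
  merged <- profiles %>%
    left_join(groups, by = "gene_id") %>%
    mutate(group_id = dplyr::coalesce(.data$group_id, .data$gene_id)) %>%
    group_by(gene_id = .data$group_id, .data$sample_id) %>%
    summarise(count_5p = max(.data$count_5p), count_3p = max(.data$count_3p),
              .groups = "drop") %>%
    mutate(total = .data$count_5p + .data$count_3p,
           dominant_arm = if_else(.data$count_5p >= .data$count_3p,
                                  "5p", "3p"),
           dominant_count = pmax(.data$count_5p, .data$count_3p)) %>%
    arrange(.data$sample_id, .data$gene_id)
  list(groups = groups, profiles = merged)
}

#' Cross-sample presence and set arithmetic
#'
#' Summarises which genes pass curation in which samples: per-sample
#' counts, the genes passing in every sample (shared), and in at least one
#' (union), broken down by known/novel status.
#'
#' @param decisions A decisions tibble from [curate_profiles()] (columns
#'   `gene_id`, `sample_id`, `passed`).
#' @param status Optional tibble (`gene_id`, `status`); when `NULL` all
#'   genes count under class `"all"` only.
#' @return A list with `presence` (wide tibble, one logical column per
#'   sample) and `summary` (tibble: `class`, one `n_<sample>` column per
#'   sample, `n_shared`, `n_union`).
#' @export
cross_sample_presence <- function(decisions, status = NULL) {
  samples <- sort(unique(decisions$sample_id))
  if (length(samples) < 2L) {
    abort("cross_sample_presence: need at least two curated samples")
  }
  presence <- decisions %>%
    select("gene_id", "sample_id", "passed") %>%
    tidyr::pivot_wider(names_from = "sample_id", values_from = "passed",
                       values_fill = FALSE)
  if (!is.null(status)) {
    presence <- presence %>%
      left_join(status %>% select("gene_id", "status"), by = "gene_id") %>%
      mutate(status = dplyr::coalesce(.data$status, "novel"))
  } else {
    presence$status <- "all"
  }
  pres_mat <- as.matrix(presence[, samples, drop = FALSE])
  summarise_class <- function(rows, label) {
    m <- pres_mat[rows, , drop = FALSE]
    out <- tibble(class = label)
    for (s in samples) out[[paste0("n_", s)]] <- sum(m[, s])
    out$n_shared <- sum(rowSums(m) == length(samples))
    out$n_union <- sum(rowSums(m) > 0)
    out
  }
  classes <- unique(presence$status)
  summary <- bind_rows(
    purrr::map(classes, ~ summarise_class(presence$status == .x, .x)))
  if (!identical(classes, "all")) {
    summary <- bind_rows(summary,
                         summarise_class(rep(TRUE, nrow(presence)), "all"))
  }
  list(presence = presence %>% select("gene_id", "status",
                                      dplyr::all_of(samples)),
       summary = summary)
}
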