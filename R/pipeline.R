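#' Load and validate a pipeline run configuration
#'
#' The configuration is a YAML file (or equivalent list) with:
#' \describe{
#'   \item{samples}{list of `{id, reads, role}` entries; `role` is
#'     `"tissue"` or `"reference"`; `reads` is a collapsed FASTA
#'     (`>{id}_x{count}`) or FASTQ path. At least one tissue sample.}
#'   \item{hairpins}{`{fasta, matures}` paths for the precursor catalogue.}
#'   \item{contaminants}{optional contaminant FASTA path.}
#'   \item{known}{optional TSV (`id`, `mature`) of catalogued matures.}
#'   \item{species}{optional named map species -> mature FASTA path.}
#'   \item{thresholds}{`cutoffs` (named per tissue sample id),
#'     `min_homogeneity` (0.95), `fold_threshold` (4), `min_len` (18),
#'     `max_len` (26), `max_mismatches` (2), `min_hit_len` (16).}
#'   \item{seed}{integer seed echoed into the manifest.}
#' }
#'
#' @param config Path to a YAML file, or a list with the same structure.
#' @return A validated list of class `run_config`.
#' @export
read_run_config <- function(config) {
  cfg <- if (is.character(config)) {
    if (!file.exists(config)) abort(paste0("config file not found: ", config))
    yaml::read_yaml(config)
  } else {
    config
  }
  if (is.null(cfg$samples) || length(cfg$samples) == 0L) {
    abort("run config: `samples` must list at least one sample")
  }
  roles <- vapply(cfg$samples, function(s) s$role %||% "tissue", character(1))
  if (!any(roles == "tissue")) {
    abort("run config: at least one sample must have role 'tissue'")
  }
  if (sum(roles == "reference") > 1L) {
    abort("run config: at most one reference sample")
  }
  if (is.null(cfg$hairpins$fasta) || is.null(cfg$hairpins$matures)) {
    abort("run config: `hairpins` needs `fasta` and `matures` paths")
  }
  defaults <- list(min_homogeneity = 0.95, fold_threshold = 4,
                   min_len = 18L, max_len = 26L, max_mismatches = 2L,
                   min_hit_len = 16L)
  cfg$thresholds <- modifyList(defaults, cfg$thresholds %||% list())
  th <- cfg$thresholds
  if (th$min_homogeneity < 0 || th$min_homogeneity > 1) {
    abort("run config: `min_homogeneity` must be in [0, 1]")
  }
  if (th$min_len > th$max_len) {
    abort("run config: `min_len` must be <= `max_len`")
  }
  tissue_ids <- vapply(cfg$samples[roles == "tissue"], `[[`, character(1), "id")
  if (is.null(th$cutoffs) || !all(tissue_ids %in% names(th$cutoffs))) {
    abort("run config: `thresholds$cutoffs` must name every tissue sample")
  }
  for (s in cfg$samples) {
    if (!file.exists(s$reads)) {
      abort(paste0("reads file not found: ", s$reads))
    }
  }
  for (p in c(cfg$hairpins$fasta, cfg$hairpins$matures, cfg$contaminants,
              cfg$known, unlist(cfg$species))) {
    if (!is.null(p) && !file.exists(p)) abort(paste0("file not found: ", p))
  }
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  structure(cfg, class = "run_config")
}

read_sample_reads <- function(path, sample_id) {
  first <- readLines(path, n = 1L)
  if (length(first) && startsWith(first, "@")) {
    read_fastq_reads(path, sample_id)
  } else {
    read_collapsed_fasta(path, sample_id)
  }
}

#' Run the full ovarian miRNA pipeline
#'
#' Executes profile -> curate -> annotate -> enrich -> stats on the
#' configured samples and writes every stage as a headed TSV plus a run
#' manifest (config echo, package version, input checksums) so any stage
#' can be inspected or re-entered. Identical config and inputs give
#' identical outputs. When no reference sample is configured, enrichment
#' fold changes are reported as NA with a warning (degraded mode).
#'
#' @param config A `run_config` (or path/list accepted by
#'   [read_run_config()]).
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list with all stage results (`profiles`,
#'   `decisions`, `presence`, `groups`, `expression`, `calls`,
#'   `annotations`, `report`).
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (inherits(config, "run_config")) config else
    read_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  th <- cfg$thresholds

  hairpins <- read_hairpins(cfg$hairpins$fasta, cfg$hairpins$matures)
  contaminants <- if (!is.null(cfg$contaminants)) {
    unname(as.character(Biostrings::readBStringSet(cfg$contaminants)))
  }
  known <- if (!is.null(cfg$known)) {
    readr::read_tsv(cfg$known, col_types = readr::cols(.default = "c"),
                    progress = FALSE)
  }
  species_catalogues <- if (!is.null(cfg$species)) {
    lapply(cfg$species, function(p) {
      x <- as.character(Biostrings::readBStringSet(p)); names(x) <- NULL; x
    })
  } else {
    list()
  }

  roles <- vapply(cfg$samples, function(s) s$role %||% "tissue", character(1))
  tissue_ids <- vapply(cfg$samples[roles == "tissue"], `[[`, character(1), "id")
  reference_id <- if (any(roles == "reference")) {
    cfg$samples[[which(roles == "reference")]]$id
  }

  message("mirovary: profiling ", length(cfg$samples), " sample(s) against ",
          nrow(hairpins), " hairpins")
  profiles <- purrr::map_dfr(cfg$samples, function(s) {
    lib <- read_sample_reads(s$reads, s$id)
    message("  ", s$id, ": ", round(library_depth(lib)), " reads (",
            nrow(lib), " unique)")
    profile_library(lib, hairpins, th$min_len, th$max_len)
  })

  status <- if (!is.null(known)) {
    annotate_known(hairpins, known, th$max_mismatches)
  } else {
    tibble(gene_id = hairpins$gene_id, known_id = NA_character_,
           status = "novel")
  }

  cutoffs <- do.call(cutoff_policy, as.list(th$cutoffs))
  decisions <- curate_profiles(
    profiles %>% filter(.data$sample_id %in% tissue_ids),
    cutoffs, hairpins = hairpins, contaminants = contaminants,
    status = status, min_homogeneity = th$min_homogeneity,
    min_hit_len = th$min_hit_len)
  message("  curation: ", sum(decisions$passed), "/", nrow(decisions),
          " gene-sample pairs pass")

  presence <- if (length(tissue_ids) >= 2L) {
    cross_sample_presence(decisions, status)
  }

  merged <- merge_shared_arm(profiles, hairpins)
  expr <- expression_table(merged$profiles)

  calls <- NULL
  if (!is.null(reference_id)) {
    calls <- call_ovary_set(expr, tissue_ids, reference_id,
                            th$fold_threshold, cutoffs)
    message("  ovary set: ", sum(calls$ovary_set), " gene group(s)")
  } else {
    warn("no reference sample configured; fold changes not computed")
  }

  annotations <- assign_origin(
    classify_conservation(hairpins, species_catalogues, th$max_mismatches))
  ann_groups <- annotations %>%
    left_join(merged$groups, by = "gene_id") %>%
    mutate(gene_id = dplyr::coalesce(.data$group_id, .data$gene_id)) %>%
    group_by(.data$gene_id) %>%
    summarise(age_class = if_else(any(.data$age_class == "conserved"),
                                  "conserved", "lineage_specific"),
              origin = first(.data$origin), .groups = "drop")

  shared_genes <- if (!is.null(presence)) {
    pr <- presence$presence
    pr$gene_id[rowSums(as.matrix(pr[, tissue_ids, drop = FALSE])) ==
                 length(tissue_ids)]
  }
  report <- age_expression_report(expr, ann_groups, subset = shared_genes)

  # stage TSVs
  wt <- function(x, f) readr::write_tsv(x, file.path(out_dir, f),
                                        progress = FALSE)
  wt(profiles, "profiles.tsv")
  wt(decisions, "decisions.tsv")
  wt(status, "annotations_known.tsv")
  if (!is.null(presence)) wt(presence$summary, "presence_summary.tsv")
  wt(expr, "expression.tsv")
  if (!is.null(calls)) wt(as_tibble(calls), "ovary_calls.tsv")
  wt(annotations %>%
       mutate(hit_species = vapply(.data$hit_species, paste,
                                   character(1), collapse = ";")),
     "annotations_age.tsv")
  wt(report$per_sample, "stats_per_sample.tsv")

  inputs <- c(vapply(cfg$samples, `[[`, character(1), "reads"),
              cfg$hairpins$fasta, cfg$hairpins$matures,
              cfg$contaminants, cfg$known, unlist(cfg$species))
  manifest <- list(
    package_version = as.character(utils::packageVersion("mirovary")),
    seed = cfg$seed,
    thresholds = th,
    samples = cfg$samples,
    input_md5 = as.list(tools::md5sum(inputs)))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))

  invisible(list(profiles = profiles, decisions = decisions,
                 presence = presence, groups = merged$groups,
                 expression = expr, calls = calls,
                 annotations = annotations, report = report))
}
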