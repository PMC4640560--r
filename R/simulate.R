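#' Simulation parameters for synthetic ovarian small-RNA data
#'
#' Collects the knobs of the synthetic-data generator. The generator
#' emulates hairpin-derived small-RNA libraries: per-gene log-normal
#' expression with an age-dependent shift, configurable 5'-arm bias,
#' isomiR 5'-start heterogeneity, degradation/contaminant reads, and a
#' planted subset of tissue-enriched genes.
#'
#' @param n_mirnas Number of hairpin genes to simulate.
#' @param conserved_fraction Proportion of genes labelled conserved
#'   (planted into at least one species catalogue).
#' @param depth Total reads per simulated library.
#' @param arm_bias Proportion of a gene's reads arising from the 5' arm.
#' @param homogeneity Probability a read starts at the canonical mature
#'   5' position of its arm; the remainder is spread over `offset_probs`.
#' @param offset_probs Named numeric vector of probabilities over non-zero
#'   5' offsets `-3..-1, 1..3`; normalised internally.
#' @param contaminant_fraction Proportion of the library drawn from
#'   contaminant/degradation sequences rather than hairpins.
#' @param enrichment_factor Multiplier applied to planted tissue-enriched
#'   genes' expression weights in tissue (ovary) samples; must be >= 1.
#' @param age_effect Shift added to the log-mean expression of conserved
#'   genes (natural-log scale).
#' @param sdlog Log-normal sd of per-gene expression weights.
#' @param n_enriched Number of genes planted as tissue-enriched; defaults
#'   to `min(5, n_mirnas)`.
#' @param n_contaminants Number of contaminant catalogue sequences.
#' @param seed Integer seed driving all randomness of the generator.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_mirnas = 150L,
                       conserved_fraction = 0.55,
                       depth = 1e6,
                       arm_bias = 0.8,
                       homogeneity = 0.98,
                       offset_probs = c(`-3` = 0.10, `-2` = 0.15, `-1` = 0.25,
                                        `1` = 0.25, `2` = 0.15, `3` = 0.10),
                       contaminant_fraction = 0.1,
                       enrichment_factor = 8,
                       age_effect = 1.5,
                       sdlog = 2,
                       n_enriched = NULL,
                       n_contaminants = 20L,
                       seed = 1L) {
  p <- list(n_mirnas = as.integer(n_mirnas),
            conserved_fraction = conserved_fraction, depth = depth,
            arm_bias = arm_bias, homogeneity = homogeneity,
            offset_probs = offset_probs / sum(offset_probs),
            contaminant_fraction = contaminant_fraction,
            enrichment_factor = enrichment_factor, age_effect = age_effect,
            sdlog = sdlog,
            n_enriched = as.integer(n_enriched %||% min(5L, n_mirnas)),
            n_contaminants = as.integer(n_contaminants),
            seed = as.integer(seed))
  check_prop <- function(field) {
    v <- p[[field]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      abort(paste0("sim_params: `", field, "` must be a proportion in [0, 1]"))
    }
  }
  for (f in c("conserved_fraction", "arm_bias", "homogeneity",
              "contaminant_fraction")) check_prop(f)
  if (!is.numeric(p$depth) || p$depth <= 0) {
    abort("sim_params: `depth` must be > 0")
  }
  if (p$enrichment_factor < 1) {
    abort("sim_params: `enrichment_factor` must be >= 1")
  }
  if (p$n_mirnas < 1L) abort("sim_params: `n_mirnas` must be >= 1")
  if (p$n_enriched > p$n_mirnas) {
    abort("sim_params: `n_enriched` must not exceed `n_mirnas`")
  }
  structure(p, class = "sim_params")
}

random_rna <- function(n_seqs, len) {
  vapply(seq_len(n_seqs), function(i) {
    paste(sample(c("a", "c", "g", "u"), len[min(i, length(len))],
                 replace = TRUE), collapse = "")
  }, character(1))
}

default_species_names <- function() {
  c("Heliconius melpomene", "Danaus plexippus", "Manduca sexta",
    "Bombyx mori", "Plutella xylostella", "Cameraria ohridella",
    "Glyphotaelius pellucidus")
}

#' Generate a synthetic hairpin catalogue with planted ground truth
#'
#' Builds `n_mirnas` hairpin precursors (60-120 nt) whose 5' and 3' mature
#' products (20-24 nt) are exact substrings separated by a loop, labels a
#' `conserved_fraction` of genes as conserved by planting their 5' mature
#' into 1-3 species catalogues, draws per-gene log-normal expression
#' weights with `age_effect` added to conserved genes' log-mean, plants
#' `n_enriched` genes as tissue-enriched, and generates a contaminant
#' catalogue. Deterministic under a fixed `seed`: the seed initialises one
#' global generator used for the catalogue and (unless reseeded) subsequent
#' library simulation.
#'
#' @param params A [sim_params()] object.
#' @return A list of class `synthetic_catalog` with elements `hairpins`
#'   (hairpin catalogue tibble), `truth` (tibble: `gene_id`, `age`,
#'   `enriched`, `expr_weight`), `species_catalogues` (named list of mature
#'   sequence vectors), `contaminants` (character), and `params`.
#' @export
simulate_catalog <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  n <- params$n_mirnas

  len5 <- sample(20:24, n, replace = TRUE)
  len3 <- sample(20:24, n, replace = TRUE)
  loop <- sample(8:15, n, replace = TRUE)
  fl5 <- sample(6:15, n, replace = TRUE)
  fl3 <- sample(6:15, n, replace = TRUE)

  gene_id <- sprintf("sim-%03d", seq_len(n))
  mature_5p <- random_rna(n, len5)
  mature_3p <- random_rna(n, len3)
  precursor <- paste0(random_rna(n, fl5), mature_5p, random_rna(n, loop),
                      mature_3p, random_rna(n, fl3))
  hairpins <- hairpin_catalog(gene_id, precursor, mature_5p, mature_3p)

  n_cons <- as.integer(round(n * params$conserved_fraction))
  conserved_ids <- sample(gene_id, n_cons)
  age <- if_else(gene_id %in% conserved_ids, "conserved", "lineage_specific")

  species <- default_species_names()
  catalogues <- setNames(
    lapply(species, function(s) random_rna(5L, sample(20:24, 5L, replace = TRUE))),
    species)
  for (g in conserved_ids) {
    hosts <- sample(species, sample(1:3, 1L))
    for (s in hosts) {
      catalogues[[s]] <- c(catalogues[[s]], hairpins$mature_5p[hairpins$gene_id == g])
    }
  }

  enriched_ids <- sample(gene_id, params$n_enriched)
  expr_weight <- rlnorm(n,
                        meanlog = params$age_effect * (age == "conserved"),
                        sdlog = params$sdlog)

  contaminants <- random_rna(params$n_contaminants,
                             sample(80:300, params$n_contaminants, replace = TRUE))

  structure(list(
    hairpins = hairpins,
    truth = tibble(gene_id = gene_id, age = age,
                   enriched = gene_id %in% enriched_ids,
                   expr_weight = expr_weight),
    species_catalogues = catalogues,
    contaminants = contaminants,
    params = params
  ), class = "synthetic_catalog")
}

# Outcome weights over (gene, arm, offset) cells plus contaminant reads.
# Exposed for tests via simulate_library(return_weights = TRUE).
library_outcome_table <- function(catalog, params, tissue) {
  hp <- catalog$hairpins
  truth <- catalog$truth
  w_gene <- truth$expr_weight *
    ifelse(tissue & truth$enriched, params$enrichment_factor, 1)
  offsets <- c(0L, as.integer(names(params$offset_probs)))
  p_off <- c(params$homogeneity, (1 - params$homogeneity) * params$offset_probs)

  cells <- tidyr::expand_grid(idx = seq_len(nrow(hp)),
                              arm = c("5p", "3p"),
                              k = seq_along(offsets))
  cells <- cells %>%
    mutate(gene_id = hp$gene_id[.data$idx],
           offset = offsets[.data$k],
           start = if_else(.data$arm == "5p",
                           hp$arm5_start[.data$idx], hp$arm3_start[.data$idx]) +
                   .data$offset,
           len = if_else(.data$arm == "5p",
                         hp$arm5_end[.data$idx] - hp$arm5_start[.data$idx],
                         hp$arm3_end[.data$idx] - hp$arm3_start[.data$idx]) + 1L,
           seq = substr(hp$precursor[.data$idx], .data$start,
                        .data$start + .data$len - 1L),
           weight = w_gene[.data$idx] *
             if_else(.data$arm == "5p", params$arm_bias, 1 - params$arm_bias) *
             p_off[.data$k]) %>%
    filter(.data$weight > 0, nchar(.data$seq) == .data$len) %>%
    select("gene_id", "arm", "offset", "seq", "weight")

  cells$weight <- cells$weight / sum(cells$weight) *
    (1 - params$contaminant_fraction)

  if (params$contaminant_fraction > 0) {
    m <- 30L
    n_frag <- m %/% 2L
    frag_src <- sample(catalog$contaminants, n_frag, replace = TRUE)
    frag_len <- sample(18:26, n_frag, replace = TRUE)
    frag_start <- vapply(seq_len(n_frag), function(i) {
      sample.int(nchar(frag_src[i]) - frag_len[i] + 1L, 1L)
    }, integer(1))
    frags <- substr(frag_src, frag_start, frag_start + frag_len - 1L)
    rand <- random_rna(m - n_frag, sample(18:26, m - n_frag, replace = TRUE))
    cont <- tibble(gene_id = NA_character_, arm = NA_character_,
                   offset = NA_integer_, seq = c(frags, rand),
                   weight = params$contaminant_fraction / m)
    cells <- bind_rows(cells, cont)
  }
  cells
}

#' Simulate one small-RNA read library from a synthetic catalogue
#'
#' Draws `depth` reads by multinomial sampling over (gene, arm, 5'-offset)
#' outcomes plus contaminant reads. Reads are length-preserving substrings
#' of the precursor: the 5' start is shifted by an offset drawn from the
#' configured distribution with probability `1 - homogeneity`, and the read
#' length equals the mature product length. Planted tissue-enriched genes
#' have their weights multiplied by `enrichment_factor` only when
#' `tissue = TRUE`.
#'
#' @param catalog A `synthetic_catalog` from [simulate_catalog()].
#' @param sample_id Sample identifier for the library.
#' @param tissue Logical; is this a tissue (ovary) sample, as opposed to
#'   the whole-body reference?
#' @param params Simulation parameters; defaults to those stored in the
#'   catalogue.
#' @param seed Optional seed; when given, the generator is re-seeded from
#'   `seed` combined with `sample_id` so each sample's library is
#'   individually reproducible. When `NULL` the ambient generator state is
#'   used (reproducible across a fixed call sequence after
#'   [simulate_catalog()]).
#' @param return_weights If `TRUE`, also return the expected outcome table.
#' @return A read library tibble (see [read_library()]); total count equals
#'   `depth` exactly. With `return_weights = TRUE`, a list
#'   `(library, weights)`.
#' @export
simulate_library <- function(catalog, sample_id, tissue = TRUE,
                             params = catalog$params, seed = NULL,
                             return_weights = FALSE) {
  stopifnot(inherits(catalog, "synthetic_catalog"))
  if (!is.numeric(params$depth) || params$depth <= 0) {
    abort("simulate_library: `depth` must be > 0")
  }
  if (!is.null(seed)) {
    set.seed((as.integer(seed) + sum(utf8ToInt(sample_id))) %% .Machine$integer.max)
  }
  cells <- library_outcome_table(catalog, params, tissue)
  counts <- as.vector(rmultinom(1L, size = as.integer(params$depth),
                                prob = cells$weight))
  lib <- tibble(seq = cells$seq, count = counts) %>%
    filter(.data$count > 0) %>%
    group_by(.data$seq) %>%
    summarise(count = sum(.data$count), .groups = "drop") %>%
    arrange(.data$seq) %>%
    mutate(sample_id = sample_id, .before = 1L)
  if (return_weights) list(library = lib, weights = cells) else lib
}

#' Write a synthetic catalogue and libraries to a fixture directory
#'
#' Writes the precursor FASTA, mature-annotation TSV, one collapsed FASTA
#' per library (`reads_<sample>.fa`, headers `>{id}_x{count}`), one FASTA
#' per species catalogue under `species/`, the contaminant FASTA, and a
#' truth TSV (`gene_id`, `age`, `enriched`, `expr_weight`). The files can
#' be read back with [read_fixture()].
#'
#' @param catalog A `synthetic_catalog`.
#' @param libraries A list of read library tibbles (may be empty).
#' @param dir Output directory, created if needed.
#' @return Invisibly, `dir`.
#' @export
write_fixture <- function(catalog, libraries, dir) {
  dir.create(file.path(dir, "species"), recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) abort(paste0("cannot create fixture directory: ", dir))
  write_hairpins(catalog$hairpins, file.path(dir, "hairpins.fa"),
                 file.path(dir, "matures.tsv"))
  readr::write_tsv(catalog$truth, file.path(dir, "truth.tsv"), progress = FALSE)
  cont <- Biostrings::BStringSet(setNames(
    catalog$contaminants,
    sprintf("contaminant_%03d", seq_along(catalog$contaminants))))
  Biostrings::writeXStringSet(cont, file.path(dir, "contaminants.fa"))
  for (s in names(catalog$species_catalogues)) {
    fn <- file.path(dir, "species", paste0(gsub("\\s+", "_", s), ".fa"))
    ss <- Biostrings::BStringSet(setNames(
      catalog$species_catalogues[[s]],
      sprintf("%s_%03d", gsub("\\s+", "_", s),
              seq_along(catalog$species_catalogues[[s]]))))
    Biostrings::writeXStringSet(ss, fn)
  }
  for (lib in libraries) {
    sid <- if (nrow(lib)) lib$sample_id[1] else "empty"
    write_collapsed_fasta(lib, file.path(dir, paste0("reads_", sid, ".fa")))
  }
  invisible(dir)
}

#' Read a fixture directory written by [write_fixture()]
#'
#' @param dir Fixture directory.
#' @return A list with `hairpins`, `truth`, `species_catalogues`,
#'   `contaminants`, and `libraries` (named list of read library tibbles).
#' @export
read_fixture <- function(dir) {
  hairpins <- read_hairpins(file.path(dir, "hairpins.fa"),
                            file.path(dir, "matures.tsv"))
  truth <- readr::read_tsv(file.path(dir, "truth.tsv"),
                           col_types = readr::cols(gene_id = "c", age = "c",
                                                   enriched = "l",
                                                   expr_weight = "d"),
                           progress = FALSE)
  contaminants <- as.character(
    Biostrings::readBStringSet(file.path(dir, "contaminants.fa")))
  names(contaminants) <- NULL
  sp_files <- list.files(file.path(dir, "species"), pattern = "\\.fa$",
                         full.names = TRUE)
  species_catalogues <- setNames(
    lapply(sp_files, function(f) {
      x <- as.character(Biostrings::readBStringSet(f)); names(x) <- NULL; x
    }),
    gsub("_", " ", sub("\\.fa$", "", basename(sp_files))))
  lib_files <- list.files(dir, pattern = "^reads_.*\\.fa$", full.names = TRUE)
  libraries <- setNames(
    lapply(lib_files, function(f) {
      sid <- sub("^reads_(.*)\\.fa$", "\\1", basename(f))
      read_collapsed_fasta(f, sample_id = sid)
    }),
    sub("^reads_(.*)\\.fa$", "\\1", basename(lib_files)))
  list(hairpins = hairpins, truth = truth,
       species_catalogues = species_catalogues,
       contaminants = contaminants, libraries = libraries)
}
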