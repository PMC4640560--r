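#' Default species-to-clade map for the speckled wood analysis
#'
#' Maps comparison species onto nested clades around *Pararge aegeria*,
#' innermost to outermost: `butterfly_lineage` (other butterflies),
#' `lepidopteran` (moths), `amphiesmenopteran` (caddisflies, i.e. the
#' clade of Lepidoptera plus Trichoptera), and `ancient` (any outgroup
#' beyond the Amphiesmenoptera).
#'
#' @param species_clades Optional tibble (`species`, `clade`) overriding
#'   the default map.
#' @param clade_order Character vector of clade labels ordered innermost
#'   to outermost.
#' @return A list of class `species_tree` with `map` (tibble) and `order`.
#' @export
species_tree <- function(species_clades = NULL,
                         clade_order = c("butterfly_lineage", "lepidopteran",
                                         "amphiesmenopteran", "ancient")) {
  map <- species_clades %||% tibble(
    species = default_species_names(),
    clade = c("butterfly_lineage", "butterfly_lineage", "lepidopteran",
              "lepidopteran", "lepidopteran", "lepidopteran",
              "amphiesmenopteran"))
  if (!all(map$clade %in% clade_order)) {
    abort("species_tree: every clade label must appear in `clade_order`")
  }
  structure(list(map = map, order = clade_order), class = "species_tree")
}

#' Classify miRNAs as conserved or lineage-specific
#'
#' A gene hits a species when either mature product matches any sequence
#' in that species' catalogue with at most `max_mismatches` substitutions
#' (windowed comparison, +/-`max_offset` nt). Genes with at least one hit
#' species are `conserved`; genes found only in the focal species are
#' `lineage_specific`.
#'
#' @param hairpins A hairpin catalogue tibble.
#' @param species_catalogues Named list: species name -> character vector
#'   of mature sequences. An empty list classifies everything as
#'   lineage-specific (with a warning).
#' @param max_mismatches,max_offset Matching budget (see
#'   [annotate_known()]).
#' @return A tibble `gene_id`, `age_class`, `hit_species` (list-column of
#'   species names).
#' @export
classify_conservation <- function(hairpins, species_catalogues,
                                  max_mismatches = 2L, max_offset = 2L) {
  if (length(species_catalogues) == 0L) {
    warn("no species catalogues supplied; all genes classified lineage_specific")
  }
  hits <- purrr::map(seq_len(nrow(hairpins)), function(i) {
    sp <- names(species_catalogues)
    hit <- vapply(sp, function(s) {
      cat_s <- rna_normalize(species_catalogues[[s]])
      mature_matches_any(hairpins$mature_5p[i], cat_s, max_mismatches,
                         max_offset) ||
        mature_matches_any(hairpins$mature_3p[i], cat_s, max_mismatches,
                           max_offset)
    }, logical(1))
    sp[hit]
  })
  tibble(gene_id = hairpins$gene_id,
         age_class = if_else(lengths(hits) > 0, "conserved",
                             "lineage_specific"),
         hit_species = hits)
}

#' Assign the phylogenetic origin of each miRNA
#'
#' The origin is the clade label of the most inclusive (outermost) clade
#' containing a hit species; genes with no hits are `species_specific`.
#'
#' @param annotations Output of [classify_conservation()].
#' @param tree A [species_tree()].
#' @return `annotations` with an added `origin` column.
#' @export
assign_origin <- function(annotations, tree = species_tree()) {
  lookup <- setNames(tree$map$clade, tree$map$species)
  origin <- vapply(annotations$hit_species, function(sp) {
    if (length(sp) == 0L) return("species_specific")
    unknown <- setdiff(sp, names(lookup))
    if (length(unknown)) {
      abort(paste0("species missing from tree: ",
                   paste(unknown, collapse = ", ")))
    }
    clades <- unname(lookup[sp])
    tree$order[max(match(clades, tree$order))]
  }, character(1))
  annotations %>% mutate(origin = origin)
}

#' Age-class composition of a gene set
#'
#' @param annotations A tibble with `gene_id` and `age_class` (and
#'   optionally `origin`).
#' @param genes Optional subset of gene ids; default all annotated genes.
#' @param by Column to tabulate (`"age_class"` or `"origin"`).
#' @return A tibble with columns `by`-level, `n`, `proportion`
#'   (proportions sum to 1).
#' @export
age_composition <- function(annotations, genes = NULL, by = "age_class") {
  sub <- if (is.null(genes)) annotations else
    annotations %>% filter(.data$gene_id %in% genes)
  if (nrow(sub) == 0L) abort("age_composition: empty gene subset")
  sub %>%
    count(.data[[by]]) %>%
    mutate(proportion = .data$n / sum(.data$n))
}
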