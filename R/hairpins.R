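#' Build a hairpin catalogue
#'
#' A hairpin catalogue is a tibble with one row per precursor, holding the
#' precursor sequence, the 5' and 3' mature products, and the located arm
#' intervals. Both mature products must occur as exact substrings of the
#' precursor, with the 5' product strictly upstream of the 3' product.
#' Intervals are 1-based inclusive positions within the precursor.
#'
#' @param gene_id Character vector of gene identifiers (unique).
#' @param precursor Character vector of precursor (hairpin) sequences.
#' @param mature_5p,mature_3p Character vectors of mature products.
#' @return A tibble with columns `gene_id`, `precursor`, `mature_5p`,
#'   `mature_3p`, `arm5_start`, `arm5_end`, `arm3_start`, `arm3_end`.
#' @export
#' @examples
#' hairpin_catalog("g1", "aaaccccgggttttaaacccgggaaa",
#'                 mature_5p = "aaccccgg", mature_3p = "cccgggaa")
hairpin_catalog <- function(gene_id, precursor, mature_5p, mature_3p) {
  if (anyDuplicated(gene_id)) {
    abort("duplicated gene_id in hairpin catalogue")
  }
  precursor <- rna_normalize(precursor)
  mature_5p <- rna_normalize(mature_5p)
  mature_3p <- rna_normalize(mature_3p)
  loc5 <- stringr::str_locate(precursor, stringr::fixed(mature_5p))
  loc3 <- stringr::str_locate(precursor, stringr::fixed(mature_3p))
  bad <- is.na(loc5[, 1]) | is.na(loc3[, 1])
  if (any(bad)) {
    abort(paste0("mature product not found in precursor for: ",
                 paste(gene_id[bad], collapse = ", ")))
  }
  # when a 3' mature also occurs upstream, take its last occurrence
  last3 <- stringr::str_locate_all(precursor, stringr::fixed(mature_3p))
  loc3 <- t(vapply(last3, function(m) m[nrow(m), ], c(start = 0, end = 0)))
  out_of_order <- loc5[, 2] >= loc3[, 1]
  if (any(out_of_order)) {
    abort(paste0("5' mature not strictly upstream of 3' mature for: ",
                 paste(gene_id[out_of_order], collapse = ", ")))
  }
  tibble(
    gene_id = as.character(gene_id),
    precursor = precursor,
    mature_5p = mature_5p,
    mature_3p = mature_3p,
    arm5_start = as.integer(loc5[, 1]),
    arm5_end = as.integer(loc5[, 2]),
    arm3_start = as.integer(loc3[, 1]),
    arm3_end = as.integer(loc3[, 2])
  )
}

#' Read a hairpin catalogue from FASTA plus mature-annotation TSV
#'
#' The FASTA holds precursor sequences keyed by `gene_id`; the TSV has
#' columns `gene_id`, `mature_5p`, `mature_3p` (tab-delimited with header).
#'
#' @param fasta Path to the precursor FASTA file.
#' @param mature_tsv Path to the mature-annotation TSV.
#' @return A hairpin catalogue tibble (see [hairpin_catalog()]).
#' @export
read_hairpins <- function(fasta, mature_tsv) {
  seqs <- Biostrings::readBStringSet(fasta)
  ids <- sub("\\s.*$", "", names(seqs))
  ann <- readr::read_tsv(mature_tsv, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  req <- c("gene_id", "mature_5p", "mature_3p")
  if (!all(req %in% names(ann))) {
    abort(paste0("mature annotation missing column(s): ",
                 paste(setdiff(req, names(ann)), collapse = ", ")))
  }
  missing <- setdiff(ann$gene_id, ids)
  if (length(missing)) {
    abort(paste0("no precursor sequence for: ", paste(missing, collapse = ", ")))
  }
  prec <- as.character(seqs)[match(ann$gene_id, ids)]
  hairpin_catalog(ann$gene_id, prec, ann$mature_5p, ann$mature_3p)
}

#' Write a hairpin catalogue to FASTA plus mature-annotation TSV
#'
#' @param hairpins A hairpin catalogue tibble.
#' @param fasta,mature_tsv Output paths.
#' @return Invisibly, the catalogue.
#' @export
write_hairpins <- function(hairpins, fasta, mature_tsv) {
  ss <- Biostrings::BStringSet(setNames(hairpins$precursor, hairpins$gene_id))
  Biostrings::writeXStringSet(ss, fasta)
  readr::write_tsv(hairpins[, c("gene_id", "mature_5p", "mature_3p")],
                   mature_tsv, progress = FALSE)
  invisible(hairpins)
}
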