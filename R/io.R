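#' Construct a read library from sequences and counts
#'
#' A read library is a tibble of unique (collapsed) read sequences with
#' occurrence counts for one sample. Sequences are RNA-normalised
#' (lower-case, T converted to U); duplicate sequences have their counts
#' summed.
#'
#' @param sequences Character vector of read sequences.
#' @param counts Integer vector of occurrence counts (recycled length 1).
#' @param sample_id Sample identifier attached to every row.
#' @return A tibble with columns `sample_id`, `seq`, `count`, sorted by
#'   sequence for order-independence.
#' @export
read_library <- function(sequences, counts = 1L, sample_id = "sample") {
  if (length(sequences) == 0L) {
    return(tibble(sample_id = character(), seq = character(),
                  count = numeric()))
  }
  if (any(nchar(sequences) == 0L)) abort("empty read sequence")
  tibble(seq = rna_normalize(sequences), count = as.numeric(counts)) %>%
    group_by(.data$seq) %>%
    summarise(count = sum(.data$count), .groups = "drop") %>%
    arrange(.data$seq) %>%
    mutate(sample_id = sample_id, .before = 1L)
}

#' Collapse a raw read multiset into a library
#'
#' @param raw Character vector of (possibly repeated) read sequences,
#'   assumed adapter-trimmed.
#' @inheritParams read_library
#' @return A read library tibble; the result does not depend on input order.
#' @export
#' @examples
#' collapse_reads(c("AAGU", "AAGU", "CCAA"))
collapse_reads <- function(raw, sample_id = "sample") {
  read_library(raw, 1L, sample_id)
}

#' Total read count of a library
#' @param library A read library tibble.
#' @return Sum of collapsed counts.
#' @export
library_depth <- function(library) sum(library$count)

#' Read collapsed reads from FASTA
#'
#' Headers carry counts as a `_x<count>` suffix (`>read1_x512`), the
#' convention used by miRDeep2-style collapsed read files. Headers without
#' the suffix count as 1.
#'
#' @param path Path to the collapsed FASTA file.
#' @param sample_id Sample identifier for the library.
#' @return A read library tibble.
#' @export
read_collapsed_fasta <- function(path, sample_id = "sample") {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) return(read_library(character(), sample_id = sample_id))
  m <- stringr::str_match(names(seqs), "_x(\\d+)\\s*$")[, 2]
  counts <- ifelse(is.na(m), 1L, as.integer(m))
  read_library(as.character(seqs), counts, sample_id)
}

#' Write a read library as collapsed FASTA
#'
#' @param library A read library tibble.
#' @param path Output path.
#' @return Invisibly, the library.
#' @export
write_collapsed_fasta <- function(library, path) {
  ids <- sprintf("r%06d_x%d", seq_len(nrow(library)),
                 as.integer(round(library$count)))
  ss <- Biostrings::BStringSet(setNames(library$seq, ids))
  Biostrings::writeXStringSet(ss, path)
  invisible(library)
}

#' Read a FASTQ file as a read library
#'
#' Each record counts once; identical sequences are collapsed.
#'
#' @inheritParams read_collapsed_fasta
#' @return A read library tibble.
#' @export
read_fastq_reads <- function(path, sample_id = "sample") {
  seqs <- Biostrings::readDNAStringSet(path, format = "fastq")
  collapse_reads(as.character(seqs), sample_id)
}
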