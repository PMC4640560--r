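#' Normalise sequences to the RNA alphabet
#'
#' Lower-cases a character vector of nucleotide sequences and converts
#' thymine to uracil, so that reads sequenced as DNA and precursors written
#' as RNA compare as equal. All internal matching in the package goes
#' through this normalisation.
#'
#' @param x Character vector of nucleotide sequences.
#' @return Character vector over the alphabet `a`, `c`, `g`, `u`
#'   (other letters, e.g. IUPAC ambiguity codes, are lower-cased but kept).
#' @export
#' @examples
#' rna_normalize(c("ACGT", "acgu"))
rna_normalize <- function(x) {
  chartr("t", "u", tolower(as.character(x)))
}

# Reverse complement on the RNA alphabet.
rna_revcomp <- function(x) {
  flipped <- chartr("acgu", "ugca", rna_normalize(x))
  vapply(strsplit(flipped, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

is_rna <- function(x) {
  grepl("^[acgu]+$", rna_normalize(x))
}

# Smallest Hamming distance between a and b over end-to-end alignments
# shifted by up to max_offset nt; mismatches are counted over the aligned
# overlap (length min(nchar) at shift 0). Used for mature-product matching
# in known-miRNA annotation and conservation calls.
window_mismatches <- function(a, b, max_offset = 2L) {
  a <- rna_normalize(a); b <- rna_normalize(b)
  la <- nchar(a); lb <- nchar(b)
  if (la == 0L || lb == 0L) return(Inf)
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  best <- Inf
  for (s in -max_offset:max_offset) {
    i0 <- max(1L, 1L + s)
    j0 <- max(1L, 1L - s)
    w <- min(la - i0 + 1L, lb - j0 + 1L)
    if (w < 1L) next
    d <- sum(av[i0:(i0 + w - 1L)] != bv[j0:(j0 + w - 1L)])
    if (d < best) best <- d
  }
  best
}

# TRUE if mature sequence `x` matches any catalogue sequence with at most
# max_mismatches substitutions under the windowed comparison.
mature_matches_any <- function(x, catalogue, max_mismatches = 2L,
                               max_offset = 2L) {
  if (length(catalogue) == 0L) return(FALSE)
  for (s in catalogue) {
    if (window_mismatches(x, s, max_offset) <= max_mismatches) return(TRUE)
  }
  FALSE
}

# Longest-common-substring test: do a and b share an exact common substring
# of length >= k? Enumerates k-mers of the shorter string. Both strands of b
# are handled by the caller.
shares_kmer <- function(a, b, k) {
  a <- rna_normalize(a); b <- rna_normalize(b)
  if (nchar(a) < k || nchar(b) < k) return(FALSE)
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  kmers <- unique(substring(a, seq_len(nchar(a) - k + 1L),
                            seq_len(nchar(a) - k + 1L) + k - 1L))
  any(stringr::str_detect(b, stringr::fixed(kmers)))
}
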