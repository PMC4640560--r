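# Small hand-built fixtures shared across test files.

library(dplyr, warn.conflicts = FALSE)
library(tibble)

# A two-gene hairpin catalogue with known arm positions.
tiny_hairpins <- function() {
  hairpin_catalog(
    gene_id = c("gA", "gB"),
    precursor = c(
      paste0("gggggg", "acguacguacguacguacgu", "uuuuuuuuuu",
             "caugcaugcaugcaugcaug", "cccccc"),
      paste0("aaaaaa", "ggccuuaaggccuuaaggcc", "cgcgcgcgcg",
             "uuagcuuagcuuagcuuagc", "gggggg")),
    mature_5p = c("acguacguacguacguacgu", "ggccuuaaggccuuaaggcc"),
    mature_3p = c("caugcaugcaugcaugcaug", "uuagcuuagcuuagcuuagc"))
}

# An arm-profile row built directly (bypassing mapping) for filter tests.
profile_row <- function(gene_id = "g", sample_id = "s",
                        count_5p = 0, count_3p = 0,
                        homogeneity_5p = NA_real_,
                        homogeneity_3p = NA_real_) {
  tibble::tibble(
    gene_id = gene_id, sample_id = sample_id,
    count_5p = count_5p, count_3p = count_3p,
    total = count_5p + count_3p,
    dominant_arm = ifelse(count_5p >= count_3p, "5p", "3p"),
    dominant_count = pmax(count_5p, count_3p),
    homogeneity_5p = homogeneity_5p, homogeneity_3p = homogeneity_3p)
}
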