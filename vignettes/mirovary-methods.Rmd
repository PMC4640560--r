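---
title: "Methods: ovarian miRNA profiling, curation and age-expression analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ovarian miRNA profiling, curation and age-expression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirovary)
library(dplyr)
```

## Overview

`mirovary` implements a small-RNA analysis for tissue miRNA surveys of
the kind run on the speckled wood butterfly ovary: reads from two or
more tissue libraries and one whole-body pooled reference library are
quantified on a catalogue of hairpin precursors, curated through a rule
cascade, stratified by evolutionary age, and tested for
tissue-enrichment and age-expression effects. This vignette is the
package's account of the procedure, its assumptions, its tunable
parameters and the design decisions taken where the method left room.

## Quantification model

Each precursor carries a 5' and a 3' mature product, both exact
substrings of the hairpin, the 5' product strictly upstream. Collapsed
reads (unique sequence with a count) map to a precursor when they occur
as an exact substring with length in 18–26 nt. We deliberately use
exact, mismatch-free matching: alignment-based quantifiers tolerate
mismatches, but exact matching is deterministic and, on hairpin-scale
references, the two approaches give very similar counts. Sequences are
normalised to a common RNA alphabet (lower case, T to U) before any
comparison.

A read landing in more than one precursor is split in equal fractional
shares across the matching genes, so total counts are conserved; within
a gene the leftmost occurrence is used. Fractional counts propagate
through every stage and are only rounded for display.

A mapped read is assigned to the arm whose mature interval contains its
start position, with a tolerance of 3 nt (configurable) on either side
of each interval; reads starting outside both tolerant intervals —
inside the loop or in the flanks — are dropped from arm counts, since
they are more consistent with degradation than with mature products.
The per-arm **5'-start homogeneity** is the fraction of the arm's reads
sharing the modal start position; precise Drosha/Dicer processing makes
this fraction high for genuine miRNAs, while degradation fragments
start diffusely. The **dominant arm** is the arm with the larger count,
ties going to 5p (the choice is arbitrary; fixing it keeps runs
deterministic).

## Curation cascade

Candidates are filtered in a fixed order, recording only the first rule
that fails:

1. **contaminant** — the precursor shares an exact substring of at least
   `min_hit_len = 16` nt with a contaminant catalogue entry (rRNA, tRNA,
   repeats), on either strand of the entry;
2. **single_arm** — reads on only one arm;
3. **low_homogeneity** — either arm's modal 5'-start fraction is below
   `min_homogeneity = 0.95`; the boundary is inclusive (exactly 0.95
   passes). The rule is read as "each arm with reads must reach 95%";
   the alternative reading ("at least one arm") is strictly weaker and
   can be recovered by lowering the threshold;
4. **below_cutoff** — the dominant-arm count is not strictly greater
   than the per-sample threshold (e.g. 18 and 50 for libraries of
   different depth; thresholds scale with sequencing depth and are
   supplied per sample via `cutoff_policy()`). Strictness matters at
   the boundary: a count of exactly 18 fails an 18 threshold.

By default rules 1–3 apply only to *novel* candidates (those without a
match in the known-miRNA catalogue), while the expression cutoff
applies to everything: previously catalogued miRNAs have already passed
structural scrutiny once, and re-testing them mostly discards genuine
genes with locally noisy coverage. `apply_structural = "all"` subjects
every gene to the full cascade.

The homogeneity rule uses read counts, not distinct sequences; the
method description leaves this ambiguous, and counts are the more
conservative choice (a single abundant aberrant isomiR can fail a
candidate).

Known/novel annotation matches mature products rather than running a
full precursor alignment: a candidate is known when either mature
matches a catalogued mature with at most `max_mismatches = 2`
substitutions, comparing end-to-end alignments shifted by up to 2 nt
and counting mismatches over the overlap. Mature identity is the
operative criterion for miRNA orthology at this scale, and the windowed
Hamming comparison is deterministic and dependency-free.

## Shared-arm merging

Paralogous precursors can produce identical mature products; their
reads are then indistinguishable and naive per-gene counting
double-counts them. Genes whose mature products (either arm) are
identical sequences are merged by transitive closure into a group named
by the joined ids; group arm counts are the per-sample **maximum** (not
sum) over members, so a shared read pool is counted once. Identity —
not near-identity — is required: "sharing arm reads" is observable
exactly as identical read sequences.

## Conservation and age

A gene is **conserved** when either mature product matches any sequence
of another species' catalogue under the same windowed comparison, and
**lineage-specific** otherwise. Catalogues stand in for genome scans:
the interface accepts any species-labelled sequence set, which keeps
the classification deterministic and download-free. Adding a catalogue
can only add hit species, so conservation calls are monotone in the
evidence.

The origin of a conserved gene is the most inclusive clade containing a
hit species, on a configurable species tree. The default map covers the
butterfly comparison set (other butterflies → `butterfly_lineage`;
moths → `lepidopteran`; caddisfly → `amphiesmenopteran`; anything
beyond → `ancient`, i.e. predating the Amphiesmenoptera, the clade of
Lepidoptera plus Trichoptera).

## Enrichment and the ovary set

Counts are normalised to **reads per million miRNA reads**: the
denominator is the total miRNA-mapped count of the sample, so
normalisation preserves within-sample proportions. Fold changes are
ratios of normalised *total* counts (both arms summed); a dominant-arm
mode is available behind a flag. No pseudocounts are used: a zero
reference count makes the fold change undefined (`NA`, never infinity)
and routes the gene to the ovary-specific category instead, which is
the honest representation of "detected only in the tissue".

- **ovary_upregulated**: fold change strictly > `fold_threshold = 4` in
  *every* tissue sample (and above the expression cutoff there);
- **ovary_specific**: zero raw reads in the reference — detection at
  any level disqualifies — and above the cutoff in every tissue sample;
- the **ovary set** is the union of the two;
- genes qualifying in at least one but not all tissue samples are
  reported separately by `upregulated_in_any()`.

RPM normalisation is compositional: multiplying a subset of genes'
abundances by $f$ deflates every gene's relative share, so the realized
fold change of an enriched gene is $f/(1+(f-1)s)$, where $s$ is the
enriched subset's share of the library. This matters both for
interpreting real fold changes (a hugely abundant enriched gene
suppresses its own apparent fold) and for simulation design (below).

## Statistics

The three tests are implemented in the package rather than wrapped,
because the reporting conventions matter for comparability:

- **Mann-Whitney U** (conserved vs lineage-specific expression):
  average ranks for ties; the reported statistic is the *smaller* of
  U₁, U₂, so 0 ≤ U ≤ n₁n₂/2 and complete separation gives U = 0. For
  n₁+n₂ ≤ 12 the two-tailed p is exact, by enumeration of all
  assignments (P(min-U ≤ observed), inherently two-sided); otherwise a
  normal approximation with tie-corrected variance and continuity
  correction is used. The degenerate all-identical case returns
  U = n₁n₂/2, p = 1.
- **Spearman's rho** (age vs expression): Pearson correlation of
  average ranks, p by the t approximation on n−2 degrees of freedom —
  standard at the catalogue sizes involved (~150 genes). Zero rank
  variance is flagged `undefined` rather than propagating NaN. The age
  indicator codes conserved = 1, lineage-specific = 0, so positive rho
  means older miRNAs are more highly expressed; flipping the coding
  negates rho exactly. `ordinal_age = TRUE` uses the five origin levels
  instead; whether a two-level or ordinal coding is the better notion
  of "age" is genuinely open, so both are provided and neither asserted
  as canonical.
- **Chi-square on a 2×2 table** (age composition of a gene subset vs
  the full set): Σ(O−E)²/E on 1 df, no continuity correction by default
  since both margins are large (~150); a `correct` flag exists.

Base R's `wilcox.test`, `cor.test` and `chisq.test` serve as
independent cross-checks in the test suite; the exact enumeration is
additionally checked against a brute-force permutation oracle.

No multiple-testing correction is applied across samples: the analysis
reports three parallel per-sample tests of one hypothesis, not a
screening family.

## The synthetic-data generator

`simulate_catalog()` builds hairpins of 60–120 nt whose mature products
(20–24 nt) are exact substrings separated by an 8–15 nt loop with
6–15 nt flanks, plants a `conserved_fraction` of genes into 1–3 species
catalogues, draws per-gene log-normal expression weights with
`age_effect` added to conserved genes' log-mean, marks `n_enriched`
genes as tissue-enriched, and generates a contaminant catalogue.
`simulate_library()` draws `depth` reads by a single multinomial over
(gene, arm, 5'-offset) outcomes plus contaminant reads, so counts sum
to depth exactly.

Reads are length-preserving substrings: a read starts at the canonical
mature 5' position with probability `homogeneity`, otherwise at an
offset drawn from `offset_probs` (±1–3 nt), and its length equals the
mature length. Only 5' heterogeneity is modelled because only the 5'
rule consumes it; 3' heterogeneity affects no filter. Contaminant reads
are an even split of random sequences and fragments of contaminant
catalogue entries, exercising both the no-hit and the contaminant-hit
removal paths. One integer seed drives all randomness through R's
global generator; `simulate_library(seed =)` reseeds from the seed
combined with the sample id so individual libraries are reproducible.

Defaults (chosen once, as plausible values for a deep ovary library):
`arm_bias = 0.8` (strong 5'-arm dominance), `homogeneity = 0.98`
(precise processing), `contaminant_fraction = 0.1`,
`conserved_fraction = 0.55` (≈ the 83/150 split of the butterfly
catalogue), `age_effect = 1.5` natural-log units, `sdlog = 2` (an
expression spread of roughly four orders of magnitude, matching deep
survey data), `depth = 1e6`, `enrichment_factor = 8`,
`n_enriched = min(5, n_mirnas)`.

What the generator does **not** emulate: sequencing errors, adapter
remnants (inputs are assumed adapter-trimmed), RNA secondary structure
(no folding or hairpin thermodynamics), 3' isomiR trimming/tailing, and
genuine cross-species sequence divergence (conservation is planted as
exact catalogue membership). Passing tests therefore demonstrate that
the pipeline's rules and statistics behave as specified on data obeying
its assumptions — not that the assumptions hold for any particular real
library.

### Adequacy of depth in recovery experiments

The recovery property — planted enriched genes called with precision
and recall 1 when the enrichment factor exceeds the fold threshold —
presupposes *adequate depth*: every gene covered well above the read
cutoff, and the planted subset a small share of the library (else the
compositional fold $f/(1+(f-1)s)$ drops below the threshold and
shallow genes drop below the cutoff or pass the homogeneity filter by
chance on a handful of reads). With the survey-like spread `sdlog = 2`,
a depth of 10⁶ leaves tail genes near the cutoff by design, so recovery
fixtures use a moderate spread (`sdlog = 1`, shallowest gene ≈ 150
reads against a cutoff of 18, planted share ≈ 4%). The same reasoning
applies to any real-data claim: fold-change recovery is only meaningful
for genes comfortably above the cutoff.

## Numerical and degenerate-input choices

- All thresholds are strict or inclusive exactly as documented: cutoffs
  strict `>`, fold threshold strict `>`, homogeneity `>=`.
- Rank-table ties break lexicographically by gene id; dominant-arm ties
  go to 5p; both purely for determinism.
- Empty libraries, zero-read profiles and empty decision tables are
  valid inputs throughout and produce empty, schema-stable outputs.
- An empty species-catalogue set classifies everything lineage-specific
  with a warning; an empty composition subset is an error.
- Fold changes with a zero reference are `NA` plus an explicit
  detection flag, never `Inf`.
- Arm intervals are stored 1-based inclusive, the R convention.

## Problem sizes in the shipped tests

The suite exercises the statistics against exhaustive enumeration for
group sizes up to 10 (hundreds of random instances), measures the rank
test's type-I error over 200 seeded replicates of 150-gene catalogues,
and runs recovery experiments at 10⁶ reads per library with 150 genes —
sizes chosen so the whole suite completes in well under a minute per
file while keeping Monte-Carlo error small relative to the assertions'
tolerances.

## Known limitations

- Exact-substring mapping misses reads with sequencing errors or SNVs;
  on real data a mismatch-tolerant quantifier will map slightly more.
- Equal-share multi-mapping is a convention, not an estimator; genes
  sharing arms should be interpreted through their merged groups.
- Conservation-by-catalogue inherits the catalogues' completeness; an
  absent species catalogue can only bias genes toward
  lineage-specific (the classification is monotone in the evidence).
- The published fold changes bundled with the package cannot be
  recomputed from raw counts without the reference library's per-gene
  counts; they are used as supplied inputs when reconstructing the
  ovary set.
- The supplementary per-gene count table of the original survey is not
  redistributable here, so the published U = 802.5 / rho = 0.582
  values can be reproduced only when a user supplies that table.
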