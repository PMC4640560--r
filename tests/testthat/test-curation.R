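test_that("contaminant screening finds planted fragments on either strand", {
  hp <- tiny_hairpins()
  frag <- substr(hp$precursor[1], 10, 29)          # 20 nt of gA
  hit <- filter_contaminants(hp, paste0("ggg", frag, "ccc"))
  expect_true(hit$contaminant_hit[hit$gene_id == "gA"])
  expect_false(hit$contaminant_hit[hit$gene_id == "gB"])
  # reverse-complement of the fragment also hits
  hit_rc <- filter_contaminants(hp, mirovary:::rna_revcomp(frag))
  expect_true(hit_rc$contaminant_hit[hit_rc$gene_id == "gA"])
  # empty catalogue: everything passes
  expect_false(any(filter_contaminants(hp, character())$contaminant_hit))
})

test_that("a random hairpin passes an unrelated catalogue (brute-force checked)", {
  set.seed(5)
  alph <- c("a", "c", "g", "u")
  hp_seq <- paste(sample(alph, 70, replace = TRUE), collapse = "")
  hp <- hairpin_catalog("r1", hp_seq, substr(hp_seq, 11, 31),
                        substr(hp_seq, 45, 65))
  catalogue <- replicate(5, paste(sample(alph, 120, replace = TRUE),
                                  collapse = ""))
  both <- c(catalogue, mirovary:::rna_revcomp(catalogue))
  stopifnot(!any(vapply(both, oracle_shares_kmer, logical(1),
                        a = hp_seq, k = 16)))
  expect_false(filter_contaminants(hp, catalogue)$contaminant_hit)
  # hit length longer than the hairpin can never fire
  expect_false(filter_contaminants(hp, catalogue,
                                   min_hit_len = 200)$contaminant_hit)
})

test_that("both-arm and homogeneity rules fire in order with inclusive boundary", {
  prof <- dplyr::bind_rows(
    profile_row("a", count_5p = 0, count_3p = 500, homogeneity_3p = 1),
    profile_row("b", count_5p = 100, count_3p = 50,
                homogeneity_5p = 1.0, homogeneity_3p = 0.94),
    profile_row("c", count_5p = 100, count_3p = 50,
                homogeneity_5p = 0.95, homogeneity_3p = 0.95))
  out <- apply_structural_filters(prof)
  expect_equal(out$structural_rule, c("single_arm", "low_homogeneity", "none"))
})

test_that("expression cutoffs are strict greater-than per sample", {
  cutoffs <- cutoff_policy(st_hubert = 18, zonza = 50)
  prof <- dplyr::bind_rows(
    profile_row("a", "st_hubert", 19, 1, 1, 1),
    profile_row("b", "st_hubert", 18, 1, 1, 1),
    profile_row("c", "zonza", 50, 1, 1, 1))
  out <- apply_expression_cutoff(prof, cutoffs)
  expect_equal(out$above_cutoff, c(TRUE, FALSE, FALSE))
  expect_error(
    apply_expression_cutoff(profile_row("a", "elsewhere", 5, 5, 1, 1),
                            cutoffs),
    "elsewhere")
})

test_that("the cascade reports only the first failing rule, in order", {
  hp <- tiny_hairpins()
  # gA is a contaminant hit AND single-arm: contaminant must be reported
  frag <- substr(hp$precursor[1], 5, 30)
  prof <- dplyr::bind_rows(
    profile_row("gA", "s", count_5p = 100, count_3p = 0,
                homogeneity_5p = 1),
    profile_row("gB", "s", count_5p = 0, count_3p = 100,
                homogeneity_3p = 1))
  dec <- curate_profiles(prof, cutoff_policy(s = 18), hairpins = hp,
                         contaminants = frag)
  expect_equal(dec$failed_rule[dec$gene_id == "gA"], "contaminant")
  expect_equal(dec$failed_rule[dec$gene_id == "gB"], "single_arm")
  expect_false(any(dec$passed))
})

test_that("structural rules spare known miRNAs by default but not with apply_structural='all'", {
  prof <- profile_row("k1", "s", count_5p = 0, count_3p = 100,
                      homogeneity_3p = 1)
  status <- tibble::tibble(gene_id = "k1", status = "known")
  dec <- curate_profiles(prof, cutoff_policy(s = 18), status = status)
  expect_true(dec$passed)
  dec_all <- curate_profiles(prof, cutoff_policy(s = 18), status = status,
                             apply_structural = "all")
  expect_equal(dec_all$failed_rule, "single_arm")
})

test_that("relaxing any threshold never shrinks the pass set (monotone cascade)", {
  set.seed(31)
  prof <- dplyr::bind_rows(lapply(1:40, function(i) {
    c5 <- rpois(1, 30); c3 <- rpois(1, 30)
    profile_row(paste0("g", i), "s", c5, c3,
                homogeneity_5p = ifelse(c5 > 0, runif(1, 0.85, 1), NA),
                homogeneity_3p = ifelse(c3 > 0, runif(1, 0.85, 1), NA))
  }))
  strict <- curate_profiles(prof, cutoff_policy(s = 30),
                            min_homogeneity = 0.97)
  relaxed_cut <- curate_profiles(prof, cutoff_policy(s = 10),
                                 min_homogeneity = 0.97)
  relaxed_hom <- curate_profiles(prof, cutoff_policy(s = 30),
                                 min_homogeneity = 0.9)
  pass <- function(d) d$gene_id[d$passed]
  expect_true(all(pass(strict) %in% pass(relaxed_cut)))
  expect_true(all(pass(strict) %in% pass(relaxed_hom)))
})

test_that("clean deep synthetic libraries pass curation in full", {
  p <- sim_params(n_mirnas = 12, depth = 1e5, homogeneity = 1,
                  contaminant_fraction = 0, sdlog = 0.3, seed = 17)
  ctl <- simulate_catalog(p)
  lib <- simulate_library(ctl, "s", tissue = TRUE, seed = 17)
  prof <- profile_library(lib, ctl$hairpins)
  dec <- curate_profiles(prof, cutoff_policy(s = 18),
                         hairpins = ctl$hairpins,
                         contaminants = ctl$contaminants)
  expect_true(all(dec$passed))
  expect_setequal(dec$gene_id, ctl$hairpins$gene_id)
})

test_that("decisions do not depend on gene processing order", {
  prof <- dplyr::bind_rows(
    profile_row("b", "s", 30, 10, 1, 1),
    profile_row("a", "s", 5, 40, 1, 0.9),
    profile_row("c", "s", 0, 25, NA, 1))
  d1 <- curate_profiles(prof, cutoff_policy(s = 18))
  d2 <- curate_profiles(prof[c(3, 1, 2), ], cutoff_policy(s = 18))
  expect_identical(d1, d2)
})

test_that("known annotation matches matures within the mismatch budget", {
  hp <- tiny_hairpins()
  known_exact <- c(`miR-x` = hp$mature_3p[1])
  out <- annotate_known(hp, known_exact)
  expect_equal(out$status, c("known", "novel"))
  expect_equal(out$known_id[1], "miR-x")
  # two substitutions still match; catalogue in DNA alphabet is normalised
  two_sub <- toupper(chartr("u", "t",
                            paste0("gg", substr(hp$mature_3p[1], 3, 20))))
  out2 <- annotate_known(hp, c(`miR-y` = two_sub))
  expect_equal(out2$status[1], "known")
})

test_that("a random mature is annotated novel (distances brute-force checked)", {
  set.seed(9)
  hp <- tiny_hairpins()
  cat22 <- replicate(6, paste(sample(c("a", "c", "g", "u"), 22,
                                     replace = TRUE), collapse = ""))
  dists5 <- vapply(cat22, oracle_window_mismatches, numeric(1),
                   a = hp$mature_5p[1])
  dists3 <- vapply(cat22, oracle_window_mismatches, numeric(1),
                   a = hp$mature_3p[1])
  stopifnot(all(dists5 > 2), all(dists3 > 2))
  out <- annotate_known(hp[1, ], cat22)
  expect_equal(out$status, "novel")
})

test_that("genes sharing a mature product merge transitively with max counts", {
  matures <- tibble::tibble(
    gene_id = c("A", "B", "C", "D"),
    mature_5p = c("aaaaacccccgggggaaaaa", "uuuuucccccgggggaaaaa",
                  "uuuuucccccgggggccccc", "acgugacgugacgugacgua"),
    mature_3p = c("ccgguuccgguuccgguucc", "ccgguuccgguuccgguucc",
                  "uuuuucccccgggggaaaaa", "ugcaugcaugcaugcaugca"))
  # A~B share a 3' mature; B~C share across arms -> {A,B,C} one group
  prof <- dplyr::bind_rows(
    profile_row("A", "s", 51, 1, 1, 1),
    profile_row("B", "s", 40, 1, 1, 1),
    profile_row("C", "s", 10, 2, 1, 1),
    profile_row("D", "s", 7, 3, 1, 1))
  merged <- merge_shared_arm(prof, matures)
  expect_setequal(unique(merged$groups$group_id[
    merged$groups$gene_id %in% c("A", "B", "C")]), "A/B/C")
  grp <- dplyr::filter(merged$profiles, gene_id == "A/B/C")
  expect_equal(grp$count_5p, 51)   # max, not sum
  expect_equal(grp$count_3p, 2)
  expect_equal(grp$total, 53)
  expect_true("D" %in% merged$profiles$gene_id)
})

test_that("genes with distinct products stay singleton groups", {
  hp <- tiny_hairpins()
  prof <- dplyr::bind_rows(profile_row("gA", "s", 5, 5, 1, 1),
                           profile_row("gB", "s", 6, 6, 1, 1))
  merged <- merge_shared_arm(prof, hp)
  expect_setequal(merged$profiles$gene_id, c("gA", "gB"))
  expect_equal(merged$profiles$total, prof$total[match(
    merged$profiles$gene_id, prof$gene_id)])
})

test_that("cross-sample presence computes set arithmetic by status class", {
  dec <- dplyr::bind_rows(
    tibble::tibble(gene_id = c("k1", "k2", "k3", "n1"), sample_id = "a",
                   passed = c(TRUE, TRUE, FALSE, TRUE)),
    tibble::tibble(gene_id = c("k1", "k2", "k3", "n1"), sample_id = "b",
                   passed = c(TRUE, FALSE, TRUE, FALSE)))
  status <- tibble::tibble(gene_id = c("k1", "k2", "k3", "n1"),
                           status = c("known", "known", "known", "novel"))
  res <- cross_sample_presence(dec, status)
  known <- dplyr::filter(res$summary, class == "known")
  expect_equal(known$n_a, 2); expect_equal(known$n_b, 2)
  expect_equal(known$n_shared, 1); expect_equal(known$n_union, 3)
  all_row <- dplyr::filter(res$summary, class == "all")
  expect_equal(all_row$n_union, 4)
  expect_error(cross_sample_presence(dec[dec$sample_id == "a", ]),
               "two")
})
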