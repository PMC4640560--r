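test_that("parameter validation names the offending field", {
  expect_error(sim_params(arm_bias = 1.2), "arm_bias")
  expect_error(sim_params(conserved_fraction = -0.1), "conserved_fraction")
  expect_error(sim_params(depth = 0), "depth")
  expect_error(sim_params(enrichment_factor = 0.5), "enrichment_factor")
})

test_that("catalogue construction honours its structural contract", {
  p <- sim_params(n_mirnas = 10, conserved_fraction = 0.5, seed = 1)
  ctl <- simulate_catalog(p)
  hp <- ctl$hairpins
  expect_equal(nrow(hp), 10)
  expect_true(all(nchar(hp$precursor) >= 60 & nchar(hp$precursor) <= 120))
  expect_true(all(nchar(hp$mature_5p) >= 20 & nchar(hp$mature_5p) <= 24))
  # matures are exact substrings (hairpin_catalog would abort otherwise),
  # 5' strictly upstream with a >= 3 nt loop gap
  expect_true(all(hp$arm3_start - hp$arm5_end - 1 >= 3))
  # exact conserved fraction at divisible n
  expect_equal(sum(ctl$truth$age == "conserved"), 5)
})

test_that("the generator is deterministic under a fixed seed", {
  p <- sim_params(n_mirnas = 8, depth = 1e4, seed = 99)
  c1 <- simulate_catalog(p)
  c2 <- simulate_catalog(p)
  expect_identical(c1, c2)
  l1 <- simulate_library(c1, "s1", tissue = TRUE, seed = 5)
  l2 <- simulate_library(c2, "s1", tissue = TRUE, seed = 5)
  expect_identical(l1, l2)
})

test_that("conserved matures are planted in species catalogues, lineage-specific are not", {
  ctl <- simulate_catalog(sim_params(n_mirnas = 20, seed = 3))
  ann <- classify_conservation(ctl$hairpins, ctl$species_catalogues)
  expect_identical(ann$age_class, ctl$truth$age)
})

test_that("library counts sum exactly to depth", {
  ctl <- simulate_catalog(sim_params(n_mirnas = 12, depth = 5e4, seed = 2))
  lib <- simulate_library(ctl, "ova", tissue = TRUE, seed = 2)
  expect_equal(library_depth(lib), 5e4)
})

test_that("degenerate settings give fully canonical, contaminant-free reads", {
  p <- sim_params(n_mirnas = 6, depth = 2e4, homogeneity = 1,
                  contaminant_fraction = 0, seed = 11)
  ctl <- simulate_catalog(p)
  lib <- simulate_library(ctl, "ova", tissue = TRUE, seed = 11)
  prof <- profile_library(lib, ctl$hairpins)
  expect_equal(sum(prof$total), 2e4)  # every read maps
  covered <- dplyr::filter(prof, count_5p > 0)
  expect_true(all(covered$homogeneity_5p == 1))
  covered3 <- dplyr::filter(prof, count_3p > 0)
  expect_true(all(covered3$homogeneity_3p == 1))
})

test_that("modal 5'-start fraction concentrates at the homogeneity parameter", {
  # one gene, deep library: binomial SE of the modal fraction ~ 0.001
  p <- sim_params(n_mirnas = 1, depth = 1e5, homogeneity = 0.9,
                  contaminant_fraction = 0, arm_bias = 0.5, sdlog = 0,
                  seed = 21)
  ctl <- simulate_catalog(p)
  lib <- simulate_library(ctl, "ova", tissue = TRUE, seed = 21)
  prof <- profile_library(lib, ctl$hairpins)
  expect_equal(prof$homogeneity_5p, 0.9, tolerance = 0.01 / 0.9)
  expect_equal(prof$homogeneity_3p, 0.9, tolerance = 0.01 / 0.9)
})

test_that("a neutral enrichment factor gives tissue-independent weights", {
  p <- sim_params(n_mirnas = 8, enrichment_factor = 1, seed = 4)
  ctl <- simulate_catalog(p)
  w_t <- simulate_library(ctl, "s", tissue = TRUE, seed = 4,
                          return_weights = TRUE)$weights
  w_r <- simulate_library(ctl, "s", tissue = FALSE, seed = 4,
                          return_weights = TRUE)$weights
  expect_equal(w_t$weight, w_r$weight)
})

test_that("a positive age effect yields a positive age-expression rank correlation", {
  ctl <- simulate_catalog(sim_params(n_mirnas = 150, age_effect = 2,
                                     seed = 8))
  rho <- spearman_rho(as.numeric(ctl$truth$age == "conserved"),
                      ctl$truth$expr_weight)
  expect_gt(rho$rho, 0)
})

test_that("fixture files round-trip the catalogue and libraries", {
  dir <- withr::local_tempdir()
  p <- sim_params(n_mirnas = 6, depth = 2e3, seed = 13)
  ctl <- simulate_catalog(p)
  lib <- simulate_library(ctl, "ova", tissue = TRUE, seed = 13)
  write_fixture(ctl, list(lib), dir)
  back <- read_fixture(dir)
  expect_equal(back$hairpins, ctl$hairpins)
  expect_equal(back$truth$age, ctl$truth$age)
  expect_equal(back$truth$expr_weight, ctl$truth$expr_weight,
               tolerance = 1e-12)
  expect_equal(sort(names(back$species_catalogues)),
               sort(names(ctl$species_catalogues)))
  expect_setequal(back$contaminants, ctl$contaminants)
  # collapsed FASTA count suffixes conserve depth
  expect_equal(library_depth(back$libraries$ova), 2e3)
  expect_equal(dplyr::arrange(back$libraries$ova, seq)[, c("seq", "count")],
               dplyr::arrange(lib, seq)[, c("seq", "count")])
})

test_that("an empty library writes valid empty files", {
  dir <- withr::local_tempdir()
  ctl <- simulate_catalog(sim_params(n_mirnas = 3, seed = 1))
  empty <- read_library(character(), sample_id = "none")
  expect_no_error(write_fixture(ctl, list(empty), dir))
  back <- read_fixture(dir)
  expect_equal(nrow(back$libraries[[1]]), 0)
})
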