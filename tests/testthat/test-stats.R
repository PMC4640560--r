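test_that("Mann-Whitney handles separation, symmetry and degeneracy", {
  sep <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$u_statistic, 0)
  same <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$u_statistic, 9 / 2)
  flat <- mann_whitney_u(rep(2, 4), rep(2, 6))
  expect_equal(flat$u_statistic, 4 * 6 / 2)
  expect_equal(flat$p_two_tailed, 1)
})

test_that("small-sample U and exact p match full enumeration", {
  res <- mann_whitney_u(c(1, 2, 4), c(3, 5))
  oracle <- oracle_mann_whitney(c(1, 2, 4), c(3, 5))
  expect_equal(res$u_statistic, oracle$u)
  expect_equal(res$p_two_tailed, oracle$p)
  expect_equal(res$method, "exact")
})

test_that("Mann-Whitney equals exhaustive enumeration on random small instances", {
  set.seed(123)
  for (i in 1:60) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    # draw from a small integer range so ties are frequent
    x <- sample(1:6, n1, replace = TRUE)
    y <- sample(1:6, n2, replace = TRUE)
    res <- mann_whitney_u(x, y)
    oracle <- oracle_mann_whitney(x, y)
    expect_equal(res$u_statistic, oracle$u, info = paste(i))
    if (length(unique(c(x, y))) > 1) {
      expect_equal(res$p_two_tailed, oracle$p, info = paste(i))
    }
  }
})

test_that("the large-sample normal approximation matches the base-R reference", {
  set.seed(7)
  x <- round(rlnorm(40, 3, 1)); y <- round(rlnorm(35, 2.4, 1))
  res <- mann_whitney_u(x, y)
  ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                             correct = TRUE))
  u_ref <- min(ref$statistic, length(x) * length(y) - ref$statistic)
  expect_equal(res$u_statistic, unname(u_ref))
  expect_equal(res$p_two_tailed, ref$p.value, tolerance = 1e-10)
})

test_that("Spearman's rho is tie-safe and matches the rank-Pearson formula", {
  up <- spearman_rho(1:8, (1:8)^3)
  expect_equal(up$rho, 1)
  down <- spearman_rho(1:8, -(1:8))
  expect_equal(down$rho, -1)
  # 6-point tied example against the direct formula computed independently
  x <- c(1, 2, 2, 4, 5, 5); y <- c(3, 1, 4, 4, 6, 7)
  res <- spearman_rho(x, y)
  ref <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
  expect_equal(res$rho, unname(ref$estimate))
  expect_equal(res$p_two_tailed,
               stats::cor.test(x, y, method = "spearman", exact = FALSE,
                               continuity = FALSE)$p.value,
               tolerance = 1e-10)
})

test_that("rho is invariant under strictly monotone transforms and flips with coding", {
  set.seed(11)
  x <- rnorm(30); y <- rnorm(30) + 0.5 * x
  base_rho <- spearman_rho(x, y)$rho
  expect_equal(spearman_rho(exp(x), y)$rho, base_rho)
  expect_equal(spearman_rho(x, 3 * y + 10)$rho, base_rho)
  expect_equal(spearman_rho(-x, y)$rho, -base_rho)
  # binary age indicator: flipping conserved/lineage coding negates rho
  age <- rep(c(0, 1), 15)
  expect_equal(spearman_rho(1 - age, y)$rho, -spearman_rho(age, y)$rho)
})

test_that("zero rank variance is flagged undefined rather than NaN", {
  res <- spearman_rho(rep(1, 5), c(1, 2, 3, 4, 5))
  expect_true(res$undefined)
  expect_true(is.na(res$rho))
  expect_error(spearman_rho(1:2, 1:2), "3")
})

test_that("the 2x2 chi-square matches the direct formula and base R", {
  even <- chi_square_2x2(matrix(c(10, 20, 5, 10), 2))
  expect_equal(even$chi_square, 0)
  expect_equal(even$p, 1)
  tab <- matrix(c(10, 20, 10, 0), 2)
  res <- chi_square_2x2(tab)
  # hand-computed sum((O-E)^2/E)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res$chi_square, sum((tab - expected)^2 / expected))
  ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  expect_equal(res$chi_square, unname(ref$statistic))
  expect_equal(res$p, ref$p.value)
  # invariant to swapping rows and/or columns
  expect_equal(chi_square_2x2(tab[2:1, ])$chi_square, res$chi_square)
  expect_equal(chi_square_2x2(tab[, 2:1])$chi_square, res$chi_square)
  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2)), "marginal")
})

test_that("the age-expression report runs per sample and flags empty groups", {
  set.seed(3)
  ann <- tibble::tibble(gene_id = paste0("g", 1:60),
                        age_class = rep(c("conserved", "lineage_specific"),
                                        each = 30))
  expr <- tidyr::expand_grid(gene_id = ann$gene_id,
                             sample_id = c("s1", "s2")) %>%
    dplyr::mutate(total = rlnorm(120, 3 +
      1.5 * (gene_id %in% paste0("g", 1:30)), 1))
  rep1 <- age_expression_report(expr, ann, subset = paste0("g", 1:20))
  expect_equal(nrow(rep1$per_sample), 2)
  expect_true(all(rep1$per_sample$computable))
  expect_true(all(rep1$per_sample$rho > 0))
  expect_s3_class(rep1$composition, "proportion_test")
  # one group absent: flagged not-computable, no error
  ann_one <- ann %>% dplyr::mutate(age_class = "conserved")
  rep2 <- age_expression_report(expr, ann_one)
  expect_false(any(rep2$per_sample$computable))
  # broom-style accessors
  expect_s3_class(tidy(rep1), "tbl_df")
  expect_equal(glance(rep1)$n_samples, 2)
  expect_named(tidy(mann_whitney_u(1:5, 2:9)),
               c("u_statistic", "z", "p.value", "n1", "n2", "method"))
})
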