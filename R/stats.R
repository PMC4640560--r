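#' Two-tailed Mann-Whitney U test
#'
#' Rank-sum test for a difference in distribution between two groups,
#' reported in the smaller-U convention: `u = min(U1, U2)`, so
#' `0 <= u <= n1*n2/2`. Ties receive average ranks. For small samples
#' (`n1 + n2 <= exact_limit`) the two-tailed p-value is computed by
#' exhaustive enumeration of all group assignments of the observed values
#' (`P(min-U <= observed)`); otherwise a normal approximation with
#' tie-corrected variance and continuity correction is used.
#'
#' @param x,y Numeric vectors (the two groups), each non-empty.
#' @param exact_limit Combined size at or below which the exact
#'   enumeration is used.
#' @return An object of class `rank_test` with fields `u_statistic`,
#'   `n1`, `n2`, `z`, `p_two_tailed`, `method`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 4), c(3, 5))
mann_whitney_u <- function(x, y, exact_limit = 12L) {
  x <- as.numeric(x); y <- as.numeric(y)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) abort("mann_whitney_u: both groups must be non-empty")
  u_from_ranks <- function(lab) {
    # lab: logical, TRUE for group x, over the pooled sample
    r <- rank(pooled)
    u1 <- sum(r[lab]) - n1 * (n1 + 1) / 2
    min(u1, n1 * n2 - u1)
  }
  pooled <- c(x, y)
  labx <- rep(c(TRUE, FALSE), c(n1, n2))
  u <- u_from_ranks(labx)

  if (length(unique(pooled)) == 1L) {
    res <- list(u_statistic = n1 * n2 / 2, n1 = n1, n2 = n2, z = 0,
                p_two_tailed = 1, method = "degenerate")
    class(res) <- "rank_test"
    return(res)
  }

  if (n1 + n2 <= exact_limit) {
    idx <- utils::combn(n1 + n2, n1)
    us <- apply(idx, 2, function(ii) {
      lab <- rep(FALSE, n1 + n2); lab[ii] <- TRUE
      u_from_ranks(lab)
    })
    p <- mean(us <= u + 1e-9)
    res <- list(u_statistic = u, n1 = n1, n2 = n2, z = NA_real_,
                p_two_tailed = p, method = "exact")
  } else {
    n <- n1 + n2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * (n + 1 - tie_term)
    mu <- n1 * n2 / 2
    z <- (u - mu + 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(z))
    res <- list(u_statistic = u, n1 = n1, n2 = n2, z = z,
                p_two_tailed = p, method = "normal_approximation")
  }
  class(res) <- "rank_test"
  res
}

#' Spearman rank correlation
#'
#' Tie-safe Spearman's rho: the Pearson correlation of average ranks. The
#' two-tailed p-value uses the t approximation on `n - 2` degrees of
#' freedom, standard at the sample sizes this pipeline works with.
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`.
#' @return An object of class `correlation_test` with fields `rho`, `n`,
#'   `p_two_tailed`, and `undefined` (TRUE when either vector has zero
#'   rank variance, in which case `rho` is NA).
#' @export
spearman_rho <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (n != length(y)) abort("spearman_rho: inputs must have equal length")
  if (n < 3L) abort("spearman_rho: need at least 3 pairs")
  rx <- rank(x); ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    res <- list(rho = NA_real_, n = n, p_two_tailed = NA_real_,
                undefined = TRUE)
    class(res) <- "correlation_test"
    return(res)
  }
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  res <- list(rho = rho, n = n, p_two_tailed = p, undefined = FALSE)
  class(res) <- "correlation_test"
  res
}

#' Chi-square test on a 2x2 contingency table
#'
#' Pearson's chi-square statistic `sum((O - E)^2 / E)` on one degree of
#' freedom, without continuity correction by default (both margins in this
#' pipeline's use are large).
#'
#' @param tab A 2x2 matrix of counts with strictly positive margins.
#' @param correct Apply Yates' continuity correction.
#' @return An object of class `proportion_test` with fields `chi_square`,
#'   `counts`, `df`, `p`.
#' @export
chi_square_2x2 <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) abort("chi_square_2x2: table must be 2x2")
  if (any(tab < 0)) abort("chi_square_2x2: counts must be >= 0")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("chi_square_2x2: zero marginal total")
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  dev <- abs(tab - expected)
  if (correct) dev <- pmax(0, dev - 0.5)
  stat <- sum(dev^2 / expected)
  res <- list(chi_square = stat, counts = tab, df = 1L,
              p = pchisq(stat, df = 1L, lower.tail = FALSE))
  class(res) <- "proportion_test"
  res
}

#' Age-expression analysis report
#'
#' For each sample, compares total read counts between conserved and
#' lineage-specific miRNAs (two-tailed Mann-Whitney U) and correlates the
#' age indicator with expression (Spearman's rho; conserved coded 1,
#' lineage-specific 0, so positive rho means older miRNAs are more highly
#' expressed). Optionally compares the age composition of a designated
#' gene subset against the full annotated set (chi-square on the 2x2
#' conserved/lineage-specific table).
#'
#' @param expr A tibble with `gene_id`, `sample_id`, `total` (e.g. an
#'   arm-profile or expression table).
#' @param annotations A tibble with `gene_id` and `age_class`.
#' @param subset Optional character vector of gene ids (e.g. the genes
#'   expressed in the ovary in all samples) for the composition test.
#' @param ordinal_age Use the 5-level `origin` column of `annotations`
#'   (ordered by [species_tree()] clade order) instead of the binary age
#'   indicator for the correlation.
#' @return A list of class `age_expression_report`: `per_sample` (tibble
#'   with `sample_id`, `u_statistic`, `u_p`, `rho`, `rho_p`, `n_conserved`,
#'   `n_lineage`, `computable`) and `composition` (a `proportion_test` or
#'   NULL).
#' @export
age_expression_report <- function(expr, annotations, subset = NULL,
                                  ordinal_age = FALSE) {
  dat <- expr %>%
    inner_join(annotations %>% select(dplyr::any_of(
      c("gene_id", "age_class", "origin"))), by = "gene_id")
  unannotated <- setdiff(unique(expr$gene_id), annotations$gene_id)
  if (length(unannotated)) {
    warn(paste0(length(unannotated), " gene(s) without age annotation dropped"))
  }
  if (ordinal_age && !"origin" %in% names(dat)) {
    abort("age_expression_report: `origin` column required for ordinal_age")
  }
  per_sample <- dat %>%
    group_by(.data$sample_id) %>%
    group_modify(function(g, key) {
      cons <- g$total[g$age_class == "conserved"]
      lin <- g$total[g$age_class == "lineage_specific"]
      if (length(cons) == 0L || length(lin) == 0L) {
        return(tibble(u_statistic = NA_real_, u_p = NA_real_,
                      rho = NA_real_, rho_p = NA_real_,
                      n_conserved = length(cons), n_lineage = length(lin),
                      computable = FALSE))
      }
      mw <- mann_whitney_u(cons, lin)
      age_ind <- if (ordinal_age) {
        ord <- c("species_specific", species_tree()$order)
        as.numeric(match(g$origin, ord))
      } else {
        as.numeric(g$age_class == "conserved")
      }
      sp <- spearman_rho(age_ind, g$total)
      tibble(u_statistic = mw$u_statistic, u_p = mw$p_two_tailed,
             rho = sp$rho, rho_p = sp$p_two_tailed,
             n_conserved = length(cons), n_lineage = length(lin),
             computable = TRUE)
    }) %>%
    ungroup()
  composition <- NULL
  if (!is.null(subset)) {
    in_sub <- annotations$gene_id %in% subset
    tab <- rbind(
      subset = c(conserved = sum(annotations$age_class[in_sub] == "conserved"),
                 lineage_specific = sum(annotations$age_class[in_sub] ==
                                          "lineage_specific")),
      full = c(sum(annotations$age_class == "conserved"),
               sum(annotations$age_class == "lineage_specific")))
    composition <- chi_square_2x2(tab)
  }
  structure(list(per_sample = per_sample, composition = composition),
            class = "age_expression_report")
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %.4g (n1 = %d, n2 = %d), two-tailed p = %.4g [%s]\n",
              x$u_statistic, x$n1, x$n2, x$p_two_tailed, x$method))
  invisible(x)
}

#' @export
print.correlation_test <- function(x, ...) {
  if (x$undefined) {
    cat("Spearman's rho undefined (zero rank variance)\n")
  } else {
    cat(sprintf("Spearman's rho = %.4g (n = %d), two-tailed p = %.4g\n",
                x$rho, x$n, x$p_two_tailed))
  }
  invisible(x)
}

#' @export
print.proportion_test <- function(x, ...) {
  cat(sprintf("Chi-square = %.4g (df = %d), p = %.4g\n",
              x$chi_square, x$df, x$p))
  invisible(x)
}

#' @export
print.age_expression_report <- function(x, ...) {
  cat("Age-expression report\n")
  print(as.data.frame(x$per_sample))
  if (!is.null(x$composition)) {
    cat("Composition (subset vs full set): ")
    print(x$composition)
  }
  invisible(x)
}

#' @rdname mann_whitney_u
#' @param x A `rank_test` object.
#' @param ... Unused.
#' @export
tidy.rank_test <- function(x, ...) {
  tibble(u_statistic = x$u_statistic, z = x$z,
         p.value = x$p_two_tailed, n1 = x$n1, n2 = x$n2, method = x$method)
}

#' @rdname spearman_rho
#' @param x A `correlation_test` object.
#' @param ... Unused.
#' @export
tidy.correlation_test <- function(x, ...) {
  tibble(estimate = x$rho, p.value = x$p_two_tailed, n = x$n,
         undefined = x$undefined)
}

#' @rdname chi_square_2x2
#' @param x A `proportion_test` object.
#' @param ... Unused.
#' @export
tidy.proportion_test <- function(x, ...) {
  tibble(statistic = x$chi_square, p.value = x$p, df = x$df)
}

#' @rdname age_expression_report
#' @param x An `age_expression_report` object.
#' @param ... Unused.
#' @export
tidy.age_expression_report <- function(x, ...) {
  x$per_sample
}

#' @rdname age_expression_report
#' @export
glance.age_expression_report <- function(x, ...) {
  tibble(n_samples = nrow(x$per_sample),
         composition_chi_square = if (is.null(x$composition)) NA_real_
           else x$composition$chi_square,
         composition_p = if (is.null(x$composition)) NA_real_
           else x$composition$p)
}
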