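#' A series of proportions across sampling units or timepoints
#'
#' Container for the k x 2 tables behind the heterogeneity tests: per group,
#' a count of "successes" (e.g. copies of one haplotype) out of a total
#' (e.g. 2n sampled chromosomes).
#'
#' @param labels group labels (blocks, sectors or timepoints).
#' @param successes integer vector of success counts.
#' @param totals integer vector of totals, all positive.
#' @return object of class `proportion_series`.
#' @export
proportion_series <- function(labels, successes, totals) {
  stopifnot(length(labels) == length(successes),
            length(successes) == length(totals))
  if (any(totals <= 0)) stop("all totals must be positive")
  if (any(successes < 0 | successes > totals)) {
    stop("successes must lie in [0, total] for every group")
  }
  structure(list(labels = as.character(labels),
                 successes = as.integer(round(successes)),
                 totals = as.integer(round(totals))),
            class = "proportion_series")
}

new_test_result <- function(statistic, df, p_value, method,
                            corrected = FALSE, degenerate = FALSE, ...) {
  structure(list(statistic = unname(statistic), df = as.integer(df),
                 p_value = unname(p_value), method = method,
                 corrected = corrected, degenerate = degenerate, ...),
            class = "kdr_test_result")
}

#' @export
print.kdr_test_result <- function(x, ...) {
  cat(sprintf("%s: chi2 = %.4g, df = %d, P = %.4g%s\n", x$method,
              x$statistic, x$df, x$p_value,
              if (isTRUE(x$degenerate)) " (degenerate table)" else ""))
  invisible(x)
}

#' Chi-square test of equal proportions across k groups
#'
#' Pearson chi-square on the k x 2 table of (successes, failures) with
#' `df = k - 1` and no continuity correction — the "multiple proportions"
#' test asking whether at least one block or sector differs from the others.
#'
#' @param series a [proportion_series()] with at least two groups.
#' @return a test result with `statistic`, `df`, `p_value`.
#' @examples
#' s <- proportion_series(c("a", "b", "c"), c(3, 7, 5), c(10, 10, 10))
#' multi_proportion_test(s)
#' @export
multi_proportion_test <- function(series) {
  stopifnot(inherits(series, "proportion_series"))
  k <- length(series$totals)
  if (k < 2) stop("need at least 2 groups")
  tab <- cbind(series$successes, series$totals - series$successes)
  if (sum(tab[, 1]) == 0 || sum(tab[, 2]) == 0) {
    # every group all-failure (or all-success): no heterogeneity measurable
    return(new_test_result(0, k - 1L, 1, "k-sample test of equal proportions",
                           degenerate = TRUE))
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  new_test_result(ct$statistic, k - 1L, ct$p.value,
                  "k-sample test of equal proportions")
}

#' Two-proportion chi-square test with Yates continuity correction
#'
#' 2x2 Pearson chi-square with the Yates correction term
#' `min(0.5, |O - E|)` (so the statistic is never negative), df = 1,
#' two-sided. This is the standard continuity-corrected test used to compare
#' e.g. allele frequencies between a Prokopack-collected and an
#' ovitrap-reared sample from the same block. A degenerate margin (all
#' successes or all failures pooled) yields statistic 0, p = 1, flagged.
#'
#' @param x1,n1 successes and total in group 1.
#' @param x2,n2 successes and total in group 2.
#' @return a test result with `statistic`, `df` (1), `p_value`,
#'   `degenerate` flag.
#' @examples
#' yates_two_proportion_test(18, 30, 20, 26)
#' @export
yates_two_proportion_test <- function(x1, n1, x2, n2) {
  stopifnot(n1 > 0, n2 > 0, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  s <- x1 + x2
  if (s == 0 || s == n1 + n2) {
    return(new_test_result(0, 1L, 1, "2-sample test of equal proportions (Yates)",
                           corrected = TRUE, degenerate = TRUE))
  }
  pt <- suppressWarnings(prop.test(c(x1, x2), c(n1, n2), correct = TRUE))
  new_test_result(pt$statistic, 1L, pt$p.value,
                  "2-sample test of equal proportions (Yates)",
                  corrected = TRUE)
}

#' Pairwise Yates-corrected comparisons with multiplicity correction
#'
#' Runs [yates_two_proportion_test()] for every unordered pair of groups and
#' adjusts the p-values for multiple comparisons.
#'
#' @param series a [proportion_series()].
#' @param correction `"bonferroni"` (default), `"holm"` or `"none"`.
#' @return tibble with one row per pair: `group1`, `group2`, `statistic`,
#'   `df`, `p_value`, `p_adjusted`, `correction`.
#' @export
pairwise_tests <- function(series,
                           correction = c("bonferroni", "holm", "none")) {
  correction <- match.arg(correction)
  stopifnot(inherits(series, "proportion_series"))
  k <- length(series$totals)
  if (k < 2) stop("need at least 2 groups")
  pairs <- combn(k, 2)
  rows <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    tr <- yates_two_proportion_test(series$successes[i], series$totals[i],
                                    series$successes[j], series$totals[j])
    tibble::tibble(group1 = series$labels[i], group2 = series$labels[j],
                   statistic = tr$statistic, df = tr$df, p_value = tr$p_value)
  })
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- p.adjust(out$p_value, method = correction)
  out$correction <- correction
  out
}

#' Haplotype heterogeneity across units from EM frequency estimates
#'
#' Converts per-unit EM haplotype frequencies into expected haplotype counts
#' (`round(2n * p)` copies out of `2n` chromosomes) and tests one haplotype
#' against the rest across units with [multi_proportion_test()]. Rounding
#' keeps the chi-square on genuine counts; the df equals (number of units
#' present) - 1, so units with no dual-genotyped individuals at a timepoint
#' reduce the df.
#'
#' @param hap_table tibble from [haplotype_frequency_table()], restricted to
#'   one timepoint.
#' @param haplotype one of `"FV"`, `"FI"`, `"CV"`, `"CI"`.
#' @return a test result (see [multi_proportion_test()]).
#' @export
haplotype_heterogeneity_test <- function(hap_table,
                                         haplotype = c("CI", "FV", "FI", "CV")) {
  haplotype <- match.arg(haplotype)
  pcol <- paste0("p_", haplotype)
  series <- proportion_series(hap_table$unit_id,
                              round(2 * hap_table$n * hap_table[[pcol]]),
                              2 * hap_table$n)
  multi_proportion_test(series)
}

#' Sample size for detecting a difference between two proportions
#'
#' Normal-approximation sample size per group for the two-sided two-sample
#' test of proportions, pooled variance under the null and unpooled under
#' the alternative, no continuity correction:
#' \deqn{n = \frac{\left(z_{1-\alpha/2}\sqrt{2\bar p \bar q} +
#'   z_{1-\beta}\sqrt{p_1 q_1 + p_2 q_2}\right)^2}{(p_1 - p_2)^2}}
#' The unit of `n` is whatever the proportions are measured on; for allele
#' frequencies each mosquito carries two alleles, so the report gives both
#' the allele count and the mosquito count (`ceiling(n_alleles / 2)`).
#'
#' @param p1,p2 the two proportions to distinguish (0 < p < 1, p1 != p2).
#' @param alpha two-sided significance level.
#' @param power target power (1 - beta).
#' @return list with `n_alleles_per_group`, `n_mosquitoes_per_group`, and
#'   the inputs.
#' @examples
#' power_sample_size(0.375, 0.625, alpha = 0.025, power = 0.8)
#' @export
power_sample_size <- function(p1, p2, alpha = 0.05, power = 0.8) {
  stopifnot(p1 > 0, p1 < 1, p2 > 0, p2 < 1, alpha > 0, alpha < 1,
            power > 0, power < 1)
  if (p1 == p2) stop("zero effect: p1 must differ from p2")
  pbar <- (p1 + p2) / 2
  za <- qnorm(1 - alpha / 2)
  zb <- qnorm(power)
  n <- (za * sqrt(2 * pbar * (1 - pbar)) +
          zb * sqrt(p1 * (1 - p1) + p2 * (1 - p2)))^2 / (p1 - p2)^2
  n_alleles <- as.integer(ceiling(n))
  list(n_alleles_per_group = n_alleles,
       n_mosquitoes_per_group = as.integer(ceiling(n_alleles / 2)),
       p1 = p1, p2 = p2, alpha = alpha, power = power)
}
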