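#' EM maximum-likelihood haplotype frequencies from unphased genotypes
#'
#' Estimates the frequencies of the four two-locus haplotypes (FV wild type,
#' FI, CV, CI double mutant) from a 3x3 joint genotype table by
#' expectation-maximisation under random mating. With two biallelic loci the
#' only phase-ambiguous class is the double heterozygote (FC, VI), which is
#' a mixture of the configurations \{FV, CI\} and \{FI, CV\}; the E-step
#' splits its count with weight
#' \eqn{2 p_{FV} p_{CI} / (2 p_{FV} p_{CI} + 2 p_{FI} p_{CV})}
#' on the coupling configuration, and the M-step re-tallies haplotype counts
#' from the eight unambiguous classes plus the expected split, divided by 2N.
#'
#' Because the allele margins are fully observed, the only free parameter is
#' the coupling-haplotype frequency, constrained to an interval by the
#' margins. EM is started at linkage equilibrium (products of the observed
#' allele frequencies) and additionally near each end of that interval:
#' tables dominated by double heterozygotes have a symmetric likelihood
#' whose equilibrium point is a stationary saddle, and the extra starts
#' guarantee the returned fit is the best of the modes. The multinomial
#' log-likelihood is non-decreasing within every run; the run with the
#' highest final likelihood is returned.
#'
#' @param counts a [joint_genotype_counts()] object with `n_complete >= 1`.
#' @param tol convergence tolerance on the maximum absolute change in any
#'   haplotype frequency between iterations.
#' @param max_iter iteration cap; if reached, `converged` is `FALSE`.
#' @return object of class `haplotype_frequencies`: list with `p_FV`, `p_FI`,
#'   `p_CV`, `p_CI` (summing to 1), `n_individuals`, `log_likelihood`,
#'   `log_likelihood_trace`, `n_iterations`, `converged`, `unit_id`,
#'   `timepoint`.
#' @examples
#' tab <- joint_genotype_counts(matrix(c(4, 0, 0, 0, 2, 0, 0, 0, 4), 3, 3,
#'                                     byrow = TRUE))
#' em_haplotype_frequencies(tab)
#' @export
em_haplotype_frequencies <- function(counts, tol = 1e-8, max_iter = 1000L) {
  stopifnot(tol > 0, max_iter >= 1)
  n <- counts$n_complete
  if (n == 0) stop("no dual-genotyped individuals")
  m <- counts$counts

  # Observed allele frequencies (fully observed margins).
  p_C <- (2 * sum(m["CC", ]) + sum(m["FC", ])) / (2 * n)
  p_I <- (2 * sum(m[, "II"]) + sum(m[, "VI"])) / (2 * n)

  n_dh <- m["FC", "VI"]
  # Haplotype counts contributed by the eight phase-unambiguous classes.
  base <- c(
    FV = 2 * m["FF", "VV"] + m["FF", "VI"] + m["FC", "VV"],
    FI = 2 * m["FF", "II"] + m["FF", "VI"] + m["FC", "II"],
    CV = 2 * m["CC", "VV"] + m["CC", "VI"] + m["FC", "VV"],
    CI = 2 * m["CC", "II"] + m["CC", "VI"] + m["FC", "II"]
  )

  em_run <- function(p) {
    ll_trace <- numeric(0)
    converged <- FALSE
    iter <- 0L
    repeat {
      iter <- iter + 1L
      denom <- p["FV"] * p["CI"] + p["FI"] * p["CV"]
      w <- if (denom > 0) unname(p["FV"] * p["CI"] / denom) else 0.5
      new_p <- (base + n_dh * c(FV = w, FI = 1 - w, CV = 1 - w, CI = w)) / (2 * n)
      ll_trace <- c(ll_trace, haplotype_loglik(m, new_p))
      delta <- max(abs(new_p - p))
      p <- new_p
      # with no double heterozygotes the M-step is constant: one pass suffices
      if (delta < tol || n_dh == 0) { converged <- TRUE; break }
      if (iter >= max_iter) break
    }
    list(p = p, ll = ll_trace[length(ll_trace)], ll_trace = ll_trace,
         iter = iter, converged = converged)
  }

  # feasible interval for the coupling (CI) frequency given the margins
  lo <- max(0, p_C + p_I - 1)
  hi <- min(p_C, p_I)
  ci_starts <- unique(c(p_C * p_I,
                        lo + 0.02 * (hi - lo),
                        hi - 0.02 * (hi - lo)))
  runs <- lapply(ci_starts, function(ci) {
    em_run(c(FV = (1 - p_C) - (p_I - ci), FI = p_I - ci,
             CV = p_C - ci, CI = ci))
  })
  best <- runs[[which.max(vapply(runs, `[[`, numeric(1), "ll"))]]
  p <- best$p
  ll_trace <- best$ll_trace
  iter <- best$iter
  converged <- best$converged

  structure(
    list(p_FV = unname(p["FV"]), p_FI = unname(p["FI"]),
         p_CV = unname(p["CV"]), p_CI = unname(p["CI"]),
         n_individuals = n,
         log_likelihood = ll_trace[length(ll_trace)],
         log_likelihood_trace = ll_trace,
         n_iterations = iter, converged = converged,
         unit_id = counts$unit_id, timepoint = counts$timepoint),
    class = "haplotype_frequencies"
  )
}

#' Multinomial log-likelihood of a joint genotype table under random mating
#'
#' Genotype class probabilities are products of haplotype frequencies (the
#' double heterozygote summing both phase configurations). Zero-count cells
#' contribute nothing even when their probability is zero.
#'
#' @param m 3x3 count matrix with the canonical dimnames.
#' @param p named haplotype frequency vector `c(FV=, FI=, CV=, CI=)`.
#' @return log-likelihood (constant multinomial coefficient omitted).
#' @export
haplotype_loglik <- function(m, p) {
  probs <- matrix(c(
    p["FV"]^2,            2 * p["FV"] * p["FI"],                       p["FI"]^2,
    2 * p["FV"] * p["CV"], 2 * (p["FV"] * p["CI"] + p["FI"] * p["CV"]), 2 * p["FI"] * p["CI"],
    p["CV"]^2,            2 * p["CV"] * p["CI"],                       p["CI"]^2
  ), nrow = 3, byrow = TRUE)
  idx <- m > 0
  sum(m[idx] * log(probs[idx]))
}

#' @export
print.haplotype_frequencies <- function(x, ...) {
  cat(sprintf("Haplotype frequencies (n = %d, %s after %d EM iterations)\n",
              x$n_individuals,
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations))
  print(round(c(FV = x$p_FV, FI = x$p_FI, CV = x$p_CV, CI = x$p_CI), 6))
  invisible(x)
}

#' Linkage disequilibrium statistics between the two kdr loci
#'
#' From estimated haplotype frequencies computes the coefficient
#' \eqn{D = p_{CI} - p_C p_I} (focal mutant alleles C1534 and I1016, so
#' \eqn{D > 0} means the mutant alleles co-occur in excess), the squared
#' correlation \eqn{r^2 = D^2 / (p_C(1-p_C) p_I(1-p_I))}, and the one-degree
#' of-freedom chi-square \eqn{\chi^2 = 2N r^2} on the 2N sampled alleles.
#' When either locus is monomorphic, D is still reported but r-squared and
#' chi-square are undefined (returned as `NA` with `undefined = TRUE`),
#' never silently 0/0.
#'
#' @param hap a `haplotype_frequencies` object.
#' @return object of class `ld_result`: list with `D`, `r_squared`,
#'   `chi_squared`, `df` (1), `n_alleles` (2N), `p_value`, `undefined`,
#'   plus `p_C`, `p_I` and unit/timepoint metadata.
#' @export
ld_statistics <- function(hap) {
  stopifnot(inherits(hap, "haplotype_frequencies"), hap$n_individuals >= 1)
  p_C <- hap$p_CV + hap$p_CI
  p_I <- hap$p_FI + hap$p_CI
  D <- hap$p_CI - p_C * p_I
  n_alleles <- 2L * hap$n_individuals
  mono <- p_C <= 0 || p_C >= 1 || p_I <= 0 || p_I >= 1
  if (mono) {
    r2 <- chi2 <- pval <- NA_real_
  } else {
    r2 <- D^2 / (p_C * (1 - p_C) * p_I * (1 - p_I))
    chi2 <- n_alleles * r2
    pval <- pchisq(chi2, df = 1, lower.tail = FALSE)
  }
  structure(
    list(D = D, r_squared = r2, chi_squared = chi2, df = 1L,
         n_alleles = n_alleles, p_value = pval, undefined = mono,
         p_C = p_C, p_I = p_I,
         unit_id = hap$unit_id, timepoint = hap$timepoint),
    class = "ld_result"
  )
}

#' @export
print.ld_result <- function(x, ...) {
  if (x$undefined) {
    cat(sprintf("LD: D = %.4f; r2/chi2 undefined (monomorphic locus), 2N = %d\n",
                x$D, x$n_alleles))
  } else {
    cat(sprintf("LD: D = %.4f, r2 = %.4f, chi2 = %.2f (df = 1, 2N = %d), P = %.4g\n",
                x$D, x$r_squared, x$chi_squared, x$n_alleles, x$p_value))
  }
  invisible(x)
}

#' Tidy table of EM haplotype frequencies across units and timepoints
#'
#' @param counts_list list of [joint_genotype_counts()] (e.g. from
#'   [aggregate_counts()]).
#' @inheritParams em_haplotype_frequencies
#' @return tibble with one row per unit x timepoint: `unit_id`, `timepoint`,
#'   `n`, `p_FV`, `p_FI`, `p_CV`, `p_CI`, `n_iterations`, `converged`.
#' @export
haplotype_frequency_table <- function(counts_list, tol = 1e-8,
                                      max_iter = 1000L) {
  rows <- lapply(counts_list, function(ct) {
    h <- em_haplotype_frequencies(ct, tol = tol, max_iter = max_iter)
    tibble::tibble(unit_id = h$unit_id, timepoint = h$timepoint,
                   n = h$n_individuals,
                   p_FV = h$p_FV, p_FI = h$p_FI, p_CV = h$p_CV, p_CI = h$p_CI,
                   n_iterations = h$n_iterations, converged = h$converged)
  })
  dplyr::bind_rows(rows)
}
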