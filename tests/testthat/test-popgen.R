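test_that("EM is exact when phase is fully observed", {
  # single genotype class: everything is the double-mutant haplotype
  h <- em_haplotype_frequencies(make_counts(list("CC,II" = 10)))
  expect_equal(h$p_CI, 1)
  expect_equal(h$p_FV + h$p_FI + h$p_CV, 0)

  # no double heterozygotes: direct gamete counting in one iteration
  h <- em_haplotype_frequencies(make_counts(list("FF,VV" = 5, "CC,II" = 5)))
  expect_equal(h$p_FV, 0.5)
  expect_equal(h$p_CI, 0.5)
  expect_equal(h$n_iterations, 1L)
  expect_true(h$converged)

  expect_error(em_haplotype_frequencies(make_counts(list())),
               "no dual-genotyped")
})

test_that("EM frequencies sum to one and the log-likelihood never decreases", {
  set.seed(202)
  for (rep in 1:40) {
    m <- random_joint_table(sample(3:50, 1))
    h <- em_haplotype_frequencies(joint_genotype_counts(m))
    expect_equal(h$p_FV + h$p_FI + h$p_CV + h$p_CI, 1, tolerance = 1e-12)
    expect_true(all(c(h$p_FV, h$p_FI, h$p_CV, h$p_CI) >= 0))
    expect_true(all(diff(h$log_likelihood_trace) >= -1e-9))
    expect_true(h$converged)
  }
})

test_that("EM matches the grid-search likelihood maximiser on small tables", {
  # random joint tables, MLE located by exhaustive grid search
  # compare by maximum absolute frequency error; when the likelihood has
  # tied global maxima (symmetric tables) accept the EM mode if it attains
  # the grid maximum likelihood
  em_matches_grid <- function(m, tol = 1e-4) {
    h <- em_haplotype_frequencies(joint_genotype_counts(m))
    g <- oracle_em_grid(m)
    err <- max(abs(c(h$p_FV, h$p_FI, h$p_CV, h$p_CI) - g))
    if (err <= tol) return(TRUE)
    ll_em <- oracle_loglik(m, h$p_FV, h$p_FI, h$p_CV, h$p_CI)
    ll_grid <- oracle_loglik(m, g["FV"], g["FI"], g["CV"], g["CI"])
    ll_em >= ll_grid - 1e-9
  }
  m0 <- make_counts(list("FF,VV" = 4, "CC,II" = 4, "FC,VI" = 2))
  expect_true(em_matches_grid(m0$counts))

  set.seed(303)
  for (rep in 1:60) {
    m <- random_joint_table(sample(1:20, 1))
    expect_true(em_matches_grid(m))
  }
})

test_that("the 1-D grid oracle agrees with a full-simplex grid search", {
  # validates the margin-fixing reduction the fast oracle relies on
  set.seed(404)
  for (rep in 1:3) {
    m <- random_joint_table(15)
    g1 <- oracle_em_grid(m, step = 1e-3)
    g3 <- oracle_em_fullgrid(m, step = 0.01)
    ll1 <- oracle_loglik(m, g1["FV"], g1["FI"], g1["CV"], g1["CI"])
    ll3 <- oracle_loglik(m, g3["FV"], g3["FI"], g3["CV"], g3["CI"])
    expect_gte(ll1, ll3 - 1e-9) # the reduced search never does worse
  }
})

test_that("LD statistics satisfy the D/r2/chi2 identities", {
  hap <- function(fv, fi, cv, ci, n = 100) {
    structure(list(p_FV = fv, p_FI = fi, p_CV = cv, p_CI = ci,
                   n_individuals = n, unit_id = "u", timepoint = "t"),
              class = "haplotype_frequencies")
  }
  # linkage equilibrium: D = r2 = chi2 = 0
  eq <- ld_statistics(hap(0.25, 0.25, 0.25, 0.25))
  expect_equal(eq$D, 0)
  expect_equal(eq$r_squared, 0)
  expect_equal(eq$chi_squared, 0)

  # complete coupling: D = 0.25, r2 = 1, chi2 = 2N
  cp <- ld_statistics(hap(0.5, 0, 0, 0.5, n = 100))
  expect_equal(cp$D, 0.25)
  expect_equal(cp$r_squared, 1)
  expect_equal(cp$chi_squared, 200)

  # monomorphic locus: D reported, r2/chi2 flagged undefined
  mono <- ld_statistics(hap(0, 0, 0.4, 0.6))
  expect_true(mono$undefined)
  expect_true(is.na(mono$r_squared))
  expect_false(is.na(mono$D))

  # identities and D bounds across random EM fits
  set.seed(505)
  for (rep in 1:30) {
    m <- random_joint_table(sample(5:60, 1))
    ld <- ld_statistics(em_haplotype_frequencies(joint_genotype_counts(m)))
    if (ld$undefined) next
    pC <- ld$p_C; pI <- ld$p_I
    expect_equal(ld$r_squared,
                 ld$D^2 / (pC * (1 - pC) * pI * (1 - pI)), tolerance = 1e-12)
    expect_equal(ld$chi_squared, ld$n_alleles * ld$r_squared,
                 tolerance = 1e-12)
    expect_gte(ld$D, max(-pC * pI, -(1 - pC) * (1 - pI)) - 1e-12)
    expect_lte(ld$D, min(pC * (1 - pI), (1 - pC) * pI) + 1e-12)
  }
})

test_that("D is positive when mutant alleles co-occur in excess", {
  set.seed(606)
  for (rep in 1:10) {
    # haplotype pool with p_CI above p_C * p_I
    p <- c(FV = 0.4, FI = 0.02, CV = 0.18, CI = 0.4)
    gt <- simulate_genotypes(300, p)
    recs <- validate_genotype_records(tibble::tibble(
      specimen_id = paste0("d", 1:300), block_id = "B1", sector_id = "S1",
      timepoint = "wet2014", gt1534 = gt$gt1534, gt1016 = gt$gt1016))
    ld <- ld_statistics(em_haplotype_frequencies(
      aggregate_counts(recs, "block")[[1]]))
    expect_gt(ld$D, 0)
  }
})
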