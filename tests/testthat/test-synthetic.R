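test_that("the same seed reproduces the study exactly", {
  a <- simulate_study(simulation_config(seed = 5))
  b <- simulate_study(simulation_config(seed = 5))
  expect_identical(a$records, b$records)
  expect_identical(a$geometry, b$geometry)
  expect_identical(a$truth, b$truth)
  c <- simulate_study(simulation_config(seed = 6))
  expect_false(identical(a$records, c$records))
})

test_that("the generated study has the survey's design", {
  st <- simulate_study(simulation_config(seed = 9))
  expect_equal(nrow(st$geometry), 24)
  expect_equal(unname(table(st$geometry$sector_id)[paste0("S", 1:4)]),
               c(5, 5, 5, 9), ignore_attr = TRUE)
  expect_setequal(unique(st$records$timepoint),
                  c("wet2014", "dry2015", "wet2015", "dry2016"))
  # wet rounds are indoor collections only; dry rounds are supplemented
  expect_false(any(st$records$method == "ovitrap" &
                     st$records$season == "wet"))
  expect_true(any(st$records$method == "ovitrap" &
                    st$records$season == "dry"))
  # supplemented dry blocks reach a genotypable sample
  dry_n <- table(st$records$block_id[st$records$timepoint == "dry2016"])
  expect_true(all(dry_n >= 30))
  # truth rows: one per block per timepoint, each on the simplex
  expect_equal(nrow(st$truth), 24 * 4)
  expect_equal(st$truth$p_FV + st$truth$p_FI + st$truth$p_CV + st$truth$p_CI,
               rep(1, 96), tolerance = 1e-12)
  # records pass the data-model validator unchanged
  expect_silent(validate_genotype_records(st$records))
})

test_that("simulated genotype margins converge to the truth (LLN)", {
  set.seed(10)
  p <- c(FV = 0.44, FI = 0.01, CV = 0.21, CI = 0.34)
  gt <- simulate_genotypes(1e5, p)
  pC_hat <- (2 * sum(gt$gt1534 == "CC") + sum(gt$gt1534 == "FC")) / (2e5)
  pI_hat <- (2 * sum(gt$gt1016 == "II") + sum(gt$gt1016 == "VI")) / (2e5)
  expect_equal(pC_hat, unname(p["CV"] + p["CI"]), tolerance = 0.005)
  expect_equal(pI_hat, unname(p["FI"] + p["CI"]), tolerance = 0.005)
})

test_that("EM recovers simulated block frequencies better as n grows", {
  set.seed(12)
  p <- c(FV = 0.42, FI = 0.02, CV = 0.2, CI = 0.36)
  rmse <- vapply(c(30, 300, 3000), function(n) {
    errs <- replicate(8, {
      gt <- simulate_genotypes(n, p)
      recs <- validate_genotype_records(tibble::tibble(
        specimen_id = paste0("s", seq_len(n)), block_id = "B1",
        sector_id = "S1", timepoint = "wet2014",
        gt1534 = gt$gt1534, gt1016 = gt$gt1016))
      h <- em_haplotype_frequencies(aggregate_counts(recs, "block")[[1]])
      sqrt(mean((c(h$p_FV, h$p_FI, h$p_CV, h$p_CI) - p)^2))
    })
    mean(errs)
  }, numeric(1))
  expect_true(all(diff(rmse) < 0))
  expect_lt(rmse[3], 0.01)
})

test_that("zero between-block variance makes blocks share sector frequencies", {
  cfg <- simulation_config(seed = 14, between_block_sd = 0,
                           dry_season_shift_delta = 0)
  st <- simulate_study(cfg)
  per_sector <- split(st$truth, st$truth$sector_id)
  for (tr in per_sector) {
    expect_equal(max(tr$p_CI) - min(tr$p_CI), 0, tolerance = 1e-12)
    expect_equal(max(tr$p_FV) - min(tr$p_FV), 0, tolerance = 1e-12)
  }
  # and with delta = 0 each block's truth is constant over time as well
  per_block <- split(st$truth$p_CI, st$truth$block_id)
  expect_true(all(vapply(per_block,
                         function(v) max(v) - min(v) < 1e-12, logical(1))))
})

test_that("the dry-season shift raises the true double-mutant frequency", {
  cfg <- simulation_config(seed = 15)
  st <- simulate_study(cfg)
  wide <- split(st$truth, st$truth$timepoint)
  shift <- mean(wide$dry2015$p_CI) - mean(wide$wet2014$p_CI)
  expect_gt(shift, 0.07)
  expect_lt(shift, 0.15)
  # wet 2015 reverts to baseline
  expect_equal(wide$wet2015$p_CI, wide$wet2014$p_CI, tolerance = 1e-12)
  # the rare haplotype stays rare
  expect_lt(max(st$truth$p_FI), 0.06)
})

test_that("null calibration harnesses have the documented shapes", {
  cfg <- simulation_config(seed = 16)
  ns <- simulate_null_spatial(cfg, n_replicates = 5)
  expect_equal(dim(ns$values), c(24, 5))
  expect_equal(nrow(ns$geometry), 24)
  empty <- simulate_null_spatial(cfg, n_replicates = 0)
  expect_equal(ncol(empty$values), 0)

  nh <- simulate_null_heterogeneity(cfg, n_replicates = 4)
  expect_length(nh, 4)
  expect_s3_class(nh[[1]], "proportion_series")

  expect_error(simulation_config(sector_mean_haplotypes = diag(4) * 2),
               "simplex")
})
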