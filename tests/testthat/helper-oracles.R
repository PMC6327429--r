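# Independent oracles used across tests. Each re-derives its quantity by
# brute force so it shares no code path with the implementation it checks.

# Multinomial log-likelihood of a 3x3 joint genotype table written out
# class by class (not via kdrhap::haplotype_loglik).
oracle_loglik <- function(m, pFV, pFI, pCV, pCI) {
  probs <- matrix(c(
    pFV^2,        2 * pFV * pFI,                 pFI^2,
    2 * pFV * pCV, 2 * (pFV * pCI + pFI * pCV),  2 * pFI * pCI,
    pCV^2,        2 * pCV * pCI,                 pCI^2), 3, 3, byrow = TRUE)
  idx <- m > 0
  sum(m[idx] * log(pmax(probs[idx], 1e-300)))
}

# Grid-search MLE over the haplotype simplex. The observed allele margins
# pin two degrees of freedom at the MLE, leaving a 1-D search over p_CI;
# that reduction is itself validated against the full 3-D grid in a test.
oracle_em_grid <- function(m, step = 1e-4) {
  n <- sum(m)
  pC <- (2 * sum(m[3, ]) + sum(m[2, ])) / (2 * n)
  pI <- (2 * sum(m[, 3]) + sum(m[, 2])) / (2 * n)
  lo <- max(0, pC + pI - 1)
  hi <- min(pC, pI)
  grid <- seq(lo, hi, by = step)
  if (length(grid) == 0 || grid[length(grid)] < hi) grid <- c(grid, hi)
  ll <- vapply(grid, function(ci) {
    oracle_loglik(m, pmax((1 - pC) - (pI - ci), 0), pmax(pI - ci, 0),
                  pmax(pC - ci, 0), ci)
  }, numeric(1))
  ci <- grid[which.max(ll)]
  c(FV = max((1 - pC) - (pI - ci), 0), FI = max(pI - ci, 0),
    CV = max(pC - ci, 0), CI = ci)
}

# Full 3-D grid over the simplex (coarse); used to validate the 1-D
# reduction above on a handful of tables.
oracle_em_fullgrid <- function(m, step = 0.01) {
  g <- seq(0, 1, by = step)
  grid <- expand.grid(FV = g, FI = g, CV = g)
  grid <- grid[grid$FV + grid$FI + grid$CV <= 1 + 1e-12, ]
  grid$CI <- pmax(1 - grid$FV - grid$FI - grid$CV, 0)
  ll <- mapply(oracle_loglik, pFV = grid$FV, pFI = grid$FI,
               pCV = grid$CV, pCI = grid$CI, MoreArgs = list(m = m))
  unlist(grid[which.max(ll), ])
}

# Textbook Pearson chi-square on a k x 2 table of successes/failures.
oracle_pearson_chi2 <- function(successes, totals) {
  obs <- cbind(successes, totals - successes)
  expd <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  sum((obs - expd)^2 / expd)
}

# Moran's I by explicit double loop.
oracle_moran <- function(x, w) {
  n <- length(x)
  z <- x - mean(x)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) num <- num + w[i, j] * z[i] * z[j]
  (n / sum(w)) * num / sum(z^2)
}

# Random 3x3 joint genotype table with a given total.
random_joint_table <- function(n) {
  p <- as.vector(stats::rmultinom(1, n, prob = runif(9)))
  m <- matrix(p, 3, 3)
  dimnames(m) <- list(gt1534 = c("FF", "FC", "CC"),
                      gt1016 = c("VV", "VI", "II"))
  m
}

# Small genotype-record fixture used by data-model tests.
fixture_records <- function() {
  tibble::tibble(
    specimen_id = c("m1", "m2", "m3"),
    block_id = c("S1_B01", "S1_B01", "S2_B01"),
    sector_id = c("S1", "S1", "S2"),
    timepoint = c("wet2014", "wet2014", "dry2015"),
    season = c("wet", "wet", "dry"),
    method = c("prokopack", "prokopack", "ovitrap"),
    sex = c("F", "M", "F"),
    gt1534 = c("FF", "FC", "CC"),
    gt1016 = c("VV", "VI", "II"))
}

make_counts <- function(cells, unit = "u", tp = "wet2014") {
  m <- matrix(0L, 3, 3,
              dimnames = list(c("FF", "FC", "CC"), c("VV", "VI", "II")))
  for (nm in names(cells)) {
    rc <- strsplit(nm, ",", fixed = TRUE)[[1]]
    m[rc[1], rc[2]] <- cells[[nm]]
  }
  joint_genotype_counts(m, unit, tp)
}

# Noise-free two-timepoint block panel used by the temporal-model tests.
noise_free_panel <- function(shift = 0.1, n_blocks = 10,
                             tps = c("wet2014", "dry2015")) {
  blocks <- sprintf("B%02d", seq_len(n_blocks))
  fb <- seq(0.2, 0.65, length.out = n_blocks)
  out <- expand.grid(unit_id = blocks, timepoint = tps,
                     stringsAsFactors = FALSE)
  out$sector_id <- rep(rep(c("S1", "S2"), length.out = n_blocks), length(tps))
  out$season <- ifelse(grepl("^dry", out$timepoint), "dry", "wet")
  out$frequency <- fb[match(out$unit_id, blocks)] +
    ifelse(out$timepoint == tps[2], shift, 0)
  out$n <- 30L
  tibble::as_tibble(out)
}
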