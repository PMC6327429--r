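#' Configuration of a synthetic kdr surveillance study
#'
#' Encodes the sampling design the generator reproduces: a town split by two
#' main roads into four sectors holding 5+5+5+9 surveyed city blocks, four
#' survey rounds alternating wet and dry seasons, per-block indoor adult
#' catches whose means and standard deviations match the reported rounds
#' (39.5 +/- 22.1, 9.1 +/- 10.9, 17.1 +/- 15.6, 2.2 +/- 3.1 adults per
#' block), strong block-to-block heterogeneity in haplotype frequencies,
#' strong positive linkage disequilibrium between C1534 and I1016, a rare
#' F1534/I1016 haplotype, and a dry-season rise in the double-mutant
#' C1534/I1016 haplotype of about 0.11 on the frequency scale.
#'
#' @param seed integer RNG seed for the whole study.
#' @param blocks_per_sector number of blocks in each sector.
#' @param timepoints a [timepoint_config()].
#' @param mean_block_sample_size,sd_block_sample_size per-timepoint mean and
#'   sd of indoor (Prokopack) adults per block; the counts are drawn
#'   negative-binomial with dispersion matched to these moments (Poisson if
#'   sd^2 <= mean).
#' @param sector_mean_haplotypes matrix (sectors x 4, columns FV, FI, CV,
#'   CI), each row a point on the simplex: the sector-mean haplotype
#'   frequencies at the wet-season baseline.
#' @param between_block_sd logistic-normal sd of block deviations from the
#'   sector mean (0 = all blocks share the sector frequencies).
#' @param dry_season_shift_delta logit-scale increase of the C1534/I1016
#'   frequency applied at every dry round (the selection signal the temporal
#'   models estimate); the default 0.505 is calibrated so that the
#'   population-mean increase is 0.11 on the frequency scale under the
#'   default sector baselines and block-level noise.
#' @param p_FI_ceiling cap on the block-level F1534/I1016 frequency (the
#'   repulsion haplotype is nearly absent in the field).
#' @param genotype_missing_rate per-locus probability a genotype call fails.
#' @param ovitrap_supplement_threshold dry-season blocks with fewer indoor
#'   adults than this get ovitrap-reared adults added.
#' @param ovitrap_supplement_range how many ovitrap-reared adults (uniform
#'   in this range) supplement such a block.
#' @param prop_female proportion of collected adults that are female.
#' @return a list of class `kdr_sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              blocks_per_sector = c(5, 5, 5, 9),
                              timepoints = timepoint_config(),
                              mean_block_sample_size = c(39.5, 9.1, 17.1, 2.2),
                              sd_block_sample_size = c(22.1, 10.9, 15.6, 3.1),
                              sector_mean_haplotypes = default_sector_haplotypes(),
                              between_block_sd = 0.5,
                              dry_season_shift_delta = 0.505,
                              p_FI_ceiling = 0.05,
                              genotype_missing_rate = 0.02,
                              ovitrap_supplement_threshold = 30L,
                              ovitrap_supplement_range = c(35L, 50L),
                              prop_female = 0.63) {
  n_sectors <- length(blocks_per_sector)
  sector_mean_haplotypes <- as.matrix(sector_mean_haplotypes)
  if (nrow(sector_mean_haplotypes) != n_sectors ||
      ncol(sector_mean_haplotypes) != 4) {
    stop("sector_mean_haplotypes must be ", n_sectors, " x 4")
  }
  if (any(sector_mean_haplotypes < 0) ||
      any(abs(rowSums(sector_mean_haplotypes) - 1) > 1e-8)) {
    stop("each sector_mean_haplotypes row must be a point on the simplex")
  }
  stopifnot(length(mean_block_sample_size) == nrow(timepoints),
            length(sd_block_sample_size) == nrow(timepoints),
            all(mean_block_sample_size > 0),
            between_block_sd >= 0,
            genotype_missing_rate >= 0, genotype_missing_rate <= 1,
            prop_female >= 0, prop_female <= 1)
  colnames(sector_mean_haplotypes) <- HAPLOTYPES
  structure(list(seed = as.integer(seed),
                 blocks_per_sector = as.integer(blocks_per_sector),
                 timepoints = timepoints,
                 mean_block_sample_size = mean_block_sample_size,
                 sd_block_sample_size = sd_block_sample_size,
                 sector_mean_haplotypes = sector_mean_haplotypes,
                 between_block_sd = between_block_sd,
                 dry_season_shift_delta = dry_season_shift_delta,
                 p_FI_ceiling = p_FI_ceiling,
                 genotype_missing_rate = genotype_missing_rate,
                 ovitrap_supplement_threshold = as.integer(ovitrap_supplement_threshold),
                 ovitrap_supplement_range = as.integer(ovitrap_supplement_range),
                 prop_female = prop_female),
            class = "kdr_sim_config")
}

#' Default sector-mean haplotype frequencies
#'
#' Baseline (wet season) sector means giving town-wide allele frequencies
#' near p_C = 0.55 and p_I = 0.35, positive D around 0.14 and a rare FI
#' haplotype — the regime observed in pyrethroid-exposed populations where
#' the double mutant rides on one genetic background.
#'
#' @return a 4 x 4 matrix, rows = sectors, columns = FV, FI, CV, CI.
#' @export
default_sector_haplotypes <- function() {
  m <- rbind(c(0.50, 0.01, 0.19, 0.30),
             c(0.40, 0.01, 0.24, 0.35),
             c(0.44, 0.02, 0.18, 0.36),
             c(0.42, 0.01, 0.22, 0.35))
  colnames(m) <- HAPLOTYPES
  m
}

# Negative-binomial size parameter matching a mean/sd pair; Inf => Poisson.
nb_size_from_moments <- function(mu, sd) {
  v <- sd^2
  if (v <= mu) Inf else mu^2 / (v - mu)
}

draw_block_n <- function(k, mu, sd) {
  size <- nb_size_from_moments(mu, sd)
  if (is.infinite(size)) stats::rpois(k, mu) else rnbinom(k, mu = mu, size = size)
}

# Shift the CI component of a simplex by delta on the logit scale and
# rescale the remaining components to keep the sum at 1.
shift_ci <- function(p, delta) {
  ci <- p["CI"]
  if (delta == 0 || ci <= 0 || ci >= 1) return(p)
  ci_new <- stats::plogis(stats::qlogis(ci) + delta)
  scale <- (1 - ci_new) / (1 - ci)
  out <- p * scale
  out["CI"] <- ci_new
  out
}

# Block-level baseline simplex: logistic-normal perturbation of the sector
# mean, then the FI rarity ceiling.
perturb_simplex <- function(mean_p, sd, fi_ceiling) {
  y <- log(pmax(mean_p, 1e-12)) + rnorm(4, 0, sd)
  p <- exp(y) / sum(exp(y))
  names(p) <- HAPLOTYPES
  if (p["FI"] > fi_ceiling) {
    excess <- p["FI"] - fi_ceiling
    p["FI"] <- fi_ceiling
    others <- setdiff(HAPLOTYPES, "FI")
    p[others] <- p[others] * (1 + excess / sum(p[others]))
  }
  p / sum(p)
}

#' Draw unphased two-locus genotypes from haplotype frequencies
#'
#' Each individual receives two haplotypes drawn independently from the
#' given frequencies (random mating / Hardy-Weinberg at the haplotype
#' level); phase is then erased to the unphased genotype pair.
#'
#' @param n number of individuals.
#' @param hap_freqs numeric length-4 vector of FV, FI, CV, CI frequencies.
#' @return tibble with columns `gt1534`, `gt1016`.
#' @export
simulate_genotypes <- function(n, hap_freqs) {
  stopifnot(length(hap_freqs) == 4, all(hap_freqs >= 0),
            abs(sum(hap_freqs) - 1) < 1e-8)
  if (n == 0) return(tibble::tibble(gt1534 = character(), gt1016 = character()))
  h1 <- sample.int(4, n, replace = TRUE, prob = hap_freqs)
  h2 <- sample.int(4, n, replace = TRUE, prob = hap_freqs)
  # haplotype index -> carries C (3,4 = CV,CI) / carries I (2,4 = FI,CI)
  nC <- (h1 >= 3) + (h2 >= 3)
  nI <- (h1 %in% c(2, 4)) + (h2 %in% c(2, 4))
  tibble::tibble(gt1534 = GT1534_LEVELS[nC + 1],
                 gt1016 = GT1016_LEVELS[nI + 1])
}

#' Simulate a complete synthetic surveillance study
#'
#' Generates per-mosquito genotype records, block centroid geometry and the
#' underlying truth for a study with the configured design: block baseline
#' haplotype frequencies are logistic-normal perturbations of sector means;
#' at every dry round the logit of the C1534/I1016 frequency rises by the
#' configured delta; per-block indoor catches are negative-binomial;
#' dry-season blocks under the supplement threshold receive ovitrap-reared
#' adults (35-50 individuals); genotypes fail per locus at the configured
#' missing rate; block centroids sit on a jittered grid split into sector
#' quadrants by two axis roads. All randomness derives from `config$seed`,
#' so the same config yields an identical study.
#'
#' @param config a [simulation_config()].
#' @return list with `records` (genotype tibble as in
#'   [read_genotype_table()]), `geometry` (block centroids), `truth`
#'   (per-block true haplotype frequencies per timepoint) and `config`.
#' @export
simulate_study <- function(config = simulation_config()) {
  stopifnot(inherits(config, "kdr_sim_config"))
  set.seed(config$seed)
  n_sectors <- length(config$blocks_per_sector)
  sector_ids <- paste0("S", seq_len(n_sectors))
  block_ids <- unlist(lapply(seq_len(n_sectors), function(s) {
    sprintf("%s_B%02d", sector_ids[s], seq_len(config$blocks_per_sector[s]))
  }))
  block_sector <- rep(sector_ids, config$blocks_per_sector)

  geometry <- block_grid_geometry(block_ids, block_sector,
                                  config$blocks_per_sector)

  # baseline (wet) haplotype simplex per block
  base <- lapply(seq_along(block_ids), function(b) {
    perturb_simplex(config$sector_mean_haplotypes[match(block_sector[b],
                                                        sector_ids), ],
                    config$between_block_sd, config$p_FI_ceiling)
  })

  tp <- config$timepoints
  truth <- list(); recs <- list(); serial <- 0L
  for (t in seq_len(nrow(tp))) {
    dry <- tp$season[t] == "dry"
    n_pro <- draw_block_n(length(block_ids),
                          config$mean_block_sample_size[t],
                          config$sd_block_sample_size[t])
    for (b in seq_along(block_ids)) {
      p <- if (dry) shift_ci(base[[b]], config$dry_season_shift_delta)
           else base[[b]]
      truth[[length(truth) + 1L]] <- tibble::tibble(
        block_id = block_ids[b], sector_id = block_sector[b],
        timepoint = tp$timepoint[t],
        p_FV = unname(p["FV"]), p_FI = unname(p["FI"]),
        p_CV = unname(p["CV"]), p_CI = unname(p["CI"]))
      n_b <- n_pro[b]
      n_ovi <- 0L
      if (dry && n_b < config$ovitrap_supplement_threshold) {
        n_ovi <- sample(seq(config$ovitrap_supplement_range[1],
                            config$ovitrap_supplement_range[2]), 1)
      }
      n_tot <- n_b + n_ovi
      if (n_tot == 0) next
      gt <- simulate_genotypes(n_tot, p)
      miss1 <- runif(n_tot) < config$genotype_missing_rate
      miss2 <- runif(n_tot) < config$genotype_missing_rate
      gt$gt1534[miss1] <- NA_character_
      gt$gt1016[miss2] <- NA_character_
      recs[[length(recs) + 1L]] <- tibble::tibble(
        specimen_id = sprintf("M%06d", serial + seq_len(n_tot)),
        block_id = block_ids[b], sector_id = block_sector[b],
        timepoint = tp$timepoint[t], season = tp$season[t],
        method = rep(c("prokopack", "ovitrap"), c(n_b, n_ovi)),
        sex = ifelse(runif(n_tot) < config$prop_female, "F", "M"),
        gt1534 = gt$gt1534, gt1016 = gt$gt1016)
      serial <- serial + n_tot
    }
  }
  list(records = dplyr::bind_rows(recs),
       geometry = geometry,
       truth = dplyr::bind_rows(truth),
       config = config)
}

# Blocks on a jittered grid inside sector quadrants delimited by two axis
# roads crossing at the origin; distances in metres.
block_grid_geometry <- function(block_ids, block_sector, blocks_per_sector) {
  quad <- cbind(x = c(1, -1, -1, 1), y = c(1, 1, -1, -1))
  n_sectors <- length(blocks_per_sector)
  rows <- list()
  for (s in seq_len(n_sectors)) {
    b <- blocks_per_sector[s]
    side <- ceiling(sqrt(b))
    gx <- ((seq_len(b) - 1) %% side) + 1
    gy <- ((seq_len(b) - 1) %/% side) + 1
    q <- quad[(s - 1) %% 4 + 1, ]
    rows[[s]] <- tibble::tibble(
      x = q["x"] * (150 + gx * 200) + runif(b, -60, 60),
      y = q["y"] * (150 + gy * 200) + runif(b, -60, 60))
  }
  out <- dplyr::bind_rows(rows)
  tibble::tibble(block_id = block_ids, sector_id = block_sector,
                 x = out$x, y = out$y)
}

#' Null replicates of block values for Moran's I calibration
#'
#' Draws spatially unstructured block-level frequency estimates (iid
#' binomial sampling around a common frequency) over a fixed geometry, the
#' harness for checking that the Moran's I test rejects at its nominal rate
#' when frequencies are randomly distributed in space.
#'
#' @param config a [simulation_config()] (supplies seed and geometry).
#' @param n_replicates number of replicate value vectors.
#' @param n_per_block individuals per block backing each estimate.
#' @param p common true frequency.
#' @return list with `geometry` and `values` (blocks x replicates matrix;
#'   zero columns when `n_replicates = 0`).
#' @export
simulate_null_spatial <- function(config = simulation_config(),
                                  n_replicates, n_per_block = 30, p = 0.35) {
  set.seed(config$seed)
  n_sectors <- length(config$blocks_per_sector)
  sector_ids <- paste0("S", seq_len(n_sectors))
  block_ids <- unlist(lapply(seq_len(n_sectors), function(s) {
    sprintf("%s_B%02d", sector_ids[s], seq_len(config$blocks_per_sector[s]))
  }))
  geometry <- block_grid_geometry(block_ids,
                                  rep(sector_ids, config$blocks_per_sector),
                                  config$blocks_per_sector)
  nb <- nrow(geometry)
  values <- matrix(rbinom(nb * n_replicates, 2 * n_per_block, p) /
                     (2 * n_per_block),
                   nrow = nb, ncol = n_replicates)
  list(geometry = geometry, values = values)
}

#' Null replicates of per-block haplotype counts for calibration
#'
#' The zero-heterogeneity regime (`between_block_sd = 0`, no dry-season
#' shift): every block shares one haplotype frequency, per-block sample
#' sizes follow the configured negative-binomial for the chosen round, and
#' haplotype copies are binomial. Feeds the type-I-error calibration of
#' [multi_proportion_test()].
#'
#' @param config a [simulation_config()].
#' @param n_replicates number of replicate series.
#' @param p common haplotype frequency.
#' @param timepoint_index which round's sample-size distribution to use.
#' @return list of [proportion_series()] (blocks with zero catch drop out,
#'   as in the real design).
#' @export
simulate_null_heterogeneity <- function(config = simulation_config(),
                                        n_replicates, p = 0.35,
                                        timepoint_index = 1L) {
  set.seed(config$seed)
  nb <- sum(config$blocks_per_sector)
  mu <- config$mean_block_sample_size[timepoint_index]
  sdv <- config$sd_block_sample_size[timepoint_index]
  lapply(seq_len(n_replicates), function(i) {
    n_b <- draw_block_n(nb, mu, sdv)
    keep <- n_b > 0
    proportion_series(sprintf("B%02d", which(keep)),
                      rbinom(sum(keep), 2 * n_b[keep], p),
                      2 * n_b[keep])
  })
}
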