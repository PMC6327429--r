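#' Run the full kdr haplotype analysis pipeline
#'
#' End-to-end composition of the analysis stages in their natural order:
#' aggregate genotype records, EM haplotype frequencies per block and sector
#' per timepoint, pooled linkage disequilibrium per timepoint, chi-square
#' heterogeneity per haplotype per timepoint at block and sector level,
#' Moran's I per haplotype per timepoint, and the temporal mixed models
#' (timepoint at block and sector level, season, abundance). Writes tidy CSV
#' outputs plus a single JSON results bundle and returns a manifest. The
#' pipeline is a pure function of (inputs, config, seed): re-running with
#' the same inputs reproduces the bundle byte for byte.
#'
#' @param records genotype records tibble (or a path to a genotypes CSV).
#' @param geometry block geometry tibble (or a path to a blocks CSV).
#' @param out_dir directory for outputs (created if needed).
#' @param config a [timepoint_config()].
#' @param focal_haplotypes haplotypes to test for heterogeneity/spatial
#'   structure and model over time.
#' @param houses_per_block divisor converting per-block Prokopack catches to
#'   mean adults per house for the abundance model (the survey sampled at
#'   least this many houses per block).
#' @param seed seed recorded in the manifest (the core pipeline is
#'   deterministic; the seed feeds any permutation options).
#' @return a `kdr_run_manifest`: list with `outputs` (paths), `results`
#'   (in-memory tables), `counts` (records read/excluded), `seed`, `stages`.
#' @export
run_all <- function(records, geometry, out_dir,
                    config = timepoint_config(),
                    focal_haplotypes = c("CI", "FV", "CV"),
                    houses_per_block = 10,
                    seed = 1L) {
  if (is.character(records)) records <- read_genotype_table(records, config)
  if (is.character(geometry)) geometry <- read_block_geometry(geometry)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- character(0)
  outputs <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # --- aggregate + EM ------------------------------------------------------
  block_counts <- stage("aggregate", aggregate_counts(records, "block"))
  sector_counts <- stage("aggregate", aggregate_counts(records, "sector"))
  n_excluded <- attr(block_counts, "n_excluded")
  stages <- c(stages, "aggregate")

  hap_block <- stage("haplotypes", haplotype_frequency_table(block_counts))
  hap_sector <- stage("haplotypes", haplotype_frequency_table(sector_counts))
  hap_block$sector_id <- geometry$sector_id[match(hap_block$unit_id,
                                                  geometry$block_id)]
  hap_all <- dplyr::bind_rows(
    dplyr::mutate(hap_block, unit_level = "block"),
    dplyr::mutate(hap_sector, unit_level = "sector", sector_id = unit_id))
  stages <- c(stages, "haplotypes")

  # --- pooled LD per timepoint --------------------------------------------
  ld_table <- stage("ld", {
  ld_rows <- lapply(unique(records$timepoint), function(tp) {
    pooled <- aggregate_counts(
      dplyr::mutate(records, pool = "all"), "block", timepoints = tp)
    m <- Reduce(`+`, lapply(pooled, function(ct) ct$counts))
    ld <- ld_statistics(em_haplotype_frequencies(
      joint_genotype_counts(m, "pooled", tp)))
    tibble::tibble(timepoint = tp, n_alleles = ld$n_alleles, D = ld$D,
                   r2 = ld$r_squared, chi2 = ld$chi_squared, df = ld$df,
                   p = ld$p_value, p_C = ld$p_C, p_I = ld$p_I)
  })
  dplyr::bind_rows(ld_rows)
  })
  stages <- c(stages, "ld")

  # --- heterogeneity per haplotype/timepoint/level ------------------------
  het_table <- stage("heterogeneity", {
  het_rows <- list()
  for (lvl in c("block", "sector")) {
    ht <- if (lvl == "block") hap_block else hap_sector
    for (tp in unique(ht$timepoint)) {
      sub <- ht[ht$timepoint == tp, , drop = FALSE]
      if (nrow(sub) < 2) next
      for (h in focal_haplotypes) {
        tr <- haplotype_heterogeneity_test(sub, h)
        het_rows[[length(het_rows) + 1L]] <- tibble::tibble(
          haplotype = h, timepoint = tp, unit_level = lvl,
          n_units = nrow(sub), chi2 = tr$statistic, df = tr$df,
          p = tr$p_value)
      }
    }
  }
  dplyr::bind_rows(het_rows)
  })
  stages <- c(stages, "heterogeneity")

  # --- Moran's I per haplotype/timepoint ----------------------------------
  moran_table <- stage("moran", {
  moran_rows <- list()
  for (tp in unique(hap_block$timepoint)) {
    sub <- hap_block[hap_block$timepoint == tp, , drop = FALSE]
    geo <- geometry[geometry$block_id %in% sub$unit_id, , drop = FALSE]
    if (nrow(geo) < 3) next
    w <- inverse_distance_weights(geo)
    for (h in focal_haplotypes) {
      vals <- sub[[paste0("p_", h)]][match(geo$block_id, sub$unit_id)]
      mr <- tryCatch(morans_i(vals, w), error = function(e) NULL)
      if (is.null(mr)) next
      moran_rows[[length(moran_rows) + 1L]] <- tibble::tibble(
        haplotype = h, timepoint = tp, n = mr$n, I = mr$observed_I,
        expected = mr$expected_I, variance = mr$variance, p = mr$p_value)
    }
  }
  dplyr::bind_rows(moran_rows)
  })
  stages <- c(stages, "moran")

  # --- temporal mixed models ----------------------------------------------
  model_rows <- list()
  add_model <- function(label, res) {
    model_rows[[length(model_rows) + 1L]] <<- dplyr::mutate(
      res$fixed_effects, model = label, .before = 1)
  }
  panel <- build_frequency_panel(hap_block, "CI",
                                 sector_lookup = geometry, config = config)
  models_meta <- list()
  stage("temporal", {
    if (length(unique(panel$timepoint)) >= 2) {
      m1 <- fit_timepoint_model(panel, config)
      add_model("timepoint_block_CI", m1)
      m2 <- fit_sector_model(aggregate_panel_to_sector(panel), config)
      add_model("timepoint_sector_CI", m2)
      panel_fv <- build_frequency_panel(hap_block, "FV",
                                        sector_lookup = geometry,
                                        config = config)
      add_model("timepoint_block_FV", fit_timepoint_model(panel_fv, config))
      models_meta <- list(method = m1$method, df_method = m1$df_method,
                          singular = m1$singular)
    }
    if (all(c("wet", "dry") %in% panel$season)) {
      add_model("season_block_CI", fit_season_model(panel))
    }
    wet_panel <- panel[panel$season == "wet", , drop = FALSE]
    if (nrow(wet_panel) > 0) {
      pro <- records[records$season == "wet" &
                       (is.na(records$method) | records$method == "prokopack"), ]
      catch <- dplyr::count(pro, .data$block_id, .data$timepoint)
      wet_panel$mean_adults_per_house <-
        catch$n[match(paste(wet_panel$unit_id, wet_panel$timepoint),
                      paste(catch$block_id, catch$timepoint))] /
        houses_per_block
      wet_panel$mean_adults_per_house[is.na(wet_panel$mean_adults_per_house)] <- 0
      add_model("abundance_block_CI", fit_abundance_model(wet_panel))
    }
  })
  temporal_table <- dplyr::bind_rows(model_rows)
  stages <- c(stages, "temporal")

  # --- write outputs -------------------------------------------------------
  tables <- list(haplotypes = hap_all, ld = ld_table,
                 heterogeneity = het_table, moran = moran_table,
                 temporal = temporal_table)
  for (nm in names(tables)) {
    path <- file.path(out_dir, paste0(nm, ".csv"))
    readr::write_csv(tables[[nm]], path)
    outputs <- c(outputs, path)
  }
  counts <- list(records_read = nrow(records),
                 dual_genotyped = nrow(records) - n_excluded,
                 excluded_single_or_no_genotype = n_excluded)
  bundle <- c(tables, list(counts = counts, models_meta = models_meta,
                           seed = seed, stages = stages))
  json_path <- file.path(out_dir, "results.json")
  jsonlite::write_json(bundle, json_path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE, na = "null")
  outputs <- c(outputs, json_path)

  structure(list(outputs = outputs, results = tables, counts = counts,
                 seed = seed, stages = stages, out_dir = out_dir),
            class = "kdr_run_manifest")
}

#' @export
print.kdr_run_manifest <- function(x, ...) {
  cat("kdr analysis run:", length(x$stages), "stages,",
      x$counts$records_read, "records (",
      x$counts$excluded_single_or_no_genotype, "without both genotypes)\n")
  cat("outputs:\n")
  for (p in x$outputs) cat("  ", p, "\n")
  invisible(x)
}
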