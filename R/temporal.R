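#' Build a frequency panel from per-unit haplotype estimates
#'
#' Reshapes a [haplotype_frequency_table()] into the response panel of the
#' temporal mixed models: one row per unit x timepoint with the frequency of
#' the chosen haplotype, the per-unit sample size, sector membership and
#' season.
#'
#' @param hap_table tibble from [haplotype_frequency_table()] at block level.
#' @param haplotype which haplotype frequency is the response.
#' @param sector_lookup data frame mapping `block_id` to `sector_id`; not
#'   needed when `hap_table` already has a `sector_id` column.
#' @param config a [timepoint_config()].
#' @return tibble with columns `unit_id`, `sector_id`, `timepoint`, `season`,
#'   `frequency`, `n`.
#' @export
build_frequency_panel <- function(hap_table,
                                  haplotype = c("CI", "FV", "FI", "CV"),
                                  sector_lookup = NULL,
                                  config = timepoint_config()) {
  haplotype <- match.arg(haplotype)
  pcol <- paste0("p_", haplotype)
  sector <- if (!is.null(sector_lookup)) {
    sector_lookup$sector_id[match(hap_table$unit_id, sector_lookup$block_id)]
  } else if ("sector_id" %in% names(hap_table)) {
    hap_table$sector_id
  } else {
    NA_character_
  }
  tibble::tibble(unit_id = hap_table$unit_id,
                 sector_id = as.character(sector),
                 timepoint = hap_table$timepoint,
                 season = season_of(hap_table$timepoint, config),
                 frequency = hap_table[[pcol]],
                 n = hap_table$n)
}

#' Aggregate a block-level panel to sectors
#'
#' Sector frequency is the count-weighted pooling of its blocks' haplotype
#' counts: `sum(n_b * p_b) / sum(n_b)` with `n` summed, which equals pooling
#' the blocks' estimated haplotype copies.
#'
#' @param panel a block-level frequency panel with a `sector_id` column.
#' @return panel aggregated to one row per sector x timepoint (`unit_id` is
#'   the sector id).
#' @export
aggregate_panel_to_sector <- function(panel) {
  panel |>
    dplyr::group_by(.data$sector_id, .data$timepoint, .data$season) |>
    dplyr::summarise(
      frequency = sum(.data$n * .data$frequency) / sum(.data$n),
      n = sum(.data$n), .groups = "drop") |>
    dplyr::mutate(unit_id = .data$sector_id) |>
    dplyr::select("unit_id", "sector_id", "timepoint", "season",
                  "frequency", "n")
}

# Shared model-fitting core: REML linear mixed model via nlme::lme, which
# uses containment (inner-outer) degrees of freedom for the fixed-effect
# t-tests. `logit` transforms the response (frequencies clamped away from
# 0/1 by half a chromosome count); `weight_by_n` gives residual variances
# proportional to 1/n.
fit_lme <- function(data, fixed, random, reference_level, method = "REML",
                    logit = FALSE, weight_by_n = FALSE) {
  if (logit) {
    eps <- 1 / (4 * pmax(data$n, 1))
    data$frequency <- stats::qlogis(pmin(pmax(data$frequency, eps), 1 - eps))
  }
  weights <- if (weight_by_n) nlme::varFixed(~ inv_n) else NULL
  if (weight_by_n) data$inv_n <- 1 / data$n
  singular <- FALSE
  # degenerate (e.g. noise-free) panels can make the default EM warm-up of
  # lme exactly singular; fall back to alternative controls before giving up
  controls <- list(
    nlme::lmeControl(maxIter = 200, msMaxIter = 200, returnObject = TRUE),
    nlme::lmeControl(maxIter = 200, msMaxIter = 200, returnObject = TRUE,
                     niterEM = 0),
    nlme::lmeControl(maxIter = 200, msMaxIter = 200, returnObject = TRUE,
                     opt = "optim"))
  fit <- NULL
  last_error <- NULL
  for (ctrl in controls) {
    fit <- tryCatch(
      withCallingHandlers(
        nlme::lme(fixed = fixed, random = random, data = data,
                  method = method, weights = weights, control = ctrl),
        warning = function(w) {
          singular <<- TRUE
          invokeRestart("muffleWarning")
        }),
      error = function(e) { last_error <<- e; NULL })
    if (!is.null(fit)) break
  }
  if (is.null(fit)) stop(last_error)
  tt <- summary(fit)$tTable
  fixed_effects <- tibble::tibble(
    term = rownames(tt),
    estimate = unname(tt[, "Value"]),
    std_error = unname(tt[, "Std.Error"]),
    df = unname(tt[, "DF"]),
    t_value = unname(tt[, "t-value"]),
    p_value = unname(tt[, "p-value"]))
  vc <- nlme::VarCorr(fit)
  re_rows <- grep("(Intercept)", rownames(vc), fixed = TRUE)
  grouping <- rownames(vc)
  # name random intercepts by the preceding grouping header (nested output)
  headers <- grep("=", grouping, fixed = TRUE)
  grp_names <- character(length(re_rows))
  for (i in seq_along(re_rows)) {
    h <- headers[headers < re_rows[i]]
    grp_names[i] <- if (length(h) > 0) {
      sub(" =.*$", "", grouping[max(h)])
    } else {
      names(fit$groups)[1]
    }
  }
  random_effect_sd <- tibble::tibble(
    grouping = grp_names,
    sd = as.numeric(vc[re_rows, "StdDev"]))
  structure(
    list(fixed_effects = fixed_effects,
         random_effect_sd = random_effect_sd,
         sigma = fit$sigma,
         reference_level = reference_level,
         method = method, df_method = "containment (inner-outer)",
         logit = logit, weighted = weight_by_n,
         singular = singular,
         n_obs = nrow(data),
         n_groups = vapply(fit$groups, function(g) length(unique(g)),
                           integer(1)),
         fit = fit),
    class = "kdr_model_result")
}

#' @export
print.kdr_model_result <- function(x, ...) {
  cat(sprintf("Linear mixed model (%s, %s df), %d obs\n",
              x$method, x$df_method, x$n_obs))
  cat("Reference level:", x$reference_level, "\n")
  print(as.data.frame(x$fixed_effects), digits = 4)
  cat("Random intercept sd:",
      paste(sprintf("%s = %.4g", x$random_effect_sd$grouping,
                    x$random_effect_sd$sd), collapse = ", "),
      "; residual =", format(x$sigma, digits = 4), "\n")
  invisible(x)
}

panel_checks <- function(panel, need_sector = FALSE) {
  stopifnot(all(c("unit_id", "timepoint", "frequency") %in% names(panel)))
  if (any(panel$frequency < 0 | panel$frequency > 1, na.rm = TRUE)) {
    stop("frequencies must lie in [0, 1]")
  }
  if (anyDuplicated(paste(panel$unit_id, panel$timepoint))) {
    stop("panel must have one row per unit x timepoint")
  }
  if (need_sector && (!"sector_id" %in% names(panel) ||
                      anyNA(panel$sector_id))) {
    stop("sector_id required for the nested model")
  }
  invisible(panel)
}

#' Mixed model for change in frequency over timepoints
#'
#' Hierarchical linear mixed model with timepoint as a categorical fixed
#' effect (first timepoint = reference, so each coefficient is the change in
#' frequency relative to the first survey round) and random intercepts for
#' sector and block nested within sector. Fit by REML; fixed-effect t-tests
#' use containment degrees of freedom.
#'
#' @param panel block-level frequency panel (see [build_frequency_panel()]).
#' @param config a [timepoint_config()]; sets the timepoint order and
#'   reference level.
#' @param logit model `logit(frequency)` instead of the raw frequency.
#' @param weight_by_n residual variance proportional to `1/n`.
#' @return object of class `kdr_model_result` with a tidy `fixed_effects`
#'   coefficient table, random-intercept standard deviations, and fit
#'   metadata (including a `singular` flag when a variance component
#'   collapsed to its boundary).
#' @export
fit_timepoint_model <- function(panel, config = timepoint_config(),
                                logit = FALSE, weight_by_n = FALSE) {
  panel_checks(panel, need_sector = TRUE)
  if (length(unique(panel$timepoint)) < 2) stop("need >= 2 timepoints")
  if (length(unique(panel$sector_id)) < 2) stop("need >= 2 sectors")
  d <- as.data.frame(panel)
  lv <- intersect(config$timepoint, unique(d$timepoint))
  d$timepoint <- factor(d$timepoint, levels = lv)
  fit_lme(d, frequency ~ timepoint, ~ 1 | sector_id / unit_id,
          reference_level = lv[1], logit = logit, weight_by_n = weight_by_n)
}

#' Sector-level mixed model for change over timepoints
#'
#' As [fit_timepoint_model()] but on a sector-aggregated panel with a single
#' random intercept for sector.
#'
#' @param panel sector-level panel (e.g. from [aggregate_panel_to_sector()]).
#' @inheritParams fit_timepoint_model
#' @return a `kdr_model_result`.
#' @export
fit_sector_model <- function(panel, config = timepoint_config(),
                             logit = FALSE, weight_by_n = FALSE) {
  panel_checks(panel)
  if (length(unique(panel$timepoint)) < 2) stop("need >= 2 timepoints")
  d <- as.data.frame(panel)
  lv <- intersect(config$timepoint, unique(d$timepoint))
  d$timepoint <- factor(d$timepoint, levels = lv)
  fit_lme(d, frequency ~ timepoint, ~ 1 | unit_id,
          reference_level = lv[1], logit = logit, weight_by_n = weight_by_n)
}

#' Mixed model for the effect of season on frequency
#'
#' Pools the wet rounds and the dry rounds and fits frequency ~ season (wet
#' reference) with a random intercept per block.
#'
#' @inheritParams fit_timepoint_model
#' @return a `kdr_model_result`; the `seasondry` coefficient is the
#'   dry-season excess frequency.
#' @export
fit_season_model <- function(panel, logit = FALSE, weight_by_n = FALSE) {
  panel_checks(panel)
  if (!all(c("wet", "dry") %in% panel$season)) {
    stop("both seasons must be present")
  }
  d <- as.data.frame(panel)
  d$season <- factor(d$season, levels = c("wet", "dry"))
  fit_lme(d, frequency ~ season, ~ 1 | unit_id,
          reference_level = "wet", logit = logit, weight_by_n = weight_by_n)
}

#' Mixed model for the relationship between adult abundance and frequency
#'
#' Regresses block-level frequency on the mean number of adult mosquitoes
#' collected per house, with a random intercept per block. Only wet-season
#' rows are used: dry-season indoor collections are too sparse to estimate
#' abundance.
#'
#' @param panel frequency panel with a `mean_adults_per_house` column.
#' @inheritParams fit_timepoint_model
#' @return a `kdr_model_result`; the `mean_adults_per_house` coefficient is
#'   the change in frequency per additional adult per house.
#' @export
fit_abundance_model <- function(panel, logit = FALSE, weight_by_n = FALSE) {
  panel_checks(panel)
  d <- as.data.frame(panel[panel$season == "wet", , drop = FALSE])
  if (!"mean_adults_per_house" %in% names(d)) {
    stop("panel lacks a mean_adults_per_house column")
  }
  if (anyNA(d$mean_adults_per_house)) {
    bad <- paste(d$unit_id[is.na(d$mean_adults_per_house)],
                 d$timepoint[is.na(d$mean_adults_per_house)], sep = "@")
    stop("missing abundance for rows: ", paste(bad, collapse = ", "))
  }
  fit_lme(d, frequency ~ mean_adults_per_house, ~ 1 | unit_id,
          reference_level = "(continuous)", logit = logit,
          weight_by_n = weight_by_n)
}
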