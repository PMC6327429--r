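#' Read a per-mosquito genotype table
#'
#' Reads a CSV of individually genotyped mosquitoes, one row per specimen,
#' with unphased genotypes at codon 1534 (`FF`/`FC`/`CC`) and codon 1016
#' (`VV`/`VI`/`II`). Genotype strings are case-insensitive; unparseable or
#' empty genotype values become `missing` with a warning rather than an
#' error, so a partially genotyped survey loads cleanly. Unknown columns are
#' preserved but ignored by the analyses.
#'
#' @param path path to a CSV file with header columns `specimen_id`,
#'   `block_id`, `sector_id`, `timepoint`, `gt1534`, `gt1016` (mandatory) and
#'   optionally `season`, `method`, `sex`.
#' @param config a [timepoint_config()]; used to derive/validate seasons.
#' @return A tibble of validated genotype records with columns
#'   `specimen_id`, `block_id`, `sector_id`, `timepoint`, `season`, `method`,
#'   `sex`, `gt1534`, `gt1016`. Missing genotypes are `NA`.
#' @export
read_genotype_table <- function(path, config = timepoint_config()) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         na = "")
  validate_genotype_records(raw, config = config)
}

#' Validate a data frame of genotype records
#'
#' @param records data frame with the columns described in
#'   [read_genotype_table()].
#' @inheritParams read_genotype_table
#' @return a validated tibble (see [read_genotype_table()]).
#' @export
validate_genotype_records <- function(records, config = timepoint_config()) {
  mandatory <- c("specimen_id", "block_id", "sector_id", "timepoint",
                 "gt1534", "gt1016")
  absent <- setdiff(mandatory, names(records))
  if (length(absent) > 0) {
    stop("missing mandatory column(s): ", paste(absent, collapse = ", "))
  }
  if (anyDuplicated(records$specimen_id)) {
    dup <- records$specimen_id[duplicated(records$specimen_id)][1]
    stop("duplicate specimen_id: ", dup)
  }
  bad_tp <- setdiff(unique(records$timepoint), config$timepoint)
  if (length(bad_tp) > 0) {
    stop("unknown timepoint label(s): ", paste(bad_tp, collapse = ", "))
  }

  gt1534 <- parse_genotype(records$gt1534, GT1534_LEVELS, "gt1534")
  gt1016 <- parse_genotype(records$gt1016, GT1016_LEVELS, "gt1016")

  season <- season_of(records$timepoint, config)
  if ("season" %in% names(records)) {
    given <- tolower(as.character(records$season))
    given[given %in% c("", "na")] <- NA
    clash <- !is.na(given) & given != season
    if (any(clash)) {
      stop("season inconsistent with timepoint for specimen(s): ",
           paste(utils::head(records$specimen_id[clash], 5), collapse = ", "))
    }
  }
  method <- if ("method" %in% names(records)) {
    m <- tolower(as.character(records$method))
    m[m %in% c("", "na")] <- NA
    if (!all(is.na(m) | m %in% c("prokopack", "ovitrap"))) {
      stop("method must be 'prokopack' or 'ovitrap'")
    }
    m
  } else NA_character_
  sex <- if ("sex" %in% names(records)) {
    s <- toupper(as.character(records$sex))
    ifelse(s %in% c("F", "M"), s, "unknown")
  } else "unknown"

  tibble::tibble(
    specimen_id = as.character(records$specimen_id),
    block_id = as.character(records$block_id),
    sector_id = as.character(records$sector_id),
    timepoint = as.character(records$timepoint),
    season = season,
    method = method,
    sex = sex,
    gt1534 = gt1534,
    gt1016 = gt1016
  )
}

# Case-insensitive genotype parser; heterozygotes accepted in either letter
# order. Anything else becomes NA with one summary warning.
parse_genotype <- function(x, levels, what) {
  up <- toupper(trimws(as.character(x)))
  rev2 <- paste0(substr(levels, 2, 2), substr(levels, 1, 1))
  out <- ifelse(up %in% levels, up, levels[match(up, rev2)])
  unparseable <- is.na(out) & !is.na(x) & !(up %in% c("", "MISSING", "."))
  if (any(unparseable)) {
    warning(sum(unparseable), " unparseable ", what,
            " value(s) set to missing (e.g. '",
            x[unparseable][1], "')", call. = FALSE)
  }
  out
}

#' Write genotype records to CSV
#'
#' Canonical column order and spelling, so that read/write round-trips are
#' the identity on the canonical columns.
#'
#' @param records tibble from [read_genotype_table()] or [simulate_study()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(records, path) {
  readr::write_csv(records, path, na = "")
  invisible(path)
}

#' Read block centroid coordinates
#'
#' @param path CSV with columns `block_id`, `sector_id`, `x`, `y` (planar
#'   coordinates, metres or arbitrary units).
#' @return tibble of block geometries with unique ids.
#' @export
read_block_geometry <- function(path) {
  geo <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("block_id", "x", "y")
  absent <- setdiff(need, names(geo))
  if (length(absent) > 0) {
    stop("missing mandatory column(s): ", paste(absent, collapse = ", "))
  }
  if (anyDuplicated(geo$block_id)) stop("duplicate block_id in geometry")
  geo$block_id <- as.character(geo$block_id)
  tibble::as_tibble(geo)
}

#' Construct a joint genotype count table
#'
#' A 3x3 table of joint genotype classes, rows indexed by the codon-1534
#' genotype (`FF`, `FC`, `CC`) and columns by the codon-1016 genotype
#' (`VV`, `VI`, `II`), for one sampling unit at one timepoint. Only
#' dual-genotyped individuals are counted.
#'
#' @param counts 3x3 non-negative integer matrix (rows 1534, cols 1016).
#' @param unit_id sampling unit (block or sector) identifier.
#' @param timepoint timepoint label.
#' @return an object of class `joint_genotype_counts`.
#' @export
joint_genotype_counts <- function(counts, unit_id = NA_character_,
                                  timepoint = NA_character_) {
  counts <- as.matrix(counts)
  stopifnot(identical(dim(counts), c(3L, 3L)), all(counts >= 0),
            all(counts == round(counts)))
  dimnames(counts) <- list(gt1534 = GT1534_LEVELS, gt1016 = GT1016_LEVELS)
  structure(
    list(unit_id = as.character(unit_id),
         timepoint = as.character(timepoint),
         counts = counts, n_complete = sum(counts)),
    class = "joint_genotype_counts"
  )
}

#' @export
print.joint_genotype_counts <- function(x, ...) {
  cat("Joint genotype counts: unit", x$unit_id, "at", x$timepoint,
      "(n =", x$n_complete, "dual-genotyped)\n")
  print(x$counts)
  invisible(x)
}

#' Aggregate genotype records into joint count tables
#'
#' Builds one 3x3 joint genotype table per sampling unit per timepoint. Only
#' records genotyped at BOTH loci enter a table; single-locus records are
#' tallied in the `n_excluded` attribute (they still contribute to
#' single-locus allele counts via [allele_counts_from_records()]). Units with
#' zero dual-genotyped records at a timepoint produce no table, so they drop
#' out of downstream degrees of freedom.
#'
#' @param records validated genotype records.
#' @param unit `"block"` or `"sector"`: the aggregation level.
#' @param timepoints optional character vector restricting the timepoints.
#' @return list of [joint_genotype_counts()] objects, with attribute
#'   `n_excluded` (records dropped for a missing genotype).
#' @export
aggregate_counts <- function(records, unit = c("block", "sector"),
                             timepoints = NULL) {
  unit <- match.arg(unit)
  if (nrow(records) == 0) {
    return(structure(list(), n_excluded = 0L))
  }
  if (!is.null(timepoints)) {
    records <- records[records$timepoint %in% timepoints, , drop = FALSE]
  }
  id_col <- if (unit == "block") "block_id" else "sector_id"
  complete <- !is.na(records$gt1534) & !is.na(records$gt1016)
  n_excluded <- sum(!complete)
  recs <- records[complete, , drop = FALSE]
  if (nrow(recs) == 0) return(structure(list(), n_excluded = n_excluded))

  key <- paste(recs[[id_col]], recs$timepoint, sep = "\r")
  out <- lapply(split(seq_len(nrow(recs)), key), function(idx) {
    tab <- table(factor(recs$gt1534[idx], GT1534_LEVELS),
                 factor(recs$gt1016[idx], GT1016_LEVELS))
    joint_genotype_counts(unclass(tab),
                          unit_id = recs[[id_col]][idx[1]],
                          timepoint = recs$timepoint[idx[1]])
  })
  names(out) <- NULL
  structure(out, n_excluded = n_excluded)
}

#' Marginal allele counts at one locus
#'
#' Marginalises a joint genotype table to mutant-allele counts at one locus:
#' two copies per homozygous mutant, one per heterozygote.
#'
#' @param counts a [joint_genotype_counts()] object.
#' @param locus `1534` (mutant allele C) or `1016` (mutant allele I).
#' @return list with `locus`, `mutant_count`, `total_alleles`.
#' @export
allele_counts <- function(counts, locus = c("1534", "1016")) {
  locus <- match.arg(as.character(locus), c("1534", "1016"))
  m <- counts$counts
  if (locus == "1534") {
    mutant <- 2 * sum(m["CC", ]) + sum(m["FC", ])
  } else {
    mutant <- 2 * sum(m[, "II"]) + sum(m[, "VI"])
  }
  list(locus = locus, mutant_count = as.integer(mutant),
       total_alleles = 2L * counts$n_complete)
}

#' Single-locus allele counts straight from records
#'
#' Unlike [allele_counts()], this uses every record genotyped at the chosen
#' locus, including specimens missing the other locus, matching how
#' per-locus genotyping totals are reported for surveys where the two assays
#' succeed on different subsets.
#'
#' @param records validated genotype records.
#' @inheritParams allele_counts
#' @return list with `locus`, `mutant_count`, `total_alleles`.
#' @export
allele_counts_from_records <- function(records, locus = c("1534", "1016")) {
  locus <- match.arg(as.character(locus), c("1534", "1016"))
  gt <- if (locus == "1534") records$gt1534 else records$gt1016
  gt <- gt[!is.na(gt)]
  hom <- if (locus == "1534") "CC" else "II"
  het <- if (locus == "1534") "FC" else "VI"
  list(locus = locus,
       mutant_count = as.integer(2 * sum(gt == hom) + sum(gt == het)),
       total_alleles = 2L * length(gt))
}
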