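#' Define the ordered timepoints of a study design
#'
#' The surveillance design is a sequence of collection rounds, each labelled
#' (e.g. `"wet2014"`) and assigned a season. Labels are ordered: the first is
#' the reference level of the temporal mixed models. The default is the
#' four-round design of a two-year survey alternating wet and dry seasons.
#'
#' @param labels character vector of timepoint labels, in temporal order.
#' @param seasons character vector the same length as `labels`, each `"wet"`
#'   or `"dry"`.
#' @return A tibble with columns `timepoint` and `season`, classed
#'   `kdr_timepoints`; label order encodes temporal order.
#' @examples
#' timepoint_config() # the default four-round design
#' timepoint_config(c("t1", "t2"), c("wet", "dry"))
#' @export
timepoint_config <- function(labels = c("wet2014", "dry2015", "wet2015", "dry2016"),
                             seasons = c("wet", "dry", "wet", "dry")) {
  stopifnot(length(labels) == length(seasons), length(labels) >= 1)
  if (anyDuplicated(labels)) stop("timepoint labels must be unique")
  if (!all(seasons %in% c("wet", "dry"))) {
    stop("seasons must be 'wet' or 'dry'")
  }
  out <- tibble::tibble(timepoint = as.character(labels),
                        season = as.character(seasons))
  class(out) <- c("kdr_timepoints", class(out))
  out
}

#' @keywords internal
season_of <- function(timepoint, config) {
  config$season[match(timepoint, config$timepoint)]
}
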