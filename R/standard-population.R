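#' Standard population weights for direct age standardisation
#'
#' @param age_group Character vector of age-group interval labels matching
#'   the dataset convention (e.g. `"[25,30)"`).
#' @param weight Non-negative weights, one per age group; they need not sum
#'   to one (they are renormalised internally).
#' @return An object of class `standard_population`: a data frame with
#'   columns `age_group`, `weight`, `weight_norm`.
#' @export
standard_population <- function(age_group, weight) {
  weight <- as.numeric(weight)
  if (length(age_group) != length(weight)) {
    stop("age_group and weight must have equal length", call. = FALSE)
  }
  if (any(!is.finite(weight)) || any(weight < 0)) {
    stop("weights must be finite and non-negative", call. = FALSE)
  }
  if (sum(weight) <= 0) stop("weights must have a positive total", call. = FALSE)
  validate_age_groups(age_group)
  out <- data.frame(age_group = as.character(age_group), weight = weight,
                    weight_norm = weight / sum(weight),
                    stringsAsFactors = FALSE)
  class(out) <- c("standard_population", "data.frame")
  out
}

#' Read a standard population from a two-column delimited file
#'
#' Expects columns `age_group` and `weight` (comma or tab separated, header
#' required).
#'
#' @param path Path to the file.
#' @return A [standard_population()].
#' @export
load_standard_population <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  sep <- detect_sep(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  if (!all(c("age_group", "weight") %in% names(tab))) {
    stop("standard population file needs columns age_group, weight", call. = FALSE)
  }
  standard_population(tab$age_group, tab$weight)
}

#' 2013 European standard population, ages 25 and over
#'
#' The Eurostat 2013 revision of the European standard population assigns,
#' per 100,000, weights 6000, 6500, 7000, 7000, 7000, 7000, 6500, 6000,
#' 5500, 5000, 4000, 2500 to the five-year groups from 25-29 through 80-84,
#' and 1500 + 1000 to 85-89 and 90+.  Because the modelling grid stops at an
#' open-ended 85+ group, the last two weights are summed.  Only ages 25+ are
#' covered, so rates standardised with these weights are per 100,000 of the
#' 25+ standard population — renormalisation over the 13 modelled groups
#' makes the absolute level differ from an all-ages standardised rate.
#'
#' @return A [standard_population()] with 13 rows aligned with
#'   [table1_fixture()] age groups.
#' @export
esp2013_standard <- function() {
  path <- system.file("extdata", "esp2013_25plus.csv", package = "gapcmap")
  load_standard_population(path)
}
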