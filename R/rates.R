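#' Crude mortality rate per 100,000 person-years
#'
#' @param deaths Non-negative death count(s).
#' @param population Strictly positive person-time.
#' @return `deaths / population * 1e5`, vectorised.
#' @examples
#' crude_rate(29, 39112750)   # about 0.074 per 100,000
#' @export
crude_rate <- function(deaths, population) {
  if (any(!(population > 0))) {
    stop("population must be strictly positive", call. = FALSE)
  }
  if (any(deaths < 0)) stop("deaths must be non-negative", call. = FALSE)
  deaths / population * 1e5
}

#' Directly standardised rate
#'
#' Weighted average of age-specific rates using external standard-population
#' weights (the *direct method*).  Weights are renormalised, so the result
#' is a convex combination of the age-specific rates.
#'
#' @param age_rates Named or ordered vector of age-specific rates (any
#'   scale; usually per 100,000).
#' @param std A [standard_population()] whose age groups match `age_rates`.
#'   If `age_rates` is named, names must equal `std$age_group` as sets;
#'   otherwise lengths must match and order is assumed aligned.
#' @return The standardised rate on the same scale as `age_rates`.
#' @export
direct_standardized_rate <- function(age_rates, std) {
  if (!inherits(std, "standard_population")) {
    stop("std must be a standard_population", call. = FALSE)
  }
  if (!is.null(names(age_rates))) {
    if (!setequal(names(age_rates), std$age_group) ||
        length(age_rates) != nrow(std)) {
      stop("alignment error: age groups of rates and standard differ",
           call. = FALSE)
    }
    age_rates <- age_rates[std$age_group]
  } else if (length(age_rates) != nrow(std)) {
    stop("alignment error: rate vector length differs from standard",
         call. = FALSE)
  }
  sum(std$weight_norm * age_rates)
}

#' Crude age-specific rates by gender
#'
#' Aggregates deaths and person-time over areas and periods and returns the
#' age-specific rate per 100,000 for each gender.
#'
#' @param dataset A [mortality_dataset()].
#' @return A data frame with columns `gender`, `age_group`, `deaths`,
#'   `population`, `rate`.
#' @export
age_specific_rates <- function(dataset) {
  d <- dataset$dims
  dth <- apply(dataset$deaths, c(1, 3), sum)
  pop <- apply(dataset$population, c(1, 3), sum)
  out <- expand.grid(gender = dataset$labels$gender,
                     age_group = dataset$labels$age_group,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$deaths <- as.vector(dth)
  out$population <- as.vector(pop)
  out$rate <- crude_rate(out$deaths, out$population)
  out
}

#' Age-standardised rate trend by gender
#'
#' For each period, aggregates over areas, computes age-specific rates per
#' gender and directly standardises them with `std`.  This reproduces the
#' usual preliminary descriptive analysis of a mortality series.
#'
#' @param dataset A [mortality_dataset()].
#' @param std A [standard_population()] covering the dataset's age groups
#'   (default: the 2013 European standard restricted to ages 25+,
#'   [esp2013_standard()]).
#' @return Data frame with columns `gender`, `year`, `asr` (per 100,000 of
#'   the standard population), plus `crude` (all-ages crude rate).
#' @export
standardized_rate_trend <- function(dataset, std = esp2013_standard()) {
  d <- dataset$dims
  if (!setequal(std$age_group, dataset$labels$age_group)) {
    stop("alignment error: standard population age groups differ from dataset",
         call. = FALSE)
  }
  std <- standard_population(
    std$age_group[match(dataset$labels$age_group, std$age_group)],
    std$weight[match(dataset$labels$age_group, std$age_group)]
  )
  dth <- apply(dataset$deaths, c(1, 3, 4), sum)      # G x I x T
  pop <- apply(dataset$population, c(1, 3, 4), sum)
  out <- expand.grid(gender = dataset$labels$gender,
                     year = dataset$labels$year,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$asr <- NA_real_
  out$crude <- NA_real_
  rowix <- 1L
  for (t in seq_len(d$T)) for (g in seq_len(d$G)) {
    rates <- crude_rate(dth[g, , t], pop[g, , t])
    out$asr[rowix] <- direct_standardized_rate(rates, std)
    out$crude[rowix] <- crude_rate(sum(dth[g, , t]), sum(pop[g, , t]))
    rowix <- rowix + 1L
  }
  out
}
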