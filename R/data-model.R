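#' Study dimensions for a gender-age-period-cohort grid
#'
#' Records the size of the modelling grid: `G` genders, `A` areas, `I`
#' five-year age groups, `T` periods, and the ratio `M` of the age-interval
#' width to the period-interval width.  The number of birth cohorts follows
#' as `K = M * (I - 1) + T`, because the cohort of a cell is indexed by
#' `k = M * (I - i) + t` (see [cohort_index()]).
#'
#' @param G,A,I,T Counts of genders, areas, age groups and periods.
#' @param M Ratio of age-interval width to period width (default 5: five-year
#'   age groups with annual periods).
#' @return An object of class `study_dims`: a list with elements
#'   `G`, `A`, `I`, `T`, `M`, `K`.
#' @examples
#' study_dims(G = 2, A = 50, I = 13, T = 24)
#' @export
study_dims <- function(G, A, I, T, M = 5L) {
  vals <- c(G = G, A = A, I = I, T = T, M = M)
  if (any(vals != round(vals)) || any(!is.finite(vals))) {
    stop("study dimensions must be finite integers", call. = FALSE)
  }
  G <- as.integer(G); A <- as.integer(A); I <- as.integer(I)
  T <- as.integer(T); M <- as.integer(M)
  if (G < 1L || A < 1L || M < 1L) {
    stop("need G >= 1, A >= 1, M >= 1", call. = FALSE)
  }
  if (I < 2L) stop("need at least 2 age groups (I >= 2)", call. = FALSE)
  # T = 1 is allowed so that period-aggregated descriptive tables (such as
  # the packaged national fixture) can be represented; model fitting with
  # period or interaction effects requires T >= 2 and checks separately.
  if (T < 1L) stop("need at least 1 period (T >= 1)", call. = FALSE)
  structure(
    list(G = G, A = A, I = I, T = T, M = M, K = M * (I - 1L) + T),
    class = "study_dims"
  )
}

#' @export
print.study_dims <- function(x, ...) {
  cat(sprintf(
    "study_dims: G=%d genders, A=%d areas, I=%d age groups, T=%d periods (M=%d) -> K=%d cohorts\n",
    x$G, x$A, x$I, x$T, x$M, x$K
  ))
  invisible(x)
}

## ---- age-group label handling -------------------------------------------

# Parse labels like "[25,30)", "[85,+)", "25-29", "85+" into (lower, upper)
# bounds in years; upper is Inf for open-ended groups.
parse_age_bounds <- function(labels) {
  labels <- as.character(labels)
  lower <- upper <- rep(NA_real_, length(labels))
  for (j in seq_along(labels)) {
    s <- gsub("\\s", "", labels[j])
    if (grepl("^\\[\\d+,(\\d+\\)|\\+\\))$", s)) {
      inner <- sub("^\\[", "", sub("\\)$", "", s))
      parts <- strsplit(inner, ",", fixed = TRUE)[[1]]
      lower[j] <- as.numeric(parts[1])
      upper[j] <- if (parts[2] == "+") Inf else as.numeric(parts[2])
    } else if (grepl("^\\d+-\\d+$", s)) {
      parts <- as.numeric(strsplit(s, "-", fixed = TRUE)[[1]])
      lower[j] <- parts[1]
      upper[j] <- parts[2] + 1  # "25-29" means [25, 30)
    } else if (grepl("^\\d+\\+$", s)) {
      lower[j] <- as.numeric(sub("\\+$", "", s))
      upper[j] <- Inf
    } else {
      stop(sprintf("cannot parse age-group label '%s'", labels[j]), call. = FALSE)
    }
  }
  cbind(lower = lower, upper = upper)
}

validate_age_groups <- function(labels) {
  b <- parse_age_bounds(labels)
  o <- order(b[, "lower"])
  b <- b[o, , drop = FALSE]
  if (any(b[, "upper"] <= b[, "lower"])) {
    stop("age-group intervals must have upper > lower", call. = FALSE)
  }
  if (nrow(b) > 1 && any(b[-nrow(b), "upper"] > b[-1, "lower"] + 1e-9)) {
    stop("age-group intervals overlap", call. = FALSE)
  }
  o
}

## ---- mortality dataset ---------------------------------------------------

#' Construct a mortality dataset on a G x A x I x T grid
#'
#' Holds observed death counts and person-time at risk for every
#' (gender, area, age group, period) cell, together with axis labels.
#' Internal storage order is `(g, a, i, t)` with `g` varying fastest.
#' Age groups are ordered youngest first, so the oldest group has index
#' `i = I`; this orientation makes the cohort index `k = M * (I - i) + t`
#' assign the earliest-born cohorts to the oldest age group.
#'
#' @param deaths Integer array of dimension `c(G, A, I, T)`; non-negative.
#' @param population Numeric array of the same dimension; strictly positive
#'   person-time (it enters the model as the offset `log n`).
#' @param labels A list with character vectors `gender`, `area`, `age_group`
#'   (interval labels such as `"[25,30)"`), and `year` (calendar labels).
#' @param M Age-to-period interval width ratio passed to [study_dims()].
#' @return An object of class `mortality_dataset` with elements `dims`
#'   (a [study_dims()] object), `deaths`, `population`, `labels`.
#' @export
mortality_dataset <- function(deaths, population, labels, M = 5L) {
  if (!is.array(deaths) || length(dim(deaths)) != 4) {
    stop("deaths must be a 4-d array (G, A, I, T)", call. = FALSE)
  }
  if (!identical(dim(deaths), dim(population))) {
    stop("deaths and population grids must have identical shape", call. = FALSE)
  }
  d <- dim(deaths)
  dims <- study_dims(G = d[1], A = d[2], I = d[3], T = d[4], M = M)
  need <- c(gender = dims$G, area = dims$A, age_group = dims$I, year = dims$T)
  for (nm in names(need)) {
    if (is.null(labels[[nm]]) || length(labels[[nm]]) != need[[nm]]) {
      stop(sprintf("labels$%s must have length %d", nm, need[[nm]]), call. = FALSE)
    }
    labels[[nm]] <- as.character(labels[[nm]])
  }
  bad <- which(deaths < 0 | deaths != round(deaths))
  if (length(bad)) {
    stop(sprintf("deaths must be non-negative integers (e.g. cell %d)", bad[1]),
         call. = FALSE)
  }
  bad <- which(!(population > 0))
  if (length(bad)) {
    stop(sprintf(
      "population must be strictly positive in every cell (it is a log offset); %d offending cells, first at index %d",
      length(bad), bad[1]
    ), call. = FALSE)
  }
  o <- validate_age_groups(labels$age_group)
  if (!identical(o, seq_len(dims$I))) {
    stop("age groups must be supplied youngest first", call. = FALSE)
  }
  structure(
    list(dims = dims, deaths = deaths, population = population, labels = labels),
    class = "mortality_dataset"
  )
}

#' @export
print.mortality_dataset <- function(x, ...) {
  d <- x$dims
  cat(sprintf(
    "mortality_dataset: %d x %d x %d x %d (gender x area x age x period)\n",
    d$G, d$A, d$I, d$T
  ))
  cat(sprintf("  total deaths %s over person-time %s\n",
              format(sum(x$deaths), big.mark = ","),
              format(sum(x$population), big.mark = ",")))
  invisible(x)
}

# Long-format table of cell indices in storage order (g fastest), with the
# cohort index attached.
cell_index_table <- function(dims) {
  tab <- expand.grid(g = seq_len(dims$G), a = seq_len(dims$A),
                     i = seq_len(dims$I), t = seq_len(dims$T),
                     KEEP.OUT.ATTRS = FALSE)
  tab$k <- dims$M * (dims$I - tab$i) + tab$t
  tab
}

## ---- delimited count tables ---------------------------------------------

default_count_schema <- function() {
  c(gender = "gender", area = "area", age_group = "age_group",
    year = "year", deaths = "deaths", population = "population")
}

detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a long-format mortality count table
#'
#' Reads a delimited text file (comma or tab, autodetected; header required)
#' with one row per (gender, area, age group, year) cell and assembles the
#' complete grid.  Every cell must appear exactly once unless
#' `fill_zero_deaths = TRUE`, in which case rows absent from the file get
#' zero deaths — but never a filled-in population, which must be observed.
#'
#' @param path Path to the delimited file.
#' @param schema Named character vector mapping the canonical column roles
#'   `gender`, `area`, `age_group`, `year`, `deaths`, `population` to the
#'   column names used in the file.  Defaults to the canonical names.
#' @param fill_zero_deaths If `TRUE`, missing (g,a,i,t) combinations are
#'   filled with zero deaths provided their population can be recovered from
#'   no other row (it cannot, so missing cells remain an error unless the
#'   file carries a population for them); in practice this flag only permits
#'   files that list population for every cell but omit zero-death rows by
#'   carrying `deaths = NA`.
#' @param M Age-to-period width ratio (see [study_dims()]).
#' @return A [mortality_dataset()].
#' @export
load_counts <- function(path, schema = NULL, fill_zero_deaths = FALSE, M = 5L) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  sch <- default_count_schema()
  if (!is.null(schema)) sch[names(schema)] <- schema
  sep <- detect_sep(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "\"", comment.char = "")
  missing_cols <- setdiff(unname(sch), names(raw))
  if (length(missing_cols)) {
    stop(sprintf("schema error: missing column(s) %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  df <- data.frame(
    gender = as.character(raw[[sch[["gender"]]]]),
    area = as.character(raw[[sch[["area"]]]]),
    age_group = as.character(raw[[sch[["age_group"]]]]),
    year = as.character(raw[[sch[["year"]]]]),
    deaths = as.numeric(raw[[sch[["deaths"]]]]),
    population = as.numeric(raw[[sch[["population"]]]]),
    stringsAsFactors = FALSE
  )

  genders <- sort(unique(df$gender))
  areas <- sort(unique(df$area))
  ages_raw <- unique(df$age_group)
  ages <- ages_raw[validate_age_groups(ages_raw)]
  yrs_num <- suppressWarnings(as.numeric(unique(df$year)))
  years <- if (anyNA(yrs_num)) sort(unique(df$year)) else
    as.character(sort(unique(as.numeric(df$year))))

  gi <- match(df$gender, genders)
  ai <- match(df$area, areas)
  ii <- match(df$age_group, ages)
  ti <- match(df$year, years)
  key <- ((ti - 1L) * length(ages) + (ii - 1L)) * length(areas) * length(genders) +
    (ai - 1L) * length(genders) + gi
  dup <- duplicated(key)
  if (any(dup)) {
    j <- which(dup)[1]
    stop(sprintf(
      "validation error: duplicate cell (gender=%s, area=%s, age_group=%s, year=%s) at row %d",
      df$gender[j], df$area[j], df$age_group[j], df$year[j], j
    ), call. = FALSE)
  }

  bad <- which(!is.na(df$deaths) & (df$deaths < 0 | df$deaths != round(df$deaths)))
  if (length(bad)) {
    stop(sprintf("validation error: negative or non-integer deaths at row(s) %s",
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  bad <- which(!(df$population > 0))
  if (length(bad)) {
    stop(sprintf("validation error: non-positive population at row(s) %s",
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  if (anyNA(df$deaths)) {
    if (!fill_zero_deaths) {
      stop("validation error: NA deaths present and fill_zero_deaths is FALSE",
           call. = FALSE)
    }
    df$deaths[is.na(df$deaths)] <- 0
  }

  G <- length(genders); A <- length(areas); I <- length(ages); T <- length(years)
  deaths <- array(NA_real_, dim = c(G, A, I, T))
  population <- array(NA_real_, dim = c(G, A, I, T))
  idx <- cbind(gi, ai, ii, ti)
  deaths[idx] <- df$deaths
  population[idx] <- df$population
  if (anyNA(population)) {
    miss <- which(is.na(population), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "validation error: missing cell (gender=%s, area=%s, age_group=%s, year=%s)%s",
      genders[miss[1]], areas[miss[2]], ages[miss[3]], years[miss[4]],
      if (fill_zero_deaths) " - population can never be filled in" else ""
    ), call. = FALSE)
  }
  mortality_dataset(
    deaths = deaths, population = population,
    labels = list(gender = genders, area = areas, age_group = ages, year = years),
    M = M
  )
}

#' Write a mortality dataset as a long-format delimited table
#'
#' Inverse of [load_counts()]: rereading the file reproduces the grid
#' cell-for-cell.
#'
#' @param dataset A [mortality_dataset()].
#' @param path Output path.
#' @param sep Field separator (`","` or `"\t"`).
#' @export
write_counts <- function(dataset, path, sep = ",") {
  tab <- as_count_table(dataset)
  # age-group labels contain commas, so CSV output must quote strings
  utils::write.table(tab, path, sep = sep, row.names = FALSE,
                     quote = (sep == ","))
  invisible(path)
}

#' Long-format view of a mortality dataset
#'
#' @param dataset A [mortality_dataset()].
#' @return A data frame with columns gender, area, age_group, year, deaths,
#'   population, one row per grid cell.
#' @export
as_count_table <- function(dataset) {
  d <- dataset$dims
  idx <- cell_index_table(d)
  data.frame(
    gender = dataset$labels$gender[idx$g],
    area = dataset$labels$area[idx$a],
    age_group = dataset$labels$age_group[idx$i],
    year = dataset$labels$year[idx$t],
    deaths = as.vector(dataset$deaths),
    population = as.vector(dataset$population),
    stringsAsFactors = FALSE
  )
}
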