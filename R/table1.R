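#' National pancreatic-cancer mortality fixture (Spain, 1990-2013)
#'
#' Age-specific pancreatic-cancer deaths and the corresponding aggregated
#' person-time by gender for the whole of Spain over 1990-2013, as published
#' with the study this package's model targets.  The table is the national
#' aggregate: a single area and a single collapsed period, thirteen
#' five-year age groups from [25,30) to the open-ended [85,+), for females
#' and males.  Column totals are 48,346 female and 54,652 male deaths
#' (102,998 in all) over 369,126,507 and 343,698,536 person-years.
#'
#' @return A [mortality_dataset()] with dims G=2, A=1, I=13, T=1.
#' @examples
#' tab <- table1_fixture()
#' sum(tab$deaths)  # 102998
#' @export
table1_fixture <- function() {
  age <- c("[25,30)", "[30,35)", "[35,40)", "[40,45)", "[45,50)", "[50,55)",
           "[55,60)", "[60,65)", "[65,70)", "[70,75)", "[75,80)", "[80,85)",
           "[85,+)")
  female_cases <- c(29, 78, 208, 456, 886, 1477, 2339, 3631, 5254, 7052,
                    8999, 8764, 9173)
  female_pop <- c(39112750, 40479316, 39037967, 36471240, 33664579, 30392137,
                  28256099, 26988257, 25364551, 22899701, 19621682, 14420414,
                  12417814)
  male_cases <- c(30, 127, 343, 950, 1819, 3165, 4751, 6563, 8319, 9015,
                  8729, 6328, 4513)
  male_pop <- c(40674966, 42050505, 40159381, 36921758, 33514408, 29678151,
                26894691, 24844905, 22216742, 18417269, 13916416, 8697951,
                5711393)
  deaths <- array(0, dim = c(2, 1, 13, 1))
  population <- array(0, dim = c(2, 1, 13, 1))
  deaths[1, 1, , 1] <- female_cases
  deaths[2, 1, , 1] <- male_cases
  population[1, 1, , 1] <- female_pop
  population[2, 1, , 1] <- male_pop
  mortality_dataset(
    deaths = deaths, population = population,
    labels = list(gender = c("female", "male"), area = "Spain",
                  age_group = age, year = "1990-2013")
  )
}
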