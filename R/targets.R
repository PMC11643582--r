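#' Published calibration targets for the synthetic survey generator
#'
#' Group-level summary statistics of a national Italian two-day dietary
#' survey (two non-consecutive diary days per person, stratified by sex and
#' six age classes), as published in aggregate form: per (sex, age class)
#' the sample size, total amount of food and beverages ingested (g/day),
#' energy intake (kcal/day), total iron intake (mg/day), the wheat- and
#' rice-attributed quantity (g/day), energy (kcal/day) and iron (mg/day)
#' components, and the total cereal-category intake (g/day). Means and,
#' where published, standard deviations.
#'
#' These figures are the default calibration targets of
#' [population_config()]: the generator draws cohorts whose two-day-mean
#' intakes reproduce them in expectation. The micro-data behind them are
#' unpublished, so this table is the study's public statistical contract.
#'
#' @return A data frame with one row per (sex, age class): columns
#'   `sex` ("male"/"female"), `age_class`, `n`, `total_g_mean`,
#'   `total_g_sd`, `energy_mean`, `energy_sd`, `iron_mean`, `iron_sd`,
#'   `wheat_g_mean`, `wheat_g_sd`, `wheat_kcal_mean`, `wheat_iron_mean`,
#'   `rice_g_mean`, `rice_g_sd`, `rice_kcal_mean`, `rice_iron_mean`,
#'   `cereal_g_mean`.
#' @export
#' @examples
#' t <- italian_survey_targets()
#' subset(t, sex == "male" & age_class == "18-64")
italian_survey_targets <- function() {
  ac <- age_class_labels()
  out <- data.frame(
    sex = rep(c("male", "female"), each = 6L),
    age_class = rep(ac, 2L),
    n = c(75L, 162L, 168L, 138L, 346L, 65L,
          75L, 160L, 171L, 138L, 380L, 91L),
    total_g_mean = c(1208, 1500, 2011, 2971, 3150, 3010,
                     1131, 1509, 1828, 2701, 2744, 2668),
    total_g_sd = c(291, 443, 582, 780, 820, 715,
                   341, 396, 488, 805, 745, 553),
    energy_mean = c(892, 1133, 1545, 2218, 2270, 2135,
                    838, 1084, 1411, 1779, 1718, 1630),
    energy_sd = c(243, 273, 410, 573, 563, 619,
                  235, 241, 327, 463, 402, 429),
    iron_mean = c(6.4, 6.3, 7.8, 11.4, 13.1, 14.2,
                  5.0, 6.1, 7.1, 9.8, 10.3, 10.3),
    iron_sd = c(3.3, 2.6, 2.7, 3.7, 4.1, 4.6,
                3.5, 2.7, 2.2, 3.2, 3.5, 3.1),
    wheat_g_mean = c(29.3, 66.7, 102.5, 163.1, 149.8, 156.7,
                     29.5, 63.8, 86.0, 121.1, 107.8, 121.1),
    wheat_g_sd = c(28.9, 33.0, 51.8, 78.1, 80.9, 76.1,
                   29.5, 29.2, 41.8, 58.3, 60.6, 61.0),
    wheat_kcal_mean = c(103.0, 228.6, 354.7, 545.4, 482.3, 484.8,
                        101.9, 214.8, 300.2, 407.9, 349.1, 371.3),
    wheat_iron_mean = c(0.8, 1.0, 1.2, 2.1, 2.0, 2.2,
                        0.8, 1.0, 1.1, 1.5, 1.5, 1.6),
    rice_g_mean = c(4.7, 12.9, 18.3, 30.5, 33.3, 18.2,
                    2.7, 15.9, 22.6, 21.3, 25.7, 15.1),
    rice_g_sd = c(7.2, 25.0, 30.8, 52.8, 43.3, 25.2,
                  5.2, 54.0, 28.7, 26.5, 37.0, 20.8),
    rice_kcal_mean = c(15.8, 33.2, 53.3, 78.3, 91.1, 57.1,
                       9.1, 30.0, 66.0, 61.4, 70.7, 40.3),
    rice_iron_mean = c(0.2, 0.1, 0.2, 0.2, 0.3, 0.2,
                       0.1, 0.1, 0.2, 0.2, 0.2, 0.1),
    cereal_g_mean = c(54.3, 121.5, 194.0, 304.2, 280.4, 248.4,
                      51.3, 113.7, 170.4, 231.0, 202.1, 197.2),
    stringsAsFactors = FALSE
  )
  out
}

#' Canonical age-class labels
#'
#' The six survey age classes, in ascending order: infants (<1 y),
#' toddlers (1-2 y), children (3-9 y), adolescents (10-17 y), adults
#' (18-64 y), elderly (65-74 y).
#'
#' @return Character vector of length 6.
#' @export
age_class_labels <- function() {
  c("<1", "1-2", "3-9", "10-17", "18-64", "65-74")
}

#' Age-class bounds in completed years
#'
#' @return Data frame with `age_class`, `min_age`, `max_age` (completed
#'   years, both inclusive; `<1` is completed age 0).
#' @export
age_class_bounds <- function() {
  data.frame(
    age_class = age_class_labels(),
    min_age = c(0L, 1L, 3L, 10L, 18L, 65L),
    max_age = c(0L, 2L, 9L, 17L, 64L, 74L),
    stringsAsFactors = FALSE
  )
}

#' Assign an age class from age in years
#'
#' Ages are taken as completed years (fractional ages are floored), the
#' convention used for the survey classes, so 17.9 years is still an
#' adolescent and 0.5 years is an infant.
#'
#' @param age_years Numeric vector of ages in years, 0 to 74.
#' @param bounds Age-class bounds as from [age_class_bounds()].
#' @return Character vector of age-class labels.
#' @export
#' @examples
#' assign_age_class(c(0.5, 17.9, 65))
assign_age_class <- function(age_years, bounds = age_class_bounds()) {
  if (any(!is.finite(age_years)))
    stop("age_years must be finite", call. = FALSE)
  if (any(age_years < 0))
    stop("age_years must be non-negative", call. = FALSE)
  completed <- floor(age_years)
  if (any(completed > max(bounds$max_age)))
    stop("age out of range: ages above ", max(bounds$max_age),
         " completed years are outside the survey classes", call. = FALSE)
  idx <- vapply(completed, function(a) {
    which(a >= bounds$min_age & a <= bounds$max_age)[1L]
  }, integer(1L))
  if (any(is.na(idx)))
    stop("age not covered by the class bounds", call. = FALSE)
  bounds$age_class[idx]
}
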