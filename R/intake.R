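#' Summary statistics for one group of values
#'
#' Mean, sample SD (n-1 denominator), median, and 5th/95th percentiles
#' (linear interpolation between order statistics, quantile type 7).
#'
#' @param values Numeric vector, length >= 1. `NA`s are not allowed.
#' @return One-row data frame: `n`, `mean`, `sd`, `median`, `p5`, `p95`.
#' @export
#' @examples
#' group_summary(1:5)
group_summary <- function(values) {
  if (length(values) == 0L)
    stop("empty input: group_summary needs at least one value",
         call. = FALSE)
  if (any(is.na(values)))
    stop("NA values are not allowed in group_summary", call. = FALSE)
  q <- stats::quantile(values, c(0.05, 0.5, 0.95), names = FALSE, type = 7)
  data.frame(
    n = length(values),
    mean = mean(values),
    sd = if (length(values) > 1L) stats::sd(values) else 0,
    median = q[2L],
    p5 = q[1L],
    p95 = q[3L]
  )
}

# join diary entries to the composition table and decompose every entry;
# errors on unknown food codes
diary_components <- function(diaries, composition) {
  idx <- match(diaries$food_code, composition$food_code)
  if (anyNA(idx)) {
    bad <- unique(diaries$food_code[is.na(idx)])
    stop("unknown food code(s): ", paste(utils::head(bad, 5L),
                                         collapse = ", "), call. = FALSE)
  }
  if (any(diaries$grams < 0))
    stop("diary grams must be >= 0", call. = FALSE)
  rec <- composition[idx, , drop = FALSE]
  comp <- decompose_item(rec, diaries$grams)
  comp$individual_id <- diaries$individual_id
  comp$day_index <- diaries$day_index
  comp$grams <- diaries$grams
  comp$kcal <- diaries$grams * rec$energy_density
  comp$iron_mg <- diaries$grams * rec$iron_density
  comp$cereal_g <- diaries$grams * (rec$category == "cereal")
  # wholegrain/brown component masses and iron, for scenario blending
  comp$wheat_whole_g <- comp$wheat_g * rec$wholegrain_share
  comp$wheat_whole_iron <- comp$wheat_whole_g * rec$iron_density_wheat_whole
  comp$wheat_refined_iron <- (comp$wheat_g - comp$wheat_whole_g) *
    rec$iron_density_wheat_refined
  comp$rice_brown_g <- comp$rice_g * rec$brown_share
  comp$rice_brown_iron <- comp$rice_brown_g * rec$iron_density_rice_brown
  comp$rice_white_iron <- (comp$rice_g - comp$rice_brown_g) *
    rec$iron_density_rice_white
  # gram-weighted component densities (fallback effective densities when
  # an individual consumes no wholegrain/brown variant at all)
  comp$w_rho_whole_g <- comp$wheat_g * rec$iron_density_wheat_whole
  comp$w_rho_refined_g <- comp$wheat_g * rec$iron_density_wheat_refined
  comp$r_rho_brown_g <- comp$rice_g * rec$iron_density_rice_brown
  comp$r_rho_white_g <- comp$rice_g * rec$iron_density_rice_white
  comp
}

sum_cols <- function() {
  c("grams", "kcal", "iron_mg", "cereal_g",
    "wheat_g", "rice_g", "wheat_kcal", "rice_kcal",
    "wheat_iron_mg", "rice_iron_mg", "other_iron_mg",
    "wheat_whole_g", "wheat_whole_iron", "wheat_refined_iron",
    "rice_brown_g", "rice_brown_iron", "rice_white_iron",
    "w_rho_whole_g", "w_rho_refined_g", "r_rho_brown_g", "r_rho_white_g")
}

# two-day-mean intake rows for a set of individuals, from decomposed
# diary entries: per-day totals are summed and the two days averaged
# (equivalently, the grand sum over both days divided by 2)
intake_from_components <- function(comp, ids) {
  m <- rowsum(as.matrix(comp[sum_cols()]),
              group = factor(comp$individual_id, levels = ids))
  m <- m[match(ids, rownames(m)), , drop = FALSE]
  m[is.na(m)] <- 0  # individuals with empty diaries
  m <- m / 2
  out <- data.frame(individual_id = ids, stringsAsFactors = FALSE)
  out$total_g_day <- m[, "grams"]
  out$energy_kcal_day <- m[, "kcal"]
  out$iron_mg_day <- m[, "iron_mg"]
  out$wheat_g_day <- m[, "wheat_g"]
  out$rice_g_day <- m[, "rice_g"]
  out$cereal_g_day <- m[, "cereal_g"]
  out$wheat_kcal_day <- m[, "wheat_kcal"]
  out$rice_kcal_day <- m[, "rice_kcal"]
  out$wheat_iron_mg_day <- m[, "wheat_iron_mg"]
  out$rice_iron_mg_day <- m[, "rice_iron_mg"]
  out$other_iron_mg_day <- m[, "other_iron_mg"]
  out$iron_density_per_1000kcal <-
    ifelse(out$energy_kcal_day > 0,
           1000 * out$iron_mg_day / out$energy_kcal_day, NA_real_)
  out$wheat_whole_g_day <- m[, "wheat_whole_g"]
  out$rice_brown_g_day <- m[, "rice_brown_g"]
  # effective per-individual component iron densities (mg/g): actual
  # iron-to-mass ratio of the consumed component where available, else
  # the gram-weighted table density over the foods actually eaten
  out$rho_wheat_whole <- ifelse(
    m[, "wheat_whole_g"] > 0,
    m[, "wheat_whole_iron"] / m[, "wheat_whole_g"],
    ifelse(m[, "wheat_g"] > 0,
           m[, "w_rho_whole_g"] / m[, "wheat_g"], NA_real_))
  refined_g <- m[, "wheat_g"] - m[, "wheat_whole_g"]
  out$rho_wheat_refined <- ifelse(
    refined_g > 0, m[, "wheat_refined_iron"] / refined_g,
    ifelse(m[, "wheat_g"] > 0,
           m[, "w_rho_refined_g"] / m[, "wheat_g"], NA_real_))
  out$rho_rice_brown <- ifelse(
    m[, "rice_brown_g"] > 0,
    m[, "rice_brown_iron"] / m[, "rice_brown_g"],
    ifelse(m[, "rice_g"] > 0,
           m[, "r_rho_brown_g"] / m[, "rice_g"], NA_real_))
  white_g <- m[, "rice_g"] - m[, "rice_brown_g"]
  out$rho_rice_white <- ifelse(
    white_g > 0, m[, "rice_white_iron"] / white_g,
    ifelse(m[, "rice_g"] > 0,
           m[, "r_rho_white_g"] / m[, "rice_g"], NA_real_))
  rownames(out) <- NULL
  out
}

#' Two-day-mean intake for one individual
#'
#' Sums every diary entry of each survey day through the recipe
#' decomposition ([decompose_item()]) and arithmetically averages the two
#' days. The individual must have exactly two survey days; an empty diary
#' day contributes zero.
#'
#' @param diaries Diary records for this individual (columns
#'   `individual_id`, `day_index` in {1, 2}, `food_code`, `grams`).
#' @param composition A validated `composition_table`.
#' @param individual A one-row data frame or list with at least
#'   `individual_id`; if `sex`/`age_years` are present they are carried
#'   through.
#' @return A one-row data frame of per-day intakes: totals, wheat/rice
#'   components (mass, energy, iron), cereal-category mass, iron density
#'   per 1000 kcal (NA when energy is zero), and the individual's
#'   wholegrain/brown component masses and effective component densities
#'   used for scenario projection.
#' @export
individual_intake <- function(diaries, composition, individual) {
  id <- individual$individual_id
  d <- diaries[diaries$individual_id == id, , drop = FALSE]
  days <- unique(d$day_index)
  if (!all(days %in% c(1, 2)))
    stop("day_index must be 1 or 2", call. = FALSE)
  if (!is.null(individual$n_days) && individual$n_days != 2L)
    stop("individual must have exactly two survey days", call. = FALSE)
  comp <- diary_components(d, composition)
  out <- intake_from_components(comp, ids = id)
  if (!is.null(individual$sex)) out$sex <- individual$sex
  if (!is.null(individual$age_years)) {
    out$age_years <- individual$age_years
    out$age_class <- assign_age_class(individual$age_years)
  }
  out
}

#' Two-day-mean intakes for a cohort
#'
#' Vectorised version of [individual_intake()] over all individuals.
#'
#' @param diaries Diary records for the cohort.
#' @param composition A validated `composition_table`.
#' @param individuals Data frame with `individual_id`, `sex`, `age_years`.
#' @return Data frame with one row per individual (see
#'   [individual_intake()]), plus `sex`, `age_years`, `age_class`.
#' @export
compute_intakes <- function(diaries, composition, individuals) {
  stray <- setdiff(unique(diaries$individual_id),
                   individuals$individual_id)
  if (length(stray))
    stop("diary records for unknown individual(s): ",
         paste(utils::head(stray, 5L), collapse = ", "), call. = FALSE)
  comp <- diary_components(diaries, composition)
  out <- intake_from_components(comp, ids = individuals$individual_id)
  out$sex <- individuals$sex
  out$age_years <- individuals$age_years
  out$age_class <- assign_age_class(individuals$age_years)
  out
}
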