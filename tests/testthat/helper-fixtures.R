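# Shared fixtures and independent oracles for the test suite.

# small composition table used across tests; the "bread" row matches the
# hand-computed worked example (100 g -> wheat 70 g, wheat iron 0.7 mg,
# other iron 0.2 mg)
tiny_composition <- function() {
  tab <- data.frame(
    food_code = c("bread", "pasta_whole", "rice_white", "rice_brown",
                  "risotto", "apple", "biscuit"),
    category = c("cereal", "cereal", "cereal", "cereal", "mixed",
                 "fruit", "sweets"),
    energy_density = c(2.7, 3.4, 1.3, 1.3, 1.6, 0.5, 4.5),
    iron_density = c(0.009, 0.02, 0.004, 0.012, 0.0016, 0.001, 0.006),
    wheat_fraction = c(0.7, 1, 0, 0, 0, 0, 0.5),
    rice_fraction = c(0, 0, 1, 1, 0.4, 0, 0),
    wholegrain_share = c(0, 1, 0, 0, 0, 0, 0),
    brown_share = c(0, 0, 0, 1, 0, 0, 0),
    iron_density_wheat_refined = 0.01,
    iron_density_wheat_whole = 0.02,
    iron_density_rice_white = 0.004,
    iron_density_rice_brown = 0.012,
    stringsAsFactors = FALSE
  )
  as_composition_table(tab)
}

# diary for one individual: a named list day -> data.frame(food, grams)
make_diary <- function(id, day1, day2) {
  build <- function(day, entries) {
    if (is.null(entries) || nrow(entries) == 0L)
      return(NULL)
    data.frame(individual_id = id, day_index = day,
               food_code = entries$food_code, grams = entries$grams,
               stringsAsFactors = FALSE)
  }
  rbind(build(1L, day1), build(2L, day2))
}

# brute-force reference for individual_intake: plain scalar loops over
# entries, no shared code with the implementation
oracle_intake <- function(diaries, composition, id) {
  totals <- list(grams = 0, kcal = 0, iron = 0, wheat_g = 0, rice_g = 0,
                 cereal_g = 0, wheat_kcal = 0, rice_kcal = 0,
                 wheat_iron = 0, rice_iron = 0)
  d <- diaries[diaries$individual_id == id, ]
  for (r in seq_len(nrow(d))) {
    rec <- composition[composition$food_code == d$food_code[r], ]
    g <- d$grams[r]
    wg <- g * rec$wheat_fraction
    rg <- g * rec$rice_fraction
    wi <- wg * (rec$wholegrain_share * rec$iron_density_wheat_whole +
                  (1 - rec$wholegrain_share) *
                  rec$iron_density_wheat_refined)
    ri <- rg * (rec$brown_share * rec$iron_density_rice_brown +
                  (1 - rec$brown_share) * rec$iron_density_rice_white)
    totals$grams <- totals$grams + g
    totals$kcal <- totals$kcal + g * rec$energy_density
    totals$iron <- totals$iron + g * rec$iron_density
    totals$wheat_g <- totals$wheat_g + wg
    totals$rice_g <- totals$rice_g + rg
    totals$wheat_kcal <- totals$wheat_kcal + wg * rec$energy_density
    totals$rice_kcal <- totals$rice_kcal + rg * rec$energy_density
    totals$wheat_iron <- totals$wheat_iron + wi
    totals$rice_iron <- totals$rice_iron + ri
    if (rec$category == "cereal")
      totals$cereal_g <- totals$cereal_g + g
  }
  lapply(totals, function(x) x / 2)
}

# first-principles Kruskal-Wallis H with tie correction: mid-ranks by
# counting, not by rank()
oracle_kw_h <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  n <- length(x)
  midrank <- vapply(x, function(v) {
    1 + sum(x < v) + (sum(x == v) - 1) / 2
  }, numeric(1))
  sizes <- vapply(groups, length, integer(1))
  starts <- cumsum(c(0, sizes[-length(sizes)]))
  h <- 0
  for (j in seq_along(groups)) {
    rj <- sum(midrank[(starts[j] + 1):(starts[j] + sizes[j])])
    h <- h + rj^2 / sizes[j]
  }
  h <- 12 / (n * (n + 1)) * h - 3 * (n + 1)
  tie_sizes <- as.integer(table(x))
  corr <- 1 - sum(tie_sizes^3 - tie_sizes) / (n^3 - n)
  h / corr
}

# a one-row intake record with explicit components, for scenario
# closed-form checks
manual_intake_row <- function(wheat_iron = 2.0, rice_iron = 0.2,
                              other_iron = 8.0, wheat_g = 200,
                              rice_g = 50, wholegrain_share = 0,
                              brown_share = 0,
                              rho_wr = 0.01, rho_ww = 0.02,
                              rho_rw = 0.004, rho_rb = 0.012,
                              sex = "male", age_years = 30) {
  data.frame(
    individual_id = "p1",
    total_g_day = 2500, energy_kcal_day = 2000,
    iron_mg_day = wheat_iron + rice_iron + other_iron,
    wheat_g_day = wheat_g, rice_g_day = rice_g,
    cereal_g_day = wheat_g + rice_g,
    wheat_kcal_day = 0, rice_kcal_day = 0,
    wheat_iron_mg_day = wheat_iron, rice_iron_mg_day = rice_iron,
    other_iron_mg_day = other_iron,
    iron_density_per_1000kcal = NA_real_,
    wheat_whole_g_day = wholegrain_share * wheat_g,
    rice_brown_g_day = brown_share * rice_g,
    rho_wheat_whole = rho_ww, rho_wheat_refined = rho_wr,
    rho_rice_brown = rho_rb, rho_rice_white = rho_rw,
    sex = sex, age_years = age_years,
    age_class = assign_age_class(age_years),
    stringsAsFactors = FALSE
  )
}

# single-group generator config for calibration tests
one_group_config <- function(sex, age_class, n = NULL, seed = 1, ...) {
  tg <- italian_survey_targets()
  tg <- tg[tg$sex == sex & tg$age_class == age_class, ]
  population_config(targets = tg, group_sizes = n, seed = seed, ...)
}
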