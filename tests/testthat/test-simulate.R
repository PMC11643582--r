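test_that("generation is byte-identical under a fixed seed", {
  cfg <- one_group_config("male", "18-64", n = 1, seed = 7)
  a <- simulate_survey(cfg)
  b <- simulate_survey(cfg)
  expect_identical(a$individuals, b$individuals)
  expect_identical(a$diaries, b$diaries)
  expect_identical(as.data.frame(a$composition),
                   as.data.frame(b$composition))
  expect_equal(nrow(a$individuals), 1L)
  expect_setequal(unique(a$diaries$day_index), c(1L, 2L))
  # different seed, different diaries
  c2 <- simulate_survey(one_group_config("male", "18-64", n = 1, seed = 8))
  expect_false(identical(a$diaries$grams, c2$diaries$grams))
})

test_that("survey structure honours the design contract", {
  cfg <- population_config(seed = 5, group_sizes = 12)
  sim <- simulate_survey(cfg)
  # exactly the configured count per (sex, age class) cell
  counts <- table(sim$individuals$sex, sim$individuals$age_class)
  expect_true(all(counts == 12))
  # two non-consecutive days at least 15 days apart
  expect_true(all(sim$individuals$day2_date -
                    sim$individuals$day1_date >= 15))
  # every individual has records on both days
  both <- tapply(sim$diaries$day_index, sim$diaries$individual_id,
                 function(d) all(c(1, 2) %in% d))
  expect_true(all(both))
  # ages stay inside their class and within 0-74
  expect_true(all(sim$individuals$age_years <= 74))
  expect_equal(assign_age_class(sim$individuals$age_years),
               sim$individuals$age_class)
  # all diary codes resolve in the composition table
  expect_true(all(sim$diaries$food_code %in%
                    sim$composition$food_code))
})

test_that("the generated composition table meets its contract", {
  cfg <- one_group_config("female", "3-9", n = 5, seed = 1)
  tab <- generate_composition_table(cfg)
  expect_s3_class(tab, "composition_table")  # implies invariants hold
  expect_true(all(tab$energy_density > 0))
  expect_true(all(tab$iron_density > 0))
  # base foods and at least 3 strictly composite wheat foods
  composite <- tab$wheat_fraction > 0 & tab$wheat_fraction < 1
  expect_gte(sum(composite), 3L)
  expect_true(any(tab$wheat_fraction == 1 & tab$wholegrain_share == 0))
  expect_true(any(tab$wheat_fraction == 1 & tab$wholegrain_share == 1))
  expect_true(any(tab$rice_fraction == 1 & tab$brown_share == 0))
  expect_true(any(tab$rice_fraction == 1 & tab$brown_share == 1))
  expect_true(all(tab$iron_density_wheat_whole >
                    tab$iron_density_wheat_refined))
  expect_true(all(tab$iron_density_rice_brown >
                    tab$iron_density_rice_white))
})

test_that("rice_zero_prob = 1 removes rice entirely", {
  cfg <- one_group_config("male", "18-64", n = 20, seed = 2,
                          rice_zero_prob = 1)
  sim <- simulate_survey(cfg)
  it <- compute_intakes(sim$diaries, sim$composition, sim$individuals)
  expect_true(all(it$rice_g_day == 0))
  expect_true(all(it$rice_iron_mg_day == 0))
})

test_that("the fraction of rice non-consumers tracks rice_zero_prob", {
  p0 <- 0.4
  cfg <- one_group_config("female", "18-64", n = 600, seed = 13,
                          rice_zero_prob = p0)
  sim <- simulate_survey(cfg)
  it <- compute_intakes(sim$diaries, sim$composition, sim$individuals)
  frac0 <- mean(it$rice_g_day == 0)
  expect_lt(abs(frac0 - p0), 3 * sqrt(p0 * (1 - p0) / 600))
})

test_that("group mean iron lands within sampling error of the target", {
  cfg <- one_group_config("male", "18-64", seed = 17)  # n = 346
  sim <- simulate_survey(cfg)
  it <- compute_intakes(sim$diaries, sim$composition, sim$individuals)
  expect_equal(nrow(it), 346L)
  expect_lt(abs(mean(it$iron_mg_day) - 13.1), 3 * 4.1 / sqrt(346))
  expect_lt(abs(mean(it$wheat_g_day) - 149.8), 3 * 80.9 / sqrt(346))
  expect_lt(abs(mean(it$wheat_iron_mg_day) - 2.0), 0.25)
})

test_that("invalid configuration names the offending field", {
  expect_error(population_config(seed = 1, rice_zero_prob = 2),
               "rice_zero_prob")
  expect_error(population_config(seed = 1, group_sizes = 0),
               "group_sizes")
  expect_error(population_config(seed = 1, wholegrain_refined_ratio = 0.5),
               "wholegrain_refined_ratio")
  expect_error(population_config(), "seed")
  tg <- italian_survey_targets()
  tg$iron_mean[1] <- -1
  expect_error(population_config(targets = tg, seed = 1), "iron_mean")
})
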