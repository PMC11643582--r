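test_that("two survey days are arithmetically averaged", {
  comp <- tiny_composition()
  # day 1: 500 g pasta_whole -> 10 mg iron; day 2: 300 g -> 6 mg
  d <- make_diary("a", data.frame(food_code = "pasta_whole", grams = 500),
                  data.frame(food_code = "pasta_whole", grams = 300))
  out <- individual_intake(d, comp, list(individual_id = "a"))
  expect_equal(out$iron_mg_day, 8.0)
  expect_equal(out$wheat_g_day, 400)
  expect_equal(out$wheat_iron_mg_day, 8.0)
})

test_that("nutrient density follows from iron and energy", {
  comp <- tiny_composition()
  d <- make_diary("a", data.frame(food_code = "pasta_whole", grams = 100),
                  data.frame(food_code = "pasta_whole", grams = 100))
  out <- individual_intake(d, comp, list(individual_id = "a"))
  expect_equal(out$iron_mg_day, 2.0)
  expect_equal(out$iron_density_per_1000kcal,
               1000 * 2.0 / out$energy_kcal_day)
})

test_that("empty diaries give all-zero intake with missing density", {
  comp <- tiny_composition()
  d <- make_diary("b", data.frame(food_code = "apple", grams = 100), NULL)
  ind <- data.frame(individual_id = c("a", "b"),
                    sex = "male", age_years = 30,
                    stringsAsFactors = FALSE)
  out <- compute_intakes(d, comp, ind)
  empty <- out[out$individual_id == "a", ]
  expect_equal(empty$iron_mg_day, 0)
  expect_equal(empty$total_g_day, 0)
  expect_true(is.na(empty$iron_density_per_1000kcal))
  # the one-day record contributes half to the two-day mean
  expect_equal(out$total_g_day[out$individual_id == "b"], 50)
})

test_that("unknown food codes and bad day indices are rejected", {
  comp <- tiny_composition()
  d <- make_diary("a", data.frame(food_code = "dragonfruit", grams = 10),
                  NULL)
  expect_error(individual_intake(d, comp, list(individual_id = "a")),
               "dragonfruit")
  d2 <- make_diary("a", data.frame(food_code = "apple", grams = 10), NULL)
  d2$day_index <- 3L
  expect_error(individual_intake(d2, comp, list(individual_id = "a")),
               "day_index")
})

test_that("intake engine matches the brute-force oracle on random diaries", {
  comp <- tiny_composition()
  set.seed(42)
  for (case in seq_len(300)) {
    n1 <- sample(0:5, 1)
    n2 <- sample(0:5, 1)
    mk <- function(n) if (n == 0) NULL else
      data.frame(food_code = sample(comp$food_code, n, replace = TRUE),
                 grams = stats::runif(n, 0, 400))
    d <- make_diary("x", mk(n1), mk(n2))
    if (is.null(d)) next
    out <- individual_intake(d, comp, list(individual_id = "x"))
    ref <- oracle_intake(d, comp, "x")
    expect_equal(out$iron_mg_day, ref$iron, tolerance = 1e-12)
    expect_equal(out$wheat_iron_mg_day, ref$wheat_iron, tolerance = 1e-12)
    expect_equal(out$rice_iron_mg_day, ref$rice_iron, tolerance = 1e-12)
    expect_equal(out$wheat_g_day, ref$wheat_g, tolerance = 1e-12)
    expect_equal(out$rice_kcal_day, ref$rice_kcal, tolerance = 1e-12)
    expect_equal(out$cereal_g_day, ref$cereal_g, tolerance = 1e-12)
    expect_equal(out$energy_kcal_day, ref$kcal, tolerance = 1e-12)
  }
})

test_that("diary record order never changes the result", {
  comp <- tiny_composition()
  set.seed(7)
  d <- make_diary("x",
                  data.frame(food_code = sample(comp$food_code, 6, TRUE),
                             grams = stats::runif(6, 1, 300)),
                  data.frame(food_code = sample(comp$food_code, 4, TRUE),
                             grams = stats::runif(4, 1, 300)))
  out1 <- individual_intake(d, comp, list(individual_id = "x"))
  out2 <- individual_intake(d[sample(nrow(d)), ], comp,
                            list(individual_id = "x"))
  expect_equal(out1, out2)
})

test_that("wheat + rice iron components never exceed total iron", {
  sim <- simulate_survey(population_config(seed = 3, group_sizes = 30))
  it <- compute_intakes(sim$diaries, sim$composition, sim$individuals)
  expect_true(all(it$wheat_iron_mg_day + it$rice_iron_mg_day <=
                    it$iron_mg_day + 1e-9))
  expect_equal(it$wheat_iron_mg_day + it$rice_iron_mg_day +
                 it$other_iron_mg_day, it$iron_mg_day, tolerance = 1e-9)
})

test_that("group_summary matches closed forms and a sort-based oracle", {
  s <- group_summary(1:5)
  expect_equal(s$mean, 3)
  expect_equal(s$median, 3)
  expect_equal(s$sd, sqrt(2.5))
  same <- group_summary(rep(4.2, 10))
  expect_equal(same$sd, 0)
  expect_equal(same$p5, same$p95)
  expect_equal(same$p5, same$median)
  expect_error(group_summary(numeric(0)), "empty")

  # type-7 percentile oracle: sorted values, h = (n-1)p + 1, linear
  # interpolation
  set.seed(5)
  x <- stats::rlnorm(1000, 2, 0.5)
  s <- group_summary(x)
  xs <- sort(x)
  q7 <- function(p) {
    h <- (length(xs) - 1) * p + 1
    lo <- floor(h)
    xs[lo] + (h - lo) * (xs[lo + 1L] - xs[lo])
  }
  expect_equal(s$p5, q7(0.05))
  expect_equal(s$median, q7(0.5))
  expect_equal(s$p95, q7(0.95))
})

test_that("age classes use completed years with inclusive lower bounds", {
  expect_equal(assign_age_class(0.5), "<1")
  expect_equal(assign_age_class(17.9), "10-17")
  expect_equal(assign_age_class(65.0), "65-74")
  expect_equal(assign_age_class(c(1, 2.99, 3, 9.5, 10, 64.9, 74.2)),
               c("1-2", "1-2", "3-9", "3-9", "10-17", "18-64", "65-74"))
  expect_error(assign_age_class(75), "out of range")
  expect_error(assign_age_class(-1), "non-negative")
})
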