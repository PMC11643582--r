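test_that("decompose_item reproduces the hand-computed bread example", {
  comp <- tiny_composition()
  bread <- comp[comp$food_code == "bread", ]
  out <- decompose_item(bread, 100)
  expect_equal(out$wheat_g, 70)
  expect_equal(out$wheat_iron_mg, 0.7)
  expect_equal(out$other_iron_mg, 0.2)
  expect_equal(out$rice_g, 0)
  expect_equal(out$other_g, 30)
})

test_that("decompose_item handles degenerate inputs", {
  comp <- tiny_composition()
  bread <- comp[comp$food_code == "bread", ]
  zero <- decompose_item(bread, 0)
  expect_true(all(as.numeric(zero) == 0))
  apple <- comp[comp$food_code == "apple", ]
  out <- decompose_item(apple, 150)
  expect_equal(out$wheat_g + out$rice_g, 0)
  expect_equal(out$other_g, 150)
  expect_equal(out$other_iron_mg, 150 * 0.001)
  expect_error(decompose_item(bread, -1), "grams")
})

test_that("decomposition conserves mass, energy, and iron and is linear", {
  comp <- tiny_composition()
  set.seed(11)
  for (i in seq_len(200)) {
    rec <- comp[sample(nrow(comp), 1L), ]
    g <- stats::runif(1, 0, 500)
    out <- decompose_item(rec, g)
    expect_equal(out$wheat_g + out$rice_g + out$other_g, g,
                 tolerance = 1e-12)
    expect_equal(out$wheat_kcal + out$rice_kcal + out$other_kcal,
                 g * rec$energy_density, tolerance = 1e-12)
    expect_equal(out$wheat_iron_mg + out$rice_iron_mg + out$other_iron_mg,
                 g * rec$iron_density, tolerance = 1e-12)
    a <- stats::runif(1, 0, 200)
    b <- stats::runif(1, 0, 200)
    sum_ab <- decompose_item(rec, a + b)
    parts <- decompose_item(rec, a) + decompose_item(rec, b)
    expect_equal(as.numeric(sum_ab), as.numeric(parts),
                 tolerance = 1e-12)
  }
})

test_that("composition validation rejects malformed tables", {
  comp <- as.data.frame(tiny_composition())
  bad <- comp; bad$wheat_fraction[1] <- 1.2
  expect_error(as_composition_table(bad), "row 1.*wheat_fraction")
  bad <- comp; bad$iron_density_wheat_whole[2] <- 0.005
  expect_error(as_composition_table(bad), "wholegrain iron density")
  bad <- comp; bad$food_code[2] <- "bread"
  expect_error(as_composition_table(bad), "duplicate")
  bad <- comp; bad$iron_density[3] <- -0.1
  expect_error(as_composition_table(bad), "negative")
  bad <- comp[, -match("iron_density", names(comp))]
  expect_error(as_composition_table(bad), "missing column")
  bad <- comp; bad$iron_density[1] <- 0.001  # below implied wheat iron
  expect_error(as_composition_table(bad), "component-implied")
})

test_that("composition CSV round-trip is idempotent", {
  comp <- tiny_composition()
  path <- withr::local_tempfile(fileext = ".csv")
  write_composition_table(comp, path)
  back <- load_composition_table(path)
  expect_equal(as.data.frame(back), as.data.frame(comp))
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_composition_table(back, path2)
  expect_identical(readLines(path), readLines(path2))
})
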