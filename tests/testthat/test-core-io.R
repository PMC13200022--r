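test_that("food table CSV loading validates and preserves records", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_food_table(tiny_foods()[1:3, ], path)
  foods <- read_food_table(path)
  expect_equal(nrow(foods), 3)
  expect_equal(foods$food_id, c("rice", "lentil", "oil"))

  bad <- tiny_foods()[1:2, ]
  bad$moisture_pct[1] <- 100
  expect_error(food_table(bad), "moisture_pct")

  dup <- tiny_foods()[c(1, 1), ]
  expect_error(food_table(dup), "Duplicate food_id")

  extra <- tiny_foods()
  extra$sodium_mg <- 1
  expect_error(food_table(extra), "Accepted keys")

  neg <- tiny_foods()
  neg$iron_mg[2] <- -0.1
  expect_error(food_table(neg), "iron_mg")
})

test_that("absent nutrient columns become explicit flagged zeros on request", {
  partial <- tiny_foods()[, setdiff(names(tiny_foods()), "vitamin_b12_ug")]
  expect_error(food_table(partial), "vitamin_b12_ug")
  filled <- food_table(partial, fill_missing = TRUE)
  expect_equal(filled$vitamin_b12_ug, rep(0, nrow(filled)))
  expect_equal(attr(filled, "filled_nutrients"), "vitamin_b12_ug")
})

test_that("moisture adjustment rescales densities and preserves dry matter", {
  f <- tiny_foods()[6, ] # spinach, 90% moisture
  f$iron_mg <- 2
  f$moisture_pct <- 80

  adj <- moisture_adjust(f, 60)
  expect_equal(adj$iron_mg, 4) # (100-60)/(100-80) = 2
  expect_equal(adj$moisture_pct, 60)
  expect_equal(adj$source, "usda_moisture_adjusted")
  expect_equal(adj$vitamin_b12_ug, 0) # zero densities stay zero

  same <- moisture_adjust(f, f$moisture_pct)
  expect_equal(same[, snp_nutrients()], f[, snp_nutrients()])

  expect_error(moisture_adjust(f, 100), "\\[0, 100\\)")
})

test_that("moisture adjustment is invertible and dry-matter-invariant", {
  foods <- tiny_foods()
  for (target in c(5, 40, 75)) {
    adj <- moisture_adjust(foods, target)
    # nutrient per dry matter unchanged
    for (k in snp_nutrients()) {
      expect_equal(adj[[k]] / (100 - adj$moisture_pct),
                   foods[[k]] / (100 - foods$moisture_pct),
                   tolerance = 1e-12)
    }
    # invert row-wise (original moistures differ by row)
    for (i in seq_len(nrow(foods))) {
      b <- moisture_adjust(adj[i, ], foods$moisture_pct[i])
      expect_equal(unlist(b[, snp_nutrients()]),
                   unlist(foods[i, snp_nutrients()]),
                   tolerance = 1e-9)
    }
  }
})

test_that("vendor price averaging follows the arithmetic mean", {
  expect_equal(mean_price(c(30, 30, 30)), 30)
  expect_equal(mean_price(c(20, 30, 40)), 30)
  expect_equal(mean_price(10), 10)
  expect_error(mean_price(numeric(0)), "at least one", ignore.case = TRUE)
  expect_error(mean_price(c(10, -2)), "> 0")
})

test_that("standards configs carry the documented version defaults", {
  s12 <- std2012()
  expect_equal(s12$energy_target_kcal, 500)
  expect_equal(s12$protein_min_g, 12)
  expect_equal(s12$fat_rule$type, "ratio")
  expect_equal(c(s12$fat_rule$lower, s12$fat_rule$upper), c(25, 35))

  s23 <- std2023()
  expect_equal(s23$energy_target_kcal, 400)
  expect_equal(s23$protein_min_g, 15)
  expect_equal(s23$protein_max_g, 20)
  expect_equal(s23$fat_rule$type, "absolute")
  expect_equal(c(s23$fat_rule$lower, s23$fat_rule$upper), c(15, 20))

  expect_error(snp_standards("snp2012", meal_fraction = 0), "meal_fraction")
  expect_error(snp_standards("snp2012", tolerance = 1), "tolerance")
  expect_error(
    snp_standards("snp2012", ear_per_day = c(selenium_ug = 10)),
    "unknown nutrient"
  )
})

test_that("standards JSON round-trips and rejects unknown fields", {
  path <- withr::local_tempfile(fileext = ".json")
  write_standards(std2012(), path)
  back <- read_standards(path)
  expect_equal(back$energy_target_kcal, 500)
  expect_equal(back$ear_per_day[snp_micronutrients()],
               default_ear_synthetic()[snp_micronutrients()])

  path23 <- withr::local_tempfile(fileext = ".json")
  write_standards(std2023(), path23)
  expect_equal(read_standards(path23)$energy_target_kcal, 400)

  raw <- jsonlite::read_json(path)
  raw$budget <- 9
  jsonlite::write_json(raw, path, auto_unbox = TRUE)
  expect_error(read_standards(path), "/budget")
})

test_that("menu JSON round-trips value-identically", {
  cfg <- synthetic_config(seed = 5, n_states = 2)
  ds <- gen_dataset(cfg)
  path <- withr::local_tempfile(fileext = ".json")
  write_menu_cycles(ds$menu, path)
  back <- read_menu_cycles(path)
  key <- c("state_id", "anganwadi_id", "day_label", "meal", "dish",
           "food_id")
  expect_equal(
    dplyr::arrange(back, dplyr::across(dplyr::all_of(key))),
    dplyr::arrange(ds$menu, dplyr::across(dplyr::all_of(key)))
  )
})

test_that("menu schema violations point at the offending node", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(
    list(cycles = list(list(
      state_id = "KA", anganwadi_id = "A1", cycle_length_days = 1,
      days = list(list(day_label = "d1", meals = list(list(
        meal = "hot_cooked_meal", dish = "x", ingredients = list()
      ))))
    ))),
    path, auto_unbox = TRUE
  )
  expect_error(read_menu_cycles(path), "/cycles/0/days/0/meals/0")

  bad <- tiny_menu()
  bad$cycle_length_days <- 3L
  expect_error(menu_cycle(bad), "cycle_length_days")
})

test_that("prices and fortification files round-trip", {
  cfg <- synthetic_config(seed = 5, n_states = 1)
  foods <- gen_food_table(cfg)
  prices <- gen_prices(cfg, foods)
  p_path <- withr::local_tempfile(fileext = ".csv")
  write_prices(prices, p_path)
  back <- read_prices(p_path)
  expect_equal(back$mean_price, prices$mean_price)
  expect_equal(back$vendor_quotes, prices$vendor_quotes)

  f_path <- withr::local_tempfile(fileext = ".json")
  spec <- gen_fortification()
  write_fortification(spec, f_path)
  back_spec <- read_fortification(f_path)
  key <- c("vehicle_food_id", "nutrient")
  expect_equal(
    dplyr::arrange(back_spec, dplyr::across(dplyr::all_of(key))),
    dplyr::arrange(spec, dplyr::across(dplyr::all_of(key)))
  )
})
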