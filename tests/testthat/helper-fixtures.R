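# small hand-written food table used across tests; densities are per 100 g
tiny_foods <- function() {
  food_table(tibble::tribble(
    ~food_id, ~name, ~group, ~moisture_pct, ~energy_kcal, ~protein_g,
    ~fat_g, ~calcium_mg, ~iron_mg, ~zinc_mg, ~folate_ug, ~vitamin_a_ug,
    ~vitamin_b6_mg, ~vitamin_b12_ug, ~source,
    "rice", "Rice raw", "cereals_millets", 12, 345, 7.5, 0.5, 10, 0.65,
    1.2, 9, 0, 0.12, 0, "synthetic",
    "lentil", "Red lentil", "pulses_legumes", 10, 330, 22, 1.5, 70, 5,
    3, 180, 5, 0.3, 0, "synthetic",
    "oil", "Edible oil", "oils_fats", 0, 900, 0, 100, 0, 0, 0, 0, 0, 0,
    0, "synthetic",
    "egg", "Hen egg", "eggs", 75, 150, 13, 10, 50, 2, 1.2, 50, 160,
    0.15, 1.1, "synthetic",
    "milk", "Cow milk", "milk_products", 86, 70, 3.5, 4, 120, 0.2, 0.4,
    8, 45, 0.05, 0.3, "synthetic",
    "spinach", "Spinach", "green_leafy_veg", 90, 30, 3, 0.5, 150, 3,
    0.5, 120, 300, 0.2, 0, "synthetic",
    "jaggery", "Jaggery", "sugars", 5, 380, 1, 0.1, 60, 3, 0.3, 2, 0,
    0.02, 0, "synthetic"
  ))
}

# one anganwadi-day: 80 g rice + 20 g lentil + 5 g oil
tiny_menu <- function(state_id = "KA", anganwadi_id = "KA_AW01",
                      cycle_length_days = 1L) {
  menu_cycle(tibble::tibble(
    state_id = state_id, anganwadi_id = anganwadi_id,
    cycle_length_days = cycle_length_days, day_label = "day_01",
    meal = "hot_cooked_meal", dish = "khichdi",
    food_id = c("rice", "lentil", "oil"),
    raw_grams_per_child = c(80, 20, 5),
    snp_funded = TRUE
  ))
}

# hand-computed totals of tiny_menu() against tiny_foods()
tiny_day_totals <- function() {
  c(
    energy_kcal = 0.8 * 345 + 0.2 * 330 + 0.05 * 900,
    protein_g = 0.8 * 7.5 + 0.2 * 22,
    fat_g = 0.8 * 0.5 + 0.2 * 1.5 + 0.05 * 100,
    calcium_mg = 0.8 * 10 + 0.2 * 70,
    iron_mg = 0.8 * 0.65 + 0.2 * 5,
    zinc_mg = 0.8 * 1.2 + 0.2 * 3,
    folate_ug = 0.8 * 9 + 0.2 * 180,
    vitamin_a_ug = 0.2 * 5,
    vitamin_b6_mg = 0.8 * 0.12 + 0.2 * 0.3,
    vitamin_b12_ug = 0
  )
}

std2012 <- function(...) {
  snp_standards("snp2012", ear_per_day = default_ear_synthetic(), ...)
}

std2023 <- function(...) {
  snp_standards("snp2023", ear_per_day = default_ear_synthetic(), ...)
}

rice_fort_spec <- function() {
  fortification_spec(tibble::tibble(
    vehicle_food_id = "rice",
    nutrient = c("iron_mg", "folate_ug", "vitamin_b12_ug"),
    amount = c(4.25, 12.5, 0.125),
    basis = "per_100g"
  ))
}

oil_fort_spec <- function(density = 0.92) {
  fortification_spec(tibble::tibble(
    vehicle_food_id = "oil", nutrient = "vitamin_a_ug", amount = 750,
    basis = "per_litre", density_g_per_ml = density
  ))
}

# toy LP problems with hand-picked constraint matrices; rows of D must
# include protein_g (the solver rescales it by the digestibility factor)
toy_lp_problem <- function(D, cost_per_g, lower, upper = setNames(numeric(0), character(0)),
                           caps = NULL, total_cap_g = 1e4, base = NULL,
                           allocation = 8) {
  ids <- colnames(D)
  if (is.null(caps)) caps <- setNames(rep(1e3, length(ids)), ids)
  if (is.null(base)) base <- setNames(rep(0, length(ids)), ids)
  structure(
    list(
      food_ids = ids, densities = D, cost_per_g = cost_per_g,
      lower = lower, upper = upper, caps = caps, total_cap_g = total_cap_g,
      base = base, mode = "full", protein = "crude", digestibility = 1,
      fat_rule = list(type = "absolute", lower = 15, upper = 20),
      allocation = allocation
    ),
    class = "snp_lp_problem"
  )
}
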