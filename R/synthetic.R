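#' Configuration for the synthetic data generator
#'
#' The generator emulates the structure of a multi-state programme survey:
#' a food-composition table spanning all food groups, vendor price quotes,
#' fortified staples, and per-state menu cycles of 6--15 repeating days,
#' with cereal-dominant meals whose cereal energy share falls in the
#' 38--77% band observed in practice. Everything is deterministic under the
#' mandatory seed.
#'
#' @param seed Integer seed (mandatory).
#' @param n_states Number of states to generate.
#' @param anganwadis_per_state Anganwadis surveyed per state (default 4).
#' @param cycle_length_range Menu cycle length range in days.
#' @param cereal_energy_share_range Target band (%) for the cereal-heavy
#'   profile's cereal energy share.
#' @param fortified_states_fraction Fraction of states whose menus use the
#'   fortified rice staple.
#' @return A list of class `snp_synth_config`.
#' @export
synthetic_config <- function(seed, n_states = 3, anganwadis_per_state = 4,
                             cycle_length_range = c(6, 15),
                             cereal_energy_share_range = c(38, 77),
                             fortified_states_fraction = 0.5) {
  if (missing(seed)) abort("A seed is mandatory for the synthetic generator.")
  stopifnot(
    n_states >= 1, anganwadis_per_state >= 1,
    length(cycle_length_range) == 2, diff(cycle_length_range) >= 0,
    cycle_length_range[1] >= 1,
    length(cereal_energy_share_range) == 2,
    diff(cereal_energy_share_range) >= 0,
    fortified_states_fraction >= 0, fortified_states_fraction <= 1
  )
  structure(
    list(
      seed = as.integer(seed), n_states = n_states,
      anganwadis_per_state = anganwadis_per_state,
      cycle_length_range = cycle_length_range,
      cereal_energy_share_range = cereal_energy_share_range,
      fortified_states_fraction = fortified_states_fraction
    ),
    class = "snp_synth_config"
  )
}

#' Plausibility ranges behind the synthetic food table
#'
#' Per-food-group ranges of moisture, nutrient densities (per 100 g raw)
#' and retail price used by [gen_food_table()]. The table is a synthetic
#' fixture with field-plausible magnitudes; it is not a published
#' food-composition database.
#'
#' @return A tibble with one row per food group.
#' @export
food_group_ranges <- function() {
  path <- system.file("extdata", "food_group_ranges_synthetic.csv",
                      package = "snpmeals", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

# canonical food ids per group, in generation order
synthetic_food_ids <- function() {
  list(
    cereals_millets = c("rice", "wheat_flour", "ragi", "millet"),
    pulses_legumes = c("lentil", "moong", "chana"),
    milk_products = c("milk", "curd"),
    eggs = "egg",
    flesh_foods = "chicken",
    green_leafy_veg = c("spinach", "amaranth"),
    other_veg = c("tomato", "beans", "pumpkin"),
    roots_tubers = c("potato", "onion"),
    fruits = c("banana", "guava"),
    oils_fats = "oil",
    sugars = "jaggery",
    nuts_seeds = "groundnut",
    condiments_other = "spice_mix"
  )
}

#' Generate a synthetic food composition table and prices
#'
#' Draws 24 foods spanning all thirteen food groups, with densities and
#' prices uniform within the per-group plausibility ranges of
#' [food_group_ranges()]. Identical seeds give identical tables.
#'
#' @param cfg An [synthetic_config()].
#' @return `gen_food_table()`: a validated food table.
#' @export
gen_food_table <- function(cfg) {
  stopifnot(inherits(cfg, "snp_synth_config"))
  ranges <- food_group_ranges()
  ids <- synthetic_food_ids()
  withr::with_seed(cfg$seed, {
    rows <- imap(ids, function(foods, grp) {
      rg <- ranges[ranges$group == grp, ]
      map(foods, function(fid) {
        rec <- tibble(
          food_id = fid,
          name = gsub("_", " ", fid),
          group = grp,
          moisture_pct = runif(1, rg$moisture_lo, rg$moisture_hi)
        )
        for (k in snp_nutrients()) {
          rec[[k]] <- runif(1, rg[[paste0(k, "_lo")]],
                            rg[[paste0(k, "_hi")]])
        }
        rec$source <- "synthetic"
        rec
      }) |> list_rbind()
    }) |> list_rbind()
    food_table(rows)
  })
}

#' @rdname gen_food_table
#' @param foods A food table from `gen_food_table()`.
#' @return `gen_prices()`: a prices tibble with three vendor quotes per
#'   food.
#' @export
gen_prices <- function(cfg, foods) {
  stopifnot(inherits(cfg, "snp_synth_config"))
  ranges <- food_group_ranges()
  withr::with_seed(cfg$seed + 1L, {
    quotes <- map(seq_len(nrow(foods)), function(i) {
      rg <- ranges[ranges$group == foods$group[i], ]
      base <- runif(1, rg$price_lo, rg$price_hi)
      round(base * runif(3, 0.9, 1.1), 2)
    })
    tibble(
      food_id = foods$food_id,
      vendor_quotes = quotes,
      mean_price = map_dbl(quotes, mean_price)
    )
  })
}

#' Programme fortification specification used by the generator
#'
#' Rice fortified with iron (4.25 mg/100 g), folic acid (12.5 µg/100 g)
#' and vitamin B12 (0.125 µg/100 g), and edible oil fortified with
#' vitamin A (750 µg/litre, density 0.92 g/ml) — the fortification levels
#' of the staples distributed through the programme.
#'
#' @return A fortification spec tibble.
#' @export
gen_fortification <- function() {
  fortification_spec(tibble(
    vehicle_food_id = c("rice", "rice", "rice", "oil"),
    nutrient = c("iron_mg", "folate_ug", "vitamin_b12_ug", "vitamin_a_ug"),
    amount = c(4.25, 12.5, 0.125, 750),
    basis = c("per_100g", "per_100g", "per_100g", "per_litre"),
    density_g_per_ml = c(NA, NA, NA, 0.92)
  ))
}

#' Generate one synthetic state's menu cycles
#'
#' Two profiles are supported. `cereal_heavy` emulates the observed
#' predominantly cereal-based pattern: each anganwadi-day serves a morning
#' snack and a cereal-dominated hot cooked meal whose cereal energy share
#' lies in the configured band, plus an occasional non-programme item
#' (flagged `snp_funded = FALSE`). `adequate` builds a guaranteed-feasible
#' fixture by solving a small full-mode linear programme against the 2012
#' standards and serving the optimal grams identically every day.
#'
#' @param cfg An [synthetic_config()].
#' @param foods,prices Output of [gen_food_table()] and [gen_prices()].
#' @param state_id State identifier.
#' @param profile `"cereal_heavy"` or `"adequate"`.
#' @param seed Per-state seed (defaults to one derived from `cfg$seed`).
#' @param fortified Use the fortified rice staple (the spec from
#'   [gen_fortification()] then applies to this state's cereal).
#' @return A menu tibble for the state.
#' @export
gen_state <- function(cfg, foods, prices, state_id = "ST01",
                      profile = c("cereal_heavy", "adequate"),
                      seed = cfg$seed + 100L, fortified = FALSE) {
  profile <- match.arg(profile)
  stopifnot(inherits(cfg, "snp_synth_config"))
  withr::with_seed(seed, {
    cycle_len <- sample(seq(cfg$cycle_length_range[1],
                            cfg$cycle_length_range[2]), 1)
    staple <- if (fortified) "rice" else "wheat_flour"
    menus <- map(seq_len(cfg$anganwadis_per_state), function(a) {
      aw_id <- sprintf("%s_AW%02d", state_id, a)
      if (profile == "adequate") {
        grams <- adequate_day_grams(foods, prices)
        days <- map(seq_len(cycle_len), function(d) {
          tibble(
            state_id = state_id, anganwadi_id = aw_id,
            cycle_length_days = cycle_len,
            day_label = sprintf("day_%02d", d),
            meal = "hot_cooked_meal", dish = "optimised khichdi",
            food_id = names(grams), raw_grams_per_child = as.numeric(grams),
            snp_funded = TRUE
          )
        })
      } else {
        days <- map(seq_len(cycle_len), function(d) {
          hcm <- tibble(
            meal = "hot_cooked_meal", dish = "khichdi",
            food_id = c(staple, "lentil", "oil", "tomato"),
            raw_grams_per_child = c(runif(1, 55, 90), runif(1, 10, 22),
                                    runif(1, 3, 7), runif(1, 0, 30)),
            snp_funded = TRUE
          )
          ms <- tibble(
            meal = "morning_snack", dish = "snack",
            food_id = c("jaggery", "groundnut"),
            raw_grams_per_child = c(runif(1, 5, 15), runif(1, 2, 8)),
            snp_funded = TRUE
          )
          extra <- if (runif(1) < 0.3) {
            # milk through another safety-net scheme: recorded, not counted
            tibble(meal = "other", dish = "scheme milk", food_id = "milk",
                   raw_grams_per_child = runif(1, 50, 100),
                   snp_funded = FALSE)
          }
          bind_rows(ms, hcm, extra) |>
            mutate(
              state_id = state_id, anganwadi_id = aw_id,
              cycle_length_days = cycle_len,
              day_label = sprintf("day_%02d", d), .before = 1
            )
        })
      }
      list_rbind(days)
    })
    menu_cycle(list_rbind(menus))
  })
}

# grams of a guaranteed-adequate day: minimum-cost full-mode LP against the
# 2012 standards over a nutrient-dense candidate list
adequate_day_grams <- function(foods, prices) {
  candidates <- c("rice", "lentil", "groundnut", "oil", "egg", "milk",
                  "spinach")
  caps <- c(rice = 150, lentil = 60, groundnut = 30, oil = 20, egg = 60,
            milk = 150, spinach = 80)
  cfg <- snp_standards("snp2012", ear_per_day = default_ear_synthetic())
  prob <- lp_problem(
    foods[foods$food_id %in% candidates, ], prices, cfg,
    portion_caps = caps, total_cap_g = 350, mode = "full"
  )
  res <- lp_solve(prob)
  if (res$status != "optimal") {
    abort("The adequate profile is infeasible for this food table.")
  }
  # a 0.5% uplift keeps binding floors strictly met after rounding
  grams <- res$grams[res$grams > 1e-6] * 1.005
  ceiling(grams * 100) / 100
}

#' Generate a full synthetic dataset
#'
#' Foods, prices, fortification and `n_states` menu cycles. States cycle
#' through the cereal-heavy profile with one adequate-profile state
#' appended when `include_adequate = TRUE`; the first
#' `fortified_states_fraction` of states use the fortified rice staple.
#'
#' @param cfg An [synthetic_config()].
#' @param include_adequate Make the last state the guaranteed-adequate
#'   fixture.
#' @return A list with `foods`, `prices`, `fortification`, `menu` and
#'   `profiles`.
#' @export
gen_dataset <- function(cfg, include_adequate = FALSE) {
  stopifnot(inherits(cfg, "snp_synth_config"))
  foods <- gen_food_table(cfg)
  prices <- gen_prices(cfg, foods)
  n <- cfg$n_states
  n_fort <- floor(cfg$fortified_states_fraction * n)
  profiles <- rep("cereal_heavy", n)
  if (include_adequate) profiles[n] <- "adequate"
  state_seeds <- withr::with_seed(cfg$seed + 2L,
                                  sample.int(.Machine$integer.max - 1L, n))
  menus <- map(seq_len(n), function(i) {
    gen_state(cfg, foods, prices, state_id = sprintf("ST%02d", i),
              profile = profiles[i], seed = state_seeds[i],
              fortified = i <= n_fort)
  })
  list(
    foods = foods, prices = prices, fortification = gen_fortification(),
    menu = list_rbind(menus),
    profiles = setNames(profiles, sprintf("ST%02d", seq_len(n)))
  )
}

#' Lognormal provision series for parameter-recovery checks
#'
#' Draws an i.i.d. lognormal daily provision series with known parameters,
#' used to verify that summarising and refitting recovers them.
#'
#' @param mu_true,sigma_true True lognormal parameters (`sigma_true >= 0`).
#' @param n_days Series length.
#' @param seed Integer seed.
#' @return Numeric vector of length `n_days`.
#' @export
gen_lognormal_case <- function(mu_true, sigma_true, n_days, seed) {
  if (sigma_true < 0) abort("sigma_true must be >= 0.")
  withr::with_seed(seed, rlnorm(n_days, meanlog = mu_true,
                                sdlog = sigma_true))
}
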