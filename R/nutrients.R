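#' The fixed nutrient panel
#'
#' The package evaluates a fixed panel of ten nutrients: energy, protein,
#' fat, calcium, iron, zinc, folate and vitamins A, B6 and B12. Column names
#' carry the unit, and all food-composition densities are expressed per
#' 100 g of raw food.
#'
#' @return Character vector of the ten nutrient keys.
#' @export
#' @examples
#' snp_nutrients()
snp_nutrients <- function() {
  c(
    "energy_kcal", "protein_g", "fat_g", "calcium_mg", "iron_mg",
    "zinc_mg", "folate_ug", "vitamin_a_ug", "vitamin_b6_mg",
    "vitamin_b12_ug"
  )
}

#' @rdname snp_nutrients
#' @export
snp_micronutrients <- function() {
  setdiff(snp_nutrients(), c("energy_kcal", "protein_g", "fat_g"))
}

#' Recognised food groups
#'
#' Food-group labels used for menu composition summaries and for the
#' synthetic generator's plausibility ranges.
#'
#' @return Character vector of group keys.
#' @export
snp_food_groups <- function() {
  c(
    "cereals_millets", "pulses_legumes", "milk_products", "eggs",
    "flesh_foods", "green_leafy_veg", "other_veg", "roots_tubers",
    "fruits", "oils_fats", "sugars", "nuts_seeds", "condiments_other"
  )
}

# kcal provided by one gram of fat (Atwater factor)
KCAL_PER_G_FAT <- 9

assert_nutrient_keys <- function(keys, what = "nutrient") {
  bad <- setdiff(keys, snp_nutrients())
  if (length(bad) > 0) {
    abort(sprintf(
      "Unknown %s key(s): %s. Accepted keys: %s.",
      what, paste(bad, collapse = ", "),
      paste(snp_nutrients(), collapse = ", ")
    ))
  }
  invisible(keys)
}
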