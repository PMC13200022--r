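#' Per-child daily nutrient provision
#'
#' Computes, for every anganwadi-day in a menu, the total amount of each
#' nutrient provided per child: `total_k = sum_f grams_f * density_{f,k} / 100`
#' over the day's ingredients. Only programme-funded ingredients
#' (`snp_funded = TRUE`) count unless `include_non_snp = TRUE`; foods
#' supplied through other initiatives are excluded but the day row is kept,
#' so a day with no programme food yields an all-zero provision (such days
#' contribute to state-level variability). Fortified densities are used
#' where a specification matches.
#'
#' @param menu A menu tibble (see [menu_cycle()]).
#' @param foods A food table (see [food_table()]).
#' @param fortification Optional fortification spec applied to `foods`
#'   first.
#' @param include_non_snp Include ingredients not funded by the programme.
#' @param fortification_mode Passed to [apply_fortification()].
#' @return A tibble with `state_id`, `anganwadi_id`, `day_label` and the
#'   ten nutrient columns, one row per anganwadi-day.
#' @export
compute_provisions <- function(menu, foods, fortification = NULL,
                               include_non_snp = FALSE,
                               fortification_mode = c("increment", "total")) {
  menu <- menu_cycle(menu)
  foods <- apply_fortification(foods, fortification,
                               mode = match.arg(fortification_mode))
  missing_ids <- setdiff(unique(menu$food_id), foods$food_id)
  if (length(missing_ids) > 0) {
    abort(sprintf("Menu ingredient(s) not in food table: %s.",
                  paste(missing_ids, collapse = ", ")))
  }
  days <- distinct(menu, .data$state_id, .data$anganwadi_id, .data$day_label)
  kept <- if (include_non_snp) menu else filter(menu, .data$snp_funded)
  dens <- foods[match(kept$food_id, foods$food_id), snp_nutrients()]
  contrib <- as_tibble(dens * kept$raw_grams_per_child / 100)
  out <- bind_cols(
    kept[, c("state_id", "anganwadi_id", "day_label")], contrib
  ) |>
    group_by(.data$state_id, .data$anganwadi_id, .data$day_label) |>
    summarise(across(all_of(snp_nutrients()), sum), .groups = "drop")
  days |>
    left_join(out, by = c("state_id", "anganwadi_id", "day_label")) |>
    mutate(across(all_of(snp_nutrients()), ~ tidyr::replace_na(.x, 0))) |>
    arrange(.data$state_id, .data$anganwadi_id, .data$day_label)
}

#' Percentage of energy provided by fat
#'
#' `100 * fat_g * 9 / energy_kcal`, using the 9 kcal/g Atwater factor.
#' Vectorised; energy must be strictly positive (the ratio is undefined for
#' a zero-energy day).
#'
#' @param energy_kcal Energy provision, kcal.
#' @param fat_g Fat provision, g.
#' @return Percentage of energy from fat.
#' @export
#' @examples
#' fat_energy_ratio(450, 15) # 30
fat_energy_ratio <- function(energy_kcal, fat_g) {
  if (any(!is.finite(energy_kcal) | energy_kcal <= 0)) {
    abort("fat_energy_ratio is undefined for energy <= 0.")
  }
  if (any(!is.finite(fat_g) | fat_g < 0)) abort("fat_g must be >= 0.")
  100 * fat_g * KCAL_PER_G_FAT / energy_kcal
}

#' Food-group contributions to energy and protein
#'
#' Pools a menu's programme-funded ingredients over the full cycle and
#' reports the percentage of total energy and of total protein contributed
#' by each food group. All groups are reported (zeros where absent) and
#' each share column sums to 100.
#'
#' @inheritParams compute_provisions
#' @return A tibble with `group`, `energy_share_pct`, `protein_share_pct`.
#' @export
food_group_shares <- function(menu, foods, fortification = NULL,
                              include_non_snp = FALSE) {
  menu <- menu_cycle(menu)
  foods <- apply_fortification(foods, fortification)
  missing_ids <- setdiff(unique(menu$food_id), foods$food_id)
  if (length(missing_ids) > 0) {
    abort(sprintf("Menu ingredient(s) not in food table: %s.",
                  paste(missing_ids, collapse = ", ")))
  }
  kept <- if (include_non_snp) menu else filter(menu, .data$snp_funded)
  idx <- match(kept$food_id, foods$food_id)
  kept$group <- foods$group[idx]
  kept$energy <- kept$raw_grams_per_child * foods$energy_kcal[idx] / 100
  kept$protein <- kept$raw_grams_per_child * foods$protein_g[idx] / 100
  tot_e <- sum(kept$energy)
  tot_p <- sum(kept$protein)
  if (tot_e <= 0) abort("Total energy of the menu is zero; shares undefined.")
  by_group <- kept |>
    group_by(.data$group) |>
    summarise(energy = sum(.data$energy), protein = sum(.data$protein),
              .groups = "drop")
  tibble(group = snp_food_groups()) |>
    left_join(by_group, by = "group") |>
    mutate(
      energy_share_pct = 100 * tidyr::replace_na(.data$energy, 0) / tot_e,
      protein_share_pct = if (tot_p > 0) {
        100 * tidyr::replace_na(.data$protein, 0) / tot_p
      } else {
        0
      }
    ) |>
    select("group", "energy_share_pct", "protein_share_pct")
}
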