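#' Digestibility-adjusted protein
#'
#' Crude protein multiplied by a digestibility factor (default 0.8, the
#' correction recommended for predominantly cereal-based diets) to
#' approximate utilisable protein.
#'
#' @param crude_g Crude protein, g (>= 0).
#' @param d Digestibility factor in (0, 1].
#' @return Digestible protein, g.
#' @export
#' @examples
#' digestible_protein(15) # 12
digestible_protein <- function(crude_g, d = 0.8) {
  if (any(!is.finite(d) | d <= 0 | d > 1)) {
    abort("Digestibility factor d must be in (0, 1].")
  }
  if (any(!is.finite(crude_g) | crude_g < 0)) {
    abort("crude_g must be finite and >= 0.")
  }
  crude_g * d
}

#' Traffic-light classification of percent-of-requirement
#'
#' Maps a percentage of requirement to the reporting colours: green for
#' >= 90%, yellow for 80 to <90%, red below 80%. For nutrients with an
#' excess rule (energy, fat) provision more than 10% above the
#' recommendation (> 110%) is also red. Band edges are half-open: exactly
#' 90 is green and exactly 80 is yellow.
#'
#' @param pct Percent of requirement, >= 0. Vectorised.
#' @param has_upper_rule Apply the > 110% excess rule.
#' @return Character vector: `"green"`, `"yellow"` or `"red"`.
#' @export
#' @examples
#' classify_status(c(79.99, 80, 89.99, 90, 115), has_upper_rule = TRUE)
classify_status <- function(pct, has_upper_rule = FALSE) {
  if (any(!is.finite(pct) | pct < 0)) abort("pct must be finite and >= 0.")
  out <- ifelse(pct >= 90, "green", ifelse(pct >= 80, "yellow", "red"))
  if (has_upper_rule) out[pct > 110] <- "red"
  out
}

adequacy_row <- function(nutrient, provision, requirement, met, status,
                         rule_applied) {
  tibble(
    nutrient = nutrient, provision = provision, requirement = requirement,
    pct_of_requirement = 100 * provision / requirement, met = met,
    status = status, rule_applied = rule_applied
  )
}

#' Score energy provision
#'
#' Energy is met if provision reaches at least 90% of the programme target
#' (500 kcal under the 2012 standard, 400 kcal under 2023). The
#' traffic-light status additionally flags provision exceeding the target
#' by more than 10% as red (excess energy).
#'
#' @param provision_kcal Energy provision, kcal (>= 0).
#' @param cfg An [snp_standards()] object.
#' @return One-row adequacy tibble.
#' @export
evaluate_energy <- function(provision_kcal, cfg) {
  stopifnot(inherits(cfg, "snp_standards"))
  if (provision_kcal < 0) abort("provision must be >= 0.")
  target <- cfg$energy_target_kcal
  pct <- 100 * provision_kcal / target
  adequacy_row(
    "energy_kcal", provision_kcal, target,
    met = pct >= 100 * (1 - cfg$tolerance),
    status = classify_status(pct, has_upper_rule = TRUE),
    rule_applied = "energy_90pct"
  )
}

#' Score protein provision
#'
#' Protein is evaluated against the lower bound of the programme standard
#' (12 g/day under 2012, 15 g under 2023), optionally after the
#' digestibility correction. The flexibility margin (`cfg$tolerance`)
#' applies to the met/not-met determination; the colour uses the raw
#' percentage bands.
#'
#' @param crude_g Crude protein provision, g.
#' @param cfg An [snp_standards()] object.
#' @param apply_digestibility Correct by `cfg$digestibility` before
#'   scoring.
#' @return One-row adequacy tibble.
#' @export
evaluate_protein <- function(crude_g, cfg, apply_digestibility = FALSE) {
  stopifnot(inherits(cfg, "snp_standards"))
  value <- if (apply_digestibility) {
    digestible_protein(crude_g, cfg$digestibility)
  } else {
    digestible_protein(crude_g, 1)
  }
  floor_g <- cfg$protein_min_g
  pct <- 100 * value / floor_g
  adequacy_row(
    "protein_g", value, floor_g,
    met = value >= floor_g * (1 - cfg$tolerance),
    status = classify_status(pct),
    rule_applied = if (apply_digestibility) "protein_digestible"
                   else "protein_floor"
  )
}

#' Score fat provision
#'
#' Under the ratio rule (2012 evaluation) fat must supply 25--35% of
#' energy; under the absolute rule (2023) the band is 15--20 g. The
#' flexibility margin widens the band (both edges by default: 22.5--38.5%
#' of energy), and provision above the widened upper edge is red (excess).
#' The reported percentage is relative to the lower edge of the band.
#'
#' @param fat_g Fat provision, g.
#' @param energy_kcal Energy provision, kcal (needed for the ratio rule).
#' @param cfg An [snp_standards()] object.
#' @return One-row adequacy tibble.
#' @export
evaluate_fat <- function(fat_g, energy_kcal, cfg) {
  stopifnot(inherits(cfg, "snp_standards"))
  rule <- cfg$fat_rule
  value <- if (rule$type == "ratio") {
    fat_energy_ratio(energy_kcal, fat_g)
  } else {
    fat_g
  }
  lo <- rule$lower * (1 - cfg$tolerance)
  hi <- if (cfg$fat_allowance == "both_edges") {
    rule$upper * (1 + cfg$tolerance)
  } else {
    rule$upper
  }
  met <- value >= lo && value <= hi
  pct <- 100 * value / rule$lower
  adequacy_row(
    "fat_g", value, rule$lower,
    met = met,
    status = if (met) "green" else classify_status(pct, has_upper_rule = TRUE),
    rule_applied = if (rule$type == "ratio") "fat_ratio_band"
                   else "fat_absolute_band"
  )
}

#' Score a micronutrient against one-third of the EAR
#'
#' The requirement is `meal_fraction` (default one-third) of the
#' age-specific Estimated Average Requirement; provision within the
#' flexibility margin (default 10%) of that requirement is considered met.
#'
#' @param provision Nutrient provision, in the nutrient's unit.
#' @param nutrient One of [snp_micronutrients()].
#' @param cfg An [snp_standards()] object with an EAR entry for `nutrient`.
#' @return One-row adequacy tibble.
#' @export
evaluate_micronutrient <- function(provision, nutrient, cfg) {
  stopifnot(inherits(cfg, "snp_standards"))
  if (!nutrient %in% snp_micronutrients()) {
    abort(sprintf("%s is not a micronutrient key.", nutrient))
  }
  ear <- unname(cfg$ear_per_day[nutrient])
  if (length(ear) != 1 || is.na(ear)) {
    abort(sprintf("No EAR configured for %s; supply ear_per_day in the standards config.",
                  nutrient))
  }
  req <- ear * cfg$meal_fraction
  pct <- 100 * provision / req
  adequacy_row(
    nutrient, provision, req,
    met = provision >= req * (1 - cfg$tolerance),
    status = classify_status(pct),
    rule_applied = "micronutrient_third_ear"
  )
}

#' Score a full provision vector
#'
#' Applies every rule to one provision vector over the ten-nutrient panel:
#' energy, crude protein, digestibility-adjusted protein, fat and the seven
#' micronutrients — eleven rows in all.
#'
#' @param provision Named numeric vector (or one-row data frame) over
#'   [snp_nutrients()].
#' @param cfg An [snp_standards()] object with a full EAR table.
#' @return An adequacy tibble with eleven rows.
#' @export
evaluate_provision <- function(provision, cfg) {
  if (is.data.frame(provision)) {
    stopifnot(nrow(provision) == 1)
    provision <- unlist(provision[, intersect(names(provision),
                                              snp_nutrients())])
  }
  missing_keys <- setdiff(snp_nutrients(), names(provision))
  if (length(missing_keys) > 0) {
    abort(sprintf("Provision vector is missing: %s.",
                  paste(missing_keys, collapse = ", ")))
  }
  micro <- map(snp_micronutrients(), function(k) {
    evaluate_micronutrient(provision[[k]], k, cfg)
  }) |>
    list_rbind()
  fat <- if (cfg$fat_rule$type == "ratio" && provision[["energy_kcal"]] <= 0) {
    # ratio undefined on a zero-energy provision: nothing was provided
    adequacy_row("fat_g", 0, cfg$fat_rule$lower, met = FALSE,
                 status = "red", rule_applied = "fat_ratio_band")
  } else {
    evaluate_fat(provision[["fat_g"]], provision[["energy_kcal"]], cfg)
  }
  bind_rows(
    evaluate_energy(provision[["energy_kcal"]], cfg),
    evaluate_protein(provision[["protein_g"]], cfg,
                     apply_digestibility = FALSE),
    evaluate_protein(provision[["protein_g"]], cfg,
                     apply_digestibility = TRUE),
    fat,
    micro
  )
}

#' Score every state in a simulated summary
#'
#' Evaluates each state's simulated median provision against a standards
#' configuration, producing one adequacy table row per state and rule
#' (eleven rows per state: energy, crude and digestible protein, fat, seven
#' micronutrients). Running the same summary under the 2012 and 2023
#' configurations yields two parallel tables.
#'
#' @param state_summary An `snp_state_summary` from [simulate_states()], or
#'   any tibble with `state_id`, `nutrient` and the column named in
#'   `value`.
#' @param cfg An [snp_standards()] object with a full EAR table.
#' @param value Column holding the provision central value (default
#'   `"sim_median"`).
#' @return A tibble of class `snp_adequacy` with `state_id`,
#'   `standard_version` and the adequacy columns.
#' @export
evaluate_state <- function(state_summary, cfg, value = "sim_median") {
  stopifnot(inherits(cfg, "snp_standards"))
  wide <- state_summary |>
    as_tibble() |>
    select("state_id", "nutrient", value = all_of(value)) |>
    pivot_wider(names_from = "nutrient", values_from = "value")
  out <- map(seq_len(nrow(wide)), function(i) {
    evaluate_provision(wide[i, ], cfg) |>
      mutate(state_id = wide$state_id[i], .before = 1)
  }) |>
    list_rbind() |>
    mutate(standard_version = cfg$standard_version, .after = "state_id")
  class(out) <- c("snp_adequacy", class(out))
  out
}

#' @exportS3Method generics::glance
glance.snp_adequacy <- function(x, ...) {
  x |>
    as_tibble() |>
    group_by(.data$standard_version) |>
    summarise(
      n_states = dplyr::n_distinct(.data$state_id),
      n_rules = dplyr::n(),
      pct_met = 100 * mean(.data$met),
      pct_green = 100 * mean(.data$status == "green"),
      .groups = "drop"
    )
}
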