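#' Food composition tables
#'
#' A food table is a tibble with one row per raw food: `food_id`, `name`,
#' `group` (one of [snp_food_groups()]), `moisture_pct` (% by mass, in
#' \[0, 100)), the ten nutrient density columns of [snp_nutrients()]
#' (amount per 100 g raw food) and `source` (`ifct`,
#' `usda_moisture_adjusted` or `synthetic`).
#'
#' `food_table()` validates a data frame against those invariants and
#' returns it as a tibble; `read_food_table()`/`write_food_table()` move it
#' through the documented CSV dialect (UTF-8, comma-separated, header row,
#' decimal point). Nutrient columns absent from the input are an error
#' unless `fill_missing = TRUE`, in which case they are added as explicit
#' zeros and flagged in the `filled_nutrients` attribute.
#'
#' @param foods A data frame of foods.
#' @param fill_missing Add absent nutrient columns as zeros instead of
#'   erroring.
#' @return A validated tibble of class `tbl_df`.
#' @export
#' @examples
#' foods <- food_table(tibble::tibble(
#'   food_id = "rice", name = "Rice, raw", group = "cereals_millets",
#'   moisture_pct = 12, energy_kcal = 345, protein_g = 7.5, fat_g = 0.5,
#'   calcium_mg = 10, iron_mg = 0.65, zinc_mg = 1.2, folate_ug = 9,
#'   vitamin_a_ug = 0, vitamin_b6_mg = 0.12, vitamin_b12_ug = 0,
#'   source = "synthetic"
#' ))
food_table <- function(foods, fill_missing = FALSE) {
  foods <- as_tibble(foods)
  meta <- c("food_id", "name", "group", "moisture_pct", "source")
  missing_meta <- setdiff(meta, names(foods))
  if (length(missing_meta) > 0) {
    abort(sprintf("Food table is missing column(s): %s.",
                  paste(missing_meta, collapse = ", ")))
  }
  extra <- setdiff(names(foods), c(meta, snp_nutrients()))
  if (length(extra) > 0) {
    abort(sprintf(
      "Unknown nutrient column(s): %s. Accepted keys: %s.",
      paste(extra, collapse = ", "), paste(snp_nutrients(), collapse = ", ")
    ))
  }
  absent <- setdiff(snp_nutrients(), names(foods))
  filled <- character(0)
  if (length(absent) > 0) {
    if (!fill_missing) {
      abort(sprintf(
        "Nutrient column(s) absent: %s. Set fill_missing = TRUE to add them as explicit zeros.",
        paste(absent, collapse = ", ")
      ))
    }
    for (k in absent) foods[[k]] <- 0
    filled <- absent
  }

  dup <- foods$food_id[duplicated(foods$food_id)]
  if (length(dup) > 0) {
    abort(sprintf("Duplicate food_id(s): %s.",
                  paste(unique(dup), collapse = ", ")))
  }
  bad_group <- setdiff(unique(foods$group), snp_food_groups())
  if (length(bad_group) > 0) {
    abort(sprintf("Unknown food group(s): %s. Accepted: %s.",
                  paste(bad_group, collapse = ", "),
                  paste(snp_food_groups(), collapse = ", ")))
  }
  bad_source <- setdiff(unique(foods$source),
                        c("ifct", "usda_moisture_adjusted", "synthetic"))
  if (length(bad_source) > 0) {
    abort(sprintf("Unknown source flag(s): %s.",
                  paste(bad_source, collapse = ", ")))
  }
  for (i in seq_len(nrow(foods))) {
    m <- foods$moisture_pct[[i]]
    if (!is.finite(m) || m < 0 || m >= 100) {
      abort(sprintf("Row %d (food_id %s), column moisture_pct: must be in [0, 100), got %s.",
                    i, foods$food_id[[i]], format(m)))
    }
    for (k in snp_nutrients()) {
      v <- foods[[k]][[i]]
      if (!is.finite(v) || v < 0) {
        abort(sprintf("Row %d (food_id %s), column %s: density must be finite and >= 0, got %s.",
                      i, foods$food_id[[i]], k, format(v)))
      }
    }
  }
  out <- foods[, c(meta[1:4], snp_nutrients(), "source")]
  attr(out, "filled_nutrients") <- filled
  out
}

#' @rdname food_table
#' @param path Path to a foods CSV file.
#' @export
read_food_table <- function(path, fill_missing = FALSE) {
  if (!file.exists(path)) abort(sprintf("Food table not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  food_table(df, fill_missing = fill_missing)
}

#' @rdname food_table
#' @export
write_food_table <- function(foods, path) {
  foods <- food_table(foods)
  readr::write_csv(foods, path, progress = FALSE)
  invisible(path)
}

#' Adjust nutrient densities to a common moisture content
#'
#' Rescales every nutrient density so the food is expressed at a different
#' moisture percentage, preserving nutrient per unit dry matter: each
#' density is multiplied by `(100 - target) / (100 - moisture_pct)`. Used to
#' make entries from different composition databases comparable. The
#' adjusted rows are flagged `source = "usda_moisture_adjusted"`.
#'
#' @param foods A food table (see [food_table()]).
#' @param target_moisture_pct Target moisture, % by mass in \[0, 100).
#'   Recycled across rows.
#' @return The adjusted food table.
#' @export
#' @examples
#' f <- food_table(tibble::tibble(
#'   food_id = "x", name = "x", group = "other_veg", moisture_pct = 80,
#'   energy_kcal = 0, protein_g = 0, fat_g = 0, calcium_mg = 0,
#'   iron_mg = 2, zinc_mg = 0, folate_ug = 0, vitamin_a_ug = 0,
#'   vitamin_b6_mg = 0, vitamin_b12_ug = 0, source = "synthetic"
#' ))
#' moisture_adjust(f, 60)$iron_mg # 4
moisture_adjust <- function(foods, target_moisture_pct) {
  foods <- food_table(foods)
  if (any(!is.finite(target_moisture_pct) | target_moisture_pct < 0 |
            target_moisture_pct >= 100)) {
    abort("target_moisture_pct must be finite and in [0, 100).")
  }
  scale <- (100 - target_moisture_pct) / (100 - foods$moisture_pct)
  for (k in snp_nutrients()) foods[[k]] <- foods[[k]] * scale
  foods$moisture_pct <- rep_len(target_moisture_pct, nrow(foods))
  foods$source <- "usda_moisture_adjusted"
  foods
}
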