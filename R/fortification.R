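#' Fortification specifications
#'
#' Staples distributed through the programme may be fortified — e.g. rice
#' or wheat flour carrying added iron, folic acid and vitamin B12, or
#' edible oil carrying vitamin A. A specification is a tibble with one row
#' per (vehicle food, nutrient): `vehicle_food_id`, `nutrient`, `amount`,
#' `basis` (`per_100g` or `per_litre`) and `density_g_per_ml` (required for
#' `per_litre`, e.g. 0.92 for edible oil).
#'
#' Per-litre amounts convert to a per-100 g basis as
#' `amount / 1000 ml * 100 / density_g_per_ml`.
#'
#' @param spec A data frame of fortificant rows.
#' @return A validated tibble.
#' @export
fortification_spec <- function(spec) {
  spec <- as_tibble(spec)
  cols <- c("vehicle_food_id", "nutrient", "amount", "basis")
  missing_cols <- setdiff(cols, names(spec))
  if (length(missing_cols) > 0) {
    abort(sprintf("Fortification spec is missing column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  if (!"density_g_per_ml" %in% names(spec)) spec$density_g_per_ml <- NA_real_
  assert_nutrient_keys(unique(spec$nutrient), "fortificant nutrient")
  if (any(!is.finite(spec$amount) | spec$amount < 0)) {
    abort("Fortificant amounts must be finite and >= 0.")
  }
  bad_basis <- setdiff(unique(spec$basis), c("per_100g", "per_litre"))
  if (length(bad_basis) > 0) {
    abort(sprintf("Unknown basis: %s (use per_100g or per_litre).",
                  paste(bad_basis, collapse = ", ")))
  }
  need_density <- spec$basis == "per_litre"
  if (any(need_density & (!is.finite(spec$density_g_per_ml) |
                            spec$density_g_per_ml <= 0))) {
    abort("density_g_per_ml is required (and must be > 0) when basis = per_litre.")
  }
  spec[, c(cols, "density_g_per_ml")]
}

#' @rdname fortification_spec
#' @param path Path to a fortification JSON document: a list of objects
#'   `{vehicle_food_id, basis, density_g_per_ml, additions: {nutrient: amount}}`.
#' @export
read_fortification <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Fortification file not found: %s", path))
  }
  doc <- jsonlite::read_json(path)
  rows <- imap(doc, function(sp, i) {
    if (is.null(sp$vehicle_food_id) || is.null(sp$additions)) {
      abort(sprintf(
        "Fortification schema violation at /%d: need vehicle_food_id and additions.",
        i - 1L
      ))
    }
    tibble(
      vehicle_food_id = sp$vehicle_food_id,
      nutrient = names(sp$additions),
      amount = as.numeric(unlist(sp$additions)),
      basis = sp$basis %||% "per_100g",
      density_g_per_ml = sp$density_g_per_ml %||% NA_real_
    )
  }) |>
    list_rbind()
  fortification_spec(rows)
}

#' @rdname fortification_spec
#' @export
write_fortification <- function(spec, path) {
  spec <- fortification_spec(spec)
  out <- spec |>
    split(~vehicle_food_id + basis, drop = TRUE) |>
    map(function(sp) {
      x <- list(
        vehicle_food_id = sp$vehicle_food_id[1],
        basis = sp$basis[1],
        additions = as.list(setNames(sp$amount, sp$nutrient))
      )
      if (is.finite(sp$density_g_per_ml[1])) {
        x$density_g_per_ml <- sp$density_g_per_ml[1]
      }
      x
    })
  jsonlite::write_json(unname(out), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# additions expressed per 100 g of vehicle, whatever the declared basis
fortificant_per_100g <- function(spec) {
  spec <- fortification_spec(spec)
  per_litre <- spec$basis == "per_litre"
  spec$amount_per_100g <- ifelse(
    per_litre,
    spec$amount / 1000 * 100 / spec$density_g_per_ml,
    spec$amount
  )
  spec
}

#' Apply fortification to a food table
#'
#' Overlays fortificant levels onto the matching vehicle foods. In
#' `"increment"` mode (the default, matching the "added amount" convention
#' of Indian fortification standards) each listed nutrient density is
#' increased by the specified amount per 100 g. In `"total"` mode the
#' specification is read as the total fortified content and the density is
#' raised to at least that level (`pmax`), so fortification never decreases
#' a density in either mode. Foods without a matching specification pass
#' through unchanged.
#'
#' @param foods A food table (see [food_table()]).
#' @param spec A fortification spec (see [fortification_spec()]); `NULL`
#'   returns `foods` unchanged.
#' @param mode `"increment"` or `"total"`.
#' @param strict Require every `vehicle_food_id` to be present in `foods`.
#' @return The fortified food table.
#' @export
#' @examples
#' # rice fortificant: +4.25 mg iron, +12.5 ug folate, +0.125 ug B12 / 100 g
#' spec <- fortification_spec(tibble::tibble(
#'   vehicle_food_id = "rice",
#'   nutrient = c("iron_mg", "folate_ug", "vitamin_b12_ug"),
#'   amount = c(4.25, 12.5, 0.125), basis = "per_100g"
#' ))
apply_fortification <- function(foods, spec, mode = c("increment", "total"),
                                strict = TRUE) {
  mode <- match.arg(mode)
  foods <- food_table(foods)
  if (is.null(spec) || nrow(spec) == 0) return(foods)
  spec <- fortificant_per_100g(spec)
  missing_vehicle <- setdiff(unique(spec$vehicle_food_id), foods$food_id)
  if (strict && length(missing_vehicle) > 0) {
    abort(sprintf("Fortification vehicle(s) not in food table: %s.",
                  paste(missing_vehicle, collapse = ", ")))
  }
  for (i in seq_len(nrow(spec))) {
    j <- match(spec$vehicle_food_id[i], foods$food_id)
    if (is.na(j)) next
    k <- spec$nutrient[i]
    foods[[k]][j] <- if (mode == "increment") {
      foods[[k]][j] + spec$amount_per_100g[i]
    } else {
      max(foods[[k]][j], spec$amount_per_100g[i])
    }
  }
  foods
}
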