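#' Menu cycles
#'
#' A menu is a long tibble with one row per ingredient serving: `state_id`,
#' `anganwadi_id`, `cycle_length_days`, `day_label`, `meal`
#' (`morning_snack`, `hot_cooked_meal` or `other`), `dish`, `food_id`,
#' `raw_grams_per_child` (grams of raw ingredient per child per day, >= 0)
#' and `snp_funded` (logical; foods supplied through other government
#' initiatives carry `FALSE` and are excluded from programme provision
#' totals by default).
#'
#' Menus repeat on a fixed cycle (typically 6--15 days);
#' `cycle_length_days` must equal the number of distinct `day_label`s of the
#' anganwadi.
#'
#' @param menu A data frame of ingredient rows.
#' @return A validated tibble.
#' @export
menu_cycle <- function(menu) {
  menu <- as_tibble(menu)
  cols <- c("state_id", "anganwadi_id", "cycle_length_days", "day_label",
            "meal", "dish", "food_id", "raw_grams_per_child", "snp_funded")
  missing_cols <- setdiff(cols, names(menu))
  if (length(missing_cols) > 0) {
    abort(sprintf("Menu is missing column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  bad_meal <- setdiff(unique(menu$meal),
                      c("morning_snack", "hot_cooked_meal", "other"))
  if (length(bad_meal) > 0) {
    abort(sprintf("Unknown meal label(s): %s.",
                  paste(bad_meal, collapse = ", ")))
  }
  g <- menu$raw_grams_per_child
  if (any(!is.finite(g) | g < 0)) {
    i <- which(!is.finite(g) | g < 0)[1]
    abort(sprintf("Row %d: raw_grams_per_child must be finite and >= 0.", i))
  }
  if (!is.logical(menu$snp_funded) || anyNA(menu$snp_funded)) {
    abort("snp_funded must be logical with no missing values.")
  }
  chk <- menu |>
    group_by(.data$state_id, .data$anganwadi_id) |>
    summarise(
      n_days = dplyr::n_distinct(.data$day_label),
      declared = .data$cycle_length_days[1],
      consistent = dplyr::n_distinct(.data$cycle_length_days) == 1,
      .groups = "drop"
    )
  bad <- chk[!chk$consistent | chk$n_days != chk$declared, ]
  if (nrow(bad) > 0) {
    abort(sprintf(
      "cycle_length_days must be constant per anganwadi and equal the number of distinct day_labels (first offender: %s/%s).",
      bad$state_id[1], bad$anganwadi_id[1]
    ))
  }
  menu[, cols]
}

#' Read and write menu cycles as JSON
#'
#' The JSON dialect nests states, anganwadis, days, meals and ingredients;
#' `read_menu_cycles()` flattens it into the long tibble documented in
#' [menu_cycle()], and `write_menu_cycles()` performs the inverse. A
#' read-write-read round trip is value-identical.
#'
#' @param path Path to a menu JSON document.
#' @return `read_menu_cycles()` returns a menu tibble.
#' @export
read_menu_cycles <- function(path) {
  if (!file.exists(path)) abort(sprintf("Menu file not found: %s", path))
  doc <- jsonlite::read_json(path)
  cycles <- doc$cycles
  if (is.null(cycles)) abort("Menu schema violation at /cycles: missing.")
  rows <- imap(cycles, function(cy, ci) {
    for (f in c("state_id", "anganwadi_id", "cycle_length_days", "days")) {
      if (is.null(cy[[f]])) {
        abort(sprintf("Menu schema violation at /cycles/%d/%s: missing.",
                      ci - 1L, f))
      }
    }
    imap(cy$days, function(day, di) {
      if (is.null(day$day_label) || is.null(day$meals)) {
        abort(sprintf(
          "Menu schema violation at /cycles/%d/days/%d: need day_label and meals.",
          ci - 1L, di - 1L
        ))
      }
      imap(day$meals, function(ml, mi) {
        ing <- ml$ingredients
        if (is.null(ing) || length(ing) == 0) {
          abort(sprintf(
            "Menu schema violation at /cycles/%d/days/%d/meals/%d/ingredients: every dish needs at least one ingredient.",
            ci - 1L, di - 1L, mi - 1L
          ))
        }
        map(ing, function(x) {
          tibble(
            state_id = cy$state_id,
            anganwadi_id = cy$anganwadi_id,
            cycle_length_days = as.integer(cy$cycle_length_days),
            day_label = day$day_label,
            meal = ml$meal %||% "other",
            dish = ml$dish %||% "dish",
            food_id = x$food_id,
            raw_grams_per_child = as.numeric(x$raw_grams_per_child),
            snp_funded = isTRUE(x$snp_funded)
          )
        }) |> list_rbind()
      }) |> list_rbind()
    }) |> list_rbind()
  }) |> list_rbind()
  menu_cycle(rows)
}

#' @rdname read_menu_cycles
#' @param menu A menu tibble (see [menu_cycle()]).
#' @export
write_menu_cycles <- function(menu, path) {
  menu <- menu_cycle(menu)
  split_keys <- function(df, keys) split(df, df[, keys], drop = TRUE)
  cycles <- menu |>
    split_keys(c("state_id", "anganwadi_id")) |>
    map(function(cy) {
      days <- cy |>
        split(factor(cy$day_label, levels = unique(cy$day_label))) |>
        map(function(day) {
          meals <- day |>
            split_keys(c("meal", "dish")) |>
            map(function(ml) {
              list(
                meal = ml$meal[1], dish = ml$dish[1],
                ingredients = pmap(
                  ml[, c("food_id", "raw_grams_per_child", "snp_funded")],
                  function(food_id, raw_grams_per_child, snp_funded) {
                    list(food_id = food_id,
                         raw_grams_per_child = raw_grams_per_child,
                         snp_funded = snp_funded)
                  }
                )
              )
            })
          list(day_label = day$day_label[1], meals = unname(meals))
        })
      list(
        state_id = cy$state_id[1], anganwadi_id = cy$anganwadi_id[1],
        cycle_length_days = cy$cycle_length_days[1], days = unname(days)
      )
    })
  jsonlite::write_json(list(cycles = unname(cycles)), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
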