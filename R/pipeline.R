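#' Pipeline run configuration
#'
#' Bundles the input paths and run parameters for [run_pipeline()]. All
#' referenced files must exist when the configuration is built.
#'
#' @param foods,menu,prices,standards Paths to the foods CSV, menu JSON,
#'   prices CSV and standards JSON.
#' @param fortification Optional path to a fortification JSON.
#' @param out_dir Output directory (created if needed).
#' @param n_draws Simulation draws per state-nutrient (default 1000).
#' @param seed Integer seed (mandatory).
#' @param allocation Per-child daily allocation, rupees (default 8).
#' @param standard_versions Standards versions to score against.
#' @param optimize Run the per-state additions-mode optimisation.
#' @param total_cap_g Meal-volume cap passed to [lp_problem()].
#' @return A list of class `snp_run_config`.
#' @export
run_config <- function(foods, menu, prices, standards,
                       fortification = NULL, out_dir, n_draws = 1000, seed,
                       allocation = 8,
                       standard_versions = c("snp2012", "snp2023"),
                       optimize = TRUE, total_cap_g = 350) {
  if (missing(seed)) abort("run_config requires a seed.")
  paths <- c(foods = foods, menu = menu, prices = prices,
             standards = standards, fortification = fortification)
  missing_files <- paths[!file.exists(paths)]
  if (length(missing_files) > 0) {
    abort(sprintf("Input file(s) not found: %s.",
                  paste(sprintf("%s (%s)", names(missing_files),
                                missing_files), collapse = ", ")))
  }
  stopifnot(n_draws >= 1, allocation > 0,
            all(standard_versions %in% c("snp2012", "snp2023")))
  structure(
    list(
      foods = foods, menu = menu, prices = prices, standards = standards,
      fortification = fortification, out_dir = out_dir, n_draws = n_draws,
      seed = as.integer(seed), allocation = allocation,
      standard_versions = standard_versions, optimize = optimize,
      total_cap_g = total_cap_g
    ),
    class = "snp_run_config"
  )
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("Pipeline stage '%s' failed: %s", name,
                  conditionMessage(e)))
  })
}

#' Run the full evaluation pipeline
#'
#' Chains provision computation, state-level simulation, adequacy scoring
#' under each requested standards version, food-group decomposition and
#' (optionally) per-state additions-mode menu optimisation, writing:
#' `provisions.csv`, `state_summary.csv`, `adequacy_<version>.csv`,
#' `foodgroup_shares.csv`, `lp_result.json` and `manifest.json` under
#' `out_dir`. Output is a pure function of (inputs, configuration): reruns
#' with the same configuration produce byte-identical CSV bodies (only the
#' manifest carries a timestamp). Traffic-light status is serialised as
#' text. Every exclusion of non-programme food rows is counted in the
#' manifest, never dropped silently.
#'
#' @param cfg An [run_config()].
#' @return Invisibly, a list with the computed objects and output paths.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "snp_run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$out_dir, f)

  foods <- stage("load_foods", read_food_table(cfg$foods))
  menu <- stage("load_menu", read_menu_cycles(cfg$menu))
  prices <- stage("load_prices", read_prices(cfg$prices))
  base_cfg <- stage("load_standards", read_standards(cfg$standards))
  fort <- if (!is.null(cfg$fortification)) {
    stage("load_fortification", read_fortification(cfg$fortification))
  }

  standards <- map(cfg$standard_versions, function(v) {
    snp_standards(
      v, ear_per_day = base_cfg$ear_per_day,
      meal_fraction = base_cfg$meal_fraction,
      tolerance = base_cfg$tolerance,
      digestibility = base_cfg$digestibility,
      fortification_mode = base_cfg$fortification_mode,
      fat_allowance = base_cfg$fat_allowance
    )
  }) |>
    setNames(cfg$standard_versions)

  provisions <- stage("provision", compute_provisions(
    menu, foods, fort, fortification_mode = base_cfg$fortification_mode
  ))
  readr::write_csv(provisions, out("provisions.csv"), progress = FALSE)

  summary <- stage("simulate", {
    summarize_states(provisions) |>
      simulate_states(n_draws = cfg$n_draws, seed = cfg$seed)
  })
  readr::write_csv(as_tibble(summary), out("state_summary.csv"),
                   progress = FALSE)

  adequacy <- map(standards, function(std) {
    stage(paste0("adequacy_", std$standard_version), {
      res <- evaluate_state(summary, std)
      readr::write_csv(as_tibble(res),
                       out(sprintf("adequacy_%s.csv",
                                   std$standard_version)),
                       progress = FALSE)
      res
    })
  })

  shares <- stage("foodgroup_shares", {
    menu |>
      group_by(.data$state_id) |>
      group_split() |>
      map(function(m) {
        food_group_shares(m, foods, fort) |>
          mutate(state_id = m$state_id[1], .before = 1)
      }) |>
      list_rbind()
  })
  readr::write_csv(shares, out("foodgroup_shares.csv"), progress = FALSE)

  lp_results <- NULL
  if (cfg$optimize) {
    lp_results <- stage("optimize", {
      foods_fort <- apply_fortification(foods, fort,
                                        mode = base_cfg$fortification_mode)
      std <- standards[[1]]
      map(sort(unique(menu$state_id)), function(st) {
        m <- filter(menu, .data$state_id == st, .data$snp_funded)
        # state base day: mean raw grams per food over the anganwadi-days
        n_days <- nrow(distinct(m, .data$anganwadi_id, .data$day_label))
        base <- m |>
          group_by(.data$food_id) |>
          summarise(g = sum(.data$raw_grams_per_child) / n_days,
                    .groups = "drop")
        res <- lp_problem(
          foods_fort, prices, std, total_cap_g = cfg$total_cap_g,
          base_menu = setNames(base$g, base$food_id), mode = "additions",
          allocation = cfg$allocation
        ) |>
          lp_solve()
        list(
          state_id = st, status = res$status,
          additional_grams = if (res$status == "optimal") {
            as.list(round(res$grams[res$grams > 1e-6], 3))
          } else {
            NULL
          },
          total_cost = res$total_cost, allocation = res$allocation,
          cost_gap = res$cost_gap, binding = res$binding
        )
      })
    })
    jsonlite::write_json(lp_results, out("lp_result.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  manifest <- list(
    package = "snpmeals",
    version = as.character(packageVersion("snpmeals")),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = cfg$seed, n_draws = cfg$n_draws, allocation = cfg$allocation,
    standard_versions = cfg$standard_versions,
    counts = list(
      states = dplyr::n_distinct(menu$state_id),
      anganwadi_days = nrow(provisions),
      menu_rows = nrow(menu),
      non_snp_rows_excluded = sum(!menu$snp_funded)
    ),
    outputs = basename(list.files(cfg$out_dir))
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)

  invisible(list(
    provisions = provisions, summary = summary, adequacy = adequacy,
    shares = shares, lp = lp_results, manifest = manifest,
    out_dir = cfg$out_dir
  ))
}
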