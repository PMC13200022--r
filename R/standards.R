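#' Programme nutrient standards
#'
#' Build the configuration object against which provision is scored. Two
#' standard versions are supported:
#'
#' * `snp2012`: 500 kcal energy target and a 12 g/day protein floor
#'   (programme upper figure 15 g, reported but not used for failure), with
#'   fat assessed as a 25--35% fat-to-energy ratio band.
#' * `snp2023`: 400 kcal energy target, a 15--20 g protein band (the 15 g
#'   floor is the operative bound) and an absolute 15--20 g fat band.
#'
#' Micronutrients are scored against `meal_fraction` (default one-third) of
#' the age-specific Estimated Average Requirement for 3--6 year olds,
#' supplied through `ear_per_day`. A relative `tolerance` (default 10%)
#' widens the met/not-met determination for macro- and micronutrients;
#' traffic-light colours always use the 80/90/110 percentage bands. Crude
#' protein may be corrected by a `digestibility` factor (default 0.8,
#' appropriate for predominantly cereal-based meals).
#'
#' @param version `"snp2012"` or `"snp2023"`.
#' @param ear_per_day Named numeric vector of daily EARs for 3--6 y, names
#'   from [snp_micronutrients()]. Units follow the key suffix.
#' @param meal_fraction Fraction of the daily requirement the programme
#'   meals are expected to supply; in (0, 1].
#' @param tolerance Relative flexibility margin in \[0, 1) applied to the
#'   met/not-met determination.
#' @param digestibility Protein digestibility scalar in (0, 1].
#' @param energy_target_kcal,protein_min_g,protein_max_g,fat_rule Overrides
#'   for the version defaults. `fat_rule` is a list with `type`
#'   (`"ratio"` for % of energy or `"absolute"` for grams), `lower`, `upper`.
#' @param fortification_mode `"increment"` (fortificant levels are added to
#'   the base density) or `"total"` (levels are total contents; the base is
#'   raised to at least the stated level).
#' @param fat_allowance Whether the tolerance widens `"both_edges"` of the
#'   fat band (default) or the `"lower_only"` edge.
#'
#' @return An object of class `snp_standards`.
#' @export
#' @examples
#' cfg <- snp_standards("snp2012", ear_per_day = default_ear_synthetic())
#' cfg$energy_target_kcal
snp_standards <- function(version = c("snp2012", "snp2023"),
                          ear_per_day = NULL,
                          meal_fraction = 1 / 3,
                          tolerance = 0.10,
                          digestibility = 0.8,
                          energy_target_kcal = NULL,
                          protein_min_g = NULL,
                          protein_max_g = NULL,
                          fat_rule = NULL,
                          fortification_mode = c("increment", "total"),
                          fat_allowance = c("both_edges", "lower_only")) {
  version <- match.arg(version)
  fortification_mode <- match.arg(fortification_mode)
  fat_allowance <- match.arg(fat_allowance)

  defaults <- switch(version,
    snp2012 = list(
      energy_target_kcal = 500, protein_min_g = 12, protein_max_g = 15,
      fat_rule = list(type = "ratio", lower = 25, upper = 35)
    ),
    snp2023 = list(
      energy_target_kcal = 400, protein_min_g = 15, protein_max_g = 20,
      fat_rule = list(type = "absolute", lower = 15, upper = 20)
    )
  )

  cfg <- list(
    standard_version = version,
    energy_target_kcal = energy_target_kcal %||% defaults$energy_target_kcal,
    protein_min_g = protein_min_g %||% defaults$protein_min_g,
    protein_max_g = protein_max_g %||% defaults$protein_max_g,
    fat_rule = fat_rule %||% defaults$fat_rule,
    ear_per_day = ear_per_day,
    meal_fraction = meal_fraction,
    tolerance = tolerance,
    digestibility = digestibility,
    fortification_mode = fortification_mode,
    fat_allowance = fat_allowance
  )
  validate_standards(cfg)
  structure(cfg, class = "snp_standards")
}

validate_standards <- function(cfg) {
  chk <- function(ok, path, msg) {
    if (!ok) abort(sprintf("Invalid standards config at %s: %s", path, msg))
  }
  chk(is.numeric(cfg$energy_target_kcal) && cfg$energy_target_kcal > 0,
      "/energy_target_kcal", "must be a positive number")
  chk(is.numeric(cfg$protein_min_g) && cfg$protein_min_g > 0,
      "/protein_min_g", "must be a positive number")
  if (!is.null(cfg$protein_max_g)) {
    chk(cfg$protein_max_g >= cfg$protein_min_g,
        "/protein_max_g", "must be >= protein_min_g")
  }
  chk(is.list(cfg$fat_rule) &&
        isTRUE(cfg$fat_rule$type %in% c("ratio", "absolute")),
      "/fat_rule/type", "must be 'ratio' or 'absolute'")
  chk(is.numeric(cfg$fat_rule$lower) && is.numeric(cfg$fat_rule$upper) &&
        cfg$fat_rule$lower > 0 && cfg$fat_rule$upper >= cfg$fat_rule$lower,
      "/fat_rule", "lower/upper must satisfy 0 < lower <= upper")
  chk(is.numeric(cfg$meal_fraction) && cfg$meal_fraction > 0 &&
        cfg$meal_fraction <= 1,
      "/meal_fraction", "must be in (0, 1]")
  chk(is.numeric(cfg$tolerance) && cfg$tolerance >= 0 && cfg$tolerance < 1,
      "/tolerance", "must be in [0, 1)")
  chk(is.numeric(cfg$digestibility) && cfg$digestibility > 0 &&
        cfg$digestibility <= 1,
      "/digestibility", "must be in (0, 1]")
  if (!is.null(cfg$ear_per_day)) {
    ear <- cfg$ear_per_day
    chk(is.numeric(ear) && !is.null(names(ear)), "/ear_per_day",
        "must be a named numeric vector")
    bad <- setdiff(names(ear), snp_micronutrients())
    chk(length(bad) == 0, "/ear_per_day",
        sprintf("unknown nutrient key(s): %s. Accepted keys: %s",
                paste(bad, collapse = ", "),
                paste(snp_micronutrients(), collapse = ", ")))
    chk(all(ear > 0), "/ear_per_day", "EAR values must be positive")
  }
  invisible(cfg)
}

#' @export
print.snp_standards <- function(x, ...) {
  cat("<snp_standards> ", x$standard_version, "\n", sep = "")
  cat("  energy target : ", x$energy_target_kcal, " kcal\n", sep = "")
  cat("  protein       : ", x$protein_min_g,
      if (!is.null(x$protein_max_g)) paste0("-", x$protein_max_g), " g\n",
      sep = "")
  fr <- x$fat_rule
  cat("  fat rule      : ", fr$type, " ", fr$lower, "-", fr$upper,
      if (fr$type == "ratio") " % of energy" else " g", "\n", sep = "")
  cat("  meal fraction ", signif(x$meal_fraction, 4),
      ", tolerance ", x$tolerance,
      ", digestibility ", x$digestibility, "\n", sep = "")
  cat("  EAR entries   : ",
      if (is.null(x$ear_per_day)) "none" else length(x$ear_per_day), "\n",
      sep = "")
  invisible(x)
}

#' Example EAR table (synthetic)
#'
#' A synthetic example of age-specific daily Estimated Average Requirements
#' for children 3--6 years, with magnitudes plausible for ICMR-style
#' recommendations. It is shipped so examples and tests run self-contained;
#' it is **not** an authoritative requirements table — supply your own EARs
#' for real analyses.
#'
#' @return Named numeric vector over [snp_micronutrients()].
#' @export
default_ear_synthetic <- function() {
  c(
    calcium_mg = 440, iron_mg = 8.7, zinc_mg = 4.9, folate_ug = 110,
    vitamin_a_ug = 290, vitamin_b6_mg = 0.75, vitamin_b12_ug = 1.0
  )
}

#' Read and write standards configurations
#'
#' JSON serialisation of [snp_standards()] objects. Unknown nutrient keys in
#' `ear_per_day` are refused with the accepted key list.
#'
#' @param path File path to a standards JSON document.
#' @return `read_standards()` returns an `snp_standards` object;
#'   `write_standards()` returns `path` invisibly.
#' @export
read_standards <- function(path) {
  if (!file.exists(path)) abort(sprintf("Standards file not found: %s", path))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c(
    "standard_version", "energy_target_kcal", "protein_min_g",
    "protein_max_g", "fat_rule", "ear_per_day", "meal_fraction",
    "tolerance", "digestibility", "fortification_mode", "fat_allowance"
  )
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0) {
    abort(sprintf("Unknown standards field(s) at /%s. Accepted: %s.",
                  paste(bad, collapse = ", /"), paste(known, collapse = ", ")))
  }
  if (is.null(raw$standard_version)) {
    abort("Invalid standards config at /standard_version: missing")
  }
  ear <- raw$ear_per_day
  if (!is.null(ear)) ear <- unlist(ear)
  snp_standards(
    version = raw$standard_version,
    ear_per_day = ear,
    meal_fraction = raw$meal_fraction %||% 1 / 3,
    tolerance = raw$tolerance %||% 0.10,
    digestibility = raw$digestibility %||% 0.8,
    energy_target_kcal = raw$energy_target_kcal,
    protein_min_g = raw$protein_min_g,
    protein_max_g = raw$protein_max_g,
    fat_rule = if (!is.null(raw$fat_rule)) as.list(raw$fat_rule),
    fortification_mode = raw$fortification_mode %||% "increment",
    fat_allowance = raw$fat_allowance %||% "both_edges"
  )
}

#' @rdname read_standards
#' @param cfg An `snp_standards` object.
#' @export
write_standards <- function(cfg, path) {
  stopifnot(inherits(cfg, "snp_standards"))
  out <- unclass(cfg)
  out$ear_per_day <- as.list(out$ear_per_day)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
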