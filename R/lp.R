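#' Build a menu-optimisation linear programme
#'
#' Sets up the classic diet problem for programme meals: choose raw grams
#' `x_f >= 0` of candidate foods to minimise cost `sum_f p_f x_f` subject
#' to nutrient constraints derived from a standards configuration:
#'
#' * energy within a band around the target (default 0.9--1.1 x target, so
#'   the optimiser does not buy adequacy through excess energy);
#' * protein at least the programme floor, using digestibility-weighted
#'   densities by default;
#' * fat as the standards' rule — an absolute gram band, or, for the
#'   ratio rule, the pair of linear constraints
#'   `9 fat - (lower/100) energy >= 0` and `9 fat - (upper/100) energy <= 0`;
#' * each micronutrient at least `meal_fraction x EAR` (floor only);
#' * per-food portion caps and a total raw-gram cap reflecting the limited
#'   gastric capacity of young children (default 350 g/day).
#'
#' In `additions` mode an existing menu day (`base_menu`, named grams per
#' food) is held fixed, its nutrient contribution is credited against the
#' constraints, and the decision variables are additions on top of it; the
#' total-gram cap then applies to base plus additions, and reported cost
#' includes the base menu's cost.
#'
#' @param foods Food table restricted to the candidate (state-listed)
#'   foods; fortification should be applied beforehand with
#'   [apply_fortification()].
#' @param prices Prices tibble ([read_prices()]) covering every candidate
#'   (and base) food, rupees/kg.
#' @param cfg An [snp_standards()] object with a full EAR table.
#' @param portion_caps Named numeric, max grams/day per food; defaults to
#'   `total_cap_g` for every food.
#' @param total_cap_g Cap on total raw grams per day.
#' @param base_menu Named numeric of fixed grams (additions mode).
#' @param mode `"full"` (design a day from scratch) or `"additions"`.
#' @param protein `"digestible"` (densities weighted by the digestibility
#'   factor) or `"crude"`.
#' @param allocation Per-child daily allocation, rupees (default 8).
#' @param energy_band Multiplicative band around the energy target.
#' @return An object of class `snp_lp_problem`.
#' @export
lp_problem <- function(foods, prices, cfg, portion_caps = NULL,
                       total_cap_g = 350, base_menu = NULL,
                       mode = c("full", "additions"),
                       protein = c("digestible", "crude"),
                       allocation = 8, energy_band = c(0.9, 1.1)) {
  mode <- match.arg(mode)
  protein <- match.arg(protein)
  stopifnot(inherits(cfg, "snp_standards"))
  foods <- food_table(foods)
  if (nrow(foods) == 0) abort("The candidate food list is empty.")
  if (mode == "additions" && is.null(base_menu)) {
    abort("additions mode requires a base_menu (named grams per food).")
  }
  if (mode == "full") base_menu <- setNames(numeric(0), character(0))
  missing_base <- setdiff(names(base_menu), foods$food_id)
  if (length(missing_base) > 0) {
    abort(sprintf("base_menu food(s) not in the food table: %s.",
                  paste(missing_base, collapse = ", ")))
  }
  unpriced <- setdiff(foods$food_id, prices$food_id)
  if (length(unpriced) > 0) {
    abort(sprintf("Food(s) without a price: %s.",
                  paste(unpriced, collapse = ", ")))
  }
  if (is.null(cfg$ear_per_day) ||
        length(setdiff(snp_micronutrients(), names(cfg$ear_per_day))) > 0) {
    abort("The standards config must carry an EAR entry for every micronutrient.")
  }

  ids <- foods$food_id
  # densities per gram of raw food
  D <- t(as.matrix(foods[, snp_nutrients()])) / 100
  colnames(D) <- ids
  cost_per_g <- prices$mean_price[match(ids, prices$food_id)] / 1000

  caps <- rep_len(total_cap_g, length(ids))
  names(caps) <- ids
  if (!is.null(portion_caps)) {
    bad <- setdiff(names(portion_caps), ids)
    if (length(bad) > 0) {
      abort(sprintf("portion_caps for unknown food(s): %s.",
                    paste(bad, collapse = ", ")))
    }
    caps[names(portion_caps)] <- portion_caps
  }
  if (any(caps < 0) || total_cap_g <= 0) {
    abort("Portion caps must be >= 0 and total_cap_g > 0.")
  }

  lower <- c(
    energy_kcal = cfg$energy_target_kcal * energy_band[1],
    protein_g = cfg$protein_min_g,
    cfg$ear_per_day[snp_micronutrients()]
  )
  upper <- c(energy_kcal = cfg$energy_target_kcal * energy_band[2])
  lower[snp_micronutrients()] <-
    cfg$ear_per_day[snp_micronutrients()] * cfg$meal_fraction
  if (cfg$fat_rule$type == "absolute") {
    lower["fat_g"] <- cfg$fat_rule$lower
    upper["fat_g"] <- cfg$fat_rule$upper
  }

  base <- setNames(rep(0, length(ids)), ids)
  base[names(base_menu)] <- base_menu

  structure(
    list(
      food_ids = ids, densities = D, cost_per_g = cost_per_g,
      lower = lower, upper = upper, caps = caps, total_cap_g = total_cap_g,
      base = base, mode = mode, protein = protein,
      digestibility = if (protein == "digestible") cfg$digestibility else 1,
      fat_rule = cfg$fat_rule, allocation = allocation
    ),
    class = "snp_lp_problem"
  )
}

#' @export
print.snp_lp_problem <- function(x, ...) {
  cat("<snp_lp_problem> ", x$mode, " mode: ", length(x$food_ids),
      " foods, ", length(x$lower), " nutrient floors, ",
      length(x$upper), " ceilings",
      if (x$fat_rule$type == "ratio") ", fat-to-energy ratio band", "\n",
      sep = "")
  invisible(x)
}

# Constraint rows as (matrix row, direction, rhs) triples on the decision
# variables x (additions over the base). Protein rows use digestibility-
# weighted densities.
lp_constraints <- function(p) {
  D <- p$densities
  Dp <- D
  Dp["protein_g", ] <- Dp["protein_g", ] * p$digestibility
  base_ach <- as.numeric(Dp %*% p$base)
  names(base_ach) <- rownames(Dp)

  rows <- list()
  add <- function(coef, dir, rhs, label) {
    rows[[length(rows) + 1]] <<- list(coef = coef, dir = dir, rhs = rhs,
                                      label = label)
  }
  for (k in names(p$lower)) {
    add(Dp[k, ], ">=", p$lower[[k]] - base_ach[[k]], paste0(k, "_min"))
  }
  for (k in names(p$upper)) {
    add(Dp[k, ], "<=", p$upper[[k]] - base_ach[[k]], paste0(k, "_max"))
  }
  if (p$fat_rule$type == "ratio") {
    r_lo <- KCAL_PER_G_FAT * D["fat_g", ] -
      p$fat_rule$lower / 100 * D["energy_kcal", ]
    r_hi <- KCAL_PER_G_FAT * D["fat_g", ] -
      p$fat_rule$upper / 100 * D["energy_kcal", ]
    b_lo <- KCAL_PER_G_FAT * base_ach[["fat_g"]] -
      p$fat_rule$lower / 100 * base_ach[["energy_kcal"]]
    b_hi <- KCAL_PER_G_FAT * base_ach[["fat_g"]] -
      p$fat_rule$upper / 100 * base_ach[["energy_kcal"]]
    add(r_lo, ">=", -b_lo, "fat_ratio_min")
    add(r_hi, "<=", -b_hi, "fat_ratio_max")
  }
  n <- length(p$food_ids)
  for (i in seq_len(n)) {
    coef <- numeric(n)
    coef[i] <- 1
    add(coef, "<=", max(0, p$caps[[i]] - p$base[[i]]),
        paste0("cap_", p$food_ids[i]))
  }
  add(rep(1, n), "<=", max(0, p$total_cap_g - sum(p$base)), "total_grams")
  rows
}

#' Solve a menu-optimisation programme
#'
#' Minimises the cost of the candidate grams subject to the problem's
#' constraints, via the two-phase simplex method. The returned solution is
#' re-checked against every constraint independently of the solver's own
#' report (tolerance 1e-6); `status` is reported faithfully
#' (`optimal` / `infeasible` / `not_converged`) and never a silent partial
#' answer.
#'
#' A secondary goal-programming objective, `"min_shortfall"`, minimises the
#' total relative shortfall below the nutrient floors subject to the cost
#' staying within the allocation — the "best feasible menu under budget"
#' question — instead of minimising cost subject to all floors.
#'
#' @param problem An [lp_problem()].
#' @param objective `"min_cost"` (default) or `"min_shortfall"`.
#' @return An object of class `snp_lp_result`: `status`, `grams` (named,
#'   decision foods), `total_cost` (rupees, including any base menu),
#'   `cost_gap` (`max(0, total_cost - allocation)`), `achieved` (named
#'   nutrient amounts including the base), `binding` (constraint labels
#'   tight at the optimum) and `shortfall` (for the secondary objective).
#' @export
lp_solve <- function(problem, objective = c("min_cost", "min_shortfall")) {
  objective <- match.arg(objective)
  stopifnot(inherits(problem, "snp_lp_problem"))
  p <- problem
  rows <- lp_constraints(p)
  n <- length(p$food_ids)

  if (objective == "min_cost") {
    a <- p$cost_per_g
    keep <- rows
  } else {
    # shortfall slacks: one per floor row; minimise relative shortfall
    # subject to the budget
    floor_rows <- which(map_chr(rows, "dir") == ">=")
    m <- length(floor_rows)
    a <- c(numeric(n), map_dbl(rows[floor_rows], function(r) {
      1 / max(abs(r$rhs), 1)
    }))
    keep <- imap(rows, function(r, i) {
      coef <- c(r$coef, numeric(m))
      if (r$dir == ">=") coef[n + match(i, floor_rows)] <- 1
      list(coef = coef, dir = r$dir, rhs = r$rhs, label = r$label)
    })
    budget <- max(0, p$allocation - sum(p$cost_per_g * p$base))
    keep[[length(keep) + 1]] <- list(
      coef = c(p$cost_per_g, numeric(m)), dir = "<=", rhs = budget,
      label = "budget"
    )
  }

  # boot::simplex needs non-negative right-hand sides: flip rows
  norm <- map(keep, function(r) {
    if (r$rhs < 0) {
      list(coef = -r$coef, dir = if (r$dir == ">=") "<=" else ">=",
           rhs = -r$rhs, label = r$label)
    } else {
      r
    }
  })
  is_le <- map_lgl(norm, function(r) r$dir == "<=")
  A1 <- do.call(rbind, map(norm[is_le], "coef"))
  b1 <- map_dbl(norm[is_le], "rhs")
  A2 <- do.call(rbind, map(norm[!is_le], "coef"))
  b2 <- map_dbl(norm[!is_le], "rhs")

  sol <- boot::simplex(
    a = a, A1 = A1, b1 = b1,
    A2 = if (length(b2) > 0) A2 else NULL,
    b2 = if (length(b2) > 0) b2 else NULL,
    maxi = FALSE, n.iter = 200 + 20 * (length(a) + length(norm))
  )
  status <- switch(as.character(sol$solved),
                   "1" = "optimal", "-1" = "infeasible", "not_converged")

  if (status != "optimal") {
    return(new_lp_result(p, status = status, x = NULL,
                         objective = objective))
  }
  x <- as.numeric(sol$soln)[seq_len(n)]
  slacks <- if (objective == "min_shortfall") {
    as.numeric(sol$soln)[-seq_len(n)]
  }

  # independent re-check of every original constraint (shortfall slacks
  # credited for the secondary objective)
  tol <- 1e-6
  fi <- 0
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    lhs <- sum(r$coef * x)
    if (objective == "min_shortfall" && r$dir == ">=") {
      fi <- fi + 1
      lhs <- lhs + slacks[fi]
    }
    ok <- if (r$dir == ">=") lhs >= r$rhs - tol * max(1, abs(r$rhs))
          else lhs <= r$rhs + tol * max(1, abs(r$rhs))
    if (!ok) {
      abort(sprintf("Solver returned a point violating constraint %s (lhs %.8g vs rhs %.8g).",
                    r$label, lhs, r$rhs))
    }
  }
  new_lp_result(p, status = "optimal", x = x, objective = objective,
                rows = rows, slacks = slacks)
}

new_lp_result <- function(p, status, x, objective, rows = NULL,
                          slacks = NULL, method = "simplex") {
  if (is.null(x)) {
    res <- list(
      status = status, objective = objective, method = method,
      grams = NULL, total_cost = NA_real_, cost_gap = NA_real_,
      achieved = NULL, binding = character(0), shortfall = NULL,
      allocation = p$allocation, food_ids = p$food_ids, problem = p
    )
    return(structure(res, class = "snp_lp_result"))
  }
  grams <- setNames(pmax(x, 0), p$food_ids)
  total <- p$base + grams
  achieved <- as.numeric(p$densities %*% total)
  names(achieved) <- rownames(p$densities)
  total_cost <- sum(p$cost_per_g * total)
  binding <- character(0)
  if (!is.null(rows)) {
    binding <- map_chr(rows, function(r) {
      lhs <- sum(r$coef * grams)
      if (abs(lhs - r$rhs) <= 1e-6 * max(1, abs(r$rhs))) r$label else NA_character_
    })
    binding <- binding[!is.na(binding)]
  }
  shortfall <- NULL
  if (objective == "min_shortfall" && !is.null(slacks)) {
    floor_rows <- rows[map_chr(rows, "dir") == ">="]
    shortfall <- setNames(slacks, map_chr(floor_rows, "label"))
  }
  structure(
    list(
      status = status, objective = objective, method = method,
      grams = grams, total_cost = total_cost,
      cost_gap = max(0, total_cost - p$allocation), achieved = achieved,
      binding = binding, shortfall = shortfall,
      allocation = p$allocation, food_ids = p$food_ids, problem = p
    ),
    class = "snp_lp_result"
  )
}

#' @export
print.snp_lp_result <- function(x, ...) {
  cat("<snp_lp_result> status: ", x$status, " (", x$objective, ", ",
      x$method, ")\n", sep = "")
  if (x$status == "optimal") {
    nz <- x$grams[x$grams > 1e-9]
    cat("  grams: ",
        if (length(nz) == 0) "none" else
          paste(sprintf("%s=%.1f", names(nz), nz), collapse = ", "),
        "\n", sep = "")
    cat(sprintf("  cost: Rs %.2f (allocation Rs %.2f, gap Rs %.2f)\n",
                x$total_cost, x$allocation, x$cost_gap))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.snp_lp_result <- function(x, ...) {
  if (x$status != "optimal") {
    return(tibble(food_id = character(0), grams = numeric(0),
                  cost = numeric(0)))
  }
  tibble(
    food_id = names(x$grams),
    grams = as.numeric(x$grams),
    base_grams = as.numeric(x$problem$base),
    cost = as.numeric((x$grams + x$problem$base) * x$problem$cost_per_g)
  )
}

#' @exportS3Method generics::glance
glance.snp_lp_result <- function(x, ...) {
  tibble(
    status = x$status, objective = x$objective, method = x$method,
    total_cost = x$total_cost, allocation = x$allocation,
    cost_gap = x$cost_gap, n_foods = length(x$food_ids),
    n_binding = length(x$binding)
  )
}

#' Brute-force grid oracle for small problems
#'
#' Exhaustive search over gram multiples of `grid_step_g` up to each food's
#' cap, returning the cheapest feasible grid point. Intended as an
#' independent check of [lp_solve()] on tiny problems; refuses more than
#' four foods (combinatorial guard).
#'
#' @param problem An [lp_problem()] with at most 4 foods and finite caps.
#' @param grid_step_g Grid resolution in grams.
#' @return An `snp_lp_result` with `method = "grid"`.
#' @export
lp_brute_force <- function(problem, grid_step_g) {
  stopifnot(inherits(problem, "snp_lp_problem"))
  p <- problem
  n <- length(p$food_ids)
  if (n > 4) abort("The grid oracle handles at most 4 foods.")
  if (grid_step_g <= 0) abort("grid_step_g must be > 0.")
  axes <- map(p$food_ids, function(f) {
    cap <- max(0, p$caps[[f]] - p$base[[f]])
    seq(0, cap, by = grid_step_g)
  })
  n_pts <- prod(lengths(axes))
  if (n_pts > 5e6) abort("Grid too large; increase grid_step_g.")
  X <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
  colnames(X) <- p$food_ids
  rows <- lp_constraints(p)
  feasible <- rep(TRUE, nrow(X))
  tol <- 1e-9
  for (r in rows) {
    lhs <- as.numeric(X %*% r$coef)
    feasible <- feasible & if (r$dir == ">=") lhs >= r$rhs - tol
                           else lhs <= r$rhs + tol
  }
  if (!any(feasible)) {
    return(new_lp_result(p, status = "infeasible", x = NULL,
                         objective = "min_cost"))
  }
  costs <- as.numeric(X %*% p$cost_per_g)
  best <- which(feasible)[which.min(costs[feasible])]
  new_lp_result(p, status = "optimal", x = as.numeric(X[best, ]),
                objective = "min_cost", rows = rows, method = "grid")
}

#' Gap between optimised cost and the per-child allocation
#'
#' `max(0, total_cost - allocation)`: the additional rupees per child per
#' day an optimal menu would require beyond the current allocation
#' (default 8 rupees).
#'
#' @param result An optimal `snp_lp_result`.
#' @param allocation Allocation in rupees; defaults to the problem's.
#' @return Rupees per child per day, >= 0.
#' @export
#' @examples
#' cost_gap_value(16, 8) # 8
cost_gap <- function(result, allocation = NULL) {
  stopifnot(inherits(result, "snp_lp_result"))
  if (result$status != "optimal") {
    abort("cost_gap is only defined for an optimal result.")
  }
  cost_gap_value(result$total_cost, allocation %||% result$allocation)
}

#' @rdname cost_gap
#' @param total_cost Total optimised cost, rupees.
#' @export
cost_gap_value <- function(total_cost, allocation) {
  if (!is.finite(total_cost) || !is.finite(allocation)) {
    abort("total_cost and allocation must be finite.")
  }
  max(0, total_cost - allocation)
}
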