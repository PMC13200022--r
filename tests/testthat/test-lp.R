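# two foods, two binding nutrient floors: 2x + y >= 10, x + 3y >= 15 with
# costs (3, 2)/g has its optimum at the intersection x = 3, y = 4, cost 17
hand_problem <- function(cost = c(3, 2)) {
  D <- rbind(
    n1 = c(2, 1), n2 = c(1, 3),
    protein_g = c(0, 0)
  )
  colnames(D) <- c("A", "B")
  toy_lp_problem(D, cost_per_g = cost, lower = c(n1 = 10, n2 = 15),
                 caps = c(A = 100, B = 100))
}

test_that("the simplex reproduces a hand-solved vertex exactly", {
  res <- lp_solve(hand_problem())
  expect_equal(res$status, "optimal")
  expect_equal(unname(res$grams), c(3, 4), tolerance = 1e-9)
  expect_equal(res$total_cost, 17, tolerance = 1e-9)
  expect_true(all(c("n1_min", "n2_min") %in% res$binding))
  expect_equal(res$achieved[["n1"]], 10, tolerance = 1e-9)

  # grid aligned with the vertex agrees exactly
  grid <- lp_brute_force(hand_problem(), grid_step_g = 0.5)
  expect_equal(grid$total_cost, 17, tolerance = 1e-9)
  expect_equal(unname(grid$grams), c(3, 4))
})

test_that("infeasibility is reported, never a partial answer", {
  p <- hand_problem()
  p$caps <- c(A = 0, B = 0)
  res <- lp_solve(p)
  expect_equal(res$status, "infeasible")
  expect_null(res$grams)
  expect_error(cost_gap(res), "optimal")
  expect_equal(lp_brute_force(p, 1)$status, "infeasible")
})

test_that("the objective is homogeneous in prices", {
  base <- lp_solve(hand_problem())
  scaled <- lp_solve(hand_problem(cost = 5 * c(3, 2)))
  expect_equal(scaled$total_cost, 5 * base$total_cost, tolerance = 1e-9)
  expect_equal(scaled$grams, base$grams, tolerance = 1e-9)
})

test_that("duplicating a food never changes the optimal cost", {
  D <- rbind(n1 = c(2, 1, 2), n2 = c(1, 3, 1), protein_g = c(0, 0, 0))
  colnames(D) <- c("A", "B", "A2")
  dup <- toy_lp_problem(D, cost_per_g = c(3, 2, 3),
                        lower = c(n1 = 10, n2 = 15),
                        caps = c(A = 100, B = 100, A2 = 100))
  expect_equal(lp_solve(dup)$total_cost, 17, tolerance = 1e-9)
})

test_that("relaxing a nutrient floor never increases the optimal cost", {
  set.seed(61)
  for (i in 1:10) {
    D <- rbind(
      n1 = runif(3, 0.5, 4), n2 = runif(3, 0.5, 4),
      protein_g = runif(3, 0, 1)
    )
    colnames(D) <- c("A", "B", "C")
    lower <- c(n1 = runif(1, 20, 60), n2 = runif(1, 20, 60))
    p <- toy_lp_problem(D, cost_per_g = runif(3, 0.01, 0.2), lower = lower,
                        caps = c(A = 200, B = 200, C = 200))
    full <- lp_solve(p)
    relaxed <- p
    relaxed$lower["n1"] <- lower[["n1"]] * 0.5
    expect_lte(lp_solve(relaxed)$total_cost,
               full$total_cost + 1e-9)
  }
})

test_that("LP optima agree with the brute-force grid oracle", {
  set.seed(17)
  step <- 5
  for (i in 1:50) {
    n <- sample(2:3, 1)
    D <- rbind(
      n1 = runif(n, 0.5, 4), n2 = runif(n, 0.5, 4),
      protein_g = runif(n, 0.05, 0.25)
    )
    colnames(D) <- paste0("f", seq_len(n))
    caps <- setNames(rep(100, n), colnames(D))
    # floors from a random feasible grid point, so the problem is feasible
    x0 <- setNames(step * sample(0:10, n, replace = TRUE), colnames(D))
    lower <- as.numeric(D %*% x0) * runif(3, 0.5, 1)
    names(lower) <- rownames(D)
    p <- toy_lp_problem(D, cost_per_g = runif(n, 0.01, 0.3), lower = lower,
                        caps = caps, total_cap_g = 1e4)
    lp <- lp_solve(p)
    oracle <- lp_brute_force(p, grid_step_g = step)
    expect_equal(lp$status, "optimal")
    expect_equal(oracle$status, "optimal")
    # the grid point is feasible, so it can never beat the LP; rounding the
    # LP point up coordinate-wise stays feasible (floor-only constraints),
    # so the oracle is within one grid step per food in cost
    expect_gte(oracle$total_cost, lp$total_cost - 1e-9)
    expect_lte(oracle$total_cost,
               lp$total_cost + sum(p$cost_per_g) * step + 1e-9)
  }
})

test_that("solutions satisfy every constraint within 1e-6 independently", {
  ds <- gen_dataset(synthetic_config(seed = 14, n_states = 1))
  foods_f <- apply_fortification(ds$foods, ds$fortification)
  prob <- lp_problem(foods_f, ds$prices, std2012())
  res <- lp_solve(prob)
  expect_equal(res$status, "optimal")
  ach <- res$achieved
  for (k in names(prob$lower)) {
    expect_gte(ach[[k]], prob$lower[[k]] - 1e-6 * max(1, prob$lower[[k]]))
  }
  for (k in names(prob$upper)) {
    expect_lte(ach[[k]], prob$upper[[k]] + 1e-6 * max(1, prob$upper[[k]]))
  }
  r <- fat_energy_ratio(ach[["energy_kcal"]], ach[["fat_g"]])
  expect_gte(r, 25 - 1e-6)
  expect_lte(r, 35 + 1e-6)
  expect_true(all(res$grams <= prob$caps + 1e-6))
  expect_lte(sum(res$grams), prob$total_cap_g + 1e-6)

  # the 2023 standard solves with the absolute fat band
  res23 <- lp_solve(lp_problem(foods_f, ds$prices, std2023()))
  expect_equal(res23$status, "optimal")
  expect_gte(res23$achieved[["fat_g"]], 15 - 1e-6)
  expect_lte(res23$achieved[["fat_g"]], 20 + 1e-6)
})

test_that("additions mode charges the base and accepts an adequate base", {
  ds <- gen_dataset(synthetic_config(seed = 14, n_states = 1))
  foods_f <- apply_fortification(ds$foods, ds$fortification)
  full <- lp_solve(lp_problem(foods_f, ds$prices, std2012()))
  base <- full$grams[full$grams > 1e-9] * 1.0001
  prob <- lp_problem(foods_f, ds$prices, std2012(), base_menu = base,
                     mode = "additions")
  res <- lp_solve(prob)
  expect_equal(res$status, "optimal")
  # the zero addition is feasible and optimal: pay only the base
  expect_equal(sum(res$grams), 0, tolerance = 1e-6)
  base_cost <- sum(prob$cost_per_g * prob$base)
  expect_equal(res$total_cost, base_cost, tolerance = 1e-6)

  # an inadequate base requires paid additions
  lean <- lp_problem(foods_f, ds$prices, std2012(),
                     base_menu = c(rice = 50), mode = "additions")
  res2 <- lp_solve(lean)
  expect_equal(res2$status, "optimal")
  expect_gt(sum(res2$grams), 0)
  expect_gte(res2$total_cost, sum(lean$cost_per_g * lean$base))
})

test_that("the budget-capped shortfall objective respects the allocation", {
  ds <- gen_dataset(synthetic_config(seed = 14, n_states = 1))
  foods_f <- apply_fortification(ds$foods, ds$fortification)
  prob <- lp_problem(foods_f, ds$prices, std2012(), allocation = 4)
  res <- lp_solve(prob, objective = "min_shortfall")
  expect_equal(res$status, "optimal")
  expect_lte(sum(res$grams * prob$cost_per_g), 4 + 1e-6)
  expect_true(all(res$shortfall >= -1e-9))
})

test_that("the cost gap is the clamped difference from the allocation", {
  expect_equal(cost_gap_value(16, 8), 8)
  expect_equal(cost_gap_value(20, 8), 12)
  expect_equal(cost_gap_value(7.5, 8), 0)
  res <- lp_solve(hand_problem())
  expect_equal(cost_gap(res, allocation = 8), 17 - 8)
  expect_equal(cost_gap(res, allocation = 20), 0)
})

test_that("problem assembly validates prices, foods and oracle guards", {
  ds <- gen_dataset(synthetic_config(seed = 14, n_states = 1))
  expect_error(
    lp_problem(ds$foods, ds$prices[-1, ], std2012()),
    "without a price"
  )
  expect_error(lp_problem(ds$foods[0, ], ds$prices, std2012()), "empty")
  expect_error(
    lp_problem(ds$foods, ds$prices,
               snp_standards("snp2012", ear_per_day = c(iron_mg = 8.7))),
    "EAR"
  )
  big <- lp_problem(ds$foods, ds$prices, std2012())
  expect_error(lp_brute_force(big, 10), "at most 4")
  # dimensions of a state-list problem: 6 candidate foods, >= 10 rows
  cand <- ds$foods[ds$foods$food_id %in%
                     c("rice", "lentil", "oil", "egg", "milk", "spinach"), ]
  p6 <- lp_problem(cand, ds$prices, std2023())
  expect_length(p6$food_ids, 6)
  expect_gte(length(p6$lower) + length(p6$upper), 10)
})
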