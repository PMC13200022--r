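#' State-level provision moments
#'
#' Summarises anganwadi-day provisions per state and nutrient: sample mean
#' `m`, unbiased sample variance `v` (n-1 denominator; 0 when a state has a
#' single observation) and the number of anganwadi-day observations
#' `n_obs`. The observation unit is one anganwadi-day, pooled across the
#' state's surveyed anganwadis.
#'
#' @param provisions Output of [compute_provisions()].
#' @return A long tibble with `state_id`, `nutrient`, `m`, `v`, `n_obs`.
#' @export
summarize_states <- function(provisions) {
  if (nrow(provisions) == 0) {
    abort("At least one provision row is required.")
  }
  provisions |>
    pivot_longer(all_of(snp_nutrients()), names_to = "nutrient",
                 values_to = "amount") |>
    group_by(.data$state_id, .data$nutrient) |>
    summarise(
      m = mean(.data$amount),
      v = if (dplyr::n() > 1) var(.data$amount) else 0,
      n_obs = dplyr::n(),
      .groups = "drop"
    ) |>
    mutate(nutrient = factor(.data$nutrient, levels = snp_nutrients())) |>
    arrange(.data$state_id, .data$nutrient) |>
    mutate(nutrient = as.character(.data$nutrient))
}

#' Lognormal parameters by moment matching
#'
#' Given a mean `m > 0` and variance `v >= 0` of daily provision, returns
#' the parameters of the lognormal distribution with exactly those moments:
#' `sigma^2 = log(1 + v / m^2)` and `mu = log(m) - sigma^2 / 2`. The
#' lognormal is a natural model for nutrient provision: positive and
#' right-skewed. Vectorised over `m` and `v`.
#'
#' @param m Sample mean(s), > 0.
#' @param v Sample variance(s), >= 0. `v = 0` gives the degenerate fit
#'   `sigma = 0`, `mu = log(m)`.
#' @return A tibble with columns `mu` and `sigma`.
#' @export
#' @examples
#' fit_lognormal(450, 5000)
fit_lognormal <- function(m, v) {
  if (any(!is.finite(m) | m <= 0)) {
    abort("fit_lognormal requires m > 0; a nutrient never provided (m = 0) should be reported as zero provision, not fitted.")
  }
  if (any(!is.finite(v) | v < 0)) abort("fit_lognormal requires v >= 0.")
  sigma2 <- log1p(v / m^2)
  tibble(mu = log(m) - sigma2 / 2, sigma = sqrt(sigma2))
}

#' Simulate daily provision draws
#'
#' Draws independent lognormal(mu, sigma) samples representing the varying
#' nutrient content of the meals. The seed is mandatory so results are
#' reproducible; the global random state is left untouched.
#'
#' @param mu,sigma Lognormal parameters (`sigma >= 0`; `sigma = 0` gives a
#'   point mass at `exp(mu)`).
#' @param n_draws Number of draws (default 1000 iterations).
#' @param seed Integer seed.
#' @return Numeric vector of length `n_draws`.
#' @export
simulate_provision <- function(mu, sigma, n_draws = 1000, seed) {
  if (missing(seed)) abort("A seed is required for reproducible simulation.")
  if (!is.finite(sigma) || sigma < 0) abort("sigma must be >= 0.")
  if (n_draws < 1) abort("n_draws must be >= 1.")
  withr::with_seed(seed, rlnorm(n_draws, meanlog = mu, sdlog = sigma))
}

#' Median and interquartile range of draws
#'
#' Empirical 25th, 50th and 75th percentiles using the linear-interpolation
#' convention (R quantile type 7). This convention is fixed because quartile
#' definitions differ across software.
#'
#' @param draws Numeric vector, length >= 1.
#' @return A tibble with `median`, `q1`, `q3`.
#' @export
median_iqr <- function(draws) {
  if (length(draws) == 0) abort("At least one draw is required.")
  q <- quantile(draws, probs = c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  tibble(median = q[2], q1 = q[1], q3 = q[3])
}

#' Simulate state provision distributions
#'
#' For every state and nutrient in a [summarize_states()] table, fits the
#' lognormal by moment matching and simulates `n_draws` daily provisions,
#' reporting the simulated median and interquartile range. Nutrients never
#' provided (`m = 0`) are reported as zero provision (all quantiles 0,
#' `sigma = 0`) and are not simulated; `v = 0` gives a point mass at `m`.
#'
#' @param state_summary Output of [summarize_states()].
#' @param n_draws Draws per state-nutrient (default 1000).
#' @param seed Integer seed fixing the full summary.
#' @return The input with `mu`, `sigma`, `sim_median`, `sim_q1`, `sim_q3`,
#'   `n_draws` and `seed` columns appended; class `snp_state_summary`.
#' @export
simulate_states <- function(state_summary, n_draws = 1000, seed) {
  if (missing(seed)) abort("A seed is required for reproducible simulation.")
  ss <- state_summary |>
    mutate(nutrient = factor(.data$nutrient, levels = snp_nutrients())) |>
    arrange(.data$state_id, .data$nutrient) |>
    mutate(nutrient = as.character(.data$nutrient))
  res <- withr::with_seed(seed, {
    pmap(ss[, c("m", "v")], function(m, v) {
      if (m <= 0) {
        return(tibble(mu = NA_real_, sigma = 0, sim_median = 0,
                      sim_q1 = 0, sim_q3 = 0))
      }
      par <- fit_lognormal(m, v)
      draws <- rlnorm(n_draws, meanlog = par$mu, sdlog = par$sigma)
      bind_cols(par, median_iqr(draws) |>
                  rename(sim_median = "median", sim_q1 = "q1",
                         sim_q3 = "q3"))
    }) |>
      list_rbind()
  })
  out <- bind_cols(ss, res) |>
    mutate(n_draws = n_draws, seed = seed)
  class(out) <- c("snp_state_summary", class(out))
  out
}

#' @exportS3Method generics::glance
glance.snp_state_summary <- function(x, ...) {
  tibble(
    n_states = dplyr::n_distinct(x$state_id),
    n_nutrients = dplyr::n_distinct(x$nutrient),
    n_draws = x$n_draws[1],
    seed = x$seed[1]
  )
}

#' @exportS3Method generics::tidy
tidy.snp_state_summary <- function(x, ...) {
  as_tibble(x)[, c("state_id", "nutrient", "m", "v", "n_obs", "mu", "sigma",
                   "sim_median", "sim_q1", "sim_q3")]
}
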