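#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Traffic-light adequacy plot
#'
#' Tile plot of states by rule, filled with the green/yellow/red adequacy
#' status — the machine-readable analogue of the coloured reporting table.
#'
#' @param object An `snp_adequacy` table from [evaluate_state()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.snp_adequacy <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(rule = factor(.data$rule_applied, levels = unique(.data$rule_applied)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rule, y = .data$state_id,
                                   fill = .data$status)) +
    ggplot2::geom_tile(colour = "white", linewidth = 0.4) +
    ggplot2::scale_fill_manual(values = c(
      green = "#2e7d32", yellow = "#f9a825", red = "#c62828"
    )) +
    ggplot2::facet_wrap(~standard_version) +
    ggplot2::labs(x = NULL, y = NULL, fill = "status") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Simulated provision distribution plot
#'
#' Median and interquartile range of the simulated daily provision per
#' state, faceted by nutrient on free scales.
#'
#' @param object An `snp_state_summary` from [simulate_states()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.snp_state_summary <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$state_id, y = .data$sim_median)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$sim_q1,
                                          ymax = .data$sim_q3)) +
    ggplot2::facet_wrap(~nutrient, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "simulated daily provision (median, IQR)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Food-group contribution plot
#'
#' Side-by-side bars of each food group's percentage contribution to
#' energy and to protein.
#'
#' @param shares Output of [food_group_shares()] (optionally with a
#'   `state_id` column for faceting).
#' @return A ggplot object.
#' @export
plot_food_group_shares <- function(shares) {
  df <- shares |>
    pivot_longer(c("energy_share_pct", "protein_share_pct"),
                 names_to = "what", values_to = "share") |>
    mutate(what = ifelse(.data$what == "energy_share_pct", "energy",
                         "protein"))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$share,
                                        fill = .data$what)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "% of total", fill = NULL) +
    ggplot2::theme_minimal()
  if ("state_id" %in% names(df)) {
    p <- p + ggplot2::facet_wrap(~state_id)
  }
  p
}
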