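# ggplot2 displays for the main result types.

#' Plot delivery ratios by season
#'
#' Boxplots of the district delivery ratios per season: a quick look at how
#' much of the applied nitrogen reaches the stream network and how that
#' varies seasonally.
#'
#' @param theta Tibble with `season` and `theta` columns (e.g. from
#'   [ndr_theta_table()] or a panel's distinct district x season rows).
#' @return A ggplot object.
#' @export
plot_delivery_ratios <- function(theta) {
  ggplot2::ggplot(theta, ggplot2::aes(x = factor(.data$season,
                                                 levels = season_levels()),
                                      y = .data$theta)) +
    ggplot2::geom_boxplot(fill = "steelblue", alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "delivery ratio θ",
                  title = "Fertilizer-attributable nitrogen delivery ratios") +
    ggplot2::theme_minimal()
}

#' Coefficient plot for a fitted share system
#'
#' @param object A `nitroplan_sur` fit.
#' @param ... Unused.
#' @return A ggplot object: estimates with ±2 standard-error bars, faceted
#'   by term.
#' @method autoplot nitroplan_sur
#' @export
autoplot.nitroplan_sur <- function(object, ...) {
  co <- object$coefficients |>
    dplyr::mutate(label = paste(.data$season, .data$crop, sep = "/"))
  ggplot2::ggplot(co, ggplot2::aes(x = .data$estimate, y = .data$label)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$estimate - 2 * .data$std.error,
                   xmax = .data$estimate + 2 * .data$std.error),
      height = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::facet_wrap(~term, scales = "free_x") +
    ggplot2::labs(x = "estimate", y = NULL,
                  title = "Land-use share system (SUR estimates)") +
    ggplot2::theme_minimal()
}

#' Export profile of an optimized solution
#'
#' @param object A `nitroplan_solution`.
#' @param panel The panel the solution was computed on (supplies baseline
#'   rates and delivery ratios).
#' @param ... Unused.
#' @return A ggplot object comparing baseline and optimized nitrogen export
#'   by season.
#' @method autoplot nitroplan_solution
#' @export
autoplot.nitroplan_solution <- function(object, panel, ...) {
  validate_panel(panel)
  dec <- panel |>
    dplyr::inner_join(object$decisions, by = c("district_id", "season", "crop"))
  by_season <- dplyr::bind_rows(
    dec |> dplyr::group_by(.data$season) |>
      dplyr::summarise(export = sum(.data$theta * .data$n_base *
                                      .data$share_b * .data$area),
                       .groups = "drop") |>
      dplyr::mutate(run = "baseline"),
    dec |> dplyr::group_by(.data$season) |>
      dplyr::summarise(export = sum(.data$theta * .data$n_opt * .data$l_opt),
                       .groups = "drop") |>
      dplyr::mutate(run = object$scenario)
  )
  ggplot2::ggplot(by_season,
                  ggplot2::aes(x = factor(.data$season, levels = season_levels()),
                               y = .data$export / 1e3, fill = .data$run)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "nitrogen export (t)",
                  title = sprintf("Nitrogen export by season: %s scenario",
                                  object$scenario)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
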