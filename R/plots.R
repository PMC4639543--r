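#' Plot lost productive time by headache type and stratum
#'
#' Bar chart of mean days lost per person per 3 months (paid and household
#' stacked) from a [lost_time_summary()].
#'
#' @param lost_time A tibble from [lost_time_summary()].
#' @param strata Which strata to show (default all present).
#' @return A ggplot object.
#' @export
plot_lost_time <- function(lost_time, strata = unique(lost_time$stratum)) {
  d <- lost_time |>
    dplyr::filter(.data$stratum %in% strata) |>
    tidyr::pivot_longer(
      c("paid_mean", "household_mean"),
      names_to = "component", values_to = "days"
    ) |>
    dplyr::mutate(component = sub("_mean$", "", .data$component))
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$category, y = .data$days, fill = .data$component
  )) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$stratum)) +
    ggplot2::labs(
      x = NULL, y = "Mean days lost / person / 3 months",
      fill = "Worktime", title = "Lost productive time by headache type"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot expenditure or WTP band distributions
#'
#' Stacked proportions over the four published INR bands per headache type,
#' from [expenditure_summary()] or [wtp_summary()] (total stratum).
#'
#' @param banded A tibble from [expenditure_summary()] or [wtp_summary()].
#' @return A ggplot object.
#' @export
plot_inr_bands <- function(banded) {
  d <- banded |>
    dplyr::filter(.data$stratum == "total", .data$n > 0) |>
    tidyr::pivot_longer(
      dplyr::starts_with("pct_band_"),
      names_to = "band", values_to = "pct"
    ) |>
    dplyr::mutate(band = factor(
      c(
        pct_band_le100 = "<=100", pct_band_101_500 = "101-500",
        pct_band_501_1000 = "501-1000", pct_band_gt1000 = ">1000"
      )[.data$band],
      levels = inr_band_levels()
    ))
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$category, y = .data$pct, fill = .data$band
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = NULL, y = "% of participants", fill = "INR band",
      title = "Amounts by headache type"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot a disability estimate
#'
#' Waterfall-style bar chart of the disability chain: ictal time fraction,
#' per-person disability and population-level disability.
#'
#' @param object A `disability_estimate`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.disability_estimate <- function(object, ...) {
  d <- tibble::tibble(
    step = factor(
      c("Ictal time", "Per-person disability", "Population disability"),
      levels = c("Ictal time", "Per-person disability", "Population disability")
    ),
    pct = c(object$ictal_time_pct, object$per_person_pct, object$population_pct)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$step, y = .data$pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f%%", .data$pct)), vjust = -0.4) +
    ggplot2::labs(
      x = NULL, y = "% of time / capacity",
      title = "Ictal-state disability chain"
    ) +
    ggplot2::theme_minimal()
}
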