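#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a disability estimate
#'
#' @param x A `disability_estimate` from [disability()] or
#'   [migraine_disability()].
#' @param ... Unused.
#' @return A long tibble with one row per component of the disability chain
#'   (`term`, `value`, `unit`).
#' @export
tidy.disability_estimate <- function(x, ...) {
  tibble::tibble(
    term = c(
      "mean_duration_h", "mean_days_per_year", "ictal_time_pct", "dw",
      "per_person_pct", "prevalence", "population_pct"
    ),
    value = c(
      x$mean_duration_h, x$mean_days_per_year, x$ictal_time_pct, x$dw,
      x$per_person_pct, x$prevalence, x$population_pct
    ),
    unit = c("hours", "days/year", "%", "weight", "%", "proportion", "%")
  )
}

#' Glance at a disability estimate
#'
#' @inheritParams tidy.disability_estimate
#' @return The one-row estimate tibble, unclassed.
#' @export
glance.disability_estimate <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @export
print.disability_estimate <- function(x, ...) {
  cat("<disability_estimate>\n")
  if (!is.na(x$mean_duration_h)) {
    cat(sprintf(
      "  inputs: mean duration %.1f h, %.1f headache days/year\n",
      x$mean_duration_h, x$mean_days_per_year
    ))
  }
  cat(sprintf("  ictal time fraction: %.1f %%\n", x$ictal_time_pct))
  cat(sprintf(
    "  per-person disability (dw = %.3f): %.1f %%\n", x$dw, x$per_person_pct
  ))
  cat(sprintf(
    "  population disability (prevalence %.1f %%): %.2f %%\n",
    100 * x$prevalence, x$population_pct
  ))
  invisible(x)
}
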