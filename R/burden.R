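#' Percent of available productive time lost
#'
#' HALT lost-time responses cover the preceding 3 months; annual losses are
#' obtained by multiplying the quarterly response by 4, and the available
#' productive time per person is taken as 240 working days/year (household
#' work is given the same denominator). The statistic is
#' `100 * sum(annualized days lost) / (n * working_days_year)`, equivalently
#' `100 * mean(quarterly days) * annualization / working_days_year`.
#'
#' @param days_lost_3m Numeric vector of per-person days lost in the
#'   preceding 3 months (paid + household for the total measure).
#' @param working_days_year Working days available per person per year
#'   (default 240).
#' @param annualization Quarters per year (default 4).
#' @return Percentage of available productive time lost; `NA` with a warning
#'   for an empty group (undefined, flagged).
#' @export
pct_productive_time_lost <- function(days_lost_3m, working_days_year = 240,
                                     annualization = 4) {
  days_lost_3m <- days_lost_3m[!is.na(days_lost_3m)]
  n <- length(days_lost_3m)
  if (n == 0) {
    warning("empty group: percent productive time lost is undefined", call. = FALSE)
    return(NA_real_)
  }
  100 * sum(days_lost_3m * annualization) / (n * working_days_year)
}

#' Scale a within-group percentage to the whole population
#'
#' Multiplies a percentage measured among affected people by the prevalence
#' of the affected group, giving the population-level percentage (e.g. 4.3 %
#' of productive time lost among the 63.9 % with headache is a 2.7 % loss
#' for the whole adult population).
#'
#' @param pct_among_affected Percentage among the affected group.
#' @param affected_prevalence Prevalence of the group as a proportion in
#'   `[0, 1]`.
#' @return Population-level percentage.
#' @export
population_time_lost <- function(pct_among_affected, affected_prevalence) {
  stopifnot(all(affected_prevalence >= 0 & affected_prevalence <= 1, na.rm = TRUE))
  pct_among_affected * affected_prevalence
}

#' Proportion of all time spent in the ictal state
#'
#' `(D / 24) * (F / 365) * 100` where `D` is the mean attack duration in
#' hours and `F` the mean headache days/year; one headache day is equated
#' with one attack, so durations longer than 24 h are capped at a full day
#' per headache day (with a warning).
#'
#' @param mean_duration_h Mean attack duration in hours (> 0).
#' @param mean_days_per_year Mean headache days/year in `[0, 365]`.
#' @return Percentage of all available time spent in the ictal state.
#' @export
ictal_time_fraction <- function(mean_duration_h, mean_days_per_year) {
  stopifnot(
    all(mean_duration_h > 0, na.rm = TRUE),
    all(mean_days_per_year >= 0 & mean_days_per_year <= 365, na.rm = TRUE)
  )
  if (any(mean_duration_h > 24, na.rm = TRUE)) {
    warning(
      "attack duration > 24 h capped at a full day per headache day",
      call. = FALSE
    )
    mean_duration_h <- pmin(mean_duration_h, 24)
  }
  (mean_duration_h / 24) * (mean_days_per_year / 365) * 100
}

#' Ictal-state disability estimate
#'
#' Multiplies the ictal time fraction by a disability weight to obtain
#' per-person disability, and that product by the group's prevalence to
#' obtain population-level disability. The default weight 0.433 is the
#' GBD2010 disability weight for the ictal (attack) state of migraine.
#'
#' @param ictal_pct Percentage of time spent in the ictal state (see
#'   [ictal_time_fraction()]).
#' @param dw Disability weight in `[0, 1]` (default 0.433).
#' @param prevalence Prevalence of the headache type as a proportion in
#'   `[0, 1]`.
#' @param mean_duration_h,mean_days_per_year Optional inputs recorded for
#'   provenance when the fraction was derived from cohort means.
#' @return A `disability_estimate`: a one-row tibble with
#'   `ictal_time_pct`, `dw`, `per_person_pct`, `prevalence` and
#'   `population_pct`.
#' @seealso [migraine_disability()] to compute the chain from a diagnosed
#'   cohort.
#' @export
disability <- function(ictal_pct, dw = 0.433, prevalence,
                       mean_duration_h = NA_real_,
                       mean_days_per_year = NA_real_) {
  stopifnot(dw >= 0, dw <= 1, prevalence >= 0, prevalence <= 1)
  out <- tibble::tibble(
    mean_duration_h = mean_duration_h,
    mean_days_per_year = mean_days_per_year,
    ictal_time_pct = ictal_pct,
    dw = dw,
    per_person_pct = ictal_pct * dw,
    prevalence = prevalence,
    population_pct = ictal_pct * dw * prevalence
  )
  class(out) <- c("disability_estimate", class(out))
  out
}

#' Disability chain computed from a diagnosed cohort
#'
#' Computes the category's mean attack duration and mean headache days/year,
#' converts them to the ictal time fraction and applies the disability
#' weight and prevalence (defaulting to the category's crude sample
#' prevalence, diagnosed count / cohort size).
#'
#' @param diagnosed A cohort from [diagnose_cohort()].
#' @param category Fine diagnostic category (default `"migraine"`).
#' @param dw Disability weight (default 0.433, ictal state of migraine).
#' @param prevalence Prevalence as a proportion; `NULL` uses the sample
#'   prevalence. Published age-standardised prevalences can be supplied
#'   instead.
#' @return A `disability_estimate` (see [disability()]).
#' @export
migraine_disability <- function(diagnosed, category = "migraine", dw = 0.433,
                                prevalence = NULL) {
  rows <- diagnosed[diagnosed$category == category, ]
  if (nrow(rows) == 0) {
    stop("no participants diagnosed as ", category, call. = FALSE)
  }
  if (is.null(prevalence)) prevalence <- nrow(rows) / nrow(diagnosed)
  d <- mean(rows$mean_attack_duration_h)
  f <- mean(rows$headache_days_per_month * 12)
  disability(
    ictal_time_fraction(d, f),
    dw = dw, prevalence = prevalence,
    mean_duration_h = d, mean_days_per_year = f
  )
}

headache_category_levels <- function() {
  setdiff(diagnosis_categories(), "no_headache")
}

#' Symptom burden by headache type
#'
#' Per-category summaries of headache frequency (days/year, i.e. 12 x
#' days/month) and usual intensity (1-3 numerical rating treated as
#' continuous): counts, mean, SD and median, plus intensity category counts
#' and percentages and the share of participants with attacks on >= 3
#' days (or attacks) per month. Empty categories are kept with `n = 0` and
#' undefined (`NA`) moments, flagged in the `flag` column; counts conserve
#' (`sum(n)` equals the number of participants with headache).
#'
#' @param diagnosed A cohort from [diagnose_cohort()].
#' @param ge3_basis Whether the ">= 3 per month" share counts
#'   `attacks_per_month` (default) or `headache_days_per_month`.
#' @return A tibble, one row per headache category.
#' @export
symptom_summary <- function(diagnosed, ge3_basis = c("attacks", "days")) {
  ge3_basis <- match.arg(ge3_basis)
  hx <- diagnosed[diagnosed$category != "no_headache", ]
  hx$category <- factor(as.character(hx$category), levels = headache_category_levels())
  ge3_col <- if (ge3_basis == "attacks") "attacks_per_month" else "headache_days_per_month"
  out <- hx |>
    dplyr::mutate(freq_days_year = .data$headache_days_per_month * 12) |>
    dplyr::group_by(category = .data$category, .drop = FALSE) |>
    dplyr::summarise(
      n = dplyr::n(),
      freq_mean = mean(.data$freq_days_year),
      freq_sd = stats::sd(.data$freq_days_year),
      freq_median = stats::median(.data$freq_days_year),
      n_intensity_1 = sum(.data$usual_intensity == 1),
      n_intensity_2 = sum(.data$usual_intensity == 2),
      n_intensity_3 = sum(.data$usual_intensity == 3),
      intensity_mean = mean(.data$usual_intensity),
      intensity_sd = stats::sd(.data$usual_intensity),
      intensity_median = stats::median(.data$usual_intensity),
      pct_ge3_per_month = 100 * mean(.data[[ge3_col]] >= 3),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      pct_intensity_1 = 100 * .data$n_intensity_1 / .data$n,
      pct_intensity_2 = 100 * .data$n_intensity_2 / .data$n,
      pct_intensity_3 = 100 * .data$n_intensity_3 / .data$n,
      flag = dplyr::if_else(.data$n == 0, "empty category", NA_character_)
    )
  # undefined, not zero, for empty categories
  num_cols <- c(
    "freq_mean", "freq_sd", "freq_median", "intensity_mean", "intensity_sd",
    "intensity_median", "pct_ge3_per_month",
    "pct_intensity_1", "pct_intensity_2", "pct_intensity_3"
  )
  out[out$n == 0, num_cols] <- NA_real_
  out
}

#' Lost productive time by headache type and stratum
#'
#' Per category and stratum (total, by sex, by habitation): mean, SD and
#' median of total, paid and household days lost per 3 months, and the
#' percent of all available productive time lost (see
#' [pct_productive_time_lost()]). Total days lost is paid + household per
#' participant.
#'
#' @inheritParams pct_productive_time_lost
#' @param diagnosed A cohort from [diagnose_cohort()].
#' @param by Grouping column: `"category"` (default) or
#'   `"grouped_category"`.
#' @return A tibble, one row per category x stratum.
#' @export
lost_time_summary <- function(diagnosed, by = c("category", "grouped_category"),
                              working_days_year = 240, annualization = 4) {
  by <- match.arg(by)
  hx <- diagnosed[diagnosed$category != "no_headache", ]
  hx$group <- droplevels(hx[[by]])
  hx$total_days_lost_3m <- hx$paid_days_lost_3m + hx$household_days_lost_3m

  if (nrow(hx) == 0) {
    moments <- paste0(
      rep(c("total", "paid", "household"), each = 3),
      c("_mean", "_sd", "_median")
    )
    out <- tibble::tibble(
      category = factor(character(), levels = levels(hx$group)),
      stratum = character(),
      n = integer()
    )
    for (col in c(moments, "pct_productive_time_lost")) out[[col]] <- double()
    return(out)
  }

  strata <- list(
    total = rep(TRUE, nrow(hx)),
    male = hx$sex == "male",
    female = hx$sex == "female",
    rural = hx$habitation == "rural",
    urban = hx$habitation == "urban"
  )
  summarise_stratum <- function(name, keep) {
    hx[keep, ] |>
      dplyr::group_by(category = .data$group) |>
      dplyr::summarise(
        stratum = name,
        n = dplyr::n(),
        total_mean = mean(.data$total_days_lost_3m),
        total_sd = stats::sd(.data$total_days_lost_3m),
        total_median = stats::median(.data$total_days_lost_3m),
        paid_mean = mean(.data$paid_days_lost_3m),
        paid_sd = stats::sd(.data$paid_days_lost_3m),
        paid_median = stats::median(.data$paid_days_lost_3m),
        household_mean = mean(.data$household_days_lost_3m),
        household_sd = stats::sd(.data$household_days_lost_3m),
        household_median = stats::median(.data$household_days_lost_3m),
        pct_productive_time_lost = pct_productive_time_lost(
          .data$total_days_lost_3m, working_days_year, annualization
        ),
        .groups = "drop"
      )
  }
  out <- purrr::map2_dfr(names(strata), strata, summarise_stratum)
  dplyr::arrange(
    dplyr::relocate(out, "category", "stratum"),
    .data$category,
    factor(.data$stratum, levels = names(strata))
  )
}
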