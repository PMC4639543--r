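#' Expenditure / WTP band classification
#'
#' Assigns non-negative INR amounts to the four published bands
#' (<=100, 101-500, 501-1,000, >1,000). Boundary values (100, 500, 1,000)
#' belong to the lower band, matching the printed band labels; the bands
#' partition the non-negative axis.
#'
#' @param x Numeric vector of INR amounts (>= 0).
#' @return Factor with levels `"<=100"`, `"101-500"`, `"501-1000"`,
#'   `">1000"`.
#' @export
inr_band <- function(x) {
  stopifnot(all(x >= 0, na.rm = TRUE))
  cut(
    x,
    breaks = c(-Inf, 100, 500, 1000, Inf),
    labels = c("<=100", "101-500", "501-1000", ">1000"),
    right = TRUE
  )
}

inr_band_levels <- function() c("<=100", "101-500", "501-1000", ">1000")

#' Expenditure as a share of quarterly income
#'
#' `100 * expenditure_3m / (3 * monthly_income)`: reported monthly income is
#' multiplied by three to put income on the same quarterly window as the
#' expenditure question. Zero expenditure is 0 % regardless of income;
#' otherwise a missing or zero income gives a missing share (excluded from
#' moments, never infinity), to be counted by the caller.
#'
#' @param expenditure_3m Expenditure in the preceding 3 months (INR).
#' @param monthly_income Reported monthly income (INR), possibly missing.
#' @return Numeric vector of percentages with `NA` where the share is
#'   undefined.
#' @export
income_share <- function(expenditure_3m, monthly_income) {
  out <- rep(NA_real_, length(expenditure_3m))
  zero_spend <- !is.na(expenditure_3m) & expenditure_3m == 0
  out[zero_spend] <- 0
  ok <- !is.na(expenditure_3m) & !zero_spend &
    !is.na(monthly_income) & monthly_income > 0
  out[ok] <- 100 * expenditure_3m[ok] / (3 * monthly_income[ok])
  out
}

#' Health-care consultation by headache type
#'
#' Per category: the percentage who consulted a health-care professional for
#' headache in the last year, and the distribution over consultation levels
#' conditional on having consulted. With zero consulters the level
#' distribution is undefined (`NA`, flagged).
#'
#' @param diagnosed A cohort from [diagnose_cohort()].
#' @return A tibble, one row per headache category.
#' @export
consultation_summary <- function(diagnosed) {
  hx <- diagnosed[diagnosed$category != "no_headache", ]
  hx$category <- factor(as.character(hx$category), levels = headache_category_levels())
  out <- hx |>
    dplyr::group_by(category = .data$category, .drop = FALSE) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_consulted = sum(.data$consulted_last_year),
      pct_consulted = 100 * mean(.data$consulted_last_year),
      pct_primary_care = 100 * sum(.data$consultation_level == "primary_care") /
        sum(.data$consulted_last_year),
      pct_specialist = 100 * sum(.data$consultation_level == "specialist") /
        sum(.data$consulted_last_year),
      pct_other = 100 * sum(.data$consultation_level == "other") /
        sum(.data$consulted_last_year),
      .groups = "drop"
    ) |>
    dplyr::mutate(flag = dplyr::case_when(
      .data$n == 0 ~ "empty category",
      .data$n_consulted == 0 ~ "no consulters: level distribution undefined",
      TRUE ~ NA_character_
    ))
  out$pct_consulted[out$n == 0] <- NA_real_
  level_cols <- c("pct_primary_care", "pct_specialist", "pct_other")
  out[out$n_consulted == 0, level_cols] <- NA_real_
  out
}

#' Expenditure on headache care by headache type
#'
#' Per category and stratum (total, by sex, by habitation): band
#' percentages over the four published INR bands, mean, SD and median of
#' 3-month expenditure, and expenditure as a percentage of quarterly income
#' (mean, SD, median over participants with a usable income; missing and
#' zero incomes are excluded and counted).
#'
#' @param diagnosed A cohort from [diagnose_cohort()].
#' @return A tibble, one row per category x stratum.
#' @export
expenditure_summary <- function(diagnosed) {
  banded_summary(diagnosed, "expenditure_3m", with_income_share = TRUE)
}

#' Willingness to pay by headache type
#'
#' Per category and stratum: band percentages, mean, SD and median of the
#' stated willingness to pay for effective treatment (INR).
#'
#' @param diagnosed A cohort from [diagnose_cohort()].
#' @return A tibble, one row per category x stratum.
#' @export
wtp_summary <- function(diagnosed) {
  banded_summary(diagnosed, "wtp", with_income_share = FALSE)
}

banded_summary <- function(diagnosed, var, with_income_share) {
  hx <- diagnosed[diagnosed$category != "no_headache", ]
  hx$category <- factor(as.character(hx$category), levels = headache_category_levels())
  hx$value <- hx[[var]]
  hx$band <- inr_band(hx$value)
  hx$share <- income_share(hx$expenditure_3m, hx$monthly_income)

  strata <- list(
    total = rep(TRUE, nrow(hx)),
    male = hx$sex == "male",
    female = hx$sex == "female",
    rural = hx$habitation == "rural",
    urban = hx$habitation == "urban"
  )
  one <- function(name, keep) {
    d <- hx[keep, ]
    out <- d |>
      dplyr::group_by(category = .data$category, .drop = FALSE) |>
      dplyr::summarise(
        stratum = name,
        n = dplyr::n(),
        pct_band_le100 = 100 * mean(.data$band == "<=100"),
        pct_band_101_500 = 100 * mean(.data$band == "101-500"),
        pct_band_501_1000 = 100 * mean(.data$band == "501-1000"),
        pct_band_gt1000 = 100 * mean(.data$band == ">1000"),
        mean = mean(.data$value),
        sd = stats::sd(.data$value),
        median = stats::median(.data$value),
        income_share_mean = mean(.data$share, na.rm = TRUE),
        income_share_sd = stats::sd(.data$share, na.rm = TRUE),
        income_share_median = stats::median(.data$share, na.rm = TRUE),
        n_income_excluded = sum(is.na(.data$share)),
        .groups = "drop"
      )
    num_cols <- setdiff(names(out), c("category", "stratum", "n", "n_income_excluded"))
    out[out$n == 0, num_cols] <- NA_real_
    out$flag <- dplyr::if_else(out$n == 0, "empty category", NA_character_)
    out
  }
  out <- purrr::map2_dfr(names(strata), strata, one)
  if (!with_income_share) {
    out <- dplyr::select(out, -dplyr::starts_with("income_share_"), -"n_income_excluded")
  }
  dplyr::arrange(
    dplyr::relocate(out, "category", "stratum"),
    .data$category,
    factor(.data$stratum, levels = names(strata))
  )
}

#' Ratio of willingness to pay to actual expenditure
#'
#' The published statistic is the mean of per-person WTP/expenditure ratios
#' (mean-of-ratios), not the ratio of the category means; both are reported
#' so the distinction stays visible. Participants with zero expenditure have
#' no finite ratio; by default they are excluded and counted
#' (`n_zero_expenditure`), or their expenditure can be floored at 1 INR.
#'
#' @param diagnosed A cohort from [diagnose_cohort()].
#' @param zero_expenditure Handling of zero-expenditure participants:
#'   `"exclude"` (default) or `"floor"` (substitute 1 INR).
#' @return A tibble, one row per headache category, with `ratio_mean`,
#'   `ratio_sd`, `n_ratio` (participants contributing to the ratio),
#'   `n_zero_expenditure`, and the ratio-of-means (`mean_wtp`,
#'   `mean_expenditure`, `ratio_of_means`).
#' @export
wtp_ratio_summary <- function(diagnosed, zero_expenditure = c("exclude", "floor")) {
  zero_expenditure <- match.arg(zero_expenditure)
  hx <- diagnosed[diagnosed$category != "no_headache", ]
  hx$category <- factor(as.character(hx$category), levels = headache_category_levels())
  denom <- hx$expenditure_3m
  if (zero_expenditure == "floor") denom <- pmax(denom, 1)
  hx$ratio <- ifelse(denom > 0, hx$wtp / denom, NA_real_)
  out <- hx |>
    dplyr::group_by(category = .data$category, .drop = FALSE) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_zero_expenditure = sum(.data$expenditure_3m == 0),
      n_ratio = sum(!is.na(.data$ratio)),
      ratio_mean = mean(.data$ratio, na.rm = TRUE),
      ratio_sd = stats::sd(.data$ratio, na.rm = TRUE),
      mean_wtp = mean(.data$wtp),
      mean_expenditure = mean(.data$expenditure_3m),
      ratio_of_means = mean(.data$wtp) / mean(.data$expenditure_3m),
      .groups = "drop"
    ) |>
    dplyr::mutate(flag = dplyr::case_when(
      .data$n == 0 ~ "empty category",
      .data$n_ratio == 0 ~ "all expenditures zero: ratio undefined",
      TRUE ~ NA_character_
    ))
  out$ratio_mean[out$n_ratio == 0] <- NA_real_
  out$ratio_sd[out$n_ratio == 0] <- NA_real_
  out
}
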