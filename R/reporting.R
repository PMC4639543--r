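#' Significance stars
#'
#' Star coding used in the published tables: `***` p < 0.001, `**` p < 0.01,
#' `*` p < 0.05, empty otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of star annotations.
#' @export
significance_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}

#' Compare groups with a standard significance test
#'
#' Welch two-sample t-test (`"t"`), one-way ANOVA (`"anova"`) or chi-squared
#' test of independence without continuity correction (`"chisq"`), returned
#' as a one-row tibble with the statistic, degrees of freedom, p-value and
#' star annotation. Degenerate inputs (zero variance everywhere) give a
#' flagged result rather than an exception: identical groups yield p = 1,
#' perfectly separated constant groups yield an infinite statistic and
#' p = 0.
#'
#' @param data A data frame.
#' @param value Column with the response (numeric for t/ANOVA, categorical
#'   for chi-squared), given as a tidy-eval column.
#' @param group Grouping column (>= 2 non-empty groups).
#' @param test One of `"t"`, `"anova"`, `"chisq"`.
#' @return A one-row tibble: `test`, `statistic`, `df`, `df2`, `p_value`,
#'   `groups`, `stars`, `flag`.
#' @export
compare_groups <- function(data, value, group, test = c("t", "anova", "chisq")) {
  test <- match.arg(test)
  v <- dplyr::pull(data, {{ value }})
  g <- factor(dplyr::pull(data, {{ group }}))
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]
  g <- droplevels(g[keep])
  k <- nlevels(g)
  if (k < 2 || any(table(g) == 0)) {
    stop("compare_groups needs at least 2 non-empty groups", call. = FALSE)
  }
  res <- switch(test,
    t = {
      if (k != 2) stop("t-test needs exactly 2 groups", call. = FALSE)
      x <- v[g == levels(g)[1]]
      y <- v[g == levels(g)[2]]
      if (stats::var(x) == 0 && stats::var(y) == 0) {
        if (mean(x) == mean(y)) {
          list(statistic = 0, df = length(v) - 2, p = 1, flag = "degenerate_variance")
        } else {
          list(statistic = Inf, df = length(v) - 2, p = 0, flag = "degenerate_variance")
        }
      } else {
        ht <- stats::t.test(x, y) # Welch
        list(
          statistic = unname(ht$statistic), df = unname(ht$parameter),
          p = ht$p.value, flag = NA_character_
        )
      }
    },
    anova = {
      within_var <- stats::ave(v, g, FUN = stats::var)
      if (all(within_var == 0, na.rm = TRUE)) {
        means <- tapply(v, g, mean)
        if (max(means) == min(means)) {
          list(statistic = 0, df = k - 1, df2 = length(v) - k, p = 1, flag = "degenerate_variance")
        } else {
          list(statistic = Inf, df = k - 1, df2 = length(v) - k, p = 0, flag = "degenerate_variance")
        }
      } else {
        ht <- stats::oneway.test(v ~ g, var.equal = TRUE)
        list(
          statistic = unname(ht$statistic),
          df = unname(ht$parameter[["num df"]]),
          df2 = unname(ht$parameter[["denom df"]]),
          p = ht$p.value, flag = NA_character_
        )
      }
    },
    chisq = {
      tab <- table(g, factor(v))
      if (ncol(tab) < 2) {
        list(statistic = 0, df = 0, p = 1, flag = "degenerate_variance")
      } else {
        ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
        flag <- if (any(ht$expected < 5)) "expected counts < 5" else NA_character_
        list(
          statistic = unname(ht$statistic), df = unname(ht$parameter),
          p = ht$p.value, flag = flag
        )
      }
    }
  )
  tibble::tibble(
    test = c(t = "two-sample-t", anova = "anova-F", chisq = "chi-squared")[[test]],
    statistic = res$statistic,
    df = res$df,
    df2 = res$df2 %||% NA_real_,
    p_value = res$p,
    groups = paste(levels(g), collapse = " vs "),
    stars = significance_stars(res$p),
    flag = res$flag
  )
}

#' Correlation between headache frequency and lost productivity
#'
#' Pearson correlations between annual headache frequency (days/year) and
#' annualized lost time (quarterly response x 4), separately for paid,
#' household and total lost productive time, over all participants with
#' headache.
#'
#' @param diagnosed A cohort from [diagnose_cohort()].
#' @param annualization Quarters per year (default 4).
#' @return A tibble with one row per measure: `measure`, `r`, `df`,
#'   `p_value`, `stars`, `flag`.
#' @export
frequency_loss_correlation <- function(diagnosed, annualization = 4) {
  hx <- diagnosed[diagnosed$category != "no_headache", ]
  freq <- hx$headache_days_per_month * 12
  measures <- list(
    paid = hx$paid_days_lost_3m * annualization,
    household = hx$household_days_lost_3m * annualization,
    total = (hx$paid_days_lost_3m + hx$household_days_lost_3m) * annualization
  )
  purrr::imap_dfr(measures, function(y, name) {
    if (length(freq) < 3 || stats::var(freq) == 0 || stats::var(y) == 0) {
      return(tibble::tibble(
        measure = name, r = NA_real_, df = NA_real_, p_value = NA_real_,
        stars = NA_character_, flag = "degenerate: zero variance or n < 3"
      ))
    }
    ht <- stats::cor.test(freq, y, method = "pearson")
    tibble::tibble(
      measure = name,
      r = unname(ht$estimate),
      df = unname(ht$parameter),
      p_value = ht$p.value,
      stars = significance_stars(ht$p.value),
      flag = NA_character_
    )
  })
}

#' Proportion with 95 % confidence interval
#'
#' Point estimate `count / n` with a Wilson score interval (the default; the
#' score interval is what [stats::prop.test()] computes without continuity
#' correction) or a Wald interval for strict mimicry of normal-approximation
#' reporting.
#'
#' @param count Number of successes (0 <= count <= n).
#' @param n Denominator (> 0).
#' @param method `"wilson"` (default) or `"wald"`.
#' @param conf_level Confidence level (default 0.95).
#' @return A one-row tibble: `count`, `n`, `proportion`, `pct`, `conf_low`,
#'   `conf_high`, `method` (interval bounds as proportions).
#' @export
prevalence_ci <- function(count, n, method = c("wilson", "wald"),
                          conf_level = 0.95) {
  method <- match.arg(method)
  if (n <= 0) stop("n must be positive", call. = FALSE)
  stopifnot(count >= 0, count <= n)
  p <- count / n
  if (method == "wilson") {
    ci <- stats::prop.test(count, n, correct = FALSE, conf.level = conf_level)$conf.int
  } else {
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    half <- z * sqrt(p * (1 - p) / n)
    ci <- c(max(0, p - half), min(1, p + half))
  }
  tibble::tibble(
    count = count, n = n, proportion = p, pct = 100 * p,
    conf_low = ci[1], conf_high = ci[2], method = method
  )
}

#' Bundle all burden and economics summaries of a diagnosed cohort
#'
#' Computes the six table analogues (symptom burden; lost time by stratum;
#' percent productive time lost; consultation; expenditure; WTP with the
#' WTP/expenditure ratio) plus the headache prevalence and the ictal-state
#' disability chain for migraine.
#'
#' @inheritParams lost_time_summary
#' @param dw Disability weight for the migraine ictal state.
#' @param prevalence Optional migraine prevalence (proportion) for the
#'   disability chain; default is the crude sample prevalence.
#' @return A list of class `headache_report`.
#' @export
burden_report <- function(diagnosed, dw = 0.433, prevalence = NULL,
                          working_days_year = 240, annualization = 4) {
  n <- nrow(diagnosed)
  n_hx <- sum(diagnosed$category != "no_headache")
  lost <- lost_time_summary(
    diagnosed,
    working_days_year = working_days_year, annualization = annualization
  )
  dis <- if (any(diagnosed$category == "migraine")) {
    migraine_disability(diagnosed, dw = dw, prevalence = prevalence)
  } else {
    NULL
  }
  structure(
    list(
      n = n,
      n_headache = n_hx,
      prevalence = if (n > 0) prevalence_ci(n_hx, n) else NULL,
      symptom = symptom_summary(diagnosed),
      lost_time = lost,
      pct_lost = dplyr::select(
        lost, "category", "stratum", "n", "pct_productive_time_lost"
      ),
      consultation = consultation_summary(diagnosed),
      expenditure = expenditure_summary(diagnosed),
      wtp = wtp_summary(diagnosed),
      wtp_ratio = wtp_ratio_summary(diagnosed),
      disability = dis
    ),
    class = "headache_report"
  )
}

#' Render a burden report as formatted tables
#'
#' Pure function of the report object: returns the six tables (and the
#' disability block when present) as text or pipe-separated markdown with
#' values rounded to 1 decimal place for presentation (all computation is
#' kept at full precision inside the report).
#'
#' @param report A [burden_report()].
#' @param format `"text"` (default) or `"markdown"`.
#' @return Character vector of lines, invisibly when printed.
#' @export
render_tables <- function(report, format = c("text", "markdown")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "headache_report"))
  fmt1 <- function(df) {
    df <- as.data.frame(df)
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], function(x) round(x, 1))
    df
  }
  render_df <- function(df) {
    df <- fmt1(df)
    if (nrow(df) == 0) {
      return("(empty)")
    }
    mat <- matrix("", nrow(df) + 1L, ncol(df))
    mat[1, ] <- names(df)
    for (j in seq_along(df)) {
      x <- as.character(df[[j]])
      x[is.na(x)] <- ""
      mat[-1, j] <- x
    }
    widths <- apply(nchar(mat), 2, max)
    pad <- function(row) {
      paste(
        mapply(formatC, row, width = widths),
        collapse = if (format == "markdown") " | " else "  "
      )
    }
    lines <- apply(mat, 1, pad)
    if (format == "markdown") {
      lines <- paste("|", lines, "|")
      sep <- paste("|", paste(strrep("-", widths), collapse = " | "), "|")
      lines <- c(lines[1], sep, lines[-1])
    }
    lines
  }
  sections <- list(
    "Symptom burden: headache frequency and intensity by type" = report$symptom,
    "Lost productive time (days/person/3 months) by type and stratum" = report$lost_time,
    "Percent of all productive time lost by type" = report$pct_lost,
    "Health-care consultation in the last year by type" = report$consultation,
    "Expenditure on headache care in the last 3 months (INR) by type" = report$expenditure,
    "Willingness to pay for effective treatment (INR) by type" = c(
      list(report$wtp), list(report$wtp_ratio)
    )
  )
  out <- character()
  for (title in names(sections)) {
    blk <- sections[[title]]
    out <- c(out, paste0(if (format == "markdown") "## " else "== ", title), "")
    if (is.data.frame(blk)) blk <- list(blk)
    for (df in blk) out <- c(out, render_df(df), "")
  }
  if (!is.null(report$disability)) {
    out <- c(
      out, paste0(if (format == "markdown") "## " else "== ", "Ictal-state disability (migraine)"),
      "", render_df(report$disability), ""
    )
  }
  out <- c(out, "Significance stars: *** p < 0.001; ** p < 0.01; * p < 0.05")
  out
}

#' @export
print.headache_report <- function(x, ...) {
  cat(render_tables(x, format = "text"), sep = "\n")
  invisible(x)
}
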