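# Independent straight-line re-implementation of the hierarchical rule
# table, deliberately written as nested if-else over one row at a time (no
# shared code with the registry evaluator).
oracle_diagnose_row <- function(r) {
  if (!isTRUE(r$headache_last_year)) {
    return("no_headache")
  }
  if (r$headache_days_per_month >= 15) {
    over <- (r$acute_medication_class == "simple_analgesic" &&
      r$acute_medication_days_per_month >= 15) ||
      (r$acute_medication_class == "combination_or_specific" &&
        r$acute_medication_days_per_month >= 10)
    return(if (over) "pmoh" else "other_ge15")
  }
  mig <- c(
    r$lifetime_attack_count_ge5,
    r$duration_4_to_72h,
    (r$pain_unilateral + r$pain_pulsating + r$pain_moderate_or_severe +
      r$pain_aggravated_by_activity) >= 2,
    r$nausea_or_vomiting || (r$photophobia && r$phonophobia)
  )
  tth <- c(
    r$lifetime_attack_count_ge5,
    r$duration_30min_to_7d,
    ((!r$pain_unilateral) + (!r$pain_pulsating) + (!r$pain_moderate_or_severe) +
      (!r$pain_aggravated_by_activity)) >= 2,
    (!r$nausea_or_vomiting) && (r$photophobia + r$phonophobia <= 1)
  )
  n_mig <- sum(!mig)
  n_tth <- sum(!tth)
  if (n_mig == 0) {
    "migraine"
  } else if (n_tth == 0) {
    "tth"
  } else if (n_mig == 1) {
    "probable_migraine"
  } else if (n_tth == 1) {
    "probable_tth"
  } else {
    "unclassified"
  }
}

oracle_diagnose <- function(cohort) {
  vapply(
    seq_len(nrow(cohort)),
    function(i) oracle_diagnose_row(as.list(cohort[i, ])),
    ""
  )
}

# Discretized feature grid: all combinations of the ten diagnostic booleans
# x frequency x medication patterns, embedded in otherwise-valid records.
feature_grid_cohort <- function(freqs = c(1, 5, 14, 15, 30),
                                med = list(
                                  c(0, "none"),
                                  c(15, "simple_analgesic"),
                                  c(10, "combination_or_specific")
                                )) {
  bools <- expand.grid(rep(list(c(FALSE, TRUE)), 10))
  names(bools) <- c(
    "pain_unilateral", "pain_pulsating", "pain_moderate_or_severe",
    "pain_aggravated_by_activity", "nausea_or_vomiting", "photophobia",
    "phonophobia", "lifetime_attack_count_ge5", "duration_4_to_72h",
    "duration_30min_to_7d"
  )
  cases <- tidyr::expand_grid(
    bools,
    freq = freqs,
    med_i = seq_along(med)
  )
  med_days <- as.numeric(vapply(med, `[[`, "", 1))[cases$med_i]
  med_class <- vapply(med, `[[`, "", 2)[cases$med_i]
  base <- make_participant()[rep(1, nrow(cases)), ]
  base$participant_id <- sprintf("G%06d", seq_len(nrow(cases)))
  for (col in names(bools)) base[[col]] <- cases[[col]]
  base$headache_days_per_month <- cases$freq
  base$attacks_per_month <- cases$freq
  base$acute_medication_days_per_month <- med_days
  base$acute_medication_class <- med_class
  base
}

# Naive loop-based recomputation of the per-category summaries, for exact
# oracle-equivalence checks on small cohorts.
naive_symptom_summary <- function(diagnosed, category) {
  freq <- c()
  intensity <- c()
  for (i in seq_len(nrow(diagnosed))) {
    if (as.character(diagnosed$category[i]) == category) {
      freq <- c(freq, diagnosed$headache_days_per_month[i] * 12)
      intensity <- c(intensity, diagnosed$usual_intensity[i])
    }
  }
  list(
    n = length(freq),
    freq_mean = mean(freq), freq_sd = sd(freq), freq_median = median(freq),
    intensity_mean = mean(intensity), intensity_median = median(intensity),
    n_intensity_2 = sum(intensity == 2)
  )
}

naive_pct_lost <- function(diagnosed, category) {
  tot <- 0
  n <- 0
  for (i in seq_len(nrow(diagnosed))) {
    if (as.character(diagnosed$category[i]) == category) {
      tot <- tot + (diagnosed$paid_days_lost_3m[i] +
        diagnosed$household_days_lost_3m[i]) * 4
      n <- n + 1
    }
  }
  100 * tot / (n * 240)
}

naive_consultation <- function(diagnosed, category) {
  n <- 0
  cons <- 0
  prim <- 0
  for (i in seq_len(nrow(diagnosed))) {
    if (as.character(diagnosed$category[i]) == category) {
      n <- n + 1
      if (diagnosed$consulted_last_year[i]) {
        cons <- cons + 1
        if (diagnosed$consultation_level[i] == "primary_care") prim <- prim + 1
      }
    }
  }
  list(pct_consulted = 100 * cons / n, pct_primary = 100 * prim / cons)
}

# Wilson score interval from the closed-form formula (independent of
# prop.test)
wilson_hand <- function(count, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- count / n
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  c(centre - half, centre + half)
}

# Textbook Welch statistic and p-value
welch_hand <- function(x, y) {
  se2 <- var(x) / length(x) + var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((var(x) / length(x))^2 / (length(x) - 1) +
    (var(y) / length(y))^2 / (length(y) - 1))
  list(statistic = t, df = df, p = 2 * pt(-abs(t), df))
}
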