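# Build a single valid participant row; override any field via ...
# Screen-negative participants get all headache-block fields set to NA.
make_participant <- function(participant_id = "P1", ...) {
  row <- list(
    participant_id = participant_id,
    age = 30L,
    sex = "female",
    habitation = "urban",
    monthly_income = 5000,
    headache_last_year = TRUE,
    headache_days_per_month = 2,
    attacks_per_month = 2,
    mean_attack_duration_h = 10,
    usual_intensity = 2L,
    pain_unilateral = TRUE,
    pain_pulsating = TRUE,
    pain_moderate_or_severe = TRUE,
    pain_aggravated_by_activity = FALSE,
    nausea_or_vomiting = TRUE,
    photophobia = FALSE,
    phonophobia = FALSE,
    lifetime_attack_count_ge5 = TRUE,
    duration_4_to_72h = TRUE,
    duration_30min_to_7d = TRUE,
    acute_medication_days_per_month = 2,
    acute_medication_class = "simple_analgesic",
    paid_days_lost_3m = 1,
    household_days_lost_3m = 2,
    consulted_last_year = TRUE,
    consultation_level = "primary_care",
    expenditure_3m = 100,
    wtp = 200
  )
  over <- list(...)
  row[names(over)] <- over
  if (!isTRUE(row$headache_last_year)) {
    block <- setdiff(names(row), c(
      "participant_id", "age", "sex", "habitation",
      "monthly_income", "headache_last_year"
    ))
    row[block] <- lapply(row[block], function(x) x[NA])
  }
  tibble::as_tibble(row)
}

make_cohort <- function(...) dplyr::bind_rows(...)

# A TTH-typical participant (satisfies the full TTH rule set, fails migraine)
make_tth_participant <- function(participant_id = "P1", ...) {
  make_participant(
    participant_id = participant_id,
    headache_days_per_month = 1,
    usual_intensity = 1L,
    pain_unilateral = FALSE,
    pain_pulsating = FALSE,
    pain_moderate_or_severe = FALSE,
    pain_aggravated_by_activity = FALSE,
    nausea_or_vomiting = FALSE,
    photophobia = FALSE,
    phonophobia = FALSE,
    ...
  )
}
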