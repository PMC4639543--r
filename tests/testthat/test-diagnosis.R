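test_that("chronic split precedes the episodic rule sets", {
  co <- make_cohort(
    # 20 days/month on simple analgesics 20 days/month -> overuse -> pMOH
    make_participant("C1",
      headache_days_per_month = 20,
      acute_medication_days_per_month = 20,
      acute_medication_class = "simple_analgesic"
    ),
    # 20 days/month without acute medication -> other >=15 d/m
    make_participant("C2",
      headache_days_per_month = 20,
      acute_medication_days_per_month = 0,
      acute_medication_class = "none"
    ),
    # screen-negative -> no_headache
    make_participant("C3", headache_last_year = FALSE),
    # migraine-perfect features but >=15 d/m: never an episodic category
    make_participant("C4",
      headache_days_per_month = 15,
      acute_medication_days_per_month = 0,
      acute_medication_class = "none"
    )
  )
  dx <- diagnose_cohort(co)
  expect_equal(
    as.character(dx$category),
    c("pmoh", "other_ge15", "no_headache", "other_ge15")
  )
  expect_equal(
    as.character(dx$grouped_category),
    c("ge15_any", "ge15_any", "no_headache", "ge15_any")
  )
})

test_that("episodic rule sets classify textbook presentations", {
  co <- make_cohort(
    # 2 d/m, 4-72 h, unilateral+pulsating+moderate, nausea, >=5 attacks
    make_participant("D1"),
    # classic TTH: bilateral, non-pulsating, mild, no migrainous symptoms
    make_tth_participant("D2"),
    # migraine missing one criterion (no associated symptoms) -> probable
    make_participant("D3",
      nausea_or_vomiting = FALSE, photophobia = FALSE, phonophobia = FALSE,
      pain_aggravated_by_activity = TRUE
    ),
    # TTH-featured but episodes too short (< 30 min): TTH misses only its
    # duration criterion while migraine misses two -> probable TTH
    make_tth_participant("D4",
      mean_attack_duration_h = 0.2,
      duration_4_to_72h = FALSE, duration_30min_to_7d = FALSE
    ),
    # fails >=2 criteria of both rule sets -> unclassified
    make_participant("D5",
      lifetime_attack_count_ge5 = FALSE,
      duration_4_to_72h = FALSE, duration_30min_to_7d = FALSE,
      mean_attack_duration_h = 0.2
    )
  )
  dx <- diagnose_cohort(co)
  expect_equal(
    as.character(dx$category),
    c("migraine", "tth", "probable_migraine", "probable_tth", "unclassified")
  )
  expect_equal(
    as.character(dx$grouped_category),
    c("all_migraine", "all_tth", "all_migraine", "all_tth", "unclassified")
  )
})

test_that("hierarchical precedence: full migraine wins over any TTH variant, and ties go to probable migraine", {
  # satisfies migraine fully AND the TTH B/C criteria
  both <- make_participant("E1",
    pain_unilateral = TRUE, pain_pulsating = TRUE,
    pain_moderate_or_severe = FALSE, pain_aggravated_by_activity = FALSE,
    nausea_or_vomiting = TRUE
  )
  dx <- diagnose_cohort(both)
  expect_equal(as.character(dx$category), "migraine")

  # fails migraine by one (duration) and TTH by one (nausea): the stated
  # evaluation order puts probable migraine first
  tie <- make_participant("E2",
    mean_attack_duration_h = 3,
    duration_4_to_72h = FALSE, duration_30min_to_7d = TRUE,
    pain_unilateral = TRUE, pain_pulsating = TRUE,
    pain_moderate_or_severe = FALSE, pain_aggravated_by_activity = FALSE,
    nausea_or_vomiting = TRUE
  )
  dx2 <- diagnose_cohort(tie)
  expect_equal(as.character(dx2$category), "probable_migraine")
})

test_that("overuse thresholds are class-specific", {
  f <- function(days, class) {
    make_participant(
      acute_medication_days_per_month = days,
      acute_medication_class = class
    )
  }
  expect_true(overuse(f(15, "simple_analgesic")))
  expect_false(overuse(f(14, "simple_analgesic")))
  expect_true(overuse(f(10, "combination_or_specific")))
  expect_false(overuse(f(9, "combination_or_specific")))
  expect_false(overuse(f(0, "none")))
  expect_false(overuse(f(30, "none"))) # class none never overuses
})

test_that("diagnosis is total, deterministic and matches the straight-line oracle on the feature grid", {
  grid <- feature_grid_cohort()
  dx <- diagnose_cohort(grid)
  # exactly one category per point, never NA
  expect_false(anyNA(dx$category))
  expect_true(all(as.character(dx$category) %in% setdiff(
    levels(dx$category), "no_headache"
  )))
  # oracle equivalence
  expect_equal(as.character(dx$category), oracle_diagnose(grid))
  # determinism
  dx2 <- diagnose_cohort(grid)
  expect_identical(dx$category, dx2$category)
})

test_that("invalid features raise a validation error, never a silent unclassified", {
  bad <- make_participant(usual_intensity = 7L)
  expect_error(diagnose_cohort(bad), "usual_intensity")
  bad2 <- make_participant(headache_days_per_month = 40)
  expect_error(diagnose_cohort(bad2), "headache_days_per_month")
})

test_that("audit trail suffices to re-derive the category", {
  co <- make_cohort(
    make_participant("F1"),
    make_participant("F2",
      headache_days_per_month = 20,
      acute_medication_days_per_month = 20
    ),
    make_participant("F3",
      lifetime_attack_count_ge5 = FALSE,
      duration_4_to_72h = FALSE, duration_30min_to_7d = FALSE,
      mean_attack_duration_h = 0.2
    )
  )
  dx <- diagnose_cohort(co)

  # migraine report names the pain-feature and associated-symptom predicates
  rep1 <- explain_diagnosis(dx, "F1")
  expect_match(rep1[1], "migraine$")
  expect_true(any(grepl("pain_features_ge2", rep1)))
  expect_true(any(grepl("associated_symptoms", rep1)))
  # an episodic win is not audited against rule sets further down the order
  expect_false(any(grepl("tth\\.", rep1)))

  # pMOH report shows the chronic-frequency and overuse predicates only
  rep2 <- explain_diagnosis(dx, "F2")
  expect_match(rep2[1], "pmoh$")
  expect_true(any(grepl("\\[TRUE\\] chronic_ge15", rep2)))
  expect_true(any(grepl("\\[TRUE\\] overuse", rep2)))
  expect_false(any(grepl("migraine\\.", rep2)))

  # unclassified report shows all four episodic rule sets failed
  rep3 <- explain_diagnosis(dx, "F3")
  expect_match(rep3[1], "unclassified$")
  expect_true(any(grepl("migraine\\.", rep3)))
  expect_true(any(grepl("tth\\.", rep3)))
  expect_true(any(grepl("\\[FALSE\\] probable_migraine", rep3)))
  expect_true(any(grepl("\\[FALSE\\] probable_tth", rep3)))

  expect_error(explain_diagnosis(dx, "NOPE"), "unknown participant")
})

test_that("criteria registry loads, prints and validates", {
  reg <- ichd2_criteria()
  expect_s3_class(reg, "criteria_registry")
  expect_equal(reg$chronic_days_per_month, 15)
  expect_equal(reg$overuse$thresholds$simple_analgesic, 15)
  expect_equal(reg$overuse$thresholds$combination_or_specific, 10)
  expect_output(print(reg), "chronic threshold")
  # a registry missing mandatory fields is rejected
  tmp <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(rule_sets = list()), tmp)
  expect_error(ichd2_criteria(tmp), "missing field")
})
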