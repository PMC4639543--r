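test_that("percent productive time lost annualizes the quarterly HALT window", {
  # mean quarterly losses map to annual percentages of a 240-day work year
  expect_equal(round(pct_productive_time_lost(rep(3.5, 10)), 1), 5.8)
  expect_equal(round(pct_productive_time_lost(rep(13.9, 4)), 1), 23.2)
  expect_equal(pct_productive_time_lost(rep(0, 25)), 0)
  expect_equal(pct_productive_time_lost(rep(60, 7)), 100) # 60 x 4 = 240
  expect_warning(out <- pct_productive_time_lost(numeric(0)), "undefined")
  expect_true(is.na(out))
  # equals 100 * mean * 4 / 240 on unequal inputs too
  x <- c(0, 0, 2, 9, 30)
  expect_equal(pct_productive_time_lost(x), 100 * mean(x) * 4 / 240)
})

test_that("population scaling multiplies the affected-group percentage by prevalence", {
  expect_equal(round(population_time_lost(4.3, 0.639), 1), 2.7)
  expect_equal(round(population_time_lost(5.8, 0.252), 1), 1.5)
  expect_equal(population_time_lost(12.3, 0), 0)
  expect_error(population_time_lost(5, 1.5))
})

test_that("ictal time fraction follows (D/24)(F/365)*100 with a 24 h cap", {
  expect_equal(round(ictal_time_fraction(13.1, 28), 1), 4.2)
  expect_equal(ictal_time_fraction(24, 365), 100)
  expect_equal(ictal_time_fraction(12, 0), 0)
  expect_warning(capped <- ictal_time_fraction(30, 100), "capped")
  expect_equal(capped, ictal_time_fraction(24, 100))
  expect_error(ictal_time_fraction(-1, 10))
  expect_error(ictal_time_fraction(10, 400))
})

test_that("disability chain multiplies fraction, weight and prevalence", {
  est <- disability(ictal_time_fraction(13.1, 28), dw = 0.433, prevalence = 597 / 2329)
  expect_equal(round(est$per_person_pct, 1), 1.8)
  expect_equal(round(est$population_pct, 2), 0.46)
  expect_equal(disability(10, 0, 0.5)$per_person_pct, 0)
  expect_equal(disability(10, 0, 0.5)$population_pct, 0)
  est2 <- disability(10, 0.5, 0.5)
  expect_equal(est2$per_person_pct, 5)
  expect_equal(est2$population_pct, 2.5)
  expect_error(disability(10, 1.5, 0.5))
  # broom-style accessors expose the chain
  td <- tidy(est)
  expect_equal(td$value[td$term == "population_pct"], est$population_pct)
  expect_equal(nrow(glance(est)), 1L)
})

test_that("monotonicity of the burden maps holds across the valid domain", {
  withr::local_seed(421)
  d <- runif(25, 0.5, 24)
  f <- runif(25, 1, 365)
  eps <- 1e-6
  expect_true(all(ictal_time_fraction(d + eps, f) > ictal_time_fraction(d, f)))
  expect_true(all(ictal_time_fraction(d, f + eps) > ictal_time_fraction(d, f)))
  dw <- runif(25)
  prev <- runif(25)
  for (i in 2:25) {
    a <- disability(5, sort(dw)[i], 0.5)
    b <- disability(5, sort(dw)[i - 1], 0.5)
    expect_gte(a$per_person_pct, b$per_person_pct)
    a2 <- disability(5, 0.4, sort(prev)[i])
    b2 <- disability(5, 0.4, sort(prev)[i - 1])
    expect_gte(a2$population_pct, b2$population_pct)
  }
})

test_that("pooled percent lost equals the n-weighted mean of subgroup percentages", {
  withr::local_seed(77)
  for (rep in 1:5) {
    days <- round(rexp(120, 1 / 3), 1)
    part <- sample(1:4, 120, replace = TRUE)
    pooled <- pct_productive_time_lost(days)
    sub <- vapply(1:4, function(g) pct_productive_time_lost(days[part == g]), 1)
    ns <- tabulate(part, 4)
    expect_equal(pooled, sum(sub * ns) / sum(ns))
  }
})

test_that("symptom summary handles single records and preserves counts", {
  co <- make_cohort(
    make_participant("S1", headache_days_per_month = 2, usual_intensity = 2L),
    make_tth_participant("S2", usual_intensity = 1L),
    make_tth_participant("S3", usual_intensity = 3L),
    make_participant("S4", headache_last_year = FALSE)
  )
  ss <- symptom_summary(diagnose_cohort(co))
  mig <- ss[ss$category == "migraine", ]
  expect_equal(mig$n, 1L)
  expect_equal(mig$freq_mean, 24)
  expect_equal(mig$freq_median, 24)
  expect_equal(mig$intensity_mean, 2)
  tth <- ss[ss$category == "tth", ]
  expect_equal(tth$intensity_mean, 2) # {1, 3} -> mean 2
  expect_equal(tth$intensity_median, 2)
  # counts conserve and empty categories are flagged with undefined moments
  expect_equal(sum(ss$n), 3L)
  empty <- ss[ss$category == "pmoh", ]
  expect_equal(empty$n, 0L)
  expect_true(is.na(empty$freq_mean))
  expect_equal(empty$flag, "empty category")
})

test_that("all summaries match a naive loop-based recomputation exactly on a small cohort", {
  co <- generate_cohort(cohort_spec(n = 50, seed = 8))
  dx <- diagnose_cohort(co)
  ss <- symptom_summary(dx)
  lt <- lost_time_summary(dx)
  cs <- consultation_summary(dx)
  for (cat in unique(as.character(dx$category))) {
    if (cat == "no_headache") next
    naive <- naive_symptom_summary(dx, cat)
    row <- ss[ss$category == cat, ]
    expect_identical(row$n, as.integer(naive$n))
    expect_equal(row$freq_mean, naive$freq_mean)
    expect_equal(row$freq_sd, naive$freq_sd)
    expect_equal(row$freq_median, naive$freq_median)
    expect_equal(row$intensity_mean, naive$intensity_mean)
    expect_equal(row$n_intensity_2, as.integer(naive$n_intensity_2))

    lt_row <- lt[lt$category == cat & lt$stratum == "total", ]
    expect_equal(lt_row$pct_productive_time_lost, naive_pct_lost(dx, cat))
    expect_equal(
      lt_row$total_mean,
      mean(dx$paid_days_lost_3m[dx$category == cat] +
        dx$household_days_lost_3m[dx$category == cat])
    )

    nc <- naive_consultation(dx, cat)
    cs_row <- cs[cs$category == cat, ]
    expect_equal(cs_row$pct_consulted, nc$pct_consulted)
    if (cs_row$n_consulted > 0) {
      expect_equal(cs_row$pct_primary_care, nc$pct_primary)
    }
  }
})

test_that("lost-time summary reports total = paid + household and strata rows", {
  co <- make_cohort(
    make_participant("L1", sex = "male", paid_days_lost_3m = 2, household_days_lost_3m = 3),
    make_participant("L2", sex = "female", habitation = "rural", paid_days_lost_3m = 0, household_days_lost_3m = 6)
  )
  lt <- lost_time_summary(diagnose_cohort(co))
  tot <- lt[lt$category == "migraine" & lt$stratum == "total", ]
  expect_equal(tot$total_mean, mean(c(5, 6)))
  expect_equal(tot$paid_mean + tot$household_mean, tot$total_mean)
  expect_setequal(
    lt$stratum[lt$category == "migraine"],
    c("total", "male", "female", "rural", "urban")
  )
  male <- lt[lt$category == "migraine" & lt$stratum == "male", ]
  expect_equal(male$n, 1L)
  expect_equal(male$total_mean, 5)
})

test_that("cohort-derived migraine disability chain composes the same arithmetic", {
  co <- make_cohort(
    make_participant("M1", mean_attack_duration_h = 13.1, headache_days_per_month = 28 / 12),
    make_participant("M2", headache_last_year = FALSE),
    make_participant("M3", headache_last_year = FALSE),
    make_participant("M4", headache_last_year = FALSE)
  )
  dx <- diagnose_cohort(co)
  est <- migraine_disability(dx)
  expect_equal(est$prevalence, 0.25)
  expect_equal(est$ictal_time_pct, ictal_time_fraction(13.1, 28))
  expect_equal(est$population_pct, est$ictal_time_pct * 0.433 * 0.25)
  # explicit published prevalence can be substituted
  est2 <- migraine_disability(dx, prevalence = 0.252)
  expect_equal(est2$population_pct, est2$per_person_pct * 0.252)
  expect_error(migraine_disability(dx, category = "pmoh"), "no participants")
})
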