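#' Generate a synthetic survey cohort
#'
#' Draws a participant-level cohort with the statistical structure described
#' by a [cohort_spec()]: demographics, headache screening, per-type
#' diagnostic features that are internally consistent with the latent type
#' (a record generated as migraine satisfies the full migraine rule set; a
#' pMOH record has >=15 headache days/month and medication days at or above
#' the class overuse threshold; "other_ge15" is chronic without overuse),
#' zero-inflated quarterly lost time with female>male and rural>urban
#' gradients, and banded expenditure/WTP responses.
#'
#' Generation is deterministic given `spec$seed`; all randomness flows from
#' that single seed and the caller's RNG state is left untouched. The latent
#' type of every participant is attached to the result and can be recovered
#' with [latent_labels()] or [label_of()].
#'
#' @param spec A [cohort_spec()].
#' @return A validated cohort tibble of `spec$n` rows carrying a
#'   `latent_type` attribute.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  spec <- validate_cohort_spec(spec)
  n <- spec$n
  empty <- empty_cohort()
  if (n == 0) {
    attr(empty, "latent_type") <- stats::setNames(character(), character())
    attr(empty, "cohort_spec") <- spec
    return(empty)
  }

  cohort <- withr::with_seed(spec$seed, {
    df <- tibble::tibble(
      participant_id = sprintf("S%05d", seq_len(n)),
      age = as.integer(round(rtnorm(n, spec$age$mean, spec$age$sd, 17.51, 65.49))),
      sex = sample(names(spec$sex_split), n, replace = TRUE, prob = spec$sex_split),
      habitation = sample(
        names(spec$habitation_split), n,
        replace = TRUE, prob = spec$habitation_split
      ),
      monthly_income = round(stats::rlnorm(n, spec$income$meanlog, spec$income$sdlog))
    )
    df$monthly_income[stats::runif(n) < spec$income$p_missing] <- NA_real_
    p_hx <- spec$p_headache_by_sex[df$sex]
    df$headache_last_year <- stats::runif(n) < p_hx

    for (col in c(feature_cols(), lost_time_cols(), economics_cols())) {
      df[[col]] <- rep(empty[[col]][NA], n)
    }

    latent <- rep("no_headache", n)
    idx_hx <- which(df$headache_last_year)
    if (length(idx_hx) > 0) {
      latent[idx_hx] <- sample(
        names(spec$type_mixture), length(idx_hx),
        replace = TRUE, prob = spec$type_mixture
      )
      for (ty in headache_types()) {
        rows <- which(latent == ty)
        if (length(rows) == 0) next
        blk <- simulate_type_block(
          ty, length(rows), spec,
          sex = df$sex[rows], habitation = df$habitation[rows]
        )
        for (col in names(blk)) df[[col]][rows] <- blk[[col]]
      }
      if (spec$boundary_noise > 0) {
        episodic <- which(latent %in% c("migraine", "tth"))
        hit <- episodic[stats::runif(length(episodic)) < spec$boundary_noise]
        # knocking out the attack-count indicator demotes a full rule set to
        # its probable variant without touching any other criterion
        df$lifetime_attack_count_ge5[hit] <- FALSE
      }
    }
    attr(df, "latent") <- latent
    df
  })

  latent <- attr(cohort, "latent")
  attr(cohort, "latent") <- NULL
  cohort <- validate_cohort(cohort)
  attr(cohort, "latent_type") <- stats::setNames(latent, cohort$participant_id)
  attr(cohort, "cohort_spec") <- spec
  cohort
}

empty_cohort <- function() {
  tibble::tibble(
    participant_id = character(),
    age = integer(),
    sex = character(),
    habitation = character(),
    monthly_income = double(),
    headache_last_year = logical(),
    headache_days_per_month = double(),
    attacks_per_month = double(),
    mean_attack_duration_h = double(),
    usual_intensity = integer(),
    pain_unilateral = logical(),
    pain_pulsating = logical(),
    pain_moderate_or_severe = logical(),
    pain_aggravated_by_activity = logical(),
    nausea_or_vomiting = logical(),
    photophobia = logical(),
    phonophobia = logical(),
    lifetime_attack_count_ge5 = logical(),
    duration_4_to_72h = logical(),
    duration_30min_to_7d = logical(),
    acute_medication_days_per_month = double(),
    acute_medication_class = character(),
    paid_days_lost_3m = double(),
    household_days_lost_3m = double(),
    consulted_last_year = logical(),
    consultation_level = character(),
    expenditure_3m = double(),
    wtp = double()
  )
}

# Simulate the feature / lost-time / economics block for m participants of a
# single latent type. Vectorized; assumes the RNG is already seeded.
simulate_type_block <- function(type, m, spec, sex, habitation) {
  tp <- spec$types[[type]]

  # -- headache frequency ----------------------------------------------------
  if (tp$freq$kind == "episodic") {
    size <- nbinom_size(tp$freq$mean_year, tp$freq$sd_year)
    days_year <- pmin(pmax(stats::rnbinom(m, size = size, mu = tp$freq$mean_year), 1), 179)
    days_pm <- days_year / 12
    freq_ref <- tp$freq$mean_year
  } else if (tp$freq$kind == "chronic") {
    sd_pm <- tp$freq$sd_year / 12
    mu_pm <- tnorm_location(tp$freq$mean_year / 12, sd_pm, 15, 30)
    days_pm <- rtnorm(m, mu_pm, sd_pm, 15, 30)
    days_year <- days_pm * 12
    freq_ref <- tp$freq$mean_year
  } else { # sparse: infrequent short-lived headaches
    days_pm <- sample(1:5, m, replace = TRUE)
    days_year <- days_pm * 12
    freq_ref <- 36
  }

  # -- attack duration -------------------------------------------------------
  if (!is.null(tp$duration$fixed)) {
    duration <- rep(tp$duration$fixed, m)
  } else {
    sigma <- lnorm_sigma_from_cv(tp$duration$mean, tp$duration$sd)
    mu <- tlnorm_location(tp$duration$mean, sigma, tp$duration$lo, tp$duration$hi)
    duration <- rtlnorm(m, mu, sigma, tp$duration$lo, tp$duration$hi)
  }

  intensity <- sample(1:3, m, replace = TRUE, prob = tp$intensity_probs)

  pain_uni <- stats::runif(m) < tp$pain[["unilateral"]]
  pain_pul <- stats::runif(m) < tp$pain[["pulsating"]]
  pain_mod <- intensity >= 2
  pain_agg <- stats::runif(m) < tp$pain[["aggravated"]]
  p_nausea <- if ("nausea" %in% names(tp$assoc)) tp$assoc[["nausea"]] else 0
  nausea <- stats::runif(m) < p_nausea
  photo <- stats::runif(m) < tp$assoc[["photophobia"]]
  phono <- stats::runif(m) < tp$assoc[["phonophobia"]]

  ge5 <- rep(TRUE, m)
  d4_72 <- duration >= 4 & duration <= 72
  d30m_7d <- duration >= 0.5 & duration <= 168

  if (type == "migraine") {
    # enforce the full migraine rule set (C: >=2 pain features; D: nausea or
    # photo+phono); A and B hold by construction of duration and ge5
    short <- (pain_uni + pain_pul + pain_mod + pain_agg) < 2
    pain_uni[short] <- TRUE
    pain_pul[short] <- TRUE
    no_assoc <- !nausea & !(photo & phono)
    nausea[no_assoc] <- TRUE
  } else if (type == "tth") {
    # enforce the full TTH rule set and failure of migraine criterion D
    nausea <- rep(FALSE, m)
    both <- photo & phono
    phono[both] <- FALSE
    few_inverse <- (!pain_uni) + (!pain_pul) + (!pain_mod) + (!pain_agg) < 2
    pain_uni[few_inverse] <- FALSE
    pain_pul[few_inverse] <- FALSE
  } else if (type == "unclassified") {
    # fails >=2 criteria of both episodic rule sets: no attack-count
    # indicator and out-of-window duration
    ge5 <- rep(FALSE, m)
    d4_72 <- rep(FALSE, m)
    d30m_7d <- rep(FALSE, m)
  }

  # -- acute medication ------------------------------------------------------
  med_class <- sample(
    names(tp$med$class_probs), m,
    replace = TRUE, prob = tp$med$class_probs
  )
  med_days <- numeric(m)
  thresholds <- c(simple_analgesic = 15, combination_or_specific = 10)
  if (type == "pmoh") {
    # at or above the class-specific overuse threshold, never beyond the
    # days actually affected
    for (cl in names(thresholds)) {
      i <- med_class == cl
      lo <- thresholds[[cl]]
      hi <- pmax(floor(days_pm[i]), lo)
      med_days[i] <- lo + floor(stats::runif(sum(i)) * (hi - lo + 1))
    }
  } else {
    # strictly below the overuse threshold
    for (cl in names(thresholds)) {
      i <- med_class == cl
      cap <- pmin(floor(days_pm[i]), thresholds[[cl]] - 1)
      med_days[i] <- floor(stats::runif(sum(i)) * (cap + 1))
    }
  }
  med_days[med_class == "none"] <- 0
  med_days <- pmin(med_days, 30)

  # -- lost productive time --------------------------------------------------
  sex_mult <- ifelse(sex == "female", spec$lost_time_mult[["female"]], 1)
  hab_mult <- ifelse(habitation == "rural", spec$lost_time_mult[["rural"]], 1)
  sex_norm <- sum(spec$sex_split * c(1, spec$lost_time_mult[["female"]])[
    1 + (names(spec$sex_split) == "female")
  ])
  hab_norm <- sum(spec$habitation_split * c(1, spec$lost_time_mult[["rural"]])[
    1 + (names(spec$habitation_split) == "rural")
  ])
  freq_mult <- 0.5 + 0.5 * days_year / freq_ref
  mult <- sex_mult * hab_mult * freq_mult / (sex_norm * hab_norm)

  draw_lost <- function(par) {
    mean_nz <- if (par[["p_zero"]] < 1) par[["mean"]] / (1 - par[["p_zero"]]) else 0
    nz <- stats::runif(m) >= par[["p_zero"]]
    out <- numeric(m)
    if (mean_nz > 0 && any(nz)) {
      out[nz] <- round(stats::rexp(sum(nz), rate = 1 / (mean_nz * mult[nz])))
    }
    pmin(out, 92)
  }
  paid <- draw_lost(tp$lost$paid)
  household <- draw_lost(tp$lost$household)

  # -- economics -------------------------------------------------------------
  consulted <- stats::runif(m) < tp$consult$p
  level <- rep("none", m)
  if (any(consulted)) {
    level[consulted] <- sample(
      names(tp$consult$levels), sum(consulted),
      replace = TRUE, prob = tp$consult$levels
    )
  }
  expenditure <- draw_banded(m, tp$expenditure_bands, p_zero_band1 = 0.35)
  wtp <- draw_banded(m, tp$wtp_bands, p_zero_band1 = 0.15)

  tibble::tibble(
    headache_days_per_month = days_pm,
    attacks_per_month = days_pm,
    mean_attack_duration_h = duration,
    usual_intensity = as.integer(intensity),
    pain_unilateral = pain_uni,
    pain_pulsating = pain_pul,
    pain_moderate_or_severe = pain_mod,
    pain_aggravated_by_activity = pain_agg,
    nausea_or_vomiting = nausea,
    photophobia = photo,
    phonophobia = phono,
    lifetime_attack_count_ge5 = ge5,
    duration_4_to_72h = d4_72,
    duration_30min_to_7d = d30m_7d,
    acute_medication_days_per_month = med_days,
    acute_medication_class = med_class,
    paid_days_lost_3m = paid,
    household_days_lost_3m = household,
    consulted_last_year = consulted,
    consultation_level = level,
    expenditure_3m = expenditure,
    wtp = wtp
  )
}

# Draw INR amounts from the four published bands (<=100, 101-500, 501-1000,
# >1000) with uniform within-band values and a lognormal tail above 1000.
draw_banded <- function(m, band_weights, p_zero_band1 = 0) {
  band <- sample(1:4, m, replace = TRUE, prob = band_weights)
  out <- numeric(m)
  i1 <- band == 1
  out[i1] <- ifelse(
    stats::runif(sum(i1)) < p_zero_band1, 0,
    round(stats::runif(sum(i1), 1, 100))
  )
  out[band == 2] <- round(stats::runif(sum(band == 2), 101, 500))
  out[band == 3] <- round(stats::runif(sum(band == 3), 501, 1000))
  i4 <- band == 4
  out[i4] <- round(1000 + stats::rlnorm(sum(i4), log(400), 1))
  out
}

#' Latent type labels of a synthetic cohort
#'
#' The generator records the latent headache type used for each simulated
#' participant; these accessors recover it for diagnosis-recovery checks.
#' Cohorts not produced by [generate_cohort()] (or stripped of the attribute
#' by data-frame surgery) raise a lookup error.
#'
#' @param cohort A cohort tibble from [generate_cohort()].
#' @return `latent_labels()`: a tibble with `participant_id` and
#'   `latent_type`; `label_of()`: a character vector of labels, one per
#'   requested id.
#' @export
latent_labels <- function(cohort) {
  lab <- attr(cohort, "latent_type", exact = TRUE)
  if (is.null(lab)) {
    stop(
      "lookup error: cohort carries no latent type labels ",
      "(not produced by generate_cohort())",
      call. = FALSE
    )
  }
  tibble::tibble(participant_id = names(lab), latent_type = unname(lab))
}

#' @rdname latent_labels
#' @param participant_id Participant identifier(s) to look up.
#' @export
label_of <- function(cohort, participant_id) {
  lab <- latent_labels(cohort)
  i <- match(participant_id, lab$participant_id)
  if (anyNA(i)) {
    stop(
      "lookup error: unknown participant id(s): ",
      paste(participant_id[is.na(i)], collapse = ", "),
      call. = FALSE
    )
  }
  lab$latent_type[i]
}
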