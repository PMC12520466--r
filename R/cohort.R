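#' Configuration for the synthetic pediatric cohort generator
#'
#' Bundles and validates the data-generating parameters of
#' [generate_cohort()]. Demographic defaults follow the typical composition
#' of a pediatric differentiated thyroid cancer treatment series: ages 11–20
#' (truncated normal, mean 16.6, SD 2.3), 65% female, weights 35–135 kg.
#' Weight is coupled linearly to age with noise so that prepubertal patients
#' occupy the low-weight tail; the default intercept/slope/SD give a cohort
#' weight distribution of roughly 57 ± 18 kg before clipping to the stated
#' range — centred on the mean implied by weight-proportional dose summaries
#' in such cohorts, with an age-conditional spread typical of the second
#' decade of life.
#'
#' Kinetics and measurement noise are synthetic with a physical rationale:
#' effective half-life lognormal with median 15 h and geometric SD 1.3
#' (λ = ln 2 / T1/2); exposure-rate readings at 1 m generated from the
#' retained activity with a body-attenuated dose-rate constant of 0.03
#' μSv/h per MBq (the unshielded I-131 point-source constant is ≈0.052
#' μSv·m²/(MBq·h)); multiplicative lognormal reading noise with CV 0.10.
#'
#' @param n_patients Number of patients (≥ 2).
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @param age_mean,age_sd,age_range Age distribution (years), truncated to
#'   `age_range`.
#' @param p_female Probability of female sex.
#' @param weight_range Weight clip range (kg).
#' @param weight_intercept,weight_slope,weight_sd Linear age–weight coupling:
#'   weight = intercept + slope × age + N(0, sd), clipped to `weight_range`.
#' @param half_life_median_h,half_life_gsd Lognormal effective half-life
#'   (hours): median and geometric SD.
#' @param reading_times_h Times of the two exposure-rate readings (h).
#' @param dose_rate_constant μSv/h at 1 m per MBq retained.
#' @param reading_noise_cv Coefficient of variation of the multiplicative
#'   lognormal reading noise (0 disables noise).
#' @param risk_mix Named probabilities over risk strata (must sum to 1).
#' @param p_rhtsh Probability of rhTSH preparation (vs withdrawal).
#' @param prepubertal_age Age below which patients are flagged prepubertal.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 20,
                          seed = 1L,
                          age_mean = 16.6,
                          age_sd = 2.3,
                          age_range = c(11, 20),
                          p_female = 0.65,
                          weight_range = c(35, 135),
                          weight_intercept = -10,
                          weight_slope = 4,
                          weight_sd = 15,
                          half_life_median_h = 15,
                          half_life_gsd = 1.3,
                          reading_times_h = c(2, 67),
                          dose_rate_constant = 0.03,
                          reading_noise_cv = 0.10,
                          risk_mix = c(therapy = 0.70, adjuvant = 0.20,
                                       metastatic = 0.10),
                          p_rhtsh = 0.75,
                          prepubertal_age = 14) {
  cfg <- list(
    n_patients = as.integer(n_patients), seed = as.integer(seed),
    age_mean = age_mean, age_sd = age_sd, age_range = age_range,
    p_female = p_female, weight_range = weight_range,
    weight_intercept = weight_intercept, weight_slope = weight_slope,
    weight_sd = weight_sd, half_life_median_h = half_life_median_h,
    half_life_gsd = half_life_gsd, reading_times_h = reading_times_h,
    dose_rate_constant = dose_rate_constant,
    reading_noise_cv = reading_noise_cv, risk_mix = risk_mix,
    p_rhtsh = p_rhtsh, prepubertal_age = prepubertal_age
  )
  if (cfg$n_patients < 2) {
    rlang::abort("n_patients must be at least 2",
                 class = "bloodmta_error_validation")
  }
  if (abs(sum(risk_mix) - 1) > 1e-8 || any(risk_mix < 0)) {
    rlang::abort("risk_mix must be non-negative and sum to 1",
                 class = "bloodmta_error_validation")
  }
  if (is.null(names(risk_mix)) || any(!nzchar(names(risk_mix)))) {
    rlang::abort("risk_mix must be a named vector of strata",
                 class = "bloodmta_error_validation")
  }
  for (rng in list(cfg$age_range, cfg$weight_range, cfg$reading_times_h)) {
    if (length(rng) != 2 || diff(rng) <= 0) {
      rlang::abort("Ranges and reading times must be increasing pairs",
                   class = "bloodmta_error_validation")
    }
  }
  if (cfg$p_female < 0 || cfg$p_female > 1 ||
      cfg$p_rhtsh < 0 || cfg$p_rhtsh > 1) {
    rlang::abort("p_female and p_rhtsh must lie in [0, 1]",
                 class = "bloodmta_error_validation")
  }
  if (cfg$reading_noise_cv < 0) {
    rlang::abort("reading_noise_cv must be non-negative",
                 class = "bloodmta_error_validation")
  }
  check_positive(cfg$age_sd, "age_sd")
  check_positive(cfg$weight_sd, "weight_sd")
  check_positive(cfg$half_life_median_h, "half_life_median_h")
  if (cfg$half_life_gsd <= 1) {
    rlang::abort("half_life_gsd must exceed 1",
                 class = "bloodmta_error_validation")
  }
  check_positive(cfg$dose_rate_constant, "dose_rate_constant")
  structure(cfg, class = "cohort_config")
}

#' Generate a synthetic pediatric cohort with known kinetics
#'
#' Simulates patients, one administration per patient at the empirical tier
#' for their risk stratum, and two timed exposure-rate readings per
#' administration:
#' \itemize{
#'   \item ages truncated-normal within range; weights age-coupled with
#'     noise, clipped to range; sex, risk stratum and preparation sampled
#'     from the configured probabilities;
#'   \item per-patient true effective half-life drawn lognormal, giving
#'     λ_true and mono-exponential retention R(t) = exp(−λ_true t);
#'   \item readings at the configured times:
#'     rate = dose_rate_constant × A0 × R(t) × lognormal noise (CV as
#'     configured; exactly R(t) when the CV is 0).
#' }
#' The true kinetics are returned alongside so parameter-recovery can be
#' verified. The same seed reproduces the cohort exactly.
#'
#' @param config A [cohort_config()].
#' @return A list of class `rai_cohort` with tibbles `patients`
#'   (patient_id, sex, age_years, weight_kg, prepubertal, risk_stratum,
#'   dutch_category), `administrations` (patient_id, course_index,
#'   activity_mbq, preparation), `readings` (patient_id, course_index,
#'   time_h, rate_usv_h) and `truth` (patient_id, half_life_h,
#'   lambda_true_per_h, tau_true_h).
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 5, seed = 7))
#' cohort$patients
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  withr::with_seed(config$seed, {
    n <- config$n_patients
    ids <- sprintf("S%03d", seq_len(n))

    # truncated normal via inverse-CDF so draws stay inside the range
    plo <- stats::pnorm(config$age_range[1], config$age_mean, config$age_sd)
    phi <- stats::pnorm(config$age_range[2], config$age_mean, config$age_sd)
    age <- stats::qnorm(stats::runif(n, plo, phi),
                        config$age_mean, config$age_sd)

    weight <- config$weight_intercept + config$weight_slope * age +
      stats::rnorm(n, 0, config$weight_sd)
    weight <- pmin(pmax(weight, config$weight_range[1]),
                   config$weight_range[2])

    sex <- ifelse(stats::runif(n) < config$p_female, "female", "male")
    risk <- sample(names(config$risk_mix), n, replace = TRUE,
                   prob = config$risk_mix)
    dutch_cat <- dplyr::case_match(risk,
      "metastatic" ~ "t4_m1",
      "therapy" ~ "t3b_n1",
      .default = "uncapped"
    )
    preparation <- ifelse(stats::runif(n) < config$p_rhtsh,
                          "rhtsh", "withdrawal")

    half_life <- exp(stats::rnorm(n, log(config$half_life_median_h),
                                  log(config$half_life_gsd)))
    lambda_true <- log(2) / half_life

    patients <- tibble::tibble(
      patient_id = ids, sex = sex, age_years = age, weight_kg = weight,
      prepubertal = age < config$prepubertal_age,
      risk_stratum = risk, dutch_category = dutch_cat
    )
    administrations <- tibble::tibble(
      patient_id = ids, course_index = 1L,
      activity_mbq = mci_to_mbq(empirical_dose(risk)),
      preparation = preparation
    )
    truth <- tibble::tibble(
      patient_id = ids, half_life_h = half_life,
      lambda_true_per_h = lambda_true, tau_true_h = 1 / lambda_true
    )

    readings <- tidyr::crossing(
      tibble::tibble(patient_id = ids, activity_mbq = administrations$activity_mbq,
                     lambda = lambda_true),
      time_h = config$reading_times_h
    ) |>
      dplyr::arrange(.data$patient_id, .data$time_h)
    noise <- if (config$reading_noise_cv > 0) {
      sdlog <- sqrt(log1p(config$reading_noise_cv^2))
      exp(stats::rnorm(nrow(readings), -sdlog^2 / 2, sdlog))
    } else {
      1
    }
    readings <- readings |>
      dplyr::mutate(
        course_index = 1L,
        rate_usv_h = config$dose_rate_constant * .data$activity_mbq *
          exp(-.data$lambda * .data$time_h) * noise
      ) |>
      dplyr::select("patient_id", "course_index", "time_h", "rate_usv_h")

    structure(
      list(patients = patients, administrations = administrations,
           readings = readings, truth = truth, config = config),
      class = "rai_cohort"
    )
  })
}

#' @export
print.rai_cohort <- function(x, ...) {
  cat(sprintf(
    "<rai_cohort> %d patients, %d administrations, %d readings (seed %d)\n",
    nrow(x$patients), nrow(x$administrations), nrow(x$readings),
    x$config$seed
  ))
  invisible(x)
}

#' Frozen synthetic reference cohort
#'
#' A fixed 20-patient cohort whose categorical composition mirrors a
#' published pediatric differentiated thyroid cancer treatment series:
#' 13 female / 7 male; 4 prepubertal (< 14 y); nodal status N0/N1a/N1b =
#' 6/4/10; 15 rhTSH / 5 withdrawal preparations; outcomes
#' remission/recurrence/persistent = 16/3/1; 16 single-course and 4
#' two-course patients; 24 administrations with the activity distribution
#' 50/100/120/150/200 mCi = 1/6/2/14/1.
#'
#' Only these categorical marginals are anchored to real cohort structure.
#' **Ages and weights are fabricated** (synthetic values within the plausible
#' 35–135 kg, 11–20 y ranges, with prepubertal patients in the low-weight
#' tail); no row corresponds to a real person, and the table must not be
#' used as patient data. No kinetic readings are included — pair with
#' [generate_cohort()] kinetics for end-to-end runs.
#'
#' @return A list with tibbles `patients` and `administrations`.
#' @examples
#' ref <- reference_cohort()
#' table(ref$patients$outcome)
#' mean(ref$administrations$activity_mci)  # 132.9 mCi over 24 treatments
#' @export
reference_cohort <- function() {
  patients <- tibble::tibble(
    patient_id = sprintf("P%02d", 1:20),
    sex = c("female", "female", "female", "female", "male", "male",
            "female", "male", "female", "female", "male", "female",
            "female", "male", "female", "male", "female", "female",
            "female", "male"),
    age_years = c(11, 18, 17, 16, 12, 13, 13, 14, 15, 15,
                  16, 16, 17, 17, 18, 18, 19, 19, 20, 20),
    weight_kg = c(35.4, 62, 55, 58, 38, 42, 40, 50, 52, 57,
                  61, 54, 66, 72, 59, 78, 63, 68, 135, 85),
    prepubertal = c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE,
                    rep(FALSE, 13)),
    nodal_status = c("N1b", "N0", "N1b", "N1b", "N0", "N1a", "N1a", "N1a",
                     "N1b", "N1b", "N1a", "N1b", "N1b", "N0", "N1b", "N0",
                     "N1b", "N1b", "N0", "N0"),
    risk_stratum = c("therapy", "therapy", "therapy", "therapy", "adjuvant",
                     rep("therapy", 15)),
    dutch_category = c("t3b_n1", "t4_m1", "t3b_n1", "t3b_n1", "uncapped",
                       "t3b_n1", "t3b_n1", "t3b_n1", "t3b_n1", "t3b_n1",
                       "t3b_n1", "t3b_n1", "t3b_n1", "uncapped", "t3b_n1",
                       "uncapped", "t3b_n1", "t3b_n1", "uncapped",
                       "uncapped"),
    preparation = c("rhtsh", "rhtsh", "rhtsh", "withdrawal", "rhtsh",
                    "rhtsh", "rhtsh", "rhtsh", "rhtsh", "rhtsh",
                    "withdrawal", "rhtsh", "rhtsh", "withdrawal", "rhtsh",
                    "withdrawal", "rhtsh", "rhtsh", "rhtsh", "withdrawal"),
    outcome = c("persistent", "recurrence", "recurrence", "recurrence",
                rep("remission", 16))
  )

  first_mci <- c(120, 150, 100, 150, 50, 100, 120, 100, 100, 150,
                 100, 150, 150, 150, 150, 150, 150, 150, 150, 100)
  second <- tibble::tibble(
    patient_id = c("P01", "P02", "P03", "P04"),
    course_index = 2L,
    activity_mci = c(150, 200, 150, 150)
  )
  administrations <- dplyr::bind_rows(
    tibble::tibble(patient_id = patients$patient_id, course_index = 1L,
                   activity_mci = first_mci),
    second
  ) |>
    dplyr::left_join(
      dplyr::select(patients, "patient_id", "preparation"),
      by = "patient_id"
    ) |>
    dplyr::mutate(activity_mbq = mci_to_mbq(.data$activity_mci)) |>
    dplyr::arrange(.data$patient_id, .data$course_index)

  list(patients = patients, administrations = administrations)
}
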