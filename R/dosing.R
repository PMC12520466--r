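#' Empirical risk-stratified activity
#'
#' Fixed-activity prescription by risk stratum, the practice at most
#' treatment centres: remnant ablation 30 mCi, adjuvant therapy 50–75 mCi,
#' therapy 100–150 mCi, metastatic palliative therapy 150–200 mCi. Strata
#' spanning a range collapse to single configurable defaults (the modal or
#' midpoint value); the multidisciplinary case-by-case adjustment that real
#' teams apply on top is deliberately not modelled — this is a lookup table.
#' Vectorised.
#'
#' @param risk_stratum Character vector drawn from the names of `tiers`.
#' @param tiers Named numeric vector of mCi defaults per stratum.
#' @return Activity in mCi.
#' @examples
#' empirical_dose(c("ablation", "therapy"))
#' @export
empirical_dose <- function(risk_stratum,
                           tiers = c(ablation = 30, adjuvant = 50,
                                     therapy = 150, metastatic = 200)) {
  check_positive(tiers, "tiers")
  unknown <- setdiff(unique(risk_stratum), names(tiers))
  if (length(unknown)) {
    rlang::abort(
      paste0("Unknown risk stratum: ", paste(unknown, collapse = ", ")),
      class = "bloodmta_error_validation"
    )
  }
  unname(tiers[risk_stratum])
}

#' Body-weight-based activity
#'
#' Linear scaling of an adult reference activity by weight:
#' weight / 70 kg × adult dose, uncapped. On a pediatric cohort spanning
#' 35–135 kg this scales the adult dose by 0.5–1.9, which is the wide
#' variability that motivates weight-independent strategies. Vectorised.
#'
#' @param weight_kg Body weight in kg, > 0.
#' @param adult_dose_mci Adult reference activity in mCi, > 0.
#' @param reference_weight_kg Adult reference weight (kg), default 70.
#' @return Activity in mCi.
#' @examples
#' bw_based_dose(35, 150)  # 75 mCi
#' @export
bw_based_dose <- function(weight_kg, adult_dose_mci,
                          reference_weight_kg = 70) {
  check_positive(weight_kg, "weight_kg")
  check_positive(adult_dose_mci, "adult_dose_mci")
  check_positive(reference_weight_kg, "reference_weight_kg")
  weight_kg / reference_weight_kg * adult_dose_mci
}

#' Dutch 100 MBq/kg pediatric recommendation
#'
#' Raw activity of 100 MBq/kg, capped by disease category: 5550 MBq for
#' T3b/N1, 7400 MBq for T4/M1, no cap for other (`"uncapped"`) patients.
#' The cap label is recorded only when it actually reduces the raw dose.
#' The rule is computed for any patient regardless of pubertal status — the
#' recommendation scopes it to the prepubertal subgroup, and the caller
#' decides whom to apply it to. Vectorised.
#'
#' @param weight_kg Body weight in kg, > 0.
#' @param dutch_category `"t3b_n1"`, `"t4_m1"` or `"uncapped"`.
#' @param constants A [dosimetry_constants()] object (supplies the rate and
#'   caps).
#' @return A tibble with `strategy`, `raw_activity_mbq`,
#'   `final_activity_mbq`, `cap_applied` (NA when no cap binds).
#' @examples
#' dutch_dose(c(35.4, 80), c("t3b_n1", "t3b_n1"))
#' @export
dutch_dose <- function(weight_kg, dutch_category,
                       constants = dosimetry_constants()) {
  check_positive(weight_kg, "weight_kg")
  n <- max(length(weight_kg), length(dutch_category))
  weight_kg <- rep_len(weight_kg, n)
  dutch_category <- rep_len(as.character(dutch_category), n)
  unknown <- setdiff(unique(dutch_category), c("t3b_n1", "t4_m1", "uncapped"))
  if (length(unknown)) {
    rlang::abort(
      paste0("Unknown Dutch category: ", paste(unknown, collapse = ", ")),
      class = "bloodmta_error_validation"
    )
  }
  raw <- constants$dutch_rate * weight_kg
  cap <- dplyr::case_match(
    dutch_category,
    "t3b_n1" ~ constants$dutch_cap_t3bn1,
    "t4_m1" ~ constants$dutch_cap_t4m1,
    "uncapped" ~ Inf
  )
  final <- pmin(raw, cap)
  tibble::tibble(
    strategy = "dutch",
    raw_activity_mbq = raw,
    final_activity_mbq = final,
    cap_applied = dplyr::if_else(
      final < raw,
      dplyr::case_match(dutch_category,
                        "t3b_n1" ~ "dutch_t3bn1",
                        "t4_m1" ~ "dutch_t4m1"),
      NA_character_
    )
  )
}

#' Cap a proposed activity at the patient's maximum tolerated activity
#'
#' The as-high-as-safe-administration (AHASA) adjustment: the proposed
#' activity is reduced to the patient's maximum tolerated activity whenever
#' it exceeds it, and never increased — safety constraints cap, they do not
#' escalate beyond the clinically chosen tier. The binding MTA constraint
#' (blood dose or 48-h whole-body retention) is recorded when a reduction
#' occurs. Vectorised.
#'
#' @param proposed_mbq Proposed activity in MBq, > 0.
#' @param mta A data frame from [max_tolerated_activity()] (columns
#'   `a_max_mbq` and `binding_constraint`), recycled against the proposal.
#' @return A tibble with `strategy = "ahasa_adjusted"`, `raw_activity_mbq`,
#'   `final_activity_mbq`, `cap_applied` (`"mta_blood"`, `"mta_benua"` or NA).
#' @examples
#' mta <- max_tolerated_activity(0.19, log(20) / 65)
#' ahasa_adjust(7400, mta)
#' @export
ahasa_adjust <- function(proposed_mbq, mta) {
  check_positive(proposed_mbq, "proposed_mbq")
  if (!all(c("a_max_mbq", "binding_constraint") %in% names(mta))) {
    rlang::abort("mta needs a_max_mbq and binding_constraint columns",
                 class = "bloodmta_error_validation")
  }
  n <- max(length(proposed_mbq), nrow(mta))
  proposed <- rep_len(proposed_mbq, n)
  a_max <- rep_len(mta$a_max_mbq, n)
  binding <- rep_len(mta$binding_constraint, n)
  final <- pmin(proposed, a_max)
  tibble::tibble(
    strategy = "ahasa_adjusted",
    raw_activity_mbq = proposed,
    final_activity_mbq = final,
    cap_applied = dplyr::if_else(
      final < proposed,
      dplyr::case_match(binding, "blood" ~ "mta_blood",
                        "benua_wb" ~ "mta_benua"),
      NA_character_
    )
  )
}

#' Plan activities for a cohort under a prescription strategy
#'
#' Data-frame-first planner producing one recommendation per patient under
#' one of four strategies:
#' \describe{
#'   \item{empirical}{risk-stratified fixed tier ([empirical_dose()]).}
#'   \item{bw}{weight/70 kg × adult dose ([bw_based_dose()]).}
#'   \item{dutch}{100 MBq/kg with category caps ([dutch_dose()]).}
#'   \item{ahasa}{the empirical tier capped at the patient-specific maximum
#'     tolerated activity, which requires `readings` (and uses first-course
#'     kinetics).}
#' }
#'
#' @param patients Data frame with `patient_id`, `weight_kg`, and
#'   `risk_stratum` / `dutch_category` as required by the strategy.
#' @param strategy One of `"empirical"`, `"bw"`, `"dutch"`, `"ahasa"`.
#' @param readings Exposure-rate readings, needed for `"ahasa"`.
#' @param adult_dose_mci Adult reference activity for `"bw"` (mCi).
#' @param constants A [dosimetry_constants()] object.
#' @param limit_gy Blood-dose limit for the AHASA MTA (Gy).
#' @return A tibble with `patient_id`, `strategy`, `raw_activity_mbq`,
#'   `final_activity_mbq`, `final_activity_mci`, `cap_applied`.
#' @export
plan_doses <- function(patients,
                       strategy = c("empirical", "bw", "dutch", "ahasa"),
                       readings = NULL, adult_dose_mci = 150,
                       constants = dosimetry_constants(),
                       limit_gy = constants$conservative_estimated_limit) {
  strategy <- match.arg(strategy)
  patients <- tibble::as_tibble(patients)
  if (!"patient_id" %in% names(patients)) {
    rlang::abort("patients needs a patient_id column",
                 class = "bloodmta_error_validation")
  }
  if (!nrow(patients)) {
    rlang::abort("patients is empty", class = "bloodmta_error_validation")
  }

  rec <- switch(strategy,
    empirical = {
      raw <- mci_to_mbq(empirical_dose(patients$risk_stratum))
      tibble::tibble(strategy = "empirical", raw_activity_mbq = raw,
                     final_activity_mbq = raw, cap_applied = NA_character_)
    },
    bw = {
      raw <- mci_to_mbq(bw_based_dose(
        patients$weight_kg, adult_dose_mci,
        reference_weight_kg = constants$adult_reference_weight
      ))
      tibble::tibble(strategy = "bw_based", raw_activity_mbq = raw,
                     final_activity_mbq = raw, cap_applied = NA_character_)
    },
    dutch = dutch_dose(patients$weight_kg, patients$dutch_category,
                       constants),
    ahasa = {
      if (is.null(readings)) {
        rlang::abort("strategy = 'ahasa' requires readings",
                     class = "bloodmta_error_validation")
      }
      fits <- fit_retention(readings) |>
        dplyr::filter(.data$course_index == min(.data$course_index),
                      .by = "patient_id")
      df <- dplyr::inner_join(patients, fits, by = "patient_id")
      if (nrow(df) < nrow(patients)) {
        missing_ids <- setdiff(patients$patient_id, df$patient_id)
        rlang::abort(
          paste0("Missing readings for patient(s): ",
                 paste(missing_ids, collapse = ", ")),
          class = "bloodmta_error_validation"
        )
      }
      bvl <- estimate_blood_volume(
        df$weight_kg,
        sex = if ("sex" %in% names(df)) df$sex else NULL,
        height_cm = if ("height_cm" %in% names(df)) df$height_cm else NULL,
        blood_volume_ml = if ("blood_volume_ml" %in% names(df)) {
          df$blood_volume_ml
        } else {
          NULL
        },
        ml_per_kg = constants$blood_ml_per_kg
      )
      d <- blood_dose_coefficient(df$weight_kg, bvl, df$tau_h, constants)
      mta <- max_tolerated_activity(d, df$lambda_eff_per_h, constants,
                                    limit_gy)
      proposed <- mci_to_mbq(empirical_dose(df$risk_stratum))
      out <- ahasa_adjust(proposed, mta)
      out$patient_id <- df$patient_id
      out
    }
  )

  if (!"patient_id" %in% names(rec)) rec$patient_id <- patients$patient_id
  rec |>
    dplyr::mutate(final_activity_mci = mbq_to_mci(.data$final_activity_mbq)) |>
    dplyr::select("patient_id", "strategy", "raw_activity_mbq",
                  "final_activity_mbq", "final_activity_mci", "cap_applied")
}
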