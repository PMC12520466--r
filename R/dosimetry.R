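#' Estimate patient blood volume
#'
#' Blood volume enters the beta self-dose term of the blood dose coefficient.
#' Three methods, in order of precedence per patient:
#' \enumerate{
#'   \item an explicitly supplied `blood_volume_ml` is passed through;
#'   \item with height and sex available, Nadler's regression equations
#'     (male: 0.3669 H\[m\]^3 + 0.03219 W + 0.6041 L;
#'      female: 0.3561 H^3 + 0.03308 W + 0.1833 L);
#'   \item otherwise a per-weight fallback of `ml_per_kg` mL/kg (default 70;
#'     pediatric references of 75–80 mL/kg can be configured).
#' }
#' Vectorised over patients.
#'
#' @param weight_kg Body weight(s) in kg, > 0.
#' @param sex Optional `"female"`/`"male"` vector (required for Nadler).
#' @param height_cm Optional height(s) in cm; NA falls back to per-kg.
#' @param blood_volume_ml Optional known blood volume(s) in mL; NA ignored.
#' @param ml_per_kg Per-weight fallback (mL/kg).
#' @return Blood volume(s) in mL.
#' @examples
#' estimate_blood_volume(50, sex = "female", height_cm = 160)  # ~3296 mL
#' estimate_blood_volume(60)                                   # 4200 mL
#' @export
estimate_blood_volume <- function(weight_kg, sex = NULL, height_cm = NULL,
                                  blood_volume_ml = NULL, ml_per_kg = 70) {
  check_positive(weight_kg, "weight_kg")
  check_positive(ml_per_kg, "ml_per_kg")
  n <- length(weight_kg)
  if (is.null(sex)) sex <- rep(NA_character_, n)
  if (is.null(height_cm)) height_cm <- rep(NA_real_, n)
  if (is.null(blood_volume_ml)) blood_volume_ml <- rep(NA_real_, n)
  sex <- rep_len(as.character(sex), n)
  height_cm <- rep_len(height_cm, n)
  blood_volume_ml <- rep_len(blood_volume_ml, n)
  if (any(height_cm <= 0, na.rm = TRUE)) {
    rlang::abort("height_cm must be strictly positive",
                 class = "bloodmta_error_validation")
  }
  if (any(blood_volume_ml <= 0, na.rm = TRUE)) {
    rlang::abort("blood_volume_ml must be strictly positive",
                 class = "bloodmta_error_validation")
  }
  bad_sex <- !is.na(sex) & !sex %in% c("female", "male")
  if (any(bad_sex)) {
    rlang::abort("sex must be 'female' or 'male'",
                 class = "bloodmta_error_validation")
  }

  h_m <- height_cm / 100
  nadler <- ifelse(
    sex == "male",
    0.3669 * h_m^3 + 0.03219 * weight_kg + 0.6041,
    0.3561 * h_m^3 + 0.03308 * weight_kg + 0.1833
  ) * 1000

  out <- ml_per_kg * weight_kg
  use_nadler <- !is.na(height_cm) & !is.na(sex)
  out[use_nadler] <- nadler[use_nadler]
  out[!is.na(blood_volume_ml)] <- blood_volume_ml[!is.na(blood_volume_ml)]
  out
}

#' Blood absorbed-dose coefficient per unit administered activity
#'
#' The simplified compartment estimator of the mean blood absorbed dose per
#' unit administered I-131 activity:
#'
#' \deqn{d = \left(\frac{15.12}{BVL} + \frac{0.0188}{wt^{2/3}}\right)\,\tau}
#'
#' in mGy/MBq (numerically equal to Gy/GBq), where BVL is the blood volume in
#' mL, wt the body weight in kg and τ the whole-body residence time in hours
#' (τ = −t / ln R(t), positive since ln R(t) < 0). The first term is the beta
#' self-dose to blood — 15.12 = 108 × 0.14, the 14% blood share of whole-body
#' residence time — and the second the photon whole-body contribution.
#' Vectorised.
#'
#' @param weight_kg Body weight in kg, > 0.
#' @param blood_volume_ml Blood volume in mL, > 0.
#' @param tau_h Whole-body residence time in hours, ≥ 0.
#' @param constants A [dosimetry_constants()] object.
#' @return Coefficient d = D_blood/A0 in mGy/MBq.
#' @examples
#' blood_dose_coefficient(60, 4200, 21.70)  # ~0.105 mGy/MBq
#' @export
blood_dose_coefficient <- function(weight_kg, blood_volume_ml, tau_h,
                                   constants = dosimetry_constants()) {
  check_positive(weight_kg, "weight_kg")
  check_positive(blood_volume_ml, "blood_volume_ml")
  check_nonnegative(tau_h, "tau_h")
  (constants$beta_self_factor / blood_volume_ml +
     constants$photon_factor / weight_kg^(2 / 3)) * tau_h
}

#' Total blood absorbed dose for an administration
#'
#' D_blood = d × A0 / 1000, converting mGy to Gy. Vectorised.
#'
#' @param coefficient_mgy_per_mbq Blood dose coefficient d (mGy/MBq), ≥ 0.
#' @param activity_mbq Administered activity A0 (MBq), ≥ 0.
#' @return Total blood dose in Gy.
#' @examples
#' total_blood_dose(0.19, 5550)  # 1.05 Gy (to two decimals)
#' @export
total_blood_dose <- function(coefficient_mgy_per_mbq, activity_mbq) {
  check_nonnegative(coefficient_mgy_per_mbq, "coefficient_mgy_per_mbq")
  check_nonnegative(activity_mbq, "activity_mbq")
  coefficient_mgy_per_mbq * activity_mbq / 1000
}

#' Flag blood doses against the safety limits
#'
#' Adds (or overwrites) two inclusive flags on a blood-dose table:
#' `within_conservative_limit` (total ≤ 1.3 Gy, the tightened limit for the
#' estimated dose, which already encodes the ~0.67 estimated-to-actual ratio)
#' and `within_actual_limit` (total ≤ 2 Gy, compared directly). Comparisons
#' are inclusive because the limits are stated as doses not to be exceeded.
#'
#' @param results A data frame with a `total_dose_gy` column.
#' @param constants A [dosimetry_constants()] object.
#' @return The input as a tibble with both logical flags set.
#' @export
check_safety <- function(results, constants = dosimetry_constants()) {
  if (!"total_dose_gy" %in% names(results)) {
    rlang::abort("results must contain a total_dose_gy column",
                 class = "bloodmta_error_validation")
  }
  tibble::as_tibble(results) |>
    dplyr::mutate(
      within_conservative_limit =
        .data$total_dose_gy <= constants$conservative_estimated_limit,
      within_actual_limit =
        .data$total_dose_gy <= constants$actual_blood_limit
    )
}

#' Maximum tolerated activity under blood-dose and 48-h retention limits
#'
#' Two classical constraints bound the administrable activity:
#' \itemize{
#'   \item blood dose: A ≤ limit × 1000 / d (MBq), so the estimated blood
#'     dose stays at or below `limit_gy`;
#'   \item 48-h whole-body retention: A ≤ 4440 / R(48) MBq, so the retained
#'     activity at 48 h stays at or below 4.4 GBq.
#' }
#' The maximum tolerated activity is the smaller of the two; the binding
#' constraint is named. (The historical 3 GBq lung limit at 24 h is carried
#' in the constants but requires lung-uptake data this pipeline does not
#' model.) Vectorised over coefficients and decay constants.
#'
#' @param coefficient_mgy_per_mbq Blood dose coefficient d (mGy/MBq), > 0.
#' @param lambda_eff_per_h Effective decay constant λ (per hour), > 0.
#' @param constants A [dosimetry_constants()] object.
#' @param limit_gy Blood-dose limit in Gy (default the conservative 1.3 Gy
#'   estimated-dose limit).
#' @return A tibble with `a_max_blood_mbq`, `a_max_benua_mbq`, `a_max_mbq`
#'   and `binding_constraint` (`"blood"` or `"benua_wb"`).
#' @examples
#' max_tolerated_activity(0.19, log(20) / 65, limit_gy = 2)
#' @export
max_tolerated_activity <- function(coefficient_mgy_per_mbq, lambda_eff_per_h,
                                   constants = dosimetry_constants(),
                                   limit_gy = constants$conservative_estimated_limit) {
  check_positive(coefficient_mgy_per_mbq, "coefficient_mgy_per_mbq")
  check_positive(lambda_eff_per_h, "lambda_eff_per_h")
  check_positive(limit_gy, "limit_gy")
  a_blood <- limit_gy * 1000 / coefficient_mgy_per_mbq
  a_benua <- constants$benua_wb_48h_limit / exp(-48 * lambda_eff_per_h)
  tibble::tibble(
    a_max_blood_mbq = a_blood,
    a_max_benua_mbq = a_benua,
    a_max_mbq = pmin(a_blood, a_benua),
    binding_constraint = ifelse(a_blood <= a_benua, "blood", "benua_wb")
  )
}

#' Per-administration blood dosimetry pipeline
#'
#' Runs the full dosimetry chain for every administration: fit the two-point
#' retention model from the readings, estimate blood volume, compute the
#' blood dose coefficient and total dose, flag the safety limits, and derive
#' the maximum tolerated activity.
#'
#' @param patients Data frame with `patient_id`, `weight_kg` and optionally
#'   `sex`, `height_cm`, `blood_volume_ml`.
#' @param administrations Data frame with `patient_id`, `activity_mbq` and
#'   optionally `course_index` (default 1) and `preparation`
#'   (`"rhtsh"`/`"withdrawal"`).
#' @param readings Data frame of exposure-rate readings; see
#'   [fit_retention()].
#' @param constants A [dosimetry_constants()] object.
#' @param limit_gy Blood-dose limit used for the MTA (default conservative
#'   1.3 Gy).
#' @param rhtsh_only If `TRUE`, restrict to administrations prepared with
#'   rhTSH before computing (dosimetry series are commonly reported for the
#'   rhTSH-stimulated subgroup only).
#' @return A tibble with one row per administration: `patient_id`,
#'   `course_index`, `activity_mbq`, `lambda_eff_per_h`, `tau_h`, `bvl_ml`,
#'   `coefficient_mgy_per_mbq`, `total_dose_gy`, the two safety flags,
#'   `a_max_mbq` and `binding_constraint`.
#' @export
blood_dosimetry <- function(patients, administrations, readings,
                            constants = dosimetry_constants(),
                            limit_gy = constants$conservative_estimated_limit,
                            rhtsh_only = FALSE) {
  patients <- tibble::as_tibble(patients)
  administrations <- tibble::as_tibble(administrations)
  for (col in c("patient_id", "weight_kg")) {
    if (!col %in% names(patients)) {
      rlang::abort(paste0("patients is missing column: ", col),
                   class = "bloodmta_error_validation")
    }
  }
  if (!all(c("patient_id", "activity_mbq") %in% names(administrations))) {
    rlang::abort("administrations needs patient_id and activity_mbq columns",
                 class = "bloodmta_error_validation")
  }
  if (!"course_index" %in% names(administrations)) {
    administrations$course_index <- 1L
  }
  if (rhtsh_only) {
    if (!"preparation" %in% names(administrations)) {
      rlang::abort("rhtsh_only requires a preparation column",
                   class = "bloodmta_error_validation")
    }
    administrations <- dplyr::filter(administrations,
                                     .data$preparation == "rhtsh")
    if (!nrow(administrations)) {
      rlang::abort("No rhTSH-prepared administrations to analyse",
                   class = "bloodmta_error_validation")
    }
    keep <- paste(administrations$patient_id, administrations$course_index)
    readings <- dplyr::filter(
      readings, paste(.data$patient_id, .data$course_index) %in% keep
    )
  }

  fits <- fit_retention(readings)

  missing_fit <- dplyr::anti_join(administrations, fits,
                                  by = c("patient_id", "course_index"))
  if (nrow(missing_fit)) {
    ids <- paste0(missing_fit$patient_id, "/", missing_fit$course_index,
                  collapse = ", ")
    rlang::abort(
      paste0("Missing readings for administration(s): ", ids),
      class = "bloodmta_error_validation"
    )
  }

  pat_cols <- intersect(
    c("patient_id", "weight_kg", "sex", "height_cm", "blood_volume_ml"),
    names(patients)
  )
  df <- administrations |>
    dplyr::inner_join(fits, by = c("patient_id", "course_index")) |>
    dplyr::inner_join(dplyr::select(patients, dplyr::all_of(pat_cols)),
                      by = "patient_id")

  df$bvl_ml <- estimate_blood_volume(
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

  df <- df |>
    dplyr::mutate(
      coefficient_mgy_per_mbq = blood_dose_coefficient(
        .data$weight_kg, .data$bvl_ml, .data$tau_h, constants
      ),
      total_dose_gy = total_blood_dose(.data$coefficient_mgy_per_mbq,
                                       .data$activity_mbq)
    ) |>
    check_safety(constants)

  mta <- max_tolerated_activity(df$coefficient_mgy_per_mbq,
                                df$lambda_eff_per_h, constants, limit_gy)
  df$a_max_mbq <- mta$a_max_mbq
  df$binding_constraint <- mta$binding_constraint

  keep_cols <- c(
    "patient_id", "course_index", "activity_mbq",
    if ("preparation" %in% names(df)) "preparation",
    "weight_kg", "lambda_eff_per_h", "tau_h", "bvl_ml",
    "coefficient_mgy_per_mbq", "total_dose_gy",
    "within_conservative_limit", "within_actual_limit",
    "a_max_mbq", "binding_constraint"
  )
  dplyr::select(df, dplyr::all_of(keep_cols))
}
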