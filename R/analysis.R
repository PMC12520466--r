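#' Regress the blood dose coefficient on body weight
#'
#' Ordinary least-squares fit of the per-MBq blood dose coefficient against
#' body weight. In weight-heterogeneous pediatric cohorts the slope is
#' negative: lighter patients have smaller blood volumes, so the beta
#' self-dose term (and with the per-weight blood-volume fallback the whole
#' coefficient) falls as weight rises. Significance of the slope is the
#' two-sided t-test with n − 2 degrees of freedom (equivalent to the test of
#' the Pearson correlation for simple OLS).
#'
#' @param data A data frame holding the regression variables.
#' @param weight,coefficient Unquoted column names of the predictor
#'   (weight, kg) and response (coefficient, mGy/MBq).
#' @return An object of class `weight_dose_fit` with fields `slope`
#'   (mGy/MBq per kg), `intercept`, `r_squared`, `p_value`, `n` and the
#'   underlying `stats::lm` fit. [generics::tidy()] and
#'   [generics::glance()] methods are provided.
#' @examples
#' df <- tibble::tibble(w = c(40, 55, 70, 90, 110),
#'                      d = c(0.17, 0.12, 0.10, 0.08, 0.07))
#' fit <- fit_weight_dose_regression(df, w, d)
#' glance(fit)
#' @export
fit_weight_dose_regression <- function(data, weight = weight_kg,
                                       coefficient = coefficient_mgy_per_mbq) {
  w <- dplyr::pull(data, {{ weight }})
  d <- dplyr::pull(data, {{ coefficient }})
  ok <- stats::complete.cases(w, d)
  w <- w[ok]
  d <- d[ok]
  if (length(w) < 3) {
    rlang::abort("At least 3 complete (weight, coefficient) pairs required",
                 class = "bloodmta_error_validation")
  }
  if (stats::var(w) == 0) {
    rlang::abort("Weights are all equal; slope is unidentifiable",
                 class = "bloodmta_error_degenerate")
  }
  fit <- stats::lm(d ~ w)
  sm <- summary(fit)
  structure(
    list(
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      r_squared = sm$r.squared,
      p_value = unname(sm$coefficients[2, 4]),
      n = length(w),
      model = fit,
      data = tibble::tibble(weight_kg = w, coefficient_mgy_per_mbq = d)
    ),
    class = "weight_dose_fit"
  )
}

#' @export
print.weight_dose_fit <- function(x, ...) {
  cat(sprintf(
    "<weight_dose_fit> n = %d, slope = %.3g mGy/MBq per kg, R^2 = %.4f, p = %.4g\n",
    x$n, x$slope, x$r_squared, x$p_value
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_weight_dose_regression
#' @param x A `weight_dose_fit` object.
#' @param ... Unused.
#' @export
tidy.weight_dose_fit <- function(x, ...) {
  sm <- summary(x$model)$coefficients
  tibble::tibble(
    term = c("(Intercept)", "weight_kg"),
    estimate = unname(sm[, 1]),
    std.error = unname(sm[, 2]),
    statistic = unname(sm[, 3]),
    p.value = unname(sm[, 4])
  )
}

#' @rdname fit_weight_dose_regression
#' @export
glance.weight_dose_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared, slope = x$slope, intercept = x$intercept,
    p.value = x$p_value, n = x$n
  )
}

#' Summarise activity per prescription strategy
#'
#' Mean and sample standard deviation (n − 1) of the final planned activity
#' in mCi, per strategy, over a plan table such as rows of [plan_doses()]
#' bound together.
#'
#' @param plans A data frame with `strategy` and `final_activity_mci` (or
#'   `final_activity_mbq`, converted on the fly) columns.
#' @return A tibble with `strategy`, `mean_mci`, `sd_mci`, `n`.
#' @export
summarize_strategies <- function(plans) {
  plans <- tibble::as_tibble(plans)
  if (!nrow(plans)) {
    rlang::abort("plans is empty", class = "bloodmta_error_validation")
  }
  if (!"final_activity_mci" %in% names(plans)) {
    if (!"final_activity_mbq" %in% names(plans)) {
      rlang::abort("plans needs final_activity_mci or final_activity_mbq",
                   class = "bloodmta_error_validation")
    }
    plans$final_activity_mci <- mbq_to_mci(plans$final_activity_mbq)
  }
  out <- plans |>
    dplyr::group_by(.data$strategy) |>
    dplyr::summarise(
      mean_mci = mean(.data$final_activity_mci),
      sd_mci = stats::sd(.data$final_activity_mci),
      n = dplyr::n(),
      .groups = "drop"
    )
  if (any(out$n < 2)) {
    rlang::abort("Each strategy needs at least 2 patients for a summary",
                 class = "bloodmta_error_validation")
  }
  out
}

#' Audit blood doses against the safety thresholds
#'
#' Counts and fractions of administrations whose total blood dose exceeds
#' 1 Gy, the conservative estimated-dose limit (1.3 Gy) and the actual limit
#' (2 Gy), plus the extreme coefficient and dose observed.
#'
#' @param results A non-empty data frame with `total_dose_gy` and
#'   `coefficient_mgy_per_mbq` columns (e.g. from [blood_dosimetry()]).
#' @param constants A [dosimetry_constants()] object.
#' @return A one-row tibble with `n`, `n_over_1gy`, `n_over_conservative`,
#'   `n_over_actual`, the matching fractions, `max_coefficient_mgy_per_mbq`
#'   and `max_total_dose_gy`.
#' @export
safety_audit <- function(results, constants = dosimetry_constants()) {
  results <- tibble::as_tibble(results)
  if (!nrow(results)) {
    rlang::abort("No dosimetry rows to audit",
                 class = "bloodmta_error_validation")
  }
  need <- c("total_dose_gy", "coefficient_mgy_per_mbq")
  if (!all(need %in% names(results))) {
    rlang::abort("results needs total_dose_gy and coefficient_mgy_per_mbq",
                 class = "bloodmta_error_validation")
  }
  n <- nrow(results)
  tot <- results$total_dose_gy
  tibble::tibble(
    n = n,
    n_over_1gy = sum(tot > 1),
    n_over_conservative = sum(tot > constants$conservative_estimated_limit),
    n_over_actual = sum(tot > constants$actual_blood_limit),
    frac_over_1gy = .data$n_over_1gy / n,
    frac_over_conservative = .data$n_over_conservative / n,
    frac_over_actual = .data$n_over_actual / n,
    max_coefficient_mgy_per_mbq = max(results$coefficient_mgy_per_mbq),
    max_total_dose_gy = max(tot)
  )
}

#' Run the full cohort study pipeline
#'
#' End-to-end analysis of a cohort: per-administration blood dosimetry
#' (retention fit, blood volume, coefficient, total dose, safety flags,
#' MTA), the three prescription strategies plus the AHASA-capped plan,
#' strategy summaries, the weight-versus-coefficient regression (first
#' courses) and the safety audit. Deterministic given its inputs.
#'
#' @inheritParams blood_dosimetry
#' @param adult_dose_mci Adult reference activity for the weight-based
#'   strategy (mCi).
#' @return A list of class `rai_study_report`:
#' \describe{
#'   \item{dosimetry}{per-administration tibble from [blood_dosimetry()].}
#'   \item{plans}{long tibble of per-patient recommendations across the
#'     empirical, weight-based, Dutch and AHASA strategies.}
#'   \item{strategy_summary}{[summarize_strategies()] output.}
#'   \item{regression}{[fit_weight_dose_regression()] fit on first-course
#'     rows (NULL if fewer than 3).}
#'   \item{safety}{[safety_audit()] output.}
#'   \item{meta}{schema version, sizes and options used.}
#' }
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 8, seed = 3))
#' report <- run_study(cohort$patients, cohort$administrations,
#'                     cohort$readings)
#' report$strategy_summary
#' @export
run_study <- function(patients, administrations, readings,
                      constants = dosimetry_constants(),
                      limit_gy = constants$conservative_estimated_limit,
                      adult_dose_mci = 150, rhtsh_only = FALSE) {
  dosimetry <- blood_dosimetry(patients, administrations, readings,
                               constants, limit_gy, rhtsh_only)

  plans <- dplyr::bind_rows(
    plan_doses(patients, "empirical", constants = constants),
    plan_doses(patients, "bw", adult_dose_mci = adult_dose_mci,
               constants = constants),
    plan_doses(patients, "dutch", constants = constants),
    plan_doses(patients, "ahasa", readings = readings,
               constants = constants, limit_gy = limit_gy)
  )

  reg_data <- dplyr::filter(dosimetry, .data$course_index == 1L)
  regression <- if (nrow(reg_data) >= 3 &&
                      stats::var(reg_data$weight_kg) > 0) {
    fit_weight_dose_regression(reg_data)
  } else {
    NULL
  }

  structure(
    list(
      dosimetry = dosimetry,
      plans = plans,
      strategy_summary = summarize_strategies(plans),
      regression = regression,
      safety = safety_audit(dosimetry, constants),
      meta = list(
        schema_version = "1.0",
        n_patients = dplyr::n_distinct(patients$patient_id),
        n_administrations = nrow(dosimetry),
        limit_gy = limit_gy,
        adult_dose_mci = adult_dose_mci,
        rhtsh_only = rhtsh_only
      )
    ),
    class = "rai_study_report"
  )
}

#' @export
print.rai_study_report <- function(x, ...) {
  cat(sprintf(
    "<rai_study_report v%s> %d patients, %d administrations%s\n",
    x$meta$schema_version, x$meta$n_patients, x$meta$n_administrations,
    if (x$meta$rhtsh_only) " (rhTSH only)" else ""
  ))
  cat(sprintf("  max blood dose %.3f Gy; %d/%d over %.2g Gy limit\n",
              x$safety$max_total_dose_gy, x$safety$n_over_conservative,
              x$safety$n, x$meta$limit_gy))
  if (!is.null(x$regression)) {
    cat(sprintf("  weight-dose regression: slope %.3g, R^2 %.3f, p %.3g\n",
                x$regression$slope, x$regression$r_squared,
                x$regression$p_value))
  }
  invisible(x)
}

#' Write a study report to JSON
#'
#' Serialises a [run_study()] report (schema version 1.0): the tabular
#' components as arrays of records, the regression and safety audit as flat
#' objects.
#'
#' @param report A `rai_study_report`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "rai_study_report"))
  payload <- list(
    schema_version = report$meta$schema_version,
    meta = report$meta[setdiff(names(report$meta), "schema_version")],
    dosimetry = report$dosimetry,
    plans = report$plans,
    strategy_summary = report$strategy_summary,
    regression = if (is.null(report$regression)) NULL else
      as.list(glance(report$regression)),
    safety = as.list(report$safety)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
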