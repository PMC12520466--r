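#' Mono-exponential retention model
#'
#' Constructs a whole-body retention model R(t) = exp(-λ t) with an anchor
#' exposure-rate reading used for prediction. The residence time is τ = 1/λ.
#'
#' @param lambda_eff_per_h Effective decay constant λ (per hour), combining
#'   physical decay and biological clearance. Must be > 0.
#' @param t_ref_h Anchor time (hours post-administration).
#' @param x_ref_usv_h Exposure rate at 1 m at the anchor time (μSv/h).
#' @return An object of class `retention_model` with fields
#'   `lambda_eff_per_h`, `tau_h`, `t_ref_h`, `x_ref_usv_h`.
#' @seealso [fit_two_point_retention()], [predict_exposure_rate()]
#' @export
retention_model <- function(lambda_eff_per_h, t_ref_h = 0,
                            x_ref_usv_h = NA_real_) {
  check_positive(lambda_eff_per_h, "lambda_eff_per_h")
  check_nonnegative(t_ref_h, "t_ref_h")
  if (!is.na(x_ref_usv_h)) check_positive(x_ref_usv_h, "x_ref_usv_h")
  structure(
    list(
      lambda_eff_per_h = lambda_eff_per_h,
      tau_h = 1 / lambda_eff_per_h,
      t_ref_h = t_ref_h,
      x_ref_usv_h = x_ref_usv_h
    ),
    class = "retention_model"
  )
}

#' @export
print.retention_model <- function(x, ...) {
  cat(sprintf(
    "<retention_model> lambda = %.5f /h, tau = %.2f h, T1/2eff = %.2f h\n",
    x$lambda_eff_per_h, x$tau_h, log(2) / x$lambda_eff_per_h
  ))
  if (!is.na(x$x_ref_usv_h)) {
    cat(sprintf("  anchor: %.3g uSv/h at %.3g h\n", x$x_ref_usv_h, x$t_ref_h))
  }
  invisible(x)
}

#' Fit a retention model to two timed exposure-rate readings
#'
#' External exposure-rate readings at 1 m are a surrogate for retained
#' whole-body activity, so under mono-exponential clearance the effective
#' decay constant is the log ratio of two readings over the elapsed interval:
#' λ = ln(X1/X2) / (t2 − t1), and the residence time is τ = 1/λ. The first
#' reading is kept as the prediction anchor. The customary reading times are
#' 2 h and 67 h post-administration (a 65-h window over the inpatient stay),
#' but any two times are accepted.
#'
#' Readings are assumed background-corrected upstream; no ambient dose-rate
#' subtraction is applied here.
#'
#' @param t1_h,rate1_usv_h Time (h) and exposure rate (μSv/h at 1 m) of the
#'   first reading.
#' @param t2_h,rate2_usv_h Time and rate of the second, later reading. The
#'   second rate must be strictly lower than the first (net clearance).
#' @return A [retention_model()].
#' @examples
#' m <- fit_two_point_retention(2, 200, 67, 10)
#' m$tau_h  # about 21.7 h
#' @export
fit_two_point_retention <- function(t1_h, rate1_usv_h, t2_h, rate2_usv_h) {
  check_nonnegative(t1_h, "t1_h")
  check_positive(rate1_usv_h, "rate1_usv_h")
  check_positive(rate2_usv_h, "rate2_usv_h")
  if (t2_h <= t1_h) {
    rlang::abort(
      "Second reading must be strictly later than the first (degenerate interval)",
      class = "bloodmta_error_degenerate"
    )
  }
  if (rate2_usv_h >= rate1_usv_h) {
    rlang::abort(
      "Exposure rate must decrease between readings (non-physical clearance)",
      class = "bloodmta_error_clearance"
    )
  }
  lambda <- log(rate1_usv_h / rate2_usv_h) / (t2_h - t1_h)
  retention_model(lambda, t_ref_h = t1_h, x_ref_usv_h = rate1_usv_h)
}

#' Fit retention models for every administration in a readings table
#'
#' Data-frame-first wrapper around [fit_two_point_retention()]: groups the
#' readings by `patient_id` (and `course_index` if present), requires exactly
#' two readings per administration, and returns one fitted row per
#' administration.
#'
#' @param readings A data frame with columns `patient_id`, `time_h`,
#'   `rate_usv_h` and optionally `course_index` (defaulting to 1).
#' @return A tibble with columns `patient_id`, `course_index`,
#'   `lambda_eff_per_h`, `tau_h`, `t_ref_h`, `x_ref_usv_h`.
#' @examples
#' readings <- tibble::tibble(
#'   patient_id = c("a", "a"), time_h = c(2, 67), rate_usv_h = c(200, 10)
#' )
#' fit_retention(readings)
#' @export
fit_retention <- function(readings) {
  need <- c("patient_id", "time_h", "rate_usv_h")
  missing_cols <- setdiff(need, names(readings))
  if (length(missing_cols)) {
    rlang::abort(
      paste0("readings is missing column(s): ",
             paste(missing_cols, collapse = ", ")),
      class = "bloodmta_error_validation"
    )
  }
  readings <- tibble::as_tibble(readings)
  if (!"course_index" %in% names(readings)) readings$course_index <- 1L

  counts <- dplyr::count(readings, .data$patient_id, .data$course_index)
  bad <- dplyr::filter(counts, .data$n != 2L)
  if (nrow(bad)) {
    ids <- paste0(bad$patient_id, "/", bad$course_index, " (", bad$n, ")",
                  collapse = ", ")
    rlang::abort(
      paste0("Each administration needs exactly two readings; offending ",
             "patient/course (count): ", ids),
      class = "bloodmta_error_validation"
    )
  }

  readings |>
    dplyr::arrange(.data$patient_id, .data$course_index, .data$time_h) |>
    dplyr::group_by(.data$patient_id, .data$course_index) |>
    dplyr::summarise(
      fit = list(fit_two_point_retention(
        .data$time_h[1], .data$rate_usv_h[1],
        .data$time_h[2], .data$rate_usv_h[2]
      )),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      lambda_eff_per_h = purrr::map_dbl(.data$fit, "lambda_eff_per_h"),
      tau_h = purrr::map_dbl(.data$fit, "tau_h"),
      t_ref_h = purrr::map_dbl(.data$fit, "t_ref_h"),
      x_ref_usv_h = purrr::map_dbl(.data$fit, "x_ref_usv_h")
    ) |>
    dplyr::select(-"fit")
}

#' Residence time from a single retention fraction
#'
#' For mono-exponential clearance, knowing that a fraction R(t) of the
#' administered activity remains at time t fixes the residence time:
#' τ = −t / ln R(t). Equivalent to the two-point fit applied to the ratio of
#' the two readings. Vectorised.
#'
#' @param t_h Elapsed time in hours, > 0.
#' @param fraction_retained Retained fraction in (0, 1).
#' @return Residence time τ in hours.
#' @examples
#' residence_time_from_fraction(65, 0.05)  # about 21.7 h
#' @export
residence_time_from_fraction <- function(t_h, fraction_retained) {
  check_positive(t_h, "t_h")
  if (!is.numeric(fraction_retained) ||
      any(fraction_retained <= 0 | fraction_retained >= 1, na.rm = TRUE)) {
    rlang::abort("fraction_retained must lie strictly between 0 and 1",
                 class = "bloodmta_error_domain")
  }
  -t_h / log(fraction_retained)
}

#' Retention fraction at a given time
#'
#' Evaluates R(t) = exp(−λ t); R(0) = 1 by construction (the model is
#' extrapolated back to administration).
#'
#' @param model A [retention_model()].
#' @param t_h Time(s) in hours, ≥ 0.
#' @return Retained fraction(s) in (0, 1].
#' @export
retention_at <- function(model, t_h) {
  stopifnot(inherits(model, "retention_model"))
  check_nonnegative(t_h, "t_h")
  exp(-model$lambda_eff_per_h * t_h)
}

#' Predict the exposure rate at 1 m at a given time
#'
#' X(t) = X_ref · exp(−λ (t − t_ref)), anchored at the model's reference
#' reading; returns the anchor rate exactly at t = t_ref.
#'
#' @inheritParams retention_at
#' @return Predicted exposure rate(s) in μSv/h at 1 m.
#' @export
predict_exposure_rate <- function(model, t_h) {
  stopifnot(inherits(model, "retention_model"))
  check_nonnegative(t_h, "t_h")
  if (is.na(model$x_ref_usv_h)) {
    rlang::abort("Model has no anchor reading; cannot predict exposure rate",
                 class = "bloodmta_error_validation")
  }
  model$x_ref_usv_h * exp(-model$lambda_eff_per_h * (t_h - model$t_ref_h))
}

#' Time at which the exposure rate falls to a threshold
#'
#' Solves X(t) = threshold for the anchored model:
#' t = t_ref + ln(X_ref / threshold) / λ. If the threshold is already met at
#' the anchor (threshold ≥ X_ref) the anchor time is returned. The usual
#' application is the 30 μSv/h at 1 m discharge criterion for the isolation
#' ward.
#'
#' @inheritParams retention_at
#' @param threshold_usv_h Dose-rate threshold (μSv/h at 1 m), > 0.
#' @return Crossing time in hours post-administration.
#' @examples
#' m <- fit_two_point_retention(2, 200, 67, 10)
#' time_to_threshold(m, 30)  # about 43.2 h
#' @export
time_to_threshold <- function(model, threshold_usv_h) {
  stopifnot(inherits(model, "retention_model"))
  check_positive(threshold_usv_h, "threshold_usv_h")
  if (is.na(model$x_ref_usv_h)) {
    rlang::abort("Model has no anchor reading; cannot locate a crossing",
                 class = "bloodmta_error_validation")
  }
  ifelse(
    threshold_usv_h >= model$x_ref_usv_h,
    model$t_ref_h,
    model$t_ref_h +
      log(model$x_ref_usv_h / threshold_usv_h) / model$lambda_eff_per_h
  )
}
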