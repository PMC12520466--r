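#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the weight-versus-coefficient regression
#'
#' Scatter of body weight against the blood dose coefficient with the fitted
#' OLS line; the caption carries R², slope p-value and n.
#'
#' @param object A `weight_dose_fit` from [fit_weight_dose_regression()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.weight_dose_fit <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$weight_kg,
                               y = .data$coefficient_mgy_per_mbq)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_abline(intercept = object$intercept,
                         slope = object$slope, colour = "steelblue") +
    ggplot2::labs(
      x = "Body weight (kg)",
      y = "Blood dose coefficient (mGy/MBq)",
      caption = sprintf("R² = %.4f, p = %.3g, n = %d",
                        object$r_squared, object$p_value, object$n)
    ) +
    ggplot2::theme_minimal()
}

#' Compare prescription strategies across a cohort
#'
#' Per-strategy distribution of planned final activities (mCi) as jittered
#' points over a boxplot — the usual picture contrasting empirical tiers,
#' weight-proportional and capped per-kg dosing.
#'
#' @param plans A plan table with `strategy` and `final_activity_mci`
#'   columns (rows of [plan_doses()] bound together, or
#'   `report$plans` from [run_study()]).
#' @return A ggplot object.
#' @export
plot_strategy_comparison <- function(plans) {
  plans <- tibble::as_tibble(plans)
  if (!"final_activity_mci" %in% names(plans)) {
    plans$final_activity_mci <- mbq_to_mci(plans$final_activity_mbq)
  }
  ggplot2::ggplot(plans,
                  ggplot2::aes(x = .data$strategy,
                               y = .data$final_activity_mci)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey92") +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.6, size = 1.5) +
    ggplot2::labs(x = NULL, y = "Planned activity (mCi)") +
    ggplot2::theme_minimal()
}

#' Plot a fitted retention curve with its readings
#'
#' Predicted exposure rate at 1 m over time for a fitted retention model,
#' with the discharge threshold drawn as a horizontal reference.
#'
#' @param model A [retention_model()] with an anchor reading.
#' @param t_max_h Right edge of the time axis (h).
#' @param threshold_usv_h Reference threshold to draw (default 30 μSv/h,
#'   the discharge criterion).
#' @return A ggplot object.
#' @export
plot_retention <- function(model, t_max_h = 96, threshold_usv_h = 30) {
  stopifnot(inherits(model, "retention_model"))
  tt <- seq(model$t_ref_h, t_max_h, length.out = 200)
  df <- tibble::tibble(time_h = tt,
                       rate_usv_h = predict_exposure_rate(model, tt))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_h, y = .data$rate_usv_h)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_hline(yintercept = threshold_usv_h, linetype = "dashed") +
    ggplot2::labs(x = "Hours post-administration",
                  y = "Exposure rate at 1 m (μSv/h)") +
    ggplot2::theme_minimal()
}
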