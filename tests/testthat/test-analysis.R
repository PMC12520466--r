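test_that("weight-dose regression matches the matrix-algebra oracle", {
  x <- 1:5
  y <- c(2, 1.9, 1.7, 1.8, 1.5)
  oracle <- ols_oracle(x, y)
  fit <- fit_weight_dose_regression(tibble::tibble(w = x, d = y), w, d)
  expect_equal(fit$slope, oracle$slope, tolerance = 1e-12)
  expect_equal(fit$intercept, oracle$intercept, tolerance = 1e-12)
  expect_equal(fit$r_squared, oracle$r_squared, tolerance = 1e-12)
  expect_equal(fit$p_value, oracle$p_value, tolerance = 1e-12)
  # frozen values from the oracle
  expect_equal(fit$slope, -0.11, tolerance = 1e-12)
  expect_equal(fit$intercept, 2.11, tolerance = 1e-12)
  expect_equal(fit$r_squared, 0.8175675676, tolerance = 1e-9)
  expect_equal(fit$p_value, 0.0350815147, tolerance = 1e-9)
  expect_equal(fit$n, 5)

  tt <- tidy(fit)
  expect_equal(tt$estimate, c(oracle$intercept, oracle$slope),
               tolerance = 1e-12)
  gg <- glance(fit)
  expect_named(gg, c("r.squared", "slope", "intercept", "p.value", "n"))
})

test_that("regression handles exact, null and degenerate cases", {
  collinear <- tibble::tibble(weight_kg = 1:6,
                              coefficient_mgy_per_mbq = 3 - 0.2 * (1:6))
  # exact fits trip stats::summary.lm's "essentially perfect fit" warning
  fit <- suppressWarnings(fit_weight_dose_regression(collinear))
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_lt(fit$p_value, 1e-10)

  flat <- tibble::tibble(weight_kg = 1:6, coefficient_mgy_per_mbq = 0.1)
  fit0 <- suppressWarnings(fit_weight_dose_regression(flat))
  expect_equal(fit0$slope, 0, tolerance = 1e-12)
  expect_equal(fit0$r_squared, 0, tolerance = 1e-12)

  expect_error(
    fit_weight_dose_regression(collinear[1:2, ]),
    class = "bloodmta_error_validation"
  )
  expect_error(
    fit_weight_dose_regression(
      tibble::tibble(weight_kg = rep(50, 5),
                     coefficient_mgy_per_mbq = runif(5))
    ),
    class = "bloodmta_error_degenerate"
  )
})

test_that("regression is invariant to row order and R^2 equals cor^2", {
  set.seed(21)
  df <- tibble::tibble(weight_kg = runif(30, 35, 135),
                       coefficient_mgy_per_mbq = runif(30, 0.05, 0.2))
  fit <- fit_weight_dose_regression(df)
  perm <- fit_weight_dose_regression(df[sample(30), ])
  expect_equal(fit$slope, perm$slope, tolerance = 1e-12)
  expect_equal(fit$r_squared, perm$r_squared, tolerance = 1e-12)
  expect_equal(fit$p_value, perm$p_value, tolerance = 1e-12)
  expect_equal(fit$r_squared,
               cor(df$weight_kg, df$coefficient_mgy_per_mbq)^2,
               tolerance = 1e-12)
})

test_that("strategy summaries use mean and sample SD", {
  plans <- tibble::tibble(
    strategy = rep(c("empirical", "dutch"), each = 3),
    final_activity_mci = c(100, 150, 200, 90, 90, 90)
  )
  out <- summarize_strategies(plans)
  emp <- out[out$strategy == "empirical", ]
  expect_equal(emp$mean_mci, 150)
  expect_equal(emp$sd_mci, 50)  # sample SD, n - 1
  expect_equal(out[out$strategy == "dutch", ]$sd_mci, 0)
  expect_equal(out$n, c(3L, 3L))

  # conversion fallback from MBq
  mbq_plans <- tibble::tibble(strategy = "x",
                              final_activity_mbq = c(3700, 7400))
  expect_equal(summarize_strategies(mbq_plans)$mean_mci, 150)

  expect_error(summarize_strategies(plans[0, ]),
               class = "bloodmta_error_validation")
  expect_error(summarize_strategies(
    tibble::tibble(strategy = "a", final_activity_mci = 1)
  ), class = "bloodmta_error_validation")
})

test_that("Dutch dosing under-doses relative to the empirical tier on a low-weight cohort", {
  # every patient's 100 MBq/kg raw dose sits below their empirical tier
  patients <- tibble::tibble(
    patient_id = sprintf("u%d", 1:5),
    weight_kg = c(36, 40, 45, 50, 54),
    risk_stratum = "therapy",
    dutch_category = "t3b_n1"
  )
  plans <- dplyr::bind_rows(plan_doses(patients, "empirical"),
                            plan_doses(patients, "dutch"))
  out <- summarize_strategies(plans)
  expect_lt(out$mean_mci[out$strategy == "dutch"],
            out$mean_mci[out$strategy == "empirical"])
})

test_that("safety audit counts exceedances against all three thresholds", {
  res <- tibble::tibble(
    total_dose_gy = c(0.3, 0.8, 1.05, 1.4, 2.5),
    coefficient_mgy_per_mbq = c(0.06, 0.1, 0.19, 0.15, 0.25)
  )
  audit <- safety_audit(res)
  expect_equal(audit$n, 5)
  expect_equal(audit$n_over_1gy, 3)
  expect_equal(audit$n_over_conservative, 2)
  expect_equal(audit$n_over_actual, 1)
  expect_equal(audit$frac_over_1gy, 0.6)
  expect_equal(audit$max_coefficient_mgy_per_mbq, 0.25)
  expect_equal(audit$max_total_dose_gy, 2.5)

  clean <- safety_audit(tibble::tibble(total_dose_gy = c(0.2, 0.9),
                                       coefficient_mgy_per_mbq = c(0.05, 0.1)))
  expect_equal(clean$n_over_1gy, 0)

  expect_error(safety_audit(res[0, ]), class = "bloodmta_error_validation")
})

test_that("run_study assembles a deterministic, schema-complete report", {
  cohort <- generate_cohort(cohort_config(n_patients = 12, seed = 42))
  r1 <- run_study(cohort$patients, cohort$administrations, cohort$readings)
  r2 <- run_study(cohort$patients, cohort$administrations, cohort$readings)
  expect_identical(r1$dosimetry, r2$dosimetry)
  expect_identical(r1$strategy_summary, r2$strategy_summary)
  expect_equal(glance(r1$regression), glance(r2$regression))

  expect_s3_class(r1, "rai_study_report")
  expect_named(r1, c("dosimetry", "plans", "strategy_summary", "regression",
                     "safety", "meta"))
  expect_setequal(unique(r1$plans$strategy),
                  c("empirical", "bw_based", "dutch", "ahasa_adjusted"))
  expect_equal(nrow(r1$plans), 4 * 12)

  # noise degrades the weight-dose correlation relative to noiseless truth
  noiseless <- generate_cohort(cohort_config(n_patients = 40, seed = 13,
                                             reading_noise_cv = 0))
  noisy <- generate_cohort(cohort_config(n_patients = 40, seed = 13,
                                         reading_noise_cv = 0.5))
  rn <- run_study(noiseless$patients, noiseless$administrations,
                  noiseless$readings)
  rq <- run_study(noisy$patients, noisy$administrations, noisy$readings)
  expect_gt(rn$regression$r_squared, rq$regression$r_squared)

  # itemised error when an administration has no readings
  expect_error(
    run_study(cohort$patients, cohort$administrations,
              cohort$readings[-(1:2), ]),
    class = "bloodmta_error_validation"
  )
})

test_that("run_study on the reference cohort with synthetic kinetics stays under 2 Gy", {
  ref <- reference_cohort()
  kin <- generate_cohort(cohort_config(n_patients = 24, seed = 7))
  readings <- ref$administrations |>
    dplyr::mutate(lambda = kin$truth$lambda_true_per_h[seq_len(24)]) |>
    tidyr::crossing(time_h = c(2, 67)) |>
    dplyr::mutate(rate_usv_h = 0.03 * activity_mbq * exp(-lambda * time_h)) |>
    dplyr::select(patient_id, course_index, time_h, rate_usv_h)

  report <- run_study(ref$patients, ref$administrations, readings)
  expect_equal(report$safety$n, 24)
  expect_equal(report$safety$n_over_actual, 0)
  expect_true(all(report$dosimetry$within_actual_limit))

  path <- withr::local_tempfile(fileext = ".json")
  write_report_json(report, path)
  parsed <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(parsed$schema_version, "1.0")
  expect_equal(nrow(parsed$dosimetry), 24)
  expect_equal(parsed$safety$n_over_actual, 0)
  expect_equal(parsed$regression$n, 20)
})

test_that("plot constructors return ggplot objects", {
  cohort <- generate_cohort(cohort_config(n_patients = 10, seed = 2))
  report <- run_study(cohort$patients, cohort$administrations,
                      cohort$readings)
  expect_s3_class(autoplot(report$regression), "ggplot")
  expect_s3_class(plot_strategy_comparison(report$plans), "ggplot")
  m <- fit_two_point_retention(2, 200, 67, 10)
  expect_s3_class(plot_retention(m), "ggplot")
})
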