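test_that("blood volume estimation follows its precedence rules", {
  # Nadler, hand-evaluated oracle
  expect_equal(estimate_blood_volume(50, sex = "female", height_cm = 160),
               (0.3561 * 1.6^3 + 0.03308 * 50 + 0.1833) * 1000,
               tolerance = 1e-12)
  expect_equal(estimate_blood_volume(50, sex = "female", height_cm = 160),
               3295.886, tolerance = 1e-3)
  expect_equal(estimate_blood_volume(70, sex = "male", height_cm = 175),
               (0.3669 * 1.75^3 + 0.03219 * 70 + 0.6041) * 1000,
               tolerance = 1e-12)
  # per-kg fallback and explicit pass-through
  expect_equal(estimate_blood_volume(60), 4200)
  expect_equal(estimate_blood_volume(60, ml_per_kg = 75), 4500)
  expect_equal(estimate_blood_volume(60, blood_volume_ml = 3000), 3000)
  # mixed vector: each patient resolved independently
  out <- estimate_blood_volume(
    c(50, 60, 60), sex = c("female", NA, NA),
    height_cm = c(160, NA, NA), blood_volume_ml = c(NA, NA, 3000)
  )
  expect_equal(out, c(3295.886, 4200, 3000), tolerance = 1e-3)
  expect_error(estimate_blood_volume(-1),
               class = "bloodmta_error_validation")
  expect_error(estimate_blood_volume(60, sex = "other", height_cm = 160),
               class = "bloodmta_error_validation")
})

test_that("blood dose coefficient matches the defining formula", {
  expect_equal(blood_dose_coefficient(60, 4200, 21.70),
               coefficient_oracle(60, 4200, 21.70), tolerance = 1e-12)
  expect_equal(blood_dose_coefficient(60, 4200, 21.70), 0.1047385,
               tolerance = 1e-6)
  expect_equal(blood_dose_coefficient(60, 4200, 0), 0)
  expect_error(blood_dose_coefficient(0, 4200, 20),
               class = "bloodmta_error_validation")
  expect_error(blood_dose_coefficient(60, -1, 20),
               class = "bloodmta_error_validation")

  # monotonicity: increasing in tau, decreasing in weight and volume
  taus <- seq(5, 45, by = 5)
  expect_true(all(diff(blood_dose_coefficient(60, 4200, taus)) > 0))
  wts <- seq(35, 135, by = 5)
  expect_true(all(diff(blood_dose_coefficient(wts, 4200, 20)) < 0))
  bvls <- seq(2000, 9000, by = 500)
  expect_true(all(diff(blood_dose_coefficient(60, bvls, 20)) < 0))
  # per-kg fallback couples both terms: still strictly decreasing in weight
  expect_true(all(diff(blood_dose_coefficient(wts, 70 * wts, 20)) < 0))
  # pure per-MBq quantity: no dependence on administered activity anywhere
})

test_that("total blood dose converts coefficient and activity to Gy", {
  expect_equal(round(total_blood_dose(0.19, 5550), 2), 1.05)
  expect_equal(total_blood_dose(0.19, 5550), 0.19 * 5550 / 1000,
               tolerance = 1e-15)
  expect_equal(total_blood_dose(0.12, 0), 0)
  expect_equal(total_blood_dose(0.06, 3700), 0.222, tolerance = 1e-12)
  expect_error(total_blood_dose(-0.1, 100),
               class = "bloodmta_error_validation")
})

test_that("safety flags are inclusive at both limits", {
  res <- tibble::tibble(total_dose_gy = c(1.05, 1.3, 2.0, 2.5, 0.4))
  flagged <- check_safety(res)
  expect_equal(flagged$within_conservative_limit,
               c(TRUE, TRUE, FALSE, FALSE, TRUE))
  expect_equal(flagged$within_actual_limit,
               c(TRUE, TRUE, TRUE, FALSE, TRUE))
  expect_error(check_safety(tibble::tibble(x = 1)),
               class = "bloodmta_error_validation")
})

test_that("maximum tolerated activity is the binding of blood and 48-h limits", {
  lam <- log(20) / 65
  mta <- max_tolerated_activity(0.19, lam, limit_gy = 2)
  expect_equal(mta$a_max_blood_mbq, 2000 / 0.19, tolerance = 1e-12)
  expect_equal(mta$a_max_blood_mbq, 10526.32, tolerance = 1e-2)
  expect_equal(mta$a_max_benua_mbq, 4440 / exp(-48 * lam), tolerance = 1e-12)
  expect_equal(mta$a_max_benua_mbq, 40564.26, tolerance = 1e-2)
  expect_equal(mta$binding_constraint, "blood")
  expect_equal(mta$a_max_mbq, mta$a_max_blood_mbq)

  expect_equal(max_tolerated_activity(0.19, lam,
                                      limit_gy = 1.3)$a_max_blood_mbq,
               1300 / 0.19, tolerance = 1e-12)

  # very slow clearance makes the 48-h whole-body limit bind for small d
  slow <- max_tolerated_activity(0.05, 0.001, limit_gy = 2)
  expect_equal(slow$a_max_benua_mbq, 4440 / exp(-0.048), tolerance = 1e-9)
  expect_equal(slow$binding_constraint, "benua_wb")
  expect_lt(slow$a_max_mbq, 2000 / 0.05)

  expect_error(max_tolerated_activity(0, lam),
               class = "bloodmta_error_validation")

  # inverse property: dosing at the blood-limited MTA hits the limit exactly
  set.seed(4)
  for (i in 1:50) {
    d <- runif(1, 0.04, 0.3)
    lim <- runif(1, 0.8, 2)
    a <- max_tolerated_activity(d, runif(1, 0.01, 0.2),
                                limit_gy = lim)$a_max_blood_mbq
    expect_equal(total_blood_dose(d, a), lim, tolerance = 1e-9)
  }
})

test_that("the dosimetry pipeline reproduces a hand-computed administration", {
  patients <- tibble::tibble(patient_id = "p1", weight_kg = 60)
  administrations <- tibble::tibble(patient_id = "p1", course_index = 1L,
                                    activity_mbq = 5550)
  readings <- tibble::tibble(patient_id = "p1", course_index = 1L,
                             time_h = c(2, 67), rate_usv_h = c(200, 10))
  out <- blood_dosimetry(patients, administrations, readings)
  expect_equal(nrow(out), 1)
  expect_equal(out$tau_h, 65 / log(20), tolerance = 1e-12)
  expect_equal(out$bvl_ml, 4200)
  expect_equal(out$coefficient_mgy_per_mbq,
               coefficient_oracle(60, 4200, 65 / log(20)), tolerance = 1e-12)
  expect_equal(out$total_dose_gy,
               out$coefficient_mgy_per_mbq * 5550 / 1000, tolerance = 1e-12)
  expect_true(out$within_conservative_limit)
  expect_true(out$within_actual_limit)
  expect_equal(out$binding_constraint, "blood")

  # a missing readings pair is itemised by patient/course
  expect_error(
    blood_dosimetry(patients,
                    dplyr::mutate(administrations, course_index = 2L),
                    readings),
    "p1/2", class = "bloodmta_error_validation"
  )
})

test_that("rhtsh_only restricts the pipeline to rhTSH administrations", {
  patients <- tibble::tibble(patient_id = c("p1", "p2"),
                             weight_kg = c(60, 80))
  administrations <- tibble::tibble(
    patient_id = c("p1", "p2"), course_index = 1L,
    activity_mbq = c(5550, 5550),
    preparation = c("rhtsh", "withdrawal")
  )
  readings <- tibble::tibble(
    patient_id = rep(c("p1", "p2"), each = 2), course_index = 1L,
    time_h = rep(c(2, 67), 2), rate_usv_h = c(200, 10, 180, 20)
  )
  out <- blood_dosimetry(patients, administrations, readings,
                         rhtsh_only = TRUE)
  expect_equal(out$patient_id, "p1")

  only_wd <- dplyr::mutate(administrations, preparation = "withdrawal")
  expect_error(blood_dosimetry(patients, only_wd, readings,
                               rhtsh_only = TRUE),
               class = "bloodmta_error_validation")
})
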