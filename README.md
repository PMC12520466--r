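# bloodmta

Blood dosimetry and activity planning for I-131 therapy in pediatric
differentiated thyroid cancer.

After total thyroidectomy, radioiodine activity prescription for children
and adolescents has to balance efficacy against the radiation burden to the
hematopoietic system. The absorbed dose to blood is the standard first-order
surrogate for red-marrow exposure, classically limited to 2 Gy together
with a whole-body retention limit of 4.4 GBq at 48 h. Full blood dosimetry
(serial blood samples and whole-body counts over ~4 days) is rarely
practical, so this package implements the simplified route used in nuclear
medicine practice: estimate whole-body kinetics from two routine
exposure-rate readings at 1 m during the isolation-ward stay, convert them
into a per-activity blood dose coefficient, and derive each patient's
maximum tolerated activity (MTA) under the "as high as safe administration"
(AHASA) principle. It is aimed at medical physicists and nuclear-medicine
researchers analysing pediatric RAI cohorts or planning doses.

## The model

Whole-body retention is mono-exponential, R(t) = exp(−λt). Two timed
exposure-rate readings (t₁, X₁), (t₂, X₂) at 1 m give

    λ = ln(X₁/X₂) / (t₂ − t₁),    τ = 1/λ  (residence time, h)

and the mean blood absorbed dose per unit administered activity is

    D_blood/A₀ [mGy/MBq] = (15.12/BVL[mL] + 0.0188/wt[kg]^(2/3)) · τ

— a beta self-dose term scaled by blood volume plus a photon whole-body
term (15.12 = 108 × 0.14, the 14% blood share of whole-body residence
time). The MTA is the largest activity keeping the estimated blood dose at
or below its limit (conservatively 1.3 Gy = 2 Gy × 0.67, the
estimated-to-actual ratio of the simplified method) while retained activity
at 48 h stays at or below 4.4 GBq. Prescription strategies compared:
empirical risk-stratified tiers, body-weight scaling (wt/70 kg × adult
dose), the Dutch 100 MBq/kg rule with category caps, and the empirical tier
capped at the patient's MTA (AHASA).

A seeded synthetic-cohort generator (`generate_cohort()`) emulates the
demographics, kinetics and measurement noise of such a cohort, and
`reference_cohort()` provides a frozen 20-patient table matching published
categorical marginals (its ages and weights are fabricated — it is not
patient data).

## Worked example

```r
library(bloodmta)

# two readings at 1 m: 200 uSv/h at 2 h, 10 uSv/h at 67 h
m <- fit_two_point_retention(2, 200, 67, 10)
m
#> <retention_model> lambda = 0.04609 /h, tau = 21.70 h, T1/2eff = 15.04 h
#>   anchor: 200 uSv/h at 2 h

d <- blood_dose_coefficient(weight_kg = 60, blood_volume_ml = 4200,
                            tau_h = m$tau_h)
d                             # 0.1047 mGy/MBq
total_blood_dose(d, 5550)     # 0.581 Gy at 150 mCi: well under the limits

max_tolerated_activity(d, m$lambda_eff_per_h)
#>   a_max_blood_mbq a_max_benua_mbq a_max_mbq binding_constraint
#> 1          12413.          40564.    12413. blood
```

The λ of 0.0461/h is an effective half-life of 15 h; τ = 21.7 h of
residence time yields 0.105 mGy per MBq to blood, so a 150 mCi (5550 MBq)
course deposits 0.58 Gy — the blood-dose constraint, not the 48-h retention
constraint, is what binds, at 12.4 GBq.

A full cohort run:

```r
cohort <- generate_cohort(cohort_config(n_patients = 12, seed = 42))
report <- run_study(cohort$patients, cohort$administrations, cohort$readings)

report$strategy_summary
#>   strategy       mean_mci sd_mci     n
#> 1 ahasa_adjusted     136.   43.1    12
#> 2 bw_based           136.   40.7    12
#> 3 dutch              150.   40.1    12
#> 4 empirical          138.   43.3    12

glance(report$regression)
#>   r.squared    slope intercept p.value     n
#> 1     0.618 -0.00253     0.268 0.00242    12
```

The regression slope is negative — lighter patients absorb more dose per
MBq — and the safety audit (`report$safety`) shows no administration above
2 Gy. `autoplot(report$regression)` and
`plot_strategy_comparison(report$plans)` draw the standard figures;
`write_report_json()` serialises the report.

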