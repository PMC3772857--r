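# coefficient set with a single doubling term, handy for exact-RR fixtures
two_rr_coeffs <- function() coefficient_set(c(alcohol_yes = log(2)))

test_that("baseline calibration divides population incidence by the mean control RR", {
  lt <- make_flat_life_table(incidence = 12e-5)
  co <- two_rr_coeffs()
  # all-baseline controls: mean RR = 1, rho equals the population rate
  ctrl0 <- do.call(rbind, replicate(5, risk_profile(), simplify = FALSE))
  bl0 <- calibrate_baseline(lt, "male", ctrl0, co)
  expect_equal(bl0$rho, lt$incidence)
  # one baseline + one doubled profile: mean RR = 1.5, 12 -> 8 per 100k
  ctrl <- rbind(risk_profile(), risk_profile(heavy_alcohol = "yes"))
  bl <- calibrate_baseline(lt, "male", ctrl, co)
  expect_equal(bl$mean_rr, 1.5)
  expect_equal(unique(bl$rho), 8e-5)
  # controls with missing covariates are refused
  ctrl_miss <- rbind(risk_profile(), risk_profile(smoking = "missing"))
  expect_error(calibrate_baseline(lt, "male", ctrl_miss, co), "missing")
})

test_that("calibration identity: mean predicted incidence equals the population rate", {
  co <- published_coefficients()
  d <- simulate_population(sim_config(200, 400, seed = 8))
  ctrl <- d[d$status == "control" & d$sex == "female", ]
  lt <- simulate_life_table("female")
  bl <- calibrate_baseline(lt, "female", ctrl, co)
  rr <- relative_risk(ctrl, co)
  for (age in c(30, 47, 60, 75, 89)) {
    mean_pred <- mean(pancrisk:::.rho_at(bl, age) * rr)
    expect_equal(mean_pred, lt$incidence[lt$age == age], tolerance = 1e-12)
  }
})

test_that("age-specific incidence is rho times RR", {
  lt <- make_flat_life_table(incidence = 5e-5)
  co <- two_rr_coeffs()
  bl <- calibrate_baseline(lt, "male",
                           do.call(rbind, replicate(3, risk_profile(),
                                                    simplify = FALSE)), co)
  expect_equal(age_specific_incidence(risk_profile(), 60, bl, co), 5e-5)
  expect_equal(age_specific_incidence(risk_profile(heavy_alcohol = "yes"),
                                      60, bl, co), 1e-4)
  expect_error(age_specific_incidence(risk_profile(), 95, bl, co), "support")
})

test_that("interval risk has the right closed forms and limits", {
  co <- two_rr_coeffs()
  base <- risk_profile()
  # h = 0 -> zero risk (and the h + m = 0 year contributes 0, not NaN)
  lt0 <- make_flat_life_table(incidence = 0, mortality = 0)
  bl0 <- calibrate_baseline(lt0, "male", base, co)
  expect_equal(interval_risk(base, 50, 60, bl0, lt0, co), 0)
  # m = 0, constant h over n years -> 1 - exp(-n h)
  h <- 4e-4
  lt1 <- make_flat_life_table(incidence = h, mortality = 0)
  bl1 <- calibrate_baseline(lt1, "male", base, co)
  expect_equal(interval_risk(base, 50, 60, bl1, lt1, co), 1 - exp(-10 * h))
  expect_error(interval_risk(base, 60, 60, bl1, lt1, co), "start_age")
  expect_error(interval_risk(base, 50, 95, bl1, lt1, co), "support")
})

test_that("interval risk matches the fine-grid hazard-integration oracle", {
  co <- published_coefficients()
  lt <- simulate_life_table("male")
  prof <- risk_profile(smoking = "current", bmi_cat = "over30",
                       abo = "AO", snp_1q32 = 2, snp_13q22 = 1)
  ctrl <- rbind(risk_profile(), prof, risk_profile(heavy_alcohol = "yes"))
  bl <- calibrate_baseline(lt, "male", ctrl, co)
  rr <- relative_risk(prof, co)
  for (win in list(c(50, 60), c(40, 85), c(84, 86))) {
    ages <- seq.int(win[1], win[2] - 1)
    got <- interval_risk(prof, win[1], win[2], bl, lt, co)
    want <- oracle_interval_risk(rr, ages, pancrisk:::.rho_at(bl, ages),
                                 lt$mortality[match(ages, lt$age)])
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("disease, competing death and survival decompose to exactly 1", {
  co <- published_coefficients()
  lt <- simulate_life_table("female")
  prof <- risk_profile(smoking = "former", abo = "AB", snp_5p15 = 2)
  bl <- calibrate_baseline(lt, "female", rbind(risk_profile(), prof), co)
  rr <- relative_risk(prof, co)
  ages <- 35:84
  h <- pancrisk:::.rho_at(bl, ages) * rr
  m <- lt$mortality[match(ages, lt$age)]
  tot <- h + m
  surv_before <- cumprod(c(1, exp(-tot)[-length(tot)]))
  p_disease <- sum(ifelse(tot > 0, h / tot, 0) * (1 - exp(-tot)) * surv_before)
  p_death <- sum(ifelse(tot > 0, m / tot, 0) * (1 - exp(-tot)) * surv_before)
  p_alive <- prod(exp(-tot))
  expect_equal(p_disease + p_death + p_alive, 1, tolerance = 1e-9)
  expect_equal(p_disease, interval_risk(prof, 35, 85, bl, lt, co))
})

test_that("interval risk recombines across a split with survival weighting", {
  co <- published_coefficients()
  lt <- simulate_life_table("male")
  prof <- risk_profile(diabetes = "gt3y", design = "cohort", snp_13q22 = 2)
  bl <- calibrate_baseline(lt, "male", rbind(risk_profile(), prof), co)
  rr <- relative_risk(prof, co)
  for (split in c(45, 60, 79)) {
    ages1 <- 40:(split - 1); ages2 <- split:79
    h <- function(a) pancrisk:::.rho_at(bl, a) * rr
    m <- function(a) lt$mortality[match(a, lt$age)]
    surv1 <- prod(exp(-(h(ages1) + m(ages1))))
    lhs <- interval_risk(prof, 40, split, bl, lt, co) +
      surv1 * interval_risk(prof, split, 80, bl, lt, co)
    expect_equal(lhs, interval_risk(prof, 40, 80, bl, lt, co),
                 tolerance = 1e-12)
  }
})

test_that("lifetime risk is the interval risk to the horizon and is monotone", {
  co <- published_coefficients()
  lt <- simulate_life_table("male")
  prof <- risk_profile(smoking = "current")
  bl <- calibrate_baseline(lt, "male", rbind(risk_profile(), prof), co)
  expect_equal(lifetime_risk(prof, 55, bl, lt, co, horizon_age = 65),
               interval_risk(prof, 55, 65, bl, lt, co))
  expect_gte(lifetime_risk(prof, 50, bl, lt, co, horizon_age = 85),
             lifetime_risk(prof, 50, bl, lt, co, horizon_age = 80))
  expect_error(lifetime_risk(prof, 85, bl, lt, co), "horizon")
})

test_that("risk percentile curves are nondecreasing and collapse when profiles tie", {
  co <- published_coefficients()
  lt <- simulate_life_table("male")
  d <- simulate_population(sim_config(100, 400, seed = 21))
  ctrl <- d[d$status == "control" & d$sex == "male", ]
  bl <- calibrate_baseline(lt, "male", ctrl, co)
  curve <- risk_percentiles(ctrl, start_age = 65, bl, lt, co)
  expect_true(all(diff(curve$risk) >= 0))
  expect_equal(nrow(curve), nrow(ctrl))
  same <- do.call(rbind, replicate(120, risk_profile(smoking = "former"),
                                   simplify = FALSE))
  flat <- risk_percentiles(same, 65, bl, lt, co)
  expect_equal(length(unique(flat$risk)), 1L)
  expect_error(risk_percentiles(ctrl[0, ], 65, bl, lt, co), "no profiles")
})
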