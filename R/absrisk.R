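# Absolute risk: baseline-hazard calibration to population incidence, and
# interval/lifetime risk accumulation under competing all-cause mortality.

#' Calibrate the baseline hazard to population incidence
#'
#' The sex-specific baseline incidence `rho_sex(t)` is the population
#' age-specific incidence divided by the average relative risk among
#' controls with no missing covariate data. The mean control RR is a single
#' sex-specific scalar applied at every age, so the calibration identity
#' `mean over controls of rho(t) * RR_i = population rate` holds exactly at
#' every age.
#'
#' @param life_table A [life_table()] (may hold both sexes).
#' @param sex Which sex to calibrate, `"male"` or `"female"`.
#' @param control_profiles Data frame of control risk profiles, all complete
#'   (a missing/unknown level is an error, matching the source protocol).
#' @param coeffs A [coefficient_set()].
#' @return An object of class `baseline_hazard`: per-age baseline incidence
#'   plus calibration metadata (`mean_rr`, `n_controls`).
#' @export
calibrate_baseline <- function(life_table, sex, control_profiles, coeffs) {
  if (!nrow(control_profiles)) {
    stop("calibration requires at least one control profile", call. = FALSE)
  }
  lt <- lt_slice(life_table, sex)
  rr <- relative_risk(control_profiles, coeffs, missing_action = "reject")
  mean_rr <- mean(rr)
  structure(list(sex = sex, age = lt$age, rho = lt$incidence / mean_rr,
                 mean_rr = mean_rr, n_controls = nrow(control_profiles)),
            class = "baseline_hazard")
}

#' @export
print.baseline_hazard <- function(x, ...) {
  cat(sprintf("<baseline_hazard> %s: ages %d-%d, mean control RR %.4f (n = %d)\n",
              x$sex, min(x$age), max(x$age), x$mean_rr, x$n_controls))
  invisible(x)
}

.rho_at <- function(baseline, ages) {
  idx <- match(ages, baseline$age)
  if (anyNA(idx)) {
    stop("age ", ages[which(is.na(idx))[1]],
         " outside the baseline hazard's support (",
         min(baseline$age), "-", max(baseline$age), ")", call. = FALSE)
  }
  baseline$rho[idx]
}

#' Age-specific incidence for a risk profile
#'
#' `rho_sex(t) * RR(X)`: the calibrated baseline hazard at the requested age
#' scaled by the profile's relative risk.
#'
#' @param profile A [risk_profile()] (one row).
#' @param age Integer age(s) within the baseline support.
#' @param baseline A `baseline_hazard` from [calibrate_baseline()].
#' @param coeffs A [coefficient_set()].
#' @return Hazard(s) per person-year.
#' @export
age_specific_incidence <- function(profile, age, baseline, coeffs) {
  rr <- relative_risk(profile, coeffs, missing_action = "reject")
  stopifnot(length(rr) == 1)
  .rho_at(baseline, age) * rr
}

# core accumulation over annual ages [start, end), vectorized over rr.
# Piecewise-constant hazards per year with the exact exponential within-year
# split between disease and competing death:
#   risk = sum_t [h/(h+m)] (1 - exp(-(h+m))) * prod_{u<t} exp(-(h_u+m_u))
.accumulate_risk <- function(rr, ages, rho, mort) {
  tot <- outer(rr, rho) + matrix(mort, length(rr), length(ages), byrow = TRUE)
  h <- outer(rr, rho)
  frac <- ifelse(tot > 0, h / tot, 0)              # limit convention at h+m=0
  yearly <- frac * (1 - exp(-tot))
  surv <- t(apply(exp(-tot), 1, function(v) cumprod(c(1, v[-length(v)]))))
  if (length(ages) == 1) surv <- matrix(1, length(rr), 1)
  rowSums(yearly * surv)
}

#' Absolute risk over an age interval under competing mortality
#'
#' Probability of developing the disease in the half-open interval
#' `[start_age, end_age)`, given alive and disease-free at `start_age`.
#' Hazards are piecewise-constant per year of age: within each year the
#' disease hazard `h(t) = rho(t) RR(X)` competes with the all-cause
#' mortality hazard `m(t)` and takes the exact share `h/(h+m)` of the
#' probability `1 - exp(-(h+m))` of leaving the risk set, discounted by the
#' probability of having survived both hazards through the earlier years.
#'
#' @param profile A one-row [risk_profile()].
#' @param start_age,end_age Integer ages, `start_age < end_age`, both within
#'   the life-table/baseline support (the last year used is `end_age - 1`).
#' @param baseline A `baseline_hazard`.
#' @param life_table The [life_table()] supplying all-cause mortality (the
#'   slice matching the baseline's sex is used).
#' @param coeffs A [coefficient_set()].
#' @return Probability in [0, 1].
#' @export
interval_risk <- function(profile, start_age, end_age, baseline, life_table,
                          coeffs) {
  if (start_age >= end_age) stop("start_age must be < end_age", call. = FALSE)
  ages <- seq.int(start_age, end_age - 1L)
  lt <- lt_slice(life_table, baseline$sex)
  idx <- match(ages, lt$age)
  if (anyNA(idx)) {
    stop("interval [", start_age, ",", end_age, ") extends outside the ",
         "life-table support", call. = FALSE)
  }
  rr <- relative_risk(profile, coeffs, missing_action = "reject")
  .accumulate_risk(rr, ages, .rho_at(baseline, ages), lt$mortality[idx])
}

#' Lifetime absolute risk
#'
#' Interval risk from the current age to a horizon age (default 85), the
#' conventional anchor for "lifetime" risk of this disease.
#'
#' @inheritParams interval_risk
#' @param current_age Integer start age (must be supplied: whether risk
#'   accumulation starts at birth or at cohort entry is an analysis choice).
#' @param horizon_age Horizon, default 85.
#' @return Probability in [0, 1].
#' @export
lifetime_risk <- function(profile, current_age, baseline, life_table, coeffs,
                          horizon_age = 85) {
  if (current_age >= horizon_age) {
    stop("current_age must be < horizon_age", call. = FALSE)
  }
  interval_risk(profile, current_age, horizon_age, baseline, life_table, coeffs)
}

#' Empirical percentile curve of interval risk over a profile population
#'
#' Ranks the supplied profiles by relative risk and returns the empirical
#' quantile function of their `window`-year absolute risk from `start_age`.
#' Because the interval risk is monotone in RR on a shared baseline, the
#' curve is nondecreasing in percentile.
#'
#' @param profiles Data frame of risk profiles (>= 100 rows for a stable
#'   curve; fewer is allowed but noisy).
#' @param start_age Integer age the risk window starts at.
#' @param baseline A `baseline_hazard`.
#' @param life_table A [life_table()].
#' @param coeffs A [coefficient_set()].
#' @param window Width of the risk window in years, default 10.
#' @return Data frame with columns `percentile` (0-100, midpoint convention),
#'   `rr` and `risk`, sorted by percentile.
#' @export
risk_percentiles <- function(profiles, start_age, baseline, life_table,
                             coeffs, window = 10) {
  if (!nrow(profiles)) stop("no profiles supplied", call. = FALSE)
  rr <- relative_risk(profiles, coeffs, missing_action = "reject")
  ages <- seq.int(start_age, start_age + window - 1L)
  lt <- lt_slice(life_table, baseline$sex)
  idx <- match(ages, lt$age)
  if (anyNA(idx)) stop("risk window extends outside the life-table support",
                       call. = FALSE)
  risk <- .accumulate_risk(rr, ages, .rho_at(baseline, ages), lt$mortality[idx])
  ord <- order(rr)
  n <- length(rr)
  data.frame(percentile = 100 * (seq_len(n) - 0.5) / n,
             rr = rr[ord], risk = risk[ord])
}
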