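# Independent oracles and small fixture builders shared across the suite.

# brute-force Mann-Whitney AUC by pair counting (O(mn))
oracle_auc <- function(cases, controls) {
  wins <- 0
  for (x in cases) wins <- wins + sum(x > controls) + 0.5 * sum(x == controls)
  wins / (length(cases) * length(controls))
}

# daily-grid piecewise-constant-hazard accumulation over annual ages
# [start, end): an independent scalar-loop integration of the same
# competing-risk model on a 365-step within-year grid
oracle_interval_risk <- function(rr, ages_idx, rho, mort, steps = 365) {
  dt <- 1 / steps
  surv <- 1
  risk <- 0
  for (i in seq_along(ages_idx)) {
    h <- rho[i] * rr
    tot <- h + mort[i]
    for (k in seq_len(steps)) {
      if (tot > 0) {
        risk <- risk + surv * (h / tot) * (1 - exp(-tot * dt))
        surv <- surv * exp(-tot * dt)
      }
    }
  }
  risk
}

# grid-search maximizer of the winner's-curse conditional likelihood,
# iteratively refined to step size 1e-8
oracle_wc_grid <- function(beta_hat, se, alpha) {
  cval <- qnorm(1 - alpha / 2)
  ll <- function(b) dnorm((beta_hat - b) / se, log = TRUE) -
    log(pnorm(-cval + b / se) + pnorm(-cval - b / se))
  lo <- 0; hi <- beta_hat
  for (pass in 1:6) {
    grid <- seq(lo, hi, length.out = 201)
    best <- grid[which.max(vapply(grid, ll, 0))]
    step <- grid[2] - grid[1]
    lo <- max(0, best - step); hi <- min(beta_hat, best + step)
  }
  best
}

# delete-one-subject jackknife variance of a paired AUC difference
oracle_jackknife_var_diff <- function(ca, ka, cb, kb) {
  m <- length(ca); n <- length(ka)
  d_full <- oracle_auc(ca, ka) - oracle_auc(cb, kb)
  th_case <- vapply(seq_len(m), function(i) {
    oracle_auc(ca[-i], ka) - oracle_auc(cb[-i], kb)
  }, 0)
  th_ctrl <- vapply(seq_len(n), function(j) {
    oracle_auc(ca, ka[-j]) - oracle_auc(cb, kb[-j])
  }, 0)
  (m - 1) / m * sum((th_case - mean(th_case))^2) +
    (n - 1) / n * sum((th_ctrl - mean(th_ctrl))^2)
}

# minimal raw subject rows for io tests
make_raw_subjects <- function(n = 4) {
  data.frame(
    id = sprintf("P%02d", seq_len(n)),
    status = rep(c("case", "control"), length.out = n),
    design = rep(c("cohort", "case_control"), length.out = n),
    study = rep(c("A", "B"), length.out = n),
    sex = rep(c("male", "female"), length.out = n),
    age_cat = rep("61-65", n),
    smoking = rep("never", n),
    diabetes = rep("never", n),
    family_history = rep("no", n),
    heavy_alcohol = rep("no", n),
    bmi_cat = rep("18.5-25", n),
    rs505922_alleles = rep(2, n),
    rs8176746_alleles = rep(0, n),
    snp_1q32 = rep(0, n),
    snp_5p15 = rep(0, n),
    snp_13q22 = rep(0, n),
    ancestry = rep("european", n),
    stringsAsFactors = FALSE
  )
}

# a constant-hazard single-sex life table for closed-form checks
make_flat_life_table <- function(sex = "male", ages = 50:80,
                                 incidence = 1e-4, mortality = 1e-2) {
  life_table(rep(sex, length(ages)), ages,
             rep(incidence, length(ages)), rep(mortality, length(ages)))
}

# an all-zero-truth coefficient set (null disease model)
null_coefficients <- function() {
  coefficient_set(stats::setNames(rep(0, length(rr_terms("all"))),
                                  rr_terms("all")),
                  model = "full", meta = list(source = "null truth"))
}
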