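test_that("ABO diplotypes are forced by the tag-SNP counts", {
  # all six consistent (o, b) combinations, enumerated by phase assignment
  expect_equal(as.character(derive_abo(2, 0)), "OO")
  expect_equal(as.character(derive_abo(1, 1)), "BO")
  expect_equal(as.character(derive_abo(1, 0)), "AO")
  expect_equal(as.character(derive_abo(0, 0)), "AA")
  expect_equal(as.character(derive_abo(0, 1)), "AB")
  expect_equal(as.character(derive_abo(0, 2)), "BB")
  expect_equal(as.character(derive_abo(c(2, 0), c(0, 2))), c("OO", "BB"))
  expect_error(derive_abo(2, 1), "inconsistent")
  expect_error(derive_abo(1, 1.5), "integers")
})

test_that("encoding follows the indicator contract", {
  prof <- risk_profile()  # all-baseline
  m <- encode_rr(prof)
  expect_true(all(m == 0))
  former <- risk_profile(smoking = "former")
  expect_equal(unname(encode_rr(former)[1, c("smoking_former", "smoking_current",
                                             "smoking_missing")]),
               c(1, 0, 0))
  # diabetes slots are selected by the design stratum
  cc <- risk_profile(diabetes = "gt3y", design = "case_control")
  enc <- encode_rr(cc)[1, ]
  expect_equal(unname(enc["diabetes_gt3y_cc"]), 1)
  expect_equal(unname(enc["diabetes_gt3y_cohort"]), 0)
  # SNP slots carry integer counts
  snp <- risk_profile(snp_1q32 = 2, snp_13q22 = 1)
  expect_equal(unname(encode_rr(snp)[1, c("snp_1q32", "snp_5p15", "snp_13q22")]),
               c(2, 0, 1))
  # complete-case rule for genetic terms
  raw <- make_raw_subjects(2)
  raw$snp_1q32[1] <- ""
  subj <- as_subjects(raw)
  expect_error(encode_rr(subj, rr_terms("all")), "complete-case")
  expect_silent(encode_rr(subj, rr_terms("nongenetic")))
})

test_that("single-covariate fit reproduces the closed-form 2x2 log odds ratio", {
  # cases: 30 exposed / 70 unexposed; controls: 10 / 90
  raw <- make_raw_subjects(200)
  raw$status <- rep(c("case", "control"), each = 100)
  raw$design <- "cohort"; raw$study <- "A"; raw$sex <- "male"
  raw$age_cat <- "61-65"
  raw$family_history <- c(rep("yes", 30), rep("no", 70),
                          rep("yes", 10), rep("no", 90))
  fit <- fit_rr_model(as_subjects(raw), model = "nongenetic")
  expect_equal(unname(fit$terms["family_history_yes"]),
               log(30 * 90 / (70 * 10)), tolerance = 1e-8)
  # identically distributed exposure -> zero association
  raw$family_history <- rep(c(rep("yes", 40), rep("no", 60)), 2)
  fit0 <- fit_rr_model(as_subjects(raw), model = "nongenetic")
  expect_lt(abs(fit0$terms["family_history_yes"]), 1e-6)
})

test_that("fit diagnostics catch degenerate designs", {
  raw <- make_raw_subjects(40)
  raw$status <- rep("case", 40)
  expect_error(fit_rr_model(as_subjects(raw)), "at least one case and one control")
  # perfect separation on an indicator
  raw2 <- make_raw_subjects(60)
  raw2$status <- rep(c("case", "control"), each = 30)
  raw2$design <- "cohort"; raw2$study <- "A"; raw2$sex <- "male"
  raw2$age_cat <- "61-65"
  raw2$heavy_alcohol <- c(rep("yes", 30), rep("no", 30))
  expect_error(fit_rr_model(as_subjects(raw2), model = "nongenetic"),
               "separation.*alcohol_yes")
})

test_that("relative risk is exp of the selected terms, reference maps to 1", {
  co <- published_coefficients()
  expect_identical(relative_risk(risk_profile(), co), 1)
  expect_equal(relative_risk(risk_profile(smoking = "current"), co), 2.20)
  expect_equal(relative_risk(risk_profile(smoking = "current",
                                          bmi_cat = "over30"), co),
               2.20 * 1.26)
  expect_equal(relative_risk(risk_profile(snp_1q32 = 2), co), 1.29^2)
  # prediction mode rejects missing levels; indicator mode scores them
  miss <- risk_profile(smoking = "missing")
  expect_error(relative_risk(miss, co), "missing/unknown")
  fitted <- coefficient_set(c(smoking_missing = log(1.5)))
  expect_equal(relative_risk(miss, fitted, missing_action = "indicator"), 1.5)
  # a profile activating a term the set lacks is an error, not silently 0
  expect_error(relative_risk(risk_profile(smoking = "current"), fitted),
               "lacks term")
})

test_that("relative risk is multiplicative across disjoint covariate blocks", {
  co <- published_coefficients()
  set.seed(41)
  for (i in 1:25) {
    smoking <- sample(c("never", "former", "current"), 1)
    bmi <- sample(c("under18.5", "18.5-25", "25-30", "over30"), 1)
    abo <- sample(pc_levels$abo, 1)
    snps <- sample(0:2, 3, replace = TRUE)
    p_both <- risk_profile(smoking = smoking, bmi_cat = bmi, abo = abo,
                           snp_1q32 = snps[1], snp_5p15 = snps[2],
                           snp_13q22 = snps[3])
    p_life <- risk_profile(smoking = smoking, bmi_cat = bmi)
    p_gene <- risk_profile(abo = abo, snp_1q32 = snps[1], snp_5p15 = snps[2],
                           snp_13q22 = snps[3])
    expect_equal(relative_risk(p_both, co),
                 relative_risk(p_life, co) * relative_risk(p_gene, co))
  }
})

test_that("the fitted linear predictor is the encode dot-product (one code path)", {
  cfg <- sim_config(n_cases = 400, n_controls = 400, seed = 5)
  d <- simulate_population(cfg)
  fit <- fit_rr_model(d, "full")
  risk_terms <- intersect(names(fit$terms), rr_terms("all"))
  lp <- drop(encode_rr(d, rr_terms("all"))[, risk_terms] %*% fit$terms[risk_terms])
  nuis <- setdiff(names(fit$terms), c(risk_terms, "(Intercept)"))
  Xn <- pancrisk:::.encode_nuisance(d)
  lp <- lp + fit$terms["(Intercept)"] + drop(Xn[, nuis] %*% fit$terms[nuis])
  y <- as.numeric(d$status == "case")
  dev <- -2 * sum(y * stats::plogis(lp, log.p = TRUE) +
                    (1 - y) * stats::plogis(-lp, log.p = TRUE))
  expect_equal(dev, fit$meta$deviance, tolerance = 1e-8)
})

test_that("fitting recovers simulated truth consistently across replicates", {
  # 24 replicates at a reduced scale; the median recovered log-OR of every
  # estimable term must sit within 3.2 Monte-Carlo SEs of the truth
  # (a simultaneous band across the ~20 jointly tested terms)
  truth <- published_coefficients()
  reps <- 24
  est <- NULL
  for (s in seq_len(reps)) {
    d <- simulate_population(sim_config(1200, 1200, seed = 5000 + s))
    f <- fit_rr_model(d, "full")
    v <- f$terms[intersect(rr_terms("all"), names(f$terms))]
    est <- if (is.null(est)) matrix(v, nrow = 1, dimnames = list(NULL, names(v)))
           else rbind(est, v[colnames(est)])
  }
  for (term in colnames(est)) {
    med <- stats::median(est[, term])
    mc_se <- 1.2533 * stats::sd(est[, term]) / sqrt(reps)
    expect_lt(abs(med - truth$terms[term]), 3.2 * mc_se,
              label = sprintf("median log-OR for %s (%.3f vs truth %.3f)",
                              term, med, truth$terms[term]))
  }
})

test_that("coefficient sets serialize to flat key-value files and back", {
  co <- published_coefficients()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_coefficients(co, path)
  back <- read_coefficients(path)
  expect_equal(back$terms, co$terms)
  expect_equal(back$model, "full")
  expect_error(coefficient_set(c(nonsense_term = 0.1)), "unknown")
})
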