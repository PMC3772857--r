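# Synthetic case-control data with the statistical structure the analysis
# assumes: covariates drawn from the published control-group frequencies,
# genotypes under Hardy-Weinberg, disease status from the logistic
# relative-risk model, design-stratified missing-completely-at-random
# masking, and SEER-like synthetic life tables.

#' Default covariate category frequencies
#'
#' Category probabilities transcribed from the published control-group
#' distribution of the pooled consortium (both design strata pooled, missing
#' rows excluded — missingness is applied separately, see
#' [default_missingness()]).
#'
#' @return Named list of probability vectors, each summing to 1.
#' @export
default_covariate_freqs <- function() {
  list(
    sex = c(male = 1903, female = 1751) / 3654,
    age_cat = stats::setNames(
      c(239, 655, 600, 715, 718, 494, 233) / 3654, pc_levels$age_cat),
    smoking = c(never = 1802, former = 1225, current = 270) / 3297,
    diabetes = c(never = 2661, gt3y = 197) / 2858,
    family_history = c(no = 2197, yes = 86) / 2283,
    heavy_alcohol = c(no = 2412, yes = 218) / 2630,
    bmi_cat = stats::setNames(c(34, 1280, 1289, 554) / 3157,
                              c("under18.5", "18.5-25", "25-30", "over30"))
  )
}

#' Default allele and haplotype frequencies
#'
#' Risk-allele frequencies for the three per-allele SNPs and O/A/B haplotype
#' frequencies for the ABO locus, estimated from the published pooled
#' control-group genotype counts. The haplotype frequencies come from direct
#' allele counting over control diplotypes, which is exact here because the
#' two tag SNPs determine the diplotype without phase ambiguity
#' (O = 4766/7302, A = 1951/7302, B = 585/7302).
#'
#' @return List with `snp` (named risk-allele frequencies) and `haplotype`
#'   (O/A/B frequencies summing to 1).
#' @export
default_allele_freqs <- function() {
  list(
    snp = c(snp_1q32 = 5512 / 7306, snp_5p15 = 3258 / 7308,
            snp_13q22 = 2692 / 7306),
    haplotype = c(O = 4766, A = 1951, B = 585) / 7302
  )
}

#' Default per-covariate missingness rates by design stratum
#'
#' Probability that a covariate is masked to its missing/unknown level,
#' transcribed per covariate and per design stratum from the published
#' control-group "missing/not available" rows.
#'
#' @return Named list of length-2 vectors `c(cohort = , case_control = )`.
#' @export
default_missingness <- function() {
  list(
    smoking        = c(cohort = 22 / 1445,  case_control = 315 / 2209),
    diabetes       = c(cohort = 69 / 1445,  case_control = 727 / 2209),
    family_history = c(cohort = 848 / 1445, case_control = 523 / 2209),
    heavy_alcohol  = c(cohort = 175 / 1445, case_control = 849 / 2209),
    bmi_cat        = c(cohort = 10 / 1445,  case_control = 487 / 2209)
  )
}

.check_probs <- function(p, what) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop("probability vector for ", what, " must be nonnegative and sum to 1",
         call. = FALSE)
  }
}

#' Configure a synthetic case-control simulation
#'
#' @param n_cases,n_controls Positive target sample sizes.
#' @param true_coefficients [coefficient_set()] used as the truth of the
#'   logistic disease model; default [published_coefficients()].
#' @param covariate_freqs See [default_covariate_freqs()].
#' @param allele_freqs See [default_allele_freqs()].
#' @param missingness Per-covariate, per-stratum masking rates; default no
#'   missingness (pass [default_missingness()] to emulate the published
#'   missing-data structure).
#' @param design_mix Proportion of subjects in the prospective cohort
#'   stratum; default the published control split 1445/3654.
#' @param n_studies Number of study labels per design stratum (nuisance
#'   structure), default 4 + 4.
#' @param pool_size Size of the source population the statuses are drawn
#'   in; default `ceiling(2.5 * (n_cases + n_controls))`.
#' @param seed Integer seed; the draw is reproducible given the seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_cases, n_controls,
                       true_coefficients = published_coefficients(),
                       covariate_freqs = default_covariate_freqs(),
                       allele_freqs = default_allele_freqs(),
                       missingness = NULL,
                       design_mix = 1445 / 3654,
                       n_studies = c(cohort = 4, case_control = 4),
                       pool_size = NULL, seed = 1L) {
  stopifnot(n_cases >= 1, n_controls >= 1, design_mix >= 0, design_mix <= 1)
  stopifnot(inherits(true_coefficients, "coefficient_set"))
  for (f in names(covariate_freqs)) .check_probs(covariate_freqs[[f]], f)
  .check_probs(allele_freqs$haplotype, "haplotype")
  if (any(allele_freqs$snp < 0 | allele_freqs$snp > 1)) {
    stop("snp allele frequencies must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(pool_size)) pool_size <- ceiling(2.5 * (n_cases + n_controls))
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 true_coefficients = true_coefficients,
                 covariate_freqs = covariate_freqs,
                 allele_freqs = allele_freqs,
                 missingness = missingness,
                 design_mix = design_mix, n_studies = n_studies,
                 pool_size = as.integer(pool_size), seed = as.integer(seed)),
            class = "sim_config")
}

# intercept such that the expected case fraction in the pool hits `target`,
# found by bisection (monotone in the intercept)
.tune_intercept <- function(lp, target) {
  f <- function(b0) mean(stats::plogis(b0 + lp)) - target
  lo <- -30; hi <- 10
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < 1e-12) break
  }
  (lo + hi) / 2
}

#' Simulate a synthetic case-control population
#'
#' Draws a source population of `pool_size` subjects: covariates
#' independently from `covariate_freqs`, SNP genotypes binomially under
#' Hardy-Weinberg, ABO diplotypes as unordered pairs of O/A/B haplotypes
#' (so tag-SNP counts are consistent by construction), and disease status
#' Bernoulli with `logit = intercept + beta . X` under the true
#' coefficients, the intercept tuned by bisection so the expected case yield
#' exceeds the request. The requested numbers of cases and controls are then
#' sampled without replacement, and missingness is masked in afterwards
#' (status assignment always uses the complete covariates).
#'
#' @param config A [sim_config()].
#' @return A `pancrisk_subjects` data frame with `n_cases + n_controls`
#'   rows; `attr(, "truth")` carries the tuned intercept.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  N <- config$pool_size
  cf <- config$covariate_freqs
  af <- config$allele_freqs
  draw <- function(p) names(p)[sample.int(length(p), N, replace = TRUE, prob = p)]

  design <- ifelse(stats::runif(N) < config$design_mix, "cohort", "case_control")
  study_id <- ifelse(design == "cohort",
                     sprintf("COH%d", sample.int(config$n_studies[["cohort"]], N, TRUE)),
                     sprintf("CC%d", sample.int(config$n_studies[["case_control"]], N, TRUE)))
  hap <- names(af$haplotype)
  h1 <- hap[sample.int(3, N, TRUE, prob = af$haplotype)]
  h2 <- hap[sample.int(3, N, TRUE, prob = af$haplotype)]
  o_cnt <- (h1 == "O") + (h2 == "O")
  b_cnt <- (h1 == "B") + (h2 == "B")

  pool <- data.frame(
    id = sprintf("S%06d", seq_len(N)),
    status = "control", design = design, study = study_id,
    sex = draw(cf$sex), age_cat = draw(cf$age_cat),
    smoking = draw(cf$smoking), diabetes = draw(cf$diabetes),
    family_history = draw(cf$family_history),
    heavy_alcohol = draw(cf$heavy_alcohol), bmi_cat = draw(cf$bmi_cat),
    rs505922_alleles = o_cnt, rs8176746_alleles = b_cnt,
    snp_1q32 = stats::rbinom(N, 2, af$snp[["snp_1q32"]]),
    snp_5p15 = stats::rbinom(N, 2, af$snp[["snp_5p15"]]),
    snp_13q22 = stats::rbinom(N, 2, af$snp[["snp_13q22"]]),
    ancestry = "european",
    stringsAsFactors = FALSE
  )
  pool$abo <- as.character(derive_abo(pool$rs505922_alleles, pool$rs8176746_alleles))

  beta <- config$true_coefficients$terms
  M <- encode_rr(pool, rr_terms("all"))
  b <- beta[colnames(M)]
  b[is.na(b)] <- 0
  lp <- drop(M %*% b)
  target <- min(0.8, 1.25 * config$n_cases / N)
  b0 <- .tune_intercept(lp, target)
  case <- stats::runif(N) < stats::plogis(b0 + lp)
  if (sum(case) < config$n_cases || sum(!case) < config$n_controls) {
    stop(sprintf(
      "simulated pool yielded %d cases and %d controls but %d/%d were requested; increase pool_size",
      sum(case), sum(!case), config$n_cases, config$n_controls), call. = FALSE)
  }
  idx <- c(sample(which(case), config$n_cases),
           sample(which(!case), config$n_controls))
  out <- pool[idx, , drop = FALSE]
  out$status <- rep(c("case", "control"), c(config$n_cases, config$n_controls))

  # diabetes lag for cases with a diabetes history: the analysis dataset is
  # post-exclusion, so lags are >= 3 years (3 + exponential, mean 8)
  lag <- rep(NA_real_, nrow(out))
  has <- out$status == "case" & out$diabetes == "gt3y"
  lag[has] <- 3 + stats::rexp(sum(has), rate = 1 / 5)
  out$diabetes_lag_years <- lag

  if (!is.null(config$missingness)) {
    miss <- config$missingness
    for (f in names(miss)) {
      rate <- miss[[f]]
      p <- ifelse(out$design == "cohort", rate[["cohort"]], rate[["case_control"]])
      hit <- stats::runif(nrow(out)) < p
      out[[f]][hit] <- if (f == "diabetes") "unknown" else "missing"
    }
    # a masked diabetes history cannot carry a lag
    out$diabetes_lag_years[out$diabetes != "gt3y"] <- NA_real_
  }
  rownames(out) <- NULL
  res <- as_subjects(out)
  attr(res, "truth") <- list(intercept = b0, coefficients = config$true_coefficients)
  res
}

#' Simulate a SEER-like life table
#'
#' A synthetic fixture for the per-sex population rate tables the absolute
#' risk pipeline consumes. Disease incidence is Gompertz-like: zero below
#' `onset_age`, then `rate_at_50 * exp(slope * (age - 50))` per 100,000
#' person-years. All-cause mortality is Gompertz,
#' `exp(mort_intercept + mort_slope * age)` per person-year, hence monotone
#' nondecreasing. Defaults are tuned so the male table integrates to a
#' population lifetime (age 85) risk of about 1.5%, the familiar magnitude
#' for this disease, with the female table slightly lower.
#'
#' @param sex `"male"` or `"female"` (switches the defaults).
#' @param ages Integer age support, default 0-89.
#' @param onset_age Age below which incidence is exactly zero, default 30.
#' @param rate_at_50 Incidence per 100,000 person-years at age 50; default
#'   14.5 (male) / 11.3 (female), tuned so the tables integrate to
#'   population lifetime risks near 1.5% / 1.3%.
#' @param slope Log-linear incidence slope per year of age, default 0.068;
#'   0 gives constant incidence above onset.
#' @param mort_intercept,mort_slope Gompertz all-cause mortality parameters;
#'   defaults -9.8 / 0.085 (male) and -10.4 / 0.088 (female).
#' @return A [life_table()] for the requested sex.
#' @export
simulate_life_table <- function(sex = c("male", "female"), ages = 0:89,
                                onset_age = 30,
                                rate_at_50 = NULL, slope = 0.068,
                                mort_intercept = NULL, mort_slope = NULL) {
  sex <- match.arg(sex)
  if (is.null(rate_at_50)) rate_at_50 <- if (sex == "male") 14.5 else 11.3
  if (is.null(mort_intercept)) mort_intercept <- if (sex == "male") -9.8 else -10.4
  if (is.null(mort_slope)) mort_slope <- if (sex == "male") 0.085 else 0.088
  stopifnot(rate_at_50 > 0, onset_age >= min(ages))
  inc <- ifelse(ages < onset_age, 0,
                rate_at_50 / 1e5 * exp(slope * (ages - 50)))
  mort <- exp(mort_intercept + mort_slope * ages)
  if (any(inc >= 1) || any(mort >= 1)) {
    stop("parameters produce a hazard >= 1 per person-year", call. = FALSE)
  }
  life_table(sex = rep(sex, length(ages)), age = ages,
             incidence = inc, mortality = mort)
}
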