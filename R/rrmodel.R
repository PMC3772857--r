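# Relative-risk model: ABO diplotype derivation, covariate encoding with
# missing-indicator and design-stratified diabetes coding, logistic fitting,
# and relative risks against the all-baseline reference profile.

#' Derive the ABO diplotype from the two tag SNPs
#'
#' Haplotypes of rs505922 and rs8176746 are perfectly correlated with the O
#' and B alleles respectively, so the unordered diplotype is determined by
#' the two allele counts: with `o` O-tagging alleles and `b` B-tagging
#' alleles, the number of A haplotypes is `2 - o - b`. A B-tagging allele
#' cannot ride an O haplotype, so `o + b > 2` is inconsistent.
#'
#' @param rs505922_alleles Count (0-2) of the O-tagging allele.
#' @param rs8176746_alleles Count (0-2) of the B-tagging allele.
#' @return Factor with levels `OO, AO, AA, BO, BB, AB`; vectorized.
#' @examples
#' derive_abo(2, 0)  # OO
#' derive_abo(1, 1)  # BO
#' @export
derive_abo <- function(rs505922_alleles, rs8176746_alleles) {
  o <- rs505922_alleles
  b <- rs8176746_alleles
  ok <- function(v) all(!is.na(v) & v %in% 0:2)
  if (!ok(o) || !ok(b)) {
    stop("tag-SNP allele counts must be integers in {0,1,2}", call. = FALSE)
  }
  if (any(o + b > 2)) {
    stop("inconsistent tag-SNP allele counts: rs505922 + rs8176746 counts exceed 2 ",
         "(a B-tagging allele cannot occur on an O haplotype)", call. = FALSE)
  }
  a <- 2L - o - b
  out <- character(length(o))
  out[o == 2] <- "OO"
  out[o == 1 & a == 1] <- "AO"
  out[a == 2] <- "AA"
  out[o == 1 & b == 1] <- "BO"
  out[b == 2] <- "BB"
  out[a == 1 & b == 1] <- "AB"
  factor(out, levels = pc_levels$abo)
}

#' Construct a risk profile
#'
#' A risk profile holds the non-nuisance covariates of a subject; every
#' argument defaults to its reference (baseline) level, so
#' `risk_profile()` is the all-baseline profile with relative risk exactly 1.
#' `design` selects which design stratum's diabetes coefficient applies when
#' `diabetes != "never"`.
#'
#' @param smoking,diabetes,design,family_history,heavy_alcohol,bmi_cat,abo
#'   Categorical levels; see [read_subjects()] for the catalogues.
#' @param snp_1q32,snp_5p15,snp_13q22 Risk-allele counts in 0..2.
#' @return A one-row data frame of class `risk_profile`.
#' @export
risk_profile <- function(smoking = "never", diabetes = "never",
                         design = "cohort", family_history = "no",
                         heavy_alcohol = "no", bmi_cat = "18.5-25",
                         abo = "OO", snp_1q32 = 0, snp_5p15 = 0,
                         snp_13q22 = 0) {
  x <- data.frame(
    smoking = factor(match.arg(smoking, pc_levels$smoking), pc_levels$smoking),
    diabetes = factor(match.arg(diabetes, pc_levels$diabetes), pc_levels$diabetes),
    design = factor(match.arg(design, pc_levels$design), pc_levels$design),
    family_history = factor(match.arg(family_history, pc_levels$family_history),
                            pc_levels$family_history),
    heavy_alcohol = factor(match.arg(heavy_alcohol, pc_levels$heavy_alcohol),
                           pc_levels$heavy_alcohol),
    bmi_cat = factor(match.arg(bmi_cat, pc_levels$bmi_cat), pc_levels$bmi_cat),
    abo = factor(match.arg(abo, pc_levels$abo), pc_levels$abo),
    snp_1q32 = as.integer(snp_1q32), snp_5p15 = as.integer(snp_5p15),
    snp_13q22 = as.integer(snp_13q22)
  )
  stopifnot(all(unlist(x[c("snp_1q32", "snp_5p15", "snp_13q22")]) %in% 0:2))
  class(x) <- c("risk_profile", "data.frame")
  x
}

#' Encode subjects or profiles as model indicator/count columns
#'
#' Produces one column per requested term of [rr_terms()]: indicator columns
#' for categorical levels (missing-indicator coding: `missing`/`unknown` is
#' its own level), design-stratified diabetes indicators, and integer
#' risk-allele counts for the three SNPs. A former smoker gets smoking
#' vector (1,0,0); a never smoker (0,0,0).
#'
#' @param x A `pancrisk_subjects` or `risk_profile` data frame (any data
#'   frame with the covariate columns works).
#' @param terms Which terms to encode, default the full catalogue.
#' @param strict_genetic If `TRUE` (default) and any genetic term is
#'   requested, rows with a missing genotype raise a complete-case error.
#' @return Numeric matrix, `nrow(x)` rows, one column per term.
#' @export
encode_rr <- function(x, terms = rr_terms("all"), strict_genetic = TRUE) {
  terms <- match.arg(terms, rr_terms("all"), several.ok = TRUE)
  n <- nrow(x)
  genetic_wanted <- any(terms %in% rr_terms("genetic"))
  if (genetic_wanted && strict_genetic) {
    bad <- is.na(x$abo) | is.na(x$snp_1q32) | is.na(x$snp_5p15) | is.na(x$snp_13q22)
    if (any(bad)) {
      stop("complete-case rule: ", sum(bad), " record(s) missing a genetic ",
           "marker cannot be encoded for a model with genetic terms",
           call. = FALSE)
    }
  }
  ind <- function(v) as.numeric(!is.na(v) & v)
  col <- list(
    "smoking_former"  = ind(x$smoking == "former"),
    "smoking_current" = ind(x$smoking == "current"),
    "smoking_missing" = ind(x$smoking == "missing"),
    "diabetes_gt3y_cohort"    = ind(x$diabetes == "gt3y" & x$design == "cohort"),
    "diabetes_unknown_cohort" = ind(x$diabetes == "unknown" & x$design == "cohort"),
    "diabetes_gt3y_cc"        = ind(x$diabetes == "gt3y" & x$design == "case_control"),
    "diabetes_unknown_cc"     = ind(x$diabetes == "unknown" & x$design == "case_control"),
    "family_history_yes"     = ind(x$family_history == "yes"),
    "family_history_missing" = ind(x$family_history == "missing"),
    "alcohol_yes"     = ind(x$heavy_alcohol == "yes"),
    "alcohol_missing" = ind(x$heavy_alcohol == "missing"),
    "bmi_under18.5" = ind(x$bmi_cat == "under18.5"),
    "bmi_25-30"     = ind(x$bmi_cat == "25-30"),
    "bmi_over30"    = ind(x$bmi_cat == "over30"),
    "bmi_missing"   = ind(x$bmi_cat == "missing"),
    "abo_AO" = ind(x$abo == "AO"), "abo_AA" = ind(x$abo == "AA"),
    "abo_BO" = ind(x$abo == "BO"), "abo_BB" = ind(x$abo == "BB"),
    "abo_AB" = ind(x$abo == "AB"),
    "snp_1q32"  = as.numeric(x$snp_1q32),
    "snp_5p15"  = as.numeric(x$snp_5p15),
    "snp_13q22" = as.numeric(x$snp_13q22)
  )
  m <- do.call(cbind, col[terms])
  rownames(m) <- NULL
  m
}

# nuisance design matrix: age-category, sex and study indicators
.encode_nuisance <- function(x) {
  has_study <- nlevels(droplevels(factor(x$study))) > 1
  f <- if (has_study) ~ age_cat + sex + study else ~ age_cat + sex
  mm <- stats::model.matrix(f, data = data.frame(
    age_cat = factor(x$age_cat, pc_levels$age_cat),
    sex = factor(x$sex, pc_levels$sex),
    study = droplevels(factor(x$study))
  ))
  mm <- mm[, -1, drop = FALSE]
  colnames(mm) <- sub("^age_cat", "age_", colnames(mm))
  colnames(mm) <- sub("^sex", "sex_", colnames(mm))
  colnames(mm) <- sub("^study", "study_", colnames(mm))
  mm
}

#' Fit the multivariable logistic relative-risk model
#'
#' Maximum-likelihood logistic regression of case-control status on the risk
#' covariates, adjusted for age category, sex and study (nuisance terms).
#' Fitting is by iteratively reweighted least squares (via
#' [stats::glm.fit()]) run to a relative log-likelihood change below 1e-12.
#' When the model includes genetic terms, records missing any genetic marker
#' are excluded (complete-case rule). Unobserved levels (all-zero indicator
#' columns) are dropped from the fit and recorded in `meta$dropped_terms`.
#'
#' @param subjects A `pancrisk_subjects` data frame with at least one case
#'   and one control.
#' @param model `"full"` (default), `"nongenetic"` or `"genetic"`: which risk
#'   terms enter; nuisance adjustment is always included.
#' @return A [coefficient_set()] with the fitted terms (risk + nuisance +
#'   intercept), the observed-information covariance matrix, and fit
#'   metadata (`n_cases`, `n_controls`, `n_genetic_excluded`, `max_score`,
#'   `dropped_terms`).
#' @export
fit_rr_model <- function(subjects, model = c("full", "nongenetic", "genetic")) {
  model <- match.arg(model)
  x <- subjects
  terms <- switch(model, full = rr_terms("all"),
                  nongenetic = rr_terms("nongenetic"),
                  genetic = rr_terms("genetic"))
  n_excluded <- 0L
  if (any(terms %in% rr_terms("genetic"))) {
    keep <- !(is.na(x$abo) | is.na(x$snp_1q32) | is.na(x$snp_5p15) |
                is.na(x$snp_13q22))
    n_excluded <- sum(!keep)
    x <- x[keep, , drop = FALSE]
  }
  y <- as.numeric(x$status == "case")
  if (sum(y) < 1 || sum(1 - y) < 1) {
    stop("fit requires at least one case and one control", call. = FALSE)
  }
  Xr <- encode_rr(x, terms)
  Xn <- .encode_nuisance(x)
  X <- cbind(Xr, Xn)
  # constant columns (unobserved or universal levels) are not estimable
  # alongside the intercept; drop them and record
  constant <- apply(X, 2, function(v) min(v) == max(v))
  dropped <- colnames(X)[constant]
  X <- X[, !constant, drop = FALSE]
  X1 <- cbind("(Intercept)" = 1, X)
  qr_x <- qr(X1)
  if (qr_x$rank < ncol(X1)) {
    dep <- colnames(X1)[qr_x$pivot[(qr_x$rank + 1):ncol(X1)]]
    stop("rank-deficient design: term(s) ", paste(dep, collapse = ", "),
         " are collinear with the rest of the model", call. = FALSE)
  }
  fit <- suppressWarnings(
    stats::glm.fit(X1, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-12, maxit = 200)))
  beta <- fit$coefficients
  big <- abs(beta) > 15 & names(beta) != "(Intercept)"
  if (any(big)) {
    stop("possible complete separation on term(s): ",
         paste(names(beta)[big], collapse = ", "), call. = FALSE)
  }
  if (!fit$converged) {
    stop("logistic fit did not converge after 200 IRLS iterations; ",
         "final deviance ", format(fit$deviance), call. = FALSE)
  }
  mu <- fit$fitted.values
  score <- drop(crossprod(X1, y - mu))
  w <- mu * (1 - mu)
  vcov <- solve(crossprod(X1 * sqrt(w)))
  dimnames(vcov) <- list(names(beta), names(beta))
  coefficient_set(
    beta, vcov = vcov, model = model,
    meta = list(n_cases = sum(y), n_controls = sum(1 - y),
                n_genetic_excluded = n_excluded,
                max_score = max(abs(score)), dropped_terms = dropped,
                deviance = fit$deviance)
  )
}

# is any missing-indicator level active in these profiles?
.has_missing_level <- function(x) {
  (!is.na(x$smoking) & x$smoking == "missing") |
    (!is.na(x$diabetes) & x$diabetes == "unknown") |
    (!is.na(x$family_history) & x$family_history == "missing") |
    (!is.na(x$heavy_alcohol) & x$heavy_alcohol == "missing") |
    (!is.na(x$bmi_cat) & x$bmi_cat == "missing")
}

#' Relative risk of a profile against the all-baseline reference
#'
#' `RR(X) = exp(sum of the non-nuisance log-odds terms selected by the
#' profile)`. Nuisance (age/sex/study) terms never enter: the relative risk
#' is anchored to population incidence via the baseline-hazard calibration,
#' which absorbs age and sex. The reference profile maps to exactly 1.
#'
#' @param profiles A `risk_profile`, or any data frame of profile rows (e.g.
#'   a subject table); vectorized over rows.
#' @param coeffs A [coefficient_set()].
#' @param missing_action `"reject"` (default, prediction mode): profiles
#'   containing a missing/unknown level are an error. `"indicator"`: score
#'   missing levels with their missing-indicator coefficients, as the fit
#'   itself does (internal-validation parity).
#' @return Numeric vector of relative risks, one per row.
#' @export
relative_risk <- function(profiles, coeffs,
                          missing_action = c("reject", "indicator")) {
  missing_action <- match.arg(missing_action)
  stopifnot(inherits(coeffs, "coefficient_set"))
  if (missing_action == "reject") {
    bad <- .has_missing_level(profiles)
    if (any(bad)) {
      stop(sum(bad), " profile(s) contain a missing/unknown covariate level; ",
           "prediction mode requires complete profiles ",
           "(use missing_action = \"indicator\" to score them)", call. = FALSE)
    }
  }
  terms <- switch(coeffs$model, full = rr_terms("all"),
                  nongenetic = rr_terms("nongenetic"),
                  genetic = rr_terms("genetic"), rr_terms("all"))
  M <- encode_rr(profiles, terms)
  active <- colnames(M)[colSums(abs(M)) > 0]
  lacking <- setdiff(active, names(coeffs$terms))
  if (length(lacking)) {
    stop("coefficient set lacks term(s) required by the profiles: ",
         paste(lacking, collapse = ", "), call. = FALSE)
  }
  beta <- coeffs$terms[colnames(M)]
  beta[is.na(beta)] <- 0
  exp(drop(M %*% beta))
}
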