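# Coefficient sets: named log-odds terms for the relative-risk model,
# optional covariance, flat key-value serialization, and the packaged
# published coefficient set.

#' Term catalogue of the relative-risk model
#'
#' Names of the non-nuisance log-odds terms. Reference levels (never smoker,
#' no diabetes, no family history, <=3 drinks/day, BMI 18.5-25, OO genotype,
#' zero risk alleles) carry an implicit coefficient of 0 and never appear.
#' The diabetes effect is stratified by study design (prospective cohort vs
#' retrospective case-control), so it has four terms.
#'
#' @param which `"all"`, `"nongenetic"` or `"genetic"`.
#' @return Character vector of term names.
#' @export
rr_terms <- function(which = c("all", "nongenetic", "genetic")) {
  which <- match.arg(which)
  nongenetic <- c(
    "smoking_former", "smoking_current", "smoking_missing",
    "diabetes_gt3y_cohort", "diabetes_unknown_cohort",
    "diabetes_gt3y_cc", "diabetes_unknown_cc",
    "family_history_yes", "family_history_missing",
    "alcohol_yes", "alcohol_missing",
    "bmi_under18.5", "bmi_25-30", "bmi_over30", "bmi_missing"
  )
  genetic <- c(
    "abo_AO", "abo_AA", "abo_BO", "abo_BB", "abo_AB",
    "snp_1q32", "snp_5p15", "snp_13q22"
  )
  switch(which,
         all = c(nongenetic, genetic),
         nongenetic = nongenetic,
         genetic = genetic)
}

is_nuisance_term <- function(term) {
  grepl("^(age_|sex_|study_)", term) | term == "(Intercept)"
}

#' Construct a coefficient set
#'
#' @param terms Named numeric vector of log-odds values. Non-nuisance names
#'   must come from [rr_terms()]; nuisance terms (prefixes `age_`, `sex_`,
#'   `study_`, plus `(Intercept)`) are carried but never enter relative
#'   risks.
#' @param vcov Optional symmetric positive-semidefinite covariance matrix
#'   with dimnames matching `terms`.
#' @param model Which model the terms describe: `"full"`, `"nongenetic"`,
#'   `"genetic"`.
#' @param meta List of provenance metadata.
#' @return An object of class `coefficient_set`.
#' @export
coefficient_set <- function(terms, vcov = NULL, model = "full", meta = list()) {
  terms <- unlist(terms)
  if (is.null(names(terms)) || any(!nzchar(names(terms)))) {
    stop("coefficient terms must be named", call. = FALSE)
  }
  if (anyNA(terms)) stop("coefficient terms must be finite", call. = FALSE)
  unknown <- setdiff(names(terms), c(rr_terms("all")))
  unknown <- unknown[!is_nuisance_term(unknown)]
  if (length(unknown)) {
    stop("unknown coefficient term(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(vcov)) {
    vcov <- as.matrix(vcov)
    if (!isTRUE(all.equal(vcov, t(vcov), tolerance = 1e-8))) {
      stop("coefficient covariance must be symmetric", call. = FALSE)
    }
    ev <- eigen(vcov, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev), 1)) {
      stop("coefficient covariance must be positive semidefinite", call. = FALSE)
    }
    if (!identical(sort(rownames(vcov)), sort(names(terms)))) {
      stop("covariance dimnames must match term names", call. = FALSE)
    }
  }
  structure(list(terms = terms, vcov = vcov, model = model, meta = meta),
            class = "coefficient_set")
}

#' @export
print.coefficient_set <- function(x, ...) {
  risk <- x$terms[!is_nuisance_term(names(x$terms))]
  cat(sprintf("<coefficient_set> model '%s': %d risk terms, %d nuisance terms%s\n",
              x$model, length(risk), length(x$terms) - length(risk),
              if (is.null(x$vcov)) "" else ", with covariance"))
  if (length(risk)) {
    df <- data.frame(term = names(risk), log_or = unname(risk),
                     or = exp(unname(risk)))
    print(df, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Write a coefficient set to a flat key-value file
#'
#' One `term<TAB>log_odds` pair per line, `#` comment lines allowed.
#' The covariance matrix, if any, is not serialized.
#'
#' @param x A `coefficient_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coefficients <- function(x, path) {
  stopifnot(inherits(x, "coefficient_set"))
  lines <- c(sprintf("# coefficient_set model=%s", x$model),
             sprintf("%s\t%.17g", names(x$terms), unname(x$terms)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a coefficient set from a flat key-value file
#'
#' @param path Path written by [write_coefficients()] (or hand-authored in
#'   the same `term<TAB>value` format).
#' @param model Model label for the returned set.
#' @return A `coefficient_set`.
#' @export
read_coefficients <- function(path, model = "full") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  m <- regmatches(lines, regexec("^# coefficient_set model=(\\S+)", lines))
  lbl <- Filter(length, m)
  if (length(lbl)) model <- lbl[[1]][2]
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2)) {
    stop("coefficient file must have term<TAB>value lines", call. = FALSE)
  }
  terms <- vapply(parts, function(p) as.numeric(p[2]), 0)
  names(terms) <- vapply(parts, `[[`, "", 1)
  coefficient_set(terms, model = model, meta = list(source = path))
}

#' The packaged published coefficient set
#'
#' Log odds ratios of the published final multivariable relative-risk model
#' for pancreatic cancer (pooled cohort and case-control consortium analysis
#' of non-Hispanic whites), shipped with the package together with the
#' published 95% confidence intervals. This set carries no nuisance
#' (age/sex/study) terms, so it supports relative-risk and absolute-risk
#' prediction but not likelihood evaluation.
#'
#' @return A `coefficient_set` whose `meta$or_table` holds the odds ratios
#'   and confidence limits as published.
#' @export
published_coefficients <- function() {
  path <- system.file("extdata", "published_coefficients.tsv",
                      package = "pancrisk", mustWork = TRUE)
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  terms <- log(tab$or)
  names(terms) <- tab$term
  coefficient_set(terms, model = "full",
                  meta = list(source = "published final model", or_table = tab))
}
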