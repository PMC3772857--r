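# Life tables: per-sex age-indexed disease incidence and all-cause mortality
# hazards (per person-year), loaded from SEER-style per-100,000 rate files.

#' Construct a life table
#'
#' @param sex `"male"` or `"female"` per row.
#' @param age Integer attained age per row.
#' @param incidence Disease incidence hazard per person-year.
#' @param mortality All-cause mortality hazard per person-year.
#' @return A data frame of class `life_table`, sorted by sex then age.
#' @export
life_table <- function(sex, age, incidence, mortality) {
  x <- data.frame(sex = factor(sex, levels = pc_levels$sex),
                  age = as.integer(age),
                  incidence = as.numeric(incidence),
                  mortality = as.numeric(mortality))
  x <- x[order(x$sex, x$age), , drop = FALSE]
  rownames(x) <- NULL
  class(x) <- c("life_table", "data.frame")
  validate_life_table(x)
}

#' Validate life-table invariants
#'
#' Per sex: contiguous, strictly increasing one-year ages; hazards in [0, 1).
#'
#' @param x A `life_table`.
#' @return `x`, invisibly usable; errors on the first violation.
#' @export
validate_life_table <- function(x) {
  if (anyNA(x$sex)) stop("life table: sex must be 'male' or 'female'", call. = FALSE)
  for (s in levels(droplevels(x$sex))) {
    a <- x$age[x$sex == s]
    if (anyDuplicated(a)) {
      stop("life table (", s, "): overlapping age bands at age ",
           a[duplicated(a)][1], call. = FALSE)
    }
    if (length(a) > 1 && any(diff(a) != 1L)) {
      stop("life table (", s, "): gap in ages after age ",
           a[which(diff(a) != 1L)[1]], call. = FALSE)
    }
  }
  for (f in c("incidence", "mortality")) {
    v <- x[[f]]
    if (any(is.na(v) | v < 0)) stop("life table: negative or missing ", f, call. = FALSE)
    if (any(v >= 1)) stop("life table: ", f, " hazard >= 1 per person-year", call. = FALSE)
  }
  invisible(x)
}

#' Read a life table from a rates CSV
#'
#' Expects columns `sex`, `incidence_per_100k`, `mortality_per_100k` and
#' either `age` (one-year rows) or `age_start`,`age_end` (inclusive bands,
#' e.g. 5-year SEER bands). Rates per 100,000 person-years are converted to
#' per-person-year hazards; bands are expanded to one row per year under a
#' constant-hazard assumption, so the mean expanded hazard over a band equals
#' the band hazard exactly.
#'
#' @param path Path to the CSV file.
#' @return A `life_table`.
#' @export
read_life_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  need <- c("sex", "incidence_per_100k", "mortality_per_100k")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("life table schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (all(c("age_start", "age_end") %in% names(raw))) {
    lo <- as.integer(raw$age_start); hi <- as.integer(raw$age_end)
    if (any(hi < lo)) stop("life table: age_end < age_start", call. = FALSE)
    reps <- hi - lo + 1L
    idx <- rep(seq_len(nrow(raw)), reps)
    age <- unlist(Map(seq.int, lo, hi), use.names = FALSE)
    raw <- raw[idx, , drop = FALSE]
    raw$age <- age
  } else if (!("age" %in% names(raw))) {
    stop("life table schema error: need 'age' or 'age_start'/'age_end' columns",
         call. = FALSE)
  }
  inc <- as.numeric(raw$incidence_per_100k)
  mort <- as.numeric(raw$mortality_per_100k)
  if (any(is.na(inc) | inc < 0) || any(is.na(mort) | mort < 0)) {
    stop("life table: negative or unparseable rate", call. = FALSE)
  }
  life_table(sex = tolower(trimws(as.character(raw$sex))), age = raw$age,
             incidence = inc / 1e5, mortality = mort / 1e5)
}

# one-sex slice, used by the absolute-risk functions
lt_slice <- function(x, sex) {
  sex <- match.arg(sex, pc_levels$sex)
  out <- x[x$sex == sex, , drop = FALSE]
  if (!nrow(out)) stop("life table has no rows for sex '", sex, "'", call. = FALSE)
  rownames(out) <- NULL
  out
}

#' @export
print.life_table <- function(x, ...) {
  for (s in levels(droplevels(x$sex))) {
    a <- x$age[x$sex == s]
    cat(sprintf("<life_table> %s: ages %d-%d\n", s, min(a), max(a)))
  }
  invisible(x)
}
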