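# Subject-table io: column contract, level catalogues, parsing, exclusions.

# Canonical level spellings. Parsing is case-insensitive for levels,
# exact for header names.
pc_levels <- list(
  status         = c("case", "control"),
  design         = c("cohort", "case_control"),
  sex            = c("male", "female"),
  age_cat        = c("<50", "51-60", "61-65", "66-70", "71-75", "76-80", "81+"),
  smoking        = c("never", "former", "current", "missing"),
  diabetes       = c("never", "gt3y", "unknown"),
  family_history = c("no", "yes", "missing"),
  heavy_alcohol  = c("no", "yes", "missing"),
  bmi_cat        = c("under18.5", "18.5-25", "25-30", "over30", "missing"),
  abo            = c("OO", "AO", "AA", "BO", "BB", "AB")
)

# covariates whose blank cells map to an explicit missing/unknown level
.blank_level <- c(
  smoking = "missing", diabetes = "unknown", family_history = "missing",
  heavy_alcohol = "missing", bmi_cat = "missing"
)

.mandatory_cols <- c(
  "status", "design", "study", "sex", "age_cat", "smoking", "diabetes",
  "family_history", "heavy_alcohol", "bmi_cat"
)

.snp_cols <- c("snp_1q32", "snp_5p15", "snp_13q22")
.tag_cols <- c("rs505922_alleles", "rs8176746_alleles")

.parse_level <- function(x, field, levels, blank_to = NA_character_) {
  x <- trimws(as.character(x))
  out <- levels[match(tolower(x), tolower(levels))]
  blank <- is.na(x) | x == ""
  out[blank] <- blank_to
  bad <- !blank & is.na(out)
  if (any(bad)) {
    stop(sprintf("invalid value '%s' for column '%s' (row %d); expected one of: %s",
                 x[which(bad)[1]], field, which(bad)[1],
                 paste(levels, collapse = ", ")), call. = FALSE)
  }
  factor(out, levels = levels)
}

.parse_allele_count <- function(x, field) {
  x <- trimws(as.character(x))
  blank <- is.na(x) | x == ""
  v <- suppressWarnings(as.numeric(x))
  bad <- !blank & (is.na(v) | v != round(v) | v < 0 | v > 2)
  if (any(bad)) {
    stop(sprintf("invalid allele count '%s' for column '%s' (row %d); must be 0, 1 or 2",
                 x[which(bad)[1]], field, which(bad)[1]), call. = FALSE)
  }
  v[blank] <- NA_real_
  as.integer(v)
}

#' Read a case-control subject table
#'
#' Reads a delimited (comma or tab) text file of one subject per row into a
#' validated `pancrisk_subjects` data frame. Level spellings are matched
#' case-insensitively against the documented catalogues; blank cells in
#' covariates that carry an explicit missing level (`smoking`,
#' `family_history`, `heavy_alcohol`, `bmi_cat`) map to `"missing"`, blank
#' diabetes maps to `"unknown"`, and blank genotype cells map to `NA`.
#'
#' Required columns: `status`, `design`, `study`, `sex`, `age_cat`,
#' `smoking`, `diabetes`, `family_history`, `heavy_alcohol`, `bmi_cat`.
#' Genetic columns are optional: either `abo` directly, or the two ABO tag-SNP
#' allele counts `rs505922_alleles` (O-tagging) and `rs8176746_alleles`
#' (B-tagging) from which the diplotype is derived, plus per-allele risk
#' counts `snp_1q32`, `snp_5p15`, `snp_13q22`. Optional: `id`,
#' `diabetes_lag_years` (cases only), `ancestry`.
#'
#' @param path Path to a delimited text file with a header row.
#' @param sep Field separator; `NULL` (default) auto-detects comma vs tab
#'   from the header line.
#' @return A data frame of class `pancrisk_subjects` with factor-coded
#'   covariates and integer allele counts.
#' @seealso [write_subjects()], [apply_exclusions()], [derive_abo()]
#' @export
read_subjects <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    hdr <- readLines(path, n = 1L)
    sep <- if (grepl("\t", hdr)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           colClasses = "character", check.names = FALSE,
                           na.strings = character(), fileEncoding = "UTF-8")
  as_subjects(raw)
}

#' Coerce a raw data frame to a validated subject table
#'
#' Applies the same column contract and level parsing as [read_subjects()].
#'
#' @param raw A data frame with character (or already-typed) columns.
#' @return A `pancrisk_subjects` data frame.
#' @export
as_subjects <- function(raw) {
  missing_cols <- setdiff(.mandatory_cols, names(raw))
  if (length(missing_cols)) {
    stop("subject table schema error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  n <- nrow(raw)
  out <- data.frame(
    id = if ("id" %in% names(raw)) as.character(raw$id) else sprintf("row%d", seq_len(n)),
    stringsAsFactors = FALSE
  )
  for (f in c("status", "design", "sex", "age_cat")) {
    out[[f]] <- .parse_level(raw[[f]], f, pc_levels[[f]])
    if (anyNA(out[[f]])) {
      stop(sprintf("column '%s' has a blank cell (row %d) but carries no missing level",
                   f, which(is.na(out[[f]]))[1]), call. = FALSE)
    }
  }
  out$study <- factor(trimws(as.character(raw$study)))
  for (f in names(.blank_level)) {
    out[[f]] <- .parse_level(raw[[f]], f, pc_levels[[f]], blank_to = .blank_level[[f]])
  }
  out$diabetes_lag_years <-
    if ("diabetes_lag_years" %in% names(raw)) {
      v <- suppressWarnings(as.numeric(trimws(as.character(raw$diabetes_lag_years))))
      neg <- !is.na(v) & v < 0
      if (any(neg)) stop("diabetes_lag_years must be nonnegative (row ",
                         which(neg)[1], ")", call. = FALSE)
      v
    } else rep(NA_real_, n)
  for (f in .tag_cols) {
    out[[f]] <- if (f %in% names(raw)) .parse_allele_count(raw[[f]], f)
                else rep(NA_integer_, n)
  }
  out$abo <-
    if ("abo" %in% names(raw)) .parse_level(raw$abo, "abo", pc_levels$abo)
    else factor(rep(NA_character_, n), levels = pc_levels$abo)
  # derive the diplotype from tag-SNP counts where it was not supplied
  need <- is.na(out$abo) & !is.na(out$rs505922_alleles) & !is.na(out$rs8176746_alleles)
  if (any(need)) {
    out$abo[need] <- derive_abo(out$rs505922_alleles[need], out$rs8176746_alleles[need])
  }
  for (f in .snp_cols) {
    out[[f]] <- if (f %in% names(raw)) .parse_allele_count(raw[[f]], f)
                else rep(NA_integer_, n)
  }
  out$ancestry <-
    if ("ancestry" %in% names(raw)) {
      a <- trimws(as.character(raw$ancestry))
      a[a == ""] <- NA_character_
      a
    } else rep(NA_character_, n)
  validate_subjects(out)
  class(out) <- c("pancrisk_subjects", "data.frame")
  out
}

#' Validate subject-table invariants
#'
#' Checks the invariants of the subject record: allele counts in 0..2, the
#' ABO diplotype consistent with the tag-SNP counts when both are present,
#' and `diabetes_lag_years` present only for cases with a diabetes history.
#'
#' @param x A subject data frame.
#' @return `x`, invisibly; errors describe the first violation found.
#' @export
validate_subjects <- function(x) {
  both <- !is.na(x$abo) & !is.na(x$rs505922_alleles) & !is.na(x$rs8176746_alleles)
  if (any(both)) {
    expected <- derive_abo(x$rs505922_alleles[both], x$rs8176746_alleles[both])
    bad <- as.character(x$abo[both]) != as.character(expected)
    if (any(bad)) {
      stop("abo diplotype inconsistent with tag-SNP allele counts (id ",
           x$id[both][which(bad)[1]], ")", call. = FALSE)
    }
  }
  lagged <- !is.na(x$diabetes_lag_years)
  bad <- lagged & (x$status != "case" | x$diabetes == "never")
  if (any(bad)) {
    stop("diabetes_lag_years may only be present for cases with a diabetes history (id ",
         x$id[which(bad)[1]], ")", call. = FALSE)
  }
  invisible(x)
}

#' Write a subject table
#'
#' Writes canonical level spellings; `NA` genotype cells are written blank,
#' so a written table reads back to an equal record list.
#'
#' @param x A `pancrisk_subjects` data frame.
#' @param path Output file path.
#' @param sep Field separator, default comma.
#' @return `path`, invisibly.
#' @export
write_subjects <- function(x, path, sep = ",") {
  out <- as.data.frame(x)
  out[] <- lapply(out, as.character)
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Apply the eligibility filters
#'
#' Restricts the analysis dataset the way the source consortium analysis did:
#' subjects reporting non-European ancestry are removed, and cases whose
#' diabetes was diagnosed less than 3 years before the cancer diagnosis are
#' removed (possible reverse causation: early tumour-induced diabetes).
#' Subjects with no recorded ancestry are retained.
#'
#' @param x A `pancrisk_subjects` data frame.
#' @param min_diabetes_lag Minimum years between diabetes and cancer
#'   diagnosis for a case to be kept; default 3.
#' @return A list with elements `kept` (subject table, input order preserved)
#'   and `excluded` (subject table with an extra `reason` column).
#' @export
apply_exclusions <- function(x, min_diabetes_lag = 3) {
  reason <- rep(NA_character_, nrow(x))
  anc <- !is.na(x$ancestry) & tolower(x$ancestry) != "european"
  reason[anc] <- "ancestry"
  recent <- is.na(reason) & x$status == "case" & !is.na(x$diabetes_lag_years) &
    x$diabetes_lag_years < min_diabetes_lag
  reason[recent] <- "recent-onset diabetes"
  kept <- x[is.na(reason), , drop = FALSE]
  excluded <- x[!is.na(reason), , drop = FALSE]
  excluded$reason <- reason[!is.na(reason)]
  class(kept) <- class(x)
  list(kept = kept, excluded = excluded)
}

#' @export
print.pancrisk_subjects <- function(x, ...) {
  cat(sprintf("<pancrisk_subjects> %d subjects (%d cases, %d controls; %d cohort, %d case-control)\n",
              nrow(x), sum(x$status == "case"), sum(x$status == "control"),
              sum(x$design == "cohort"), sum(x$design == "case_control")))
  print(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat("...", nrow(x) - 6, "more rows\n")
  invisible(x)
}
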