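#' Cohort CSV schema
#'
#' Column names of the cohort interchange CSV, one row per individual.  The
#' five clustering variables are age at first visit (years), BMI (kg/m2),
#' HbA1c (mmol/mol, IFCC), C-peptide (nmol/l) and HDL-cholesterol (mmol/l);
#' HbA1c is stored on the IFCC scale only, the NGSP percent scale is a
#' display conversion (see [hba1c_ifcc_to_ngsp()]).
#'
#' @return Character vector of the mandatory column names, in order.
#' @export
cohort_schema <- function() {
  c("subject_id", "cohort_id", "sex", "age_at_diagnosis", "age_at_first_visit",
    "bmi", "hba1c_mmol_mol", "c_peptide_nmol_l", "hdl_mmol_l", "gad_positive",
    "diagnosis_date", "first_visit_date")
}

#' Read a cohort table from CSV
#'
#' Reads one cross-sectional cohort (one row per individual) and validates it
#' against the schema of [cohort_schema()].  Blank numeric cells become `NA`
#' (never zero); a missing mandatory column raises a schema error naming the
#' column; an unparseable date raises a row-level error with the row index.
#'
#' @param path Path to a CSV file with a header row.
#' @param schema Named character vector mapping schema names to file column
#'   names, for files whose headers differ from [cohort_schema()].  Defaults
#'   to the identity mapping.
#' @return A tibble with the columns of [cohort_schema()]: `sex` is
#'   `"male"`/`"female"`, `gad_positive` is logical (may be `NA`), the two
#'   date columns are `Date`.
#' @seealso [write_cohort()], [apply_inclusion_criteria()]
#' @export
read_cohort <- function(path, schema = NULL) {
  if (!file.exists(path)) {
    abort_diabclust(sprintf("cohort file not found: %s", path),
                    "diabclust_io_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!is.null(schema)) {
    hit <- intersect(unname(schema), names(raw))
    names(raw)[match(hit, names(raw))] <- names(schema)[match(hit, unname(schema))]
  }
  assert_cols(raw, cohort_schema(), what = sprintf("cohort file '%s'", path))
  raw <- raw[cohort_schema()]

  num_cols <- c("age_at_diagnosis", CLUSTER_VARS)
  parse_num <- function(x, col) {
    x <- trimws(x)
    x[!nzchar(x) | is.na(x)] <- NA_character_
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad) > 0) {
      abort_diabclust(sprintf("row %d: cannot parse '%s' as number in column %s",
                              bad[1], x[bad[1]], col), "diabclust_parse_error")
    }
    out
  }
  parse_date <- function(x, col) {
    x <- trimws(x)
    x[!nzchar(x) | is.na(x)] <- NA_character_
    out <- as.Date(rep(NA_character_, length(x)))
    ok <- !is.na(x)
    out[ok] <- as.Date(vapply(x[ok], function(v) {
      d <- tryCatch(as.Date(v, format = "%Y-%m-%d"), error = function(e) NA)
      if (is.na(d)) NA_character_ else format(d)
    }, character(1)))
    bad <- which(ok & is.na(out))
    if (length(bad) > 0) {
      abort_diabclust(sprintf("row %d: cannot parse '%s' as ISO date in column %s",
                              bad[1], x[bad[1]], col), "diabclust_parse_error")
    }
    out
  }

  out <- tibble(
    subject_id = raw$subject_id,
    cohort_id = raw$cohort_id,
    sex = tolower(trimws(raw$sex)))
  bad_sex <- which(!out$sex %in% c("male", "female"))
  if (length(bad_sex) > 0) {
    abort_diabclust(sprintf("row %d: sex must be 'male' or 'female', got '%s'",
                            bad_sex[1], raw$sex[bad_sex[1]]), "diabclust_parse_error")
  }
  for (col in num_cols) out[[col]] <- parse_num(raw[[col]], col)
  gp <- toupper(trimws(raw$gad_positive))
  gp[!nzchar(gp) | gp == "NA"] <- NA_character_
  bad_gad <- which(!is.na(gp) & !gp %in% c("TRUE", "FALSE"))
  if (length(bad_gad) > 0) {
    abort_diabclust(sprintf("row %d: gad_positive must be TRUE/FALSE/blank, got '%s'",
                            bad_gad[1], raw$gad_positive[bad_gad[1]]),
                    "diabclust_parse_error")
  }
  out$gad_positive <- gp == "TRUE"
  out$diagnosis_date <- parse_date(raw$diagnosis_date, "diagnosis_date")
  out$first_visit_date <- parse_date(raw$first_visit_date, "first_visit_date")
  out <- out[cohort_schema()]
  validate_cohort(out)
  out
}

#' Validate cohort invariants
#'
#' Checks subject-level invariants: unique `subject_id` within cohort,
#' strictly positive clustering variables where present, and
#' `first_visit_date >= diagnosis_date` where both dates are present.
#'
#' @param cohort A cohort tibble.
#' @return The input, invisibly, if valid; otherwise an error.
#' @export
validate_cohort <- function(cohort) {
  assert_cols(cohort, cohort_schema(), "cohort")
  dup <- cohort |>
    count(.data$cohort_id, .data$subject_id) |>
    filter(n > 1)
  if (nrow(dup) > 0) {
    abort_diabclust(sprintf("duplicated subject_id within cohort: %s",
                            dup$subject_id[1]), "diabclust_invariant_error")
  }
  for (col in CLUSTER_VARS) {
    bad <- which(!is.na(cohort[[col]]) & cohort[[col]] <= 0)
    if (length(bad) > 0) {
      abort_diabclust(sprintf("row %d: %s must be strictly positive, got %g",
                              bad[1], col, cohort[[col]][bad[1]]),
                      "diabclust_invariant_error")
    }
  }
  bad <- which(!is.na(cohort$diagnosis_date) & !is.na(cohort$first_visit_date) &
                 cohort$first_visit_date < cohort$diagnosis_date)
  if (length(bad) > 0) {
    abort_diabclust(sprintf("row %d: first_visit_date precedes diagnosis_date",
                            bad[1]), "diabclust_invariant_error")
  }
  invisible(cohort)
}

#' Write a cohort table to CSV
#'
#' Inverse of [read_cohort()]: `read_cohort(write_cohort(x, f))` is
#' cell-identical to `x` for well-formed input.
#'
#' @param cohort A cohort tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  assert_cols(cohort, cohort_schema(), "cohort")
  readr::write_csv(cohort[cohort_schema()], path, na = "", progress = FALSE)
  invisible(path)
}

#' Convert HbA1c between the IFCC and NGSP scales
#'
#' The master equation relating the two reporting scales of glycated
#' haemoglobin: `NGSP % = 0.09148 * IFCC mmol/mol + 2.152`.  The two
#' functions are mutually inverse to better than 1e-9 before rounding;
#' e.g. 49.7 mmol/mol is 6.7% and 69 mmol/mol is 8.5% (1 d.p.).
#'
#' @param ifcc HbA1c in mmol/mol (IFCC); must be strictly positive.
#' @param ngsp HbA1c in percent (NGSP); must exceed 2.152 (the image of 0).
#' @return The converted value(s).
#' @export
#' @examples
#' hba1c_ifcc_to_ngsp(49.7)  # 6.7 to 1 d.p.
#' hba1c_ngsp_to_ifcc(8.5)
hba1c_ifcc_to_ngsp <- function(ifcc) {
  if (any(!is.finite(ifcc)) || any(ifcc <= 0)) {
    abort_diabclust("IFCC HbA1c must be finite and strictly positive",
                    "diabclust_domain_error")
  }
  0.09148 * ifcc + 2.152
}

#' @rdname hba1c_ifcc_to_ngsp
#' @export
hba1c_ngsp_to_ifcc <- function(ngsp) {
  if (any(!is.finite(ngsp)) || any(ngsp <= 2.152)) {
    abort_diabclust("NGSP HbA1c must be finite and exceed 2.152%",
                    "diabclust_domain_error")
  }
  (ngsp - 2.152) / 0.09148
}

#' Apply the cohort inclusion criteria
#'
#' Retains individuals diagnosed at age 35 or older, with clinical data
#' available within two years of diagnosis, not GAD-positive, and with all
#' five clustering variables present.  Each excluded individual is counted
#' under the *first* failing rule in the fixed order `age`, `window`, `gad`,
#' `completeness`, so the report is deterministic.  Filtering is idempotent.
#'
#' @param cohort A cohort tibble (see [read_cohort()]).
#' @param gad_policy `"exclude_only_positive"` (default) drops only subjects
#'   with a recorded positive GAD antibody test, keeping unmeasured ones;
#'   `"require_negative"` also drops subjects whose GAD status is missing.
#' @param window_days Maximum days between diagnosis and first visit
#'   (default 730, the two-year convention).
#' @return The retained cohort tibble, with an `"inclusion_report"` attribute
#'   (see [inclusion_report()]).
#' @export
#' @examples
#' cohort <- simulate_cross_section(mixture_config(n_subjects = 50), "DCS")$cohort
#' included <- apply_inclusion_criteria(cohort)
#' inclusion_report(included)
apply_inclusion_criteria <- function(cohort,
                                     gad_policy = c("exclude_only_positive",
                                                    "require_negative"),
                                     window_days = DAYS_2_YEARS) {
  gad_policy <- match.arg(gad_policy)
  assert_cols(cohort, cohort_schema(), "cohort")

  fail_age <- is.na(cohort$age_at_diagnosis) | cohort$age_at_diagnosis < 35
  gap_days <- as.numeric(cohort$first_visit_date - cohort$diagnosis_date)
  fail_window <- is.na(gap_days) | gap_days > window_days
  fail_gad <- if (gad_policy == "require_negative") {
    is.na(cohort$gad_positive) | cohort$gad_positive
  } else {
    !is.na(cohort$gad_positive) & cohort$gad_positive
  }
  fail_complete <- !complete.cases(cohort[CLUSTER_VARS])

  rule <- rep(NA_character_, nrow(cohort))
  rule[fail_complete] <- "completeness"
  rule[fail_gad] <- "gad"
  rule[fail_window] <- "window"
  rule[fail_age] <- "age"          # last assignment wins: first in rule order

  retained <- cohort[is.na(rule), , drop = FALSE]
  excl <- table(factor(rule, levels = c("age", "window", "gad", "completeness")))
  report <- structure(
    list(n_input = nrow(cohort), n_retained = nrow(retained),
         n_excluded_by_rule = as.list(setNames(as.integer(excl), names(excl))),
         gad_policy = gad_policy, window_days = window_days),
    class = "inclusion_report")
  attr(retained, "inclusion_report") <- report
  retained
}

#' Retrieve the inclusion report of a filtered cohort
#'
#' @param cohort The tibble returned by [apply_inclusion_criteria()].
#' @return An `inclusion_report` object: input count, retained count, and the
#'   exclusion count per rule (first-failing-rule attribution).
#' @export
inclusion_report <- function(cohort) {
  rep <- attr(cohort, "inclusion_report")
  if (is.null(rep)) {
    abort_diabclust("no inclusion report attached; run apply_inclusion_criteria() first",
                    "diabclust_usage_error")
  }
  rep
}

#' @export
print.inclusion_report <- function(x, ...) {
  cat(sprintf("Inclusion report: %d of %d subjects retained\n",
              x$n_retained, x$n_input))
  for (r in names(x$n_excluded_by_rule)) {
    cat(sprintf("  excluded by %-12s %d\n", paste0(r, ":"),
                x$n_excluded_by_rule[[r]]))
  }
  invisible(x)
}

#' Serialize an inclusion report to JSON
#'
#' @param report An `inclusion_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_inclusion_report <- function(report, path) {
  stopifnot(inherits(report, "inclusion_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
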