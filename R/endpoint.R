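#' Endpoint derivation constants
#'
#' Constants of the composite time-to-insulin-requirement endpoint: a
#' subject reaches the endpoint at the earlier of (a) the start of a
#' sustained insulin episode (duration strictly greater than
#' `sustained_min_days`, default 183 — the six-month convention) or (b) the
#' second of two HbA1c measurements strictly above `threshold` mmol/mol
#' (default 69, i.e. 8.5%) at least `min_separation_days` apart (default 90,
#' three months) while at least `min_oral_classes` distinct non-insulin
#' glucose-lowering drug classes are active at both measurement dates.
#' Prescription intervals whose gaps do not exceed `max_gap_days` are merged
#' into treatment episodes first.
#'
#' @param threshold Glycaemic threshold, mmol/mol (strict `>`).
#' @param min_separation_days Minimum days between the two qualifying
#'   measurements (`>=`).
#' @param min_oral_classes Minimum distinct active non-insulin drug classes.
#' @param sustained_min_days Minimum insulin episode duration in days
#'   (strict `>`).
#' @param max_gap_days Maximum gap bridged when merging prescription
#'   intervals into episodes.
#' @return An `endpoint_config` list.
#' @export
endpoint_config <- function(threshold = 69, min_separation_days = DAYS_3_MONTHS,
                            min_oral_classes = 2,
                            sustained_min_days = DAYS_6_MONTHS,
                            max_gap_days = DAYS_3_MONTHS) {
  stopifnot(threshold > 0, min_separation_days > 0, min_oral_classes >= 1,
            sustained_min_days > 0, max_gap_days >= 0)
  structure(list(threshold = threshold,
                 min_separation_days = min_separation_days,
                 min_oral_classes = min_oral_classes,
                 sustained_min_days = sustained_min_days,
                 max_gap_days = max_gap_days),
            class = "endpoint_config")
}

#' Merge prescription intervals into treatment episodes
#'
#' Per subject and drug class, date-sorted intervals whose gap to the
#' running episode does not exceed `max_gap_days` are merged into one
#' episode.  An interval with a missing `end_date` is open-ended and extends
#' the episode indefinitely.
#'
#' @param prescriptions Tibble `subject_id`, `drug_class`, `is_insulin`,
#'   `start_date`, `end_date` (Date; `end_date` may be `NA` for open
#'   intervals).
#' @param max_gap_days Maximum bridged gap in days (default 90).
#' @return A tibble `subject_id`, `drug_class`, `is_insulin`,
#'   `episode_start`, `episode_end` (`NA` when open), `duration_days`
#'   (`Inf` when open), `n_intervals`.
#' @export
treatment_episodes <- function(prescriptions, max_gap_days = DAYS_3_MONTHS) {
  assert_cols(prescriptions, c("subject_id", "drug_class", "is_insulin",
                               "start_date", "end_date"), "prescriptions")
  if (nrow(prescriptions) == 0) {
    return(tibble(subject_id = character(), drug_class = character(),
                  is_insulin = logical(), episode_start = as.Date(character()),
                  episode_end = as.Date(character()), duration_days = numeric(),
                  n_intervals = integer()))
  }
  bad <- which(!is.na(prescriptions$end_date) &
                 prescriptions$end_date < prescriptions$start_date)
  if (length(bad) > 0) {
    abort_diabclust(sprintf("row %d: end_date precedes start_date", bad[1]),
                    "diabclust_invariant_error")
  }
  origin <- min(prescriptions$start_date)
  eps <- prescriptions |>
    mutate(s = as.numeric(.data$start_date - origin),
           e = ifelse(is.na(.data$end_date), Inf,
                      as.numeric(.data$end_date - origin))) |>
    arrange(.data$subject_id, .data$drug_class, .data$s, .data$e) |>
    group_by(.data$subject_id, .data$drug_class, .data$is_insulin) |>
    mutate(reach = cummax(dplyr::lag(.data$e, default = -Inf)),
           new_episode = .data$s > .data$reach + max_gap_days,
           episode = cumsum(.data$new_episode | dplyr::row_number() == 1)) |>
    group_by(.data$subject_id, .data$drug_class, .data$is_insulin,
             .data$episode) |>
    summarise(s = min(.data$s), e = max(.data$e), n_intervals = dplyr::n(),
              .groups = "drop")
  eps |>
    mutate(episode_start = origin + .data$s,
           episode_end = dplyr::if_else(is.finite(.data$e),
                                        origin + .data$e, as.Date(NA)),
           duration_days = .data$e - .data$s) |>
    select("subject_id", "drug_class", "is_insulin", "episode_start",
           "episode_end", "duration_days", "n_intervals") |>
    arrange(.data$subject_id, .data$drug_class, .data$episode_start)
}

#' Detect sustained insulin treatment
#'
#' The earliest insulin episode longer than `sustained_min_days` (strictly);
#' the event date is the episode start.
#'
#' @param episodes Output of [treatment_episodes()] (or raw prescriptions,
#'   which are merged first with `max_gap_days`).
#' @param config An [endpoint_config()].
#' @return A tibble `subject_id`, `event_date` — one row per subject with a
#'   qualifying episode.
#' @export
detect_sustained_insulin <- function(episodes, config = endpoint_config()) {
  if (!"episode_start" %in% names(episodes)) {
    episodes <- treatment_episodes(episodes, config$max_gap_days)
  }
  episodes |>
    filter(.data$is_insulin, .data$duration_days > config$sustained_min_days) |>
    group_by(.data$subject_id) |>
    dplyr::slice_min(.data$episode_start, n = 1, with_ties = FALSE) |>
    ungroup() |>
    select("subject_id", event_date = "episode_start")
}

#' Detect the glycaemic insulin-requirement pathway
#'
#' Finds, per subject, the earliest pair of HbA1c measurements both strictly
#' above the threshold, at least `min_separation_days` apart, with at least
#' `min_oral_classes` distinct non-insulin drug-class episodes active on
#' both dates; the event date is the second measurement (the date the
#' requirement is established).
#'
#' @param hba1c Tibble `subject_id`, `date`, `value_mmol_mol`.
#' @param episodes Output of [treatment_episodes()] (or raw prescriptions).
#' @param config An [endpoint_config()].
#' @return A tibble `subject_id`, `event_date`.
#' @export
detect_glycaemic_requirement <- function(hba1c, episodes,
                                         config = endpoint_config()) {
  assert_cols(hba1c, c("subject_id", "date", "value_mmol_mol"), "hba1c")
  if (!"episode_start" %in% names(episodes)) {
    episodes <- treatment_episodes(episodes, config$max_gap_days)
  }
  high <- filter(hba1c, .data$value_mmol_mol > config$threshold)
  if (nrow(high) == 0) {
    return(tibble(subject_id = character(), event_date = as.Date(character())))
  }
  oral <- filter(episodes, !.data$is_insulin)
  qualifying <- high |>
    inner_join(oral, by = "subject_id", relationship = "many-to-many") |>
    filter(.data$date >= .data$episode_start,
           is.na(.data$episode_end) | .data$date <= .data$episode_end) |>
    distinct(.data$subject_id, .data$date, .data$drug_class) |>
    count(.data$subject_id, .data$date) |>
    filter(.data$n >= config$min_oral_classes)
  # the earliest admissible second measurement pairs with the earliest
  # qualifying one, so the event date is the first qualifying date at least
  # `min_separation_days` after the first
  qualifying |>
    arrange(.data$subject_id, .data$date) |>
    group_by(.data$subject_id) |>
    mutate(sep_ok = as.numeric(.data$date - .data$date[1]) >=
             config$min_separation_days) |>
    filter(.data$sep_ok) |>
    dplyr::slice_min(.data$date, n = 1, with_ties = FALSE) |>
    ungroup() |>
    select("subject_id", event_date = "date")
}

#' Derive the composite time-to-insulin-requirement endpoint
#'
#' For every subject in `followup`, the endpoint is the earlier of the
#' sustained-insulin event and the glycaemic-requirement event; subjects
#' with neither are censored at their censor date.  Time is counted in days
#' from the subject's time zero.
#'
#' @param followup Tibble `subject_id`, `time_zero`, `censor_date`.
#' @param prescriptions Prescription intervals (see [treatment_episodes()]).
#' @param hba1c HbA1c measurement series.
#' @param config An [endpoint_config()].
#' @return A tibble `subject_id`, `time_days`, `event` (logical), `pathway`
#'   (`"sustained_insulin"`, `"glycaemic_requirement"` or `"censored"`).
#' @export
#' @examples
#' study <- simulate_study(100, "DCS", seed = 2)
#' ep <- time_to_insulin_requirement(study$DCS$followup,
#'                                   study$DCS$prescriptions, study$DCS$hba1c)
#' table(ep$pathway)
time_to_insulin_requirement <- function(followup, prescriptions, hba1c,
                                        config = endpoint_config()) {
  assert_cols(followup, c("subject_id", "time_zero", "censor_date"), "followup")
  episodes <- treatment_episodes(prescriptions, config$max_gap_days)
  ins <- detect_sustained_insulin(episodes, config)
  gly <- detect_glycaemic_requirement(hba1c, episodes, config)
  out <- followup |>
    left_join(rename(ins, insulin_date = "event_date"), by = "subject_id") |>
    left_join(rename(gly, glycaemic_date = "event_date"), by = "subject_id") |>
    mutate(event_date = pmin(.data$insulin_date, .data$glycaemic_date,
                             na.rm = TRUE))
  bad <- which(!is.na(out$event_date) & out$event_date < out$time_zero)
  if (length(bad) > 0) {
    abort_diabclust(sprintf("subject %s: event date %s precedes time zero %s",
                            out$subject_id[bad[1]],
                            format(out$event_date[bad[1]]),
                            format(out$time_zero[bad[1]])),
                    "diabclust_data_error")
  }
  out |>
    mutate(
      event = !is.na(.data$event_date),
      pathway = dplyr::case_when(
        !.data$event ~ "censored",
        !is.na(.data$insulin_date) &
          (is.na(.data$glycaemic_date) |
             .data$insulin_date <= .data$glycaemic_date) ~ "sustained_insulin",
        TRUE ~ "glycaemic_requirement"),
      time_days = as.numeric(dplyr::if_else(.data$event, .data$event_date,
                                            .data$censor_date) -
                               .data$time_zero)) |>
    select("subject_id", "time_days", "event", "pathway")
}

#' Build a follow-up frame from a cohort table
#'
#' Helper for real (non-simulated) data: fixes each subject's time zero to
#' the diagnosis date (default, matching the progression-from-diagnosis
#' framing) or the first visit date, with a common or per-subject censor
#' date.
#'
#' @param cohort A cohort tibble.
#' @param censor_date A single `Date` or a per-subject vector.
#' @param time_zero `"diagnosis_date"` (default) or `"first_visit_date"`.
#' @return A tibble `subject_id`, `time_zero`, `censor_date`.
#' @export
followup_frame <- function(cohort, censor_date,
                           time_zero = c("diagnosis_date", "first_visit_date")) {
  time_zero <- match.arg(time_zero)
  assert_cols(cohort, c("subject_id", time_zero), "cohort")
  tibble(subject_id = cohort$subject_id,
         time_zero = cohort[[time_zero]],
         censor_date = rep(as.Date(censor_date), length.out = nrow(cohort)))
}

#' Read longitudinal CSV files
#'
#' Prescriptions: `subject_id,drug_class,is_insulin,start_date,end_date`
#' (blank `end_date` = open interval).  HbA1c:
#' `subject_id,date,value_mmol_mol` (IFCC scale).
#'
#' @param path CSV path.
#' @return A validated tibble.
#' @export
read_prescriptions <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(), drug_class = readr::col_character(),
    is_insulin = readr::col_logical(), start_date = readr::col_date(),
    end_date = readr::col_date()), progress = FALSE)
  assert_cols(x, c("subject_id", "drug_class", "is_insulin", "start_date",
                   "end_date"), sprintf("prescriptions file '%s'", path))
  x
}

#' @rdname read_prescriptions
#' @export
read_hba1c <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(), date = readr::col_date(),
    value_mmol_mol = readr::col_double()), progress = FALSE)
  assert_cols(x, c("subject_id", "date", "value_mmol_mol"),
              sprintf("hba1c file '%s'", path))
  if (any(!is.na(x$value_mmol_mol) & x$value_mmol_mol <= 0)) {
    abort_diabclust("hba1c values must be strictly positive",
                    "diabclust_invariant_error")
  }
  x
}
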