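# builders for small hand-written fixtures

make_cohort_row <- function(subject_id = "s1", cohort_id = "DCS", sex = "male",
                            age_at_diagnosis = 55, age_at_first_visit = 55.5,
                            bmi = 30, hba1c_mmol_mol = 50,
                            c_peptide_nmol_l = 1.2, hdl_mmol_l = 1.2,
                            gad_positive = FALSE,
                            diagnosis_date = as.Date("2010-01-01"),
                            first_visit_date = as.Date("2010-07-01")) {
  tibble::tibble(subject_id, cohort_id, sex, age_at_diagnosis,
                 age_at_first_visit, bmi, hba1c_mmol_mol, c_peptide_nmol_l,
                 hdl_mmol_l, gad_positive, diagnosis_date, first_visit_date)
}

make_cohort <- function(n = 3, ...) {
  dplyr::bind_rows(lapply(seq_len(n), function(i)
    make_cohort_row(subject_id = sprintf("s%d", i), ...)))
}

rx_row <- function(subject_id, drug_class, is_insulin, start, end,
                   origin = as.Date("2010-01-01")) {
  tibble::tibble(subject_id = subject_id, drug_class = drug_class,
                 is_insulin = is_insulin,
                 start_date = origin + start,
                 end_date = if (is.na(end)) as.Date(NA) else origin + end)
}

hba_row <- function(subject_id, day, value, origin = as.Date("2010-01-01")) {
  tibble::tibble(subject_id = subject_id, date = origin + day,
                 value_mmol_mol = value)
}

fu_row <- function(subject_id, censor = 1460, origin = as.Date("2010-01-01")) {
  tibble::tibble(subject_id = subject_id, time_zero = origin,
                 censor_date = origin + censor)
}

# independent permutation enumeration (test-side oracle, recursion distinct
# from the package's implementation)
oracle_perms <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (p in oracle_perms(k - 1)) {
    for (pos in 0:(k - 1)) {
      out[[length(out) + 1L]] <- append(p, k, after = pos)
    }
  }
  out
}

# best label agreement over all cluster relabelings
best_agreement <- function(truth_idx, est_idx, k) {
  perms <- oracle_perms(k)
  best <- 0
  for (p in perms) {
    best <- max(best, mean(p[est_idx] == truth_idx))
  }
  best
}
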